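#' Read and write volumes as MetaImage (.mha) or NRRD (.nrrd)
#'
#' Minimal single-file readers/writers for the two de-facto research volume
#' formats, sufficient for density grids, dose grids and masks. Data are
#' stored raw (uncompressed), little-endian; doubles for scalar fields and
#' unsigned bytes for masks, so round trips are bit-exact.
#'
#' @param path file path ending in `.mha` or `.nrrd`
#' @param x a [voxel_grid()], a logical mask (with `grid` giving geometry),
#'   or a numeric 3-D array (with `grid`)
#' @param grid geometry carrier when `x` is a bare array/mask
#' @return `write_volume` returns `path` invisibly. `read_volume` returns a
#'   [voxel_grid()] (scalar volumes) or a logical array (8-bit volumes,
#'   attributes `spacing`/`origin` attached).
#' @name volume-io
NULL

volume_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (!ext %in% c("mha", "nrrd")) {
    stop("unsupported volume extension '.", ext, "' (use .mha or .nrrd)")
  }
  ext
}

#' @rdname volume-io
#' @export
write_volume <- function(path, x, grid = NULL) {
  fmt <- volume_format(path)
  if (inherits(x, "voxel_grid")) {
    arr <- x$density; spacing <- x$spacing; origin <- x$origin
  } else {
    if (is.null(grid)) stop("write_volume: `grid` required for a bare array")
    arr <- x; spacing <- grid$spacing; origin <- grid$origin
    if (!identical(dim(arr), grid$dims)) stop("write_volume: dims mismatch with grid")
  }
  is_mask <- is.logical(arr)
  dims <- dim(arr)
  con <- file(path, "wb")
  on.exit(close(con))
  if (fmt == "mha") {
    hdr <- c(
      "ObjectType = Image", "NDims = 3", "BinaryData = True",
      "BinaryDataByteOrderMSB = False", "CompressedData = False",
      "TransformMatrix = 1 0 0 0 1 0 0 0 1",
      paste("Offset =", paste(origin, collapse = " ")),
      paste("ElementSpacing =", paste(spacing, collapse = " ")),
      paste("DimSize =", paste(dims, collapse = " ")),
      paste("ElementType =", if (is_mask) "MET_UCHAR" else "MET_DOUBLE"),
      "ElementDataFile = LOCAL")
    writeLines(hdr, con)
  } else {
    hdr <- c(
      "NRRD0004",
      paste("type:", if (is_mask) "unsigned char" else "double"),
      "dimension: 3",
      paste("sizes:", paste(dims, collapse = " ")),
      paste("spacings:", paste(spacing, collapse = " ")),
      paste("axis mins:", paste(origin, collapse = " ")),
      "encoding: raw", "endian: little", "")
    writeLines(hdr, con)
  }
  if (is_mask) {
    writeBin(as.integer(arr), con, size = 1L)
  } else {
    writeBin(as.numeric(arr), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' @rdname volume-io
#' @param reference_grid optional [voxel_grid()]; when given, the file's
#'   dims must match it (error otherwise).
#' @export
read_volume <- function(path, reference_grid = NULL) {
  fmt <- volume_format(path)
  con <- file(path, "rb")
  on.exit(close(con))
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("read_volume: premature end of header")
    if (fmt == "nrrd" && !nzchar(line)) break
    if (grepl("[:=]", line)) {
      kv <- strsplit(line, "[:=]", fixed = FALSE)[[1]]
      key <- trimws(kv[1])
      fields[[tolower(key)]] <- trimws(paste(kv[-1], collapse = ":"))
    }
    if (fmt == "mha" && grepl("^ElementDataFile", line)) break
  }
  nums <- function(key) as.numeric(strsplit(fields[[key]], "\\s+")[[1]])
  if (fmt == "mha") {
    dims <- as.integer(nums("dimsize"))
    spacing <- nums("elementspacing")
    origin <- nums("offset")
    type <- fields[["elementtype"]]
    is_mask <- identical(type, "MET_UCHAR")
    if (!is_mask && !identical(type, "MET_DOUBLE")) {
      stop("read_volume: unsupported ElementType ", type)
    }
  } else {
    dims <- as.integer(nums("sizes"))
    spacing <- nums("spacings")
    origin <- if (!is.null(fields[["axis mins"]])) nums("axis mins") else c(0, 0, 0)
    type <- fields[["type"]]
    is_mask <- type %in% c("unsigned char", "uchar", "uint8")
    if (!is_mask && !type %in% c("double")) {
      stop("read_volume: unsupported nrrd type ", type)
    }
  }
  n <- prod(dims)
  if (!is.null(reference_grid) && !identical(dims, reference_grid$dims)) {
    stop("read_volume: dims ", paste(dims, collapse = "x"),
         " do not match reference grid ",
         paste(reference_grid$dims, collapse = "x"))
  }
  if (is_mask) {
    vals <- readBin(con, "integer", n = n, size = 1L, signed = FALSE)
    out <- array(vals != 0L, dim = dims)
    attr(out, "spacing") <- spacing
    attr(out, "origin") <- origin
    out
  } else {
    vals <- readBin(con, "numeric", n = n, size = 8L, endian = "little")
    voxel_grid(dims, spacing, origin, array(vals, dim = dims))
  }
}
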