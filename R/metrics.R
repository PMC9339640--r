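#' Round half away from zero
#'
#' Report rounding used in the comparison tables (1.65 -> 1.7, -1.65 ->
#' -1.7), as opposed to R's round-half-even.
#'
#' @param x numeric
#' @param digits decimal places (default 1)
#' @export
round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Per-subject, per-structure dose metrics
#'
#' Builds the rows of a metric table (the unit of cohort aggregation) for
#' one plan's dose distribution.
#'
#' @param dose 3-D dose array (Gy)
#' @param structures a [structure_set()]
#' @param prescription prescription dose, Gy
#' @param subject subject id (e.g. `"m1"`)
#' @param plan plan label (e.g. `"SOC"`, `"3D"`)
#' @param report structure names to report (default: the classic organs at
#'   risk present in the set)
#' @return data frame with columns `subject`, `plan`, `structure`,
#'   `median_pct`, `mean_pct`
#' @export
compute_metric_table <- function(dose, structures, prescription, subject, plan,
                                 report = NULL) {
  if (is.null(report)) {
    report <- intersect(c("lungs", "kidneys", "liver", "heart", "bowel"),
                        names(structures$masks))
  }
  rows <- lapply(report, function(s) {
    m <- get_mask(structures, s)
    data.frame(subject = subject, plan = plan, structure = s,
               median_pct = median_dose_percent(dose, m, prescription),
               mean_pct = mean_dose_percent(dose, m, prescription))
  })
  do.call(rbind, rows)
}

#' Cohort mean and standard deviation per plan and structure
#'
#' @param metrics a metric table (data frame with `subject`, `plan`,
#'   `structure` and the value column)
#' @param value name of the value column (default `median_pct`)
#' @return data frame with `plan`, `structure`, `n`, `mean`, `sd` (sample
#'   SD, n-1 denominator; `NA` when n < 2) and report-rounded `mean_r`,
#'   `sd_r` (one decimal, half away from zero)
#' @export
summarize_cohort <- function(metrics, value = "median_pct") {
  stopifnot(value %in% names(metrics))
  key <- interaction(metrics$plan, metrics$structure, drop = TRUE)
  rows <- lapply(split(metrics, key), function(g) {
    v <- g[[value]]
    data.frame(plan = g$plan[1], structure = g$structure[1], n = length(v),
               mean = mean(v), sd = if (length(v) >= 2) sd(v) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$mean_r <- round_half_up(out$mean, 1)
  out$sd_r <- round_half_up(out$sd, 1)
  out
}

#' Paired comparison of two plans across a cohort
#'
#' Pairs subjects across the two plans structure by structure and reports
#' the mean paired difference (plan A minus plan B), the
#' reduction-versus-prescription `100 - mean(plan B)`, and a two-sided
#' p-value from the configured paired test.
#'
#' @param metrics a metric table covering both plans with the same subjects
#' @param plan_a,plan_b plan labels; the comparison is A - B (typically the
#'   baseline minus the conformal plan)
#' @param value value column (default `median_pct`)
#' @param test `"t"` (paired t-test, default) or `"wilcoxon"` (paired
#'   signed-rank)
#' @return data frame per structure: `n`, `mean_a`, `mean_b`, `mean_diff`,
#'   `sd_diff`, `reduction_vs_prescription`, `p_value`, plus report-rounded
#'   `mean_diff_r` and `reduction_r`
#' @export
compare_plans <- function(metrics, plan_a = "3D", plan_b = "SOC",
                          value = "median_pct", test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  stopifnot(value %in% names(metrics))
  a <- metrics[metrics$plan == plan_a, ]
  b <- metrics[metrics$plan == plan_b, ]
  structures <- unique(metrics$structure)
  rows <- lapply(structures, function(s) {
    as_ <- a[a$structure == s, ]
    bs_ <- b[b$structure == s, ]
    as_ <- as_[order(as_$subject), ]
    bs_ <- bs_[order(bs_$subject), ]
    if (!identical(as_$subject, bs_$subject)) {
      stop("subject mismatch between plans for structure '", s, "'")
    }
    va <- as_[[value]]; vb <- bs_[[value]]
    diffs <- va - vb
    p <- if (length(diffs) >= 2) {
      if (test == "t") stats::t.test(va, vb, paired = TRUE)$p.value
      else stats::wilcox.test(va, vb, paired = TRUE, exact = FALSE)$p.value
    } else NA_real_
    data.frame(structure = s, n = length(diffs),
               mean_a = mean(va), mean_b = mean(vb),
               mean_diff = mean(diffs),
               sd_diff = if (length(diffs) >= 2) sd(diffs) else NA_real_,
               reduction_vs_prescription = 100 - mean(vb),
               p_value = p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$mean_diff_r <- round_half_up(out$mean_diff, 1)
  out$reduction_r <- round_half_up(out$reduction_vs_prescription, 1)
  out
}
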