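# Reproducibility and reliability statistics for repeated component-position
# measurements, plus the CT effective-dose conversion.

#' Round half away from zero
#'
#' Reporting precision for reproducibility tables: 0.25 -> 0.3,
#' -0.25 -> -0.3 (base R `round()` rounds half to even).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Maximum absolute deviation from the mean
#'
#' The reproducibility spread statistic: `max |v - mean(v)|`, in the same
#' units as the input.
#'
#' @param values numeric vector, n >= 2, finite.
#' @return maximum absolute deviation from the mean.
#' @export
max_abs_dev <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L || !all(is.finite(values)))
    stop("max_abs_dev needs at least 2 finite values")
  max(abs(values - mean(values)))
}

#' 95% confidence interval half-width of the mean
#'
#' z-based: `1.96 * sd(values) / sqrt(n)` (sample SD). Same units as the
#' input.
#'
#' @param values numeric vector, n >= 2, finite.
#' @return the CI half-width.
#' @export
ci95 <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L || !all(is.finite(values)))
    stop("ci95 needs at least 2 finite values")
  1.96 * stats::sd(values) / sqrt(length(values))
}

#' Intra-class correlation coefficient
#'
#' Computed from the two-way ANOVA decomposition of a complete
#' subjects-by-raters matrix. The default, ICC(2,1) (two-way random
#' effects, absolute agreement, single measurement), treats raters as a
#' random sample of interchangeable observers:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#' ICC(3,1) (two-way mixed, consistency) is available via `model`.
#'
#' @param ratings n subjects x k raters numeric matrix, complete.
#' @param model `"ICC2"` (absolute agreement, default) or `"ICC3"`
#'   (consistency).
#' @return the ICC, in `[-1, 1]`.
#' @export
icc <- function(ratings, model = c("ICC2", "ICC3")) {
  model <- match.arg(model)
  x <- as.matrix(ratings)
  if (!all(is.finite(x))) stop("ratings matrix must be complete and finite")
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stop("icc needs at least 2 subjects and 2 raters")
  gm <- mean(x)
  rm_ <- rowMeans(x); cm <- colMeans(x)
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sst <- sum((x - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- switch(model,
                  ICC2 = msr + (k - 1) * mse + k * (msc - mse) / n,
                  ICC3 = msr + (k - 1) * mse)
  if (abs(denom) < 1e-30) stop("ICC undefined: zero total variance")
  (msr - mse) / denom
}

#' Clinical interpretation band for an ICC value
#'
#' `> 0.9` excellent; `(0.80, 0.9]` very good; `(0.75, 0.80]` good;
#' `[0.5, 0.75]` moderate; `< 0.5` poor.
#'
#' @param value ICC in `[-1, 1]`.
#' @return one of `"excellent"`, `"very good"`, `"good"`, `"moderate"`,
#'   `"poor"`.
#' @export
icc_band <- function(value) {
  if (!is.finite(value) || value < -1 || value > 1)
    stop("ICC value must lie in [-1, 1]")
  if (value > 0.9) "excellent"
  else if (value > 0.80) "very good"
  else if (value > 0.75) "good"
  else if (value >= 0.5) "moderate"
  else "poor"
}

#' Effective dose from dose-length product
#'
#' @param dlp_mGy_cm dose-length product, mGy cm.
#' @param coefficient_mSv_per_mGy_cm anatomic conversion coefficient,
#'   mSv / (mGy cm).
#' @return effective dose, mSv.
#' @export
effective_dose <- function(dlp_mGy_cm, coefficient_mSv_per_mGy_cm) {
  if (any(dlp_mGy_cm < 0) || any(coefficient_mSv_per_mGy_cm < 0))
    stop("dose inputs must be non-negative")
  dlp_mGy_cm * coefficient_mSv_per_mGy_cm
}

#' Per-case reproducibility summary
#'
#' For a long-format measurement table (columns `case`, `operator`, `run`,
#' `variable`, `value`), computes per case and variable the maximum absolute
#' deviation from the case mean and the 95% CI half-width, both raw and
#' rounded (half away from zero) to reporting precision.
#'
#' @param table data.frame with columns `case`, `operator`, `run`,
#'   `variable`, `value`.
#' @param digits reporting precision (decimal places).
#' @return data.frame with columns `case`, `variable`, `n`, `max_abs_dev`,
#'   `ci95`, `max_abs_dev_rounded`, `ci95_rounded`.
#' @export
repro_summary <- function(table, digits = 1) {
  required <- c("case", "operator", "run", "variable", "value")
  missing <- setdiff(required, names(table))
  if (length(missing) > 0L)
    stop(sprintf("measurement table is missing column(s): %s",
                 paste(missing, collapse = ", ")))
  if (any(!is.finite(table$value)))
    stop(sprintf("non-finite value in measurement table row %s",
                 paste(which(!is.finite(table$value)), collapse = ", ")))
  groups <- split(table, list(table$case, table$variable), drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    data.frame(case = g$case[1L], variable = g$variable[1L], n = nrow(g),
               max_abs_dev = max_abs_dev(g$value), ci95 = ci95(g$value))
  }))
  out <- out[order(out$case, out$variable), , drop = FALSE]
  out$max_abs_dev_rounded <- round_half_away(out$max_abs_dev, digits)
  out$ci95_rounded <- round_half_away(out$ci95, digits)
  rownames(out) <- NULL
  out
}

#' Per-variable inter-rater ICC from a long measurement table
#'
#' Aggregates replicate runs to one value per case and operator, reshapes to
#' a subjects-by-raters matrix, and reports the ICC and its interpretation
#' band per variable.
#'
#' @param table data.frame as in [repro_summary()].
#' @param model passed to [icc()].
#' @return data.frame with columns `variable`, `n_subjects`, `n_raters`,
#'   `icc`, `band`.
#' @export
icc_by_variable <- function(table, model = "ICC2") {
  groups <- split(table, table$variable)
  out <- do.call(rbind, lapply(groups, function(g) {
    agg <- stats::aggregate(value ~ case + operator, data = g, FUN = mean)
    m <- stats::reshape(agg, idvar = "case", timevar = "operator",
                        direction = "wide")
    mat <- as.matrix(m[, -1L, drop = FALSE])
    val <- icc(mat, model = model)
    data.frame(variable = g$variable[1L], n_subjects = nrow(mat),
               n_raters = ncol(mat), icc = val, band = icc_band(val))
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a two-way reliability study
#'
#' Draws `n_subjects x n_raters` measurements for each of `n_variables`
#' variables from the additive model `value = subject effect + rater noise`,
#' with subject effects `N(0, subject_sd^2)` and independent noise
#' `N(0, noise_sd^2)`. The closed-form population ICC is
#' `subject_sd^2 / (subject_sd^2 + noise_sd^2)`.
#'
#' @param n_subjects,n_raters study dimensions.
#' @param subject_sd between-subject SD (measurement units).
#' @param noise_sd within-subject (rater) noise SD.
#' @param n_variables number of independent variables to simulate.
#' @param seed integer seed.
#' @return list with `tables` (list of subjects x raters matrices) and
#'   `expected_icc` (the closed form).
#' @export
simulate_reliability_study <- function(n_subjects = 11, n_raters = 2,
                                       subject_sd = 2.5, noise_sd = 0.3,
                                       n_variables = 6, seed = 42) {
  with_seed(seed, {
    tables <- lapply(seq_len(n_variables), function(v) {
      subj <- rnorm(n_subjects, 0, subject_sd)
      matrix(subj, n_subjects, n_raters) +
        matrix(rnorm(n_subjects * n_raters, 0, noise_sd), n_subjects, n_raters)
    })
    list(tables = tables,
         expected_icc = subject_sd^2 / (subject_sd^2 + noise_sd^2))
  })
}
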