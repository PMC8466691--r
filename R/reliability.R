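# Inter-rater / inter-method reliability battery: CV, paired t, Pearson,
# ICC (two-way, single measures), Cronbach's alpha, Bland-Altman limits
# of agreement.

#' Coefficient of variation
#'
#' Sample standard deviation (n-1 denominator) divided by the mean.
#' Either pass a vector of values, or pass summary statistics directly
#' via `mean` and `sd` (the entry point used with published group tables).
#'
#' @param x numeric vector (n >= 2) with non-zero mean.
#' @param mean,sd alternative summary-statistic entry point; used when `x`
#'   is missing.
#' @return Unitless ratio.
#' @examples
#' cv(c(1, 2, 3))            # 0.5
#' cv(mean = 60.27, sd = 26.66)
#' @export
cv <- function(x, mean = NULL, sd = NULL) {
  if (missing(x)) {
    if (is.null(mean) || is.null(sd)) stop("need either 'x' or 'mean' and 'sd'")
    if (mean == 0) stop("coefficient of variation undefined for zero mean")
    return(sd / mean)
  }
  if (length(x) < 2L) stop("need at least two values")
  m <- base::mean(x)
  if (m == 0) stop("coefficient of variation undefined for zero mean")
  stats::sd(x) / m
}

check_pairs <- function(a, b, n_min = 3L) {
  if (length(a) != length(b)) stop("paired vectors differ in length")
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < length(a))
    warning(sprintf("%d incomplete pair(s) dropped", sum(!ok)))
  if (sum(ok) < n_min)
    stop(sprintf("need at least %d complete pairs; have %d", n_min, sum(ok)))
  list(a = a[ok], b = b[ok], n = sum(ok))
}

#' Paired t-test on rating differences
#'
#' Classical paired t on `a - b`; two-sided p from the Student t
#' distribution with n-1 degrees of freedom. Degenerate cases: all-zero
#' differences give t = 0, p = 1; a constant non-zero difference is the
#' p -> 0 limit and is flagged with a warning.
#'
#' @param a,b paired numeric vectors (n >= 3).
#' @return List with `t`, `p`, `df`, `mean_diff`.
#' @export
paired_t <- function(a, b) {
  p <- check_pairs(a, b)
  d <- p$a - p$b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, p = 1, df = p$n - 1L, mean_diff = 0))
    warning("zero variance of differences with non-zero mean: p = 0 limit")
    return(list(t = sign(mean(d)) * Inf, p = 0, df = p$n - 1L,
                mean_diff = mean(d)))
  }
  tt <- stats::t.test(p$a, p$b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = unname(tt$estimate))
}

# Two-way mean squares for n subjects x 2 raters (single observation/cell)
two_way_ms <- function(a, b) {
  n <- length(a)
  k <- 2L
  x <- cbind(a, b)
  grand <- mean(x)
  rm <- rowMeans(x)
  cm <- colMeans(x)
  msr <- k * sum((rm - grand)^2) / (n - 1)
  msc <- n * sum((cm - grand)^2) / (k - 1)
  resid <- x - outer(rm, rep(1, k)) - outer(rep(1, n), cm) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  list(msr = msr, msc = msc, mse = mse, n = n, k = k)
}

#' Intraclass correlation coefficient for two raters
#'
#' Two-way model, single measures, computed from the ANOVA mean squares.
#' The default is absolute agreement (ICC(A,1) in McGraw-Wong terms),
#' appropriate when the question is whether two raters produce the *same*
#' value; `type = "consistency"` (ICC(C,1)) ignores a constant rater
#' offset and is always >= the agreement form.
#'
#' @param a,b paired numeric vectors (n >= 3), one value per subject and
#'   rater.
#' @param type `"agreement"` (default) or `"consistency"`.
#' @return ICC estimate (<= 1).
#' @export
icc <- function(a, b, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  p <- check_pairs(a, b)
  ms <- two_way_ms(p$a, p$b)
  if (ms$msr == 0)
    stop("zero between-subject variance: ICC decomposition is degenerate")
  if (type == "consistency")
    (ms$msr - ms$mse) / (ms$msr + (ms$k - 1) * ms$mse)
  else
    (ms$msr - ms$mse) /
      (ms$msr + (ms$k - 1) * ms$mse + ms$k * (ms$msc - ms$mse) / ms$n)
}

#' Cronbach's alpha for two raters
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance of sums)` with
#' k = 2 raters treated as items.
#'
#' @param a,b paired numeric vectors (n >= 3).
#' @return Alpha estimate (<= 1).
#' @export
cronbach_alpha <- function(a, b) {
  p <- check_pairs(a, b)
  vtot <- stats::var(p$a + p$b)
  if (vtot == 0) stop("zero total variance: alpha undefined")
  2 * (1 - (stats::var(p$a) + stats::var(p$b)) / vtot)
}

#' Bland-Altman agreement analysis
#'
#' Differences `a - b`: mean, sample SD and limits of agreement
#' `mean +/- 1.96 * SD`, plus the per-pair (mean, difference) coordinates
#' used for plotting.
#'
#' @param a,b paired numeric vectors (n >= 2).
#' @return Object of class `bland_altman`: `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n`, and data frame `points` with `mean` and
#'   `diff` columns.
#' @export
bland_altman <- function(a, b) {
  p <- check_pairs(a, b, n_min = 2L)
  d <- p$a - p$b
  md <- mean(d)
  sd_d <- stats::sd(d)
  structure(list(mean_diff = md, sd_diff = sd_d,
                 loa_low = md - 1.96 * sd_d, loa_high = md + 1.96 * sd_d,
                 n = p$n,
                 points = data.frame(mean = (p$a + p$b) / 2, diff = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): mean diff %.4g, SD %.4g, LoA [%.4g, %.4g]\n",
              x$n, x$mean_diff, x$sd_diff, x$loa_low, x$loa_high))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, main = "Bland-Altman", xlab = "Mean of pair",
                              ylab = "Difference", ...) {
  graphics::plot(x$points$mean, x$points$diff, pch = 19, main = main,
                 xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = x$mean_diff, col = "red3", lwd = 2)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 2)
  invisible(x)
}

#' Full reliability report for one metric and two raters or methods
#'
#' Aligns two per-muscle metric tables (from [extract_msb()] or
#' [vbt_report()], optionally stacked over subjects) on their shared key
#' columns, then computes the complete battery: per-rater CV, ICC
#' (agreement and consistency), Cronbach's alpha, Pearson r, paired t and
#' Bland-Altman limits of agreement. An optional fat-fraction stratum
#' restricts the pairs to fatty-infiltrated muscles (`ff > ff_threshold`),
#' using the pairwise mean of the tables' `ff` columns.
#'
#' @param table_a,table_b data frames with the metric column plus key
#'   columns (any of `subject`, `muscle`, `label`).
#' @param metric metric column name, e.g. `"md"`.
#' @param ff_threshold optional fat-fraction cut; requires `ff` columns.
#' @return Object of class `reliability_report`.
#' @export
reliability_report <- function(table_a, table_b, metric,
                               ff_threshold = NULL) {
  keys <- intersect(c("subject", "muscle", "label"),
                    intersect(names(table_a), names(table_b)))
  if (!length(keys)) stop("tables share no key column (subject/muscle/label)")
  if (!metric %in% names(table_a) || !metric %in% names(table_b))
    stop("metric column '", metric, "' missing from a table")
  keep <- unique(c(keys, metric, if ("ff" %in% names(table_a) &&
                                     "ff" %in% names(table_b)) "ff"))
  m <- merge(table_a[intersect(keep, names(table_a))],
             table_b[intersect(keep, names(table_b))],
             by = keys, suffixes = c("_a", "_b"))
  n_dropped <- (nrow(table_a) + nrow(table_b)) / 2 - nrow(m)
  a <- m[[paste0(metric, "_a")]]
  b <- m[[paste0(metric, "_b")]]
  if (!is.null(ff_threshold)) {
    if (!all(c("ff_a", "ff_b") %in% names(m)))
      stop("fat-fraction stratification requires 'ff' columns in both tables")
    sel <- (m$ff_a + m$ff_b) / 2 > ff_threshold
    a <- a[sel]; b <- b[sel]; m <- m[sel, , drop = FALSE]
  }
  p <- check_pairs(a, b)
  ba <- bland_altman(p$a, p$b)
  out <- list(metric = metric, n = p$n, n_dropped = n_dropped,
              cv_a = cv(p$a), cv_b = cv(p$b),
              icc = icc(p$a, p$b, "agreement"),
              icc_consistency = icc(p$a, p$b, "consistency"),
              icc_model = "two-way, single measures; agreement = ICC(A,1), consistency = ICC(C,1)",
              cronbach_alpha = cronbach_alpha(p$a, p$b),
              pearson_r = stats::cor(p$a, p$b),
              paired_t = paired_t(p$a, p$b),
              bland_altman = ba,
              ff_threshold = ff_threshold,
              pairs = data.frame(m[seq_along(p$a), keys, drop = FALSE],
                                 a = p$a, b = p$b))
  class(out) <- "reliability_report"
  out
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("Reliability report for '%s' (n = %d pairs%s)\n", x$metric, x$n,
              if (!is.null(x$ff_threshold))
                sprintf(", FF > %g stratum", x$ff_threshold) else ""))
  cat(sprintf("  CV: %.3f / %.3f   ICC(A,1): %.3f   ICC(C,1): %.3f   alpha: %.3f\n",
              x$cv_a, x$cv_b, x$icc, x$icc_consistency, x$cronbach_alpha))
  cat(sprintf("  Pearson r: %.3f   paired t: %.3f (p = %.3g)\n",
              x$pearson_r, x$paired_t$t, x$paired_t$p))
  print(x$bland_altman)
  invisible(x)
}

#' @export
plot.reliability_report <- function(x, which = c("bland_altman", "scatter"),
                                    ...) {
  which <- match.arg(which)
  if (which == "bland_altman") {
    plot(x$bland_altman,
         main = sprintf("Bland-Altman: %s", x$metric), ...)
  } else {
    graphics::plot(x$pairs$a, x$pairs$b, pch = 19,
                   xlab = "Rater/method A", ylab = "Rater/method B",
                   main = sprintf("%s  (ICC = %.3f, r = %.3f)", x$metric,
                                  x$icc, x$pearson_r), ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}

#' Serialise a reliability report to JSON
#'
#' @param x a [reliability_report()].
#' @param path output path; the JSON embeds all statistics and settings.
#' @export
write_reliability_json <- function(x, path) {
  stopifnot(inherits(x, "reliability_report"))
  obj <- list(metric = x$metric, n = x$n, cv_a = x$cv_a, cv_b = x$cv_b,
              icc = x$icc, icc_consistency = x$icc_consistency,
              icc_model = x$icc_model, cronbach_alpha = x$cronbach_alpha,
              pearson_r = x$pearson_r,
              paired_t = x$paired_t,
              bland_altman = x$bland_altman[c("mean_diff", "sd_diff",
                                              "loa_low", "loa_high")],
              ff_threshold = x$ff_threshold,
              package_version = as.character(utils::packageVersion("muscledti")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
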