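# Test-retest reliability battery: coefficient of variation, Bland-Altman
# bias and limits of agreement, and the two-way random-effects single-measure
# absolute-agreement intraclass correlation ICC(2,1).

#' Acceptability threshold for the coefficient of variation (percent)
#'
#' Intra-subject CVs at or below this value are conventionally read as low
#' relative variability.
#' @export
CV_THRESHOLD_PERCENT <- 5

#' Coefficient of variation (percent)
#'
#' `100 * sd / mean`, with the population standard deviation (divisor n):
#' for the two-value site pairs this equals `100 * |x1 - x2| / (x1 + x2)`.
#' Undefined for fewer than two values or zero mean.
#'
#' @param values numeric vector, length >= 2.
#' @return CV in percent.
#' @examples
#' cv_percent(c(0.748, 0.784))  # ~2.35
#' @export
cv_percent <- function(values) {
  if (length(values) < 2) stopf("CV needs at least two values")
  m <- mean(values)
  if (m == 0) stopf("CV is undefined for zero mean")
  100 * sqrt(mean((values - m)^2)) / m
}

#' Bland-Altman agreement analysis
#'
#' Bias is the mean of the paired differences `x1 - x2`; the 95% limits of
#' agreement are `bias +/- 1.96 * sd` with the sample standard deviation
#' (divisor n - 1) of the differences. A bias near zero with narrow limits
#' indicates no systematic difference between the two measurements.
#'
#' @param x1,x2 paired measurements, equal length n >= 2.
#' @return object of class `bland_altman`: list with `bias`, `loa_low`,
#'   `loa_high`, `sd_diff`, `n`.
#' @export
bland_altman <- function(x1, x2) {
  if (length(x1) != length(x2))
    stopf("paired measurements differ in length (%d vs %d)",
          length(x1), length(x2))
  if (length(x1) < 2) stopf("Bland-Altman needs at least two pairs")
  d <- x1 - x2
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, sd_diff = s, n = length(d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.4g, 95%% LoA (%.4g, %.4g)\n",
              x$n, x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

icc_bands <- function(icc) {
  if (is.na(icc)) "undefined"
  else if (icc < 0.5) "poor" else if (icc < 0.75) "moderate"
  else if (icc <= 0.9) "good" else "excellent"
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, single-measure, absolute-agreement intraclass
#' correlation, computed directly from the two-way ANOVA mean squares:
#' `ICC = (MS_S - MS_E) / (MS_S + (k - 1) MS_E + (k / n) (MS_R - MS_E))`,
#' where MS_S is the between-subject, MS_R the between-rater and MS_E the
#' error mean square, n the number of subjects and k the number of raters
#' (here, acquisition sites). Interpretation bands: < 0.5 poor, 0.5-0.75
#' moderate, 0.75-0.9 good, > 0.9 excellent.
#'
#' @param data n x k numeric matrix (subjects x raters), no missing cells.
#' @return object of class `icc`: list with `icc`, `interpretation`, the
#'   three mean squares, `n` and `k`.
#' @export
icc_2_1 <- function(data) {
  X <- as.matrix(data)
  if (anyNA(X)) stopf("ICC(2,1) requires complete data (no missing cells)")
  n <- nrow(X); k <- ncol(X)
  if (n < 2 || k < 2) stopf("ICC(2,1) needs n >= 2 subjects and k >= 2 raters")
  gm <- mean(X)
  ms_s <- k * sum((rowMeans(X) - gm)^2) / (n - 1)
  ms_r <- n * sum((colMeans(X) - gm)^2) / (k - 1)
  ss_e <- sum((X - outer(rowMeans(X), colMeans(X), "+") + gm)^2)
  ms_e <- ss_e / ((n - 1) * (k - 1))
  icc <- (ms_s - ms_e) / (ms_s + (k - 1) * ms_e + (k / n) * (ms_r - ms_e))
  structure(list(icc = icc, interpretation = icc_bands(icc),
                 ms_subjects = ms_s, ms_raters = ms_r, ms_error = ms_e,
                 n = n, k = k),
            class = "icc")
}

#' @export
print.icc <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.3f (%s reliability; n = %d subjects, k = %d raters)\n",
              x$icc, x$interpretation, x$n, x$k))
  invisible(x)
}

#' Reliability table across weightings and metrics
#'
#' Reproduces the statistical block of a two-site network-metric table: for
#' every (weighting, metric) pair it computes the per-subject CV across the
#' site pair, and the Bland-Altman bias, limits of agreement and ICC(2,1)
#' across subjects. Input rows must form exactly one pair of sites per
#' (subject, weighting, metric).
#'
#' @param per_subject data.frame with columns `subject`, `site`,
#'   `weighting`, `metric`, `value`.
#' @return object of class `reliability_table`: list with `stats`
#'   (weighting, metric, ba_bias, loa_low, loa_high, icc, icc_band) and
#'   `cvs` (weighting, metric, subject, cv_percent; `NA` for a site pair
#'   with zero mean, where the CV is undefined).
#' @export
reliability_table <- function(per_subject) {
  need <- c("subject", "site", "weighting", "metric", "value")
  if (!all(need %in% names(per_subject)))
    stopf("per-subject data must have columns %s", paste(need, collapse = ", "))
  sites <- sort(unique(per_subject$site))
  if (length(sites) != 2) stopf("exactly 2 sites required, found %d",
                                length(sites))
  key <- interaction(per_subject$subject, per_subject$weighting,
                     per_subject$metric, drop = TRUE)
  if (any(table(key) != 2) || any(tapply(per_subject$site, key,
                                         function(s) length(unique(s))) != 2))
    stopf("unpaired rows: every (subject, weighting, metric) needs one value per site")
  stats_rows <- list(); cv_rows <- list()
  for (w in unique(per_subject$weighting)) {
    for (m in unique(per_subject$metric[per_subject$weighting == w])) {
      sub <- per_subject[per_subject$weighting == w & per_subject$metric == m, ]
      sub <- sub[order(sub$site, sub$subject), ]  # site1 before site2
      wide <- stats::reshape(sub[, c("subject", "site", "value")],
                             idvar = "subject", timevar = "site",
                             direction = "wide")
      X <- as.matrix(wide[, -1])
      ba <- bland_altman(X[, 1], X[, 2])
      ic <- icc_2_1(X)
      stats_rows[[length(stats_rows) + 1]] <- data.frame(
        weighting = w, metric = m, ba_bias = ba$bias, loa_low = ba$loa_low,
        loa_high = ba$loa_high, icc = ic$icc, icc_band = ic$interpretation)
      cv_rows[[length(cv_rows) + 1]] <- data.frame(
        weighting = w, metric = m, subject = wide$subject,
        cv_percent = apply(X, 1, function(v)
          if (mean(v) == 0) NA_real_ else cv_percent(v)))
    }
  }
  structure(list(stats = do.call(rbind, stats_rows),
                 cvs = do.call(rbind, cv_rows)),
            class = "reliability_table")
}

#' @export
print.reliability_table <- function(x, ...) {
  cat("Inter-site reliability of network metrics\n")
  df <- x$stats
  agg <- stats::aggregate(cv_percent ~ weighting + metric, x$cvs, max)
  df <- merge(df, stats::setNames(agg, c("weighting", "metric", "max_cv_percent")),
              sort = FALSE)
  print(format(df, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Packaged two-site network-metric values
#'
#' Per-subject network metrics (density, global efficiency, modularity,
#' clustering coefficient, mean nodal strength) for four healthy volunteers
#' scanned at two sites, for FA-, MD-, INVF- and ECVF-weighted connectomes;
#' the input of the reliability battery. `table_printed_stats()` and
#' `table_printed_cvs()` return the independently reported statistics rows
#' for the same data, for comparison.
#'
#' @return `table_metrics_fixture`: data.frame with columns weighting,
#'   metric, subject, site1, site2 (and the same data in long form via
#'   `long = TRUE`, columns subject, site, weighting, metric, value).
#' @param long return the long (one row per measurement) form.
#' @export
table_metrics_fixture <- function(long = FALSE) {
  path <- system.file("extdata", "tables_1_2.csv", package = "mwconn",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!long) return(df)
  rbind(data.frame(subject = df$subject, site = "site1", weighting = df$weighting,
                   metric = df$metric, value = df$site1),
        data.frame(subject = df$subject, site = "site2", weighting = df$weighting,
                   metric = df$metric, value = df$site2))
}

#' @rdname table_metrics_fixture
#' @export
table_printed_stats <- function() {
  utils::read.csv(system.file("extdata", "tables_1_2_printed_stats.csv",
                              package = "mwconn", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' @rdname table_metrics_fixture
#' @export
table_printed_cvs <- function() {
  utils::read.csv(system.file("extdata", "tables_1_2_printed_cv.csv",
                              package = "mwconn", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
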