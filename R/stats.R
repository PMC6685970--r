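#' Two-sample t-test from group summaries (mean, s.e.m., n)
#'
#' Published quantifications report mean +/- s.e.m. and n; this recomputes the
#' two-tailed two-sample t-test directly from those summaries.
#' `t = (m1 - m2) / sqrt(sem1^2 + sem2^2)` with Welch-Satterthwaite df
#' (`flavor = "welch"`, the default) or the pooled-variance statistic with
#' `n1 + n2 - 2` df (`flavor = "pooled"`). With equal group sizes the two
#' t statistics coincide and only the df differ.
#'
#' @param m1,sem1,n1 mean, standard error of the mean, and group size of
#'   group 1.
#' @param m2,sem2,n2 same for group 2.
#' @param flavor `"welch"` or `"pooled"`.
#' @return list of class `test_result`: `t`, `df`, `p` (two-tailed),
#'   `flavor`, `estimate` (m1 - m2).
#' @export
ttest_from_summary <- function(m1, sem1, n1, m2, sem2, n2,
                               flavor = c("welch", "pooled")) {
  flavor <- match.arg(flavor)
  if (n1 < 2 || n2 < 2) stop("t-test needs n >= 2 per group")
  stopifnot(sem1 >= 0, sem2 >= 0)
  if (sem1 == 0 && sem2 == 0) {
    # degenerate: no within-group variance
    t_stat <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
    df <- if (flavor == "pooled") n1 + n2 - 2 else NA_real_
    p <- if (m1 == m2) 1 else 0
    return(structure(list(t = t_stat, df = df, p = p, flavor = flavor,
                          estimate = m1 - m2), class = "test_result"))
  }
  s1sq <- sem1^2 * n1          # sample variances
  s2sq <- sem2^2 * n2
  if (flavor == "welch") {
    se <- sqrt(sem1^2 + sem2^2)
    t_stat <- (m1 - m2) / se
    df <- (sem1^2 + sem2^2)^2 / (sem1^4 / (n1 - 1) + sem2^4 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * s1sq + (n2 - 1) * s2sq) / (n1 + n2 - 2)
    t_stat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  p <- 2 * pt(-abs(t_stat), df)
  structure(list(t = t_stat, df = df, p = p, flavor = flavor,
                 estimate = m1 - m2), class = "test_result")
}

#' Two-sample t-test on raw samples
#'
#' Wraps [stats::t.test()] and returns the same `test_result` structure as
#' [ttest_from_summary()]; the two agree exactly when the summaries are
#' derived from the samples.
#'
#' @param x1,x2 numeric sample vectors (each n >= 2).
#' @param flavor `"welch"` or `"pooled"`.
#' @return a `test_result` list.
#' @export
ttest_raw <- function(x1, x2, flavor = c("welch", "pooled")) {
  flavor <- match.arg(flavor)
  if (length(x1) < 2 || length(x2) < 2) stop("t-test needs n >= 2 per group")
  if (sd(x1) == 0 && sd(x2) == 0) {
    return(ttest_from_summary(mean(x1), 0, length(x1),
                              mean(x2), 0, length(x2), flavor = flavor))
  }
  ht <- stats::t.test(x1, x2, var.equal = (flavor == "pooled"))
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, flavor = flavor,
                 estimate = mean(x1) - mean(x2)),
            class = "test_result")
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH adjustment of a family of p-values (delegates to
#' [stats::p.adjust()] after validation).
#'
#' @param pvals numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' log2 expression normalized to an internal control
#'
#' `log2(signal / control_signal)`, the per-gene value used for
#' internal-control (e.g. GAPDH) normalized expression heat maps. Zero
#' signals have no logarithm; they are mapped to a configurable floor.
#'
#' @param signal numeric vector of signal intensities (>= 0).
#' @param control_signal internal-control intensity (> 0), scalar or vector.
#' @param zero_floor value substituted for `log2(0)`; default
#'   `log2(min(signal[signal > 0]) / 2 / control)`, i.e. half the smallest
#'   positive signal.
#' @return numeric vector of log2 normalized values.
#' @export
log2_norm <- function(signal, control_signal, zero_floor = NULL) {
  stopifnot(all(control_signal > 0), all(signal >= 0))
  out <- log2(signal / control_signal)
  if (any(signal == 0)) {
    if (is.null(zero_floor)) {
      pos <- signal[signal > 0]
      if (!length(pos)) stop("all signals zero: no floor can be derived")
      zero_floor <- log2((min(pos) / 2) /
                         (if (length(control_signal) > 1)
                            control_signal[signal == 0][1] else control_signal))
    }
    out[signal == 0] <- zero_floor
  }
  out
}

#' Pseudocount fold change between FPKM values
#'
#' `(fpkm_mut + pseudo) / (fpkm_ctrl + pseudo)` with the study's +0.1
#' pseudocount, plus its log2.
#'
#' @param fpkm_mut,fpkm_ctrl FPKM values (>= 0), vectorized.
#' @param pseudo pseudocount (default 0.1).
#' @return data.frame `fold_change`, `log2_fc`.
#' @export
fold_change_pseudo <- function(fpkm_mut, fpkm_ctrl, pseudo = 0.1) {
  stopifnot(all(fpkm_mut >= 0), all(fpkm_ctrl >= 0))
  fc <- (fpkm_mut + pseudo) / (fpkm_ctrl + pseudo)
  data.frame(fold_change = fc, log2_fc = log2(fc))
}

#' Dorsal-ventral distribution over 10 equal segments
#'
#' Positions along the unrolled septum are normalized by the map length and
#' counted in 10 equal bins; bin `i` (0-based) is `[i/10, (i+1)/10)` with the
#' final bin closed at 1.
#'
#' @param positions numeric vector, `0 <= position <= map_length`.
#' @param map_length total map length (same units as positions).
#' @param n_bins number of segments (default 10).
#' @return integer vector of length `n_bins` (counts; sums to
#'   `length(positions)`).
#' @export
dv_distribution <- function(positions, map_length, n_bins = 10L) {
  stopifnot(map_length > 0, all(positions >= 0), all(positions <= map_length))
  z <- positions / map_length
  bin <- pmin(floor(z * n_bins), n_bins - 1L)
  tabulate(bin + 1L, nbins = n_bins)
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("two-sample t-test (%s): t = %.4g, df = %.4g, p = %.4g\n",
              x$flavor, x$t, x$df, x$p))
  invisible(x)
}

#' @export
print.aversion_result <- function(x, ...) {
  cat(sprintf(
    "aversion index (%s): T_odor = %.1f s, mean T_DW = %.1f s (n = %d) -> %.1f s\n",
    x$window, x$T_odor, x$T_dw_mean, x$n_controls, x$index))
  invisible(x)
}

#' @export
print.response_histogram <- function(x, ...) {
  cat(sprintf(
    "response columns (OCAM-negative dorsal region): weak %d, medium %d, high %d (unclassified %d of %d)\n",
    x$weak, x$medium, x$high, x$unclassified, x$n_region))
  invisible(x)
}
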