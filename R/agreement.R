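#' Bland-Altman agreement between two measurement routes
#'
#' Differences `d = a - b`; bias is their mean, the limits of agreement
#' are `bias +- 1.96 * SD` with the n-1 sample standard deviation.
#' Agreement is flagged clinically acceptable when |bias| <= 1 mEq/L and
#' the maximal absolute difference is < 3 mEq/L.
#'
#' @param a,b paired numeric vectors (e.g., measured and expected SID).
#' @param acceptable_bias,acceptable_max acceptability thresholds, mEq/L.
#' @return An object of class `"bland_altman"`: list with `bias`,
#'   `sd_diff`, `loa_low`, `loa_high`, `n_pairs`, `max_abs_diff`,
#'   `acceptable`.
#' @examples
#' ba <- bland_altman(c(1, 2, 3), c(2, 2, 2))
#' ba$bias; ba$loa_high
#' @export
bland_altman <- function(a, b, acceptable_bias = 1, acceptable_max = 3) {
  stopifnot(length(a) == length(b))
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2)
    stop("Bland-Altman needs >= 2 complete pairs", call. = FALSE)
  d <- a - b
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  structure(
    list(bias = bias, sd_diff = sd_diff,
         loa_low = bias - 1.96 * sd_diff, loa_high = bias + 1.96 * sd_diff,
         n_pairs = length(d), max_abs_diff = max(abs(d)),
         acceptable = abs(bias) <= acceptable_bias &&
           max(abs(d)) < acceptable_max),
    class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.2f [%.2f; %.2f] mEq/L, n = %d, max |d| = %.2f (%s)\n",
              x$bias, x$loa_low, x$loa_high, x$n_pairs, x$max_abs_diff,
              if (x$acceptable) "acceptable" else "not acceptable"))
  invisible(x)
}

#' Plot a Bland-Altman comparison
#'
#' @param x a `"bland_altman"` object.
#' @param a,b the original paired vectors (means on x, differences on y);
#'   if omitted only the bias and limit lines are drawn.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bland_altman <- function(x, a = NULL, b = NULL, ...) {
  if (!is.null(a) && !is.null(b)) {
    m <- (a + b) / 2; d <- a - b
    graphics::plot(m, d, xlab = "mean of methods (mEq/L)",
                   ylab = "difference (mEq/L)",
                   ylim = range(d, x$loa_low, x$loa_high), pch = 19, ...)
  } else {
    graphics::plot(NA, xlim = 0:1, ylim = range(0, x$loa_low, x$loa_high),
                   xlab = "", ylab = "difference (mEq/L)", ...)
  }
  graphics::abline(h = c(x$bias, x$loa_low, x$loa_high), lty = c(1, 2, 2))
  invisible(x)
}

#' Two-sample comparison and correlation
#'
#' Student's two-sample t test (equal variances) for group differences,
#' with Pearson's r available through [pearson_r()] for associations.
#'
#' @param values_a,values_b numeric vectors, each with >= 2 values.
#' @return list with `t` (statistic), `p` (two-tailed), `df`,
#'   `mean_a`, `mean_b`.
#' @export
compare_groups <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each group needs >= 2 values", call. = FALSE)
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0 &&
      mean(values_a) == mean(values_b))
    return(list(t = 0, p = 1, df = length(values_a) + length(values_b) - 2,
                mean_a = mean(values_a), mean_b = mean(values_b)))
  tt <- stats::t.test(values_a, values_b, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter),
       mean_a = mean(values_a), mean_b = mean(values_b))
}

#' Pearson correlation between two variables
#'
#' @param x,y numeric vectors of equal length (>= 3 complete pairs).
#' @return list with `r` and two-tailed `p`.
#' @export
pearson_r <- function(x, y) {
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Fencl-Stewart partition of base excess
#'
#' The bedside decomposition of base excess into sodium-chloride, albumin
#' and lactate effects, with the remainder attributed to unmeasured ions.
#' The Story-type variant is used: sodium-chloride effect
#' `(Na - Cl) - 38`, albumin effect `0.25 * (42 - 10 * albumin)` (albumin
#' in g/dL, reference 42 g/L), lactate effect `-Lac`. This comparator
#' assumes any SID deviation from a fixed reference maps one-to-one onto
#' BE — i.e., it ignores pH-driven electrolyte redistribution — which is
#' exactly the assumption the expected-SID model corrects; its output is
#' reported for contrast, never asserted numerically.
#'
#' @param na,cl,lac plasma concentrations, mEq/L.
#' @param albumin albumin, g/dL.
#' @param be whole-blood base excess, mEq/L.
#' @return An object of class `"fencl_partition"`: list with
#'   `sodium_chloride_effect`, `albumin_effect`, `lactate_effect`,
#'   `unmeasured_ions` (components sum to `be` by construction).
#' @examples
#' fencl_stewart(na = 144, cl = 118, lac = 1.5, albumin = 4.6, be = -10)
#' @export
fencl_stewart <- function(na, cl, lac, albumin, be) {
  nacl <- (na - cl) - 38
  alb <- 0.25 * (42 - 10 * albumin)
  lacef <- -lac
  structure(
    list(sodium_chloride_effect = nacl, albumin_effect = alb,
         lactate_effect = lacef,
         unmeasured_ions = be - (nacl + alb + lacef)),
    class = "fencl_partition")
}

#' @export
print.fencl_partition <- function(x, ...) {
  cat("Fencl-Stewart partition of base excess (mEq/L):\n")
  cat(sprintf("  sodium-chloride effect: %6.2f\n", x$sodium_chloride_effect))
  cat(sprintf("  albumin effect:         %6.2f\n", x$albumin_effect))
  cat(sprintf("  lactate effect:         %6.2f\n", x$lactate_effect))
  cat(sprintf("  unmeasured ions:        %6.2f\n", x$unmeasured_ions))
  invisible(x)
}
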