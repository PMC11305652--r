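#' Noncarbonic whole-blood buffer value from a titration curve
#'
#' The buffer value is the negative of the slope of the bicarbonate/pH
#' relation along a CO2 titration at constant metabolic state,
#' `beta = -d[HCO3]/dpH`, estimated here as the negated ordinary
#' least-squares slope of HCO3 on pH over all of the series' steps.
#'
#' @param series a [tonometry_series()] with at least 2 steps at distinct pH.
#' @return buffer value, mEq/L per pH unit (positive for physiologic blood).
#' @examples
#' st <- data.frame(fco2 = c(0.02, 0.2), pco2 = c(20, 120),
#'                  ph = c(7.6, 7.2), hco3 = c(15, 27),
#'                  na = 140, k = 4, ca = 1.1, mg = 2, cl = 105, lac = 1.5)
#' s <- tonometry_series("ex", "healthy", 4.8, 14.2, st)
#' estimate_beta(s)  # 30
#' @export
estimate_beta <- function(series) {
  stopifnot(inherits(series, "tonometry_series"))
  ph <- series$steps$ph
  hco3 <- series$steps$hco3
  if (length(unique(ph)) < 2)
    stop("beta estimation needs >= 2 steps with distinct pH", call. = FALSE)
  -unname(stats::coef(stats::lm(hco3 ~ ph))[2])
}

#' Select the baseline equilibration step
#'
#' The baseline is the step with pH closest to 7.40 and PCO2 closest to
#' 40 mmHg. Operationally: experiment 1 uses the 5\% CO2 step, experiment 2
#' the 12\% CO2 step, and experiment 3 the control (no added acid) step
#' with PCO2 closest to 40 mmHg. Ties break on smallest |PCO2 - 40|, then
#' lowest step index.
#'
#' @param series a [tonometry_series()].
#' @param experiment `"exp1"`, `"exp2"` or `"exp3"`.
#' @return the row index of the baseline step in `series$steps`.
#' @export
select_baseline <- function(series, experiment = c("exp1", "exp2", "exp3")) {
  experiment <- match.arg(experiment)
  st <- series$steps
  if (experiment %in% c("exp1", "exp2")) {
    want <- if (experiment == "exp1") 0.05 else 0.12
    cand <- which(abs(st$fco2 - want) <= 0.01)
    if (!length(cand))
      stop(sprintf("no %g%% CO2 step to serve as baseline", 100 * want),
           call. = FALSE)
  } else {
    cand <- which(st$acid_load == 0)
    if (!length(cand))
      stop("exp3 baseline needs at least one step with no acid load",
           call. = FALSE)
  }
  cand[order(abs(st$pco2[cand] - 40), cand)][1]
}

#' Fit the expected-SID model to a tonometry series
#'
#' The workhorse of the package: given one sample's CO2 titration, selects
#' the baseline step, estimates the noncarbonic buffer value, and derives
#' per step the measured SID, the albumin and hemoglobin titrable charges,
#' the expected SID by all three routes (protein charges; fitted buffer
#' value; standardized CLSI buffer value), whole-blood base excess, and the
#' changes from baseline including the whole-blood SID change
#' `r * (SID - SID_exp(beta))`.
#'
#' Isolated-plasma series use the albumin charge only and skip the
#' buffer-value and base-excess columns (those are whole-blood concepts).
#'
#' For acid-loaded samples of a paired design, pass the control sample's
#' baseline (from [extract_baseline()]) so that all deltas refer to the
#' subject's control state; the buffer value is still the sample's own.
#' A series with a single step must carry a known `beta` column.
#'
#' @param series a [tonometry_series()].
#' @param params a [buffer_params()] object.
#' @param experiment which experiment's baseline rule to apply, see
#'   [select_baseline()].
#' @param beta_mode `"fitted"` uses the series' own estimated (or supplied)
#'   buffer value in the expected-SID and base-excess equations; `"clsi"`
#'   uses the standardized [beta_clsi()] value throughout.
#' @param baseline `NULL` to take the baseline from this series, or a
#'   baseline description from [extract_baseline()].
#' @return An object of class `"tonometry_fit"` with components `series`,
#'   `params`, `beta` (fitted), `beta_clsi`, `beta_used`, `baseline`
#'   (list: `index`, `sid`, `ph`, `z_albumin`, `z_hemoglobin`, `be`,
#'   `be_clsi`, `external`), and `derived` (a data frame, one row per step).
#' @examples
#' fit <- tonometry_fit(tonometry_fixture("table1")[[1]], experiment = "exp1")
#' coef(fit)
#' @export
tonometry_fit <- function(series, params = buffer_params(),
                          experiment = c("exp1", "exp2", "exp3"),
                          beta_mode = c("fitted", "clsi"),
                          baseline = NULL) {
  stopifnot(inherits(series, "tonometry_series"))
  experiment <- match.arg(experiment)
  beta_mode <- match.arg(beta_mode)
  st <- series$steps
  plasma <- series$sample_kind == "isolated_plasma"

  b_clsi <- beta_clsi(series$hemoglobin, params)
  b_fit <- if (length(unique(st$ph)) >= 2) estimate_beta(series)
           else if (any(is.finite(st$beta))) st$beta[is.finite(st$beta)][1]
           else NA_real_
  b_use <- switch(beta_mode, fitted = b_fit, clsi = b_clsi)
  if (!plasma && !is.finite(b_use))
    stop("no usable buffer value: series has < 2 distinct pH steps and no ",
         "'beta' column", call. = FALSE)

  sid <- compute_sid(st$na, st$k, st$ca, st$mg, st$cl, st$lac)
  z_alb <- albumin_zph(series$albumin, st$ph, params)
  z_hb <- if (plasma) rep(0, nrow(st))
          else hemoglobin_zph(series$hemoglobin, st$ph, params)
  r <- bicarbonate_ratio(series$hemoglobin, params)

  if (is.null(baseline)) {
    i0 <- select_baseline(series, experiment)
    base <- list(index = i0, sid = sid[i0], ph = st$ph[i0],
                 z_albumin = z_alb[i0], z_hemoglobin = z_hb[i0],
                 external = FALSE)
    base$be <- if (plasma) NA_real_ else
      base_excess(st$hco3[i0], st$ph[i0], b_use, series$hemoglobin,
                  st$so2[i0], params)
    base$be_clsi <- if (plasma) NA_real_ else
      base_excess(st$hco3[i0], st$ph[i0], b_clsi, series$hemoglobin,
                  st$so2[i0], params)
  } else {
    base <- baseline
    base$index <- NA_integer_
    base$external <- TRUE
  }

  sid_exp <- expected_sid(base$sid, z_alb - base$z_albumin,
                          z_hb - base$z_hemoglobin)
  if (!plasma) {
    sid_exp_beta <- expected_sid_beta(base$sid, base$ph, st$ph, b_use)
    sid_exp_clsi <- expected_sid_beta(base$sid, base$ph, st$ph, b_clsi)
    be <- base_excess(st$hco3, st$ph, b_use, series$hemoglobin, st$so2, params)
    be_c <- base_excess(st$hco3, st$ph, b_clsi, series$hemoglobin, st$so2,
                        params)
    d_wb <- delta_sid_wb(sid, sid_exp_beta, r)
    d_wb_c <- delta_sid_wb(sid, sid_exp_clsi, r)
    d_be <- be - base$be
    d_be_c <- be_c - base$be_clsi
  } else {
    sid_exp_beta <- sid_exp_clsi <- be <- be_c <- d_wb <- d_wb_c <-
      d_be <- d_be_c <- rep(NA_real_, nrow(st))
  }

  derived <- data.frame(
    fco2 = st$fco2, pco2 = st$pco2, ph = st$ph, hco3 = st$hco3,
    sid = sid, z_albumin = z_alb, z_hemoglobin = z_hb,
    sid_exp = sid_exp, sid_exp_beta = sid_exp_beta,
    sid_exp_clsi = sid_exp_clsi,
    be = be, be_clsi = be_c,
    delta_sid = sid - base$sid, delta_be = d_be, delta_be_clsi = d_be_c,
    delta_sid_wb = d_wb, delta_sid_wb_clsi = d_wb_c,
    is_baseline = seq_len(nrow(st)) == (base$index %||% 0L) &
      !isTRUE(base$external))

  structure(
    list(series = series, params = params, experiment = experiment,
         beta_mode = beta_mode, beta = b_fit, beta_clsi = b_clsi,
         beta_used = b_use, r = r, baseline = base, derived = derived),
    class = "tonometry_fit")
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Extract a baseline description from a fitted control series
#'
#' Packages the baseline step of a fitted control sample (SID, pH, protein
#' charges, base excess) for reuse as the reference state of the same
#' subject's acid-loaded samples in [tonometry_fit()].
#'
#' @param fit a `"tonometry_fit"` on the control sample.
#' @return A list usable as the `baseline` argument of [tonometry_fit()].
#' @export
extract_baseline <- function(fit) {
  stopifnot(inherits(fit, "tonometry_fit"))
  fit$baseline[c("sid", "ph", "z_albumin", "z_hemoglobin", "be", "be_clsi")]
}

#' @export
print.tonometry_fit <- function(x, ...) {
  cat(sprintf("Expected-SID fit: subject '%s' (%s, %s), %d step(s)\n",
              x$series$subject_id, x$series$group, x$series$sample_kind,
              nrow(x$derived)))
  if (is.finite(x$beta))
    cat(sprintf("  buffer value beta: %.2f mEq/L per pH (CLSI %.2f), mode '%s'\n",
                x$beta, x$beta_clsi, x$beta_mode))
  cat(sprintf("  baseline: %s, SID %.2f mEq/L at pH %.3f\n",
              if (isTRUE(x$baseline$external)) "external (paired control)"
              else sprintf("step %d", x$baseline$index),
              x$baseline$sid, x$baseline$ph))
  invisible(x)
}

#' @export
summary.tonometry_fit <- function(object, ...) {
  res <- stats::residuals(object)
  out <- list(fit = object,
              resid = res,
              mean_abs_resid = mean(abs(res)))
  class(out) <- "summary.tonometry_fit"
  out
}

#' @export
print.summary.tonometry_fit <- function(x, ...) {
  print(x$fit)
  cat("\nPer-step derived quantities:\n")
  print(round(x$fit$derived[, c("fco2", "ph", "sid", "sid_exp",
                                "sid_exp_beta", "be", "delta_sid_wb")], 2))
  cat(sprintf("\nMean |SID - SID_exp|: %.2f mEq/L\n", x$mean_abs_resid))
  invisible(x)
}

#' @export
coef.tonometry_fit <- function(object, ...) {
  c(beta = object$beta, beta_clsi = object$beta_clsi,
    sid_baseline = object$baseline$sid, ph_baseline = object$baseline$ph,
    r = object$r)
}

#' Predict expected SID at new pH values
#'
#' @param object a `"tonometry_fit"`.
#' @param ph plasma pH values at which to predict (defaults to the fitted
#'   steps).
#' @param method `"zph"` predicts from protein titrable charges,
#'   `"beta"` from the fit's buffer value, `"clsi"` from the standardized
#'   buffer value.
#' @param ... unused.
#' @return numeric vector of expected SID, mEq/L.
#' @export
predict.tonometry_fit <- function(object, ph = NULL,
                                  method = c("zph", "beta", "clsi"), ...) {
  method <- match.arg(method)
  if (is.null(ph)) ph <- object$series$steps$ph
  b <- object$baseline
  p <- object$params
  s <- object$series
  switch(method,
    zph = {
      dz_a <- albumin_zph(s$albumin, ph, p) - b$z_albumin
      dz_h <- if (s$sample_kind == "isolated_plasma") 0 else
        hemoglobin_zph(s$hemoglobin, ph, p) - b$z_hemoglobin
      expected_sid(b$sid, dz_a, dz_h)
    },
    beta = expected_sid_beta(b$sid, b$ph, ph, object$beta_used),
    clsi = expected_sid_beta(b$sid, b$ph, ph, object$beta_clsi))
}

#' @export
fitted.tonometry_fit <- function(object, ...) object$derived$sid_exp

#' Residuals: measured minus expected SID
#'
#' @param object a `"tonometry_fit"`.
#' @param method expectation route, see [predict.tonometry_fit()].
#' @param ... unused.
#' @return numeric vector, mEq/L.
#' @export
residuals.tonometry_fit <- function(object, method = c("zph", "beta", "clsi"),
                                    ...) {
  method <- match.arg(method)
  col <- switch(method, zph = "sid_exp", beta = "sid_exp_beta",
                clsi = "sid_exp_clsi")
  object$derived$sid - object$derived[[col]]
}

#' Plot a fitted titration curve
#'
#' Measured SID against plasma pH with the expected-SID curves overlaid.
#'
#' @param x a `"tonometry_fit"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.tonometry_fit <- function(x, ...) {
  d <- x$derived
  ph_grid <- seq(min(d$ph), max(d$ph), length.out = 50)
  exp_z <- predict(x, ph_grid, method = "zph")
  ylim <- range(d$sid, d$sid_exp, exp_z, na.rm = TRUE)
  graphics::plot(d$ph, d$sid, xlab = "plasma pH", ylab = "SID (mEq/L)",
                 ylim = ylim, pch = 19,
                 main = sprintf("CO2 titration, subject %s",
                                x$series$subject_id), ...)
  graphics::lines(ph_grid, exp_z, lty = 1)
  if (all(is.finite(d$sid_exp_beta)))
    graphics::lines(ph_grid, predict(x, ph_grid, method = "beta"), lty = 2)
  graphics::points(d$ph[d$is_baseline], d$sid[d$is_baseline], pch = 1, cex = 2)
  graphics::legend("topright", bty = "n", lty = c(NA, 1, 2), pch = c(19, NA, NA),
                   legend = c("measured", "expected (Z_pH)",
                              "expected (beta)"))
  invisible(x)
}
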