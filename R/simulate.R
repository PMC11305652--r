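# Group-level distributions and baseline electrolyte templates, taken from
# published group means (baseline column of the corresponding experiment).
.group_profiles <- list(
  healthy     = list(albumin = c(4.8, 0.2), hemoglobin = c(14.2, 0.9),
                     sid0 = c(36.6, 2.2),
                     panel = c(na = 138.9, k = 4.25, ca = 1.17, mg = 2.11,
                               lac = 1.7)),
  septic      = list(albumin = c(3.1, 0.5), hemoglobin = c(10.4, 0.8),
                     sid0 = c(33.4, 4.8),
                     panel = c(na = 138.9, k = 4.32, ca = 1.10, mg = 2.05,
                               lac = 3.6)),
  diluted     = list(albumin = c(5.0, 0.2), hemoglobin = c(7.0, 0.9),
                     sid0 = c(44.1, 1.9),
                     panel = c(na = 141.6, k = 3.98, ca = 1.28, mg = 2.07,
                               lac = 1.4)),
  undiluted   = list(albumin = c(5.0, 0.3), hemoglobin = c(14.1, 1.7),
                     sid0 = c(43.3, 2.3),
                     panel = c(na = 142.0, k = 4.12, ca = 1.28, mg = 2.06,
                               lac = 1.7)),
  experiment3 = list(albumin = c(5.0, 0.2), hemoglobin = c(13.9, 1.3),
                     sid0 = c(42.9, 2.5),
                     panel = c(na = 142.9, k = 4.0, ca = 1.1, mg = 2.0,
                               lac = 1.6)))

# analyzer-grade measurement noise (SD per analyte)
.default_noise <- c(ph = 0.005, pco2 = 1, hco3 = 0.3, na = 0.5, cl = 0.5,
                    k = 0.05, ca = 0.01, lac = 0.1, mg = 0)

# Gaussian draw truncated at +-3 SD (rejection; keeps physiology bounded)
.rtnorm3 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- abs(x - mean) > 3 * sd))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Define a simulation scenario
#'
#' Describes one simulated tonometry experiment: the subject group (which
#' fixes the albumin/hemoglobin/baseline-SID distributions to published
#' group means +- SD), the CO2 equilibration levels, the strong-acid loads
#' (one generated series per subject per load), the measurement-noise
#' model, and the seed that fully determines the output.
#'
#' @param group `"healthy"`, `"septic"`, `"diluted"`, `"undiluted"` or
#'   `"experiment3"`.
#' @param n_subjects number of simulated subjects (>= 1).
#' @param fco2_levels equilibration gas CO2 fractions, each in
#'   \[0.01, 0.25\].
#' @param acid_loads data frame with columns `kind` (`"none"`, `"hcl"`,
#'   `"lactic"`) and `load` (mEq/L of blood); default a single control.
#' @param noise named vector of per-analyte Gaussian SDs overriding the
#'   analyzer-grade defaults (pH 0.005, PCO2 1 mmHg, HCO3 0.3, Na/Cl 0.5,
#'   K 0.05, Ca 0.01, Lac 0.1 mEq/L); set all to 0 for noise-free data.
#' @param seed integer seed.
#' @param params a [buffer_params()] object.
#' @param beta_source `"zph"` sets each subject's true buffer value to the
#'   slope of the protein titrable-charge model at pH 7.4; `"clsi"` uses
#'   the standardized [beta_clsi()] value.
#' @param split strong-ion allocation fractions of a required SID change
#'   (must sum to 1); see [redistribute_electrolytes()].
#' @return An object of class `"simulation_scenario"`.
#' @export
simulation_scenario <- function(group = "healthy", n_subjects = 10,
                                fco2_levels = c(0.02, 0.05, 0.12, 0.20),
                                acid_loads = data.frame(kind = "none",
                                                        load = 0),
                                noise = NULL, seed = 1,
                                params = buffer_params(),
                                beta_source = c("zph", "clsi"),
                                split = c(cl = 0.55, na = 0.40,
                                          ca = 0.04, k = 0.01)) {
  group <- match.arg(group, names(.group_profiles))
  beta_source <- match.arg(beta_source)
  stopifnot(n_subjects >= 1,
            all(fco2_levels >= 0.01 & fco2_levels <= 0.25),
            is.data.frame(acid_loads),
            all(c("kind", "load") %in% names(acid_loads)))
  nz <- .default_noise
  if (!is.null(noise)) {
    if (length(noise) == 1 && is.null(names(noise))) {
      nz[] <- noise
    } else {
      unknown <- setdiff(names(noise), names(nz))
      if (length(unknown))
        stop("unknown noise component(s): ", paste(unknown, collapse = ", "),
             call. = FALSE)
      nz[names(noise)] <- noise
    }
  }
  structure(list(group = group, n_subjects = n_subjects,
                 fco2_levels = sort(fco2_levels), acid_loads = acid_loads,
                 noise = nz, seed = as.integer(seed), params = params,
                 beta_source = beta_source, split = split),
            class = "simulation_scenario")
}

#' Draw one subject's protein panel and baseline state
#'
#' Albumin, hemoglobin and baseline SID are drawn from Gaussians with the
#' group's published mean +- SD, truncated at +-3 SD; baseline base excess
#' from N(0, 1.5) mEq/L. Uses the current RNG state.
#'
#' @param group group name, see [simulation_scenario()].
#' @param params a [buffer_params()] object.
#' @return list with `albumin`, `hemoglobin`, `sid0`, `be0` and the
#'   group's baseline electrolyte `panel` (chloride solved so that the
#'   panel's SID equals `sid0` exactly).
#' @export
sample_subject <- function(group, params = buffer_params()) {
  pr <- .group_profiles[[match.arg(group, names(.group_profiles))]]
  alb <- .rtnorm3(1, pr$albumin[1], pr$albumin[2])
  hb <- .rtnorm3(1, pr$hemoglobin[1], pr$hemoglobin[2])
  sid0 <- .rtnorm3(1, pr$sid0[1], pr$sid0[2])
  be0 <- .rtnorm3(1, 0, 1.5)
  p <- pr$panel
  panel <- data.frame(na = p[["na"]], k = p[["k"]], ca = p[["ca"]],
                      mg = p[["mg"]],
                      cl = p[["na"]] + p[["k"]] + 2 * p[["ca"]] + p[["mg"]] -
                        p[["lac"]] - sid0,
                      lac = p[["lac"]])
  list(albumin = alb, hemoglobin = hb, sid0 = sid0, be0 = be0, panel = panel)
}

#' Solve plasma pH from PCO2 and a base-excess target
#'
#' Inverts the base-excess equation with bicarbonate supplied by
#' Henderson-Hasselbalch: finds the pH in \[6.5, 7.9\] at which
#' `base_excess(hh_bicarbonate(ph, pco2), ph, beta, hb, so2)` equals
#' `be_target`. The residual is strictly increasing in pH, so the root is
#' unique; bisection (via [stats::uniroot()]) is run to a residual below
#' 1e-9 mEq/L.
#'
#' @param pco2 CO2 partial pressure, mmHg (in \[10, 200\]).
#' @param be_target base excess to realize, mEq/L.
#' @param beta noncarbonic buffer value, mEq/L per pH unit.
#' @param hb hemoglobin, g/dL.
#' @param so2 oxygen saturation fraction.
#' @param params a [buffer_params()] object.
#' @return plasma pH.
#' @examples
#' solve_ph(40, 0, 28, 14)  # ~7.40
#' @export
solve_ph <- function(pco2, be_target, beta, hb, so2 = 1,
                     params = buffer_params()) {
  stopifnot(pco2 >= 10, pco2 <= 200)
  f <- function(ph)
    base_excess(hh_bicarbonate(ph, pco2, params), ph, beta, hb, so2, params) -
      be_target
  lo <- 6.5; hi <- 7.9
  if (f(lo) > 0 || f(hi) < 0)
    stop("no pH in [6.5, 7.9] realizes the requested base excess",
         call. = FALSE)
  stats::uniroot(f, c(lo, hi), tol = 1e-13)$root
}

#' Redistribute strong ions to hit a target SID
#'
#' Emulates pH-driven electrolyte/water redistribution: the added acid
#' anion (lactic -> lactate; hydrochloric -> chloride) is first placed in
#' plasma, then the remaining SID change is allocated across analytes with
#' fixed fractions (defaults: Cl -0.55, Na +0.40, Ca +0.04, K +0.01 of the
#' required change, the chloride-shift-dominated pattern seen in tonometry
#' tables), so that the panel's [compute_sid()] equals `sid_target` exactly
#' before measurement noise. Calcium's allocation is applied in mMol/L
#' (half its charge share).
#'
#' @param sid_target target plasma SID, mEq/L.
#' @param panel one-row data frame with `na`, `k`, `ca`, `mg`, `cl`, `lac`.
#' @param acid_kind `"none"`, `"hcl"` or `"lactic"`.
#' @param acid_load mEq/L of added strong acid.
#' @param split named allocation fractions (`cl`, `na`, `ca`, `k`) summing
#'   to 1.
#' @return the adjusted panel (one-row data frame).
#' @export
redistribute_electrolytes <- function(sid_target, panel,
                                      acid_kind = "none", acid_load = 0,
                                      split = c(cl = 0.55, na = 0.40,
                                                ca = 0.04, k = 0.01)) {
  stopifnot(is.finite(sid_target))
  if (abs(sum(split) - 1) > 1e-9)
    stop("allocation fractions must sum to 1", call. = FALSE)
  p <- panel
  if (acid_load > 0) {
    if (acid_kind == "lactic") p$lac <- p$lac + acid_load
    else if (acid_kind == "hcl") p$cl <- p$cl + acid_load
    else stop("acid_load > 0 with acid_kind 'none'", call. = FALSE)
  }
  d <- sid_target - compute_sid(p$na, p$k, p$ca, p$mg, p$cl, p$lac)
  p$cl <- p$cl - split[["cl"]] * d
  p$na <- p$na + split[["na"]] * d
  p$ca <- p$ca + split[["ca"]] * d / 2
  p$k <- p$k + split[["k"]] * d
  p
}

#' Simulate a tonometry experiment
#'
#' Forward-generates a dataset with the structure the analysis pipeline
#' assumes. Per subject: draw proteins and baseline state
#' ([sample_subject()]); set the true buffer value (protein-charge slope or
#' CLSI per `beta_source`); the true base excess of an acid-loaded series
#' is the baseline base excess minus the acid load. Per CO2 level: PCO2 is
#' the dry-gas fraction times 713 mmHg; pH solves the base-excess equation
#' ([solve_ph()]); bicarbonate follows Henderson-Hasselbalch; plasma SID is
#' the buffer-value expectation plus the whole-blood change scaled back to
#' plasma (`- load / r`); electrolytes are redistributed to hit that SID
#' exactly ([redistribute_electrolytes()]); analyzer noise is added last.
#'
#' The generator's truth model is the package's own buffer model — it is a
#' consistency engine for the pipeline, not an independent physical model
#' of the red cell.
#'
#' @param scenario a [simulation_scenario()].
#' @return list with `data` (list of [tonometry_series()]) and `truth`
#'   (list of data frames `subjects` and `steps` holding the noise-free
#'   ground truth: true buffer values, baseline SID/pH/BE, per-step true
#'   BE, SID, pH, HCO3 and the configured acid loads).
#' @examples
#' sim <- simulate_tonometry(simulation_scenario(n_subjects = 2, seed = 7))
#' length(sim$data)
#' @export
simulate_tonometry <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  set.seed(scenario$seed, kind = "Mersenne-Twister")
  p <- scenario$params
  nz <- scenario$noise
  data <- list(); truth_subj <- list(); truth_steps <- list()

  for (i in seq_len(scenario$n_subjects)) {
    id <- sprintf("S%02d", i)
    sub <- sample_subject(scenario$group, p)
    r <- bicarbonate_ratio(sub$hemoglobin, p)
    beta_true <- switch(scenario$beta_source,
      clsi = beta_clsi(sub$hemoglobin, p),
      zph = {
        h <- 1e-4
        z <- function(ph) albumin_zph(sub$albumin, ph, p) +
          hemoglobin_zph(sub$hemoglobin, ph, p)
        -(z(p$ph_ref + h) - z(p$ph_ref - h)) / (2 * h)
      })
    ph0 <- solve_ph(40, sub$be0, beta_true, sub$hemoglobin, 1, p)
    truth_subj[[id]] <- data.frame(
      subject_id = id, albumin = sub$albumin, hemoglobin = sub$hemoglobin,
      beta_true = beta_true, sid_baseline = sub$sid0, ph_baseline = ph0,
      be_baseline = sub$be0)

    for (j in seq_len(nrow(scenario$acid_loads))) {
      kind <- scenario$acid_loads$kind[j]
      load <- scenario$acid_loads$load[j]
      be_true <- sub$be0 - load
      rows <- lapply(scenario$fco2_levels, function(fc) {
        pco2 <- 713 * fc
        ph <- solve_ph(pco2, be_true, beta_true, sub$hemoglobin, 1, p)
        hco3 <- hh_bicarbonate(ph, pco2, p)
        sid <- expected_sid_beta(sub$sid0, ph0, ph, beta_true) - load / r
        panel <- redistribute_electrolytes(sid, sub$panel, kind, load,
                                           scenario$split)
        list(true = data.frame(subject_id = id, acid_kind = kind,
                               acid_load = load, fco2 = fc, pco2 = pco2,
                               ph = ph, hco3 = hco3, sid = sid,
                               be_true = be_true),
             meas = data.frame(
               fco2 = fc,
               pco2 = pco2 + stats::rnorm(1, 0, nz[["pco2"]]),
               ph = ph + stats::rnorm(1, 0, nz[["ph"]]),
               hco3 = hco3 + stats::rnorm(1, 0, nz[["hco3"]]),
               so2 = 1,
               na = panel$na + stats::rnorm(1, 0, nz[["na"]]),
               k = panel$k + stats::rnorm(1, 0, nz[["k"]]),
               ca = panel$ca + stats::rnorm(1, 0, nz[["ca"]]),
               mg = panel$mg + stats::rnorm(1, 0, nz[["mg"]]),
               cl = panel$cl + stats::rnorm(1, 0, nz[["cl"]]),
               lac = panel$lac + stats::rnorm(1, 0, nz[["lac"]]),
               acid_kind = kind, acid_load = load))
      })
      truth_steps[[paste(id, j)]] <- do.call(rbind, lapply(rows, `[[`, "true"))
      steps <- do.call(rbind, lapply(rows, `[[`, "meas"))
      data[[paste0(id, "_", kind, "_", load)]] <- tonometry_series(
        subject_id = id, group = scenario$group, albumin = sub$albumin,
        hemoglobin = sub$hemoglobin, steps = steps)
    }
  }
  list(data = data,
       truth = list(seed = scenario$seed,
                    subjects = do.call(rbind, c(truth_subj,
                                                make.row.names = FALSE)),
                    steps = do.call(rbind, c(truth_steps,
                                             make.row.names = FALSE))))
}

#' Write simulated data and ground truth to disk
#'
#' The dataset goes to the package CSV dialect ([write_tonometry()]); the
#' ground truth to a JSON sidecar embedding the seed.
#'
#' @param sim result of [simulate_tonometry()].
#' @param csv_path output CSV path.
#' @param truth_path output JSON path (default: `csv_path` with
#'   `_truth.json`).
#' @return `csv_path`, invisibly.
#' @export
write_simulation <- function(sim, csv_path,
                             truth_path = sub("\\.csv$", "_truth.json",
                                              csv_path)) {
  write_tonometry(sim$data, csv_path)
  jsonlite::write_json(sim$truth, truth_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(csv_path)
}
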