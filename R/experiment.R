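#' Run a full tonometry experiment analysis
#'
#' Orchestrates the study-level pipeline over a dataset of tonometry
#' series: fits every series with [tonometry_fit()], pools per-step derived
#' quantities, runs the Bland-Altman agreement analyses (baseline steps are
#' excluded, measured and expected SID being equal there by definition),
#' and compares groups.
#'
#' For the respiratory-acidosis designs (`"exp1"`, `"exp2"`) the agreement
#' sets are measured SID against the charge-based and CLSI expectations,
#' and the group comparison is the SID rise from the lowest to the highest
#' CO2 step. For the acid-loading design (`"exp3"`) each subject's control
#' sample provides the baseline for its acid-loaded samples (own buffer
#' value per sample); agreement sets are: control-series SID against all
#' three expectations (respiratory), and changes from baseline in plasma
#' SID and in whole-blood SID against the change in BE (differences taken
#' as delta-SID minus delta-BE), both at constant CO2 (`metabolic_*`, the
#' step with PCO2 closest to 40 mmHg) and across all CO2 steps
#' (`mixed_*`).
#'
#' @param dataset list of [tonometry_series()].
#' @param experiment `"exp1"`, `"exp2"` or `"exp3"`.
#' @param params a [buffer_params()] object.
#' @param beta_mode see [tonometry_fit()].
#' @return An object of class `"experiment_report"`: list with `fits`,
#'   `derived` (stacked data frame with subject/acid identifiers),
#'   `agreement` (named list of [bland_altman()] results), `group_means`,
#'   and `comparisons`.
#' @export
run_experiment <- function(dataset, experiment = c("exp1", "exp2", "exp3"),
                           params = buffer_params(),
                           beta_mode = c("fitted", "clsi")) {
  experiment <- match.arg(experiment)
  beta_mode <- match.arg(beta_mode)
  stopifnot(length(dataset) >= 1,
            all(vapply(dataset, inherits, TRUE, "tonometry_series")))

  if (experiment == "exp3") {
    fits <- .fit_exp3(dataset, params, beta_mode)
  } else {
    fits <- lapply(dataset, tonometry_fit, params = params,
                   experiment = experiment, beta_mode = beta_mode)
  }

  derived <- do.call(rbind, lapply(fits, function(f) {
    d <- f$derived
    cbind(data.frame(subject_id = f$series$subject_id,
                     group = f$series$group,
                     sample_kind = f$series$sample_kind,
                     acid_kind = f$series$steps$acid_kind,
                     acid_load = f$series$steps$acid_load),
          d)
  }))
  rownames(derived) <- NULL

  agreement <- .agreement_sets(derived, experiment)
  group_means <- stats::aggregate(
    cbind(ph, hco3, sid, z_albumin, z_hemoglobin, sid_exp) ~ group + fco2,
    data = derived, FUN = mean)
  comparisons <- .group_comparisons(derived, experiment)

  structure(list(experiment = experiment, fits = fits, derived = derived,
                 agreement = agreement, group_means = group_means,
                 comparisons = comparisons),
            class = "experiment_report")
}

# exp3: pair each subject's acid-loaded samples with its control baseline
.fit_exp3 <- function(dataset, params, beta_mode) {
  subj <- vapply(dataset, function(s) s$subject_id, "")
  is_ctrl <- vapply(dataset, function(s) all(s$steps$acid_load == 0), TRUE)
  fits <- vector("list", length(dataset))
  for (id in unique(subj)) {
    ci <- which(subj == id & is_ctrl)
    if (!length(ci))
      stop("exp3 subject '", id, "' has no control series", call. = FALSE)
    ctrl_fit <- tonometry_fit(dataset[[ci[1]]], params, "exp3", beta_mode)
    fits[[ci[1]]] <- ctrl_fit
    base <- extract_baseline(ctrl_fit)
    for (ai in setdiff(which(subj == id), ci[1]))
      fits[[ai]] <- tonometry_fit(dataset[[ai]], params, "exp3", beta_mode,
                                  baseline = base)
  }
  fits
}

.agreement_sets <- function(derived, experiment) {
  nb <- derived[!derived$is_baseline, , drop = FALSE]
  out <- list()
  ctrl <- nb[nb$acid_load == 0, , drop = FALSE]
  if (nrow(ctrl) >= 2) {
    out$sid_vs_exp <- bland_altman(ctrl$sid, ctrl$sid_exp)
    out$sid_vs_exp_clsi <- bland_altman(ctrl$sid, ctrl$sid_exp_clsi)
    if (experiment == "exp3")
      out$sid_vs_exp_beta <- bland_altman(ctrl$sid, ctrl$sid_exp_beta)
  }
  if (experiment == "exp3") {
    acid <- nb[nb$acid_load > 0, , drop = FALSE]
    if (nrow(acid) >= 2) {
      # constant-CO2 subset: per series, the step with PCO2 closest to 40
      key <- interaction(acid$subject_id, acid$acid_kind, acid$acid_load,
                         drop = TRUE)
      pick <- unlist(lapply(split(seq_len(nrow(acid)), key), function(ix)
        ix[which.min(abs(acid$pco2[ix] - 40))]))
      met <- acid[pick, , drop = FALSE]
      # difference convention: delta-SID minus delta-BE
      if (nrow(met) >= 2) {
        out$metabolic_dsid_vs_dbe <- bland_altman(met$delta_sid, met$delta_be)
        out$metabolic_dsidwb_vs_dbe <-
          bland_altman(met$delta_sid_wb, met$delta_be)
        out$metabolic_dsidwb_vs_dbe_clsi <-
          bland_altman(met$delta_sid_wb_clsi, met$delta_be_clsi)
      }
      out$mixed_dsid_vs_dbe <- bland_altman(acid$delta_sid, acid$delta_be)
      out$mixed_dsidwb_vs_dbe <-
        bland_altman(acid$delta_sid_wb, acid$delta_be)
      out$mixed_dsidwb_vs_dbe_clsi <-
        bland_altman(acid$delta_sid_wb_clsi, acid$delta_be_clsi)
    }
  }
  out
}

.group_comparisons <- function(derived, experiment) {
  out <- list()
  if (experiment %in% c("exp1", "exp2")) {
    # per-subject SID rise from lowest to highest CO2 step
    rise <- lapply(split(derived, derived[c("subject_id", "group")], drop = TRUE),
                   function(g) {
                     g <- g[order(g$fco2), ]
                     data.frame(group = g$group[1],
                                rise = g$sid[nrow(g)] - g$sid[1])
                   })
    rise <- do.call(rbind, rise)
    out$sid_rise <- rise
    gs <- split(rise$rise, rise$group)
    gs <- gs[lengths(gs) >= 2]
    if (length(gs) == 2)
      out$sid_rise_test <- compare_groups(gs[[1]], gs[[2]])
  }
  out
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("Tonometry experiment report (%s): %d series, %d steps\n",
              x$experiment, length(x$fits), nrow(x$derived)))
  cat("Agreement analyses (baseline steps excluded):\n")
  for (nm in names(x$agreement)) {
    cat(sprintf("  %-28s ", nm)); print(x$agreement[[nm]])
  }
  invisible(x)
}

#' Write an experiment report to files
#'
#' Writes the stacked derived table as CSV and the agreement/comparison
#' summaries as JSON into a directory.
#'
#' @param report an `"experiment_report"`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "experiment_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$derived, file.path(dir, "derived_steps.csv"),
                   row.names = FALSE)
  summ <- list(
    experiment = report$experiment,
    agreement = lapply(report$agreement, unclass),
    comparisons = report$comparisons)
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
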