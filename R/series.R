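#' Construct a tonometry series
#'
#' One sample's ordered CO2 equilibration steps together with its protein
#' panel. Steps are sorted by equilibrated CO2 fraction. Soft physiologic
#' range checks (sodium 100-200, chloride 70-140 mEq/L, pH 6.0-8.2) emit
#' warnings, not errors, so that pathological inputs remain analyzable.
#'
#' @param subject_id sample/subject identifier.
#' @param group one of `"healthy"`, `"septic"`, `"diluted"`, `"undiluted"`,
#'   `"experiment3"`.
#' @param albumin albumin, g/dL (in (0, 8\]).
#' @param hemoglobin hemoglobin, g/dL (in \[0, 25\]).
#' @param steps data frame with one row per equilibration step and columns
#'   `fco2` (equilibration gas CO2 fraction, in \[0.01, 0.25\]), `pco2`
#'   (mmHg), `ph`, `hco3` (mEq/L), `so2` (fraction, NA -> 1), `na`, `k`
#'   (mEq/L), `ca` (mMol/L, ionized), `mg`, `cl`, `lac` (mEq/L). Optional:
#'   `acid_kind` (`"none"`, `"hcl"`, `"lactic"`), `acid_load` (mEq/L of
#'   added strong acid, 0 for controls), `beta` (a known buffer value,
#'   used when the series is too short to fit one).
#' @param sample_kind `"whole_blood"` or `"isolated_plasma"`.
#' @param phosphate phosphate, mg/dL; recorded but never used in
#'   computation (phosphate buffering is outside the model).
#' @return An object of class `"tonometry_series"`.
#' @export
tonometry_series <- function(subject_id, group, albumin, hemoglobin, steps,
                             sample_kind = c("whole_blood", "isolated_plasma"),
                             phosphate = NA_real_) {
  sample_kind <- match.arg(sample_kind)
  group <- match.arg(group,
                     c("healthy", "septic", "diluted", "undiluted", "experiment3"))
  stopifnot(is.data.frame(steps), nrow(steps) >= 1)
  needed <- c("fco2", "pco2", "ph", "hco3", "na", "k", "ca", "mg", "cl", "lac")
  missing_cols <- setdiff(needed, names(steps))
  if (length(missing_cols))
    stop("steps missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!"so2" %in% names(steps)) steps$so2 <- 1
  steps$so2[is.na(steps$so2)] <- 1
  if (!"acid_kind" %in% names(steps)) steps$acid_kind <- "none"
  if (!"acid_load" %in% names(steps)) steps$acid_load <- 0
  if (!"beta" %in% names(steps)) steps$beta <- NA_real_

  if (!(albumin > 0 && albumin <= 8))
    stop("albumin outside (0, 8] g/dL", call. = FALSE)
  if (!(hemoglobin >= 0 && hemoglobin <= 25))
    stop("hemoglobin outside [0, 25] g/dL", call. = FALSE)
  if (any(steps$fco2 < 0.01 | steps$fco2 > 0.25))
    stop("fco2 outside [0.01, 0.25]", call. = FALSE)
  if (any(steps$pco2 <= 0) || any(steps$hco3 <= 0))
    stop("pco2 and hco3 must be > 0", call. = FALSE)
  if (any(steps$ph < 6.0 | steps$ph > 8.2))
    warning("pH outside [6.0, 8.2] for subject ", subject_id)
  if (any(steps$na < 100 | steps$na > 200))
    warning("sodium outside [100, 200] mEq/L for subject ", subject_id)
  if (any(steps$cl < 70 | steps$cl > 140))
    warning("chloride outside [70, 140] mEq/L for subject ", subject_id)

  steps <- steps[order(steps$fco2), , drop = FALSE]
  rownames(steps) <- NULL
  structure(
    list(subject_id = as.character(subject_id), group = group,
         sample_kind = sample_kind,
         albumin = albumin, hemoglobin = hemoglobin, phosphate = phosphate,
         steps = steps),
    class = "tonometry_series")
}

#' @export
print.tonometry_series <- function(x, ...) {
  acid <- unique(x$steps$acid_kind[x$steps$acid_load > 0])
  load <- max(x$steps$acid_load)
  cat(sprintf("Tonometry series '%s' (%s, %s): %d step(s), pH %.2f-%.2f\n",
              x$subject_id, x$group, x$sample_kind, nrow(x$steps),
              min(x$steps$ph), max(x$steps$ph)))
  cat(sprintf("  albumin %.2f g/dL, hemoglobin %.2f g/dL%s\n",
              x$albumin, x$hemoglobin,
              if (load > 0) sprintf(", %s load %.1f mEq/L", acid, load) else ""))
  invisible(x)
}

# column order of the on-disk CSV dialect
.tono_cols <- c("subject_id", "group", "sample_kind", "albumin_g_dl",
                "hemoglobin_g_dl", "fco2", "pco2_mmhg", "ph", "hco3_meq_l",
                "so2", "na", "k", "ca_mmol_l", "mg_meq_l", "cl", "lac",
                "acid_kind", "acid_load_meq_l", "beta")

#' Read tonometry records from CSV
#'
#' Reads the package's long CSV dialect (one row per equilibration step,
#' units frozen in the column names) and groups rows into
#' [tonometry_series()] objects by subject, sample kind and acid load.
#' A missing `so2` cell means fully saturated (1.0). An optional `beta`
#' column carries a known buffer value for series too short to fit one.
#'
#' @param path path to a CSV file.
#' @return A list of `tonometry_series`.
#' @export
read_tonometry <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                error = function(e)
                  stop("empty or unparseable tonometry file: ", path,
                       call. = FALSE))
  if (nrow(d) == 0) stop("empty tonometry file: ", path, call. = FALSE)
  required <- setdiff(.tono_cols, c("so2", "acid_kind", "acid_load_meq_l", "beta"))
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!"so2" %in% names(d)) d$so2 <- 1
  if (!"acid_kind" %in% names(d)) d$acid_kind <- "none"
  if (!"acid_load_meq_l" %in% names(d)) d$acid_load_meq_l <- 0
  if (!"beta" %in% names(d)) d$beta <- NA_real_
  num_cols <- setdiff(.tono_cols, c("subject_id", "group", "sample_kind",
                                    "acid_kind"))
  for (cc in num_cols) {
    v <- d[[cc]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(conv))
      if (length(bad))
        stop(sprintf("non-numeric value in column '%s', row %d", cc, bad[1]),
             call. = FALSE)
      d[[cc]] <- conv
    }
  }
  key <- interaction(d$subject_id, d$sample_kind, d$acid_kind,
                     d$acid_load_meq_l, drop = TRUE)
  dup <- duplicated(data.frame(key, d$fco2))
  if (any(dup))
    stop(sprintf("duplicate (subject, fco2) at row %d", which(dup)[1]),
         call. = FALSE)
  lapply(split(d, key), function(g) {
    tonometry_series(
      subject_id = g$subject_id[1], group = g$group[1],
      albumin = g$albumin_g_dl[1], hemoglobin = g$hemoglobin_g_dl[1],
      sample_kind = g$sample_kind[1],
      steps = data.frame(fco2 = g$fco2, pco2 = g$pco2_mmhg, ph = g$ph,
                         hco3 = g$hco3_meq_l, so2 = g$so2, na = g$na,
                         k = g$k, ca = g$ca_mmol_l, mg = g$mg_meq_l,
                         cl = g$cl, lac = g$lac, acid_kind = g$acid_kind,
                         acid_load = g$acid_load_meq_l, beta = g$beta))
  })
}

#' Write tonometry series to CSV
#'
#' Inverse of [read_tonometry()]; the round trip is lossless to full
#' double precision for all numeric fields.
#'
#' @param series a list of [tonometry_series()] objects (or a single one).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tonometry <- function(series, path) {
  if (inherits(series, "tonometry_series")) series <- list(series)
  rows <- lapply(series, function(s) {
    st <- s$steps
    data.frame(subject_id = s$subject_id, group = s$group,
               sample_kind = s$sample_kind, albumin_g_dl = s$albumin,
               hemoglobin_g_dl = s$hemoglobin, fco2 = st$fco2,
               pco2_mmhg = st$pco2, ph = st$ph, hco3_meq_l = st$hco3,
               so2 = st$so2, na = st$na, k = st$k, ca_mmol_l = st$ca,
               mg_meq_l = st$mg, cl = st$cl, lac = st$lac,
               acid_kind = st$acid_kind, acid_load_meq_l = st$acid_load,
               beta = st$beta)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(format(out, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Packaged group-mean tonometry fixtures
#'
#' Returns the published group-mean tonometry tables shipped with the
#' package as lists of pseudo-series (one "subject" per group mean):
#' `"table1"` — whole-blood respiratory acidosis in healthy and septic
#' groups, four CO2 steps; `"table2"` — diluted (anemic) vs undiluted
#' whole blood, three CO2 steps; `"table3"` — control and acid-loaded
#' samples at constant CO2, with the published per-sample buffer values in
#' the `beta` column. These are group means, not raw per-subject data.
#'
#' @param table `"table1"`, `"table2"` or `"table3"`.
#' @return A list of [tonometry_series()].
#' @examples
#' fx <- tonometry_fixture("table3")
#' names(fx)
#' @export
tonometry_fixture <- function(table = c("table1", "table2", "table3")) {
  table <- match.arg(table)
  fn <- c(table1 = "table1_whole_blood_means.csv",
          table2 = "table2_dilution_means.csv",
          table3 = "table3_acid_load_means.csv")[[table]]
  path <- system.file("extdata", fn, package = "sidexp", mustWork = TRUE)
  read_tonometry(path)
}
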