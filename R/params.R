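#' Physical constants of the buffer model
#'
#' Collects every constant used by the charge, buffer-value and base-excess
#' equations into a validated list. Defaults reproduce published group-mean
#' tonometry tables; any element can be overridden.
#'
#' @details
#' The titrable charge of a plasma protein is carried by its imidazole
#' groups, with an average dissociation constant `pk_imidazole` (6.75).
#' Albumin contributes `n_albumin` (16) titrable groups per molecule of
#' `mw_albumin` (66,500 g/mol) and is titrated at plasma pH. Hemoglobin is
#' parameterized per tetramer (`mw_hemoglobin` 64,458 g/mol) and titrated at
#' erythrocyte pH, obtained from plasma pH through the linear map
#' `rbc_ph_slope * pH + rbc_ph_intercept`. The hemoglobin group count
#' (`n_hemoglobin` = 27) and the red-cell pH map (slope 0.74, intercept
#' 1.739, giving RBC pH 7.22 at plasma pH 7.40) were calibrated jointly
#' against published titrable-charge grids; see the package vignette.
#'
#' `clsi_slope` and `clsi_intercept` define the standardized (CLSI)
#' whole-blood buffer value `1.43*[Hb] + 7.7` used by blood-gas analyzers.
#' `hco3_ref` (24.26 mEq/L) and `ph_ref` (7.40) are the Lang-Zander
#' reference point of base excess; `r_coeff` (0.0143 per g/dL) sets the
#' bicarbonate distribution ratio `r = 1 - 0.0143*[Hb]` and `s_coeff`
#' (0.2 per g/dL) the desaturation term `s = 0.2*[Hb]*(1 - sO2)`.
#' `hh_pk` (6.105) and `hh_solubility` (0.0307 mMol/L/mmHg) are the
#' Henderson-Hasselbalch constants used by the simulator and consistency
#' checks; measured bicarbonate from the analyzer is used everywhere else.
#'
#' @param ... named overrides of any default listed above.
#' @return An object of class `"buffer_params"`: a named list of constants.
#' @examples
#' p <- buffer_params()
#' p$pk_imidazole
#' buffer_params(n_hemoglobin = 30)$n_hemoglobin
#' @export
buffer_params <- function(...) {
  p <- list(
    pk_imidazole     = 6.75,
    n_albumin        = 16,
    mw_albumin       = 66500,
    n_hemoglobin     = 27,
    mw_hemoglobin    = 64458,
    rbc_ph_slope     = 0.74,
    rbc_ph_intercept = 1.739,
    clsi_slope       = 1.43,
    clsi_intercept   = 7.7,
    hco3_ref         = 24.26,
    ph_ref           = 7.40,
    r_coeff          = 0.0143,
    s_coeff          = 0.2,
    hh_pk            = 6.105,
    hh_solubility    = 0.0307
  )
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over))))
      stop("buffer_params overrides must be named", call. = FALSE)
    unknown <- setdiff(names(over), names(p))
    if (length(unknown))
      stop("unknown buffer_params field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    p[names(over)] <- over
  }
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all buffer_params must be finite and strictly positive", call. = FALSE)
  if (p$pk_imidazole < 6 || p$pk_imidazole > 8)
    stop("pk_imidazole outside [6, 8]", call. = FALSE)
  structure(p, class = "buffer_params")
}

#' @export
print.buffer_params <- function(x, ...) {
  cat("Buffer model constants:\n")
  for (nm in names(x)) cat(sprintf("  %-16s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Read a run configuration file
#'
#' Reads a YAML (or JSON) configuration with optional `params` overrides for
#' [buffer_params()] plus run settings (`experiment`, `beta_mode`, `seed`,
#' and a `scenario` block for the simulator). Unknown top-level keys are
#' rejected so that typos fail loudly.
#'
#' @param path path to a `.yaml`/`.yml`/`.json` file.
#' @return A list with elements `params` (a `buffer_params` object) and any
#'   of `experiment`, `beta_mode`, `seed`, `scenario` present in the file.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  allowed <- c("params", "experiment", "beta_mode", "seed", "scenario",
               "fencl_variant", "output_dir")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg$params <- do.call(buffer_params, as.list(cfg$params))
  cfg
}
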