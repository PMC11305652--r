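#' Plasma strong ion difference
#'
#' SID = \[Na+\] + \[K+\] + \[Ca2+\] + \[Mg2+\] - \[Cl-\] - \[Lac-\], all in
#' mEq/L. Ionized calcium is measured in mMol/L and, being divalent, counts
#' twice; magnesium is taken as already expressed in mEq/L (it is typically
#' measured at baseline only and held constant through a tonometry run).
#'
#' @param na,k,mg,cl,lac concentrations in mEq/L.
#' @param ca ionized calcium in mMol/L (divalent; doubled internally).
#' @return SID in mEq/L. Vectorized over all arguments.
#' @examples
#' compute_sid(na = 142.7, k = 4.48, ca = 1.36, mg = 2.11, cl = 104, lac = 1.7)
#' @export
compute_sid <- function(na, k, ca, mg, cl, lac) {
  vals <- c(na, k, ca, mg, cl, lac)
  if (any(!is.finite(vals)))
    stop("electrolyte concentrations must be finite", call. = FALSE)
  if (any(vals < 0))
    stop("electrolyte concentrations must be non-negative", call. = FALSE)
  na + k + 2 * ca + mg - cl - lac
}

#' Titrable imidazole charge of a protein
#'
#' The positive, pH-dependent charge carried by a protein's imidazole
#' groups: `Z = c * n * 10^(-pH) / (10^(-pK) + 10^(-pH))`, with `c` the
#' protein concentration in mMol/L and `n` the number of titrable groups
#' per molecule. `Z` is bounded by `(0, c*n)`, strictly decreasing in pH,
#' and equals `c*n/2` at pH = pK.
#'
#' @param c_mmol protein concentration, mMol/L.
#' @param n titrable groups per molecule.
#' @param ph pH at the protein's location (plasma for albumin, erythrocyte
#'   for hemoglobin).
#' @param pk average dissociation constant of the imidazole groups.
#' @return charge in mEq/L. Vectorized over `ph` (and `c_mmol`).
#' @export
titrable_charge <- function(c_mmol, n, ph, pk = 6.75) {
  if (any(!is.finite(c(c_mmol, n, ph, pk))))
    stop("titrable_charge: non-finite input", call. = FALSE)
  if (any(c_mmol < 0)) stop("protein concentration must be >= 0", call. = FALSE)
  if (n <= 0) stop("n must be > 0", call. = FALSE)
  c_mmol * n * 10^(-ph) / (10^(-pk) + 10^(-ph))
}

#' Albumin titrable charge at plasma pH
#'
#' Converts albumin from g/dL to mMol/L via its molecular weight and
#' evaluates [titrable_charge()] with the albumin group count at plasma pH.
#'
#' @param albumin albumin, g/dL.
#' @param ph plasma pH.
#' @param params a [buffer_params()] object.
#' @return charge in mEq/L. Vectorized over `ph` (and `albumin`).
#' @examples
#' albumin_zph(4.8, 7.07)
#' @export
albumin_zph <- function(albumin, ph, params = buffer_params()) {
  titrable_charge(albumin * 1e4 / params$mw_albumin, params$n_albumin,
                  ph, params$pk_imidazole)
}

#' Erythrocyte pH from plasma pH
#'
#' Linear map `rbc_ph_slope * pH + rbc_ph_intercept`. Red-cell pH runs
#' below plasma pH under physiologic conditions (about 7.22 at plasma 7.40
#' with defaults) because hemoglobin's net negative charge holds protons
#' inside the cell at the Donnan equilibrium.
#'
#' @inheritParams albumin_zph
#' @return erythrocyte pH, same length as `ph`.
#' @export
rbc_ph <- function(ph, params = buffer_params()) {
  params$rbc_ph_slope * ph + params$rbc_ph_intercept
}

#' Hemoglobin titrable charge at erythrocyte pH
#'
#' Hemoglobin is parameterized per tetramer: g/dL is converted to mMol/L of
#' tetramer via `mw_hemoglobin`, and [titrable_charge()] is evaluated with
#' `n_hemoglobin` groups at [rbc_ph()] of the plasma pH. A per-monomer
#' parameterization with `n/4` groups and `mw/4` gives identical results.
#'
#' @param hb hemoglobin, g/dL.
#' @inheritParams albumin_zph
#' @return charge in mEq/L. Vectorized over `ph` (and `hb`).
#' @examples
#' hemoglobin_zph(14.2, 7.46)
#' @export
hemoglobin_zph <- function(hb, ph, params = buffer_params()) {
  titrable_charge(hb * 1e4 / params$mw_hemoglobin, params$n_hemoglobin,
                  rbc_ph(ph, params), params$pk_imidazole)
}

#' Expected plasma SID from protein charge changes
#'
#' The plasma SID expected from electrolyte/water redistribution alone:
#' baseline SID plus the change (from baseline) in albumin — and, for whole
#' blood, hemoglobin — titrable charge. For isolated plasma pass
#' `dz_hemoglobin = 0`.
#'
#' @param sid_baseline measured SID at the baseline step, mEq/L.
#' @param dz_albumin change in albumin charge from baseline, mEq/L.
#' @param dz_hemoglobin change in hemoglobin charge from baseline, mEq/L.
#' @return expected SID, mEq/L.
#' @export
expected_sid <- function(sid_baseline, dz_albumin, dz_hemoglobin = 0) {
  sid_baseline + dz_albumin + dz_hemoglobin
}

#' Expected plasma SID from a buffer value
#'
#' `SID_exp = SID(baseline) - beta * (pH - pH(baseline))`: the buffer-value
#' route to the expected SID, usable with a fitted noncarbonic buffer value
#' or with the standardized [beta_clsi()] value.
#'
#' @inheritParams expected_sid
#' @param ph_baseline plasma pH at the baseline step.
#' @param ph plasma pH of the step being predicted.
#' @param beta noncarbonic buffer value, mEq/L per pH unit (> 0).
#' @return expected SID, mEq/L. Vectorized over `ph`.
#' @export
expected_sid_beta <- function(sid_baseline, ph_baseline, ph, beta) {
  if (any(beta <= 0)) stop("beta must be > 0", call. = FALSE)
  sid_baseline - beta * (ph - ph_baseline)
}

#' Standardized (CLSI) whole-blood buffer value
#'
#' `beta = 1.43 * [Hb] + 7.7` mEq/L per pH unit, the buffer value assumed
#' by bedside blood-gas analyzers. With `hb = 0` it reduces to the
#' plasma-like value 7.7.
#'
#' @inheritParams hemoglobin_zph
#' @return buffer value, mEq/L per pH unit.
#' @export
beta_clsi <- function(hb, params = buffer_params()) {
  if (any(hb < 0)) stop("hb must be >= 0", call. = FALSE)
  params$clsi_slope * hb + params$clsi_intercept
}

#' Bicarbonate distribution ratio
#'
#' `r = 1 - 0.0143 * [Hb]`: the fraction of a whole-blood bicarbonate (or
#' strong-ion) change that appears in plasma, reflecting partition between
#' plasma and erythrocyte water.
#'
#' @inheritParams hemoglobin_zph
#' @return ratio in (0, 1].
#' @export
bicarbonate_ratio <- function(hb, params = buffer_params()) {
  if (any(hb < 0)) stop("hb must be >= 0", call. = FALSE)
  r <- 1 - params$r_coeff * hb
  if (any(r <= 0))
    stop("hemoglobin too high: bicarbonate ratio would be <= 0", call. = FALSE)
  r
}

#' Whole-blood base excess (Lang-Zander)
#'
#' `BE = r * [(HCO3 - 24.26) + beta * (pH - 7.4)] - s`, with
#' `r = 1 - 0.0143*[Hb]` the bicarbonate distribution ratio and
#' `s = 0.2*[Hb]*(1 - sO2)` the hemoglobin-desaturation correction.
#' BE is exactly 0 at (HCO3 = 24.26, pH = 7.40, sO2 = 1) for any beta.
#'
#' @param hco3 plasma bicarbonate, mEq/L.
#' @param ph plasma pH.
#' @param beta noncarbonic buffer value, mEq/L per pH unit.
#' @param hb hemoglobin, g/dL.
#' @param so2 hemoglobin oxygen saturation as a fraction in \[0, 1\]
#'   (tonometry at 21\% O2 keeps samples fully saturated, hence default 1).
#' @param params a [buffer_params()] object.
#' @return base excess, mEq/L. Vectorized over step quantities.
#' @examples
#' base_excess(hco3 = 15.3, ph = 7.18, beta = 33.1, hb = 13.9)
#' @export
base_excess <- function(hco3, ph, beta, hb, so2 = 1,
                        params = buffer_params()) {
  if (any(beta <= 0)) stop("beta must be > 0", call. = FALSE)
  r <- bicarbonate_ratio(hb, params)
  r * ((hco3 - params$hco3_ref) + beta * (ph - params$ph_ref)) -
    params$s_coeff * hb * (1 - so2)
}

#' Change in whole-blood SID
#'
#' `dSID_wb = r * (SID - SID_exp)`: the deviation of measured plasma SID
#' from its expectation, scaled to whole blood by the bicarbonate
#' distribution ratio. Under the model this equals the change in base
#' excess caused by true (non-redistributive) strong-ion loads.
#'
#' @param sid measured plasma SID, mEq/L.
#' @param sid_expected expected plasma SID, mEq/L (from [expected_sid()],
#'   [expected_sid_beta()] or the CLSI route).
#' @param r bicarbonate distribution ratio in (0, 1\], see
#'   [bicarbonate_ratio()].
#' @return whole-blood SID change, mEq/L.
#' @export
delta_sid_wb <- function(sid, sid_expected, r) {
  if (any(r <= 0) || any(r > 1)) stop("r must lie in (0, 1]", call. = FALSE)
  r * (sid - sid_expected)
}

#' Bicarbonate from pH and PCO2 (Henderson-Hasselbalch)
#'
#' `HCO3 = sol * PCO2 * 10^(pH - pK')` with the CLSI convention pK' 6.105,
#' solubility 0.0307 mMol/L/mmHg. Used by the simulator and consistency
#' checks; analyzers report bicarbonate directly.
#'
#' @param ph plasma pH.
#' @param pco2 carbon dioxide partial pressure, mmHg (> 0).
#' @inheritParams albumin_zph
#' @return bicarbonate, mEq/L. Vectorized.
#' @export
hh_bicarbonate <- function(ph, pco2, params = buffer_params()) {
  if (any(pco2 <= 0)) stop("pco2 must be > 0", call. = FALSE)
  params$hh_solubility * pco2 * 10^(ph - params$hh_pk)
}
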