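# build a minimal whole-blood series with given (ph, hco3) points
make_series <- function(ph, hco3, fco2 = seq(0.02, 0.20, length.out = length(ph)),
                        albumin = 4.8, hemoglobin = 14.2, na = 140, k = 4.2,
                        ca = 1.2, mg = 2.1, cl = 105, lac = 1.6,
                        acid_kind = "none", acid_load = 0, ...) {
  tonometry_series(
    subject_id = "t", group = "healthy", albumin = albumin,
    hemoglobin = hemoglobin,
    steps = data.frame(fco2 = fco2, pco2 = 713 * fco2, ph = ph, hco3 = hco3,
                       na = na, k = k, ca = ca, mg = mg, cl = cl, lac = lac,
                       acid_kind = acid_kind, acid_load = acid_load), ...)
}

# printed group-mean grids used as oracles in several files
table1_healthy <- data.frame(
  ph = c(7.61, 7.46, 7.24, 7.07),
  z_alb = c(1.4, 1.9, 2.8, 3.7),
  z_hb = c(11.2, 13.7, 17.9, 22.9))
table1_sepsis <- data.frame(
  ph = c(7.56, 7.41, 7.17, 6.98),
  z_alb = c(1.0, 1.4, 2.1, 2.7),
  z_hb = c(8.7, 10.7, 14.3, 17.4))
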