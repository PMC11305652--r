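test_that("SID arithmetic counts divalent calcium twice", {
  expect_equal(compute_sid(142.7, 4.48, 1.36, 2.11, 104, 1.7), 46.31)
  expect_equal(compute_sid(139.2, 4.10, 1.09, 2.02, 110, 1.9), 35.60)
  expect_equal(compute_sid(0, 0, 0, 0, 0, 0), 0)
  expect_error(compute_sid(NA, 4, 1, 2, 100, 1), "finite")
  expect_error(compute_sid(140, 4, 1, 2, -1, 1), "non-negative")
})

test_that("titrable charge is bounded, monotone and half-titrated at pK", {
  cn <- 0.722 * 16
  expect_equal(titrable_charge(0.722, 16, ph = 6.75, pk = 6.75), cn / 2,
               tolerance = 1e-12)
  ph <- seq(6.0, 8.2, by = 0.05)
  z <- titrable_charge(0.722, 16, ph)
  expect_true(all(z > 0 & z < cn))
  expect_true(all(diff(z) < 0))
  expect_error(titrable_charge(0.7, 16, Inf), "non-finite")
})

test_that("albumin charge reproduces the printed healthy-subject grid", {
  # all four printed cells with 16 groups / MW 66,500
  z <- albumin_zph(4.8, table1_healthy$ph)
  expect_true(all(abs(z - table1_healthy$z_alb) <= 0.1))
  z_sep <- albumin_zph(3.1, table1_sepsis$ph)
  expect_true(all(abs(z_sep - table1_sepsis$z_alb) <= 0.1))
  expect_equal(albumin_zph(0, 7.4), 0)
  # delegation identity: g/dL -> mMol/L conversion then titrable_charge
  expect_equal(albumin_zph(5.0, 7.24),
               titrable_charge(5.0 * 1e4 / 66500, 16, 7.24, 6.75))
})

test_that("red-cell pH map is linear, increasing, below plasma pH", {
  p_id <- buffer_params(rbc_ph_slope = 1, rbc_ph_intercept = 1e-12)
  expect_equal(rbc_ph(7.31, p_id), 7.31, tolerance = 1e-9)
  ph <- seq(6.8, 8.0, by = 0.1)
  out <- rbc_ph(ph)
  expect_true(all(diff(out) > 0))
  expect_true(all(out < ph))
  # calibrated default map at plasma 7.40
  expect_equal(rbc_ph(7.40), 0.74 * 7.40 + 1.739)
})

test_that("hemoglobin charge matches the calibrated printed grid", {
  expect_equal(hemoglobin_zph(0, 7.4), 0)
  z_h <- hemoglobin_zph(14.2, table1_healthy$ph)
  expect_true(all(abs(z_h - table1_healthy$z_hb) <= 0.7))
  z_s <- hemoglobin_zph(10.4, table1_sepsis$ph)
  expect_true(all(abs(z_s - table1_sepsis$z_hb) <= 0.7))
  expect_lt(abs(hemoglobin_zph(14.2, 7.46) - 13.7), 0.5)
  expect_lt(abs(hemoglobin_zph(14.2, 7.07) - 22.9), 0.7)
})

test_that("per-tetramer and per-monomer hemoglobin parameterizations agree", {
  p4 <- buffer_params()
  p1 <- buffer_params(n_hemoglobin = p4$n_hemoglobin / 4,
                      mw_hemoglobin = p4$mw_hemoglobin / 4)
  ph <- seq(6.8, 7.8, by = 0.1)
  expect_equal(hemoglobin_zph(14.2, ph, p1), hemoglobin_zph(14.2, ph, p4),
               tolerance = 1e-12)
})

test_that("expected SID recovers printed cells from printed charge rows", {
  expect_equal(expected_sid(36.6, 0, 0), 36.6)
  # sepsis 12%: baseline (5%) SID plus printed charge changes
  expect_equal(expected_sid(33.4, 2.1 - 1.4, 14.3 - 10.7), 37.7)
  # healthy 2%
  expect_lt(abs(expected_sid(36.6, 1.4 - 1.9, 11.2 - 13.7) - 33.5), 0.2)
})

test_that("buffer-value route to expected SID", {
  expect_equal(expected_sid_beta(42.9, 7.40, 7.40, 28.5), 42.9)
  expect_equal(expected_sid_beta(42.9, 7.40, 7.18, 33.1), 50.182)
  expect_equal(expected_sid_beta(42.9, 7.40, 7.30, 30.6), 45.96)
  expect_error(expected_sid_beta(42.9, 7.4, 7.3, -1), "beta")
})

test_that("CLSI buffer value and bicarbonate distribution ratio", {
  expect_equal(beta_clsi(0), 7.7)
  expect_equal(beta_clsi(10), 22.0)
  expect_equal(beta_clsi(14.2), 28.006)
  expect_equal(bicarbonate_ratio(0), 1)
  expect_equal(bicarbonate_ratio(13.9), 1 - 0.0143 * 13.9)
  expect_equal(bicarbonate_ratio(10.4), 0.85128)
  expect_error(bicarbonate_ratio(80), "too high")
})

test_that("base excess vanishes at the reference point and tracks the s term", {
  for (beta in c(10, 28.5, 40))
    expect_equal(base_excess(24.26, 7.40, beta, hb = 13.9, so2 = 1), 0)
  # pure desaturation term
  expect_equal(base_excess(24.26, 7.40, 28, hb = 10, so2 = 0.5), -1.0)
  # acid-load column means, differenced against the control column
  be_lac15 <- base_excess(15.3, 7.18, 33.1, 13.9)
  be_ctr <- base_excess(24.8, 7.40, 28.5, 13.9)
  expect_equal(be_lac15, -13.01, tolerance = 0.005)
  expect_lt(abs((be_lac15 - be_ctr) - (-13.4)), 0.1)
})

test_that("whole-blood SID change scales the plasma deviation by r", {
  expect_equal(delta_sid_wb(40, 40, 0.8), 0)
  expect_lt(abs(delta_sid_wb(37.5, 45.96, 0.80123) - (-6.7)), 0.2)
  expect_lt(abs(delta_sid_wb(33.3, 50.314, 0.80123) - (-13.5)), 0.2)
  expect_error(delta_sid_wb(40, 40, 0), "r must")
})

test_that("Henderson-Hasselbalch bicarbonate is consistent and monotone", {
  p <- buffer_params()
  expect_equal(hh_bicarbonate(p$hh_pk, 40), 0.0307 * 40)
  expect_lt(abs(hh_bicarbonate(7.40, 40) - 24.26), 0.2)
  expect_true(all(diff(hh_bicarbonate(seq(6.8, 7.8, 0.1), 40)) > 0))
  expect_true(all(diff(hh_bicarbonate(7.4, seq(20, 120, 10))) > 0))
  expect_error(hh_bicarbonate(7.4, 0), "pco2")
})

test_that("buffer parameter validation rejects bad overrides", {
  expect_error(buffer_params(nope = 1), "unknown")
  expect_error(buffer_params(pk_imidazole = 9), "pk_imidazole")
  expect_error(buffer_params(hco3_ref = -1), "positive")
  expect_equal(buffer_params(n_hemoglobin = 30)$n_hemoglobin, 30)
})
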