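test_that("subject sampling follows the group distributions", {
  set.seed(3)
  alb <- replicate(10000, sample_subject("healthy")$albumin)
  expect_lt(abs(mean(alb) - 4.8), 0.05)
  expect_lt(abs(sd(alb) - 0.2), 0.03)  # slight shrinkage from +-3 SD truncation
  # panel chloride is solved so the baseline panel hits the drawn SID exactly
  sub <- sample_subject("septic")
  expect_equal(compute_sid(sub$panel$na, sub$panel$k, sub$panel$ca,
                           sub$panel$mg, sub$panel$cl, sub$panel$lac),
               sub$sid0, tolerance = 1e-12)
})

test_that("pH solver inverts the base-excess equation", {
  expect_lt(abs(solve_ph(40, 0, 28, 14) - 7.40), 0.01)
  # round trip at tight tolerance
  for (be in c(-12, -5, 0, 4)) {
    ph <- solve_ph(55, be, 30, 12)
    expect_lt(abs(base_excess(hh_bicarbonate(ph, 55), ph, 30, 12) - be), 1e-9)
  }
  expect_lt(solve_ph(120, 0, 28, 14), 7.15)
  phs <- vapply(c(20, 40, 80, 160), solve_ph, 0, be_target = 0,
                beta = 28, hb = 14)
  expect_true(all(diff(phs) < 0))
  expect_error(solve_ph(20, -100, 28, 14), "no pH")
})

test_that("electrolyte redistribution hits the target SID exactly", {
  panel <- data.frame(na = 140, k = 4.2, ca = 1.2, mg = 2.1, cl = 105,
                      lac = 1.6)
  sid0 <- compute_sid(panel$na, panel$k, panel$ca, panel$mg, panel$cl,
                      panel$lac)
  expect_equal(redistribute_electrolytes(sid0, panel), panel)
  for (target in c(sid0 - 8, sid0 + 5, sid0 + 12)) {
    out <- redistribute_electrolytes(target, panel, "lactic", 7.5)
    expect_equal(compute_sid(out$na, out$k, out$ca, out$mg, out$cl, out$lac),
                 target, tolerance = 1e-12)
    expect_equal(out$lac, panel$lac + 7.5)  # acid anion stays in plasma
  }
  expect_error(redistribute_electrolytes(40, panel, split = c(cl = 0.5)),
               "sum to 1")
  expect_error(redistribute_electrolytes(40, panel, "none", 5), "acid_kind")
})

test_that("respiratory run moves chloride and sodium like the chloride shift", {
  sc <- simulation_scenario(group = "healthy", n_subjects = 1,
                            fco2_levels = c(0.02, 0.05, 0.12, 0.20),
                            noise = 0, seed = 5)
  sim <- simulate_tonometry(sc)
  st <- sim$data[[1]]$steps  # sorted by fco2: pH falls, SID rises
  expect_true(all(diff(st$cl) < 0))
  expect_true(all(diff(st$na) > 0))
})

test_that("seeded simulation is bit-reproducible", {
  sc <- simulation_scenario(n_subjects = 3, seed = 99)
  expect_identical(simulate_tonometry(sc), simulate_tonometry(sc))
  sc2 <- simulation_scenario(n_subjects = 3, seed = 100)
  expect_false(identical(simulate_tonometry(sc)$truth$steps,
                         simulate_tonometry(sc2)$truth$steps))
})

test_that("noise-free output is internally consistent to 1e-9", {
  loads <- data.frame(kind = c("none", "lactic"), load = c(0, 10))
  sc <- simulation_scenario(group = "experiment3", n_subjects = 3,
                            fco2_levels = c(0.02, 0.056, 0.12, 0.20),
                            acid_loads = loads, noise = 0, seed = 8)
  sim <- simulate_tonometry(sc)
  p <- buffer_params()
  tr <- sim$truth$steps
  # every step satisfies Henderson-Hasselbalch and the base-excess relation
  expect_equal(tr$hco3, hh_bicarbonate(tr$ph, tr$pco2, p), tolerance = 1e-9)
  hb <- sim$truth$subjects$hemoglobin[match(tr$subject_id,
                                            sim$truth$subjects$subject_id)]
  beta <- sim$truth$subjects$beta_true[match(tr$subject_id,
                                             sim$truth$subjects$subject_id)]
  expect_lt(max(abs(base_excess(tr$hco3, tr$ph, beta, hb) - tr$be_true)), 1e-9)

  # analysis round trip: fitted buffer value and recovered acid load
  rep3 <- run_experiment(sim$data, "exp3")
  for (f in rep3$fits) {
    truth <- sim$truth$subjects[sim$truth$subjects$subject_id ==
                                  f$series$subject_id, ]
    expect_lt(abs(f$beta - truth$beta_true), 0.1)
  }
  acid <- rep3$derived[rep3$derived$acid_load > 0, ]
  expect_lt(max(abs(acid$delta_be - (-acid$acid_load))), 0.1)
  expect_lt(max(abs(acid$delta_sid_wb - (-acid$acid_load))), 0.1)
})

test_that("fitted and CLSI buffer values coincide on CLSI-generated data", {
  sc <- simulation_scenario(n_subjects = 3, noise = 0, seed = 21,
                            beta_source = "clsi")
  sim <- simulate_tonometry(sc)
  for (s in sim$data)
    expect_lt(abs(estimate_beta(s) - beta_clsi(s$hemoglobin)), 1e-6)
})

test_that("healthy respiratory scenario spans a physiologic pH and SID range", {
  sc <- simulation_scenario(group = "healthy", n_subjects = 5, seed = 17,
                            fco2_levels = c(0.02, 0.05, 0.12, 0.20))
  sim <- simulate_tonometry(sc)
  for (s in sim$data) {
    st <- s$steps
    expect_true(all(diff(st$ph) < 0))           # pH falls as CO2 rises
    expect_gt(max(st$ph), 7.5)
    expect_lt(min(st$ph), 7.2)
    rise <- compute_sid(st$na[4], st$k[4], st$ca[4], st$mg[4], st$cl[4],
                        st$lac[4]) -
      compute_sid(st$na[1], st$k[1], st$ca[1], st$mg[1], st$cl[1], st$lac[1])
    expect_gt(rise, 8); expect_lt(rise, 18)
  }
})

test_that("acid-mass bookkeeping is exact", {
  loads <- data.frame(kind = c("none", "lactic", "hcl"), load = c(0, 7.5, 15))
  sc <- simulation_scenario(group = "experiment3", n_subjects = 2,
                            acid_loads = loads, noise = 0, seed = 31)
  sim <- simulate_tonometry(sc)
  tr <- sim$truth$steps
  expect_setequal(unique(tr$acid_load), c(0, 7.5, 15))
  for (s in sim$data) {
    load <- s$steps$acid_load[1]
    if (s$steps$acid_kind[1] == "lactic" && load > 0) {
      base <- sim$data[[paste0(s$subject_id, "_none_0")]]
      # plasma lactate rise never exceeds the configured load
      expect_true(all(s$steps$lac - base$steps$lac <= load + 1e-9))
    }
    # ground truth records the configured load exactly
    key <- tr$subject_id == s$subject_id & tr$acid_kind == s$steps$acid_kind[1]
    expect_true(all(tr$acid_load[key] == load))
  }
})
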