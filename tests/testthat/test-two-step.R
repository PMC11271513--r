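test_that("two-step parameter validation and preset calibration", {
  expect_error(two_step_params(-1, 1, 1, 1), "non-negative")
  p <- two_step_preset("ksi6666")
  # encounter Kd 30 nM, apparent Kd 6 nM, tight-state residence 9.41 h
  expect_equal(p$k_1 / p$k1, 30)
  expect_equal((p$k_1 / p$k1) / (1 + p$k2 / p$k_2), 6, tolerance = 1e-12)
  koff_eff <- p$k_2 * p$k_1 / (p$k_1 + p$k2)
  expect_equal(log(2) / koff_eff, 9.41, tolerance = 0.02)
  w <- two_step_preset("w146")
  expect_equal(w$k2, 0)
  expect_equal(log(2) / w$k_1, 0.2, tolerance = 1e-12)
  c4 <- two_step_preset("compound4")
  expect_equal(log(2) / (c4$k_2 * c4$k_1 / (c4$k_1 + c4$k2)), 0.98,
               tolerance = 0.02)
})

test_that("receptor species are conserved along the ODE solution", {
  p <- two_step_preset("ksi6666")
  sol <- metakin:::integrate_two_step(p, c(RA = 0, RI = 0, RIs = 0),
                                      agonist_conc = 50, inhibitor_conc = 100,
                                      duration = 5, n_out = 101)
  species <- sol[, c("RA", "RI", "RIs")]
  free <- 1 - rowSums(species)
  expect_true(all(species >= -1e-8 & species <= 1 + 1e-8))
  expect_true(all(free >= -1e-8 & free <= 1 + 1e-8))
})

test_that("no pretreatment means full agonist response", {
  s <- simulate_two_step_competition(two_step_preset("ksi6666"), 0)
  expect_equal(s$emax, 100, tolerance = 1e-6)
  expect_true(all(abs(s$table$response - 100) < 1e-6))
})

test_that("surmountable antagonist is fully displaced at long readout", {
  ev <- emax_vs_pretreatment(two_step_preset("w146"),
                             pretreat_grid = c(1, 10, 100, 1000),
                             readout_time = 10,
                             agonist_concs = 10^seq(-1, 5, 0.5))
  expect_true(all(abs(ev$emax - 100) < 1))
})

test_that("pseudoirreversible preset depresses Emax with pretreatment", {
  ev <- emax_vs_pretreatment(two_step_preset("ksi6666"),
                             pretreat_grid = c(1, 10, 100, 1000))
  expect_true(all(diff(ev$emax) < 0))
  expect_lt(ev$emax[4], 90)
})

test_that("frozen tight-state limit matches the closed-form Emax", {
  # washout with k_2 = 0: receptors in the tight complex at agonist
  # addition never return, and each remaining encounter complex either
  # isomerizes (k2) into the trap or releases (k_1) into the agonist pool,
  # so the unavailable fraction is RIs + RI * k2 / (k2 + k_1)
  p <- two_step_params(k1 = 0.2, k_1 = 6, k2 = 20, k_2 = 0)
  s <- simulate_two_step_competition(p, pretreat_conc = 30,
                                     pretreat_time = 0.15,
                                     agonist_concs = 10^seq(0, 3, 0.5),
                                     readout_time = 20, washout = TRUE)
  frozen <- s$species[["RIs"]] +
    s$species[["RI"]] * p$k2 / (p$k2 + p$k_1)
  expect_equal(s$emax, 100 * (1 - frozen), tolerance = 0.02)
})

test_that("zero-length pretreatment is rejected, empty grid rejected", {
  p <- two_step_preset("ksi6666")
  expect_error(simulate_two_step_competition(p, 10, pretreat_time = 0),
               "positive")
  expect_error(emax_vs_pretreatment(p, pretreat_grid = c(10, 5)),
               "increasing")
})

test_that("occupancy ODE matches closed forms in limiting regimes", {
  # no drug: pure exponential decay of occupancy
  occ <- simulate_receptor_occupancy_pk(list(c0 = 0, kel = 0.1), kon = 0.01,
                                        koff = 0.5, duration = 10,
                                        n_grid = 101, occ0 = 1)
  expect_equal(occ$occupancy, exp(-0.5 * occ$time), tolerance = 1e-6)
  # constant exposure: Langmuir steady state C / (C + koff/kon)
  occ2 <- simulate_receptor_occupancy_pk(list(c0 = 20, kel = 0), kon = 0.05,
                                         koff = 0.5, duration = 40,
                                         n_grid = 201)
  expect_equal(occ2$occupancy[201], 20 / (20 + 0.5 / 0.05), tolerance = 1e-6)
  expect_true(all(occ2$occupancy >= 0 & occ2$occupancy <= 1))
})

test_that("slow dissociation sustains occupancy after exposure falls", {
  pk <- list(c0 = 100, kel = log(2) / 6.65)
  slow <- simulate_receptor_occupancy_pk(pk, kon = 0.01,
                                         koff = log(2) / 9.41)
  fast <- simulate_receptor_occupancy_pk(pk, kon = 0.01,
                                         koff = log(2) / 0.98)
  o32 <- function(o) o$occupancy[which.min(abs(o$time - 32))]
  expect_gt(o32(slow), o32(fast))
  # the slow compound's occupancy outlasts the pharmacokinetic half-life
  expect_gt(persistence_metric(slow, 0.5), 6.65)
  expect_lt(persistence_metric(fast, 0.5), 6.65)
})

test_that("persistence metric integrates time above threshold", {
  occ <- structure(data.frame(time = 0:10, conc = 0,
                              occupancy = rep(1, 11)),
                   class = c("occupancy_timecourse", "data.frame"))
  expect_equal(persistence_metric(occ, 0.5), 10)
  occ$occupancy <- rep(0.2, 11)
  expect_equal(persistence_metric(occ, 0.5), 0)
  # linear crossing: above threshold from t = 0 until y drops through 0.5
  occ$occupancy <- seq(1, 0, length.out = 11)
  expect_equal(persistence_metric(occ, 0.5), 5)
  expect_error(persistence_metric(occ, 1.5), "threshold")
  # monotone in residence time at fixed exposure
  pk <- list(c0 = 50, kel = 0.2)
  dur <- vapply(c(2, 1, 0.5, 0.25, 0.1), function(koff)
    persistence_metric(simulate_receptor_occupancy_pk(pk, 0.02, koff), 0.3),
    numeric(1))
  expect_true(all(diff(dur) >= 0))
})
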