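test_that("assembled topology has the expected structure", {
  ind <- reference_individual()
  rux <- builtin_compound("ruxolitinib")
  m1 <- assemble_model(ind, rux, rux_bid_regimen(duration_days = 1))
  expect_s3_class(m1, "pbpk_model")
  expect_equal(m1$n_state, 78L)
  expect_length(m1$state_names, 78L)
  # two compounds with interaction: victim flagged inhibitable
  pos <- builtin_compound("posaconazole")
  m2 <- assemble_model(ind, list(rux, pos),
                       list(rux_bid_regimen(1), pos_qd_regimen(300, 1)))
  expect_equal(m2$inhibitable, c(TRUE, FALSE))
  # interaction demanded but impossible
  expect_error(assemble_model(ind, list(rux, rux),
                              list(rux_bid_regimen(1), rux_bid_regimen(1)),
                              interactions = TRUE),
               "no perpetrator Ki")
})

test_that("zero dose yields identically zero concentrations", {
  ind <- reference_individual()
  rux <- builtin_compound("ruxolitinib")
  reg <- rux_bid_regimen(duration_days = 1, dose_mg = 0)
  res <- simulate_profile(assemble_model(ind, rux, reg))
  expect_true(all(res$profiles$conc_ng_mL == 0))
})

test_that("one-compartment reduction matches the closed form to < 0.01%", {
  ind <- reference_individual()
  k <- 0.3
  probe <- probe_compound(k_el_per_h = k)
  reg <- iv_bolus_regimen("probe", dose_mg = 10, duration_days = 2)
  m <- assemble_model(ind, probe, reg, minimal = TRUE)
  res <- simulate_profile(m, grid_h = 0.1, rtol = 1e-10, atol = 1e-12)
  v_ven <- unname(ind$blood_L[["venous_L"]])
  pred <- res$profiles$conc_ng_mL
  tt <- res$profiles$time_h
  c0 <- 10 / 300 * 1000 / v_ven * 300     # mg -> umol -> ng/mL via MW
  analytic <- c0 * exp(-k * tt)
  sel <- tt > 0
  expect_lt(max(abs(pred[sel] / analytic[sel] - 1)), 1e-4)
})

test_that("mass balance closes to < 1e-6 at all output times", {
  ind <- reference_individual()
  rux <- builtin_compound("ruxolitinib")
  pos <- builtin_compound("posaconazole")
  res1 <- simulate_profile(assemble_model(ind, rux, rux_bid_regimen(3)),
                           duration_h = 72)
  expect_lt(max(res1$mass_balance$residual), 1e-6)
  res2 <- simulate_profile(
    assemble_model(ind, list(rux, pos),
                   list(rux_bid_regimen(3), pos_qd_regimen(300, 3))),
    duration_h = 72, rtol = 1e-8, atol = 1e-10)
  expect_lt(max(res2$mass_balance$residual), 1e-6)
})

test_that("the linear model doubles exposure when the dose doubles", {
  ind <- reference_individual()
  rux <- builtin_compound("ruxolitinib")
  n10 <- nca(simulate_profile(assemble_model(ind, rux,
                                             rux_bid_regimen(2, 10))),
             interval = c(0, 48))
  n20 <- nca(simulate_profile(assemble_model(ind, rux,
                                             rux_bid_regimen(2, 20))),
             interval = c(0, 48))
  expect_equal(n20$cmax_ng_mL / n10$cmax_ng_mL, 2, tolerance = 1e-3)
  expect_equal(n20$auc_last_ng_h_mL / n10$auc_last_ng_h_mL, 2,
               tolerance = 1e-3)
})

test_that("steady-state interval AUC superposes onto the single-dose AUC", {
  ind <- reference_individual()
  rux <- builtin_compound("ruxolitinib")
  ss <- nca(simulate_profile(assemble_model(ind, rux, rux_bid_regimen(10)),
                             rtol = 1e-8, atol = 1e-10),
            interval = c(216, 228))
  sd <- dosing_regimen("ruxolitinib", "oral", 10, schedule = "SD",
                       duration_days = 5,
                       formulation = builtin_formulation("rux_er"))
  auc_inf <- nca(simulate_profile(assemble_model(ind, rux, sd),
                                  rtol = 1e-8, atol = 1e-10),
                 interval = c(0, 120))$auc_last_ng_h_mL
  expect_equal(ss$auc_last_ng_h_mL, auc_inf, tolerance = 0.01)
})

test_that("halving the output grid leaves NCA metrics stable", {
  ind <- reference_individual()
  rux <- builtin_compound("ruxolitinib")
  n1 <- nca(simulate_profile(assemble_model(ind, rux, rux_bid_regimen(2)),
                             grid_h = 0.1), interval = c(12, 24))
  n2 <- nca(simulate_profile(assemble_model(ind, rux, rux_bid_regimen(2)),
                             grid_h = 0.05), interval = c(12, 24))
  expect_lt(abs(n2$cmax_ng_mL / n1$cmax_ng_mL - 1), 0.005)
  expect_lt(abs(n2$auc_last_ng_h_mL / n1$auc_last_ng_h_mL - 1), 0.005)
})

test_that("simulation results are bit-reproducible for fixed inputs", {
  ind <- reference_individual()
  rux <- builtin_compound("ruxolitinib")
  r1 <- simulate_profile(assemble_model(ind, rux, rux_bid_regimen(2)))
  r2 <- simulate_profile(assemble_model(ind, rux, rux_bid_regimen(2)))
  expect_identical(r1$profiles, r2$profiles)
})

test_that("NCA reproduces trapezoid identities", {
  prof <- tibble::tibble(compound = "x", time_h = c(0, 1),
                         conc_ng_mL = c(0, 2))
  n <- nca(prof)
  expect_equal(n$auc_last_ng_h_mL, 1)
  expect_equal(n$cmax_ng_mL, 2)
  const <- tibble::tibble(compound = "x", time_h = 0:10,
                          conc_ng_mL = rep(3, 11))
  nc <- nca(const)
  expect_equal(nc$auc_last_ng_h_mL, 30)
  expect_equal(nc$cmax_ng_mL, 3)
  expect_equal(nc$ctrough_ng_mL, 3)
  # dense exponential decay vs analytic integral
  tt <- seq(0, 24, by = 0.02)
  k <- 0.25
  dec <- tibble::tibble(compound = "x", time_h = tt,
                        conc_ng_mL = 100 * exp(-k * tt))
  nd <- nca(dec)
  expect_equal(nd$auc_last_ng_h_mL, 100 / k * (1 - exp(-k * 24)),
               tolerance = 1e-3)
  expect_error(nca(prof, interval = c(5, 5)), "empty")
})

test_that("tidy/glance/autoplot methods work on simulation results", {
  ind <- reference_individual()
  rux <- builtin_compound("ruxolitinib")
  res <- simulate_profile(assemble_model(ind, rux, rux_bid_regimen(1)))
  td <- tidy(res)
  expect_true(all(c("compound", "time_h", "conc_ng_mL") %in% names(td)))
  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_lt(gl$max_mass_balance_residual, 1e-6)
  expect_s3_class(autoplot(res), "ggplot")
})
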