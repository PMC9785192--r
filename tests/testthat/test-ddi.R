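test_that("competitive-inhibition factor follows its closed form", {
  expect_equal(apparent_clearance_factor(0, 1), 1)
  expect_equal(apparent_clearance_factor(1, 1), 0.5)
  expect_equal(apparent_clearance_factor(9, 1), 0.1)
  expect_error(apparent_clearance_factor(-1, 1))
  expect_error(apparent_clearance_factor(1, 0))
})

test_that("DDI ratios are exact elementwise ratios", {
  mk <- function(cmax, auc) tibble::tibble(
    compound = "x", t_start = 0, t_end = 12, cmax_ng_mL = cmax,
    tmax_h = 1, auc_last_ng_h_mL = auc, ctrough_ng_mL = 0.1)
  same <- ddi_ratio(mk(5, 50), mk(5, 50))
  expect_equal(same$cmax_ratio, 1)
  expect_equal(same$auc_last_ratio, 1)
  r <- ddi_ratio(mk(140.21, 382.17), mk(116.31, 239.88))
  expect_equal(round(r$auc_last_ratio, 2), 1.59)
  expect_equal(round(r$cmax_ratio, 2), 1.21)
  expect_error(ddi_ratio(mk(1, 1), mk(0, 1)), "zero denominator")
  bad <- mk(1, 1); bad$t_end <- 24
  expect_error(ddi_ratio(bad, mk(1, 1)), "identical intervals")
})

test_that("exposure ratios collapse to 1 without a perpetrator signal", {
  ind <- reference_individual()
  rux <- builtin_compound("ruxolitinib")
  pos <- builtin_compound("posaconazole")
  rreg <- rux_bid_regimen(duration_days = 3)
  # perpetrator dose 0
  d0 <- simulate_ddi(list(compound = rux, regimen = rreg),
                     list(compound = pos,
                          regimen = pos_qd_regimen(0, 3)),
                     ind, interval = c(60, 72),
                     rtol = 1e-9, atol = 1e-12)
  expect_lt(abs(glance(d0)$auc_last_ratio - 1), 1e-6)
  expect_lt(abs(glance(d0)$cmax_ratio - 1), 1e-6)
  # Ki -> infinity
  pos_inert <- pos
  pos_inert$interactions <- list(interaction_parameters("CYP3A4",
                                                        ki = 1e6))
  dinf <- simulate_ddi(list(compound = rux, regimen = rreg),
                       list(compound = pos_inert,
                            regimen = pos_qd_regimen(300, 3)),
                       ind, interval = c(60, 72),
                       rtol = 1e-9, atol = 1e-12)
  expect_lt(abs(glance(dinf)$auc_last_ratio - 1), 1e-6)
  expect_lt(abs(glance(dinf)$cmax_ratio - 1), 1e-6)
})

test_that("victim exposure ratio is monotone in perpetrator dose and in 1/Ki", {
  ind <- reference_individual()
  rux <- builtin_compound("ruxolitinib")
  pos <- builtin_compound("posaconazole")
  rreg <- rux_bid_regimen(duration_days = 4)
  ratio_at <- function(dose, ki = 5.22e-3) {
    p <- pos
    p$interactions <- list(interaction_parameters("CYP3A4", ki = ki))
    glance(simulate_ddi(list(compound = rux, regimen = rreg),
                        list(compound = p,
                             regimen = pos_qd_regimen(dose, 4)),
                        ind, interval = c(84, 96),
                        grid_h = 0.1))$auc_last_ratio
  }
  r_dose <- vapply(c(50, 150, 450), ratio_at, numeric(1))
  expect_true(all(diff(r_dose) > 0))
  r_ki <- vapply(c(5.22e-3, 5.22e-2, 5.22e-1), function(k)
    ratio_at(300, ki = k), numeric(1))
  expect_true(all(diff(r_ki) < 0))
})

test_that("gut-wall CYP3A4 makes the oral-victim AUC ratio exceed the i.v. ratio", {
  ratios <- purrr::map_dbl(c(iv = "iv", oral = "oral"), function(rt) {
    st <- mdz_setup(rt, pos_dose = 200, pos_formulation = "pos_sus")
    glance(simulate_ddi(st$victim, st$perpetrator, st$individual,
                        interval = c(168, 180), grid_h = 0.25))$auc_last_ratio
  })
  expect_gt(ratios[["oral"]], ratios[["iv"]])
  expect_gt(ratios[["iv"]], 1)
})

test_that("Ki is recovered to < 1% from noise-free interaction data", {
  st <- mdz_setup("iv", pos_dose = 400, pos_formulation = "pos_sus")
  pop1 <- population_spec(n = 1, age = 30, weight = 73, height = 176,
                          proportion_female = 0, seed = 7)
  des <- study_design(st$victim$compound, st$victim$regimen,
                      n_subjects = 1,
                      sampling_times_h = 168 + c(0.5, 1, 2, 3, 4, 6, 8,
                                                 10, 12, 16),
                      residual_sd_log10 = 0,
                      iiv_cv = c(clearance = 0, fu_p = 0, t50 = 0,
                                 permeability = 0),
                      population = pop1, perpetrator = st$perpetrator,
                      seed = 7)
  ds <- generate_study_dataset(des, grid_h = 0.5)
  fit <- estimate_ki(list(ds), list(st), start = 0.42,
                     bounds = c(1e-4, 1), n_starts = 1, seed = 1,
                     grid_h = 0.5)
  expect_true(fit$converged)
  expect_lt(abs(fit$ki_hat / 5.22e-3 - 1), 0.01)
  # optimizer contract: escapes the literature start value
  obj_start <- fit$trace$objective[1]
  expect_lt(fit$objective_value, obj_start + 1e-12)
  expect_lt(abs(log10(fit$ki_hat / 0.42)), 5)  # moved off the start
})

test_that("ddi_result tidiers and plots work", {
  ind <- reference_individual()
  rux <- builtin_compound("ruxolitinib")
  pos <- builtin_compound("posaconazole")
  dd <- simulate_ddi(list(compound = rux, regimen = rux_bid_regimen(2)),
                     list(compound = pos, regimen = pos_qd_regimen(300, 2)),
                     ind, interval = c(36, 48))
  expect_s3_class(tidy(dd), "tbl_df")
  expect_equal(nrow(glance(dd)), 1)
  expect_s3_class(autoplot(dd), "ggplot")
})
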