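test_that("Weibull dissolution hits its defining points", {
  frm <- formulation_model("weibull", t50_min = 145, shape = 1.67,
                           lag_min = 30)
  expect_equal(weibull_fraction_dissolved(30 + 145, frm), 0.5)
  expect_equal(weibull_fraction_dissolved(c(0, 10, 30), frm), c(0, 0, 0))
  expect_error(weibull_fraction_dissolved(-1, frm))
  # non-decreasing, asymptote 1
  tt <- seq(0, 2000, by = 5)
  ff <- weibull_fraction_dissolved(tt, frm)
  expect_true(all(diff(ff) >= 0))
  expect_gt(weibull_fraction_dissolved(5000, frm), 0.9999)
})

test_that("extended-release tablet profile matches the hand-evaluated formula", {
  rux_er <- builtin_formulation("rux_er")
  # t50 = 15 min, shape = 1.10, lag = 0; hand evaluation at t = 30 min
  hand <- 1 - exp(-log(2) * (30 / 15)^1.10)
  expect_equal(weibull_fraction_dissolved(30, rux_er), hand,
               tolerance = 1e-12)
  expect_equal(hand, 0.77367, tolerance = 1e-4)
})

test_that("particle dissolution rate obeys its limiting cases", {
  sus <- builtin_formulation("pos_sus")
  expect_equal(particle_dissolution_rate(100, 0.79, 0.79, sus), 0)
  expect_equal(particle_dissolution_rate(0, 0, 0.79, sus), 0)
  # supersaturated local fluid cannot give a negative rate
  expect_equal(particle_dissolution_rate(100, 1.0, 0.79, sus), 0)
  expect_error(particle_dissolution_rate(1, 0, 1,
                                         formulation_model("weibull",
                                                           t50_min = 10,
                                                           shape = 1)))
})

test_that("constant-surface dissolution under sink conditions is linear in time", {
  sus <- builtin_formulation("pos_sus")
  m0 <- 50
  rate0 <- particle_dissolution_rate(m0, 0, 0.01, sus,
                                     constant_surface = TRUE,
                                     reference_mass_mg = m0)
  # integrate with small steps; under sink + constant surface the rate
  # is constant, so dissolved mass is rate0 * t
  dt <- 0.01
  t_end <- 2
  solid <- m0; dissolved <- 0
  for (i in seq_len(t_end / dt)) {
    r <- particle_dissolution_rate(solid, 0, 0.01, sus,
                                   constant_surface = TRUE,
                                   reference_mass_mg = m0)
    solid <- solid - r * dt; dissolved <- dissolved + r * dt
  }
  expect_equal(dissolved, rate0 * t_end, tolerance = 1e-3)
})

test_that("precipitation conserves mass and decays supersaturation exponentially", {
  sus <- builtin_formulation("pos_sus")
  seg <- list(solid_mg = 10, dissolved_mg = 40, volume_L = 0.025)
  cs <- 0.8  # mg/mL -> 20 mg at saturation
  # below saturation: unchanged
  seg_lo <- list(solid_mg = 1, dissolved_mg = 5, volume_L = 0.025)
  expect_identical(apply_precipitation(seg_lo, cs, sus), seg_lo)
  # instantaneous: clipped to Cs, mass conserved to machine precision
  out <- apply_precipitation(seg, cs, sus, instantaneous = TRUE)
  expect_equal(out$dissolved_mg, 20)
  expect_equal(out$solid_mg + out$dissolved_mg,
               seg$solid_mg + seg$dissolved_mg, tolerance = 1e-15)
  # first-order: remaining excess follows exp(-k tau)
  tau <- 7
  out2 <- apply_precipitation(seg, cs, sus, dt_min = tau)
  k <- log(2) / sus$precipitation_halflife_min
  expect_equal(out2$dissolved_mg - 20, (40 - 20) * exp(-k * tau),
               tolerance = 1e-12)
  expect_equal(out2$solid_mg + out2$dissolved_mg, 50, tolerance = 1e-12)
})

test_that("gastric emptying slows linearly with meal calories", {
  expect_equal(gastric_emptying_modifier(meal_event(0, 0)), 1)
  m200 <- gastric_emptying_modifier(meal_event(0, 200))
  m841 <- gastric_emptying_modifier(meal_event(0, 841))
  expect_gt(m841, m200)
  expect_gt(m200, 1)
  m0 <- gastric_emptying_modifier(meal_event(0, 0))
  m400 <- gastric_emptying_modifier(meal_event(0, 400))
  m800 <- gastric_emptying_modifier(meal_event(0, 800))
  expect_equal(m400, (m0 + m800) / 2, tolerance = 1e-12)
  expect_error(meal_event(0, -5))
})

test_that("intestinal permeation is linear in permeability and dissolved mass", {
  expect_equal(intestinal_permeation_rate(0, 0.08, 650, 2e-3), 0)
  f1 <- intestinal_permeation_rate(10, 0.08, 650, 2e-3)
  expect_equal(intestinal_permeation_rate(10, 0.08, 650, 4e-3), 2 * f1)
  expect_equal(intestinal_permeation_rate(20, 0.08, 650, 2e-3), 2 * f1)
  # tagged-unit normalization: tablet (cm/s) vs suspension (cm/min)
  p_dr <- normalize_permeability(builtin_formulation("pos_dr")$permeability)
  p_sus <- normalize_permeability(builtin_formulation("pos_sus")$permeability)
  r <- intestinal_permeation_rate(10, 0.08, 650, p_dr) /
    intestinal_permeation_rate(10, 0.08, 650, p_sus)
  expect_equal(r, (4.80e-5 * 60) / 5.05e-5, tolerance = 1e-12)
})

test_that("fed state increases the suspension's absorbed fraction", {
  ind <- reference_individual()
  pos <- builtin_compound("posaconazole")
  sus <- builtin_formulation("pos_sus")
  fabs <- function(meals) {
    reg <- dosing_regimen("posaconazole", "oral", 400, schedule = "SD",
                          duration_days = 3, formulation = sus,
                          meals = meals)
    res <- simulate_profile(assemble_model(ind, pos, reg),
                            rtol = 1e-6, atol = 1e-9)
    res$amounts[nrow(res$amounts), "c1_gi_absorbed"] / 400
  }
  expect_gt(fabs(list(meal_event(0, 841))), fabs(list()))
})

test_that("the extended-release tablet is fully dissolved well before the dosing interval", {
  ind <- reference_individual()
  rux <- builtin_compound("ruxolitinib")
  res <- simulate_profile(assemble_model(ind, rux,
                                         rux_bid_regimen(duration_days = 1)),
                          rtol = 1e-8, atol = 1e-10)
  i6 <- which(abs(res$amounts[, "time"] - 6) < 1e-9)
  undissolved <- sum(res$amounts[i6, grep("c1_U_", colnames(res$amounts))])
  expect_lt(undissolved / 10, 0.01)  # > 99% released by 6 h (< 12 h tau)
})
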