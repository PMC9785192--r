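test_that("near-neutral lipid-free compound partitions like tissue water", {
  ind <- reference_individual()
  neutral <- compound_parameters(
    name = "neutral", molecular_weight = 300, logP = 0, fu_p = 1,
    pka = NULL, solubility_reference = list(value = 1, ph = 7),
    permeability = list(value = 1e-3, unit = "cm/min"),
    partition_method = "rodgers_rowland")
  lean <- reference_physiology()$organs$organ != "adipose"
  for (method in c("rodgers_rowland", "poulin_theil")) {
    kp <- partition_coefficients(neutral, ind, method = method)
    water <- ind$organs$f_ew + ind$organs$f_iw
    # adipose is excluded: its 85% neutral-lipid fraction dominates
    # even at logP = 0 (P = 1)
    expect_true(all(abs(kp$kp[lean] / water[lean] - 1) < 0.2),
                label = paste("method", method))
  }
})

test_that("adipose Kp increases strictly with lipophilicity", {
  ind <- reference_individual()
  kp_ad <- function(logp, method) {
    cmp <- compound_parameters(
      name = "x", molecular_weight = 300, logP = logp, fu_p = 0.1,
      pka = tibble::tibble(value = 4, type = "base"),
      solubility_reference = list(value = 1, ph = 7),
      permeability = list(value = 1e-3, unit = "cm/min"),
      partition_method = method)
    kp <- partition_coefficients(cmp, ind)
    kp$kp[kp$organ == "adipose"]
  }
  for (method in c("rodgers_rowland", "poulin_theil")) {
    vals <- vapply(c(0, 1, 2, 3, 4), kp_ad, numeric(1), method = method)
    expect_true(all(diff(vals) > 0), label = method)
  }
})

test_that("Rodgers-Rowland implementation matches an independent scalar transcription", {
  ind <- reference_individual()
  # weak base (extended class)
  rux <- builtin_compound("ruxolitinib")
  expect_equal(partition_coefficients(rux, ind)$kp, oracle_rr_kp(rux, ind),
               tolerance = 1e-12)
  # moderate-to-strong base (acidic-phospholipid class)
  strong <- compound_parameters(
    name = "strongbase", molecular_weight = 350, logP = 2.5, fu_p = 0.2,
    pka = tibble::tibble(value = 9.1, type = "base"),
    solubility_reference = list(value = 1, ph = 7),
    permeability = list(value = 1e-3, unit = "cm/min"),
    partition_method = "rodgers_rowland", blood_plasma_ratio = 1.2)
  expect_equal(partition_coefficients(strong, ind)$kp,
               oracle_rr_kp(strong, ind), tolerance = 1e-12)
  # organ-order invariance / bit reproducibility
  expect_identical(partition_coefficients(rux, ind),
                   partition_coefficients(rux, ind))
})

test_that("calculated permeability reproduces its calibration anchor and is monotone", {
  expect_equal(calculated_specific_permeability(700.78, 4.32), 1.81e-4,
               tolerance = 1e-3)
  # hand evaluation for the midazolam inputs
  expect_equal(calculated_specific_permeability(325.77, 3.13),
               3.3147e-5 * 10^(0.5 * 3.13) / sqrt(325.77),
               tolerance = 1e-12)
  expect_gt(calculated_specific_permeability(300, 4),
            calculated_specific_permeability(300, 2))
  expect_error(calculated_specific_permeability(-1, 2))
})

test_that("permeability unit tags are mandatory and normalized to cm/min", {
  expect_equal(normalize_permeability(list(value = 4.80e-5, unit = "cm/s")),
               4.80e-5 * 60)
  expect_equal(normalize_permeability(list(value = 5.05e-5, unit = "cm/min")),
               5.05e-5)
  expect_error(normalize_permeability(list(value = 1)), "unit tag")
  expect_error(normalize_permeability(list(value = 1, unit = "m/s")),
               "unsupported")
})

test_that("posaconazole pH-solubility profile passes through both anchors", {
  pos <- builtin_compound("posaconazole")
  expect_equal(ph_solubility(pos, 1), 0.79, tolerance = 2e-3)
  expect_equal(ph_solubility(pos, 7), 0.001, tolerance = 1e-12)
})

test_that("solubility is flat for neutral compounds and non-increasing for bases", {
  neutral <- compound_parameters(
    name = "n", molecular_weight = 200, logP = 1, fu_p = 0.5,
    pka = NULL, solubility_reference = list(value = 0.4, ph = 6.2),
    permeability = list(value = 1e-3, unit = "cm/min"))
  expect_equal(ph_solubility(neutral, c(1, 4, 7, 10)), rep(0.4, 4))

  pos <- builtin_compound("posaconazole")
  ph_grid <- seq(1, 8, by = 0.1)
  s <- ph_solubility(pos, ph_grid)
  expect_true(all(diff(s) <= 1e-12))
})

test_that("compound YAML fixtures round-trip through the loader", {
  pos <- builtin_compound("posaconazole")
  expect_s3_class(pos, "compound_parameters")
  expect_equal(pos$interactions[[1]]$ki, 5.22e-3)
  rux <- builtin_compound("ruxolitinib")
  vals <- purrr::map_dbl(rux$clearances, "value")
  enz <- purrr::map_chr(rux$clearances, "enzyme")
  expect_equal(unname(vals[enz == "CYP3A4"]), 0.46)
  expect_equal(unname(vals[enz == "CYP2C9"]), 0.65)
  expect_error(compound_parameters("bad", 100, 1, fu_p = 2),
               "fu_p")
})
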