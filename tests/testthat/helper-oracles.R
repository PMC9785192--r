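# Independent oracles and shared fixtures for the test suite.

# Straight-line scalar transcription of the Rodgers-Rowland equations,
# written independently of R/partition.R (loops, no vectorization).
oracle_rr_kp <- function(compound, individual) {
  org <- individual$organs
  P <- 10^compound$logP
  fu <- compound$fu_p
  ion <- function(pka_tbl, ph) {
    if (is.null(pka_tbl) || nrow(pka_tbl) == 0) return(0)
    total <- 0
    b <- sort(pka_tbl$value[pka_tbl$type == "base"], decreasing = TRUE)
    run <- 1
    for (pk in b) { run <- run * 10^(pk - ph); total <- total + run }
    a <- sort(pka_tbl$value[pka_tbl$type == "acid"])
    run <- 1
    for (pk in a) { run <- run * 10^(ph - pk); total <- total + run }
    total
  }
  X <- ion(compound$pka, 7.4)
  Y <- ion(compound$pka, 7.0)
  strong_base <- !is.null(compound$pka) &&
    any(compound$pka$type == "base" & compound$pka$value >= 7)
  kp <- numeric(nrow(org))
  for (i in seq_len(nrow(org))) {
    lip <- (P * org$f_nl[i] + (0.3 * P + 0.7) * org$f_np[i]) / (1 + X)
    if (strong_base) {
      hct <- individual$hematocrit
      bp <- compound$blood_plasma_ratio
      kpu_bc <- (bp - (1 - hct)) / (hct * fu)
      y_bc <- ion(compound$pka, 7.22)
      lip_bc <- (P * 0.0017 + (0.3 * P + 0.7) * 0.0029) / (1 + X)
      ka_ap <- (kpu_bc - (1 + y_bc) / (1 + X) * 0.603 - lip_bc) *
        (1 + X) / (0.5 * y_bc)
      if (ka_ap < 0) ka_ap <- 0
      kpu <- org$f_ew[i] + (1 + Y) / (1 + X) * org$f_iw[i] +
        ka_ap * org$ap_mg_g[i] * Y / (1 + X) + lip
    } else {
      pl <- individual$plasma
      plasma_lip <- P * pl[["f_nl"]] + (0.3 * P + 0.7) * pl[["f_np"]]
      prot <- (1 / fu - 1 - plasma_lip)
      if (prot < 0) prot <- 0
      kpu <- org$f_ew[i] + (1 + Y) / (1 + X) * org$f_iw[i] + lip +
        prot * org$ra_tp[i]
    }
    kp[i] <- kpu * fu
  }
  kp
}

# one-compartment probe: fu = 1, single hepatic process giving a known
# first-order elimination rate in the minimal engine topology
probe_compound <- function(k_el_per_h = 0.3,
                           enzyme_conc = 8.6) {
  clspec <- k_el_per_h / (enzyme_conc * 60)
  compound_parameters(
    name = "probe", molecular_weight = 300, logP = 1, fu_p = 1,
    pka = NULL, solubility_reference = list(value = 1, ph = 7),
    permeability = list(value = 1e-3, unit = "cm/min"),
    partition_method = "rodgers_rowland",
    clearances = list(clearance_process("CYP3A4",
                                        "first_order_specific_clearance",
                                        clspec)))
}

iv_bolus_regimen <- function(compound_name, dose_mg, duration_days = 2) {
  dosing_regimen(compound_name, "iv_infusion", dose_mg, schedule = "SD",
                 duration_days = duration_days, infusion_duration_min = 0,
                 formulation = formulation_model("iv_infusion"))
}

reference_individual <- function() build_individual(demographics())

rux_bid_regimen <- function(duration_days = 10, dose_mg = 10) {
  dosing_regimen("ruxolitinib", "oral", dose_mg, schedule = "BID",
                 duration_days = duration_days,
                 formulation = builtin_formulation("rux_er"))
}

pos_qd_regimen <- function(dose_mg = 300, duration_days = 10) {
  dosing_regimen("posaconazole", "oral", dose_mg, schedule = "QD",
                 duration_days = duration_days,
                 formulation = builtin_formulation("pos_dr"))
}

mdz_setup <- function(route = c("iv", "oral"), pos_dose = 200,
                      pos_formulation = "pos_sus") {
  route <- match.arg(route)
  vreg <- if (route == "iv") {
    dosing_regimen("midazolam", "iv_infusion", 0.4, times_h = 7 * 24,
                   infusion_duration_min = 30, duration_days = 8,
                   formulation = builtin_formulation("mdz_iv"))
  } else {
    dosing_regimen("midazolam", "oral", 2, times_h = 7 * 24,
                   duration_days = 8,
                   formulation = builtin_formulation("mdz_oral"))
  }
  preg <- dosing_regimen("posaconazole", "oral", pos_dose,
                         schedule = "QD", duration_days = 8,
                         formulation = builtin_formulation(pos_formulation))
  list(victim = list(compound = builtin_compound("midazolam"),
                     regimen = vreg),
       perpetrator = list(compound = builtin_compound("posaconazole"),
                          regimen = preg),
       individual = reference_individual())
}
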