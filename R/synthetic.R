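#' Dense study design for synthetic concentration-time data
#'
#' Describes a classical rich-sampling PK study: per-subject virtual
#' individuals, log-normal inter-individual variability (IIV) on
#' selected model parameters, fixed nominal sampling times, and
#' multiplicative log-normal residual error.
#'
#' Default IIV coefficients of variation place absorption-related
#' variability inside the 18-73% range reported for the suspension's
#' absorption rate constant and bioavailability.
#'
#' @param compound A [compound_parameters()].
#' @param regimen A [dosing_regimen()].
#' @param n_subjects Number of subjects.
#' @param sampling_times_h Nominal sampling times (h since first dose).
#' @param residual_sd_log10 SD of residual error on the log10 scale.
#' @param iiv_cv Named numeric vector of log-normal CVs; supported
#'   names: `clearance`, `fu_p`, `t50`, `permeability`.
#' @param population A [population_spec()] for the demographic draw.
#' @param perpetrator Optional co-administered perpetrator, a list with
#'   `compound` and `regimen`; the victim is then simulated under the
#'   coupled interaction model.
#' @param seed Integer seed.
#' @return A `study_design` list.
#' @export
study_design <- function(compound, regimen, n_subjects = 10,
                         sampling_times_h,
                         residual_sd_log10 = 0.1,
                         iiv_cv = c(clearance = 0.3, fu_p = 0.1,
                                    t50 = 0.3, permeability = 0.4),
                         population = NULL, perpetrator = NULL,
                         seed = 1L) {
  stopifnot(n_subjects >= 1, residual_sd_log10 >= 0, all(iiv_cv >= 0),
            all(sampling_times_h >= 0),
            all(sampling_times_h <= regimen$duration_days * 24))
  if (is.null(population))
    population <- population_spec(n = n_subjects, seed = seed)
  structure(list(compound = compound, regimen = regimen,
                 n_subjects = as.integer(n_subjects),
                 sampling_times_h = sampling_times_h,
                 residual_sd_log10 = residual_sd_log10,
                 iiv_cv = iiv_cv, population = population,
                 perpetrator = perpetrator,
                 seed = as.integer(seed)),
            class = "study_design")
}

#' Sparse therapeutic-drug-monitoring design
#'
#' Extends [study_design()] with clinical-routine features: few samples
#' per patient at irregular times-since-dose, recorded (nominal) dose
#' times differing from true intake times by a jitter draw, and an
#' assumed co-timing of the perpetrator dose with the victim dose.
#'
#' @inheritParams study_design
#' @param samples_per_subject Length-2 range of samples per patient.
#' @param time_since_dose_range_h Sampling window within the dosing
#'   interval (h since last dose).
#' @param dose_time_jitter_sd_h SD (h) of the discrepancy between true
#'   and recorded time since last dose.
#' @param perpetrator_cotiming_assumed Assume the perpetrator is taken
#'   at the victim's dose times (its dose times are aligned to the
#'   victim's).
#' @param perpetrator Optional co-administered perpetrator (list with
#'   `compound` and `regimen`).
#' @return A `tdm_design` list.
#' @export
tdm_design <- function(compound, regimen, n_subjects = 19,
                       samples_per_subject = c(8, 9),
                       time_since_dose_range_h = c(0.5, 12),
                       dose_time_jitter_sd_h = 0.5,
                       residual_sd_log10 = 0.1,
                       iiv_cv = c(clearance = 0.3, fu_p = 0.1,
                                  t50 = 0.3, permeability = 0.4),
                       perpetrator_cotiming_assumed = TRUE,
                       population = NULL, perpetrator = NULL,
                       seed = 1L) {
  stopifnot(dose_time_jitter_sd_h >= 0, length(samples_per_subject) == 2)
  if (is.null(population))
    population <- population_spec(n = n_subjects, seed = seed)
  if (!is.null(perpetrator) && perpetrator_cotiming_assumed) {
    tv <- regimen$times_h
    tp <- perpetrator$regimen$times_h
    perpetrator$regimen$times_h <-
      tv[vapply(tp, function(t) which.min(abs(tv - t)), integer(1))] |>
      unique()
  }
  structure(list(compound = compound, regimen = regimen,
                 n_subjects = as.integer(n_subjects),
                 samples_per_subject = samples_per_subject,
                 time_since_dose_range_h = time_since_dose_range_h,
                 dose_time_jitter_sd_h = dose_time_jitter_sd_h,
                 residual_sd_log10 = residual_sd_log10,
                 iiv_cv = iiv_cv,
                 perpetrator_cotiming_assumed = perpetrator_cotiming_assumed,
                 population = population, perpetrator = perpetrator,
                 seed = as.integer(seed)),
            class = "tdm_design")
}

perturb_compound <- function(compound, iiv_cv, draws) {
  # log-normal multiplicative perturbations; draws: named std normals
  lnorm_mult <- function(cv, z) {
    if (cv <= 0) return(1)
    sdlog <- sqrt(log(1 + cv^2))
    exp(z * sdlog - sdlog^2 / 2)
  }
  cmp <- compound
  if ("clearance" %in% names(draws)) {
    m <- lnorm_mult(iiv_cv[["clearance"]], draws[["clearance"]])
    cmp$clearances <- purrr::map(cmp$clearances, function(p) {
      p$value <- p$value * m; p
    })
    cmp$biliary_clearance_per_min <- cmp$biliary_clearance_per_min * m
  }
  if ("fu_p" %in% names(draws)) {
    cmp$fu_p <- min(cmp$fu_p *
                      lnorm_mult(iiv_cv[["fu_p"]], draws[["fu_p"]]), 1)
  }
  if ("permeability" %in% names(draws)) {
    cmp$permeability_cm_min <- cmp$permeability_cm_min *
      lnorm_mult(iiv_cv[["permeability"]], draws[["permeability"]])
  }
  cmp
}

perturb_formulation <- function(formulation, iiv_cv, draws) {
  frm <- formulation
  if (frm$kind == "weibull" && "t50" %in% names(draws)) {
    sdlog <- sqrt(log(1 + iiv_cv[["t50"]]^2))
    frm$t50_min <- frm$t50_min * exp(draws[["t50"]] * sdlog - sdlog^2 / 2)
  }
  frm
}

simulate_one_subject <- function(design, ind, zdraws, grid_h, rtol, atol) {
  cmp <- perturb_compound(design$compound, design$iiv_cv, zdraws)
  reg <- design$regimen
  reg$formulation <- perturb_formulation(reg$formulation, design$iiv_cv,
                                         zdraws)
  m <- if (is.null(design$perpetrator)) {
    assemble_model(ind, cmp, reg)
  } else {
    assemble_model(ind, list(cmp, design$perpetrator$compound),
                   list(reg, design$perpetrator$regimen),
                   interactions = TRUE)
  }
  simulate_profile(m, grid_h = grid_h, rtol = rtol, atol = atol)
}

#' Generate dense synthetic study datasets
#'
#' Per subject: draw a virtual individual, perturb the compound and
#' formulation parameters per the IIV model, simulate, evaluate the
#' profile at the nominal sampling times and multiply by log-normal
#' residual error. The unperturbed model prediction and the per-subject
#' truth multipliers are stored alongside for recovery tests.
#'
#' @param design A [study_design()].
#' @param grid_h,rtol,atol Solver settings.
#' @return An `observed_dataset` tibble: dataset_id, subject_id,
#'   compound, time_h, time_since_dose_h, conc_ng_mL, conc_true_ng_mL,
#'   dose_mg, route, lloq_flag; attribute `truth` (tibble of per-subject
#'   parameter multipliers).
#' @export
generate_study_dataset <- function(design, grid_h = 0.1, rtol = 1e-6,
                                   atol = 1e-9) {
  stopifnot(inherits(design, "study_design"))
  individuals <- sample_population(design$population)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(design$seed + 1L)

  parn <- names(design$iiv_cv)
  rows <- list(); truths <- list()
  for (i in seq_len(design$n_subjects)) {
    z <- stats::setNames(stats::rnorm(length(parn)), parn)
    if (all(design$iiv_cv == 0)) z[] <- 0
    res <- simulate_one_subject(design, individuals[[i]], z,
                                grid_h, rtol, atol)
    prof <- res$profiles[res$profiles$compound == design$compound$name, ]
    ctrue <- stats::approx(prof$time_h, prof$conc_ng_mL,
                           xout = design$sampling_times_h)$y
    eps <- stats::rnorm(length(ctrue), 0, design$residual_sd_log10)
    cobs <- ctrue * 10^eps
    tsd <- vapply(design$sampling_times_h, function(tt) {
      past <- design$regimen$times_h[design$regimen$times_h <= tt]
      if (length(past)) tt - max(past) else NA_real_
    }, numeric(1))
    rows[[i]] <- tibble::tibble(
      dataset_id = paste0(design$compound$name, "_study"),
      subject_id = sprintf("S%03d", i),
      compound = design$compound$name,
      time_h = design$sampling_times_h,
      time_since_dose_h = tsd,
      conc_ng_mL = cobs, conc_true_ng_mL = ctrue,
      dose_mg = design$regimen$dose_mg,
      route = design$regimen$route,
      lloq_flag = FALSE)
    truths[[i]] <- tibble::tibble(
      subject_id = sprintf("S%03d", i),
      parameter = parn,
      z = unname(z))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "truth") <- dplyr::bind_rows(truths)
  class(out) <- c("observed_dataset", class(out))
  out
}

#' Generate sparse TDM datasets
#'
#' Steady-state clinical-routine sampling: per patient, a few samples at
#' random times since the (true) last dose; the *recorded* time since
#' dose differs from the true one by a normal jitter, emulating
#' patient/nurse-reported intake and sampling times. Concentrations are
#' evaluated at the true times and reported against the recorded times.
#'
#' @param design A [tdm_design()].
#' @param grid_h,rtol,atol Solver settings.
#' @return An `observed_dataset` tibble as in
#'   [generate_study_dataset()], plus columns `time_since_dose_true_h`
#'   and `time_since_dose_recorded_h`.
#' @export
generate_tdm_dataset <- function(design, grid_h = 0.1, rtol = 1e-6,
                                 atol = 1e-9) {
  stopifnot(inherits(design, "tdm_design"))
  individuals <- sample_population(design$population)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(design$seed + 2L)

  reg <- design$regimen
  tau <- if (length(reg$times_h) > 1) min(diff(reg$times_h)) else 24
  t_last <- max(reg$times_h)
  parn <- names(design$iiv_cv)
  rows <- list()
  for (i in seq_len(design$n_subjects)) {
    z <- stats::setNames(stats::rnorm(length(parn)), parn)
    if (all(design$iiv_cv == 0)) z[] <- 0
    res <- simulate_one_subject(design, individuals[[i]], z,
                                grid_h, rtol, atol)
    prof <- res$profiles[res$profiles$compound == design$compound$name, ]
    ns <- sample(design$samples_per_subject[1]:design$samples_per_subject[2], 1)
    tsd_true <- stats::runif(ns, design$time_since_dose_range_h[1],
                             min(design$time_since_dose_range_h[2], tau))
    jit <- stats::rnorm(ns, 0, design$dose_time_jitter_sd_h)
    tsd_rec <- pmax(tsd_true + jit, 0)
    t_abs <- t_last + tsd_true
    ctrue <- stats::approx(prof$time_h, prof$conc_ng_mL, xout = t_abs,
                           rule = 2)$y
    cobs <- ctrue * 10^stats::rnorm(ns, 0, design$residual_sd_log10)
    rows[[i]] <- tibble::tibble(
      dataset_id = paste0(design$compound$name, "_tdm"),
      subject_id = sprintf("P%03d", i),
      compound = design$compound$name,
      time_h = t_abs,
      time_since_dose_true_h = tsd_true,
      time_since_dose_recorded_h = tsd_rec,
      conc_ng_mL = cobs, conc_true_ng_mL = ctrue,
      dose_mg = reg$dose_mg, route = reg$route,
      perpetrator_cotiming_assumed = design$perpetrator_cotiming_assumed,
      lloq_flag = FALSE)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("observed_dataset", class(out))
  out
}
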