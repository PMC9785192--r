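#' Reference adult physiology
#'
#' Embedded single reference adult (male, 30 years, 73 kg, 176 cm) with
#' organ volumes, regional blood flows, tissue composition used by the
#' partition-coefficient methods, and hepatic/intestinal enzyme
#' concentrations. Values are representative ICRP-type adult data as
#' tabulated in the open systems-pharmacology literature; they are the
#' package's auditable substrate for allometric scaling, not a per-study
#' fit.
#'
#' @return A list with elements `organs` (tibble: organ, volume_L,
#'   flow_L_min, plus composition fractions), `reference` (demographics of
#'   the embedded adult), `enzymes` (tibble: enzyme, organ,
#'   concentration_umol_L), `gfr_mL_min` (named, by sex) and
#'   `hematocrit` (named, by sex).
#' @export
reference_physiology <- function() {
  organs <- tibble::tibble(
    organ = c("lung", "adipose", "bone", "brain", "heart", "kidney",
              "muscle", "skin", "gonads", "rest", "spleen", "stomach_wall",
              "gut_wall", "liver"),
    volume_L = c(0.53, 14.6, 10.2, 1.45, 0.33, 0.31,
                 29.0, 3.3, 0.035, 2.9, 0.15, 0.15,
                 1.05, 1.80),
    # fraction of cardiac output; "rest" closes the balance exactly
    flow_frac = c(NA, 0.050, 0.050, 0.120, 0.040, 0.190,
                  0.170, 0.050, 0.0005, NA, 0.030, 0.010,
                  0.140, 0.065),
    # tissue composition: extracellular water, intracellular water,
    # neutral lipid, neutral phospholipid (fractional volumes) and
    # acidic phospholipid (mg/g); Rodgers-Rowland-type reference values
    f_ew = c(0.336, 0.135, 0.100, 0.162, 0.320, 0.273,
             0.118, 0.382, 0.141, 0.130, 0.207, 0.282,
             0.282, 0.161),
    f_iw = c(0.446, 0.017, 0.346, 0.620, 0.456, 0.483,
             0.630, 0.291, 0.595, 0.620, 0.579, 0.475,
             0.475, 0.573),
    f_nl = c(0.022, 0.853, 0.017, 0.039, 0.014, 0.012,
             0.010, 0.060, 0.0030, 0.010, 0.0077, 0.038,
             0.038, 0.014),
    f_np = c(0.0128, 0.0016, 0.0017, 0.0015, 0.0111, 0.0242,
             0.0072, 0.0044, 0.0120, 0.0072, 0.0113, 0.0125,
             0.0125, 0.0240),
    ap_mg_g = c(3.91, 0.40, 0.67, 0.40, 2.25, 5.03,
                1.53, 1.32, 2.00, 1.53, 3.18, 2.41,
                2.41, 4.56),
    # tissue-to-plasma albumin ratio (used by the extended
    # Rodgers-Rowland class for neutrals/weak bases/acids)
    ra_tp = c(0.212, 0.049, 0.100, 0.048, 0.157, 0.130,
              0.064, 0.277, 0.110, 0.100, 0.097, 0.158,
              0.158, 0.086)
  )
  list(
    organs = organs,
    blood = c(arterial_L = 1.70, venous_L = 3.90),
    cardiac_output_L_min = 5.60,
    reference = demographics(sex = "male", age = 30, weight = 73,
                             height = 176),
    enzymes = tibble::tibble(
      enzyme = c("CYP3A4", "CYP2C9", "UGT1A4", "CYP3A4"),
      organ = c("liver", "liver", "liver", "gut_wall"),
      concentration_umol_L = c(8.6, 10.8, 5.0, 1.4)
    ),
    gfr_mL_min = c(male = 125, female = 105),
    hematocrit = c(male = 0.45, female = 0.40),
    plasma = c(f_w = 0.945, f_nl = 0.0023, f_np = 0.0013)
  )
}

#' Demographic description of one subject
#'
#' @param sex `"male"` or `"female"`.
#' @param age Age in years (> 0).
#' @param weight Body weight in kg (> 0).
#' @param height Height in cm (> 0).
#' @param population_label Free-text label carried through outputs.
#' @return A `demographics` list.
#' @export
demographics <- function(sex = c("male", "female"), age = 30, weight = 73,
                         height = 176, population_label = "reference") {
  sex <- match.arg(sex)
  if (!is.finite(age) || age <= 0) stop("age must be > 0", call. = FALSE)
  if (!is.finite(weight) || weight <= 0) stop("weight must be > 0", call. = FALSE)
  if (!is.finite(height) || height <= 0) stop("height must be > 0", call. = FALSE)
  if (age > 120 || weight > 300 || height > 250)
    stop("non-physiologic demographics rejected", call. = FALSE)
  structure(list(sex = sex, age = age, weight = weight, height = height,
                 population_label = population_label),
            class = "demographics")
}

bsa_dubois <- function(weight, height) {
  0.007184 * weight^0.425 * height^0.725
}

#' Build a virtual individual from demographics
#'
#' Organ volumes are scaled proportionally to body weight and blood flows
#' with an allometric exponent of 0.75 relative to the embedded reference
#' adult. GFR scales with body surface area (DuBois) relative to 1.73 m2,
#' with sex-specific reference values. The sum of systemic organ blood
#' flows is closed against cardiac output through the "rest" compartment,
#' so flow conservation holds exactly.
#'
#' @param demo A [demographics()] object.
#' @param physiology Reference physiology, defaults to
#'   [reference_physiology()].
#' @return A `virtual_individual` list with `demographics`, `organs`
#'   (tibble with scaled `volume_L`, `flow_L_min` and composition),
#'   `blood_L`, `cardiac_output_L_min`, `enzymes`, `gfr_mL_min`,
#'   `hematocrit`.
#' @export
#' @examples
#' ind <- build_individual(demographics())
#' sum(ind$organs$flow_L_min[ind$organs$organ != "lung"])
build_individual <- function(demo, physiology = reference_physiology()) {
  if (!inherits(demo, "demographics")) demo <- do.call(demographics, demo)
  ref <- physiology$reference
  needed <- c("lung", "adipose", "bone", "brain", "heart", "kidney",
              "muscle", "skin", "gonads", "rest", "spleen", "stomach_wall",
              "gut_wall", "liver")
  if (!all(needed %in% physiology$organs$organ))
    stop("physiology table is missing organs: ",
         paste(setdiff(needed, physiology$organs$organ), collapse = ", "),
         call. = FALSE)

  w_scale <- demo$weight / ref$weight
  q_scale <- w_scale^0.75
  organs <- physiology$organs
  # mild sex adjustment of body composition (more adipose, less muscle)
  if (demo$sex == "female") {
    organs$volume_L[organs$organ == "adipose"] <-
      organs$volume_L[organs$organ == "adipose"] * 1.25
    organs$volume_L[organs$organ == "muscle"] <-
      organs$volume_L[organs$organ == "muscle"] * 0.85
  }
  organs$volume_L <- organs$volume_L * w_scale
  co <- physiology$cardiac_output_L_min * q_scale
  systemic <- organs$organ != "lung"
  organs$flow_L_min <- organs$flow_frac * co
  # close the flow balance through "rest"
  known <- sum(organs$flow_L_min[systemic], na.rm = TRUE)
  organs$flow_L_min[organs$organ == "rest"] <- co - known
  organs$flow_L_min[organs$organ == "lung"] <- co
  if (organs$flow_L_min[organs$organ == "rest"] <= 0)
    stop("flow fractions exceed cardiac output", call. = FALSE)

  bsa <- bsa_dubois(demo$weight, demo$height)
  gfr <- unname(physiology$gfr_mL_min[demo$sex]) * bsa / 1.73

  out <- list(
    demographics = demo,
    organs = organs,
    blood_L = physiology$blood * w_scale,
    cardiac_output_L_min = co,
    enzymes = physiology$enzymes,
    gfr_mL_min = gfr,
    hematocrit = unname(physiology$hematocrit[demo$sex]),
    plasma = physiology$plasma
  )
  class(out) <- "virtual_individual"
  validate_individual(out)
  out
}

validate_individual <- function(ind) {
  org <- ind$organs
  stopifnot(all(org$volume_L > 0), all(org$flow_L_min > 0),
            all(ind$enzymes$concentration_umol_L >= 0),
            ind$hematocrit > 0, ind$hematocrit < 1, ind$gfr_mL_min > 0)
  systemic <- org$organ != "lung"
  rel <- abs(sum(org$flow_L_min[systemic]) - ind$cardiac_output_L_min) /
    ind$cardiac_output_L_min
  if (rel > 1e-9) stop("organ blood flows do not sum to cardiac output",
                       call. = FALSE)
  invisible(ind)
}

#' Specify a virtual population
#'
#' Demographics are sampled independently: age/weight/height from
#' truncated normal distributions (`mean`, `sd`, `min`, `max`) or fixed
#' values, sex from `proportion_female`. Organ scaling is then
#' deterministic per individual.
#'
#' @param n Number of individuals (>= 1).
#' @param age,weight,height Either a single fixed value or a list/vector
#'   with elements `mean`, `sd`, `min`, `max`.
#' @param proportion_female Fraction in `[0, 1]`.
#' @param label Population label.
#' @param seed Integer seed; sampling is fully reproducible.
#' @return A `population_spec` list.
#' @export
population_spec <- function(n = 100,
                            age = list(mean = 45, sd = 12, min = 18, max = 70),
                            weight = list(mean = 75, sd = 12, min = 50, max = 110),
                            height = list(mean = 172, sd = 9, min = 150, max = 200),
                            proportion_female = 0.4,
                            label = "virtual",
                            seed = 1L) {
  stopifnot(n >= 1, proportion_female >= 0, proportion_female <= 1)
  norm_range <- function(x, what) {
    if (is.numeric(x) && length(x) == 1) {
      list(mean = x, sd = 0, min = x, max = x)
    } else {
      x <- as.list(x)
      if (!all(c("mean", "sd", "min", "max") %in% names(x)))
        stop(what, " range needs mean/sd/min/max or a fixed value", call. = FALSE)
      if (x$min > x$max) stop("infeasible ", what, " range", call. = FALSE)
      x
    }
  }
  structure(list(n = as.integer(n), age = norm_range(age, "age"),
                 weight = norm_range(weight, "weight"),
                 height = norm_range(height, "height"),
                 proportion_female = proportion_female,
                 label = label, seed = as.integer(seed)),
            class = "population_spec")
}

rtruncnorm1 <- function(n, rng) {
  if (rng$sd == 0 || rng$min == rng$max) return(rep(rng$mean, n))
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    x <- stats::rnorm(length(todo), rng$mean, rng$sd)
    ok <- x >= rng$min & x <= rng$max
    out[todo[ok]] <- x[ok]
    todo <- todo[!ok]
  }
  out
}

#' Sample a virtual population
#'
#' @param spec A [population_spec()].
#' @param physiology Reference physiology table.
#' @return List of `virtual_individual`, length `spec$n`.
#' @export
sample_population <- function(spec, physiology = reference_physiology()) {
  stopifnot(inherits(spec, "population_spec"))
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(spec$seed)
    code
  }
  withr_seed({
    sexes <- ifelse(stats::runif(spec$n) < spec$proportion_female,
                    "female", "male")
    ages <- rtruncnorm1(spec$n, spec$age)
    weights <- rtruncnorm1(spec$n, spec$weight)
    heights <- rtruncnorm1(spec$n, spec$height)
    purrr::pmap(list(sexes, ages, weights, heights), function(s, a, w, h) {
      build_individual(
        demographics(sex = s, age = a, weight = w, height = h,
                     population_label = spec$label),
        physiology = physiology)
    })
  })
}

#' Tabulate a population
#'
#' One row per individual: demographics plus scaled whole-body summaries.
#'
#' @param individuals List of `virtual_individual` (from
#'   [sample_population()]).
#' @return A tibble.
#' @export
population_table <- function(individuals) {
  purrr::imap_dfr(individuals, function(ind, i) {
    tibble::tibble(
      id = i,
      sex = ind$demographics$sex,
      age = ind$demographics$age,
      weight = ind$demographics$weight,
      height = ind$demographics$height,
      cardiac_output_L_min = ind$cardiac_output_L_min,
      liver_volume_L = ind$organs$volume_L[ind$organs$organ == "liver"],
      gfr_mL_min = ind$gfr_mL_min,
      hematocrit = ind$hematocrit
    )
  })
}

#' Population specification for the transplant-cohort simulations
#'
#' Adult demographics representative of a graft-versus-host-disease
#' therapeutic-drug-monitoring cohort (allogeneic stem-cell transplant
#' recipients): middle-aged adults of both sexes with wide weight
#' spread. Used by default for the day-10 steady-state population
#' simulations.
#'
#' @param n Population size (100 by default).
#' @param seed Integer seed.
#' @return A [population_spec()].
#' @export
gvhd_population_spec <- function(n = 100, seed = 1L) {
  population_spec(
    n = n,
    age = list(mean = 55, sd = 12, min = 18, max = 75),
    weight = list(mean = 75, sd = 14, min = 48, max = 115),
    height = list(mean = 172, sd = 10, min = 150, max = 200),
    proportion_female = 0.4,
    label = "gvhd_cohort", seed = seed)
}

#' Load a population-specification file
#'
#' YAML schema: `n`, `proportion_female`, `seed`, `label`, and for each
#' of `age`/`weight`/`height` either a fixed value or a map with
#' `mean`, `sd`, `min`, `max`.
#'
#' @param path Path to a population YAML file.
#' @return A [population_spec()].
#' @export
load_population_spec <- function(path) {
  y <- yaml::read_yaml(path)
  rng <- function(x) if (is.list(x)) x else as.numeric(x)
  population_spec(n = y$n, age = rng(y$age), weight = rng(y$weight),
                  height = rng(y$height),
                  proportion_female = y$proportion_female %||% 0.5,
                  label = y$label %||% "virtual",
                  seed = y$seed %||% 1L)
}
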