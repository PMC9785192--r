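#' Formulation / release model
#'
#' @param kind `"iv_infusion"`, `"solution"`, `"weibull"` or
#'   `"particle"`.
#' @param t50_min Time to 50% dissolution (min, Weibull; > 0).
#' @param shape Weibull dissolution shape (> 0).
#' @param lag_min Lag time before any release (min, >= 0).
#' @param gastric_release_blocked If `TRUE` (enteric coating), no release
#'   in the stomach segment.
#' @param particle_radius_um Monodisperse particle radius (um).
#' @param drug_density_g_cm3 Density of the solid drug.
#' @param unstirred_water_layer_um Diffusion-layer thickness (um).
#' @param supersaturation_enabled Allow transient supersaturation with
#'   first-order precipitation (the precipitate is treated as soluble
#'   drug recycled to the solid mass, enlarging the dissolvable pool).
#' @param precipitation_halflife_min Half-life of the supersaturation
#'   decay (min).
#' @param permeability Optional formulation-specific permeability
#'   override, a list with `value` and `unit` tag.
#' @param area_amplification Mucosal surface amplification factor
#'   mapping a source-convention "specific" permeability (referenced to
#'   villous mucosal area) onto the package's smooth-surface segment
#'   areas; 1 for effective permeabilities.
#' @param intestinal_solubility_mg_mL Optional named per-segment
#'   solubility override (mg/mL) applied instead of the pH profile
#'   (the delayed-release tablet workaround).
#' @return A `formulation_model` list.
#' @export
formulation_model <- function(kind = c("iv_infusion", "solution", "weibull",
                                       "particle"),
                              t50_min = NULL, shape = NULL, lag_min = 0,
                              gastric_release_blocked = FALSE,
                              particle_radius_um = NULL,
                              drug_density_g_cm3 = NULL,
                              unstirred_water_layer_um = NULL,
                              supersaturation_enabled = FALSE,
                              precipitation_halflife_min = 10,
                              permeability = NULL,
                              area_amplification = 1,
                              intestinal_solubility_mg_mL = NULL) {
  kind <- match.arg(kind)
  stopifnot(lag_min >= 0)
  if (kind == "weibull")
    stopifnot(t50_min > 0, shape > 0)
  if (kind == "particle")
    stopifnot(particle_radius_um > 0, drug_density_g_cm3 > 0,
              unstirred_water_layer_um > 0)
  structure(list(kind = kind, t50_min = t50_min, shape = shape,
                 lag_min = lag_min,
                 gastric_release_blocked = gastric_release_blocked,
                 particle_radius_um = particle_radius_um,
                 drug_density_g_cm3 = drug_density_g_cm3,
                 unstirred_water_layer_um = unstirred_water_layer_um,
                 supersaturation_enabled = supersaturation_enabled,
                 precipitation_halflife_min = precipitation_halflife_min,
                 permeability = permeability,
                 area_amplification = area_amplification,
                 intestinal_solubility_mg_mL = intestinal_solubility_mg_mL),
            class = "formulation_model")
}

#' Load a formulation file
#'
#' @param path YAML file as shipped under `inst/extdata`.
#' @return A [formulation_model()].
#' @export
load_formulation <- function(path) {
  y <- yaml::read_yaml(path)
  sol <- y$intestinal_solubility_mg_mL
  if (!is.null(sol)) sol <- unlist(sol)
  formulation_model(
    kind = y$kind, t50_min = y$t50_min, shape = y$shape,
    lag_min = y$lag_min %||% 0,
    gastric_release_blocked = isTRUE(y$gastric_release_blocked),
    particle_radius_um = y$particle_radius_um,
    drug_density_g_cm3 = y$drug_density_g_cm3,
    unstirred_water_layer_um = y$unstirred_water_layer_um,
    supersaturation_enabled = isTRUE(y$supersaturation_enabled),
    precipitation_halflife_min = y$precipitation_halflife_min %||% 10,
    permeability = y$permeability,
    area_amplification = y$area_amplification %||% 1,
    intestinal_solubility_mg_mL = sol)
}

#' Built-in formulation models
#'
#' Packaged release models: posaconazole i.v. (`pos_iv`), oral suspension
#' (`pos_sus`, particle dissolution with supersaturation), delayed-release
#' tablet (`pos_dr`, Weibull with enteric release block and adapted
#' intestinal solubility), ruxolitinib extended-release tablet (`rux_er`)
#' and midazolam solution/i.v. (`mdz_oral`, `mdz_iv`).
#'
#' @param name Formulation identifier.
#' @return A [formulation_model()].
#' @export
builtin_formulation <- function(name = c("pos_iv", "pos_sus", "pos_dr",
                                         "rux_er", "mdz_oral", "mdz_iv")) {
  name <- match.arg(name)
  load_formulation(system.file("extdata", paste0("formulation_", name,
                                                 ".yaml"),
                               package = "pbpkddi", mustWork = TRUE))
}

#' Weibull fraction dissolved
#'
#' \deqn{F(t) = 1 - \exp(-\ln 2\,((t - lag)/t_{50})^{shape})} for
#' `t > lag`, else 0; `F(lag + t50) = 0.5` by construction.
#'
#' @param t_min Time since dose in minutes (>= 0); vectorized.
#' @param formulation A Weibull [formulation_model()].
#' @return Fraction dissolved in `[0, 1)`.
#' @export
weibull_fraction_dissolved <- function(t_min, formulation) {
  stopifnot(formulation$kind == "weibull", all(t_min >= 0))
  te <- pmax(t_min - formulation$lag_min, 0)
  1 - exp(-log(2) * (te / formulation$t50_min)^formulation$shape)
}

# Weibull release hazard h(t) = f(t)/(1-F(t)), used by the ODE engine on
# the undissolved-in-formulation pool (time measured since last dose)
weibull_release_hazard <- function(t_min, formulation) {
  te <- t_min - formulation$lag_min
  ifelse(te <= 0, 0,
         log(2) * formulation$shape * te^(formulation$shape - 1) /
           formulation$t50_min^formulation$shape)
}

#' Particle dissolution rate (Noyes-Whitney / Nernst-Brunner)
#'
#' Monodisperse spheres dissolving through an unstirred water layer:
#' \deqn{dM/dt = -\frac{3 D}{r h \rho} M (C_s - C)} (mg/min), clamped so
#' the rate is zero when the solid is exhausted and never drives the
#' dissolved mass above saturation. With `constant_surface = TRUE` the
#' per-mass surface term is frozen at the initial solid mass
#' (constant-surface-area variant; under sink conditions the dissolved
#' mass then grows linearly).
#'
#' @param solid_mg Remaining solid mass (mg).
#' @param dissolved_conc_mg_mL Local dissolved concentration.
#' @param solubility_mg_mL Local saturation solubility Cs (> 0).
#' @param formulation A particle [formulation_model()].
#' @param diffusion_cm2_min Aqueous diffusion coefficient (cm2/min).
#' @param constant_surface Freeze surface area at `reference_mass_mg`.
#' @param reference_mass_mg Reference mass for the constant-surface
#'   variant.
#' @return Dissolution rate in mg/min (>= 0).
#' @export
particle_dissolution_rate <- function(solid_mg, dissolved_conc_mg_mL,
                                      solubility_mg_mL, formulation,
                                      diffusion_cm2_min = 3e-4,
                                      constant_surface = FALSE,
                                      reference_mass_mg = solid_mg) {
  stopifnot(formulation$kind == "particle",
            formulation$particle_radius_um > 0,
            formulation$unstirred_water_layer_um > 0)
  if (solid_mg <= 0) return(0)
  r_cm <- formulation$particle_radius_um * 1e-4
  h_cm <- formulation$unstirred_water_layer_um * 1e-4
  rho_mg_cm3 <- formulation$drug_density_g_cm3 * 1000
  k <- 3 * diffusion_cm2_min / (r_cm * h_cm * rho_mg_cm3)  # mL/mg/min
  m_eff <- if (constant_surface) reference_mass_mg else solid_mg
  max(k * m_eff * (solubility_mg_mL - dissolved_conc_mg_mL), 0)
}

#' Apply precipitation to one lumen segment state
#'
#' When the dissolved concentration exceeds the local saturation
#' solubility, the excess precipitates first-order with the
#' formulation's precipitation half-life; the precipitate is added to
#' the solid mass (treated as re-dissolvable drug), conserving total
#' segment mass exactly. With `instantaneous = TRUE` the dissolved pool
#' is clipped to saturation in one step.
#'
#' @param segment List with `solid_mg`, `dissolved_mg`, `volume_L`.
#' @param solubility_mg_mL Local Cs.
#' @param formulation A [formulation_model()] with supersaturation
#'   enabled.
#' @param dt_min Time step over which the first-order decay acts.
#' @param instantaneous Clip to saturation instead of decaying.
#' @return Updated segment list (same fields).
#' @export
apply_precipitation <- function(segment, solubility_mg_mL, formulation,
                                dt_min = 1, instantaneous = FALSE) {
  stopifnot(isTRUE(formulation$supersaturation_enabled))
  v_mL <- segment$volume_L * 1000
  cs_mg <- solubility_mg_mL * v_mL
  excess <- segment$dissolved_mg - cs_mg
  if (excess <= 0) return(segment)
  moved <- if (instantaneous) {
    excess
  } else {
    k <- log(2) / formulation$precipitation_halflife_min
    excess * (1 - exp(-k * dt_min))
  }
  segment$dissolved_mg <- segment$dissolved_mg - moved
  segment$solid_mg <- segment$solid_mg + moved
  segment
}

#' Gastric-emptying modifier of a meal
#'
#' Multiplier on the gastric emptying *half-time*: `1 + kcal / 320`,
#' linear in caloric content (0 kcal returns 1; an 841 kcal high-fat
#' meal slows emptying ~3.6-fold). The stomach transit rate is divided
#' by this factor, decaying back to fasted state with a 1.5 h time
#' constant after the meal.
#'
#' @param meal A [meal_event()] or a list with `energy_kcal`.
#' @return Multiplier (>= 1) on the emptying half-time.
#' @export
gastric_emptying_modifier <- function(meal) {
  stopifnot(meal$energy_kcal >= 0)
  1 + meal$energy_kcal / 320
}

#' Meal event
#'
#' @param time_h Time after first dose (h).
#' @param energy_kcal Caloric content (>= 0); the conventional anchor
#'   values are 841 kcal (high-fat) and 200 kcal (non-fat meal).
#' @param solid_fraction Solid fraction of the meal in `[0, 1]`
#'   (kept at 0.8 by default; carried for reporting, the emptying
#'   modifier is driven by calories).
#' @return A `meal_event` list.
#' @export
meal_event <- function(time_h, energy_kcal, solid_fraction = 0.8) {
  stopifnot(energy_kcal >= 0, solid_fraction >= 0, solid_fraction <= 1)
  structure(list(time_h = time_h, energy_kcal = energy_kcal,
                 solid_fraction = solid_fraction), class = "meal_event")
}

#' Intestinal permeation rate from one segment
#'
#' Flux = permeability x absorptive area x dissolved concentration; only
#' dissolved drug permeates. Drug crossing the apical membrane enters
#' the gut-wall compartment, where mucosal CYP3A4 acts before the portal
#' vein (handled by the ODE engine).
#'
#' @param dissolved_mg Dissolved mass in the segment (>= 0).
#' @param volume_L Segment luminal water volume.
#' @param area_cm2 Effective absorptive area of the segment.
#' @param permeability_cm_min Unit-normalized permeability (from
#'   [normalize_permeability()]).
#' @return Permeation rate in mg/min.
#' @export
intestinal_permeation_rate <- function(dissolved_mg, volume_L, area_cm2,
                                       permeability_cm_min) {
  stopifnot(dissolved_mg >= 0)
  conc_mg_cm3 <- dissolved_mg / (volume_L * 1000)
  permeability_cm_min * area_cm2 * conc_mg_cm3
}

#' Gastrointestinal segment reference
#'
#' Five lumped lumen segments with fixed pH profile, luminal water
#' volumes, effective absorptive areas and first-order transit rates.
#' The pH profile follows the physiological gradient (acidic fasted
#' stomach, rising distally) and is configurable.
#'
#' @return Tibble: segment, ph, volume_L, area_cm2, transit_per_h.
#' @export
gi_reference <- function() {
  tibble::tibble(
    segment = c("stomach", "duodenum", "jejunum", "ileum", "colon"),
    ph = c(1.6, 5.6, 6.5, 7.0, 6.8),
    volume_L = c(0.050, 0.030, 0.080, 0.080, 0.030),
    area_cm2 = c(100, 250, 650, 650, 300),
    transit_per_h = c(log(2) / 0.25, 60 / 15, 1 / 1.6, 1 / 1.6, 1 / 14)
  )
}
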