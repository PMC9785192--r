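#' Dosing regimen
#'
#' @param compound Compound name the regimen applies to.
#' @param route `"iv_infusion"` or `"oral"`.
#' @param dose_mg Dose per administration (> 0, or 0 for a null arm).
#' @param schedule `"SD"`, `"QD"`, `"BID"` or `"TID"`; expanded to
#'   explicit dose times over `duration_days`. Ignored when `times_h`
#'   is given.
#' @param times_h Explicit dose times (h since simulation start),
#'   strictly increasing.
#' @param duration_days Treatment duration in days.
#' @param infusion_duration_min Infusion length for i.v. dosing (0 =
#'   bolus).
#' @param formulation A [formulation_model()].
#' @param meals List of [meal_event()] objects.
#' @return A `dosing_regimen` list with explicit `times_h`.
#' @export
#' @examples
#' dosing_regimen("ruxolitinib", "oral", 10, schedule = "BID",
#'                duration_days = 10,
#'                formulation = builtin_formulation("rux_er"))
dosing_regimen <- function(compound, route = c("oral", "iv_infusion"),
                           dose_mg, schedule = c("QD", "BID", "TID", "SD"),
                           times_h = NULL, duration_days = 1,
                           infusion_duration_min = 60,
                           formulation, meals = list()) {
  route <- match.arg(route)
  stopifnot(dose_mg >= 0, inherits(formulation, "formulation_model"))
  if (is.null(times_h)) {
    schedule <- match.arg(schedule)
    step <- switch(schedule, SD = NA, QD = 24, BID = 12, TID = 8)
    times_h <- if (schedule == "SD") 0 else {
      seq(0, duration_days * 24 - 1e-6, by = step)
    }
  }
  if (any(diff(times_h) <= 0))
    stop("dose times must be strictly increasing", call. = FALSE)
  if (route == "iv_infusion" && infusion_duration_min < 0)
    stop("infusion duration must be >= 0", call. = FALSE)
  if (route == "iv_infusion" && formulation$kind != "iv_infusion")
    stop("i.v. route requires an iv_infusion formulation", call. = FALSE)
  structure(list(compound = compound, route = route, dose_mg = dose_mg,
                 times_h = times_h, duration_days = duration_days,
                 infusion_duration_min = infusion_duration_min,
                 formulation = formulation, meals = meals),
            class = "dosing_regimen")
}

#' Load a dosing-regimen file
#'
#' YAML schema: `compound`, `route`, `dose_mg`, either `schedule` +
#' `duration_days` or explicit `times_h`, optional
#' `infusion_duration_min`, `formulation` (name of a packaged
#' formulation or a path), and `meals` (list of `{time_h, energy_kcal,
#' solid_fraction}`).
#'
#' @param path Path to a regimen YAML file.
#' @return A [dosing_regimen()].
#' @export
load_regimen <- function(path) {
  y <- yaml::read_yaml(path)
  frm <- if (file.exists(y$formulation %||% "")) {
    load_formulation(y$formulation)
  } else {
    builtin_formulation(y$formulation)
  }
  meals <- purrr::map(y$meals %||% list(), function(m) {
    meal_event(m$time_h, m$energy_kcal, m$solid_fraction %||% 0.8)
  })
  dosing_regimen(
    compound = y$compound, route = y$route, dose_mg = y$dose_mg,
    schedule = y$schedule %||% "QD",
    times_h = if (!is.null(y$times_h)) as.numeric(y$times_h),
    duration_days = y$duration_days %||% 1,
    infusion_duration_min = y$infusion_duration_min %||% 60,
    formulation = frm, meals = meals)
}
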