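#' Describe one clearance process
#'
#' @param enzyme One of `"CYP3A4"`, `"CYP2C9"`, `"UGT1A4"`, `"biliary"`,
#'   `"renal_gfr"`.
#' @param kind `"first_order_specific_clearance"` (L/umol/min, scaled by
#'   the local enzyme concentration) or `"kcat"` (1/min). A `kcat`
#'   process is linearized at its working range, i.e. treated as a
#'   first-order rate per enzyme concentration; no saturable kinetics are
#'   modeled.
#' @param value Nonnegative rate parameter in the unit implied by `kind`.
#' @return A `clearance_process` list.
#' @export
clearance_process <- function(enzyme = c("CYP3A4", "CYP2C9", "UGT1A4",
                                         "biliary", "renal_gfr"),
                              kind = c("first_order_specific_clearance",
                                       "kcat"),
                              value) {
  enzyme <- match.arg(enzyme)
  kind <- match.arg(kind)
  stopifnot(is.numeric(value), value >= 0)
  structure(list(enzyme = enzyme, kind = kind, value = value),
            class = "clearance_process")
}

#' Competitive-inhibition interaction parameters
#'
#' @param target_enzyme Enzyme inhibited by the compound.
#' @param ki Inhibition constant in umol/L (> 0).
#' @param mechanism Only `"competitive"` is supported.
#' @return An `interaction_parameters` list.
#' @export
interaction_parameters <- function(target_enzyme = "CYP3A4", ki,
                                   mechanism = "competitive") {
  stopifnot(mechanism == "competitive", is.numeric(ki), ki > 0)
  structure(list(target_enzyme = target_enzyme, mechanism = mechanism,
                 ki = ki), class = "interaction_parameters")
}

#' Drug-dependent parameter set
#'
#' Container for physicochemistry, binding, clearance processes and
#' interaction constants of one compound. Permeability values must carry
#' an explicit unit tag (`"cm/min"` or `"cm/s"`); they are normalized to
#' cm/min internally so that mixed-unit sources cannot silently differ by
#' a factor of 60.
#'
#' @param name Compound name.
#' @param molecular_weight g/mol (> 0).
#' @param logP Lipophilicity (log10 octanol-water partition coefficient).
#' @param fu_p Fraction unbound in plasma, in (0, 1].
#' @param pka Data frame / tibble with columns `value` and `type`
#'   (`"acid"` or `"base"`), or `NULL` for a neutral compound.
#' @param solubility_reference List with `value` (mg/mL) and `ph`.
#' @param solubility_gain_per_charge Max solubility gain factor per
#'   ionization step (>= 1).
#' @param permeability List with `value` and `unit` (`"cm/min"` or
#'   `"cm/s"`), or `NULL` to use [calculated_specific_permeability()].
#' @param partition_method `"rodgers_rowland"` or `"poulin_theil"`.
#' @param clearances List of [clearance_process()] objects.
#' @param gfr_fraction Fraction of GFR driving renal filtration (>= 0).
#' @param biliary_clearance_per_min Specific biliary clearance (1/min),
#'   referenced to unbound liver concentration.
#' @param interactions List of [interaction_parameters()].
#' @param blood_plasma_ratio Blood-to-plasma concentration ratio.
#' @return A `compound_parameters` list.
#' @export
compound_parameters <- function(name, molecular_weight, logP, fu_p,
                                pka = NULL,
                                solubility_reference = list(value = 1, ph = 7),
                                solubility_gain_per_charge = 1,
                                permeability = NULL,
                                partition_method = c("rodgers_rowland",
                                                     "poulin_theil"),
                                clearances = list(),
                                gfr_fraction = 0,
                                biliary_clearance_per_min = 0,
                                interactions = list(),
                                blood_plasma_ratio = 1) {
  partition_method <- match.arg(partition_method)
  stopifnot(molecular_weight > 0, fu_p > 0, fu_p <= 1, gfr_fraction >= 0,
            biliary_clearance_per_min >= 0, solubility_gain_per_charge >= 1)
  if (!is.null(pka)) {
    pka <- tibble::as_tibble(pka)
    stopifnot(all(c("value", "type") %in% names(pka)),
              all(pka$type %in% c("acid", "base")))
  }
  perm_cm_min <- if (is.null(permeability)) {
    calculated_specific_permeability(molecular_weight, logP)
  } else {
    normalize_permeability(permeability)
  }
  structure(list(
    name = name, molecular_weight = molecular_weight, logP = logP,
    fu_p = fu_p, pka = pka,
    solubility_reference = solubility_reference,
    solubility_gain_per_charge = solubility_gain_per_charge,
    permeability_cm_min = perm_cm_min,
    partition_method = partition_method,
    clearances = clearances,
    gfr_fraction = gfr_fraction,
    biliary_clearance_per_min = biliary_clearance_per_min,
    interactions = interactions,
    blood_plasma_ratio = blood_plasma_ratio
  ), class = "compound_parameters")
}

#' Normalize a tagged permeability to cm/min
#'
#' @param p List with `value` and `unit` (`"cm/min"` or `"cm/s"`).
#' @return Numeric permeability in cm/min.
#' @export
normalize_permeability <- function(p) {
  if (is.null(p$unit)) stop("permeability requires a unit tag", call. = FALSE)
  switch(p$unit,
         "cm/min" = p$value,
         "cm/s" = p$value * 60,
         stop("unsupported permeability unit: ", p$unit, call. = FALSE))
}

#' Calculated specific intestinal permeability
#'
#' Closed-form initial estimate of transcellular intestinal permeability
#' from molecular weight and lipophilicity,
#' \deqn{P = K \cdot 10^{0.5\,\mathrm{logP}} / \sqrt{MW}\ \mathrm{(cm/min)},}
#' with the calibration constant `K = 3.3147e-5` fixed so that the
#' posaconazole parameter set (MW 700.78 g/mol, logP 4.32) yields
#' 1.81e-4 cm/min. The estimate is a starting value only; compound or
#' formulation files may override it with measured values.
#'
#' @param molecular_weight g/mol (> 0).
#' @param logP Lipophilicity.
#' @return Permeability in cm/min.
#' @export
calculated_specific_permeability <- function(molecular_weight, logP) {
  stopifnot(molecular_weight > 0)
  3.3147e-5 * 10^(0.5 * logP) / sqrt(molecular_weight)
}

#' pH-dependent solubility
#'
#' Henderson-Hasselbalch-type profile through the compound's reference
#' solubility point. Each ionization step contributes a factor
#' `min(10^(pKa - pH), gain)` for bases (`10^(pH - pKa)` for acids),
#' capping the gain per charge at `solubility_gain_per_charge`; the
#' neutral (intrinsic) solubility is inferred from the reference point.
#'
#' @param compound A [compound_parameters()] object.
#' @param ph pH value(s) in `[0, 14]`; vectorized.
#' @return Solubility in mg/mL.
#' @export
#' @examples
#' pos <- builtin_compound("posaconazole")
#' ph_solubility(pos, 1)    # fasted-stomach solubility
#' ph_solubility(pos, 7)    # distal-intestine solubility
ph_solubility <- function(compound, ph) {
  stopifnot(all(ph >= 0), all(ph <= 14))
  ref <- compound$solubility_reference
  if (is.null(compound$pka) || nrow(compound$pka) == 0) {
    if (is.null(ref)) stop("no pKa and no reference solubility", call. = FALSE)
    return(rep(ref$value, length(ph)))
  }
  gain <- compound$solubility_gain_per_charge
  factor_total <- function(p) {
    # cumulative ionization: bases protonate as pH drops (sorted by pKa
    # descending), acids deprotonate as pH rises
    tot <- 1
    bases <- sort(compound$pka$value[compound$pka$type == "base"],
                  decreasing = TRUE)
    run <- 1
    for (pk in bases) {
      run <- run * min(10^(pk - p), gain)
      tot <- tot + run
    }
    acids <- sort(compound$pka$value[compound$pka$type == "acid"])
    run <- 1
    for (pk in acids) {
      run <- run * min(10^(p - pk), gain)
      tot <- tot + run
    }
    tot
  }
  s_neutral <- ref$value / factor_total(ref$ph)
  s_neutral * vapply(ph, factor_total, numeric(1))
}

#' Load a compound parameter file
#'
#' Reads the YAML schema shipped under `inst/extdata` (one file per
#' compound, each field annotated with its source).
#'
#' @param path Path to a compound YAML file.
#' @return A [compound_parameters()] object.
#' @export
load_compound <- function(path) {
  y <- yaml::read_yaml(path)
  cl <- purrr::map(y$clearances %||% list(), function(p) {
    clearance_process(enzyme = p$enzyme, kind = p$kind, value = p$value)
  })
  ia <- purrr::map(y$interactions %||% list(), function(p) {
    interaction_parameters(target_enzyme = p$target_enzyme, ki = p$ki)
  })
  pka <- if (!is.null(y$pka)) {
    tibble::tibble(value = purrr::map_dbl(y$pka, "value"),
                   type = purrr::map_chr(y$pka, "type"))
  }
  compound_parameters(
    name = y$name, molecular_weight = y$molecular_weight, logP = y$logP,
    fu_p = y$fu_p, pka = pka,
    solubility_reference = y$solubility_reference,
    solubility_gain_per_charge = y$solubility_gain_per_charge %||% 1,
    permeability = y$permeability,
    partition_method = y$partition_method,
    clearances = cl, gfr_fraction = y$gfr_fraction %||% 0,
    biliary_clearance_per_min = y$biliary_clearance_per_min %||% 0,
    interactions = ia,
    blood_plasma_ratio = y$blood_plasma_ratio %||% 1
  )
}

#' Built-in compound parameter sets
#'
#' Returns the packaged parameter sets for posaconazole, ruxolitinib and
#' midazolam, loaded from the YAML files under `inst/extdata`. Printed
#' literature values (specific CYP clearances, Ki, formulation
#' parameters, tagged permeabilities, the two anchor solubilities) are
#' carried verbatim; unpublished values were identified against the
#' published exposure metrics and are annotated as such in the files.
#'
#' @param name `"posaconazole"`, `"ruxolitinib"` or `"midazolam"`.
#' @return A [compound_parameters()] object.
#' @export
builtin_compound <- function(name = c("posaconazole", "ruxolitinib",
                                      "midazolam")) {
  name <- match.arg(name)
  load_compound(system.file("extdata", paste0(name, ".yaml"),
                            package = "pbpkddi", mustWork = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
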