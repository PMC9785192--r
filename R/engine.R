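# Layout constants mirrored from src/pbpk_model.c
.organ_order <- c("lung", "adipose", "bone", "brain", "heart", "kidney",
                  "muscle", "skin", "gonads", "rest", "spleen",
                  "stomach_wall", "gut_wall", "liver")
.NORG <- 14L; .NCOMP <- 16L; .NSEG <- 5L; .MAXD <- 64L; .MAXM <- 40L
.NSTATE_C <- 39L
.CPLEN <- 169L
.P_CBASE <- 131L
.NPARMS <- .P_CBASE + 2L * .CPLEN

.state_names_c <- function(prefix) {
  seg <- c("stomach", "duodenum", "jejunum", "ileum", "colon")
  paste0(prefix, c(.organ_order, "arterial", "venous",
                   paste0("U_", seg), paste0("S_", seg), paste0("D_", seg),
                   "met_cyp3a4", "met_cyp2c9", "met_ugt1a4", "met_gut3a4",
                   "elim_renal", "elim_biliary", "gi_out", "gi_absorbed"))
}

enzyme_rate_per_h <- function(compound, individual, enzyme, organ) {
  # first-order metabolic rate constant (1/h) referenced to the unbound
  # equilibrated plasma concentration: CL_spec [L/umol/min] x [E] x 60
  ez <- individual$enzymes
  conc <- ez$concentration_umol_L[ez$enzyme == enzyme & ez$organ == organ]
  if (length(conc) == 0) return(NA_real_)
  procs <- purrr::keep(compound$clearances, ~ .x$enzyme == enzyme)
  if (length(procs) == 0) return(0)
  sum(purrr::map_dbl(procs, "value")) * conc * 60
}

segment_solubilities <- function(compound, formulation, gi) {
  cs <- ph_solubility(compound, gi$ph)
  ov <- formulation$intestinal_solubility_mg_mL
  if (!is.null(ov)) {
    idx <- match(names(ov), gi$segment)
    if (anyNA(idx)) stop("unknown GI segment in solubility override",
                         call. = FALSE)
    cs[idx] <- as.numeric(ov)
  }
  cs
}

compound_parm_block <- function(compound, regimen, individual, kp,
                                inhibitable, diffusion_cm2_min = 3e-4) {
  cp <- numeric(.CPLEN)
  frm <- regimen$formulation
  cp[1] <- 1                              # active
  cp[2] <- compound$molecular_weight
  cp[3] <- compound$fu_p
  cp[4] <- if (regimen$route == "oral") 1 else 0
  cp[5:18] <- kp$kp[match(.organ_order, kp$organ)]
  k3a4 <- enzyme_rate_per_h(compound, individual, "CYP3A4", "liver")
  k2c9 <- enzyme_rate_per_h(compound, individual, "CYP2C9", "liver")
  kugt <- enzyme_rate_per_h(compound, individual, "UGT1A4", "liver")
  kg3a4 <- enzyme_rate_per_h(compound, individual, "CYP3A4", "gut_wall")
  used <- unique(purrr::map_chr(compound$clearances, "enzyme"))
  for (e in intersect(used, c("CYP3A4", "CYP2C9", "UGT1A4"))) {
    kval <- switch(e, CYP3A4 = k3a4, CYP2C9 = k2c9, UGT1A4 = kugt)
    if (is.na(kval))
      stop("enzyme ", e, " used by ", compound$name,
           " is absent from the individual", call. = FALSE)
  }
  na_zero <- function(x) if (is.na(x)) 0 else x
  cp[19] <- na_zero(k3a4); cp[20] <- na_zero(k2c9); cp[21] <- na_zero(kugt)
  cp[22] <- na_zero(kg3a4)
  cp[23] <- compound$biliary_clearance_per_min * 60
  cp[24] <- compound$gfr_fraction
  ki <- purrr::keep(compound$interactions,
                    ~ .x$target_enzyme == "CYP3A4")
  cp[25] <- if (length(ki)) ki[[1]]$ki else 0
  cp[26] <- if (inhibitable) 1 else 0
  perm <- if (!is.null(frm$permeability)) {
    normalize_permeability(frm$permeability)
  } else compound$permeability_cm_min
  cp[27] <- perm * (frm$area_amplification %||% 1) * 60   # cm/h
  cp[28] <- switch(frm$kind, iv_infusion = 0, solution = 1, weibull = 2,
                   particle = 3)
  cp[29] <- (frm$t50_min %||% 1) / 60
  cp[30] <- frm$shape %||% 1
  cp[31] <- (frm$lag_min %||% 0) / 60
  cp[32] <- if (isTRUE(frm$gastric_release_blocked)) 1 else 0
  cp[33] <- log(2) / (frm$precipitation_halflife_min / 60)
  d_h <- diffusion_cm2_min * 60
  cp[34] <- if (frm$kind == "particle") {
    3 * d_h / (frm$particle_radius_um * 1e-4 *
               frm$unstirred_water_layer_um * 1e-4 *
               frm$drug_density_g_cm3 * 1000)
  } else {
    # redissolution of precipitated drug: generic fine precipitate
    3 * d_h / (5e-4 * 30e-4 * 1200)
  }
  gi <- gi_reference()
  cp[35:39] <- segment_solubilities(compound, frm, gi)
  nd <- length(regimen$times_h)
  if (nd > .MAXD) stop("more than ", .MAXD, " doses", call. = FALSE)
  cp[40] <- nd
  cp[41] <- regimen$infusion_duration_min / 60
  cp[42:(41 + nd)] <- regimen$times_h
  cp[106:(105 + nd)] <- rep(regimen$dose_mg, nd)
  cp
}

#' Assemble the whole-body ODE system
#'
#' Builds the full state-vector and parameter description for one
#' individual and one or two compounds with their dosing regimens. With
#' two compounds and `interactions = TRUE`, the victim's CYP3A4 terms
#' are scaled by `1 / (1 + I_u / Ki)` using the perpetrator's local
#' unbound concentration (liver and gut mucosa, or venous plasma when
#' `inhibition_driver = "plasma"`).
#'
#' @param individual A `virtual_individual`.
#' @param compounds List of one or two [compound_parameters()].
#' @param regimens List of matching [dosing_regimen()] objects.
#' @param interactions Enable the competitive-inhibition coupling.
#' @param inhibition_driver `"local"` (liver/gut unbound tissue
#'   concentration) or `"plasma"` (unbound venous plasma).
#' @param minimal Reduce to a single well-stirred compartment with
#'   first-order elimination (verification topology).
#' @return A `pbpk_model` list.
#' @export
assemble_model <- function(individual, compounds, regimens,
                           interactions = TRUE,
                           inhibition_driver = c("local", "plasma"),
                           minimal = FALSE) {
  inhibition_driver <- match.arg(inhibition_driver)
  if (inherits(compounds, "compound_parameters")) compounds <- list(compounds)
  if (inherits(regimens, "dosing_regimen")) regimens <- list(regimens)
  stopifnot(length(compounds) %in% 1:2,
            length(regimens) == length(compounds))
  n <- length(compounds)

  has_ki <- function(cmp) any(purrr::map_lgl(
    cmp$interactions, ~ .x$target_enzyme == "CYP3A4"))
  uses_3a4 <- function(cmp) any(purrr::map_lgl(
    cmp$clearances, ~ .x$enzyme == "CYP3A4"))
  inhibitable <- logical(n)
  if (interactions && n == 2) {
    for (i in 1:2) {
      other <- compounds[[3 - i]]
      if (uses_3a4(compounds[[i]]) && has_ki(other)) inhibitable[i] <- TRUE
    }
    if (!any(inhibitable))
      stop("interaction enabled but no perpetrator Ki matches a victim ",
           "CYP3A4 clearance", call. = FALSE)
  }

  p <- numeric(.NPARMS)
  p[1] <- n
  p[2] <- if (minimal) 1 else 0
  p[3] <- if (inhibition_driver == "plasma") 1 else 0
  p[4] <- individual$gfr_mL_min * 60 / 1000      # L/h
  org <- individual$organs
  vols <- org$volume_L[match(.organ_order, org$organ)]
  p[5:20] <- c(vols, unname(individual$blood_L[c("arterial_L", "venous_L")]))
  flows <- org$flow_L_min[match(.organ_order, org$organ)] * 60
  flows[1] <- individual$cardiac_output_L_min * 60
  p[21:34] <- flows
  gi <- gi_reference()
  p[35:39] <- gi$volume_L
  p[40:44] <- gi$area_cm2
  p[45:49] <- gi$transit_per_h

  meals <- purrr::list_flatten(purrr::map(regimens, "meals"))
  nm <- length(meals)
  if (nm > .MAXM) stop("more than ", .MAXM, " meal events", call. = FALSE)
  p[50] <- nm
  p[51] <- 1.5                                    # meal decay tau (h)
  if (nm > 0) {
    p[52:(51 + nm)] <- purrr::map_dbl(meals, "time_h")
    p[(52 + .MAXM):(51 + .MAXM + nm)] <-
      purrr::map_dbl(meals, gastric_emptying_modifier) - 1
  }

  kps <- purrr::map(compounds, partition_coefficients,
                    individual = individual)
  for (i in seq_len(n)) {
    blk <- compound_parm_block(compounds[[i]], regimens[[i]], individual,
                               kps[[i]], inhibitable[i])
    p[(.P_CBASE + (i - 1) * .CPLEN + 1):(.P_CBASE + i * .CPLEN)] <- blk
  }

  structure(list(
    parms = p, individual = individual, compounds = compounds,
    regimens = regimens, kp = kps, minimal = minimal,
    inhibitable = inhibitable,
    n_state = 2L * .NSTATE_C,
    state_names = c(.state_names_c("c1_"), .state_names_c("c2_"))
  ), class = "pbpk_model")
}

dose_events <- function(model) {
  ev <- list()
  for (i in seq_along(model$regimens)) {
    reg <- model$regimens[[i]]
    off <- (i - 1L) * .NSTATE_C
    frm <- reg$formulation
    if (reg$route == "oral") {
      var <- off + switch(frm$kind, weibull = 17L, particle = 22L,
                          solution = 27L,
                          stop("oral route needs an oral formulation",
                               call. = FALSE))
      ev[[length(ev) + 1]] <- data.frame(
        var = var, time = reg$times_h, value = reg$dose_mg, method = "add")
    } else {
      if (reg$infusion_duration_min <= 0) {
        dose_umol <- reg$dose_mg * 1000 / model$compounds[[i]]$molecular_weight
        ev[[length(ev) + 1]] <- data.frame(
          var = off + 16L, time = reg$times_h, value = dose_umol,
          method = "add")
      } else {
        # zero-impulse events force solver restarts at infusion edges
        edges <- c(reg$times_h, reg$times_h + reg$infusion_duration_min / 60)
        ev[[length(ev) + 1]] <- data.frame(
          var = off + 16L, time = edges, value = 0, method = "add")
      }
    }
    for (m in reg$meals) {
      ev[[length(ev) + 1]] <- data.frame(var = off + 16L, time = m$time_h,
                                         value = 0, method = "add")
    }
  }
  ev <- dplyr::arrange(dplyr::bind_rows(ev), time, var)
  ev
}

#' Simulate a PBPK model
#'
#' Integrates the assembled system with a stiff-capable solver
#' (`deSolve::lsoda`, compiled right-hand side), restarting at every
#' dose, infusion edge and meal event. Returns venous plasma
#' concentration-time profiles per compound plus the full compartment
#' amounts and the cumulative-elimination ledger.
#'
#' @param model A `pbpk_model` from [assemble_model()].
#' @param duration_h Simulation horizon (defaults to the longest regimen).
#' @param grid_h Output grid step (h).
#' @param rtol,atol Solver tolerances.
#' @return A `pbpk_result` list: `profiles` (tibble: compound, time_h,
#'   conc_ng_mL), `amounts` (matrix of all states on the grid),
#'   `mass_balance` (tibble per compound: time_h, residual), `model`.
#' @export
simulate_profile <- function(model, duration_h = NULL, grid_h = 0.1,
                             rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "pbpk_model"))
  if (is.null(duration_h))
    duration_h <- max(purrr::map_dbl(model$regimens,
                                     ~ .x$duration_days * 24))
  grid <- seq(0, duration_h, by = grid_h)
  ev <- dose_events(model)
  ev <- ev[ev$time <= duration_h, , drop = FALSE]
  times <- sort(unique(c(grid, ev$time)))
  y0 <- stats::setNames(numeric(model$n_state), model$state_names)
  out <- deSolve::ode(
    y = y0, times = times, func = "pbpk_derivs", parms = model$parms,
    dllname = "pbpkddi", initfunc = "pbpk_init", method = "lsoda",
    rtol = rtol, atol = atol, maxsteps = 100000,
    events = list(data = ev))
  if (attr(out, "istate")[1] < 0)
    stop("ODE solver failed (istate = ", attr(out, "istate")[1], ")",
         call. = FALSE)
  keep <- out[, "time"] %in% grid
  out <- out[keep, , drop = FALSE]

  profiles <- purrr::imap_dfr(model$compounds, function(cmp, i) {
    off <- (i - 1L) * .NSTATE_C
    ven <- out[, 1 + off + 16L]
    v_ven <- model$parms[20]
    tibble::tibble(compound = cmp$name, time_h = out[, "time"],
                   conc_ng_mL = ven / v_ven * cmp$molecular_weight)
  })

  mb <- purrr::imap_dfr(model$compounds, function(cmp, i) {
    off <- (i - 1L) * .NSTATE_C
    reg <- model$regimens[[i]]
    mw <- cmp$molecular_weight
    t_out <- out[, "time"]
    dosed_mg <- vapply(t_out, function(tt) {
      if (reg$route == "iv_infusion" && reg$infusion_duration_min > 0) {
        dur <- reg$infusion_duration_min / 60
        frac <- pmin(pmax((tt - reg$times_h) / dur, 0), 1)
        sum(frac * reg$dose_mg)
      } else {
        # state snapshots at dose times precede the dose event
        sum(reg$times_h < tt) * reg$dose_mg
      }
    }, numeric(1))
    sys_umol <- rowSums(out[, 1 + off + 1:16, drop = FALSE]) +
      rowSums(out[, 1 + off + 32:37, drop = FALSE])
    gi_mg <- rowSums(out[, 1 + off + 17:31, drop = FALSE]) +
      out[, 1 + off + 38L]
    total_mg <- sys_umol * mw / 1000 + gi_mg
    denom <- pmax(dosed_mg, .Machine$double.eps)
    tibble::tibble(compound = cmp$name, time_h = t_out,
                   residual = ifelse(dosed_mg > 0,
                                     abs(total_mg - dosed_mg) / denom, 0))
  })

  structure(list(profiles = profiles, amounts = out,
                 mass_balance = mb, model = model),
            class = "pbpk_result")
}

#' @export
print.pbpk_result <- function(x, ...) {
  cat("<pbpk_result> ", length(x$model$compounds), " compound(s), ",
      nrow(x$profiles), " profile points, horizon ",
      max(x$profiles$time_h), " h\n", sep = "")
  invisible(x)
}

#' Noncompartmental metrics of a simulated profile
#'
#' Cmax/tmax from the grid maximum, AUC by linear trapezoid on the
#' output grid, Ctrough as the concentration at the interval end.
#'
#' @param result A `pbpk_result` (or a tibble with `time_h` and
#'   `conc_ng_mL`).
#' @param compound Compound name (defaults to the first).
#' @param interval `c(t_start, t_end)` in hours; defaults to the whole
#'   profile.
#' @return One-row tibble: compound, t_start, t_end, cmax_ng_mL,
#'   tmax_h, auc_last_ng_h_mL, ctrough_ng_mL.
#' @export
nca <- function(result, compound = NULL, interval = NULL) {
  prof <- if (inherits(result, "pbpk_result")) result$profiles else result
  if (is.null(compound)) compound <- prof$compound[1]
  prof <- prof[prof$compound == compound, ]
  if (is.null(interval)) interval <- range(prof$time_h)
  sel <- prof$time_h >= interval[1] - 1e-9 & prof$time_h <= interval[2] + 1e-9
  tt <- prof$time_h[sel]; cc <- prof$conc_ng_mL[sel]
  if (length(tt) < 2) stop("empty NCA interval", call. = FALSE)
  auc <- sum(diff(tt) * (utils::head(cc, -1) + utils::tail(cc, -1)) / 2)
  imax <- which.max(cc)
  tibble::tibble(compound = compound,
                 t_start = interval[1], t_end = interval[2],
                 cmax_ng_mL = cc[imax], tmax_h = tt[imax],
                 auc_last_ng_h_mL = auc,
                 ctrough_ng_mL = cc[length(cc)])
}
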