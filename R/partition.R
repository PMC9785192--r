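#' Tissue-to-plasma partition coefficients
#'
#' Computes perfusion-limited partition coefficients (Kp, tissue:plasma)
#' for every organ of an individual, using either the Rodgers-Rowland
#' mechanistic tissue-composition equations or the Poulin-Theil method.
#' The method choice changes only the Kp values, never the model
#' topology.
#'
#' For Rodgers-Rowland, moderate-to-strong bases (any basic pKa >= 7)
#' use the acidic-phospholipid association class, with the association
#' constant back-calculated from the blood-to-plasma ratio and
#' hematocrit; neutrals, weak bases and acids use the extended class
#' with tissue albumin binding via the tissue:plasma albumin ratio.
#'
#' @param compound A [compound_parameters()] object.
#' @param individual A `virtual_individual` from [build_individual()].
#' @param method Override of the compound's `partition_method`.
#' @return A tibble with columns `organ` and `kp` (all > 0), in the
#'   individual's organ ordering.
#' @export
#' @examples
#' kp <- partition_coefficients(builtin_compound("ruxolitinib"),
#'                              build_individual(demographics()))
partition_coefficients <- function(compound, individual,
                                   method = compound$partition_method) {
  org <- individual$organs
  req <- c("f_ew", "f_iw", "f_nl", "f_np", "ap_mg_g", "ra_tp")
  if (!all(req %in% names(org)))
    stop("individual lacks tissue composition fractions", call. = FALSE)
  kp <- switch(method,
    rodgers_rowland = kp_rodgers_rowland(compound, individual),
    poulin_theil = kp_poulin_theil(compound, individual),
    stop("unsupported partition method: ", method, call. = FALSE))
  stopifnot(all(kp > 0))
  tibble::tibble(organ = org$organ, kp = kp)
}

ionization_terms <- function(pka, ph) {
  # returns sum over charged species of cumulative 10^(pKa-pH) products
  if (is.null(pka) || nrow(pka) == 0) return(0)
  tot <- 0
  bases <- sort(pka$value[pka$type == "base"], decreasing = TRUE)
  run <- 1
  for (pk in bases) {
    run <- run * 10^(pk - ph)
    tot <- tot + run
  }
  acids <- sort(pka$value[pka$type == "acid"])
  run <- 1
  for (pk in acids) {
    run <- run * 10^(ph - pk)
    tot <- tot + run
  }
  tot
}

kp_rodgers_rowland <- function(compound, individual) {
  org <- individual$organs
  pl <- individual$plasma
  P <- 10^compound$logP
  fu <- compound$fu_p
  ph_p <- 7.4; ph_iw <- 7.0; ph_bc <- 7.22
  X <- ionization_terms(compound$pka, ph_p)   # plasma
  Y <- ionization_terms(compound$pka, ph_iw)  # intracellular water
  lip <- function(f_nl, f_np) (P * f_nl + (0.3 * P + 0.7) * f_np) / (1 + X)

  is_strong_base <- !is.null(compound$pka) &&
    any(compound$pka$type == "base" & compound$pka$value >= 7)

  if (is_strong_base) {
    # class 1: association to acidic phospholipids, Ka from blood cells
    hct <- individual$hematocrit
    bp <- compound$blood_plasma_ratio
    kpu_bc <- (bp - (1 - hct)) / (hct * fu)
    y_bc <- ionization_terms(compound$pka, ph_bc)
    f_iw_bc <- 0.603; f_nl_bc <- 0.0017; f_np_bc <- 0.0029; ap_bc <- 0.5
    ka_ap <- (kpu_bc - (1 + y_bc) / (1 + X) * f_iw_bc -
                (P * f_nl_bc + (0.3 * P + 0.7) * f_np_bc) / (1 + X)) *
      (1 + X) / (ap_bc * y_bc)
    ka_ap <- max(ka_ap, 0)
    kpu <- org$f_ew + (1 + Y) / (1 + X) * org$f_iw +
      ka_ap * org$ap_mg_g * Y / (1 + X) +
      lip(org$f_nl, org$f_np)
  } else {
    # class 2: neutrals, weak bases, acids; tissue albumin binding
    plasma_lip <- P * pl[["f_nl"]] + (0.3 * P + 0.7) * pl[["f_np"]]
    prot <- pmax(1 / fu - 1 - plasma_lip, 0) * org$ra_tp
    kpu <- org$f_ew + (1 + Y) / (1 + X) * org$f_iw +
      lip(org$f_nl, org$f_np) + prot
  }
  as.numeric(kpu * fu)
}

kp_poulin_theil <- function(compound, individual) {
  org <- individual$organs
  pl <- individual$plasma
  P <- 10^compound$logP
  fu <- compound$fu_p
  fu_t <- 1 / (1 + 0.5 * (1 - fu) / fu)
  f_w_t <- org$f_ew + org$f_iw
  f_w_p <- pl[["f_w"]]
  denom <- P * (pl[["f_nl"]] + 0.3 * pl[["f_np"]]) +
    (f_w_p + 0.7 * pl[["f_np"]])
  num <- P * (org$f_nl + 0.3 * org$f_np) + (f_w_t + 0.7 * org$f_np)
  kp <- num / denom * fu / fu_t
  # adipose: octanol-water D at plasma pH, no tissue protein binding
  ad <- org$organ == "adipose"
  X <- ionization_terms(compound$pka, 7.4)
  D <- P / (1 + X)
  num_ad <- D * (org$f_nl[ad] + 0.3 * org$f_np[ad]) +
    (f_w_t[ad] + 0.7 * org$f_np[ad])
  denom_ad <- D * (pl[["f_nl"]] + 0.3 * pl[["f_np"]]) +
    (f_w_p + 0.7 * pl[["f_np"]])
  kp[ad] <- num_ad / denom_ad * fu
  as.numeric(kp)
}
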