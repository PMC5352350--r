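#' Die-casting decision
#'
#' Commits a stochastic cell decision by comparing a uniform draw against
#' the behavior probability.
#'
#' @param p Probability in `[0, 1]`.
#' @return TRUE with probability `p`; reproducible under a seeded RNG.
#' @export
decide <- function(p) {
  if (!is.finite(p) || p < 0 || p > 1) stop("decide(): p must be in [0, 1]")
  stats::runif(1) < p
}

#' Hill-shaped behavior probability
#'
#' `pmax * x^n / (H^n + x^n)`: the saturating coupling used to turn local
#' signals (stiffness, cytokine levels, drug doses) into per-step behavior
#' probabilities. Bounded by `pmax`, equal to `pmax/2` at `x = H`.
#'
#' @param x Non-negative signal level.
#' @param pmax Probability ceiling in `[0, 1]`.
#' @param H Half-saturation (> 0), in the units of `x`.
#' @param n Hill exponent (>= 1).
#' @return Probability in `[0, pmax]`.
#' @export
hill_prob <- function(x, pmax, H, n = 1) {
  if (any(x < 0)) stop("hill_prob(): x must be >= 0")
  if (any(pmax < 0) || any(pmax > 1)) stop("hill_prob(): pmax must be in [0, 1]")
  if (any(H <= 0) || any(n < 1)) stop("hill_prob(): H > 0 and n >= 1 required")
  pmax * x^n / (H^n + x^n)
}

#' Moore neighborhood of a lattice site
#' @param site Integer `c(x, y, z)`.
#' @param dims Lattice dimensions `c(nx, ny, nz)`.
#' @return Integer matrix (up to 26 rows) of in-bounds neighbor sites.
#' @export
moore_neighbors <- function(site, dims) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  nb <- sweep(off, 2, site, "+")
  ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 &
    nb[, 2] <= dims[2] & nb[, 3] >= 1 & nb[, 3] <= dims[3]
  unname(nb[ok, , drop = FALSE])
}

#' Myeloma-initiating-cell fate choice
#'
#' A cycling MIC either self-renews (two MIC daughters) or differentiates
#' (two MM daughters); the parent is consumed either way. The self-renewal
#' probability is a Hill function of the stiffness-derived proliferation
#' signal.
#'
#' @param prolif_signal Local stiffness signal in Pa.
#' @param rules Behavior constants (see [habm_rules()]).
#' @return `"SELF_RENEW"` or `"DIFFERENTIATE"`.
#' @export
mic_fate <- function(prolif_signal, rules = habm_rules()) {
  q <- hill_prob(prolif_signal, rules$mic$selfrenew_pmax,
                 rules$mic$selfrenew_H, rules$mic$selfrenew_n)
  if (decide(q)) "SELF_RENEW" else "DIFFERENTIATE"
}

#' Daughter placement for a dividing agent
#'
#' The daughter is placed uniformly at random among the free Moore
#' neighbor sites of the parent; if none is free the division is deferred
#' and the parent remains in M-phase.
#'
#' @param site Parent site `c(x, y, z)`.
#' @param occupied Logical 3D array (TRUE = site not available).
#' @return Integer site for the daughter, or `NULL` when deferred.
#' @export
divide_site <- function(site, occupied) {
  nb <- moore_neighbors(site, dim(occupied))
  free <- nb[!occupied[nb], , drop = FALSE]
  if (!nrow(free)) return(NULL)
  free[sample.int(nrow(free), 1), ]
}

#' One-step migration move
#'
#' Moves one site toward the kind-specific target: MIC climbs the local
#' stiffness gradient, CD8 heads for the nearest myeloma cell within its
#' sensing radius, Treg for the nearest CD8, and MM performs an unbiased
#' random walk. Ties are broken uniformly at random; if no neighbor site
#' is free the agent stays.
#'
#' @param site Current site.
#' @param occupied Logical 3D occupancy array.
#' @param kind One of `"MIC"`, `"MM"`, `"CD8"`, `"TREG"`.
#' @param stiffness_at Optional function(site-matrix) -> Pa, used by MIC.
#' @param target Optional target site (`c(x, y, z)`) for CD8/Treg
#'   chemotaxis; `NULL` means no target in range (random walk).
#' @return The new site, or the old site when blocked/staying.
#' @export
migrate_step <- function(site, occupied, kind, stiffness_at = NULL,
                         target = NULL) {
  nb <- moore_neighbors(site, dim(occupied))
  free <- nb[!occupied[nb], , drop = FALSE]
  if (!nrow(free)) return(site)
  score <- switch(kind,
    MIC = if (is.null(stiffness_at)) rep(0, nrow(free)) else stiffness_at(free),
    CD8 = ,
    TREG = if (is.null(target)) rep(0, nrow(free)) else
      -sqrt(rowSums(sweep(free, 2, target)^2)),
    MM = rep(0, nrow(free)))
  best <- which(score == max(score))
  free[best[sample.int(length(best), 1)], ]
}

#' CTL lysis attempt on an adjacent myeloma cell
#'
#' Kill with probability `p_lysis`, attenuated by the protection factor
#' when the target is attached to a BMSC (cell-adhesion-mediated immune
#' protection).
#'
#' @param cd8_site,target_site Sites of the CTL and the target; must be
#'   Moore-adjacent.
#' @param attached Whether the target is BMSC-attached.
#' @param rules Behavior constants.
#' @return `"KILLED"` or `"ESCAPED"`.
#' @export
attempt_lysis <- function(cd8_site, target_site, attached = FALSE,
                          rules = habm_rules()) {
  if (max(abs(cd8_site - target_site)) > 1 || all(cd8_site == target_site))
    stop("attempt_lysis(): cells are not adjacent")
  p <- rules$cd8$p_lysis * if (attached) rules$cd8$attach_protection else 1
  if (decide(p)) "KILLED" else "ESCAPED"
}

#' Treg suppression of an adjacent CD8+ T cell
#'
#' With the suppression probability, a second dice roll selects cell-cycle
#' arrest (the CD8 skips its next proliferation opportunity) or apoptosis.
#'
#' @param rules Behavior constants.
#' @return `"ARREST"`, `"APOPTOSIS"`, or `"NONE"`.
#' @export
treg_suppress <- function(rules = habm_rules()) {
  if (!decide(rules$treg$p_suppress)) return("NONE")
  if (decide(rules$treg$arrest_frac)) "ARREST" else "APOPTOSIS"
}

#' CD8+ proliferation probability
#'
#' Baseline probability decreased by the local TGF-beta level and by
#' adjacent Tregs, increased by a lenalidomide Hill term; clamped to
#' `[0, 1]`.
#'
#' @param tgfb Local TGF-beta level (relative units, >= 0).
#' @param treg_count Tregs in the Moore neighborhood (>= 0).
#' @param len_uM Lenalidomide dose in uM (>= 0).
#' @param rules Behavior constants.
#' @return Probability in `[0, 1]`.
#' @export
cd8_proliferation_prob <- function(tgfb, treg_count = 0, len_uM = 0,
                                   rules = habm_rules()) {
  if (min(tgfb, treg_count, len_uM) < 0) stop("inputs must be >= 0")
  r <- rules$cd8
  p <- r$p_div0 / (1 + (tgfb / r$tgfb_H)^r$tgfb_n) /
    (1 + treg_count / r$treg_K) +
    r$len_pmax * len_uM / (r$len_H + len_uM)
  min(max(p, 0), 1)
}

#' Treg proliferation probability
#'
#' Hill-increasing in local TGF-beta, suppressed by lenalidomide.
#'
#' @inheritParams cd8_proliferation_prob
#' @return Probability in `[0, 1]`.
#' @export
treg_proliferation_prob <- function(tgfb, len_uM = 0, rules = habm_rules()) {
  r <- rules$treg
  p <- hill_prob(tgfb, r$p_div_pmax, r$tgfb_H, r$tgfb_n) *
    (1 - r$len_supp_max * len_uM / (r$len_supp_H + len_uM))
  min(max(p, 0), 1)
}

#' Bortezomib kill probability for MM cells (per 2-h step)
#' @param btz_nM Dose in nM.
#' @param rules Behavior constants.
#' @return Probability in `[0, 1]`.
#' @export
mm_btz_kill_prob <- function(btz_nM, rules = habm_rules()) {
  hill_prob(btz_nM, rules$mm$btz_pmax, rules$mm$btz_H, 1)
}

#' Thalidomide attenuation factor on SDF-1-triggered BMSC stiffening
#'
#' Multiplies the effective SDF-1 input of the BMSC signaling system and
#' the BMSC TGF-beta secretion rate; 1 at zero dose, decreasing with
#' dose.
#'
#' @param thal_uM Dose in uM.
#' @param rules Behavior constants.
#' @return Factor in `(0, 1]`.
#' @export
thal_attenuation <- function(thal_uM, rules = habm_rules()) {
  r <- rules$bmsc
  1 - r$thal_emax * thal_uM / (r$thal_H + thal_uM)
}

#' Per-step MIC death probability implied by the survival ODE
#'
#' Converts the day-6 Survival readout ratio (treated vs untreated at the
#' same stiffness) into a per-2-h death probability spread uniformly over
#' the 72 steps of the 144-h exposure, plus the baseline apoptosis rate.
#'
#' @param stiffness_pa Local stiffness in Pa.
#' @param btz_nM Bortezomib dose in nM.
#' @param params MIC ODE parameters.
#' @param rules Behavior constants.
#' @return Probability in `[0, 1]`.
#' @export
mic_death_prob <- function(stiffness_pa, btz_nM, params = habm_params()$mic,
                           rules = habm_rules()) {
  base <- rules$mic$p_apop0
  if (btz_nM <= 0) return(base)
  s1 <- mic_survival_rate(stiffness_pa, btz_nM, params, t = 144)
  s0 <- mic_survival_rate(stiffness_pa, 0, params, t = 144)
  ratio <- min(max(s1 / max(s0, 1e-12), 1e-9), 1)
  min(base + (1 - ratio^(1 / 72)), 1)
}
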