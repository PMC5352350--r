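#' Saturating Hill activation
#'
#' The shared production term used throughout the intracellular signaling
#' models: `k * x / (H + x)`. Bounded above by `k`, monotone increasing in
#' `x`, and equal to `k/2` at `x = H`.
#'
#' @param x Non-negative input level (fold-change units).
#' @param k Maximal production rate (per hour).
#' @param H Half-saturation constant (fold-change units), strictly positive.
#' @return Production rate, in `[0, k]`.
#' @examples
#' hill(0, 2, 0.5)   # 0
#' hill(0.5, 2, 0.5) # 1, half-saturation
#' @export
hill <- function(x, k, H) {
  if (any(!is.finite(H)) || any(H <= 0)) stop("hill(): H must be > 0")
  if (any(!is.finite(x)) || any(x < 0)) stop("hill(): x must be >= 0")
  if (any(!is.finite(k)) || any(k < 0)) stop("hill(): k must be >= 0")
  k * x / (H + x)
}

#' Construct a Hill-activation signaling network
#'
#' A directed network in which every edge contributes a saturating Hill
#' production term on its target and every non-input species carries one
#' first-order degradation term. External drug doses may subtract a
#' dose-dependent Hill term from designated targets.
#'
#' @param species Character vector of all node names (inputs included).
#' @param inputs Subset of `species` held constant during integration.
#' @param edges Data frame with columns `source`, `target`, `k`, `H`
#'   (the latter two are parameter ids, e.g. `"k1"`, `"H1"`).
#' @param degradations Named character vector mapping each non-input
#'   species to its decay-rate id (e.g. `c(PI3K = "d1")`).
#' @param inhibitions Optional data frame with columns `dose` (external
#'   dose symbol), `target`, `K`, `H` (parameter ids) for drug terms.
#' @param outputs Designated readout nodes.
#' @return An object of class `signaling_network`.
#' @export
signaling_network <- function(species, inputs, edges, degradations,
                              inhibitions = NULL, outputs = character()) {
  stopifnot(is.character(species), all(inputs %in% species))
  if (!all(edges$source %in% species) || !all(edges$target %in% species))
    stop("signaling_network(): edge endpoints must be declared species")
  non_inputs <- setdiff(species, inputs)
  if (!setequal(names(degradations), non_inputs))
    stop("signaling_network(): every non-input species needs exactly one degradation term")
  if (!is.null(inhibitions) && !all(inhibitions$target %in% non_inputs))
    stop("signaling_network(): inhibition targets must be non-input species")
  structure(
    list(species = species, inputs = inputs,
         states = non_inputs, edges = edges,
         degradations = degradations, inhibitions = inhibitions,
         outputs = outputs),
    class = "signaling_network")
}

#' @export
print.signaling_network <- function(x, ...) {
  cat("Hill-activation signaling network\n")
  cat("  inputs: ", paste(x$inputs, collapse = ", "), "\n")
  cat("  states: ", paste(x$states, collapse = ", "), "\n")
  cat("  edges:  ", nrow(x$edges), " Hill productions\n", sep = "")
  if (!is.null(x$inhibitions))
    cat("  drug terms on: ", paste(x$inhibitions$target, collapse = ", "), "\n")
  invisible(x)
}

#' SDF-1/CXCR4 signaling network of the BMSC compartment
#'
#' Seven-state network translating the local SDF-1 level into a
#' dimensionless stiffness state: SDF1 activates PI3K and MEK; PI3K
#' activates FAK and (with MEK) RhoA; MEK activates ERK; RhoA and ERK
#' converge on MYL2; FAK and MYL2 drive the stiffness output. Parameters
#' are k1-k10, H1-H10 (one pair per edge) and d1-d7 (one decay per state).
#'
#' @return A `signaling_network` with input `SDF1` and output `stiffness`.
#' @export
build_bmsc_network <- function() {
  edges <- data.frame(
    source = c("SDF1", "SDF1", "PI3K", "PI3K", "MEK", "MEK", "RhoA", "ERK",
               "FAK", "MYL2"),
    target = c("PI3K", "MEK", "FAK", "RhoA", "RhoA", "ERK", "MYL2", "MYL2",
               "stiffness", "stiffness"),
    k = paste0("k", 1:10), H = paste0("H", 1:10),
    stringsAsFactors = FALSE)
  degr <- c(PI3K = "d1", MEK = "d2", FAK = "d3", RhoA = "d4", ERK = "d5",
            MYL2 = "d6", stiffness = "d7")
  signaling_network(
    species = c("SDF1", "PI3K", "MEK", "FAK", "RhoA", "ERK", "MYL2", "stiffness"),
    inputs = "SDF1", edges = edges, degradations = degr,
    outputs = "stiffness")
}

#' Integrin/FAK signaling network of the MIC compartment
#'
#' Nine-state network translating local niche stiffness (and the local
#' bortezomib dose `D1`) into adhesion and survival probabilities:
#' stiffness activates FAK; FAK activates Rac and PI3K; PI3K feeds Rac and
#' AKT; Rac drives JNK and NFKB; AKT drives NFKB; JNK-cJUN drives
#' Adhesion; NFKB drives Survival, which additionally carries the
#' dose-dependent inhibition `-K_BTZ * D1 / (H_BTZ + D1)`.
#'
#' @return A `signaling_network` with inputs `stiffness`, `D1` and outputs
#'   `Adhesion`, `Survival`.
#' @export
build_mic_network <- function() {
  edges <- data.frame(
    source = c("stiffness", "FAK", "PI3K", "FAK", "PI3K", "Rac", "JNK",
               "Rac", "AKT", "cJUN", "NFKB"),
    target = c("FAK", "Rac", "Rac", "PI3K", "AKT", "JNK", "cJUN",
               "NFKB", "NFKB", "Adhesion", "Survival"),
    k = paste0("k", 1:11), H = paste0("H", 1:11),
    stringsAsFactors = FALSE)
  degr <- c(FAK = "d1", Rac = "d2", PI3K = "d3", AKT = "d4", JNK = "d5",
            cJUN = "d6", NFKB = "d7", Adhesion = "d8", Survival = "d9")
  inhib <- data.frame(dose = "D1", target = "Survival",
                      K = "K_BTZ", H = "H_BTZ", stringsAsFactors = FALSE)
  signaling_network(
    species = c("stiffness", "D1", "FAK", "Rac", "PI3K", "AKT", "JNK",
                "cJUN", "NFKB", "Adhesion", "Survival"),
    inputs = c("stiffness", "D1"), edges = edges, degradations = degr,
    inhibitions = inhib, outputs = c("Adhesion", "Survival"))
}

check_parameters <- function(net, params) {
  need <- c(net$edges$k, net$edges$H, unname(net$degradations),
            if (!is.null(net$inhibitions)) c(net$inhibitions$K, net$inhibitions$H))
  have <- c(params$k, params$H, params$d, unlist(params$drug))
  miss <- setdiff(need, names(have))
  if (length(miss))
    stop("missing parameters: ", paste(miss, collapse = ", "))
  if (any(!is.finite(have)) || any(have <= 0))
    stop("all parameters must be strictly positive and finite")
  invisible(TRUE)
}

flat_params <- function(params) {
  c(params$k, params$H, params$d, unlist(params$drug))
}

# Right-hand side of the assembled ODE system. Inputs (and doses) are held
# constant; Hill arguments are floored at 0 so a transiently negative state
# (only Survival can cross 0, via its subtractive drug term) cannot inject
# negative production downstream. Parameter ids are resolved to numeric
# vectors once, outside the solver loop.
network_rhs <- function(net, params, inputs, doses) {
  p <- flat_params(params)
  states <- net$states
  ns <- length(states)
  lv_names <- c(states, names(inputs), names(doses))
  lv_const <- c(rep(0, ns), unname(inputs), unname(doses))
  src <- match(net$edges$source, lv_names)
  tgt <- match(net$edges$target, states)
  kv <- unname(p[net$edges$k])
  Hv <- unname(p[net$edges$H])
  dv <- unname(p[unname(net$degradations[states])])
  # 0/1 aggregation matrix: one row per state, one column per edge
  A <- matrix(0, ns, length(tgt))
  A[cbind(tgt, seq_along(tgt))] <- 1
  inh <- rep(0, ns)
  if (!is.null(net$inhibitions)) {
    for (i in seq_len(nrow(net$inhibitions))) {
      D <- lv_const[match(net$inhibitions$dose[i], lv_names)]
      j <- match(net$inhibitions$target[i], states)
      inh[j] <- inh[j] + p[[net$inhibitions$K[i]]] * D /
        (p[[net$inhibitions$H[i]]] + D)
    }
  }
  function(t, y, parms) {
    lv <- lv_const
    lv[seq_len(ns)] <- pmax(y, 0)
    x <- lv[src]
    list(as.vector(A %*% (kv * x / (Hv + x))) - inh - dv * y)
  }
}

#' Integrate a signaling network
#'
#' Solves the coupled Hill-activation ODE system with `deSolve::lsoda`
#' (stiff-capable, adaptive; rtol 1e-6, atol 1e-9). All non-input states
#' start at 1 (fold-change units relative to t = 0) unless overridden;
#' input species are held constant at the supplied levels. Returned states
#' are clamped at 0 from below.
#'
#' @param net A `signaling_network`.
#' @param params Parameter list with elements `k`, `H`, `d` (named numeric
#'   vectors) and optionally `drug` (named list/vector of drug constants).
#' @param inputs Named vector covering all of `net$inputs`.
#' @param times Time grid in hours, starting at 0.
#' @param y0 Optional named initial state for the non-input species.
#' @param doses Named vector of external dose symbols (e.g. `c(D1 = 5)`);
#'   defaults to 0 for any symbol the network declares.
#' @return A `time_course`: list with `times` and `values` (matrix species
#'   x time, inputs included as constant rows).
#' @export
integrate_network <- function(net, params, inputs, times, y0 = NULL,
                              doses = NULL) {
  check_parameters(net, params)
  if (!all(net$inputs %in% names(inputs)))
    stop("inputs must cover: ", paste(net$inputs, collapse = ", "))
  if (times[1] != 0) stop("time grid must start at 0")
  dose_syms <- if (is.null(net$inhibitions)) character() else unique(net$inhibitions$dose)
  # input species doubling as dose symbols (MIC net: D1) are taken from `inputs`
  all_in <- inputs[intersect(net$inputs, names(inputs))]
  d <- stats::setNames(rep(0, length(dose_syms)), dose_syms)
  if (!is.null(doses)) d[names(doses)] <- doses
  d[intersect(dose_syms, names(all_in))] <- all_in[intersect(dose_syms, names(all_in))]
  if (any(d < 0)) stop("doses must be non-negative")
  inp <- all_in[setdiff(net$inputs, dose_syms)]
  if (any(inp < 0)) stop("input levels must be non-negative")
  y <- stats::setNames(rep(1, length(net$states)), net$states)
  if (!is.null(y0)) y[names(y0)] <- y0
  rhs <- network_rhs(net, params, inp, d)
  sol <- deSolve::lsoda(y, times, rhs, parms = NULL,
                        rtol = 1e-6, atol = 1e-9)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed (lsoda istate ",
         attr(sol, "istate")[1], "); check parameter magnitudes")
  vals <- t(pmax(sol[, net$states, drop = FALSE], 0))
  vals <- rbind(vals, matrix(rep(c(inp, d[setdiff(dose_syms, names(inp))]),
                                 each = length(times)),
                             ncol = length(times), byrow = TRUE,
                             dimnames = list(setdiff(net$species, net$states))))
  vals <- vals[net$species, , drop = FALSE]
  structure(list(times = times, values = vals), class = "time_course")
}

#' Algebraic steady state of an acyclic signaling network
#'
#' Solves production = degradation node-by-node in topological order; used
#' as an independent oracle for long-time integration.
#'
#' @inheritParams integrate_network
#' @return Named steady-state vector over the non-input species.
#' @export
network_fixed_point <- function(net, params, inputs, doses = NULL) {
  p <- flat_params(params)
  lv <- as.list(inputs)
  dose_syms <- if (is.null(net$inhibitions)) character() else unique(net$inhibitions$dose)
  for (s in dose_syms) if (is.null(lv[[s]])) lv[[s]] <- 0
  if (!is.null(doses)) lv[names(doses)] <- doses
  remaining <- net$states
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(s) {
      src <- net$edges$source[net$edges$target == s]
      all(src %in% names(lv))
    }, logical(1))]
    if (!length(ready)) stop("network has a cycle; no topological order")
    for (s in ready) {
      idx <- which(net$edges$target == s)
      prod <- sum(vapply(idx, function(i) {
        x <- lv[[net$edges$source[i]]]
        p[[net$edges$k[i]]] * x / (p[[net$edges$H[i]]] + x)
      }, numeric(1)))
      if (!is.null(net$inhibitions)) {
        jdx <- which(net$inhibitions$target == s)
        for (j in jdx) {
          D <- lv[[net$inhibitions$dose[j]]]
          prod <- prod - p[[net$inhibitions$K[j]]] * D / (p[[net$inhibitions$H[j]]] + D)
        }
      }
      lv[[s]] <- max(prod / p[[net$degradations[[s]]]], 0)
    }
    remaining <- setdiff(remaining, ready)
  }
  unlist(lv[net$states])
}

#' Map the dimensionless stiffness state to Pascals
#'
#' Affine, clamped map anchored at two observations: the resting state
#' (all-ones initial condition) corresponds to 400 Pa, and the saturating
#' SDF-1 response at 60 min corresponds to the 530 Pa ceiling.
#'
#' @param x Dimensionless stiffness state (>= 0).
#' @param calib Calibration list with `x_sat` (stiffness state reached at
#'   60 min under the saturating SDF-1 reference input 1.0), and optional
#'   `baseline_pa` (400) / `max_pa` (530).
#' @return Stiffness in Pa, clamped to `[baseline_pa, max_pa]`.
#' @export
stiffness_map <- function(x, calib) {
  lo <- calib$baseline_pa %||% 400
  hi <- calib$max_pa %||% 530
  pmin(pmax(lo + (hi - lo) * (x - 1) / (calib$x_sat - 1), lo), hi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' BMSC stiffness response to SDF-1
#'
#' Integrates the BMSC signaling network from the all-ones resting state
#' under a constant relative SDF-1 level and maps the stiffness state to
#' Pascals. The relative dose scale is anchored so that 1.0 is the
#' saturating 100 ng/ml reference; the calibration constant
#' `sdf1_rel_per_nM` places molar doses on that scale.
#'
#' The stiffness state is referenced to the time-matched zero-dose
#' trajectory (the unstimulated control), so a zero dose maps to exactly
#' the 400 Pa baseline at any evaluation time.
#'
#' @param sdf1 Relative SDF-1 level (1.0 = saturating reference), >= 0.
#' @param params BMSC parameter list (see [habm_params()]).
#' @param t Evaluation time in hours (default 1 h = the 60-min response).
#' @return Stiffness in Pa (scalar, or vector over `sdf1`).
#' @export
bmsc_stiffness_response <- function(sdf1, params = habm_params()$bmsc,
                                    t = 1) {
  if (any(sdf1 < 0)) stop("sdf1 must be >= 0")
  net <- build_bmsc_network()
  x_at <- function(s) {
    integrate_network(net, params, c(SDF1 = s),
                      times = c(0, t))$values["stiffness", 2]
  }
  x0 <- x_at(0)
  vapply(sdf1, function(s) {
    stiffness_map(1 + x_at(s) - x0, params$calib)
  }, numeric(1))
}

#' Convert an SDF-1 dose in nM to the model's relative scale
#' @param nM Dose in nM.
#' @param params BMSC parameter list.
#' @return Relative SDF-1 level.
#' @export
sdf1_rel_from_nM <- function(nM, params = habm_params()$bmsc) {
  params$calib$sdf1_rel_per_nM * nM
}

mic_inputs <- function(stiffness_pa, btz_nM) {
  c(stiffness = stiffness_pa / 530, D1 = btz_nM)
}

#' MIC survival probability under local stiffness and bortezomib
#'
#' Integrates the MIC signaling network with the niche stiffness (Pa,
#' normalised by the 530 Pa ceiling on input) and bortezomib dose `D1`
#' held constant, and returns the Survival readout clamped to `[0, 1]`.
#' Decreasing in the dose, increasing in stiffness.
#'
#' @param stiffness_pa Local stiffness in Pa.
#' @param btz_nM Bortezomib dose in nM (>= 0).
#' @param params MIC parameter list (see [habm_params()]).
#' @param t Evaluation time in hours (default 144 h = day 6).
#' @return Survival probability in `[0, 1]`.
#' @export
mic_survival_rate <- function(stiffness_pa, btz_nM = 0,
                              params = habm_params()$mic, t = 144) {
  if (any(btz_nM < 0)) stop("btz_nM must be >= 0")
  net <- build_mic_network()
  tc <- integrate_network(net, params, mic_inputs(stiffness_pa, btz_nM),
                          times = c(0, t))
  min(max(tc$values["Survival", 2], 0), 1)
}

#' MIC adhesion probability under local stiffness
#'
#' The Adhesion readout of the MIC signaling network (the stiffness-driven
#' component) plus a constant 20% contribution from non-stiffness factors,
#' clamped to `[0, 1]`. Monotone non-decreasing in stiffness.
#'
#' @inheritParams mic_survival_rate
#' @param t Evaluation time in hours (default 24 h, the adhesion assay time).
#' @param component One of `"total"` (default) or `"stiffness"` (the ODE
#'   component alone, without the constant floor).
#' @return Adhesion probability in `[0, 1]`.
#' @export
mic_adhesion_rate <- function(stiffness_pa, params = habm_params()$mic,
                              t = 24, component = c("total", "stiffness")) {
  component <- match.arg(component)
  net <- build_mic_network()
  tc <- integrate_network(net, params, mic_inputs(stiffness_pa, 0),
                          times = c(0, t))
  comp <- min(max(tc$values["Adhesion", 2], 0), 1)
  if (component == "stiffness") return(comp)
  min(comp + (params$calib$adhesion_floor %||% 0.2), 1)
}

#' Export a time course as a data frame
#' @param tc A `time_course` from [integrate_network()].
#' @return Data frame with `time_h` and one column per species.
#' @export
time_course_frame <- function(tc) {
  data.frame(time_h = tc$times, t(tc$values), check.names = FALSE)
}
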