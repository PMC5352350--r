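#' L1 calibration objective
#'
#' Sum of absolute differences between measured fold-changes and the model
#' trajectories, over every observed (species, time) pair. This is the
#' objective minimised by the genetic algorithm for both signaling
#' networks.
#'
#' @param params Parameter list (`k`, `H`, `d`, optionally `drug`).
#' @param net A `signaling_network`.
#' @param obs Observation table: data frame with columns `species`,
#'   `time_h`, `fold_change`. Entries at `time_h == 0` are the
#'   normalisation anchor (all 1).
#' @param inputs Named input levels held constant during integration.
#' @return Non-negative loss.
#' @export
l1_objective <- function(params, net, obs, inputs) {
  miss <- setdiff(unique(obs$species), net$species)
  if (length(miss))
    stop("observed species not in network: ", paste(miss, collapse = ", "))
  times <- sort(unique(c(0, obs$time_h)))
  tc <- integrate_network(net, params, inputs, times)
  sim <- tc$values[cbind(match(obs$species, rownames(tc$values)),
                         match(obs$time_h, times))]
  sum(abs(obs$fold_change - sim))
}

ga_param_template <- function(net) {
  ids <- list(k = unique(net$edges$k), H = unique(net$edges$H),
              d = unique(unname(net$degradations)))
  if (!is.null(net$inhibitions))
    ids$drug <- unique(c(net$inhibitions$K, net$inhibitions$H))
  ids
}

vec_to_params <- function(theta, template) {
  out <- list()
  i <- 0
  for (cls in names(template)) {
    n <- length(template[[cls]])
    out[[cls]] <- stats::setNames(theta[i + seq_len(n)], template[[cls]])
    i <- i + n
  }
  if (!is.null(out$drug)) out$drug <- as.list(out$drug)
  out
}

params_to_vec <- function(params, template) {
  unlist(lapply(names(template), function(cls) {
    v <- if (cls == "drug") unlist(params$drug) else params[[cls]]
    unname(v[template[[cls]]])
  }))
}

default_ga_bounds <- function(template) {
  lo <- hi <- numeric(0)
  for (cls in names(template)) {
    n <- length(template[[cls]])
    if (cls == "H") { l <- 1e-2; u <- 1e1 } else { l <- 1e-3; u <- 1e2 }
    lo <- c(lo, rep(l, n)); hi <- c(hi, rep(u, n))
  }
  list(lower = lo, upper = hi)
}

#' Fit signaling-network parameters with a genetic algorithm
#'
#' Real-coded GA on log-scaled parameters: tournament selection, blend
#' crossover, gaussian mutation, elitism (the best individual always
#' survives, so the reported loss is non-increasing across generations).
#' Optionally followed by a Nelder-Mead polish of the best individual.
#' Bounds default to log-uniform k, d in 1e-3..1e2 and H in 1e-2..1e1,
#' spanning the normalised fold-change data scale.
#'
#' @param net A `signaling_network`.
#' @param obs Observation table (see [l1_objective()]).
#' @param inputs Named input levels used during calibration.
#' The fit may use several experimental conditions at once (e.g. the two
#' seeding stiffnesses of the adhesion assays, or drug-present vs
#' drug-free survival): pass a `calibration_set` (see
#' [calibration_observations()]) as `obs`, in which case `inputs` is
#' taken per condition and the objective is the sum of the per-condition
#' L1 losses.
#'
#' @param ga_config List overriding any of: `pop_size` (100),
#'   `generations` (300), `lower`/`upper` bounds (per-parameter vectors),
#'   `tournament` (3), `p_crossover` (0.9), `p_mutation` (0.15),
#'   `mut_sd` (0.35, log10 scale), `elite` (2), `refine` (TRUE),
#'   `refine_maxit` (400).
#' @param seed Integer seed; the fit is reproducible given the seed.
#' @param trace If TRUE, print best loss every 25 generations.
#' @return Parameter list with attributes `loss` and `history` (best loss
#'   per generation).
#' @export
fit_parameters_ga <- function(net, obs, inputs = NULL, ga_config = list(),
                              seed = 1, trace = FALSE) {
  cfg <- utils::modifyList(list(
    pop_size = 100, generations = 300, tournament = 3, p_crossover = 0.9,
    p_mutation = 0.15, mut_sd = 0.35, elite = 2, refine = TRUE,
    refine_maxit = 400), ga_config)
  template <- ga_param_template(net)
  b <- default_ga_bounds(template)
  if (!is.null(cfg$lower)) b$lower <- cfg$lower
  if (!is.null(cfg$upper)) b$upper <- cfg$upper
  if (any(b$lower <= 0)) stop("bounds must be strictly positive")
  llo <- log10(b$lower); lhi <- log10(b$upper)
  np <- length(llo)

  conditions <- if (inherits(obs, "calibration_set")) obs
    else list(list(inputs = inputs, obs = obs))
  residuals_of <- function(ltheta) {
    p <- vec_to_params(10^ltheta, template)
    unlist(lapply(conditions, function(cd) {
      times <- sort(unique(c(0, cd$obs$time_h)))
      tc <- integrate_network(net, p, cd$inputs, times)
      sim <- tc$values[cbind(match(cd$obs$species, rownames(tc$values)),
                             match(cd$obs$time_h, times))]
      cd$obs$fold_change - sim
    }))
  }
  loss_of <- function(ltheta) {
    tryCatch(sum(abs(residuals_of(ltheta))), error = function(e) Inf)
  }
  l2_of <- function(ltheta) {
    tryCatch(sum(residuals_of(ltheta)^2), error = function(e) Inf)
  }

  set.seed(seed)
  pop <- matrix(stats::runif(cfg$pop_size * np, llo, lhi),
                nrow = cfg$pop_size, byrow = TRUE)
  fit <- apply(pop, 1, loss_of)
  if (all(!is.finite(fit))) stop("no feasible individual in initial population")
  history <- numeric(cfg$generations)

  for (g in seq_len(cfg$generations)) {
    ord <- order(fit)
    newpop <- pop[ord[seq_len(cfg$elite)], , drop = FALSE]
    while (nrow(newpop) < cfg$pop_size) {
      pick <- function() {
        cand <- sample.int(cfg$pop_size, cfg$tournament)
        cand[which.min(fit[cand])]
      }
      p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
      if (stats::runif(1) < cfg$p_crossover) {
        a <- stats::runif(np, -0.25, 1.25)  # blend (BLX-alpha style)
        child <- a * p1 + (1 - a) * p2
      } else child <- p1
      mut <- stats::runif(np) < cfg$p_mutation
      child[mut] <- child[mut] + stats::rnorm(sum(mut), 0, cfg$mut_sd)
      newpop <- rbind(newpop, pmin(pmax(child, llo), lhi))
    }
    pop <- newpop
    fit <- c(fit[ord[seq_len(cfg$elite)]],
             apply(pop[-seq_len(cfg$elite), , drop = FALSE], 1, loss_of))
    history[g] <- min(fit)
    if (trace && g %% 25 == 0)
      message(sprintf("generation %d: best loss %.5f", g, min(fit)))
  }

  best <- pop[which.min(fit), ]
  best_loss <- min(fit)
  if (isTRUE(cfg$refine)) {
    # two-stage polish: BFGS on the smooth least-squares surrogate finds
    # the basin (the L1 surface is piecewise-linear near zero residuals),
    # then Nelder-Mead touches up the L1 objective itself
    op2 <- tryCatch(
      stats::optim(best, l2_of, method = "BFGS",
                   control = list(maxit = 300)),
      error = function(e) NULL)
    if (!is.null(op2)) {
      cand <- pmin(pmax(op2$par, llo), lhi)
      if (loss_of(cand) < best_loss) {
        best <- cand
        best_loss <- loss_of(cand)
      }
    }
    op <- stats::optim(best, loss_of, method = "Nelder-Mead",
                       control = list(maxit = cfg$refine_maxit))
    cand <- pmin(pmax(op$par, llo), lhi)
    if (loss_of(cand) < best_loss) {
      best <- cand
      best_loss <- loss_of(cand)
    }
  }
  out <- vec_to_params(10^best, template)
  attr(out, "loss") <- best_loss
  attr(out, "history") <- history
  out
}

#' Local one-at-a-time parameter sensitivity
#'
#' Perturbs each parameter by +/- `perturbation` (default 10%), re-integrates,
#' and reports the maximum absolute relative change of each readout at the
#' final time. Parameters with no directed path to a readout score exactly
#' zero for it.
#'
#' @param net A `signaling_network`.
#' @param params Parameter list.
#' @param inputs Named input levels.
#' @param readouts Readout species (default `net$outputs`).
#' @param t_eval Evaluation time in hours.
#' @param perturbation Fractional perturbation in (0, 0.5].
#' @param signed If TRUE, additionally return the signed relative change
#'   for the + perturbation.
#' @return Data frame: `parameter`, one column per readout (max-abs
#'   relative change), and `<readout>_signed` columns when `signed`.
#' @export
local_sensitivity <- function(net, params, inputs, readouts = net$outputs,
                              t_eval = 1, perturbation = 0.1,
                              signed = FALSE) {
  if (perturbation <= 0 || perturbation > 0.5)
    stop("perturbation must be in (0, 0.5]")
  template <- ga_param_template(net)
  theta0 <- params_to_vec(params, template)
  ids <- unlist(template, use.names = FALSE)
  readout_at <- function(theta) {
    p <- vec_to_params(theta, template)
    tc <- integrate_network(net, p, inputs, c(0, t_eval))
    tc$values[readouts, 2]
  }
  base <- readout_at(theta0)
  # structural zeros: a parameter attached to a node with no directed
  # path to a readout cannot move it
  downstream <- function(node) {
    seen <- node
    repeat {
      nxt <- unique(net$edges$target[net$edges$source %in% seen])
      new <- setdiff(nxt, seen)
      if (!length(new)) return(seen)
      seen <- c(seen, new)
    }
  }
  param_node <- stats::setNames(rep(NA_character_, length(ids)), ids)
  for (i in seq_len(nrow(net$edges))) {
    param_node[net$edges$k[i]] <- net$edges$target[i]
    param_node[net$edges$H[i]] <- net$edges$target[i]
  }
  for (s in names(net$degradations)) param_node[net$degradations[[s]]] <- s
  if (!is.null(net$inhibitions))
    for (i in seq_len(nrow(net$inhibitions))) {
      param_node[net$inhibitions$K[i]] <- net$inhibitions$target[i]
      param_node[net$inhibitions$H[i]] <- net$inhibitions$target[i]
    }
  res <- matrix(0, nrow = length(ids), ncol = length(readouts),
                dimnames = list(ids, readouts))
  sgn <- res
  for (i in seq_along(ids)) {
    reach <- downstream(param_node[[ids[i]]])
    if (!any(readouts %in% reach)) next
    up <- theta0; up[i] <- up[i] * (1 + perturbation)
    dn <- theta0; dn[i] <- dn[i] * (1 - perturbation)
    r_up <- (readout_at(up) - base) / base
    r_dn <- (readout_at(dn) - base) / base
    mask <- readouts %in% reach
    res[i, mask] <- pmax(abs(r_up), abs(r_dn))[mask]
    sgn[i, mask] <- r_up[mask]
  }
  out <- data.frame(parameter = ids, res, check.names = FALSE,
                    row.names = NULL)
  if (signed)
    for (r in readouts) out[[paste0(r, "_signed")]] <- sgn[, r]
  out
}

#' Parameter uncertainty analysis
#'
#' Statistical experiments in which every parameter is independently
#' rescaled by Uniform(1 - range, 1 + range) draws; each sampled vector is
#' integrated from the all-ones state and the readouts at `t_eval` are
#' normalised by the baseline model output. One experiment per sample
#' size.
#'
#' @param net A `signaling_network`.
#' @param params Baseline parameter list.
#' @param inputs Named input levels.
#' @param range_frac Perturbation half-range (default 0.05 = +/-5%).
#' @param sizes Sample sizes, default the nine experiment sizes
#'   30...10000.
#' @param t_eval Evaluation time in hours.
#' @param readouts Readout species (default `net$outputs`).
#' @param seed Integer seed.
#' @return Data frame: `size`, `readout`, `mean_norm`, `sd_norm`
#'   (normalised by the baseline readout).
#' @export
uncertainty_analysis <- function(net, params, inputs, range_frac = 0.05,
                                 sizes = c(30, 100, 200, 500, 1000, 2000,
                                           5000, 8000, 10000),
                                 t_eval = 1, readouts = net$outputs,
                                 seed = 1) {
  if (!length(sizes)) stop("sizes must be non-empty")
  template <- ga_param_template(net)
  theta0 <- params_to_vec(params, template)
  readout_at <- function(theta) {
    tc <- integrate_network(net, vec_to_params(theta, template), inputs,
                            c(0, t_eval))
    tc$values[readouts, 2]
  }
  base <- readout_at(theta0)
  set.seed(seed)
  out <- list()
  for (n in sizes) {
    draws <- matrix(NA_real_, nrow = n, ncol = length(readouts))
    for (i in seq_len(n)) {
      scale <- stats::runif(length(theta0), 1 - range_frac, 1 + range_frac)
      draws[i, ] <- readout_at(theta0 * scale) / base
    }
    out[[length(out) + 1]] <- data.frame(
      size = n, readout = readouts,
      mean_norm = colMeans(draws),
      sd_norm = apply(draws, 2, stats::sd))
  }
  do.call(rbind, out)
}
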