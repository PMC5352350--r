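the_habm <- new.env(parent = emptyenv())

read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (cls in c("k", "H", "d")) x[[cls]] <- unlist(x[[cls]])
  if (!is.null(x$drug)) x$drug <- as.list(unlist(x$drug))
  x
}

#' Calibrated signaling-network parameters
#'
#' Loads (and caches) the fitted parameter sets shipped with the package:
#' GA fits against the synthetic proteomics fixtures, anchored to the
#' in-vitro observations (400 to 526 Pa stiffening under 5 nM SDF-1, 89.2%
#' viability reduction under 5 nM bortezomib at day 6, and the 47% + 20%
#' adhesion split). Each list carries `k`, `H`, `d`, optionally `drug`,
#' and a `calib` block with the anchoring constants.
#'
#' @return List with elements `bmsc` and `mic`.
#' @export
habm_params <- function() {
  if (is.null(the_habm$params)) {
    the_habm$params <- list(
      bmsc = read_params_json(system.file("extdata", "params_bmsc.json",
                                          package = "habm", mustWork = TRUE)),
      mic = read_params_json(system.file("extdata", "params_mic.json",
                                         package = "habm", mustWork = TRUE)))
  }
  the_habm$params
}

#' Calibrated agent-behavior constants
#'
#' The stochastic rule constants of the agent-based model (per-step
#' probabilities, Hill constants of the behavior couplings, cycle lengths,
#' sensing radii, drug-response constants), tuned so the assembled model
#' reproduces the population-level anchors (5.98x MIC expansion at 4
#' weeks, 49.5% myeloma reduction at 48 h under 1.5 nM bortezomib, and
#' the 38.4%/46.4% CD8+ increases under 5/10 uM lenalidomide).
#'
#' @return Named list of behavior constants.
#' @export
habm_rules <- function() {
  if (is.null(the_habm$rules)) {
    the_habm$rules <- jsonlite::read_json(
      system.file("extdata", "abm_rules.json", package = "habm",
                  mustWork = TRUE), simplifyVector = TRUE)
  }
  the_habm$rules
}
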