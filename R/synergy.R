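#' Factorial dose grid for the three-drug sweep
#'
#' Eleven levels per drug: level 0 is no drug, levels 1-10 span 0.1x to
#' 1.0x of the maximum simulated dose (bortezomib 5 nM, lenalidomide
#' 10 uM, thalidomide 10 uM).
#'
#' @param levels Level indices to include (default 0:10).
#' @param btz_max,len_max,thal_max Maximum doses.
#' @return List with per-drug dose vectors named by level.
#' @export
dose_grid <- function(levels = 0:10, btz_max = 5, len_max = 10,
                      thal_max = 10) {
  if (any(levels < 0 | levels > 10)) stop("levels must be in 0..10")
  lv <- sort(unique(as.integer(levels)))
  list(levels = lv,
       btz_nM = stats::setNames(btz_max * lv / 10, lv),
       len_uM = stats::setNames(len_max * lv / 10, lv),
       thal_uM = stats::setNames(thal_max * lv / 10, lv))
}

#' Survival ratio of myeloma cells after treatment
#'
#' `(MIC + MM)` of the treated run divided by the matched untreated
#' control at the evaluation time, clamped to `[0, 1]`.
#'
#' @param treated,control `population_ts` / `summary_ts` objects on the
#'   same time grid.
#' @param t_eval Evaluation time in hours (default 144, the end of the
#'   treatment window).
#' @return Survival ratio D in `[0, 1]`.
#' @export
survival_ratio <- function(treated, control, t_eval = 144) {
  tg <- if (inherits(treated, "summary_ts")) treated$time_h else treated$time_h
  cg <- if (inherits(control, "summary_ts")) control$time_h else control$time_h
  if (!isTRUE(all.equal(tg, cg))) stop("time grids differ")
  i <- match(t_eval, tg)
  if (is.na(i)) stop("t_eval not on the time grid")
  ctrl <- myeloma_total(control)[i]
  if (ctrl <= 0) stop("control myeloma count is zero at t_eval")
  min(max(myeloma_total(treated)[i] / ctrl, 0), 1)
}

#' Three-drug synergy index
#'
#' `C = (Di*Djk + Dj*Dik + Dk*Dij - 2*Di*Dj*Dk) / Dijk`, where the D's
#' are myeloma survival ratios under the single, pairwise and triple
#' treatments. Under multiplicative independence of the three drugs the
#' numerator collapses to `Di*Dj*Dk` and C = 1; C > 1 is synergistic,
#' C < 1 antagonistic.
#'
#' @param Di,Dj,Dk Single-drug survival ratios in `[0, 1]`.
#' @param Dij,Dik,Djk Pairwise survival ratios.
#' @param Dijk Triple-combination survival ratio; when 0 the index is
#'   undefined and `Inf` is returned as a maximal-synergy sentinel.
#' @return The synergy index C (possibly `Inf`).
#' @export
synergy_index <- function(Di, Dj, Dk, Dij, Dik, Djk, Dijk) {
  d <- c(Di, Dj, Dk, Dij, Dik, Djk, Dijk)
  if (any(d < 0 | d > 1)) stop("survival ratios must be in [0, 1]")
  num <- Di * Djk + Dj * Dik + Dk * Dij - 2 * Di * Dj * Dk
  if (Dijk == 0) return(Inf)
  num / Dijk
}

#' Classify a synergy index
#'
#' `SYNERGISTIC` when C > 1, `ANTAGONISTIC` when C < 1, `ADDITIVE` within
#' the tolerance band `|C - 1| <= eps`.
#'
#' @param C Synergy index (finite, or `Inf` = maximal synergy).
#' @param eps Additivity tolerance (default 0.02).
#' @return One of `"SYNERGISTIC"`, `"ANTAGONISTIC"`, `"ADDITIVE"`.
#' @export
classify_synergy <- function(C, eps = 0.02) {
  if (is.infinite(C)) return("SYNERGISTIC")
  if (abs(C - 1) <= eps) "ADDITIVE"
  else if (C > 1) "SYNERGISTIC"
  else "ANTAGONISTIC"
}

#' Dose-grid sweep with synergy evaluation
#'
#' Enumerates every level triple of the grid, runs replicate simulations
#' per condition, fills the replicate-mean survival ratios D and, for
#' triples with all three levels >= 1, the synergy index C and its label.
#' The full 11^3 grid at 200 replicates reproduces the 1331-condition /
#' 266,200-run factorial and is cluster-scale; the default desk-scale
#' sweep is a reduced grid.
#'
#' @param config Base [habm_config()] (regimen overridden per condition).
#' @param grid A [dose_grid()].
#' @param replicates Replicates per condition.
#' @param master_seed Master seed; conditions share replicate seeds
#'   (paired comparisons).
#' @param t_eval Evaluation time for D (hours).
#' @return A `synergy_cube` data frame: `i`, `j`, `k`, doses, `D_mean`,
#'   `D_sd`, `C`, `label`; attribute `n_runs` counts condition-replicates.
#' @export
synergy_sweep <- function(config, grid = dose_grid(), replicates = 20,
                          master_seed = 1, t_eval = 144) {
  if (replicates < 1) stop("replicates must be >= 1")
  lv <- grid$levels
  cond <- expand.grid(i = lv, j = lv, k = lv)
  res <- data.frame(cond,
                    dose_btz_nM = grid$btz_nM[as.character(cond$i)],
                    dose_len_uM = grid$len_uM[as.character(cond$j)],
                    dose_thal_uM = grid$thal_uM[as.character(cond$k)],
                    D_mean = NA_real_, D_sd = NA_real_, C = NA_real_,
                    label = NA_character_)
  n_t <- config$horizon_h / config$dt_h + 1
  it <- match(t_eval, seq(0, config$horizon_h, by = config$dt_h))
  if (is.na(it)) stop("t_eval not on the time grid")

  run_cond <- function(btz, len, thal) {
    cfg <- config
    cfg$regimen <- drug_regimen(btz, len, thal,
                                start_h = config$regimen$start_h,
                                duration_h = config$regimen$duration_h)
    vals <- vapply(seq_len(replicates), function(r) {
      ts <- habm_run(cfg, seed = replicate_seed(master_seed, r))
      ts$MIC[it] + ts$MM[it]
    }, numeric(1))
    vals
  }

  ctrl <- run_cond(0, 0, 0)
  ctrl_mean <- mean(ctrl)
  if (ctrl_mean <= 0) stop("control myeloma count is zero at t_eval")
  for (r in seq_len(nrow(res))) {
    if (res$i[r] == 0 && res$j[r] == 0 && res$k[r] == 0) {
      res$D_mean[r] <- 1; res$D_sd[r] <- stats::sd(ctrl / ctrl_mean)
      next
    }
    v <- run_cond(res$dose_btz_nM[r], res$dose_len_uM[r], res$dose_thal_uM[r])
    res$D_mean[r] <- min(max(mean(v) / ctrl_mean, 0), 1)
    res$D_sd[r] <- stats::sd(v / ctrl_mean)
  }
  lookup <- function(i, j, k)
    res$D_mean[res$i == i & res$j == j & res$k == k]
  for (r in seq_len(nrow(res))) {
    i <- res$i[r]; j <- res$j[r]; k <- res$k[r]
    if (i == 0 || j == 0 || k == 0) next
    C <- synergy_index(lookup(i, 0, 0), lookup(0, j, 0), lookup(0, 0, k),
                       lookup(i, j, 0), lookup(i, 0, k), lookup(0, j, k),
                       res$D_mean[r])
    res$C[r] <- C
    res$label[r] <- classify_synergy(C)
  }
  attr(res, "n_runs") <- nrow(res) * replicates
  class(res) <- c("synergy_cube", class(res))
  res
}
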