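#' Default observation grids and panels for the proteomics fixtures
#'
#' The BMSC phospho-panel (pMEK, pFAK, pRhoA, pERK, pMYL2) is sampled at
#' 0/5/10/15/60 min; the MIC panel (FAK, PI3K, AKT, JNK, cJUN, NFKB) at
#' 0/0.5/1 h with the Adhesion and Survival readouts at 24 and 96 h.
#'
#' @param model `"bmsc"` or `"mic"`.
#' @return List with `species`, `times_h` and (for mic) `readouts`,
#'   `readout_times_h`.
#' @export
proteomics_design <- function(model = c("bmsc", "mic")) {
  model <- match.arg(model)
  if (model == "bmsc")
    list(species = c("MEK", "FAK", "RhoA", "ERK", "MYL2"),
         times_h = c(0, 5, 10, 15, 60) / 60,
         readouts = "stiffness",
         readout_times_h = c(5, 10, 15, 60) / 60)
  else
    list(species = c("FAK", "PI3K", "AKT", "JNK", "cJUN", "NFKB"),
         times_h = c(0, 0.5, 1),
         readouts = c("Adhesion", "Survival"),
         readout_times_h = c(24, 96))
}

#' Generating ("true") parameter sets for the synthetic proteomics
#'
#' Fixed reference kinetics used to synthesise the calibration fixtures:
#' minutes-scale activation for the BMSC network (responses developing
#' between 5 and 60 min) and sub-hour protein kinetics with slow
#' adhesion/survival readouts for the MIC network. These stand in for
#' unavailable measured tables and are labelled synthetic throughout.
#'
#' @param model `"bmsc"` or `"mic"`.
#' @return Parameter list (`k`, `H`, `d`, optionally `drug`).
#' @export
synthetic_true_params <- function(model = c("bmsc", "mic")) {
  model <- match.arg(model)
  if (model == "bmsc") {
    list(
      k = stats::setNames(c(6, 5, 4, 3.5, 2.5, 4.5, 3, 2.5, 2.2, 2.8),
                          paste0("k", 1:10)),
      H = stats::setNames(c(0.5, 0.5, 1.2, 1.2, 1.0, 1.0, 1.5, 1.5, 1.2, 1.6),
                          paste0("H", 1:10)),
      d = stats::setNames(c(2.0, 1.8, 1.5, 1.6, 1.8, 1.4, 1.2),
                          paste0("d", 1:7)))
  } else {
    # anchored so that, at the myeloma-BMSC operating point (400 Pa), the
    # adhesion component is 0.47 at 24 h, drug-free survival is 0.90 at
    # 144 h, and 5 nM bortezomib reduces survival by 89.2%
    list(
      k = stats::setNames(c(2, 2, 1.5, 1.8, 1.8, 2.2, 2.5, 1.6, 1.4,
                            13.7952, 15.7349), paste0("k", 1:11)),
      H = stats::setNames(c(0.6, 6, 6, 6, 6, 6, 6, 6, 6, 6, 6),
                          paste0("H", 1:11)),
      d = stats::setNames(c(1.2, 0.9, 0.9, 0.9, 0.9, 0.8, 0.8, 0.35, 0.4),
                          paste0("d", 1:9)),
      drug = list(K_BTZ = 0.48168, H_BTZ = 2.5),
      calib = list(adhesion_floor = 0.2))
  }
}

#' Generate a synthetic proteomics observation table
#'
#' Integrates the network with the generating parameters from the
#' all-ones state, samples the requested species/time grid, and applies
#' multiplicative lognormal noise with the given coefficient of
#' variation. Entries at t = 0 are forced to 1 (the RPPA normalisation
#' anchor).
#'
#' @param net A `signaling_network`.
#' @param true_params Generating parameters.
#' @param inputs Named input levels held constant.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (0 = noiseless).
#' @param species Observed species.
#' @param t_grid Observation times in hours (must include 0).
#' @param seed Integer seed.
#' @return Observation table: data frame `species`, `time_h`,
#'   `fold_change`.
#' @export
generate_synthetic_proteomics <- function(net, true_params, inputs,
                                          noise_cv = 0.1,
                                          species = NULL, t_grid = NULL,
                                          seed = 1) {
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (is.null(species)) species <- setdiff(net$states, net$outputs)
  if (is.null(t_grid)) t_grid <- c(0, 0.25, 0.5, 1)
  times <- sort(unique(c(0, t_grid)))
  tc <- integrate_network(net, true_params, inputs, times)
  obs <- expand.grid(species = species, time_h = t_grid,
                     stringsAsFactors = FALSE)
  obs$fold_change <- tc$values[cbind(match(obs$species, rownames(tc$values)),
                                     match(obs$time_h, times))]
  if (noise_cv > 0) {
    set.seed(seed)
    sdlog <- sqrt(log(1 + noise_cv^2))
    nz <- obs$time_h > 0
    obs$fold_change[nz] <- obs$fold_change[nz] *
      stats::rlnorm(sum(nz), -sdlog^2 / 2, sdlog)
  }
  obs$fold_change[obs$time_h == 0] <- 1
  obs[order(obs$species, obs$time_h), ]
}

panel_with_readouts <- function(net, true_params, inputs, dsn, noise_cv,
                                seed) {
  obs1 <- generate_synthetic_proteomics(net, true_params, inputs,
                                        noise_cv = noise_cv,
                                        species = dsn$species,
                                        t_grid = dsn$times_h, seed = seed)
  obs2 <- generate_synthetic_proteomics(net, true_params, inputs,
                                        noise_cv = noise_cv,
                                        species = dsn$readouts,
                                        t_grid = dsn$readout_times_h,
                                        seed = seed + 1)
  rbind(obs1, obs2)
}

#' Multi-condition calibration set for a model
#'
#' Builds the observation set used to fit a network, mirroring the
#' experimental design: for the BMSC model, the phospho-panel plus the
#' stiffness output under the saturating SDF-1 reference and under a
#' sub-saturating dose (which identifies the dose response); for the MIC
#' model, the panel plus adhesion/survival readouts on 400 Pa and 100 Pa
#' substrates, plus drug-treated survival at 400 Pa under 5 nM
#' bortezomib. Each condition carries its own constant inputs; the L1
#' objective sums over conditions (mixed observation grids).
#'
#' @param model `"bmsc"` or `"mic"`.
#' @param true_params Generating parameters (default
#'   [synthetic_true_params()]).
#' @param noise_cv Noise CV.
#' @param seed Integer seed.
#' @return A `calibration_set`: list of conditions, each with `inputs`
#'   and an observation table `obs`.
#' @export
calibration_observations <- function(model = c("bmsc", "mic"),
                                     true_params = synthetic_true_params(model),
                                     noise_cv = 0, seed = 1) {
  model <- match.arg(model)
  dsn <- proteomics_design(model)
  if (model == "bmsc") {
    net <- build_bmsc_network()
    # saturating reference plus two sub-saturating doses: identifies the
    # dose response down to near-zero stimulation
    conds <- lapply(c(1, 0.3, 0.05), function(dose) {
      list(inputs = c(SDF1 = dose),
           obs = panel_with_readouts(net, true_params, c(SDF1 = dose), dsn,
                                     noise_cv, seed + 10 * (dose < 1) +
                                       10 * (dose < 0.1)))
    })
  } else {
    net <- build_mic_network()
    in400 <- c(stiffness = 400 / 530, D1 = 0)
    in100 <- c(stiffness = 100 / 530, D1 = 0)
    in_btz <- c(stiffness = 400 / 530, D1 = 5)
    conds <- list(
      list(inputs = in400,
           obs = panel_with_readouts(net, true_params, in400, dsn,
                                     noise_cv, seed)),
      list(inputs = in100,
           obs = panel_with_readouts(net, true_params, in100, dsn,
                                     noise_cv, seed + 10)),
      list(inputs = in_btz,
           obs = generate_synthetic_proteomics(
             net, true_params, in_btz, noise_cv = noise_cv,
             species = "Survival", t_grid = dsn$readout_times_h,
             seed = seed + 20)))
  }
  structure(conds, class = "calibration_set")
}

#' In-silico calibration anchor suite
#'
#' The machine-readable validation anchors of the assembled model. Each
#' anchor carries the expected value, a comparison mode and an executable
#' recipe (a function of `seed` and, for the stochastic anchors,
#' `replicates`).
#'
#' @return List of anchors; each is a list with `name`, `expected`,
#'   `units`, `cmp` (`"eq"` or `"le"`), `stochastic`, and `run`.
#' @export
anchor_suite <- function() {
  list(
    bmsc_stiffness_5nM = list(
      name = "BMSC stiffness under 5 nM SDF-1",
      expected = 526, units = "Pa", cmp = "eq", stochastic = FALSE,
      run = function(seed = 1, replicates = NULL) {
        p <- habm_params()$bmsc
        bmsc_stiffness_response(sdf1_rel_from_nM(5, p), p, t = 1)
      }),
    mic_btz_kill_day6 = list(
      name = "MIC viability reduction, 5 nM BTZ, day 6",
      expected = 89.2, units = "%", cmp = "eq", stochastic = FALSE,
      run = function(seed = 1, replicates = NULL) {
        p <- habm_params()$mic
        100 * (1 - mic_survival_rate(400, 5, p, t = 144) /
                 mic_survival_rate(400, 0, p, t = 144))
      }),
    mic_adhesion_total = list(
      name = "Total MIC adhesion at myeloma-BMSC stiffness",
      expected = 67, units = "%", cmp = "eq", stochastic = FALSE,
      run = function(seed = 1, replicates = NULL) {
        100 * mic_adhesion_rate(400, habm_params()$mic)
      }),
    mic_expansion_4wk = list(
      name = "MIC fold-expansion at 4 weeks, immune absent, untreated",
      expected = 5.98, units = "fold", cmp = "eq", stochastic = TRUE,
      run = function(seed = 1, replicates = 50) {
        cfg <- habm_config(n_cd8 = 0, n_treg = 0, horizon_h = 672)
        sm <- run_replicates(cfg, n = replicates, master_seed = seed)
        sm$mean[nrow(sm$mean), "MIC"] / cfg$n_mic
      }),
    btz_myeloma_48h = list(
      name = "Myeloma reduction at 48 h, 1.5 nM BTZ",
      expected = 49.5, units = "%", cmp = "eq", stochastic = TRUE,
      run = function(seed = 1, replicates = 50) {
        cfg0 <- habm_config(horizon_h = 48)
        cfg1 <- habm_config(horizon_h = 48,
                            regimen = drug_regimen(btz_nM = 1.5))
        s0 <- run_replicates(cfg0, n = replicates, master_seed = seed)
        s1 <- run_replicates(cfg1, n = replicates, master_seed = seed)
        100 * (1 - myeloma_total(s1)[25] / myeloma_total(s0)[25])
      }),
    len_cd8_increase = list(
      name = "CD8+ increase at end of treatment, 5/10 uM LEN",
      expected = c(38.4, 46.4), units = "%", cmp = "eq", stochastic = TRUE,
      run = function(seed = 1, replicates = 100) {
        s0 <- run_replicates(habm_config(horizon_h = 144), n = replicates,
                             master_seed = seed)
        out <- vapply(c(5, 10), function(d) {
          s1 <- run_replicates(
            habm_config(horizon_h = 144, regimen = drug_regimen(len_uM = d)),
            n = replicates, master_seed = seed)
          i <- nrow(s1$mean)
          100 * (s1$mean[i, "CD8"] / s0$mean[i, "CD8"] - 1)
        }, numeric(1))
        stats::setNames(out, c("len5", "len10"))
      }),
    uncertainty_bmsc = list(
      name = "BMSC output deviation under +/-5% parameters (n = 5000)",
      expected = 4, units = "%", cmp = "le", stochastic = TRUE,
      run = function(seed = 1, replicates = 5000) {
        p <- habm_params()$bmsc
        u <- uncertainty_analysis(build_bmsc_network(), p, c(SDF1 = 1),
                                  sizes = replicates, t_eval = 1,
                                  seed = seed)
        max(abs(u$mean_norm - 1)) * 100
      }),
    uncertainty_mic = list(
      name = "MIC output deviation under +/-5% parameters (n = 5000)",
      expected = 5, units = "%", cmp = "le", stochastic = TRUE,
      run = function(seed = 1, replicates = 5000) {
        p <- habm_params()$mic
        u <- uncertainty_analysis(build_mic_network(), p,
                                  c(stiffness = 400 / 530, D1 = 0),
                                  sizes = replicates, t_eval = 96,
                                  seed = seed)
        max(abs(u$mean_norm - 1)) * 100
      }),
    synergy_additivity = list(
      name = "Synergy index under multiplicative independence",
      expected = 1, units = "", cmp = "eq", stochastic = FALSE,
      run = function(seed = 1, replicates = NULL) {
        set.seed(seed)
        d <- stats::runif(3, 0.2, 0.9)
        synergy_index(d[1], d[2], d[3], d[1] * d[2], d[1] * d[3],
                      d[2] * d[3], d[1] * d[2] * d[3])
      }))
}

#' Execute the anchor suite
#'
#' Runs every anchor recipe and tabulates observed vs expected values.
#'
#' @param seed Integer seed.
#' @param fast Use desk-scale replicate counts (TRUE: 20 replicates for
#'   the agent-based anchors, 1000 uncertainty samples).
#' @param tol_rel Relative tolerance for the pass flag on `eq` anchors.
#' @return Data frame: `anchor`, `expected`, `observed`, `units`, `cmp`,
#'   `pass`.
#' @export
run_anchors <- function(seed = 1, fast = TRUE, tol_rel = 0.15) {
  suite <- anchor_suite()
  rows <- list()
  for (a in suite) {
    reps <- if (a$stochastic) {
      if (grepl("uncertainty", a$name, ignore.case = TRUE))
        (if (fast) 1000 else 5000)
      else (if (fast) 20 else 50)
    } else NULL
    obs <- a$run(seed = seed, replicates = reps)
    for (i in seq_along(obs)) {
      exp_i <- if (length(a$expected) > 1) a$expected[i] else a$expected
      pass <- if (a$cmp == "le") obs[i] <= exp_i
        else abs(obs[i] - exp_i) <= tol_rel * abs(exp_i)
      nm <- if (length(obs) > 1 && !is.null(names(obs)))
        paste0(a$name, " [", names(obs)[i], "]") else a$name
      rows[[length(rows) + 1]] <- data.frame(
        anchor = nm, expected = exp_i, observed = unname(obs[i]),
        units = a$units, cmp = a$cmp, pass = pass)
    }
  }
  do.call(rbind, rows)
}
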