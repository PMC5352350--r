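test_that("L1 objective matches a literal double loop and its identities", {
  net <- build_bmsc_network()
  p <- synthetic_true_params("bmsc")
  obs <- calibration_observations("bmsc", noise_cv = 0.15, seed = 7)[[1]]$obs
  # independent oracle: integrate once, loop over entries
  times <- sort(unique(c(0, obs$time_h)))
  tc <- integrate_network(net, p, c(SDF1 = 1), times)
  acc <- 0
  for (r in seq_len(nrow(obs))) {
    sim <- tc$values[obs$species[r], which(times == obs$time_h[r])]
    acc <- acc + abs(obs$fold_change[r] - sim)
  }
  expect_equal(l1_objective(p, net, obs, c(SDF1 = 1)), unname(acc),
               tolerance = 1e-10)

  noiseless <- calibration_observations("bmsc", noise_cv = 0, seed = 1)
  for (cond in noiseless)
    expect_equal(l1_objective(p, net, cond$obs, cond$inputs), 0,
                 tolerance = 1e-6)
  one <- data.frame(species = "MEK", time_h = 0.25, fold_change = 1.5)
  tc1 <- integrate_network(net, p, c(SDF1 = 1), c(0, 0.25))
  expect_equal(l1_objective(p, net, one, c(SDF1 = 1)),
               as.numeric(abs(1.5 - tc1$values["MEK", 2])))
  bad <- data.frame(species = "NOTANODE", time_h = 0.25, fold_change = 1)
  expect_error(l1_objective(p, net, bad, c(SDF1 = 1)), "NOTANODE")
})

test_that("the GA is reproducible and monotone under elitism", {
  net <- build_bmsc_network()
  obs <- calibration_observations("bmsc", noise_cv = 0.1, seed = 3)
  cfg <- list(pop_size = 16, generations = 8, refine = FALSE)
  f1 <- fit_parameters_ga(net, obs, ga_config = cfg, seed = 9)
  f2 <- fit_parameters_ga(net, obs, ga_config = cfg, seed = 9)
  expect_identical(f1, f2)
  h <- attr(f1, "history")
  expect_true(all(diff(h) <= 1e-12))
  expect_lte(attr(f1, "loss"), h[length(h)] + 1e-12)
})

test_that("GA fit recovers output trajectories from noiseless data", {
  net <- build_bmsc_network()
  truth <- synthetic_true_params("bmsc")
  cond <- calibration_observations("bmsc", noise_cv = 0, seed = 1)[[1]]
  fit <- fit_parameters_ga(net, cond$obs, inputs = cond$inputs,
                           ga_config = list(pop_size = 60, generations = 80,
                                            refine_maxit = 2000),
                           seed = 4)
  times <- c(0, 5, 10, 15, 60) / 60
  tc_true <- integrate_network(net, truth, cond$inputs, times)
  tc_fit <- integrate_network(net, fit, cond$inputs, times)
  obs_sp <- unique(cond$obs$species)
  rel <- abs(tc_fit$values[obs_sp, -1] / tc_true$values[obs_sp, -1] - 1)
  expect_lt(max(rel), 0.05)
})

test_that("sensitivity is zero off-path and signed as expected", {
  net <- build_mic_network()
  p <- synthetic_true_params("mic")
  inp <- c(stiffness = 0.7, D1 = 0)
  sens <- local_sensitivity(net, p, inp, readouts = c("Adhesion", "Survival"),
                            t_eval = 24, signed = TRUE)
  # the cJUN->Adhesion branch cannot reach Survival, and vice versa
  expect_equal(sens$Survival[sens$parameter %in% c("k10", "H10", "d8")],
               c(0, 0, 0))
  expect_equal(sens$Adhesion[sens$parameter %in% c("k11", "H11", "d9")],
               c(0, 0, 0))
  # raising a degradation rate lowers its own node's readout
  expect_lt(sens$Adhesion_signed[sens$parameter == "d8"], 0)
  expect_lt(sens$Survival_signed[sens$parameter == "d9"], 0)
})

test_that("sensitivity agrees with an independent finite-difference oracle", {
  net <- build_bmsc_network()
  p <- synthetic_true_params("bmsc")
  sens <- local_sensitivity(net, p, c(SDF1 = 1), readouts = "stiffness",
                            t_eval = 1, perturbation = 0.1, signed = TRUE)
  base <- integrate_network(net, p, c(SDF1 = 1), c(0, 1))$values["stiffness", 2]
  for (id in c("k1", "d7", "H9")) {
    cls <- substr(id, 1, 1)
    p2 <- p
    p2[[cls]][[id]] <- p[[cls]][[id]] * 1.1
    pert <- integrate_network(net, p2, c(SDF1 = 1),
                              c(0, 1))$values["stiffness", 2]
    expect_equal(sens$stiffness_signed[sens$parameter == id],
                 as.numeric((pert - base) / base), tolerance = 1e-6)
  }
})

test_that("uncertainty analysis is exact at zero range and stable at 5%", {
  net <- build_bmsc_network()
  p <- synthetic_true_params("bmsc")
  u0 <- uncertainty_analysis(net, p, c(SDF1 = 1), range_frac = 0,
                             sizes = 20, t_eval = 1, seed = 2)
  expect_equal(u0$mean_norm, 1, tolerance = 1e-12)
  expect_equal(u0$sd_norm, 0, tolerance = 1e-12)
  u <- uncertainty_analysis(net, p, c(SDF1 = 1), range_frac = 0.05,
                            sizes = c(30, 300), t_eval = 1, seed = 2)
  expect_true(all(u$mean_norm > 0))
  expect_lt(max(abs(u$mean_norm - 1)), 0.06)
})
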