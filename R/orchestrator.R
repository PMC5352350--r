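#' Simulation configuration
#'
#' Assembles and validates the full configuration of a hybrid-model run:
#' domain, initial counts, BMSC scaffold, cytokine field constants, drug
#' regimen, clock and replicate settings. Defaults are the reference
#' study conditions: a 50x50x50 lattice with an inscribed cylindrical
#' mask, BMSCs on every 4th site, 100 MIC / 100 MM / 20 CD8+ / 5 Treg
#' seeded in a central sphere, 2-h steps to a 600-h horizon.
#'
#' @param nx,ny,nz Lattice dimensions.
#' @param n_mic,n_mm,n_cd8,n_treg Initial cell counts.
#' @param bmsc_spacing BMSC scaffold spacing in sites (every k-th site).
#' @param horizon_h Simulated horizon in hours (multiple of `dt_h`).
#' @param dt_h Agent-based step in hours (default 2).
#' @param regimen A [drug_regimen()].
#' @param D Cytokine diffusion coefficient (sites^2/h), shared by SDF-1
#'   and TGF-beta.
#' @param boundary Dirichlet boundary value for both fields.
#' @param sdf1_rate SDF-1 secretion per MIC (units/h).
#' @param tgfb_rate_mm,tgfb_rate_bmsc TGF-beta secretion per MM / BMSC
#'   (units/h).
#' @param replicates Default replicate count for [run_replicates()].
#' @param rules Behavior constants (default the shipped calibration).
#' @param params ODE parameter sets (default the shipped calibration).
#' @return A validated `habm_config` list.
#' @export
habm_config <- function(nx = 50, ny = 50, nz = 50,
                        n_mic = 100, n_mm = 100, n_cd8 = 20, n_treg = 5,
                        bmsc_spacing = 4, horizon_h = 600, dt_h = 2,
                        regimen = drug_regimen(), D = 2, boundary = 0,
                        sdf1_rate = 1, tgfb_rate_mm = 0.5,
                        tgfb_rate_bmsc = 0.1, replicates = 50,
                        rules = habm_rules(), params = habm_params()) {
  if (min(n_mic, n_mm, n_cd8, n_treg) < 0) stop("counts must be >= 0")
  if (horizon_h %% dt_h != 0) stop("horizon_h must be a multiple of dt_h")
  if (!inherits(regimen, "drug_regimen")) stop("regimen must be a drug_regimen")
  dom <- habm_domain(nx, ny, nz)
  structure(list(
    domain = dom, n_mic = n_mic, n_mm = n_mm, n_cd8 = n_cd8,
    n_treg = n_treg, bmsc_spacing = bmsc_spacing, horizon_h = horizon_h,
    dt_h = dt_h, regimen = regimen, D = D, boundary = boundary,
    sdf1_rate = sdf1_rate, tgfb_rate_mm = tgfb_rate_mm,
    tgfb_rate_bmsc = tgfb_rate_bmsc, replicates = replicates,
    rules = rules, params = params), class = "habm_config")
}

lin_index <- function(x, y, z, dims) {
  x + dims[1] * (y - 1) + dims[1] * dims[2] * (z - 1)
}

bmsc_scaffold_sites <- function(config) {
  dom <- config$domain
  k <- config$bmsc_spacing
  g <- expand.grid(x = seq(ceiling(k / 2), dom$nx, by = k),
                   y = seq(ceiling(k / 2), dom$ny, by = k),
                   z = seq(ceiling(k / 2), dom$nz, by = k))
  idx <- lin_index(g$x, g$y, g$z, c(dom$nx, dom$ny, dom$nz))
  idx[dom$mask[idx]]
}

central_sphere_sites <- function(config, exclude) {
  dom <- config$domain
  total <- config$n_mic + config$n_mm + config$n_cd8 + config$n_treg
  cx <- (dom$nx + 1) / 2; cy <- (dom$ny + 1) / 2; cz <- (dom$nz + 1) / 2
  r <- max(2, ceiling((3 * total / (4 * pi))^(1 / 3)))
  repeat {
    g <- expand.grid(x = seq_len(dom$nx), y = seq_len(dom$ny),
                     z = seq_len(dom$nz))
    keep <- (g$x - cx)^2 + (g$y - cy)^2 + (g$z - cz)^2 <= r^2
    idx <- lin_index(g$x[keep], g$y[keep], g$z[keep],
                     c(dom$nx, dom$ny, dom$nz))
    idx <- setdiff(idx[dom$mask[idx]], exclude)
    if (length(idx) >= total) return(idx)
    if (r > max(dom$nx, dom$ny, dom$nz))
      stop("central sphere too small for the initial cell counts")
    r <- r + 1
  }
}

# ODE-derived lookup tables consumed by the compiled step engine; cached
# on the parameter values.
engine_tables <- function(params) {
  key <- paste(format(c(unlist(params$bmsc[c("k", "H", "d", "calib")]),
                        unlist(params$mic)), digits = 15), collapse = ",")
  if (!is.null(the_habm$tables) && identical(the_habm$tables_key, key))
    return(the_habm$tables)
  stiff_x <- c(seq(0, 0.5, by = 0.05), seq(0.6, 1.6, by = 0.1), 2, 3, 5)
  stiff_y <- bmsc_stiffness_response(stiff_x, params$bmsc, t = 1)
  micd_stiff <- c(100, 200, 300, 400, 465, 530)
  micd_btz <- c(0, 0.25, 0.5, 1, 1.5, 2, 3, 4, 5)
  micd_p <- matrix(0, length(micd_stiff), length(micd_btz))
  for (i in seq_along(micd_stiff)) {
    s0 <- mic_survival_rate(micd_stiff[i], 0, params$mic, t = 144)
    for (j in seq_along(micd_btz)) {
      if (micd_btz[j] == 0) next
      s1 <- mic_survival_rate(micd_stiff[i], micd_btz[j], params$mic, t = 144)
      ratio <- min(max(s1 / max(s0, 1e-12), 1e-9), 1)
      micd_p[i, j] <- 1 - ratio^(1 / 72)
    }
  }
  adh_x <- seq(100, 530, length.out = 9)
  adh_y <- vapply(adh_x, function(s) mic_adhesion_rate(s, params$mic),
                  numeric(1))
  the_habm$tables <- list(stiff_x = stiff_x, stiff_y = stiff_y,
                          micd_stiff = micd_stiff, micd_btz = micd_btz,
                          micd_p = micd_p, adh_x = adh_x, adh_y = adh_y)
  the_habm$tables_key <- key
  the_habm$tables
}

engine_config <- function(config, n_steps, return_fields = FALSE,
                          return_agents = FALSE) {
  dom <- config$domain
  bmsc <- bmsc_scaffold_sites(config)
  sphere <- central_sphere_sites(config, exclude = bmsc)
  mask <- config$domain$mask
  mask[bmsc] <- FALSE  # scaffold sites are not free for mobile agents
  tb <- engine_tables(config$params)
  list(nx = dom$nx, ny = dom$ny, nz = dom$nz, mask = as.vector(mask),
       bmsc_sites = as.integer(bmsc), sphere_sites = as.integer(sphere),
       n_mic = config$n_mic, n_mm = config$n_mm, n_cd8 = config$n_cd8,
       n_treg = config$n_treg, n_steps = as.integer(n_steps),
       dt = config$dt_h, D = config$D, boundary = config$boundary,
       sdf1_rate = config$sdf1_rate, tgfb_rate_mm = config$tgfb_rate_mm,
       tgfb_rate_bmsc = config$tgfb_rate_bmsc,
       btz_nM = config$regimen$btz_nM, len_uM = config$regimen$len_uM,
       thal_uM = config$regimen$thal_uM, start_h = config$regimen$start_h,
       duration_h = config$regimen$duration_h,
       stiff_x = tb$stiff_x, stiff_y = tb$stiff_y,
       micd_stiff = tb$micd_stiff, micd_btz = tb$micd_btz,
       micd_p = as.vector(tb$micd_p), adh_x = tb$adh_x, adh_y = tb$adh_y,
       rules = config$rules,
       return_fields = return_fields, return_agents = return_agents)
}

#' Initialize a simulation state
#'
#' Places the BMSC scaffold and seeds the tumor/immune agents uniformly
#' at random inside the central sphere, with uniform fields at the
#' boundary value; returns a snapshot without advancing the clock.
#'
#' @param config A [habm_config()].
#' @param seed Integer seed.
#' @return List with `agents` (data frame), `bmsc_sites`, `pop` (initial
#'   counts) and `fields`.
#' @export
habm_initialize <- function(config, seed = 1) {
  set.seed(seed)
  ec <- engine_config(config, n_steps = 0, return_fields = TRUE,
                      return_agents = TRUE)
  res <- run_habm_cpp(ec)
  kinds <- c("MIC", "MM", "CD8", "TREG")
  ag <- res$agents
  ag$kind <- kinds[ag$kind]
  dims <- c(config$domain$nx, config$domain$ny, config$domain$nz)
  list(agents = ag, bmsc_sites = ec$bmsc_sites,
       pop = stats::setNames(as.numeric(res$pop[1, ]), kinds),
       fields = list(
         sdf1 = array(res$sdf1, dim = dims),
         tgfb = array(res$tgfb, dim = dims)))
}

#' Run one simulation replicate
#'
#' Advances the full multiscale loop (secretion + diffusion, BMSC
#' stiffness updates, shuffled stochastic agent phase) from a seeded
#' initial state to the horizon, recording populations every step.
#'
#' @param config A [habm_config()].
#' @param seed Integer seed; runs are bit-reproducible given the seed.
#' @param return_agents,return_fields Also return the final agent table /
#'   cytokine fields.
#' @return A `population_ts`: data frame with `time_h`, `MIC`, `MM`,
#'   `CD8`, `TREG`, `stiff_pa` (mean BMSC stiffness), with the per-step
#'   birth/death ledger in attributes `births` / `deaths`.
#' @export
habm_run <- function(config, seed = 1, return_agents = FALSE,
                     return_fields = FALSE) {
  n_steps <- as.integer(config$horizon_h / config$dt_h)
  set.seed(seed)
  res <- run_habm_cpp(engine_config(config, n_steps,
                                    return_fields = return_fields,
                                    return_agents = return_agents))
  out <- data.frame(time_h = seq(0, config$horizon_h, by = config$dt_h),
                    MIC = res$pop[, 1], MM = res$pop[, 2],
                    CD8 = res$pop[, 3], TREG = res$pop[, 4],
                    stiff_pa = res$stiff_mean)
  colnames(res$births) <- colnames(res$deaths) <- c("MIC", "MM", "CD8", "TREG")
  attr(out, "births") <- res$births
  attr(out, "deaths") <- res$deaths
  if (return_agents) {
    ag <- res$agents
    ag$kind <- c("MIC", "MM", "CD8", "TREG")[ag$kind]
    attr(out, "agents") <- ag
  }
  if (return_fields) {
    dims <- c(config$domain$nx, config$domain$ny, config$domain$nz)
    attr(out, "fields") <- list(sdf1 = array(res$sdf1, dim = dims),
                                tgfb = array(res$tgfb, dim = dims))
  }
  class(out) <- c("population_ts", class(out))
  out
}

replicate_seed <- function(master_seed, i) {
  as.integer((as.double(master_seed) + 77777 * i) %% 2147483629)
}

#' Run replicate simulations and summarise
#'
#' Runs `n` independently seeded replicates of the same configuration.
#' Replicate seeds are derived from the master seed by index only, so two
#' configurations compared under the same master seed are paired
#' (common-random-number variance reduction for treatment contrasts).
#'
#' @param config A [habm_config()].
#' @param n Number of replicates (default `config$replicates`).
#' @param master_seed Master seed.
#' @return A `summary_ts`: list with `time_h`, `mean` and `sd` (matrices
#'   time x kind, kinds MIC/MM/CD8/TREG plus `stiff_pa`), and `runs` (3D
#'   array time x kind x replicate).
#' @export
run_replicates <- function(config, n = config$replicates, master_seed = 1) {
  if (n < 1) stop("n must be >= 1")
  cols <- c("MIC", "MM", "CD8", "TREG", "stiff_pa")
  nt <- config$horizon_h / config$dt_h + 1
  runs <- array(NA_real_, dim = c(nt, length(cols), n),
                dimnames = list(NULL, cols, NULL))
  for (i in seq_len(n)) {
    ts <- habm_run(config, seed = replicate_seed(master_seed, i))
    runs[, , i] <- as.matrix(ts[, cols])
  }
  m <- apply(runs, c(1, 2), mean)
  s <- if (n > 1) apply(runs, c(1, 2), stats::sd) else m * 0
  structure(list(time_h = seq(0, config$horizon_h, by = config$dt_h),
                 mean = m, sd = s, n = n, runs = runs),
            class = "summary_ts")
}

#' Total myeloma burden (MIC + MM) of a run or summary
#' @param x A `population_ts` or `summary_ts`.
#' @return Numeric vector over the time grid.
#' @export
myeloma_total <- function(x) {
  if (inherits(x, "summary_ts")) x$mean[, "MIC"] + x$mean[, "MM"]
  else x$MIC + x$MM
}
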