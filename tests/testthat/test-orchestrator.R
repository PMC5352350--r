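small_cfg <- function(horizon_h = 48, ...) {
  habm_config(nx = 21, ny = 21, nz = 21, horizon_h = horizon_h, ...)
}

test_that("initialization seeds the stated compartments inside the mask", {
  cfg <- small_cfg()
  st <- habm_initialize(cfg, seed = 3)
  expect_equal(unname(st$pop),
               c(100, 100, 20, 5))
  ag <- st$agents
  expect_equal(table(factor(ag$kind, c("MIC", "MM", "CD8", "TREG"))),
               table(factor(rep(c("MIC", "MM", "CD8", "TREG"),
                                c(100, 100, 20, 5)),
                            c("MIC", "MM", "CD8", "TREG"))))
  # inside the cylindrical mask, one agent per site, never on the scaffold
  idx <- ag$x + 21 * (ag$y - 1) + 441 * (ag$z - 1)
  expect_true(all(cfg$domain$mask[idx]))
  expect_false(any(duplicated(idx)))
  expect_false(any(idx %in% st$bmsc_sites))
  # fields start uniform at the boundary value
  expect_true(all(st$fields$sdf1 == cfg$boundary))
  st2 <- habm_initialize(cfg, seed = 3)
  expect_identical(st$agents, st2$agents)
  st3 <- habm_initialize(cfg, seed = 4)
  expect_false(identical(st$agents, st3$agents))
})

test_that("initialization fails when the sphere cannot hold the cells", {
  expect_error(habm_initialize(habm_config(nx = 7, ny = 7, nz = 3)),
               "sphere")
})

test_that("the event ledger balances every compartment at every step", {
  ts <- habm_run(small_cfg(), seed = 21)
  pop <- as.matrix(ts[, c("MIC", "MM", "CD8", "TREG")])
  expect_equal(diff(pop),
               attr(ts, "births") - attr(ts, "deaths"),
               ignore_attr = TRUE)
  expect_true(all(pop >= 0))
})

test_that("runs are bit-reproducible under the same seed", {
  cfg <- small_cfg()
  t1 <- habm_run(cfg, seed = 33)
  t2 <- habm_run(cfg, seed = 33)
  expect_identical(as.matrix(t1), as.matrix(t2))
  expect_identical(attr(t1, "births"), attr(t2, "births"))
  t3 <- habm_run(cfg, seed = 34)
  expect_false(identical(as.matrix(t1), as.matrix(t3)))
})

test_that("site exclusivity holds after stepping", {
  ts <- habm_run(small_cfg(horizon_h = 96), seed = 5, return_agents = TRUE)
  ag <- attr(ts, "agents")
  idx <- ag$x + 21 * (ag$y - 1) + 441 * (ag$z - 1)
  expect_false(any(duplicated(idx)))
  cfg <- small_cfg()
  expect_true(all(cfg$domain$mask[idx]))
})

test_that("untreated myeloma burden trends upward over the horizon", {
  cfg <- habm_config(nx = 31, ny = 31, nz = 31, horizon_h = 300,
                     n_cd8 = 0, n_treg = 0)
  sm <- run_replicates(cfg, n = 4, master_seed = 2)
  tot <- sm$mean[, "MIC"] + sm$mean[, "MM"]
  expect_gt(tot[length(tot)], tot[1])
  # trend, not path: thirds of the horizon are ordered
  thirds <- split(tot, cut(seq_along(tot), 3))
  expect_true(mean(thirds[[1]]) < mean(thirds[[2]]))
  expect_true(mean(thirds[[2]]) < mean(thirds[[3]]))
})

test_that("immune surveillance slows tumor growth", {
  base <- habm_config(nx = 31, ny = 31, nz = 31, horizon_h = 240)
  off <- habm_config(nx = 31, ny = 31, nz = 31, horizon_h = 240,
                     n_cd8 = 0, n_treg = 0)
  s_on <- run_replicates(base, n = 6, master_seed = 7)
  s_off <- run_replicates(off, n = 6, master_seed = 7)
  tum_on <- s_on$mean[, "MIC"] + s_on$mean[, "MM"]
  tum_off <- s_off$mean[, "MIC"] + s_off$mean[, "MM"]
  # replicate-mean trajectory with immunity never exceeds the immune-free
  # one by more than counting noise, and is strictly below at the horizon
  expect_true(all(tum_on <= tum_off + pmax(3, 0.1 * tum_off)))
  expect_lt(tum_on[length(tum_on)], tum_off[length(tum_off)])
})

test_that("replicate summaries pool runs and shrink their standard error", {
  cfg <- small_cfg()
  s1 <- run_replicates(cfg, n = 1, master_seed = 9)
  one <- habm_run(cfg, seed = replicate_seed(9, 1))
  expect_equal(s1$mean[, "MIC"], one$MIC, ignore_attr = TRUE)
  expect_true(all(s1$sd == 0))
  # SD of replicate means shrinks roughly like 1/sqrt(n)
  finals <- function(n, seed) {
    vapply(1:4, function(b) {
      sm <- run_replicates(cfg, n = n, master_seed = seed + b * 1000)
      sm$mean[nrow(sm$mean), "MM"]
    }, numeric(1))
  }
  sd_small <- sd(finals(2, 100))
  sd_big <- sd(finals(8, 200))
  expect_lt(sd_big, sd_small * 1.5)  # loose CLT-scaling check
})

test_that("configs round-trip through serialisation and reject bad input", {
  cfg <- habm_config(nx = 21, ny = 21, nz = 21,
                     regimen = drug_regimen(btz_nM = 1.5))
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(serialize_config(cfg), path, auto_unbox = TRUE)
  cfg2 <- parse_config(path)
  expect_equal(serialize_config(cfg2), serialize_config(cfg))
  # empty file -> defaults
  p2 <- tempfile(fileext = ".json"); writeLines("{}", p2)
  expect_equal(serialize_config(parse_config(p2)),
               serialize_config(habm_config()))
  p3 <- tempfile(fileext = ".json"); writeLines('{"nonsense": 1}', p3)
  expect_error(parse_config(p3), "unknown config keys")
  expect_error(habm_config(horizon_h = 601), "multiple")
  expect_error(parse_config(tempfile()), "not found")
})
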