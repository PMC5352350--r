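# behavior constants used by the rule-primitive tests, independent of the
# shipped calibration
test_rules <- function(over = list()) {
  utils::modifyList(list(
    mic = list(p_apop0 = 0.001, div_pmax = 0.03, div_H = 300, div_n = 2,
               selfrenew_pmax = 0.75, selfrenew_H = 200, selfrenew_n = 2,
               p_mig = 0.5, cycle_h = 24),
    mm = list(p_apop0 = 0.002, btz_pmax = 0.09, btz_H = 1, div_pmax = 0.06,
              div_H = 300, div_n = 2, p_mig = 0.5, cycle_h = 24, lgn = 5),
    cd8 = list(p_div0 = 0.02, tgfb_H = 2, tgfb_n = 1, treg_K = 1,
               len_pmax = 0.006, len_H = 2, p_die = 0.004, p_lysis = 0.5,
               attach_protection = 0.3, p_mig = 0.8, cycle_h = 12,
               sense_radius = 5),
    treg = list(p_div_pmax = 0.02, tgfb_H = 1.5, tgfb_n = 1,
                len_supp_max = 0.6, len_supp_H = 3, p_die = 0.005,
                p_suppress = 0.4, arrest_frac = 0.5, p_mig = 0.8,
                cycle_h = 12, sense_radius = 5),
    bmsc = list(thal_emax = 0.85, thal_H = 2, ecm_floor_pa = 100)), over)
}

test_that("die casting matches its probability", {
  set.seed(1)
  expect_false(any(replicate(50, decide(0))))
  expect_true(all(replicate(50, decide(1))))
  expect_error(decide(1.2), "p must be")
  expect_error(decide(-0.1), "p must be")
  set.seed(42)
  acc <- mean(replicate(1e5, decide(0.3)))
  expect_lt(abs(acc - 0.3), 0.005)
})

test_that("hill_prob satisfies its identities and bounds", {
  expect_equal(hill_prob(0, 0.8, 2, 2), 0)
  expect_equal(hill_prob(2, 0.8, 2, 2), 0.4)
  x <- seq(0, 10, by = 0.5)
  p <- hill_prob(x, 0.8, 2, 3)
  expect_true(all(diff(p) > 0))
  expect_true(all(p >= 0 & p <= 0.8))
  expect_error(hill_prob(-1, 0.5, 1, 1), "x must be")
  expect_error(hill_prob(1, 1.5, 1, 1), "pmax")
})

test_that("MIC fate follows the configured self-renewal probability", {
  r1 <- test_rules(list(mic = list(selfrenew_pmax = 1, selfrenew_H = 1e-6)))
  r0 <- test_rules(list(mic = list(selfrenew_pmax = 0)))
  set.seed(5)
  expect_true(all(replicate(20, mic_fate(400, r1)) == "SELF_RENEW"))
  expect_true(all(replicate(20, mic_fate(400, r0)) == "DIFFERENTIATE"))
  r <- test_rules()
  q <- hill_prob(400, r$mic$selfrenew_pmax, r$mic$selfrenew_H,
                 r$mic$selfrenew_n)
  set.seed(6)
  frac <- mean(replicate(1e4, mic_fate(400, r)) == "SELF_RENEW")
  expect_lt(abs(frac - q), 0.02)
})

test_that("daughter placement is uniform over free Moore sites", {
  occ <- array(FALSE, dim = c(5, 5, 5))
  # fully crowded neighborhood defers division
  occ2 <- occ; occ2[2:4, 2:4, 2:4] <- TRUE
  expect_null(divide_site(c(3, 3, 3), occ2))
  # exactly one free site is chosen with certainty
  occ3 <- occ2; occ3[2, 3, 3] <- FALSE
  expect_equal(divide_site(c(3, 3, 3), occ3), c(2, 3, 3))
  # chi-square uniformity over the 26 free sites
  set.seed(7)
  draws <- t(replicate(13000, divide_site(c(3, 3, 3), occ)))
  key <- paste(draws[, 1], draws[, 2], draws[, 3])
  tab <- table(key)
  expect_length(tab, 26)
  chi2 <- sum((tab - 500)^2 / 500)
  expect_lt(chi2, 52.6)  # qchisq(.999, df = 25)
})

test_that("migration seeks kind-specific targets and respects occupancy", {
  occ <- array(FALSE, dim = c(7, 7, 7))
  # blocked: no free neighbor
  occf <- occ; occf[, , ] <- TRUE; occf[4, 4, 4] <- FALSE
  expect_equal(migrate_step(c(4, 4, 4), occf, "MM"), c(4, 4, 4))
  # MIC moves up the stiffness gradient
  stiff <- function(sites) ifelse(sites[, 1] > 4, 400, 100)
  s <- migrate_step(c(4, 4, 4), occ, "MIC", stiffness_at = stiff)
  expect_equal(s[1], 5)
  # CD8 approaches its target
  s2 <- migrate_step(c(4, 4, 4), occ, "CD8", target = c(7, 4, 4))
  expect_equal(s2, c(5, 4, 4))
  # no target: unbiased walk, near-zero mean displacement
  set.seed(8)
  disp <- t(replicate(1000, migrate_step(c(4, 4, 4), occ, "CD8") - c(4, 4, 4)))
  expect_lt(max(abs(colMeans(disp))), 0.08)
})

test_that("CTL lysis honors adjacency and attachment protection", {
  r <- test_rules(list(cd8 = list(p_lysis = 1)))
  expect_error(attempt_lysis(c(1, 1, 1), c(3, 1, 1), FALSE, r), "adjacent")
  set.seed(9)
  expect_identical(attempt_lysis(c(1, 1, 1), c(2, 1, 1), FALSE, r), "KILLED")
  r2 <- test_rules(list(cd8 = list(p_lysis = 0.5, attach_protection = 0.3)))
  set.seed(10)
  k_un <- mean(replicate(5000, attempt_lysis(c(1, 1, 1), c(2, 1, 1),
                                             FALSE, r2)) == "KILLED")
  k_at <- mean(replicate(5000, attempt_lysis(c(1, 1, 1), c(2, 1, 1),
                                             TRUE, r2)) == "KILLED")
  expect_gt(k_un, k_at)          # attached cells escape more often
  expect_lt(abs(k_un - 0.5), 0.03)
  expect_lt(abs(k_at - 0.15), 0.03)
})

test_that("Treg suppression splits arrest and apoptosis by dice roll", {
  r0 <- test_rules(list(treg = list(p_suppress = 0)))
  set.seed(11)
  expect_true(all(replicate(30, treg_suppress(r0)) == "NONE"))
  r <- test_rules(list(treg = list(p_suppress = 1, arrest_frac = 0.5)))
  set.seed(12)
  out <- replicate(1e4, treg_suppress(r))
  expect_false(any(out == "NONE"))
  expect_lt(abs(mean(out == "ARREST") - 0.5), 0.01)
})

test_that("CD8 proliferation responds to TGF-beta, Tregs and LEN", {
  r <- test_rules()
  p0 <- cd8_proliferation_prob(0, 0, 0, r)
  expect_equal(p0, r$cd8$p_div0)
  expect_lt(cd8_proliferation_prob(5, 0, 0, r), p0)       # TGFb suppresses
  expect_lt(cd8_proliferation_prob(0, 2, 0, r), p0)       # Tregs suppress
  expect_gt(cd8_proliferation_prob(0, 0, 5, r), p0)       # LEN stimulates
  expect_gt(cd8_proliferation_prob(0, 0, 10, r),
            cd8_proliferation_prob(0, 0, 5, r))
  # saturating TGFb floors the baseline at the LEN contribution
  expect_equal(cd8_proliferation_prob(1e9, 0, 0, r), 0, tolerance = 1e-6)
  expect_error(cd8_proliferation_prob(-1, 0, 0, r), ">= 0")
})

test_that("Treg proliferation rises with TGF-beta and falls with LEN", {
  r <- test_rules()
  expect_equal(treg_proliferation_prob(0, 0, r), 0)
  expect_gt(treg_proliferation_prob(3, 0, r), treg_proliferation_prob(1, 0, r))
  expect_lt(treg_proliferation_prob(3, 10, r), treg_proliferation_prob(3, 0, r))
})

test_that("drug response primitives behave as calibrated couplings", {
  r <- test_rules()
  expect_equal(mm_btz_kill_prob(0, r), 0)
  expect_gt(mm_btz_kill_prob(5, r), mm_btz_kill_prob(1.5, r))
  expect_equal(thal_attenuation(0, r), 1)
  expect_lt(thal_attenuation(10, r), thal_attenuation(1, r))
  expect_gt(thal_attenuation(1e6, r), 0)
})
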