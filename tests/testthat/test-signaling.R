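test_that("hill production term satisfies its identities", {
  expect_equal(hill(0, 3, 0.5), 0)
  expect_equal(hill(0.5, 3, 0.5), 1.5)      # half-saturation
  expect_equal(hill(1e9, 3, 0.5), 3, tolerance = 1e-6)  # saturation
  x <- seq(0, 5, by = 0.25)
  expect_true(all(diff(hill(x, 2, 1)) > 0))  # monotone
  expect_error(hill(-1, 1, 1), "x must be")
  expect_error(hill(1, 1, 0), "H must be")
})

test_that("the BMSC network has the stated topology", {
  net <- build_bmsc_network()
  expect_length(net$states, 7)
  expect_identical(net$inputs, "SDF1")
  expect_equal(nrow(net$edges), 10)
  # MYL2 converges RhoA and ERK
  expect_setequal(net$edges$source[net$edges$target == "MYL2"],
                  c("RhoA", "ERK"))
  # the input carries no degradation term
  expect_false("SDF1" %in% names(net$degradations))
  expect_setequal(names(net$degradations), net$states)
})

test_that("the MIC network has the stated topology and drug term", {
  net <- build_mic_network()
  expect_setequal(net$inputs, c("stiffness", "D1"))
  expect_setequal(net$outputs, c("Adhesion", "Survival"))
  expect_equal(nrow(net$edges), 11)
  expect_setequal(net$edges$source[net$edges$target == "Rac"],
                  c("FAK", "PI3K"))
  # Survival: one Hill production (NFKB) and one dose inhibition
  expect_identical(net$edges$source[net$edges$target == "Survival"], "NFKB")
  expect_identical(net$inhibitions$target, "Survival")
  expect_identical(net$inhibitions$dose, "D1")
})

test_that("malformed networks are rejected", {
  expect_error(signaling_network(
    species = c("A", "B"), inputs = "A",
    edges = data.frame(source = "A", target = "C", k = "k1", H = "H1"),
    degradations = c(B = "d1")), "declared species")
  expect_error(signaling_network(
    species = c("A", "B"), inputs = "A",
    edges = data.frame(source = "A", target = "B", k = "k1", H = "H1"),
    degradations = c(X = "d1")), "degradation")
})

test_that("near-zero production reduces to exponential decay", {
  net <- build_bmsc_network()
  p <- synthetic_true_params("bmsc")
  p$k[] <- 1e-12
  tc <- integrate_network(net, p, c(SDF1 = 1), times = c(0, 0.5, 1, 2))
  for (s in net$states) {
    d <- p$d[[unname(net$degradations[s])]]
    expect_equal(unname(tc$values[s, ]), exp(-d * tc$times),
                 tolerance = 1e-5)
  }
})

test_that("long-time integration matches the topological fixed point", {
  for (model in c("bmsc", "mic")) {
    net <- if (model == "bmsc") build_bmsc_network() else build_mic_network()
    p <- synthetic_true_params(model)
    inputs <- if (model == "bmsc") c(SDF1 = 0.7)
      else c(stiffness = 0.6, D1 = 1)
    fp <- network_fixed_point(net, p, inputs)
    tc <- integrate_network(net, p, inputs, times = c(0, 400))
    expect_equal(unname(tc$values[net$states, 2]), unname(fp),
                 tolerance = 1e-4)
  }
})

test_that("states stay within the production/degradation bounds", {
  net <- build_mic_network()
  p <- synthetic_true_params("mic")
  tc <- integrate_network(net, p, c(stiffness = 1, D1 = 5),
                          times = seq(0, 200, by = 5))
  for (s in net$states) {
    k_in <- sum(p$k[net$edges$k[net$edges$target == s]])
    d <- p$d[[unname(net$degradations[s])]]
    expect_true(all(tc$values[s, ] >= 0))
    expect_true(all(tc$values[s, ] <= k_in / d + 1 + 1e-8))
  }
})

test_that("zero dose nullifies the drug inhibition term", {
  net <- build_mic_network()
  p <- synthetic_true_params("mic")
  p2 <- p; p2$drug$K_BTZ <- 1e-12
  t1 <- integrate_network(net, p, c(stiffness = 0.7, D1 = 0), c(0, 50))
  t2 <- integrate_network(net, p2, c(stiffness = 0.7, D1 = 0), c(0, 50))
  expect_equal(t1$values, t2$values, tolerance = 1e-9)
})

test_that("stiffness map is anchored, monotone and saturating", {
  calib <- habm_params()$bmsc$calib
  expect_equal(stiffness_map(1, calib), 400)
  x <- seq(0.5, calib$x_sat + 2, by = 0.1)
  expect_true(all(diff(stiffness_map(x, calib)) >= 0))
  expect_equal(stiffness_map(calib$x_sat, calib), 530)
  expect_equal(stiffness_map(calib$x_sat + 5, calib), 530)
})

test_that("stiffness response is 400 Pa at zero dose and capped at 530", {
  p <- habm_params()$bmsc
  expect_equal(bmsc_stiffness_response(0, p), 400)
  expect_equal(bmsc_stiffness_response(1, p), 530, tolerance = 1e-6)
  doses <- c(0, 0.05, 0.15, 0.4, 0.8, 1)
  resp <- bmsc_stiffness_response(doses, p)
  expect_true(all(diff(resp) >= -1e-9))
})

test_that("survival falls with bortezomib and rises with stiffness", {
  p <- habm_params()$mic
  s_by_dose <- vapply(c(0, 0.5, 1.5, 3, 5),
                      function(b) mic_survival_rate(400, b, p), numeric(1))
  expect_true(all(diff(s_by_dose) <= 1e-9))
  s_by_stiff <- vapply(c(100, 250, 400, 530),
                       function(s) mic_survival_rate(s, 0, p), numeric(1))
  expect_true(all(diff(s_by_stiff) >= -1e-9))
  expect_true(all(s_by_dose >= 0 & s_by_dose <= 1))
  expect_error(mic_survival_rate(400, -1, p), "btz_nM")
})

test_that("adhesion combines a stiffness component with a 20% floor", {
  p <- habm_params()$mic
  comp <- mic_adhesion_rate(400, p, component = "stiffness")
  total <- mic_adhesion_rate(400, p)
  expect_equal(total, comp + 0.2, tolerance = 1e-9)
  expect_gte(mic_adhesion_rate(400, p), mic_adhesion_rate(100, p))
  # zero stiffness input: the cascade decays, leaving (nearly) the floor
  expect_lt(mic_adhesion_rate(0, p, t = 400, component = "stiffness"), 0.02)
})

test_that("time courses export as tidy frames", {
  net <- build_bmsc_network()
  tc <- integrate_network(net, synthetic_true_params("bmsc"), c(SDF1 = 1),
                          times = c(0, 0.5, 1))
  df <- time_course_frame(tc)
  expect_identical(df$time_h, c(0, 0.5, 1))
  expect_true(all(net$species %in% names(df)))
  expect_equal(df$stiffness[1], 1)
})
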