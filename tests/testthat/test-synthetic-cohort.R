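# The multivariate-normal cohort generator, native embedding, and scaled
# clone cohorts.

test_that("identical parameters and seed reproduce the cohort bit-exactly", {
  a <- simulate_cohort(cohort_params(n = 10, seed = 101))
  b <- simulate_cohort(cohort_params(n = 10, seed = 101))
  expect_identical(lapply(a, `[[`, "points"), lapply(b, `[[`, "points"))
  expect_identical(vapply(a, `[[`, numeric(1), "age"),
                   vapply(b, `[[`, numeric(1), "age"))
  c <- simulate_cohort(cohort_params(n = 10, seed = 102))
  expect_false(identical(a[[1]]$points, c[[1]]$points))
})

test_that("default draws satisfy the landmark-set invariants", {
  cohort <- simulate_cohort(cohort_params(n = 30, seed = 1))
  expect_length(cohort, 30)
  for (s in cohort) {
    p <- s$points
    expect_identical(s$frame, "acpc")
    expect_true(p["AC", "y"] > 0 && p["PC", "y"] < 0)
    expect_equal(p["AC", "y"], -p["PC", "y"])
    expect_true(all(p[c("PU_A_R", "PU_L_R", "RN_R"), "x"] > 0))
    expect_true(all(p[c("PU_A_L", "PU_L_L", "RN_L"), "x"] < 0))
    expect_gte(s$third_ventricle_width, 0)
  }
})

test_that("empirical moments converge to the generating parameters", {
  big <- simulate_cohort(cohort_params(n = 10000, seed = 7))
  rnx <- vapply(big, function(s) s$points["RN_R", "x"], numeric(1))
  # 3-sigma bands: mean 4.58 +/- 3*0.49/sqrt(n); sd 0.49 +/- 3*sd/sqrt(2n)
  expect_lt(abs(mean(rnx) - 4.58), 3 * 0.49 / sqrt(10000))
  expect_lt(abs(sd(rnx) - 0.49), 3 * 0.49 / sqrt(2 * 10000))
  acpc <- vapply(big, acpc_length, numeric(1))
  expect_lt(abs(mean(acpc) - 24.52), 3 * 0.78 / sqrt(10000))
  pul <- vapply(big, function(s) s$points["PU_L_R", "x"], numeric(1))
  expect_lt(abs(cor(rnx, pul) - 0.546), 0.03)
})

test_that("unattainable correlation patterns are refused with a repair message", {
  # A near-singular pattern: x correlated 0.95 with two variables that are
  # themselves anticorrelated cannot be completed positive definite.
  bad <- cohort_params(n = 5, seed = 1, correlations = list(
    list("ACPC", "OX_Y", 0.95), list("ACPC", "OX_Z", 0.95),
    list("OX_Y", "OX_Z", -0.9)))
  expect_message(try(simulate_cohort(bad), silent = TRUE), "repaired")
  expect_error(suppressMessages(simulate_cohort(bad)), "max_repair")
  ok <- cohort_params(n = 5, seed = 1, correlations = list(
    list("ACPC", "OX_Y", 0.95), list("ACPC", "OX_Z", 0.95),
    list("OX_Y", "OX_Z", -0.9)), allow_large_repair = TRUE)
  expect_message(co <- simulate_cohort(ok), "repaired")
  expect_length(co, 5)
})

test_that("nearest-PD repair is a no-op on valid matrices and logs its size", {
  R <- diag(3); R[1, 2] <- R[2, 1] <- 0.5
  out <- nearest_pd_correlation(R)
  expect_identical(attr(out, "repair_delta"), 0)
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  fixed <- nearest_pd_correlation(bad)
  expect_gt(attr(fixed, "repair_delta"), 0)
  expect_gte(min(eigen(fixed, symmetric = TRUE)$values), 0)
  expect_equal(unname(diag(fixed)), rep(1, 3))
})

test_that("native embedding round-trips through the frame conversion", {
  cohort <- simulate_cohort(cohort_params(n = 100, seed = 41))
  set.seed(41)
  worst <- 0
  for (s in cohort) {
    emb <- embed_native(s, rigid_jitter(max_rotation = 15))
    rec <- native_to_acpc(emb$landmarks)
    worst <- max(worst, max(abs(rec$points - s$points)))
    # the returned ground-truth transform maps acpc points to the embedding
    p <- landmark(s, "RN_R")
    expect_equal(as.numeric(apply_transform(emb$transform, p)),
                 unname(emb$landmarks$points["RN_R", ]), tolerance = 1e-9)
  }
  expect_lt(worst, 1e-6)
})

test_that("zero jitter is a pure convention flip plus translation", {
  s <- make_acpc_set()
  emb <- embed_native(s, rigid_jitter(max_rotation = 0,
                                      translation_range = 0,
                                      translation_base = c(100, 110, 90)))
  expect_equal(emb$transform$rotation, diag(c(1, -1, -1)))
  expect_equal(unname(emb$landmarks$points["AC", ]),
               c(0, -11.85, 0) + c(100, 110, 90))
  d0 <- as.numeric(dist(s$points))
  expect_equal(as.numeric(dist(emb$landmarks$points)), d0,
               tolerance = 1e-9)
})

test_that("jitter bounds are validated", {
  expect_error(rigid_jitter(max_rotation = 45), "30")
  expect_error(rigid_jitter(max_rotation = -1), "30")
})

test_that("scaled clones apply one factor per axis to every landmark", {
  atlas <- cvh_atlas()
  frozen <- scaled_clone_cohort(atlas, c(0, 0, 0), n = 3, seed = 1)
  for (s in frozen) {
    expect_equal(s$points, atlas$landmarks$points)
  }
  cohort <- scaled_clone_cohort(atlas, c(0.1, 0.05, 0.08), n = 10, seed = 2)
  f <- attr(cohort, "scale_factors")
  for (i in seq_along(cohort)) {
    expect_equal(cohort[[i]]$points,
                 sweep(atlas$landmarks$points, 2, f[i, ], `*`),
                 tolerance = 1e-12)
  }
  # ratio of any two x coordinates is preserved (single factor per axis)
  r1 <- cohort[[1]]$points["RN_R", "x"] / cohort[[1]]$points["PU_L_R", "x"]
  expect_equal(r1, atlas$landmarks$points["RN_R", "x"] /
                 atlas$landmarks$points["PU_L_R", "x"], tolerance = 1e-12)
})

test_that("no-stretch deviation on scaled clones matches its Monte-Carlo magnitude", {
  atlas <- cvh_atlas()
  sdx <- 0.06
  cohort <- scaled_clone_cohort(atlas, c(sdx, 0, 0), n = 5000, seed = 3)
  ev <- evaluate_schemes(cohort, atlas,
                         x_choices = "NONE", y_choices = "NONE",
                         z_choices = "NONE")
  none_x <- ev[ev$axis == "x" & ev$side == "right", "mean_abs_mm"]
  # oracle: E|c - 1| for lognormal(0, sd) factors, by direct simulation
  set.seed(1234)
  e_abs <- mean(abs(rlnorm(2e5, 0, sdx) - 1))
  expected <- abs(atlas$landmarks$points["RN_R", "x"]) * e_abs
  expect_lt(abs(none_x - expected) / expected, 0.1)
})
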