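# Pearson correlations, atlas comparisons, normality screening.

test_that("pearson handles perfect linearity and a frozen small example", {
  x <- c(1, 5, 2, 8, 3)
  up <- pearson(x, 2 * x + 1)
  expect_equal(up$r, 1, tolerance = 1e-12)
  down <- pearson(x, -x)
  expect_equal(down$r, -1, tolerance = 1e-12)
  small <- pearson(c(1, 2, 3, 4), c(1, 3, 2, 5))
  expect_equal(small$r, 0.8315218406203, tolerance = 1e-10)
  expect_equal(round(small$r, 2), 0.83)
  expect_equal(small$p, 0.1684781593797, tolerance = 1e-10)
  expect_equal(small$n, 4)
})

test_that("pearson is symmetric and affine-invariant", {
  set.seed(13)
  for (i in 1:10) {
    x <- rnorm(25); y <- rnorm(25)
    a <- pearson(x, y); b <- pearson(y, x)
    expect_equal(a$r, b$r, tolerance = 1e-12)
    shifted <- pearson(3 * x + 7, -2 * y + 1)
    expect_equal(shifted$r, -a$r, tolerance = 1e-12)
    expect_equal(shifted$p, a$p, tolerance = 1e-12)
  }
})

test_that("statistics match brute-force references within 1e-10", {
  set.seed(17)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 4))
    y <- 0.4 * x + rnorm(n)
    pr <- pearson(x, y)
    bf <- pearson_bf(x, y)
    expect_equal(pr$r, bf$r, tolerance = 1e-10)
    expect_equal(pr$p, bf$p, tolerance = 1e-10)

    mu <- rnorm(1)
    tt <- one_sample_vs_atlas(x, mu)
    tb <- t_one_sample_bf(x, mu)
    expect_equal(tt$t, tb$t, tolerance = 1e-10)
    expect_equal(tt$df, tb$df)
    expect_equal(tt$p, tb$p, tolerance = 1e-10)

    ks <- ks_normality(x, mean = 0, sd = 1)
    kb <- ks_bf(x, 0, 1)
    expect_equal(ks$D, kb$D, tolerance = 1e-10)
    expect_equal(ks$p, kb$p, tolerance = 1e-10)
  }
})

test_that("one-sample t against the atlas constant matches closed forms", {
  same <- one_sample_vs_atlas(c(1, 2, 3), 2)
  expect_equal(same$t, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)
  vs0 <- one_sample_vs_atlas(c(1, 2, 3), 0)
  expect_equal(vs0$t, 3.46410161513775, tolerance = 1e-10)
  expect_equal(vs0$df, 2)
  welch <- one_sample_vs_atlas(c(1, 2, 3, 4), 0,
                               atlas_replicates = c(2, 3, 4, 5))
  expect_match(welch$method, "Welch")
  ref <- t.test(c(1, 2, 3, 4), c(2, 3, 4, 5), var.equal = FALSE)
  expect_equal(welch$t, unname(ref$statistic), tolerance = 1e-12)
})

test_that("degenerate inputs raise the specified errors", {
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson(1:2, 1:2), "at least 3")
  expect_error(pearson(1:4, 1:3), "equal length")
  expect_error(one_sample_vs_atlas(c(2, 2, 2), 1), "variance")
  expect_error(one_sample_vs_atlas(3, 1), "at least 2")
  expect_error(ks_normality(c(1, 1, 1, 1, 1)), "variance")
  expect_error(ks_normality(c(1, 2)), "at least 5")
})

test_that("KS screen separates normal from exponential samples", {
  set.seed(19)
  ps <- vapply(1:50, function(i) ks_normality(rnorm(500))$p, numeric(1))
  expect_gte(mean(ps > 0.05), 0.94)
  expect_lt(ks_normality(rexp(10000))$p, 0.05)
})

test_that("KS statistic at half-spaced quantiles equals 0.5/n", {
  n <- 40
  v <- qnorm((seq_len(n) - 0.5) / n, mean = 3, sd = 2)
  ks <- ks_normality(v, mean = 3, sd = 2)
  expect_equal(ks$D, 0.5 / n, tolerance = 1e-12)
  expect_false(ks$parameters_estimated)
  expect_true(ks_normality(v)$parameters_estimated)
})

test_that("correlation report pools hemispheres with reflected lateral signs", {
  # build a noiseless cohort where RN x is an exact affine image of the
  # lateral putamen tip on both sides in the mirrored convention
  base <- make_acpc_set()
  cohort <- lapply(1:6, function(i) {
    pts <- base$points
    pul <- 28 + i
    pts["PU_L_R", "x"] <- pul
    pts["PU_L_L", "x"] <- -pul
    pts["RN_R", "x"] <- 0.2 * pul + 1
    pts["RN_L", "x"] <- -(0.2 * pul + 1)
    # deterministic variation elsewhere so no covariate is constant
    pts["RN_R", c("y", "z")] <- pts["RN_R", c("y", "z")] + 0.03 * i^2
    pts["RN_L", c("y", "z")] <- pts["RN_L", c("y", "z")] + 0.02 * i
    pts["PU_A_R", c("x", "y")] <- pts["PU_A_R", c("x", "y")] + 0.05 * i
    pts["PU_A_L", c("x", "y")] <- pts["PU_A_L", c("x", "y")] - 0.07 * i
    pts["OX", c("y", "z")] <- pts["OX", c("y", "z")] + c(0.04, -0.06) * i
    pts[c("AC", "PC"), "y"] <- pts[c("AC", "PC"), "y"] * (1 + 0.002 * i)
    landmark_set(paste0("s", i), pts, third_ventricle_width = 2 + 0.1 * i,
                 age = 40 + i, frame = "acpc")
  })
  rep <- correlation_report(cohort)
  cell <- rep[rep$rn_axis == "RN_X" & rep$variable == "PU_L_X", ]
  expect_equal(cell$r, 1, tolerance = 1e-9)
  expect_equal(cell$n, 12)  # 2n pooled observations
  expect_equal(cell$sig, "**")
})

test_that("correlation report recovers the generating sign pattern at large n", {
  big <- simulate_cohort(cohort_params(n = 10000, seed = 23))
  rep <- correlation_report(big)
  rnx <- rep[rep$rn_axis == "RN_X", ]
  get <- function(v) rnx[rnx$variable == v, ]
  expect_gt(get("PU_A_X")$r, 0.3)
  expect_gt(get("PU_L_X")$r, 0.4)
  expect_gt(get("V3")$r, 0.3)
  expect_lt(get("AGE")$r, -0.3)
  expect_equal(get("PU_L_X")$r, 0.546, tolerance = 0.03)
  # unlisted pairs stay near zero
  expect_lt(abs(get("OX_Y")$r), 0.05)
  expect_lt(abs(get("OX_Z")$r), 0.05)
})

test_that("independent variables yield near-zero correlations at large n", {
  p <- cohort_params(n = 10000, seed = 29, correlations = list(),
                     mirror_r = 0)
  rep <- correlation_report(simulate_cohort(p))
  expect_lt(max(abs(rep$r)), 0.05)
})

test_that("cohort summary recovers generator moments and flags outliers", {
  atlas <- cvh_atlas()
  cohort <- simulate_cohort(cohort_params(n = 30, seed = 31))
  cs <- cohort_summary(cohort, atlas)
  row <- cs[cs$variable == "RN_X" & cs$side == "right", ]
  expect_equal(row$n, 30)
  # 3-sigma sampling band around the generating mean 4.58 (sd 0.49)
  expect_lt(abs(row$mean_mm - 4.58), 3 * 0.49 / sqrt(30))
  expect_true(row$min_mm <= row$mean_mm && row$mean_mm <= row$max_mm)
  expect_equal(row$atlas_mm, 4.43)

  # an atlas value far outside the cohort range is strongly rejected
  far <- one_sample_vs_atlas(cs_values <- vapply(
    cohort, function(s) s$points["RN_R", "x"], numeric(1)), 20)
  expect_lt(far$p, 0.001)

  # identical subjects collapse the range and flag degeneracy
  clones <- scaled_clone_cohort(atlas, c(0, 0, 0), n = 4, seed = 1)
  cs0 <- cohort_summary(clones, atlas)
  expect_true(all(cs0$degenerate))
  expect_true(all(cs0$sd_mm == 0))
  expect_true(all(cs0$min_mm == cs0$max_mm))
  expect_true(all(is.na(cs0$t)))
})

test_that("the normality screen passes a Gaussian synthetic cohort", {
  cohort <- simulate_cohort(cohort_params(n = 30, seed = 37))
  nr <- cohort_normality(cohort)
  expect_equal(nrow(nr), 16)
  expect_gte(mean(nr$normal_at_05), 0.9)
})
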