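# Per-axis stretch ratios, red-nucleus registration, and cohort-level
# scheme evaluation.

test_that("stretch ratios follow atlas/subject with NONE fixed at 1", {
  atlas <- cvh_atlas()
  s <- make_acpc_set()
  expect_identical(stretch_ratio(s, atlas, "x", "NONE", "right"), 1)
  expect_identical(stretch_ratio(s, atlas, "y", "NONE", "left"), 1)

  # a subject with a known lateral putamen tip: cohort-mean coordinates
  s$points["PU_L_R", "x"] <- 31.19
  expect_equal(stretch_ratio(s, atlas, "x", "PU_L", "right"),
               0.910548252645078, tolerance = 1e-12)

  # subject identical to the atlas: every ratio is 1
  clone <- landmark_set("clone", atlas$landmarks$points,
                        atlas$third_ventricle_width, frame = "acpc")
  for (case in list(c("x", "PU_A", "left"), c("x", "PU_L", "right"),
                    c("y", "ACPC", "right"), c("z", "OX", "left"))) {
    expect_equal(stretch_ratio(clone, atlas, case[1], case[2], case[3]), 1,
                 tolerance = 1e-12)
  }
})

test_that("invalid fiducial choices and degenerate fiducials error", {
  atlas <- cvh_atlas()
  s <- make_acpc_set()
  expect_error(stretch_ratio(s, atlas, "y", "PU_A", "right"), "not a valid")
  s$points["OX", "z"] <- 17.2  # sign-flipped relative to the atlas
  expect_error(stretch_ratio(s, atlas, "z", "OX", "right"), "sign-flipped")
})

test_that("registration scales the red nucleus by the per-axis ratios", {
  atlas <- cvh_atlas()
  s <- make_acpc_set()
  s$points["PU_L_R", "x"] <- 31.19
  s$points["RN_R", "x"] <- 4.58

  res <- register_rn(s, atlas, stretch_scheme(x = "PU_L"))
  expect_equal(res$right$registered_rn[["x"]], 4.17031099711446,
               tolerance = 1e-12)
  expect_equal(res$right$deviation[1], -0.259689002885541,
               tolerance = 1e-12)
  # y and z are untouched under NONE
  expect_equal(res$right$registered_rn[["y"]], s$points["RN_R", "y"])
  expect_equal(res$right$ratios[["y"]], 1)

  # all-NONE never changes any coordinate
  none <- register_rn(s, atlas, stretch_scheme())
  expect_identical(as.numeric(none$left$registered_rn),
                   unname(s$points["RN_L", ]))
  expect_identical(as.numeric(none$right$registered_rn),
                   unname(s$points["RN_R", ]))

  # subject equal to the atlas: zero deviation under any scheme
  clone <- landmark_set("clone", atlas$landmarks$points,
                        atlas$third_ventricle_width, frame = "acpc")
  full <- register_rn(clone, atlas, stretch_scheme("PU_A", "ACPC", "OX"))
  expect_equal(full$left$deviation, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(full$right$deviation, c(0, 0, 0), tolerance = 1e-12)
})

test_that("x-scale equivariance: putamen stretches undo a shared lateral scale", {
  atlas <- cvh_atlas()
  for (c_scale in c(0.85, 1.1, 1.3)) {
    pts <- atlas$landmarks$points
    pts[, "x"] <- pts[, "x"] * c_scale
    subj <- landmark_set("scaled", pts, atlas$third_ventricle_width,
                         frame = "acpc")
    for (fid in c("PU_A", "PU_L")) {
      res <- register_rn(subj, atlas, stretch_scheme(x = fid))
      expect_equal(res$right$deviation[1], 0, tolerance = 1e-9)
      expect_equal(res$left$deviation[1], 0, tolerance = 1e-9)
    }
    none <- register_rn(subj, atlas, stretch_scheme())
    expect_equal(abs(none$right$deviation[1]),
                 abs(atlas$landmarks$points["RN_R", "x"]) * abs(c_scale - 1),
                 tolerance = 1e-9)
  }
})

test_that("deviation summaries match hand-computed statistics", {
  atlas <- cvh_atlas()
  # two subjects whose right RN x deviates by +0.2 and -0.4 under NONE
  mk <- function(id, dx) {
    pts <- atlas$landmarks$points
    pts["RN_R", "x"] <- pts["RN_R", "x"] + dx
    landmark_set(id, pts, atlas$third_ventricle_width, frame = "acpc")
  }
  ev <- evaluate_schemes(list(mk("a", 0.2), mk("b", -0.4)), atlas)
  row <- ev[ev$side == "right" & ev$axis == "x" & ev$fiducial == "NONE", ]
  expect_equal(row$mean_abs_mm, 0.3, tolerance = 1e-12)
  expect_equal(row$max_abs_mm, 0.4, tolerance = 1e-12)
  expect_equal(row$sd_mm, 0.14142135623731, tolerance = 1e-10)
  expect_equal(row$n, 2)

  # cohort of atlas copies: every statistic is zero
  clones <- scaled_clone_cohort(atlas, c(0, 0, 0), n = 3, seed = 1)
  ev0 <- evaluate_schemes(clones, atlas)
  expect_true(all(ev0$mean_abs_mm < 1e-12))
  expect_true(all(ev0$max_abs_mm < 1e-12))
})

test_that("summary statistics agree with a naive loop on random cohorts", {
  atlas <- cvh_atlas()
  set.seed(5)
  cohort <- simulate_cohort(cohort_params(n = 12, seed = 5))
  ev <- evaluate_schemes(cohort, atlas)
  for (k in sample(nrow(ev), 8)) {
    row <- ev[k, ]
    devs <- numeric(0)
    for (subj in cohort) {
      s <- stretch_ratio(subj, atlas, row$axis, row$fiducial, row$side)
      rn <- if (row$side == "right") "RN_R" else "RN_L"
      reg <- subj$points[rn, row$axis] * s
      devs <- c(devs, abs(reg - atlas$landmarks$points[rn, row$axis]))
    }
    expect_equal(row$mean_abs_mm, mean(devs), tolerance = 1e-12)
    expect_equal(row$sd_mm, sd(devs), tolerance = 1e-12)
    expect_equal(row$max_abs_mm, max(devs), tolerance = 1e-12)
  }
})

test_that("the generating scheme wins on exactly-scaled clone cohorts", {
  atlas <- cvh_atlas()
  cohort <- scaled_clone_cohort(atlas, scale_sds = c(0.08, 0, 0), n = 20,
                                seed = 9)
  ev <- evaluate_schemes(cohort, atlas)
  x <- ev[ev$axis == "x", ]
  for (side in c("left", "right")) {
    expect_lt(x[x$side == side & x$fiducial == "PU_L", "mean_abs_mm"], 1e-9)
    expect_lt(x[x$side == side & x$fiducial == "PU_A", "mean_abs_mm"], 1e-9)
    expect_gt(x[x$side == side & x$fiducial == "NONE", "mean_abs_mm"], 0.01)
  }
})

test_that("empty cohorts and frame mixing are rejected", {
  atlas <- cvh_atlas()
  expect_error(evaluate_schemes(list(), atlas), "empty")
  nat <- embed_native(make_acpc_set())$landmarks
  expect_error(evaluate_schemes(list(nat), atlas), "acpc")
  expect_error(register_rn(nat, atlas), "acpc")
})

test_that("side pooling averages the two sides' mean deviations", {
  atlas <- cvh_atlas()
  cohort <- simulate_cohort(cohort_params(n = 8, seed = 2))
  ev <- evaluate_schemes(cohort, atlas)
  pooled <- pool_sides(ev)
  for (k in seq_len(nrow(pooled))) {
    i <- ev$axis == pooled$axis[k] & ev$fiducial == pooled$fiducial[k]
    expect_equal(pooled$mean_abs_mm[k], mean(ev$mean_abs_mm[i]))
  }
  expect_equal(sum(pooled$minimal), 3)  # one winner per axis
})
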