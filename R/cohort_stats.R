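# Cohort-level statistics: Pearson correlations of the red nucleus against
# the fiducials and age, normality screening, per-variable summaries, and
# cohort-vs-atlas mean comparisons.

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation between two equal-length vectors with the
#' two-sided p-value from the t transform on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors, equal length >= 3, neither constant.
#' @return A list with `r`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

# Per-subject variable table, one row per subject. Left-side x coordinates
# keep their native (negative) sign here.
cohort_table <- function(cohort) {
  stopifnot(length(cohort) > 0)
  row <- function(s) {
    p <- s$points
    data.frame(
      subject_id = s$id,
      rn_x_r = p["RN_R", "x"], rn_y_r = p["RN_R", "y"], rn_z_r = p["RN_R", "z"],
      rn_x_l = p["RN_L", "x"], rn_y_l = p["RN_L", "y"], rn_z_l = p["RN_L", "z"],
      pu_a_x_r = p["PU_A_R", "x"], pu_a_y_r = p["PU_A_R", "y"],
      pu_a_x_l = p["PU_A_L", "x"], pu_a_y_l = p["PU_A_L", "y"],
      pu_l_x_r = p["PU_L_R", "x"], pu_l_x_l = p["PU_L_L", "x"],
      ox_y = p["OX", "y"], ox_z = p["OX", "z"],
      ac_y = p["AC", "y"], pc_y = p["PC", "y"],
      acpc = acpc_length(s),
      v3 = s$third_ventricle_width, age = s$age)
  }
  do.call(rbind, lapply(cohort, row))
}

# Hemisphere-pooled table: one row per subject-side (2n rows). Lateral x
# coordinates of the left side are reflected (multiplied by -1) so both
# sides share a positive-lateral convention; midline variables are repeated
# per side.
pooled_table <- function(cohort) {
  tab <- cohort_table(cohort)
  right <- data.frame(
    rn_x = tab$rn_x_r, rn_y = tab$rn_y_r, rn_z = tab$rn_z_r,
    pu_a_x = tab$pu_a_x_r, pu_a_y = tab$pu_a_y_r, pu_l_x = tab$pu_l_x_r,
    ox_y = tab$ox_y, ox_z = tab$ox_z, acpc = tab$acpc,
    v3 = tab$v3, age = tab$age)
  left <- data.frame(
    rn_x = -tab$rn_x_l, rn_y = tab$rn_y_l, rn_z = tab$rn_z_l,
    pu_a_x = -tab$pu_a_x_l, pu_a_y = tab$pu_a_y_l, pu_l_x = -tab$pu_l_x_l,
    ox_y = tab$ox_y, ox_z = tab$ox_z, acpc = tab$acpc,
    v3 = tab$v3, age = tab$age)
  rbind(right, left)
}

#' Correlation report of red-nucleus coordinates against fiducials and age
#'
#' Pools hemispheres to 2n observations by reflecting left-side x
#' coordinates (so lateral position is positive on both sides) and
#' correlates each red-nucleus coordinate against the fiducial variables and
#' age; midline variables (commissural length, optic chiasm, third-ventricle
#' width, age) are repeated for each side. Significance is flagged at the
#' 0.05 (`*`) and 0.001 (`**`) levels, without multiplicity correction.
#'
#' @param cohort List of AC-PC-frame `landmark_set` objects, length >= 3.
#' @return A data.frame with one row per (red-nucleus coordinate, variable)
#'   pair: `rn_axis`, `variable`, `r`, `p`, `n`, `sig`.
#' @export
correlation_report <- function(cohort) {
  if (length(cohort) < 3) stop("need at least 3 subjects")
  pool <- pooled_table(cohort)
  rn_vars <- c(RN_X = "rn_x", RN_Y = "rn_y", RN_Z = "rn_z")
  covars <- c(PU_A_X = "pu_a_x", PU_A_Y = "pu_a_y", OX_Y = "ox_y",
              OX_Z = "ox_z", ACPC = "acpc", PU_L_X = "pu_l_x",
              V3 = "v3", AGE = "age")
  rows <- list()
  for (i in seq_along(rn_vars)) {
    for (j in seq_along(covars)) {
      pr <- pearson(pool[[rn_vars[i]]], pool[[covars[j]]])
      rows[[length(rows) + 1]] <- data.frame(
        rn_axis = names(rn_vars)[i], variable = names(covars)[j],
        r = pr$r, p = pr$p, n = pr$n,
        sig = if (pr$p < 0.001) "**" else if (pr$p < 0.05) "*" else "")
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "pooling") <- paste(
    "hemispheres pooled to 2n observations; left-side x coordinates",
    "reflected; midline variables repeated per side")
  out
}

#' One-sample (or Welch two-sample) t-test of a cohort against an atlas value
#'
#' Default: one-sample t of the cohort values against the atlas constant,
#' `t = (mean - atlas) * sqrt(n) / sd` on `n - 1` degrees of freedom,
#' two-sided. When per-specimen atlas replicates are supplied, a Welch
#' unequal-variance two-sample t-test is computed instead.
#'
#' @param values Numeric cohort values, n >= 2, non-constant.
#' @param atlas_value The atlas reference value (mm).
#' @param atlas_replicates Optional numeric vector of per-specimen atlas
#'   values for the two-sample variant.
#' @return A list with `t`, `df`, `p`, `method`.
#' @export
one_sample_vs_atlas <- function(values, atlas_value, atlas_replicates = NULL) {
  if (length(values) < 2) stop("need at least 2 cohort values")
  if (stats::sd(values) == 0) {
    stop("zero variance in cohort values; t statistic undefined")
  }
  if (is.null(atlas_replicates)) {
    tt <- stats::t.test(values, mu = atlas_value, alternative = "two.sided")
    method <- "one-sample t vs atlas constant"
  } else {
    tt <- stats::t.test(values, atlas_replicates, var.equal = FALSE,
                        alternative = "two.sided")
    method <- "Welch two-sample t vs atlas replicates"
  }
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, method = method)
}

#' Kolmogorov-Smirnov normality screen
#'
#' One-sample two-sided KS statistic of the values against a normal
#' distribution, with the p-value taken from the asymptotic KS distribution.
#' By default the reference normal uses the sample's own mean and standard
#' deviation; note the caveat that with estimated parameters the asymptotic
#' p-value is conservative (true type-I error below nominal), as in the
#' common practice this screen mirrors. Pass explicit `mean`/`sd` to test
#' against a fully specified normal.
#'
#' @param values Numeric vector, n >= 5, non-constant.
#' @param mean,sd Optional reference-normal parameters; estimated from the
#'   sample when `NULL`.
#' @return A list with `D`, `p`, and `parameters_estimated`.
#' @export
ks_normality <- function(values, mean = NULL, sd = NULL) {
  if (length(values) < 5) stop("need at least 5 values")
  if (stats::sd(values) == 0) stop("zero variance; KS test undefined")
  estimated <- is.null(mean) || is.null(sd)
  if (is.null(mean)) mean <- base::mean(values)
  if (is.null(sd)) sd <- stats::sd(values)
  kt <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean = mean, sd = sd, exact = FALSE))
  D <- unname(kt$statistic)
  list(D = D, p = kolmogorov_sf(sqrt(length(values)) * D),
       parameters_estimated = estimated)
}

# Survival function of the asymptotic two-sided Kolmogorov distribution,
# P(K > s), evaluated to machine precision: the Jacobi theta form converges
# fast for small s, the alternating exponential series for large s.
kolmogorov_sf <- function(s) {
  if (s <= 0) return(1)
  if (s < 1) {
    k <- 1:20
    cdf <- sqrt(2 * pi) / s * sum(exp(-(2 * k - 1)^2 * pi^2 / (8 * s^2)))
    p <- 1 - cdf
  } else {
    k <- 1:200
    p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * s^2))
  }
  min(max(p, 0), 1)
}

# The Table-5-style summary variables: accessor into cohort_table() rows
# plus the matching atlas quantity.
summary_variables <- function() {
  list(
    list(variable = "RN_X", side = "right", col = "rn_x_r",
         atlas = function(a) a$landmarks$points["RN_R", "x"]),
    list(variable = "RN_Y", side = "right", col = "rn_y_r",
         atlas = function(a) a$landmarks$points["RN_R", "y"]),
    list(variable = "RN_Z", side = "right", col = "rn_z_r",
         atlas = function(a) a$landmarks$points["RN_R", "z"]),
    list(variable = "RN_X", side = "left", col = "rn_x_l",
         atlas = function(a) a$landmarks$points["RN_L", "x"]),
    list(variable = "RN_Y", side = "left", col = "rn_y_l",
         atlas = function(a) a$landmarks$points["RN_L", "y"]),
    list(variable = "RN_Z", side = "left", col = "rn_z_l",
         atlas = function(a) a$landmarks$points["RN_L", "z"]),
    list(variable = "AC_Y", side = "midline", col = "ac_y",
         atlas = function(a) a$landmarks$points["AC", "y"]),
    list(variable = "PC_Y", side = "midline", col = "pc_y",
         atlas = function(a) a$landmarks$points["PC", "y"]),
    list(variable = "PU_A_X", side = "right", col = "pu_a_x_r",
         atlas = function(a) a$landmarks$points["PU_A_R", "x"]),
    list(variable = "PU_A_X", side = "left", col = "pu_a_x_l",
         atlas = function(a) a$landmarks$points["PU_A_L", "x"]),
    list(variable = "PU_L_X", side = "right", col = "pu_l_x_r",
         atlas = function(a) a$landmarks$points["PU_L_R", "x"]),
    list(variable = "PU_L_X", side = "left", col = "pu_l_x_l",
         atlas = function(a) a$landmarks$points["PU_L_L", "x"]),
    list(variable = "OX_Y", side = "midline", col = "ox_y",
         atlas = function(a) a$landmarks$points["OX", "y"]),
    list(variable = "OX_Z", side = "midline", col = "ox_z",
         atlas = function(a) a$landmarks$points["OX", "z"]),
    list(variable = "ACPC_LENGTH", side = "midline", col = "acpc",
         atlas = function(a) acpc_length(a$landmarks)),
    list(variable = "V3_WIDTH", side = "midline", col = "v3",
         atlas = function(a) a$third_ventricle_width)
  )
}

#' Cohort summary with atlas comparison
#'
#' Per-variable range, mean, and sample standard deviation over the cohort
#' (left and right sides reported separately for lateral structures), the
#' matching atlas value, and the one-sample t-test of the cohort mean
#' against it. Variables with zero cohort variance are flagged
#' (`degenerate = TRUE`) and carry `NA` test results rather than an error.
#'
#' @param cohort Non-empty list of AC-PC-frame `landmark_set` objects.
#' @param atlas An `atlas_model` with landmarks.
#' @return A data.frame with columns `variable`, `side`, `min_mm`, `max_mm`,
#'   `mean_mm`, `sd_mm`, `n`, `atlas_mm`, `t`, `df`, `p`, `degenerate`.
#' @export
cohort_summary <- function(cohort, atlas) {
  if (length(cohort) == 0) stop("cohort is empty")
  tab <- cohort_table(cohort)
  rows <- lapply(summary_variables(), function(v) {
    vals <- tab[[v$col]]
    av <- v$atlas(atlas)
    degenerate <- length(vals) < 2 || stats::sd(vals) == 0
    if (degenerate) {
      t <- df <- p <- NA_real_
    } else {
      tt <- one_sample_vs_atlas(vals, av)
      t <- tt$t; df <- tt$df; p <- tt$p
    }
    data.frame(variable = v$variable, side = v$side,
               min_mm = min(vals), max_mm = max(vals),
               mean_mm = mean(vals),
               sd_mm = if (length(vals) > 1) stats::sd(vals) else 0,
               n = length(vals), atlas_mm = av,
               t = t, df = df, p = p, degenerate = degenerate)
  })
  out <- do.call(rbind, rows)
  attr(out, "test") <- "one-sample t of the cohort against the atlas constant"
  out
}

#' Normality screen over the cohort summary variables
#'
#' Runs [ks_normality()] on each summary variable of the cohort.
#'
#' @param cohort Non-empty list of AC-PC-frame `landmark_set` objects.
#' @return A data.frame with `variable`, `side`, `D`, `p`, `normal_at_05`.
#' @export
cohort_normality <- function(cohort) {
  tab <- cohort_table(cohort)
  rows <- lapply(summary_variables(), function(v) {
    ks <- ks_normality(tab[[v$col]])
    data.frame(variable = v$variable, side = v$side,
               D = ks$D, p = ks$p, normal_at_05 = ks$p > 0.05)
  })
  do.call(rbind, rows)
}
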