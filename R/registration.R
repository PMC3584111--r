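# Fiducial-stretch registration of subject landmark sets to the atlas and
# cohort-level evaluation of the competing per-axis stretch schemes.
#
# Registration here is deliberately minimal: both subject and atlas are
# already in the midcommissural frame, so only per-axis anisotropic scale
# remains. For each axis a stretch ratio s = atlas_value / subject_value is
# computed from one fiducial (or fixed at 1 for no stretch), and the
# red-nucleus coordinate on that axis is multiplied by s. The localization
# error is the registered red-nucleus coordinate minus the atlas red nucleus
# of the same side.

X_CHOICES <- c("PU_A", "PU_L", "NONE")
Y_CHOICES <- c("ACPC", "NONE")
Z_CHOICES <- c("OX", "NONE")

#' Per-axis stretch scheme
#'
#' Which fiducial drives the stretch on each axis: the anterior or lateral
#' putamen tip (x, side-matched), the commissural length (y), the optic
#' chiasm depth (z), or no stretch (`"NONE"`, ratio fixed at 1).
#'
#' @param x One of `"PU_A"`, `"PU_L"`, `"NONE"`.
#' @param y One of `"ACPC"`, `"NONE"`.
#' @param z One of `"OX"`, `"NONE"`.
#' @return An object of class `stretch_scheme`.
#' @export
stretch_scheme <- function(x = "NONE", y = "NONE", z = "NONE") {
  x <- match.arg(toupper(x), X_CHOICES)
  y <- match.arg(toupper(y), Y_CHOICES)
  z <- match.arg(toupper(z), Z_CHOICES)
  structure(list(x = x, y = y, z = z), class = "stretch_scheme")
}

#' @export
print.stretch_scheme <- function(x, ...) {
  cat("<stretch_scheme> x: ", x$x, ", y: ", x$y, ", z: ", x$z, "\n", sep = "")
  invisible(x)
}

# Subject-side counterpart of atlas_reference_value().
subject_reference_value <- function(subject, fiducial, side) {
  sfx <- if (side == "right") "R" else "L"
  p <- subject$points
  switch(fiducial,
         PU_A = p[paste0("PU_A_", sfx), "x"],
         PU_L = p[paste0("PU_L_", sfx), "x"],
         ACPC = acpc_length(subject),
         OX = p["OX", "z"],
         stop("unknown fiducial '", fiducial, "'"))
}

#' Stretch ratio for one axis
#'
#' The multiplier applied to a subject coordinate on one axis to land it in
#' atlas space: `s = atlas_value / subject_value`, where the value is the x
#' coordinate of the side-matched putamen tip (`PU_A`, `PU_L`), the
#' commissural length (`ACPC`), the optic-chiasm z (`OX`), or exactly 1 for
#' `NONE`. A subject fiducial whose coordinate is zero or has the opposite
#' sign to the atlas value would give a non-positive ratio and raises an
#' error.
#'
#' @param subject An AC-PC-frame `landmark_set`.
#' @param atlas An `atlas_model` with landmarks.
#' @param axis `"x"`, `"y"` or `"z"` (determines the admissible fiducials).
#' @param fiducial The fiducial choice for that axis (see
#'   [stretch_scheme()]).
#' @param side `"left"` or `"right"`; used for the side-matched x fiducials.
#' @return A positive scalar ratio.
#' @export
stretch_ratio <- function(subject, atlas, axis = c("x", "y", "z"),
                          fiducial, side = c("right", "left")) {
  axis <- match.arg(axis)
  side <- match.arg(side)
  fiducial <- toupper(fiducial)
  allowed <- switch(axis, x = X_CHOICES, y = Y_CHOICES, z = Z_CHOICES)
  if (!fiducial %in% allowed) {
    stop("fiducial '", fiducial, "' is not a valid choice for the ", axis,
         " axis (one of ", paste(allowed, collapse = ", "), ")")
  }
  if (fiducial == "NONE") return(1)
  if (!identical(subject$frame, "acpc")) {
    stop("subject '", subject$id, "' must be in the acpc frame")
  }
  a <- atlas_reference_value(atlas, fiducial, side)
  s <- subject_reference_value(subject, fiducial, side)
  if (!is.finite(s) || s == 0 || sign(s) != sign(a)) {
    stop("subject '", subject$id, "' has a zero or sign-flipped ", fiducial,
         " value (", s, ") on the ", axis, " axis; stretch ratio undefined")
  }
  a / s
}

#' Register a subject's red nuclei to the atlas under a stretch scheme
#'
#' Applies the per-axis stretch ratios to the subject's red-nucleus gravity
#' centers (side-matched fiducials on x; the commissural length and chiasm
#' depth are midline quantities shared by both sides) and reports the signed
#' deviation from the atlas red nucleus of the same side.
#'
#' @param subject An AC-PC-frame `landmark_set`.
#' @param atlas An `atlas_model` with landmarks.
#' @param scheme A `stretch_scheme`.
#' @return A list with elements `left` and `right`, each a
#'   `registration_result`: `subject_id`, `side`, `registered_rn`
#'   (AC-PC point), `deviation` (registered minus atlas, signed, mm),
#'   `ratios` (per-axis multipliers), `scheme`.
#' @export
register_rn <- function(subject, atlas, scheme = stretch_scheme()) {
  stopifnot(inherits(subject, "landmark_set"), inherits(scheme, "stretch_scheme"))
  if (!identical(subject$frame, "acpc")) {
    stop("subject '", subject$id, "' must be in the acpc frame")
  }
  one_side <- function(side) {
    ratios <- c(x = stretch_ratio(subject, atlas, "x", scheme$x, side),
                y = stretch_ratio(subject, atlas, "y", scheme$y, side),
                z = stretch_ratio(subject, atlas, "z", scheme$z, side))
    rn_name <- if (side == "right") "RN_R" else "RN_L"
    rn <- subject$points[rn_name, ] * ratios
    atlas_rn <- atlas$landmarks$points[rn_name, ]
    structure(
      list(subject_id = subject$id, side = side,
           registered_rn = as_frame_point(rn, "acpc"),
           deviation = unname(rn - atlas_rn),
           ratios = ratios, scheme = scheme),
      class = "registration_result")
  }
  list(left = one_side("left"), right = one_side("right"))
}

#' Evaluate competing stretch schemes over a cohort
#'
#' For every axis, candidate fiducial and side, registers every subject's
#' red nucleus and summarizes the absolute deviation from the atlas red
#' nucleus: mean, sample standard deviation (n - 1), and maximum. Axes are
#' evaluated independently (each axis has its own candidate list), and the
#' choice attaining the minimal mean absolute deviation is flagged per axis
#' and side.
#'
#' Statistics are computed on absolute deviations; signed deviations remain
#' available per subject through [register_rn()].
#'
#' @param cohort Non-empty list of AC-PC-frame `landmark_set` objects.
#' @param atlas An `atlas_model` with landmarks.
#' @param x_choices,y_choices,z_choices Candidate fiducials per axis.
#' @return A data.frame with columns `side`, `axis`, `fiducial`,
#'   `mean_abs_mm`, `sd_mm`, `max_abs_mm`, `n`, `minimal` (logical flag for
#'   the minimal-mean choice within each side and axis).
#' @export
evaluate_schemes <- function(cohort, atlas,
                             x_choices = X_CHOICES,
                             y_choices = Y_CHOICES,
                             z_choices = Z_CHOICES) {
  if (length(cohort) == 0) stop("cohort is empty")
  frames <- vapply(cohort, `[[`, character(1), "frame")
  if (!all(frames == "acpc")) {
    stop("all cohort subjects must be in the acpc frame")
  }
  choices <- list(x = x_choices, y = y_choices, z = z_choices)
  rows <- list()
  for (side in c("left", "right")) {
    rn_name <- if (side == "right") "RN_R" else "RN_L"
    atlas_rn <- atlas$landmarks$points[rn_name, ]
    for (axis in c("x", "y", "z")) {
      for (fid in choices[[axis]]) {
        dev <- vapply(cohort, function(subj) {
          s <- stretch_ratio(subject = subj, atlas = atlas, axis = axis,
                             fiducial = fid, side = side)
          subj$points[rn_name, axis] * s - atlas_rn[[axis]]
        }, numeric(1))
        a <- abs(dev)
        rows[[length(rows) + 1]] <- data.frame(
          side = side, axis = axis, fiducial = fid,
          mean_abs_mm = mean(a),
          sd_mm = if (length(a) > 1) stats::sd(a) else 0,
          max_abs_mm = max(a),
          n = length(a))
      }
    }
  }
  out <- do.call(rbind, rows)
  out$minimal <- FALSE
  for (side in unique(out$side)) {
    for (axis in unique(out$axis)) {
      i <- which(out$side == side & out$axis == axis)
      out$minimal[i[which.min(out$mean_abs_mm[i])]] <- TRUE
    }
  }
  rownames(out) <- NULL
  out
}

#' Pool both sides of a scheme evaluation
#'
#' Averages the two sides' per-subject absolute deviations for each axis and
#' fiducial (both sides contribute equally many subjects), giving the pooled
#' mean absolute deviation used for axis-level scheme comparison.
#'
#' @param summary A data.frame from [evaluate_schemes()].
#' @return A data.frame with columns `axis`, `fiducial`, `mean_abs_mm`,
#'   `minimal`.
#' @export
pool_sides <- function(summary) {
  agg <- stats::aggregate(mean_abs_mm ~ axis + fiducial, data = summary,
                          FUN = mean)
  agg$minimal <- FALSE
  for (axis in unique(agg$axis)) {
    i <- which(agg$axis == axis)
    agg$minimal[i[which.min(agg$mean_abs_mm[i])]] <- TRUE
  }
  agg[order(agg$axis, agg$fiducial), , drop = FALSE]
}

#' Fraction of replicate cohorts on which no-stretch is the best scheme
#'
#' Simulates replicate cohorts in which the red-nucleus coordinates are
#' statistically independent of every fiducial scale (all red-nucleus /
#' fiducial correlations zero), evaluates all candidate schemes on each
#' cohort, and returns the fraction of cohorts on which the no-stretch
#' choice attains the minimal pooled mean absolute deviation on each axis.
#'
#' @param atlas An `atlas_model` with landmarks.
#' @param n_cohorts Number of replicate cohorts.
#' @param n Subjects per cohort.
#' @param seed Integer seed; replicate c uses `seed + c - 1`.
#' @param params Base [cohort_params()]; its correlation list is cleared so
#'   red-nucleus coordinates are independent of the fiducials.
#' @return Named numeric vector of win fractions for axes `x`, `y`, `z`.
#' @export
none_scheme_win_rate <- function(atlas, n_cohorts = 100, n = 30, seed = 1,
                                 params = cohort_params()) {
  params$correlations <- list()
  wins <- c(x = 0, y = 0, z = 0)
  for (k in seq_len(n_cohorts)) {
    params$n <- n
    params$seed <- seed + k - 1
    cohort <- simulate_cohort(params)
    pooled <- pool_sides(evaluate_schemes(cohort, atlas))
    for (axis in names(wins)) {
      i <- pooled$axis == axis
      wins[[axis]] <- wins[[axis]] +
        (pooled$fiducial[i][pooled$minimal[i]] == "NONE")
    }
  }
  wins / n_cohorts
}
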