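# Synthetic landmark cohorts: a multivariate-normal generative model over
# the per-subject landmark variables, with mirrored left/right convention,
# plus helpers that embed AC-PC sets into a jittered image-native frame and
# build exactly-scaled atlas clones for registration ground truth.

# Sided variables are drawn in the mirrored (positive lateral) convention
# and negated on output for the left side; midline variables are drawn once
# per subject.
SIDED_VARS <- c("RN_X", "RN_Y", "RN_Z", "PU_A_X", "PU_A_Y", "PU_L_X")
MIDLINE_VARS <- c("ACPC", "OX_Y", "OX_Z", "V3", "AGE")

default_cohort_means <- function() {
  c(RN_X_R = 4.58, RN_X_L = 4.46,
    RN_Y_R = -6.01, RN_Y_L = -6.06,
    RN_Z_R = -5.46, RN_Z_L = -5.46,
    PU_A_X_R = 18.88, PU_A_X_L = 19.21,
    PU_A_Y_R = 28.78, PU_A_Y_L = 28.38,
    PU_L_X_R = 31.19, PU_L_X_L = 31.35,
    ACPC = 24.52, OX_Y = 19.22, OX_Z = -16.36,
    V3 = 2.88, AGE = 48.2)
}

default_cohort_sds <- function() {
  c(RN_X_R = 0.49, RN_X_L = 0.48,
    RN_Y_R = 0.63, RN_Y_L = 0.61,
    RN_Z_R = 1.06, RN_Z_L = 1.06,
    PU_A_X_R = 1.83, PU_A_X_L = 1.41,
    PU_A_Y_R = 1.5, PU_A_Y_L = 1.5,
    PU_L_X_R = 1.66, PU_L_X_L = 1.74,
    ACPC = 0.78, OX_Y = 1.58, OX_Z = 1.47,
    V3 = 1.12, AGE = 10.55)
}

default_cohort_correlations <- function() {
  list(list("RN_X", "PU_A_X", 0.433),
       list("RN_X", "PU_L_X", 0.546),
       list("RN_X", "V3", 0.404),
       list("RN_X", "AGE", -0.415))
}

#' Parameters of the synthetic-cohort generative model
#'
#' The generator draws, per subject, the vector of landmark variables
#' (red-nucleus x/y/z on both sides, putamen-tip x on both sides, the
#' commissural length, optic-chiasm y/z, third-ventricle width, age) from a
#' multivariate normal. Lateral (sided) variables are parameterized in the
#' mirrored positive convention and negated on output for the left side.
#' Defaults are the cohort means and standard deviations of the landmark
#' variables on 3 T T2 imaging of adult patients, with the four
#' significantly nonzero red-nucleus/fiducial correlations; all unlisted
#' pairs default to zero.
#'
#' Correlation entries use side-generic names (`RN_X`, `PU_A_X`, `PU_L_X`,
#' `ACPC`, `OX_Y`, `OX_Z`, `V3`, `AGE`, ...). A correlation involving a
#' sided variable is treated as a subject-level association — lateral
#' positions co-vary with overall brain proportions, not with one
#' hemisphere only — so a sided/sided entry is applied to all four
#' right/left combinations and a sided/midline entry to both sides. This,
#' together with a high inter-hemispheric correlation (`mirror_r`), is what
#' makes the printed pooled-hemisphere correlation pattern jointly
#' attainable: a side-matched correlation with independent hemispheres and
#' zero cross-side terms has no positive-definite completion.
#'
#' @param n Number of subjects.
#' @param seed Integer seed; the draw is bit-reproducible given (params,
#'   seed).
#' @param means,sds Named numeric vectors over the generator variables
#'   (sided variables carry `_R`/`_L` suffixes); entries override the
#'   defaults.
#' @param correlations List of `list(var_i, var_j, r)` entries with
#'   side-generic names and |r| < 1.
#' @param mirror_r Inter-hemispheric correlation assigned to the right/left
#'   pair of every sided variable. Homologous bilateral measurements are
#'   strongly correlated (typically 0.8-0.9), and a high value is also a
#'   joint-consistency requirement for the default correlation pattern (see
#'   above).
#' @param max_repair Largest acceptable Frobenius-norm change when the
#'   assembled correlation matrix needs a nearest-positive-definite repair;
#'   larger repairs error unless `allow_large_repair = TRUE`.
#' @param allow_large_repair Permit repairs above `max_repair`.
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n = 30, seed = 1,
                          means = NULL, sds = NULL,
                          correlations = default_cohort_correlations(),
                          mirror_r = 0.85,
                          max_repair = 0.05, allow_large_repair = FALSE) {
  if (abs(mirror_r) >= 1) stop("|mirror_r| must be < 1")
  m <- default_cohort_means()
  s <- default_cohort_sds()
  if (!is.null(means)) {
    unknown <- setdiff(names(means), names(m))
    if (length(unknown) > 0) {
      stop("unknown mean variable(s): ", paste(unknown, collapse = ", "))
    }
    m[names(means)] <- means
  }
  if (!is.null(sds)) {
    unknown <- setdiff(names(sds), names(s))
    if (length(unknown) > 0) {
      stop("unknown sd variable(s): ", paste(unknown, collapse = ", "))
    }
    s[names(sds)] <- sds
  }
  if (any(s <= 0)) stop("all sds must be positive")
  for (e in correlations) {
    if (length(e) != 3 || abs(as.numeric(e[[3]])) >= 1) {
      stop("correlation entries must be list(var_i, var_j, r) with |r| < 1")
    }
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 means = m, sds = s, correlations = correlations,
                 mirror_r = mirror_r, max_repair = max_repair,
                 allow_large_repair = allow_large_repair),
            class = "cohort_params")
}

# Expand side-generic correlation entries to the side-suffixed variable set.
expand_correlations <- function(correlations, varnames) {
  expand_one <- function(v) {
    if (v %in% SIDED_VARS) paste0(v, c("_R", "_L"))
    else if (v %in% MIDLINE_VARS) v
    else if (v %in% varnames) v
    else stop("unknown correlation variable '", v, "'")
  }
  out <- list()
  for (e in correlations) {
    a <- expand_one(e[[1]]); b <- expand_one(e[[2]]); r <- as.numeric(e[[3]])
    # subject-level association: every right/left combination gets r
    for (ai in a) for (bi in b) {
      out[[length(out) + 1]] <- list(ai, bi, r)
    }
  }
  out
}

#' Nearest positive-definite repair of a correlation matrix
#'
#' Eigenvalue clipping: eigenvalues below `eps` are raised to `eps`, the
#' matrix is reassembled and rescaled to unit diagonal. The Frobenius-norm
#' change is attached as attribute `repair_delta` (0 when the input was
#' already positive definite).
#'
#' @param R Symmetric matrix with unit diagonal.
#' @param eps Smallest admissible eigenvalue.
#' @return The repaired correlation matrix.
#' @export
nearest_pd_correlation <- function(R, eps = 1e-8) {
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) >= eps) {
    attr(R, "repair_delta") <- 0
    return(R)
  }
  vals <- pmax(ev$values, eps)
  R2 <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
  d <- sqrt(diag(R2))
  R2 <- R2 / tcrossprod(d)
  diag(R2) <- 1
  R2 <- (R2 + t(R2)) / 2
  dimnames(R2) <- dimnames(R)
  attr(R2, "repair_delta") <- norm(R2 - R, type = "F")
  R2
}

# Assemble the full correlation matrix from the entry list.
build_correlation_matrix <- function(params) {
  vn <- names(params$means)
  R <- diag(length(vn))
  dimnames(R) <- list(vn, vn)
  mr <- if (is.null(params$mirror_r)) 0 else params$mirror_r
  for (v in SIDED_VARS) {
    R[paste0(v, "_R"), paste0(v, "_L")] <-
      R[paste0(v, "_L"), paste0(v, "_R")] <- mr
  }
  for (e in expand_correlations(params$correlations, vn)) {
    i <- e[[1]]; j <- e[[2]]
    if (identical(i, j)) next
    R[i, j] <- R[j, i] <- e[[3]]
  }
  R <- nearest_pd_correlation(R)
  delta <- attr(R, "repair_delta")
  if (delta > 0) {
    message(sprintf(
      "correlation matrix repaired to nearest positive definite (Frobenius change %.4g)",
      delta))
    if (delta > params$max_repair && !params$allow_large_repair) {
      stop(sprintf(
        "correlation matrix repair (%.4g) exceeds max_repair (%.4g); the requested correlation pattern is not jointly attainable",
        delta, params$max_repair))
    }
  }
  R
}

#' Simulate a synthetic landmark cohort
#'
#' Draws the per-subject variable vector from the multivariate normal
#' defined by [cohort_params()] and assembles AC-PC-frame landmark sets:
#' the commissures are placed at `(0, L/2, 0)` and `(0, -L/2, 0)` from the
#' drawn commissural length `L`, putamen tips and red nuclei take their
#' drawn coordinates (left-side x negated from the mirrored convention), and
#' the optic chiasm sits on the midsagittal plane. Third-ventricle width is
#' truncated below at 0.01 mm and age at 1 year (both are >4-sigma events
#' under the defaults). Identical parameters and seed give bit-identical
#' cohorts.
#'
#' @param params A [cohort_params()] object.
#' @return A list of `landmark_set` objects in the AC-PC frame.
#' @export
simulate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  R <- build_correlation_matrix(params)
  sds <- params$sds
  Sigma <- R * tcrossprod(sds)
  set.seed(params$seed)
  draws <- MASS::mvrnorm(params$n, mu = params$means, Sigma = Sigma)
  if (params$n == 1) draws <- matrix(draws, nrow = 1,
                                     dimnames = list(NULL, names(params$means)))
  draws[, "V3"] <- pmax(draws[, "V3"], 0.01)
  draws[, "AGE"] <- pmax(draws[, "AGE"], 1)
  lapply(seq_len(params$n), function(i) {
    v <- draws[i, ]
    L <- v[["ACPC"]]
    pts <- rbind(
      AC = c(0, L / 2, 0),
      PC = c(0, -L / 2, 0),
      PU_A_L = c(-v[["PU_A_X_L"]], v[["PU_A_Y_L"]], 0),
      PU_A_R = c(v[["PU_A_X_R"]], v[["PU_A_Y_R"]], 0),
      PU_L_L = c(-v[["PU_L_X_L"]], 0, 0),
      PU_L_R = c(v[["PU_L_X_R"]], 0, 0),
      OX = c(0, v[["OX_Y"]], v[["OX_Z"]]),
      RN_L = c(-v[["RN_X_L"]], v[["RN_Y_L"]], v[["RN_Z_L"]]),
      RN_R = c(v[["RN_X_R"]], v[["RN_Y_R"]], v[["RN_Z_R"]]))
    landmark_set(sprintf("S%03d", i), pts,
                 third_ventricle_width = v[["V3"]],
                 age = v[["AGE"]], frame = "acpc")
  })
}

#' Rigid jitter specification for native-frame embedding
#'
#' @param max_rotation Largest rotation angle in degrees, in `[0, 30]`.
#' @param translation_base Length-3 translation placing the midcommissural
#'   point in a plausible positive native position (mm from the image
#'   corner).
#' @param translation_range Half-width of the uniform jitter added to the
#'   base translation, mm.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return An object of class `rigid_jitter`.
#' @export
rigid_jitter <- function(max_rotation = 10, translation_base = c(115, 110, 85),
                         translation_range = 10, seed = NULL) {
  if (max_rotation < 0 || max_rotation > 30) {
    stop("max_rotation must be in [0, 30] degrees")
  }
  stopifnot(length(translation_base) == 3, translation_range >= 0)
  structure(list(max_rotation = max_rotation,
                 translation_base = as.numeric(translation_base),
                 translation_range = translation_range, seed = seed),
            class = "rigid_jitter")
}

# Rotation by `angle` radians about unit axis `u` (Rodrigues).
axis_angle_rotation <- function(u, angle) {
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Embed an AC-PC landmark set into a jittered image-native frame
#'
#' Applies the axis-convention change from the AC-PC frame (anterior and
#' superior positive) to the native frame (posterior and inferior positive),
#' composes it with a random proper rotation within the jitter bound, and
#' translates all coordinates into a plausible positive native range. The
#' exact ground-truth transform is returned alongside the embedded set so
#' recovery can be checked against it.
#'
#' @param subject An AC-PC-frame `landmark_set`.
#' @param jitter A [rigid_jitter()].
#' @return A list with `landmarks` (the native-frame set) and `transform`
#'   (the ground-truth `rigid_transform` from `"acpc"` to `"native"`).
#' @export
embed_native <- function(subject, jitter = rigid_jitter()) {
  stopifnot(inherits(subject, "landmark_set"),
            identical(subject$frame, "acpc"),
            inherits(jitter, "rigid_jitter"))
  if (!is.null(jitter$seed)) set.seed(jitter$seed)
  flip <- diag(c(1, -1, -1))  # acpc axes -> native axis senses
  if (jitter$max_rotation > 0) {
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    angle <- stats::runif(1, 0, jitter$max_rotation) * pi / 180
    Rj <- axis_angle_rotation(u, angle)
  } else {
    Rj <- diag(3)
  }
  tr <- jitter$translation_base +
    stats::runif(3, -jitter$translation_range, jitter$translation_range)
  t <- rigid_transform(Rj %*% flip, tr,
                       source_frame = "acpc", target_frame = "native")
  pts <- t(apply(subject$points, 1, function(v) {
    as.numeric(apply_transform(t, as_frame_point(v, "acpc")))
  }))
  native <- landmark_set(subject$id, pts, subject$third_ventricle_width,
                         subject$age, frame = "native")
  list(landmarks = native, transform = t)
}

#' Cohort of exactly-scaled atlas clones
#'
#' Each subject is the atlas landmark set with one multiplicative factor per
#' axis, drawn lognormal(0, `scale_sds[axis]`), applied identically to every
#' landmark coordinate on that axis — fiducials and red nuclei alike. In
#' this regime a per-axis fiducial stretch is exactly correct: the matching
#' scheme recovers the atlas red nucleus with zero deviation, while no
#' stretch leaves a deviation of `|atlas RN| * |c - 1|` on each scaled axis.
#' The third-ventricle width (an x extent) is scaled by the x factor.
#'
#' @param atlas An `atlas_model` with landmarks.
#' @param scale_sds Length-3 non-negative lognormal sigma per axis (x, y,
#'   z); 0 means no scaling on that axis.
#' @param n Number of clone subjects.
#' @param seed Integer seed.
#' @return A list of `landmark_set` objects; the per-subject factors are
#'   attached as attribute `scale_factors` (an n-by-3 matrix).
#' @export
scaled_clone_cohort <- function(atlas, scale_sds = c(0.05, 0, 0), n = 30,
                                seed = 1) {
  stopifnot(inherits(atlas, "atlas_model"), !is.null(atlas$landmarks),
            length(scale_sds) == 3, all(scale_sds >= 0))
  set.seed(seed)
  factors <- sapply(scale_sds, function(s) {
    if (s == 0) rep(1, n) else stats::rlnorm(n, 0, s)
  })
  factors <- matrix(factors, nrow = n,
                    dimnames = list(NULL, c("x", "y", "z")))
  base <- atlas$landmarks
  cohort <- lapply(seq_len(n), function(i) {
    pts <- sweep(base$points, 2, factors[i, ], `*`)
    landmark_set(sprintf("clone_%03d", i), pts,
                 third_ventricle_width =
                   base$third_ventricle_width * factors[i, "x"],
                 age = base$age, frame = "acpc")
  })
  attr(cohort, "scale_factors") <- factors
  cohort
}
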