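# Midcommissural (AC-PC) coordinate frame construction and rigid conversion.
#
# Two frames are used throughout the package, both in continuous millimetres:
#   "native" — the image-native frame: origin at the upper-left corner pixel
#              of the first image of a sequence; x positive toward the
#              subject's right, y positive toward posterior, z positive
#              toward inferior.
#   "acpc"   — the midcommissural stereotactic frame: origin at the midpoint
#              of the AC-PC segment; x positive right, y positive anterior,
#              z positive superior.
# Both axis triads are right-handed, so a proper rotation maps one onto the
# other. Frame tags are mandatory: mixing frames is always an error, because
# the two conventions differ only by axis signs and would otherwise fail
# silently.

#' Canonical landmark vocabulary
#'
#' Names of the anatomical fiducials a complete landmark set carries:
#' the centers of the anterior and posterior commissures (`AC`, `PC`), the
#' anterior and lateral putamen tips on each side (`PU_A_L/R`, `PU_L_L/R`),
#' the anterior tip of the optic chiasm (`OX`, a midsagittal point), and the
#' red-nucleus gravity centers (`RN_L/R`).
#'
#' @export
LANDMARK_NAMES <- c("AC", "PC", "PU_A_L", "PU_A_R",
                    "PU_L_L", "PU_L_R", "OX", "RN_L", "RN_R")

#' Frame-tagged 3D point
#'
#' A point is a named numeric vector of length 3 (mm) carrying a `frame`
#' attribute, either `"native"` or `"acpc"`.
#'
#' @param x,y,z Coordinates in millimetres; must be finite.
#' @param frame Frame tag, `"native"` or `"acpc"`.
#' @return A numeric vector of length 3 with names `x`, `y`, `z` and a
#'   `frame` attribute.
#' @examples
#' p <- frame_point(1, 2, 3, frame = "acpc")
#' point_frame(p)
#' @export
frame_point <- function(x, y, z, frame = c("acpc", "native")) {
  frame <- match.arg(frame)
  p <- c(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  if (!all(is.finite(p))) {
    stop("point coordinates must be finite, got (",
         paste(p, collapse = ", "), ")")
  }
  attr(p, "frame") <- frame
  p
}

#' @rdname frame_point
#' @param p A point or landmark set.
#' @export
point_frame <- function(p) attr(p, "frame")

# Tag a bare numeric(3) with a frame, validating length/finiteness.
as_frame_point <- function(p, frame) {
  stopifnot(length(p) == 3)
  frame_point(p[[1]], p[[2]], p[[3]], frame = frame)
}

#' Rigid transform between tagged frames
#'
#' A proper rigid transform `q = R p + t` with an orthonormal rotation
#' (`det(R) = +1`), carrying source and target frame tags so that points can
#' only be pushed through transforms that match their frame.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1 (checked to
#'   1e-9).
#' @param translation Numeric length-3 translation in mm.
#' @param source_frame,target_frame Frame tags.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation, translation, source_frame, target_frame) {
  rotation <- as.matrix(rotation)
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    stop("rotation matrix is not orthonormal within 1e-9")
  }
  if (abs(det(rotation) - 1) > 1e-9) {
    stop("rotation matrix must be proper (determinant +1), got det = ",
         format(det(rotation)))
  }
  structure(
    list(rotation = rotation, translation = as.numeric(translation),
         source_frame = source_frame, target_frame = target_frame),
    class = "rigid_transform"
  )
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform> ", x$source_frame, " -> ", x$target_frame, "\n",
      sep = "")
  cat("rotation:\n")
  print(round(x$rotation, 6))
  cat("translation (mm): ", paste(round(x$translation, 6), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Invert a rigid transform
#'
#' @param t A `rigid_transform`.
#' @return The inverse transform (target frame back to source frame).
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  Rt <- t(t$rotation)
  rigid_transform(Rt, -Rt %*% t$translation,
                  source_frame = t$target_frame,
                  target_frame = t$source_frame)
}

#' Compose two rigid transforms
#'
#' `compose_transforms(b, a)` applies `a` first, then `b`; frames must chain.
#'
#' @param b,a `rigid_transform` objects with `a$target_frame ==
#'   b$source_frame`.
#' @return The composed `rigid_transform`.
#' @export
compose_transforms <- function(b, a) {
  if (!identical(a$target_frame, b$source_frame)) {
    stop("cannot compose: first transform targets '", a$target_frame,
         "' but second expects '", b$source_frame, "'")
  }
  rigid_transform(b$rotation %*% a$rotation,
                  b$rotation %*% a$translation + b$translation,
                  source_frame = a$source_frame,
                  target_frame = b$target_frame)
}

#' Apply a rigid transform to a frame-tagged point
#'
#' @param t A `rigid_transform`.
#' @param p A frame-tagged point whose frame equals `t$source_frame`.
#' @return The transformed point, tagged with `t$target_frame`.
#' @export
apply_transform <- function(t, p) {
  stopifnot(inherits(t, "rigid_transform"))
  pf <- point_frame(p)
  if (is.null(pf)) stop("point carries no frame tag")
  if (!identical(pf, t$source_frame)) {
    stop("frame mismatch: point is in '", pf, "' but transform expects '",
         t$source_frame, "'")
  }
  q <- as.numeric(t$rotation %*% as.numeric(p) + t$translation)
  as_frame_point(q, t$target_frame)
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Build the native-to-AC-PC rigid transform from three landmarks
#'
#' Constructs the midcommissural frame analytically from the anterior
#' commissure, the posterior commissure and one additional midsagittal
#' reference point (by convention the anterior optic-chiasm tip, which lies
#' on the midsagittal plane below the AC-PC plane). The resulting transform
#' maps native coordinates to AC-PC coordinates such that:
#'
#' * the AC-PC midpoint maps to the origin;
#' * AC maps onto the +y axis at `(0, L/2, 0)` with `L = ||AC - PC||`
#'   (anterior positive);
#' * the plane through AC, PC and the midsagittal reference maps onto the
#'   `x = 0` plane, with the reference at negative z (inferior structures
#'   below the AC-PC plane);
#' * handedness is preserved, so the native axis conventions (posterior and
#'   inferior positive) are absorbed into a proper rotation and a
#'   right-sided structure keeps positive x.
#'
#' @param ac,pc Native-frame points at the commissure centers; must differ.
#' @param midsagittal_ref Native-frame point on the midsagittal plane, not
#'   collinear with the AC-PC line, lying inferior to it.
#' @param tol Collinearity tolerance in mm (perpendicular distance of the
#'   reference from the AC-PC line).
#' @return A `rigid_transform` from `"native"` to `"acpc"`.
#' @export
build_acpc_transform <- function(ac, pc, midsagittal_ref, tol = 1e-6) {
  for (nm in c("ac", "pc", "midsagittal_ref")) {
    p <- get(nm)
    if (!identical(point_frame(p), "native")) {
      stop("'", nm, "' must be a native-frame point")
    }
  }
  d <- as.numeric(ac) - as.numeric(pc)
  if (sqrt(sum(d^2)) < tol) {
    stop("degenerate geometry: AC and PC coincide (distance < ", tol, " mm)")
  }
  origin <- (as.numeric(ac) + as.numeric(pc)) / 2
  e_y <- unit(d)  # anterior direction (AC is anterior to PC)
  w <- as.numeric(midsagittal_ref) - origin
  w_perp <- w - sum(w * e_y) * e_y
  if (sqrt(sum(w_perp^2)) < tol) {
    stop("degenerate geometry: midsagittal reference is collinear with the ",
         "AC-PC line (landmarks AC, PC, midsagittal_ref)")
  }
  # The reference lies in the midsagittal plane at negative z, so the
  # superior axis is opposite its in-plane offset. The lateral axis follows
  # by right-handedness (anterior x superior = right), which both numeric
  # frames share.
  e_z <- -unit(w_perp)
  e_x <- cross3(e_y, e_z)
  R <- rbind(e_x, e_y, e_z)
  dimnames(R) <- NULL
  rigid_transform(R, -R %*% origin,
                  source_frame = "native", target_frame = "acpc")
}

#' Landmark set for one subject or specimen
#'
#' Bundles one subject's named fiducial points with the scalar measurements
#' taken alongside them (third-ventricle width, age), all tagged with a
#' single frame. In the AC-PC frame the commissures are constrained to the
#' y axis and lateral structures must carry the sign of their side.
#'
#' @param id Subject or specimen identifier.
#' @param points A 9x3 numeric matrix of coordinates in mm with rownames
#'   exactly `LANDMARK_NAMES` (any order), or a named list of length-3
#'   vectors.
#' @param third_ventricle_width Width of the third ventricle in mm (>= 0),
#'   or `NA`.
#' @param age Age in years, or `NA`.
#' @param frame Frame tag shared by all points.
#' @param validate Check AC-PC-frame invariants (commissures on the y axis,
#'   lateral sign conventions)?
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(id, points, third_ventricle_width = NA_real_,
                         age = NA_real_, frame = c("acpc", "native"),
                         validate = TRUE) {
  frame <- match.arg(frame)
  if (is.list(points)) {
    points <- do.call(rbind, lapply(points, as.numeric))
  }
  points <- as.matrix(points)
  missing <- setdiff(LANDMARK_NAMES, rownames(points))
  if (length(missing) > 0) {
    stop("landmark set '", id, "' is missing required landmarks: ",
         paste(missing, collapse = ", "))
  }
  points <- points[LANDMARK_NAMES, , drop = FALSE]
  colnames(points) <- c("x", "y", "z")
  if (!all(is.finite(points))) {
    bad <- rownames(points)[!apply(is.finite(points), 1, all)]
    stop("landmark set '", id, "' has non-finite coordinates for: ",
         paste(bad, collapse = ", "))
  }
  if (!is.na(third_ventricle_width) && third_ventricle_width < 0) {
    stop("third_ventricle_width must be >= 0")
  }
  set <- structure(
    list(id = as.character(id), points = points,
         third_ventricle_width = as.numeric(third_ventricle_width),
         age = as.numeric(age), frame = frame),
    class = "landmark_set"
  )
  if (validate && frame == "acpc") validate_acpc_set(set)
  set
}

# AC-PC frame invariants: commissures on the y axis with AC anterior,
# right-sided structures at positive x, left-sided at negative x.
validate_acpc_set <- function(set, tol = 1e-6) {
  p <- set$points
  if (max(abs(p[c("AC", "PC"), c("x", "z")])) > tol) {
    stop("landmark set '", set$id, "': AC and PC must lie on the y axis ",
         "in the acpc frame (|x|,|z| <= ", tol, " mm)")
  }
  if (p["AC", "y"] <= p["PC", "y"]) {
    stop("landmark set '", set$id, "': AC must be anterior to PC ",
         "(AC.y > PC.y) in the acpc frame")
  }
  rights <- c("PU_A_R", "PU_L_R", "RN_R")
  lefts  <- c("PU_A_L", "PU_L_L", "RN_L")
  if (any(p[rights, "x"] <= 0) || any(p[lefts, "x"] >= 0)) {
    stop("landmark set '", set$id, "': right-sided landmarks must have ",
         "x > 0 and left-sided x < 0 in the acpc frame")
  }
  invisible(set)
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set> ", x$id, " [", x$frame, " frame]\n", sep = "")
  print(round(x$points, 3))
  cat("third-ventricle width: ", x$third_ventricle_width, " mm; age: ",
      x$age, " y\n", sep = "")
  invisible(x)
}

#' Retrieve one landmark of a set as a frame-tagged point
#'
#' @param set A `landmark_set`.
#' @param name One of `LANDMARK_NAMES`.
#' @export
landmark <- function(set, name) {
  stopifnot(inherits(set, "landmark_set"))
  if (!name %in% rownames(set$points)) {
    stop("no landmark '", name, "' in set '", set$id, "'")
  }
  as_frame_point(set$points[name, ], set$frame)
}

#' AC-PC length of a landmark set
#'
#' Euclidean distance between the commissure centers, invariant under rigid
#' conversion.
#'
#' @param set A `landmark_set`.
#' @return Length in mm.
#' @export
acpc_length <- function(set) {
  sqrt(sum((set$points["AC", ] - set$points["PC", ])^2))
}

#' Convert a native-frame landmark set to the AC-PC frame
#'
#' Builds the midcommissural transform from the set's own AC, PC and
#' midsagittal reference landmark and applies it to every point. Scalar
#' fields (third-ventricle width, age) are carried through unchanged; the
#' AC-PC length is preserved exactly up to floating-point error because the
#' conversion is a rigid isometry.
#'
#' @param set A `landmark_set` in the native frame (an AC-PC-frame set is
#'   also accepted, in which case the conversion is the identity up to
#'   floating point — the frame is rebuilt from the same landmarks).
#' @param midsagittal_ref Name of the landmark used as midsagittal
#'   reference; defaults to the optic chiasm tip `"OX"`.
#' @return The converted `landmark_set`, frame `"acpc"`.
#' @export
native_to_acpc <- function(set, midsagittal_ref = "OX") {
  stopifnot(inherits(set, "landmark_set"))
  required <- c("AC", "PC", midsagittal_ref)
  missing <- setdiff(required, rownames(set$points))
  if (length(missing) > 0) {
    stop("cannot build the AC-PC frame for '", set$id,
         "': missing landmark(s) ", paste(missing, collapse = ", "))
  }
  # Rebuild the frame from the set's own landmarks regardless of tag; on an
  # acpc-frame set this is the identity (idempotence). Points are re-tagged
  # native for the construction, which only reads coordinates.
  as_native <- function(v) as_frame_point(v, "native")
  t <- build_acpc_transform(as_native(set$points["AC", ]),
                            as_native(set$points["PC", ]),
                            as_native(set$points[midsagittal_ref, ]))
  pts <- t(apply(set$points, 1, function(v) {
    as.numeric(apply_transform(t, as_native(v)))
  }))
  landmark_set(set$id, pts, set$third_ventricle_width, set$age,
               frame = "acpc", validate = FALSE)
}

#' Read / write landmark sets as TSV
#'
#' The on-disk format is one row per landmark with columns `subject_id`,
#' `landmark`, `x_mm`, `y_mm`, `z_mm`, `frame`. Scalar measurements use the
#' pseudo-landmark names `THIRD_VENTRICLE_WIDTH` and `AGE`, with the value
#' in `x_mm` and empty `y_mm`/`z_mm`.
#'
#' @param path File path.
#' @return `read_landmarks()`: a named list of `landmark_set` objects.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          comment.char = "#")
  need <- c("subject_id", "landmark", "x_mm", "y_mm", "z_mm", "frame")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("landmark TSV is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  sets <- lapply(split(df, df$subject_id), function(d) {
    scalars <- d[d$landmark %in% c("THIRD_VENTRICLE_WIDTH", "AGE"), ]
    coords <- d[!d$landmark %in% c("THIRD_VENTRICLE_WIDTH", "AGE"), ]
    pts <- as.matrix(coords[, c("x_mm", "y_mm", "z_mm")])
    rownames(pts) <- coords$landmark
    getval <- function(name) {
      v <- scalars$x_mm[scalars$landmark == name]
      if (length(v) == 1) v else NA_real_
    }
    landmark_set(d$subject_id[1], pts,
                 third_ventricle_width = getval("THIRD_VENTRICLE_WIDTH"),
                 age = getval("AGE"),
                 frame = unique(d$frame))
  })
  sets[order(names(sets))]
}

#' @rdname read_landmarks
#' @param sets A `landmark_set` or list of them.
#' @export
write_landmarks <- function(sets, path) {
  if (inherits(sets, "landmark_set")) sets <- list(sets)
  rows <- lapply(sets, function(s) {
    coord <- data.frame(subject_id = s$id,
                        landmark = rownames(s$points),
                        x_mm = s$points[, "x"], y_mm = s$points[, "y"],
                        z_mm = s$points[, "z"], frame = s$frame,
                        row.names = NULL)
    scal <- data.frame(subject_id = s$id,
                       landmark = c("THIRD_VENTRICLE_WIDTH", "AGE"),
                       x_mm = c(s$third_ventricle_width, s$age),
                       y_mm = NA_real_, z_mm = NA_real_, frame = s$frame)
    rbind(coord, scal)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
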