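# Shared fixtures and independent brute-force oracles used across tests.

# A plausible AC-PC-frame landmark set with round coordinates.
make_acpc_set <- function(id = "T1", tvw = 2.5, age = 50) {
  pts <- rbind(
    AC = c(0, 11.85, 0),
    PC = c(0, -11.85, 0),
    PU_A_L = c(-15.8, 28.4, 0),
    PU_A_R = c(15.6, 28.8, 0),
    PU_L_L = c(-28.7, 0, 0),
    PU_L_R = c(28.4, 0, 0),
    OX = c(0, 18.6, -17.2),
    RN_L = c(-4.65, -5.93, -6.38),
    RN_R = c(4.43, -5.90, -6.40))
  landmark_set(id, pts, third_ventricle_width = tvw, age = age,
               frame = "acpc")
}

as_native <- function(v) frame_point(v[1], v[2], v[3], frame = "native")

# Random proper rotation via QR of a Gaussian matrix (sign-fixed).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

random_rigid <- function(source = "native", target = "native") {
  rigid_transform(random_rotation(), stats::rnorm(3, sd = 20),
                  source_frame = source, target_frame = target)
}

# --- independent statistical oracles (plain-formula implementations) ---

pearson_bf <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  r <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

t_one_sample_bf <- function(v, mu) {
  n <- length(v)
  t <- (mean(v) - mu) * sqrt(n) / stats::sd(v)
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}

# Two-sided KS statistic against N(mean, sd) and the asymptotic p
# (alternating Kolmogorov series).
ks_bf <- function(v, mean, sd) {
  n <- length(v)
  F <- stats::pnorm(sort(v), mean, sd)
  i <- seq_len(n)
  D <- max(i / n - F, F - (i - 1) / n)
  s <- sqrt(n) * D
  k <- 1:500
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * s^2))
  list(D = D, p = min(max(p, 0), 1))
}
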