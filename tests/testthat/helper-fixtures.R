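# geometric fixtures and small ground-truth builders used across tests

# circle arc polyline of radius r, CCW from angle a0, arc angle `arc`
circle_points <- function(r, arc, n = 400, a0 = 0, center = c(0, 0)) {
  th <- seq(a0, a0 + arc, length.out = n)
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

# sinusoid y = a sin(2 pi x / lambda), densely sampled over x in [0, len]
sinusoid_points <- function(a, lambda, len, n = 2000) {
  x <- seq(0, len, length.out = n)
  cbind(x, a * sin(2 * pi * x / lambda))
}

# analytic signed curvature of the sinusoid at position x
sinusoid_curvature <- function(a, lambda, x) {
  k <- 2 * pi / lambda
  yp <- a * k * cos(k * x)
  ypp <- -a * k^2 * sin(k * x)
  ypp / (1 + yp^2)^1.5
}

# compact noise-free ground truth for fast simulations
quick_truth <- function(species = "Macrobiotus shonaicus", frequency = 50,
                        speed = 200, heading_rate = 0, duration = 0.2,
                        seed = 1, noise_sd = 0, ...) {
  ground_truth(species_presets(species),
               beat_parameters(frequency = frequency, noise_sd = noise_sd,
                               ...),
               swim_parameters(speed = speed, heading_rate = heading_rate,
                               duration = duration, seed = seed))
}

# rigid transform of a 2-column point matrix
rigid_transform <- function(pts, angle = 0, shift = c(0, 0)) {
  rot <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  sweep(pts %*% t(rot), 2, shift, `+`)
}

# brute-force exact two-sided Mann-Whitney p by enumerating all subsets of
# pooled ranks (independent oracle for the DP implementation)
mw_enumerate_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(na + nb, na)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  lo <- mean(u_all <= u_obs)
  hi <- mean(u_all >= u_obs)
  min(1, 2 * min(lo, hi))
}
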