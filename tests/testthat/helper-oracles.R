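# independent oracles and small fixture builders used across test files

# rigid transform: rotate about z, then y, then translate
rigid_transform_morphology <- function(m, angles = c(0.3, -0.7),
                                       shift = c(5, -3, 12)) {
  rz <- matrix(c(cos(angles[1]), -sin(angles[1]), 0,
                 sin(angles[1]), cos(angles[1]), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  ry <- matrix(c(cos(angles[2]), 0, sin(angles[2]),
                 0, 1, 0,
                 -sin(angles[2]), 0, cos(angles[2])), 3, 3, byrow = TRUE)
  rot <- rz %*% ry
  tx <- function(xyz) sweep(xyz %*% t(rot), 2, shift, "+")
  m$soma <- as.numeric(tx(matrix(m$soma, 1)))
  m$neurites <- lapply(m$neurites, function(n) {
    xyz <- tx(as.matrix(n[, c("x", "y", "z")]))
    n$x <- xyz[, 1]; n$y <- xyz[, 2]; n$z <- xyz[, 3]
    n
  })
  m
}

# straight-line morphology along a direction, one node per knot
line_morphology <- function(knots, soma = c(0, 0, 0), id = "line") {
  neuron_morphology(id, soma,
                    list(data.frame(x = knots[, 1], y = knots[, 2],
                                    z = knots[, 3], radius = 0.2,
                                    parent = seq_len(nrow(knots)) - 1L)))
}

# brute-force upper-tail binomial p = P(X >= k), X ~ Bin(n, prob)
brute_binom_tail <- function(k, n, prob) {
  if (k <= 0) return(1)
  sum(stats::dbinom(seq(k, n), n, prob))
}

# brute-force hypergeometric upper tail P(X >= k) for the 2x2 Fisher table
brute_hyper_tail <- function(k, n, K, N) {
  if (k <= 0) return(1)
  hi <- min(n, K)
  if (k > hi) return(0)
  sum(vapply(seq(k, hi), function(i)
    exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)), 0))
}

# biexponential EPSC kernel identical in shape to the generator's
biexp_kernel <- function(rise_ms, decay_ms, fs, length_ms = 8 * decay_ms) {
  tt <- (seq_len(round(length_ms / 1000 * fs)) - 1L) / fs * 1000
  tpk <- log(decay_ms / rise_ms) * rise_ms * decay_ms / (decay_ms - rise_ms)
  norm <- exp(-tpk / decay_ms) - exp(-tpk / rise_ms)
  (exp(-tt / decay_ms) - exp(-tt / rise_ms)) / norm
}

# plant events of given amplitudes at given onsets into a noise trace (pA)
plant_epsc_events <- function(duration_s, fs, times_s, amps_pa, noise_sd,
                              rise_ms = 0.5, decay_ms = 4) {
  n <- round(duration_s * fs)
  x <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
  k <- biexp_kernel(rise_ms, decay_ms, fs)
  for (i in seq_along(times_s)) {
    j <- round(times_s[i] * fs) + 1L
    idx <- j:min(j + length(k) - 1L, n)
    x[idx] <- x[idx] - amps_pa[i] * k[seq_along(idx)]
  }
  ephys_trace(x, fs, mode = "vc")
}

# match detected event times to planted times within a window (seconds);
# returns c(recall, precision)
match_events <- function(detected_s, planted_s, window_s = 2e-3) {
  rec <- if (length(planted_s) == 0) NA_real_ else
    mean(vapply(planted_s, function(t) any(abs(detected_s - t) <= window_s), TRUE))
  prec <- if (length(detected_s) == 0) NA_real_ else
    mean(vapply(detected_s, function(t) any(abs(planted_s - t) <= window_s), TRUE))
  c(recall = rec, precision = prec)
}

# textbook balanced two-way ANOVA (type-I == type-II on balanced designs)
balanced_two_way_oracle <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  n <- length(y)
  gm <- mean(y)
  ma <- tapply(y, a, mean); mb <- tapply(y, b, mean)
  mab <- tapply(y, list(a, b), mean)
  nab <- table(a, b)
  ss_a <- sum(table(a) * (ma - gm)^2)
  ss_b <- sum(table(b) * (mb - gm)^2)
  ss_ab <- sum(nab * (mab - outer(ma, rep(1, nlevels(b))) -
                        outer(rep(1, nlevels(a)), mb) + gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_err <- ss_tot - ss_a - ss_b - ss_ab
  df_a <- nlevels(a) - 1; df_b <- nlevels(b) - 1
  df_ab <- df_a * df_b
  df_e <- n - nlevels(a) * nlevels(b)
  data.frame(
    factor = c("A", "B", "A:B"),
    F = c((ss_a / df_a) / (ss_err / df_e),
          (ss_b / df_b) / (ss_err / df_e),
          (ss_ab / df_ab) / (ss_err / df_e)),
    df1 = c(df_a, df_b, df_ab), df2 = df_e)
}
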