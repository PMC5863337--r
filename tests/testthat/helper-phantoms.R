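# Shared fixtures: all synthetic, built in code at test time.

noiseless <- list(speckle_sd = 0, additive_sd = 0)

truth_basic <- function(seed = 7, Dd = 1.0, Ds = 1.2, pwv = 2.0,
                        noise = noiseless, period = 0.16) {
  phantom_truth(seed = seed,
                diameter = list(Dd = Dd, Ds = Ds, period = period,
                                upstroke_frac = 0.25),
                pwv = pwv, noise = noise)
}

# PRF giving 25% headroom above the coupled waveform peak (the sonographer's
# scale-to-fit adjustment).
prf_for <- function(pwv, Dd, Ds, v_offset = 0) {
  peak <- 2 * pwv * 1000 * log(Ds / Dd) + v_offset
  max(9500, ceiling(1.25 * peak / 0.0642))
}

# Analytic trajectories (no tracking): points of a ring scaled by k(t).
analytic_ring_traj <- function(k_of_t, r0 = 1, n_pts = 24L, time = NULL) {
  theta <- seq(0, 2 * pi, length.out = n_pts + 1L)[-(n_pts + 1L)]
  time <- time %||% seq(0, 1, length.out = length(k_of_t))
  arr <- array(NA_real_, dim = c(length(k_of_t), n_pts, 2L))
  for (i in seq_along(k_of_t)) {
    arr[i, , 1L] <- k_of_t[i] * r0 * cos(theta)
    arr[i, , 2L] <- k_of_t[i] * r0 * sin(theta)
  }
  structure(list(time = time, sets = list(ring = arr), view = "SAX"),
            class = "trajectories")
}

# Independent brute-force Mann-Whitney oracle: enumerate every assignment of
# the pooled values to group A, recompute U from scratch each time.
mw_brute_force <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  idx <- utils::combn(length(pooled), na)
  u_of <- function(av, bv) sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  u_obs <- u_of(a, b)
  mu <- na * length(b) / 2
  us <- apply(idx, 2L, function(ix) u_of(pooled[ix], pooled[-ix]))
  list(U = u_obs, p = mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9))
}
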