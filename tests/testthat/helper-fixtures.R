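# Shared fixtures. Expensive Monte Carlo runs are cached per session so the
# acceptance tests and module tests reuse the same grids.

.fixture_env <- new.env(parent = emptyenv())

cached_mc <- function(energy, n_histories, seed, ...) {
  key <- paste0("mc_", energy, "_", n_histories, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    beam <- beam_spec("electron", energy = energy, n_histories = n_histories,
                      seed = seed)
    .fixture_env[[key]] <- simulate_electron_beam(beam, geometry_spec(), ...)
  }
  .fixture_env[[key]]
}

# local maxima of a lightly smoothed histogram, above a count floor
histogram_peaks <- function(vh, floor_frac = 0.01) {
  cnt <- stats::filter(vh$count, rep(1 / 3, 3), sides = 2)
  cnt <- as.numeric(cnt)
  cnt[is.na(cnt)] <- vh$count[is.na(cnt)]
  n <- length(cnt)
  floor <- floor_frac * sum(vh$count)
  idx <- which(cnt > floor &
                 cnt >= c(-Inf, cnt[-n]) & cnt >= c(cnt[-1], -Inf))
  # merge adjacent plateau indices
  if (length(idx) > 1) idx <- idx[c(TRUE, diff(idx) > 2)]
  vh$bin_mid[idx]
}

nrmse_in_circle <- function(recon, truth, shrink = 0.95) {
  N <- nrow(truth)
  xs <- seq_len(N) - (N + 1) / 2
  mask <- outer(xs, xs, function(a, b) a^2 + b^2) <= (shrink * N / 2)^2
  sqrt(mean((recon[mask] - truth[mask])^2)) / (max(truth) - min(truth))
}
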