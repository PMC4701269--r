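# Shared fixtures and independent oracles for the test suite.

# deterministic harmonic tone with 1/k amplitudes (no jitter, no seed needed)
make_tone <- function(f0, dur = 0.5, rate = 16000, n_harmonics = 8,
                      amplitude = 0.8) {
  t <- seq_len(round(dur * rate)) / rate
  ks <- seq_len(n_harmonics)
  ks <- ks[ks * f0 < rate / 2]
  x <- rowSums(sapply(ks, function(k) sin(2 * pi * k * f0 * t) / k))
  audio_signal(x * amplitude / sum(1 / ks), rate)
}

# hand-built pitch track from explicit strength / f0 vectors
make_track <- function(strength, f0 = rep(200, length(strength)), hop = 0.01,
                       rate = 48000) {
  voicemark:::new_pitch_track(
    tibble::tibble(
      time = (seq_along(strength) - 1) * hop,
      f0 = f0, strength = strength
    ),
    rate = rate, hop = hop
  )
}

# segments tibble from start/end vectors
make_segments <- function(start, end) {
  tibble::tibble(
    segment_id = seq_along(start), start = start, end = end,
    first_frame = NA_integer_, last_frame = NA_integer_
  )
}

# --- independent enumeration oracles -------------------------------------

# all permutations of seq_len(n), built iteratively by insertion (distinct
# from the package's recursive block construction)
perms_by_insertion <- function(n) {
  rows <- list(1L)
  for (k in 2:n) {
    rows <- unlist(
      lapply(rows, function(p) {
        lapply(seq_len(k), function(pos) append(p, k, after = pos - 1L))
      }),
      recursive = FALSE
    )
  }
  do.call(rbind, rows)
}

# exact two-sided Spearman p by brute force over all n! orderings of y
oracle_spearman_p <- function(x, y) {
  n <- length(x)
  perms <- perms_by_insertion(n)
  rho_obs <- stats::cor(rank(x), rank(y))
  rho_all <- apply(perms, 1, function(p) stats::cor(rank(x), rank(y[p])))
  mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
}

# KS statistic evaluated pointwise on the pooled values (independent of the
# package's ecdf-based computation)
oracle_ks_d <- function(a, b) {
  pts <- sort(c(a, b))
  max(abs(vapply(pts, function(p) mean(a <= p) - mean(b <= p), 0)))
}

# exact two-sample KS p by enumerating all label assignments of the pool
oracle_ks_p <- function(a, b) {
  pool <- c(a, b)
  na <- length(a)
  d_obs <- oracle_ks_d(a, b)
  splits <- utils::combn(length(pool), na)
  d_all <- apply(splits, 2, function(idx) oracle_ks_d(pool[idx], pool[-idx]))
  mean(d_all >= d_obs - 1e-12)
}
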