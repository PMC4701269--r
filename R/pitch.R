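#' ERB auditory frequency scale
#'
#' Convert between frequency in Hz and ERB-number (equivalent rectangular
#' bandwidth scale). The spectrum is sampled uniformly on this scale before
#' sawtooth-kernel matching, so that spectral resolution follows auditory
#' resolution: `erb = 21.4 * log10(1 + 0.00437 * f)`.
#'
#' @param f Frequency in Hz (vectorised, non-negative).
#' @param e ERB-number (vectorised, non-negative).
#' @return `hz_to_erb()` returns ERB-numbers; `erb_to_hz()` returns Hz.
#' @examples
#' hz_to_erb(1000)
#' erb_to_hz(hz_to_erb(137.5))
#' @export
hz_to_erb <- function(f) {
  if (any(f < 0, na.rm = TRUE)) stop("frequency must be non-negative", call. = FALSE)
  21.4 * log10(1 + 0.00437 * f)
}

#' @rdname hz_to_erb
#' @export
erb_to_hz <- function(e) {
  if (any(e < 0, na.rm = TRUE)) stop("ERB-number must be non-negative", call. = FALSE)
  (10^(e / 21.4) - 1) / 0.00437
}

# primes <= n (plain sieve; n is the harmonic count, always small)
primes_upto <- function(n) {
  if (n < 2) return(integer(0))
  is_p <- rep(TRUE, n)
  is_p[1] <- FALSE
  for (i in 2:floor(sqrt(n))) {
    if (i > n) break
    if (is_p[i]) is_p[seq(i * i, n, by = i)] <- FALSE
  }
  which(is_p)
}

#' Sawtooth-harmonic matching kernel for one pitch candidate
#'
#' Builds the spectral template a pitch candidate is matched against: positive
#' cosine lobes centred on the first and prime-numbered harmonics of the
#' candidate (harmonics 1, 2, 3, 5, 7, ...), flanked by negative half-weight
#' valleys between lobes, with lobe weight decaying as `1/sqrt(f)` so that low
#' harmonics dominate as they do in a sawtooth spectrum. The kernel is
#' normalised to unit Euclidean norm, so the inner product with a
#' unit-normalised square-root-compressed spectrum is a cosine similarity in
#' \[-1, 1\].
#'
#' @param f_candidate Candidate fundamental frequency in Hz (positive scalar).
#' @param freq_grid Strictly increasing vector of grid frequencies in Hz
#'   (typically ERB-spaced).
#' @return Numeric vector of kernel weights, one per grid frequency.
#' @examples
#' grid <- erb_to_hz(seq(hz_to_erb(25), hz_to_erb(4000), by = 0.1))
#' k <- build_kernel(200, grid)
#' grid[which.max(k)]
#' @export
build_kernel <- function(f_candidate, freq_grid) {
  if (!is.numeric(f_candidate) || length(f_candidate) != 1 || f_candidate <= 0) {
    stop("`f_candidate` must be a single positive frequency in Hz", call. = FALSE)
  }
  if (is.unsorted(freq_grid, strictly = TRUE)) {
    stop("`freq_grid` must be strictly increasing", call. = FALSE)
  }
  q <- freq_grid / f_candidate
  k <- numeric(length(q))
  n_harm <- floor(max(freq_grid) / f_candidate - 0.75)
  if (n_harm < 1) {
    stop("`freq_grid` must extend past the candidate's first harmonic lobe", call. = FALSE)
  }
  for (i in c(1L, primes_upto(n_harm))) {
    a <- abs(q - i)
    lobe <- a < 0.25
    k[lobe] <- cos(2 * pi * q[lobe])
    valley <- a > 0.25 & a < 0.75
    k[valley] <- k[valley] + cos(2 * pi * q[valley]) / 2
  }
  # decay envelope: weight ~ amplitude of the sawtooth harmonic at that freq
  pos_f <- freq_grid > 0
  k[pos_f] <- k[pos_f] * sqrt(1 / freq_grid[pos_f])
  k[!pos_f] <- 0
  nrm <- sqrt(sum(k^2))
  if (nrm > 0) k <- k / nrm
  k
}

# hann window matching the common "no zero endpoints" convention
hann_window <- function(n) {
  0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
}

# short-time magnitude spectra of x with window size ws (samples) and hop dn
# (samples); frames are centred at (0:(nf-1)) * dn samples, zero-padded at the
# edges. Returns list(mag = (ws/2+1) x nf matrix, freq, centers_s).
stft_mag <- function(x, fs, ws, dn) {
  nf <- floor(length(x) / dn) + 2L
  half <- ws %/% 2L
  xp <- c(numeric(half), x, numeric(half + nf * dn))
  idx <- outer(seq_len(ws), (seq_len(nf) - 1L) * dn, "+")
  frames <- matrix(xp[idx], nrow = ws) * hann_window(ws)
  spec <- stats::mvfft(frames)[seq_len(half + 1L), , drop = FALSE]
  list(
    mag = Mod(spec),
    freq = (0:half) * fs / ws,
    centers_s = (seq_len(nf) - 1L) * dn / fs
  )
}

#' Estimate per-frame fundamental frequency and pitch strength
#'
#' Tracks F0 by spectral matching: for every analysis frame the magnitude
#' spectrum is interpolated onto an ERB-spaced grid, square-root compressed
#' (an amplitude/loudness compression), unit-normalised, and compared against
#' the sawtooth-harmonic kernel of every pitch candidate on a log2-spaced
#' candidate grid. The per-frame pitch strength of a candidate is the cosine
#' similarity between compressed spectrum and kernel; the reported F0 is the
#' strength-maximising candidate refined by parabolic interpolation on the
#' log-frequency grid, and the reported strength is that maximum.
#'
#' Each candidate is analysed with the two power-of-two window sizes that
#' bracket its optimal window of eight pitch periods, and the two strengths
#' are blended linearly in log window size. Frames are centred at
#' `t = i * hop` starting at 0; windows are zero-padded at the signal edges.
#' Frames with no signal energy in any window get `f0 = NA` and strength 0.
#' The estimate is invariant to positive rescaling of the input amplitude.
#'
#' @param audio An [audio_signal()].
#' @param f_min,f_max Pitch search range in Hz. `f_max` must stay below the
#'   Nyquist frequency. Defaults 75-500 Hz cover adult conversational speech
#'   of both sexes.
#' @param hop Frame hop in seconds (default 0.01 s).
#' @param candidate_step Candidate spacing in octaves (default 1/96).
#' @param erb_step Spectral grid spacing in ERB units (default 0.1).
#' @return A `pitch_track`: a tibble with columns `time` (s), `f0` (Hz, `NA`
#'   when missing) and `strength` (\[-1, 1\]), one row per hop, with the
#'   sampling `rate` and `hop` stored as attributes.
#' @examples
#' x <- audio_signal(sin(2 * pi * 200 * seq(0, 0.5, by = 1 / 8000)), 8000)
#' trk <- estimate_pitch(x, hop = 0.02)
#' dplyr::summarise(trk, f0 = stats::median(f0, na.rm = TRUE))
#' @export
estimate_pitch <- function(audio, f_min = 75, f_max = 500, hop = 0.01,
                           candidate_step = 1 / 96, erb_step = 0.1) {
  stopifnot(inherits(audio, "audio_signal"))
  x <- audio$samples
  fs <- audio$rate
  if (length(x) == 0) stop("audio is empty", call. = FALSE)
  if (!(f_min > 0 && f_min < f_max)) {
    stop("need 0 < f_min < f_max", call. = FALSE)
  }
  if (f_max >= fs / 2) {
    stop("`f_max` must be below the Nyquist frequency", call. = FALSE)
  }
  if (hop <= 0) stop("`hop` must be positive", call. = FALSE)
  dur <- length(x) / fs
  if (dur < 8 / f_min) {
    stop("audio shorter than one analysis window at `f_min`", call. = FALSE)
  }

  n_frames <- max(1L, as.integer(floor(dur / hop + 1e-9)))
  t_out <- (seq_len(n_frames) - 1L) * hop

  log2pc <- seq(log2(f_min), log2(f_max), by = candidate_step)
  pc <- 2^log2pc
  n_cand <- length(pc)

  # power-of-two window sizes bracketing 8 periods of every candidate
  log_ws <- round(log2(8 * fs / c(f_min, f_max)))
  ws_all <- 2^seq(log_ws[1], log_ws[2], by = -1)
  p_opt <- 8 * fs / ws_all
  d <- 1 + log2pc - log2(8 * fs / ws_all[1])

  f_erbs <- erb_to_hz(seq(hz_to_erb(min(pc) / 4), hz_to_erb(fs / 2), by = erb_step))
  S <- matrix(0, n_cand, n_frames)

  for (i in seq_along(ws_all)) {
    ws <- ws_all[i]
    # spectra are computed at (at least) the output frame rate so each
    # frame's strength reflects its own window, not an interpolated one
    dn <- max(1L, min(as.integer(round(4 * fs / p_opt[i])),
      as.integer(round(hop * fs))))
    sp <- stft_mag(x, fs, ws, dn)

    # loudness: sqrt of magnitude interpolated onto the ERB grid
    L <- apply(sp$mag, 2, function(col) {
      m <- stats::spline(sp$freq, col, xout = f_erbs, method = "natural")$y
      sqrt(pmax(0, m))
    })
    L <- matrix(L, nrow = length(f_erbs))
    nrm <- sqrt(colSums(L^2))
    live <- nrm > 0
    L[, live] <- sweep(L[, live, drop = FALSE], 2, nrm[live], "/")
    L[, !live] <- 0

    # candidates analysed at this window size, with blending weights
    if (length(ws_all) == 1L) {
      j <- seq_len(n_cand); mu <- rep(1, length(j))
    } else if (i == length(ws_all)) {
      j <- which(d - i > -1)
      mu <- rep(1, length(j))
      k <- which(d[j] - i < 0)
      mu[k] <- 1 - abs(d[j][k] - i)
    } else if (i == 1L) {
      j <- which(d - i < 1)
      mu <- rep(1, length(j))
      k <- which(d[j] - i > 0)
      mu[k] <- 1 - abs(d[j][k] - i)
    } else {
      j <- which(abs(d - i) < 1)
      mu <- 1 - abs(d[j] - i)
    }
    if (length(j) == 0L) next

    K <- t(vapply(pc[j], build_kernel, numeric(length(f_erbs)), freq_grid = f_erbs))
    Si <- K %*% L

    # linear interpolation of strengths from STFT frame centres to t_out
    pos <- findInterval(t_out, sp$centers_s, rightmost.closed = TRUE)
    pos <- pmin(pmax(pos, 1L), length(sp$centers_s) - 1L)
    w <- (t_out - sp$centers_s[pos]) / (sp$centers_s[pos + 1L] - sp$centers_s[pos])
    w <- pmin(pmax(w, 0), 1)
    Si_out <- Si[, pos, drop = FALSE] * rep(1 - w, each = length(j)) +
      Si[, pos + 1L, drop = FALSE] * rep(w, each = length(j))
    S[j, ] <- S[j, ] + mu * Si_out
  }

  # frames whose largest window sees only zeros carry no pitch information
  ws_max <- ws_all[1]
  csum <- cumsum(c(0, x^2))
  lo <- pmax(0L, as.integer(round(t_out * fs)) - ws_max %/% 2L)
  hi <- pmin(length(x), as.integer(round(t_out * fs)) + ws_max %/% 2L)
  frame_energy <- csum[hi + 1L] - csum[lo + 1L]
  dead <- frame_energy <= 0

  f0 <- rep(NA_real_, n_frames)
  strength <- numeric(n_frames)
  for (fr in which(!dead)) {
    l <- which.max(S[, fr])
    s_max <- S[l, fr]
    if (l > 1L && l < n_cand) {
      # parabolic refinement on the log2-spaced candidate grid
      s3 <- S[(l - 1L):(l + 1L), fr]
      denom <- s3[1] - 2 * s3[2] + s3[3]
      delta <- if (denom < 0) 0.5 * (s3[1] - s3[3]) / denom else 0
      delta <- min(max(delta, -0.5), 0.5)
      f0[fr] <- 2^(log2pc[l] + delta * candidate_step)
      s_max <- s3[2] - 0.25 * (s3[1] - s3[3]) * delta
    } else {
      f0[fr] <- pc[l]
    }
    strength[fr] <- min(max(s_max, -1), 1)
  }
  f0 <- pmin(pmax(f0, f_min), f_max)

  new_pitch_track(
    tibble::tibble(time = t_out, f0 = f0, strength = strength),
    rate = fs, hop = hop, f_min = f_min, f_max = f_max
  )
}

new_pitch_track <- function(tbl, rate, hop, f_min = NA_real_, f_max = NA_real_) {
  structure(
    tbl,
    rate = rate, hop = hop, f_min = f_min, f_max = f_max,
    class = c("pitch_track", class(tibble::tibble()))
  )
}

#' @export
print.pitch_track <- function(x, ...) {
  cat(sprintf(
    "# A pitch track: %d frames, hop %g s, rate %g Hz\n",
    nrow(x), attr(x, "hop"), attr(x, "rate")
  ))
  NextMethod()
}

track_hop <- function(track) {
  h <- attr(track, "hop")
  if (is.null(h)) h <- stats::median(diff(track$time))
  h
}

track_duration <- function(track) {
  nrow(track) * track_hop(track)
}
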