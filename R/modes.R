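#' SSFP configuration modes by discrete Fourier transform
#'
#' Extracts the three lowest-order SSFP configurations (F-1, F0, F1) from a
#' complex phase-cycle profile as the Fourier coefficients
#' `F_n = (1/N) * sum_j S_j * exp(-i * n * phi_j)` over the (uniformly spaced)
#' RF phase increments `phi_j`. The kernel sign is fixed so a pure
#' `exp(+i*phi_j)` profile maps onto `F_plus1`. Which physical pathway (echo
#' vs FID) lands on which signed mode depends on the RF phase-sign convention;
#' downstream relaxometry uses mode magnitudes only, which are unaffected.
#'
#' @param profile A `bssfp_profile` tibble (see [simulate_profile()]), or any
#'   data frame with columns `phase_increment` and `signal`.
#' @param orders Integer mode orders to return (default -1, 0, +1).
#' @return A one-row tibble with complex columns `F_minus1`, `F_0`, `F_plus1`
#'   (plus `F_<n>` for any further orders requested).
#' @export
#' @examples
#' prof <- simulate_profile(tissue_table(T1 = 1, T2 = 0.06), seq_params())
#' Mod(unlist(configuration_modes(prof)))
configuration_modes <- function(profile, orders = c(-1L, 0L, 1L)) {
  phi <- profile$phase_increment
  s <- profile$signal
  n <- length(phi)
  if (n < 3) abort("need at least 3 phase cycles to extract modes.")
  dphi <- diff(phi)
  if (max(abs(dphi - dphi[1])) > 1e-9)
    abort("phase increments must be uniformly spaced.")
  if (any(!is.finite(Re(s)) | !is.finite(Im(s))))
    abort("profile contains non-finite samples.")
  vals <- vapply(orders, function(m) sum(s * exp(-1i * m * phi)) / n, complex(1))
  nm <- ifelse(orders < 0, paste0("F_minus", -orders),
               ifelse(orders == 0, "F_0", paste0("F_plus", orders)))
  as_tibble(as.list(setNames(vals, nm)))
}

# Trigonometric (Fourier) interpolation of a real periodic sequence sampled at
# uniform angles phi_j = phi[1] + 2*pi*j/n onto a grid `upsample` times finer.
# The Nyquist term (even n) is kept as a pure cosine so the real samples are
# reproduced exactly.
fourier_upsample <- function(values, phi, upsample = 64L) {
  n <- length(values)
  m <- n * upsample
  X <- fft(values)                       # X_k, k = 0..n-1
  s <- (seq_len(m) - 1) * (2 * pi / m)   # angle relative to first sample
  half <- n %/% 2
  kmax <- if (n %% 2 == 0) half - 1 else half
  dense <- rep(Re(X[1]) / n, m)
  for (k in seq_len(kmax))
    dense <- dense + (2 / n) * Re(X[k + 1] * exp(1i * k * s))
  if (n %% 2 == 0)
    dense <- dense + (1 / n) * Re(X[half + 1] * exp(1i * half * s))
  list(grid = phi[1] + s, values = dense)
}

#' Profile asymmetry index
#'
#' Quantifies the asymmetry of the bSSFP frequency response as
#' `AI = (h_p - h_n) / (h_p + h_n)`, where `h_p` and `h_n` are the signal
#' peaks at positive and negative frequency offsets of the B0-corrected
#' magnitude profile. The 12-sample magnitude profile is trigonometrically
#' interpolated by `upsample` (Fourier interpolation of the periodic
#' response), then centred by circularly shifting the global magnitude
#' minimum (stopband) onto the edge of the phase-cycle axis; the two peaks
#' are the global maxima of each half-axis (ties broken towards the smaller
#' absolute frequency). The phase-cycle axis maps to frequency as
#' `f = phi / (2*pi*TR)` relative to the profile centre.
#'
#' @param profile A `bssfp_profile` tibble (columns `phase_increment`,
#'   `signal`).
#' @param upsample Fourier interpolation factor (default 64).
#' @return One-row tibble with columns `AI`, `h_p`, `h_n`, `b0_shift`
#'   (radians the profile was rotated for centring) and `flat` (TRUE when the
#'   profile was degenerate and AI was defined as 0).
#' @export
#' @examples
#' prof <- simulate_profile(tissue_table(T1 = 1, T2 = 0.06), seq_params())
#' asymmetry_index(prof)
asymmetry_index <- function(profile, upsample = 64L) {
  mag <- Mod(profile$signal)
  if (all(mag == 0)) abort("profile magnitude is identically zero.")
  up <- fourier_upsample(mag, profile$phase_increment, upsample)
  v <- up$values
  m <- length(v)
  rng <- max(v) - min(v)
  if (rng <= 1e-12 * max(v)) {
    warn("flat magnitude profile; AI defined as 0.")
    return(tibble(AI = 0, h_p = max(v), h_n = max(v), b0_shift = 0, flat = TRUE))
  }
  k_min <- which.min(v)
  # centre index: passband centre sits half a period from the stopband
  centre <- ((k_min - 1 + m %/% 2) %% m) + 1
  d <- ((seq_len(m) - centre + m %/% 2) %% m) - m %/% 2  # signed offset index
  pos <- d > 0
  neg <- d < 0
  pick <- function(sel) {
    vv <- v[sel]; dd <- abs(d[sel])
    top <- which(vv >= max(vv) - .Machine$double.eps * 4 * max(vv))
    vv[top[which.min(dd[top])]]
  }
  h_p <- pick(pos)
  h_n <- pick(neg)
  shift <- (up$grid[centre] - up$grid[1 + m %/% 2]) %% (2 * pi)
  tibble(AI = (h_p - h_n) / (h_p + h_n), h_p = h_p, h_n = h_n,
         b0_shift = shift, flat = FALSE)
}
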