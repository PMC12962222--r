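#' Fiber-to-field angle
#'
#' Angle between the principal diffusion direction V1 and the main field B0
#' (scanner z-axis), folded into 0-90 degrees:
#' `theta = acos(|V1 . z| / |V1|)`.
#'
#' @param v1x,v1y,v1z Components of the principal eigenvector (any norm > 0);
#'   vectorized.
#' @return Angle(s) in degrees in \[0, 90\].
#' @export
#' @examples
#' fiber_to_field_angle(0, 0, 1)            # 0
#' fiber_to_field_angle(1, 0, 1) / 45       # 1
fiber_to_field_angle <- function(v1x, v1y, v1z) {
  nrm <- sqrt(v1x^2 + v1y^2 + v1z^2)
  if (any(nrm == 0)) abort("zero-length orientation vector.")
  acos(pmin(1, abs(v1z) / nrm)) * 180 / pi
}

#' Diffusion-tensor scalar maps from eigenvalues
#'
#' Fractional anisotropy, axial diffusivity (AD = lambda1) and radial
#' diffusivity (RD = (lambda2 + lambda3)/2) from the sorted eigenvalues of
#' the diffusion tensor. `FA = sqrt(3/2) * sqrt(sum((l - lbar)^2)) /
#' sqrt(sum(l^2))`.
#'
#' @param l1,l2,l3 Eigenvalues, `l1 >= l2 >= l3 >= 0`, not all zero;
#'   vectorized.
#' @return A tibble with columns `FA`, `AD`, `RD`.
#' @export
#' @examples
#' fa_from_eigenvalues(1.7e-3, 0.3e-3, 0.3e-3)
fa_from_eigenvalues <- function(l1, l2, l3) {
  if (any(l1 + l2 + l3 == 0)) abort("all-zero diffusion tensor.")
  if (any(l1 < 0 | l2 < 0 | l3 < 0)) abort("eigenvalues must be non-negative.")
  lbar <- (l1 + l2 + l3) / 3
  fa <- sqrt(1.5) * sqrt((l1 - lbar)^2 + (l2 - lbar)^2 + (l3 - lbar)^2) /
    sqrt(l1^2 + l2^2 + l3^2)
  tibble(FA = fa, AD = l1, RD = (l2 + l3) / 2)
}

#' Offset angle between principal and apparent fiber direction
#'
#' `epsilon0 = arctan(RD / AD)` in degrees; the apparent-fiber offset used by
#' the epsilon-corrected generalized magic-angle-effect model.
#'
#' @param AD Axial diffusivity (> 0); vectorized.
#' @param RD Radial diffusivity.
#' @return Degrees in \[0, 45\] when `RD <= AD`.
#' @export
#' @examples
#' epsilon0_angle(1.7e-3, 0.3e-3)
epsilon0_angle <- function(AD, RD) {
  if (any(AD <= 0)) abort("AD must be positive.")
  atan(RD / AD) * 180 / pi
}

#' Orientation maps from a voxel table of tensors
#'
#' Convenience wrapper computing `FA`, `AD`, `RD`, `theta` and `epsilon0` from
#' eigenvalue and principal-eigenvector columns.
#'
#' @param data Data frame with columns `l1`, `l2`, `l3`, `v1x`, `v1y`, `v1z`.
#' @return `data` with the orientation columns appended.
#' @export
orientation_maps <- function(data) {
  fa <- fa_from_eigenvalues(data$l1, data$l2, data$l3)
  dplyr::bind_cols(
    as_tibble(data),
    fa,
    tibble(theta = fiber_to_field_angle(data$v1x, data$v1y, data$v1z),
           epsilon0 = epsilon0_angle(fa$AD, fa$RD))
  )
}

# the three binning strategies: FA edges x angle edges
binning_strategy <- function(strategy) {
  switch(as.character(strategy),
    "1" = list(fa = seq(0, 1, by = 0.2), ang = seq(0, 90, by = 7.5)),
    "2" = list(fa = c(0.5, 1.0), ang = seq(0, 90, by = 2.5)),
    "3" = list(fa = seq(0, 0.8, by = 0.05), ang = seq(15, 90, by = 5)),
    abort("`strategy` must be 1, 2 or 3.")
  )
}

# half-open [lo, hi) bins, final bin closed; values within 1e-9 of an edge are
# snapped to it so ties go to the upper bin regardless of how the edge grid
# was computed in floating point
bin_index <- function(x, edges) {
  for (e in edges) x[abs(x - e) < 1e-9] <- e
  i <- findInterval(x, edges, rightmost.closed = TRUE)
  i[x < edges[1] | x > edges[length(edges)]] <- NA_integer_
  i
}

#' Bin a quantitative parameter over (FA, angle) cells
#'
#' Implements the three white-matter binning strategies: (1) FA 0-1 in 0.2
#' steps crossed with theta 0-90 in 7.5 degree steps; (2) a single high-FA
#' stratum (0.5-1.0) with fine 2.5 degree theta sampling; (3) FA 0-0.8 in
#' 0.05 steps crossed with angle 15-90 in 5 degree steps. Bins are half-open
#' `[lo, hi)` with the final bin closed. With `angle = "epsilon"` the voxel
#' offset angle is subtracted first (`epsilon = theta - epsilon0`, clamped to
#' \[0, 90\]) and binning runs over epsilon.
#'
#' @param data Voxel table with columns `FA`, `theta` (and `epsilon0` when
#'   `angle = "epsilon"`) plus the parameter column.
#' @param value Name of the parameter column (string or bare name).
#' @param strategy Binning strategy 1, 2 or 3.
#' @param angle `"theta"` or `"epsilon"`.
#' @return A `binned_curve` tibble: `fa_lo`, `fa_hi`, `ang_lo`, `ang_hi`,
#'   `angle_mid`, `mean`, `sd`, `n`.
#' @export
#' @examples
#' vox <- tibble::tibble(FA = runif(500, 0.5, 1), theta = runif(500, 0, 90))
#' vox$R2 <- 20 + 3 * sin(vox$theta * pi / 180)^4
#' bin_parameter(vox, "R2", strategy = 2)
bin_parameter <- function(data, value, strategy = 2,
                          angle = c("theta", "epsilon")) {
  angle <- match.arg(angle)
  value <- rlang::as_name(rlang::ensym(value))
  if (nrow(data) == 0) abort("empty voxel table.")
  br <- binning_strategy(strategy)
  ang_val <- if (angle == "epsilon") {
    pmin(90, pmax(0, data$theta - data$epsilon0))
  } else data$theta
  fa_i <- bin_index(data$FA, br$fa)
  an_i <- bin_index(ang_val, br$ang)
  ok <- !is.na(fa_i) & !is.na(an_i) & is.finite(data[[value]])
  grid <- tidyr::expand_grid(fa_bin = seq_len(length(br$fa) - 1L),
                             ang_bin = seq_len(length(br$ang) - 1L))
  binned <- tibble(fa_bin = fa_i[ok], ang_bin = an_i[ok],
                   v = data[[value]][ok]) |>
    dplyr::group_by(.data$fa_bin, .data$ang_bin) |>
    dplyr::summarise(mean = mean(.data$v), sd = sd(.data$v),
                     n = dplyr::n(), .groups = "drop")
  out <- grid |>
    dplyr::left_join(binned, by = c("fa_bin", "ang_bin")) |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      fa_lo = br$fa[.data$fa_bin], fa_hi = br$fa[.data$fa_bin + 1L],
      ang_lo = br$ang[.data$ang_bin], ang_hi = br$ang[.data$ang_bin + 1L],
      angle_mid = (.data$ang_lo + .data$ang_hi) / 2
    ) |>
    dplyr::select("fa_lo", "fa_hi", "ang_lo", "ang_hi", "angle_mid",
                  "mean", "sd", "n")
  attr(out, "value") <- value
  attr(out, "angle") <- angle
  class(out) <- c("binned_curve", class(out))
  out
}

#' Orientation anisotropy of a binned curve
#'
#' For relaxation rates: `100 * (max - min) / (max + min)` over the bin means;
#' for the inherently normalized asymmetry index: `100 * (max - min)`. The
#' same formulas applied to a field-strength difference curve give the
#' difference-map anisotropy. Empty bins are excluded.
#'
#' @param curve A `binned_curve` (or any data frame with `mean` and `n`
#'   columns; rows should span the angle bins of a single FA stratum).
#' @param kind `"rate"` or `"ai"`.
#' @return Anisotropy in percent.
#' @export
#' @examples
#' anisotropy_percent(tibble::tibble(mean = c(22, 18), n = c(5, 5)))
anisotropy_percent <- function(curve, kind = c("rate", "ai")) {
  kind <- match.arg(kind)
  m <- curve$mean[curve$n > 0 & is.finite(curve$mean)]
  if (length(m) < 2) abort("need at least two non-empty bins.")
  if (kind == "rate") 100 * (max(m) - min(m)) / (max(m) + min(m))
  else 100 * (max(m) - min(m))
}
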