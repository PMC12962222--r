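# Label codes for the hollow-cylinder axon substrate.
LBL_EXTRA <- 0L
LBL_INTRA <- 1L
LBL_MYELIN <- 2L

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Truncated gamma sampler parameterized by mean/variance (shape = mean^2/var,
# scale = var/mean), rejection on the stated range.
sample_radii <- function(n, mean, var, range) {
  shape <- mean^2 / var
  scale <- var / mean
  out <- numeric(0)
  while (length(out) < n) {
    r <- rgamma(2L * n, shape = shape, scale = scale)
    out <- c(out, r[r >= range[1] & r <= range[2]])
  }
  out[seq_len(n)]
}

# minimum-image displacement on a periodic square domain
periodic_diff <- function(d, L) d - L * round(d / L)

#' Pack a hollow-cylinder axon substrate
#'
#' Generates a two-dimensional white-matter substrate: axons are parallel
#' hollow cylinders (intra-axonal core, myelin annulus) packed into a periodic
#' square domain, with gamma-distributed radii (defaults: mean 0.7 um,
#' variance 0.25 um^2, truncated to 0.25-5 um) and g-ratios (inner/outer
#' radius) uniform in 0.6-0.7. Placement is random sequential insertion
#' followed by repulsive relaxation of overlapping pairs; after packing, a
#' uniformly random `dropout` fraction of axons is removed whole (myelin and
#' core revert to extra-axonal space), emulating the AM100/AM75/AM50 packing
#' variants at dropout 0/0.25/0.5.
#'
#' The packing density is controlled by `target_area_fraction`: axons are
#' sampled in surplus and uniformly random ones removed until the total
#' outer-disk area fits the budget, which keeps the realized density (and
#' hence the myelin volume fraction, about 0.39 at zero dropout) stable
#' against the heavy tail of the radius distribution; see the methods
#' vignette for the geometric budget behind these defaults.
#'
#' @param n_axons Number of axons sampled before the area cap.
#' @param target_area_fraction Outer-disk area budget as a fraction of the
#'   domain area.
#' @param radius_mean,radius_var,radius_range Gamma radius distribution
#'   parameters (um, um^2, um).
#' @param g_range Uniform g-ratio range.
#' @param domain Side length of the square domain in um.
#' @param dropout Fraction of packed axons removed after packing.
#' @param px Grid resolution in um/pixel (default 0.05).
#' @param delta_chi Myelin susceptibility shift in ppm relative to
#'   intra-/extra-axonal water (default -0.1).
#' @param tissues Compartment table (rows ordered extra-axonal, intra-axonal,
#'   myelin) attached to the substrate; default [wm_compartments()] at 3T.
#' @param seed Optional integer seed; identical seeds give identical grids.
#' @param max_relax Maximum relaxation sweeps.
#' @return An `axon_substrate` object: list with `labels` (integer matrix),
#'   `axons` (tibble: x, y, radius_outer, radius_inner, g_ratio), `px`,
#'   `domain`, `delta_chi`, `tissues`, `dropout`.
#' @export
#' @examples
#' sub <- pack_axons(n_axons = 25, domain = 15, seed = 1)
#' volume_and_water_fractions(sub)
pack_axons <- function(n_axons = 220, radius_mean = 0.7, radius_var = 0.25,
                       radius_range = c(0.25, 5), g_range = c(0.6, 0.7),
                       domain = 43, dropout = 0, px = 0.05,
                       target_area_fraction = 0.68,
                       delta_chi = -0.1, tissues = wm_compartments("3T"),
                       seed = NULL, max_relax = 4000L) {
  with_seed(seed, {
    r_in <- sample_radii(n_axons, radius_mean, radius_var, radius_range)
    g <- runif(n_axons, g_range[1], g_range[2])
    r_out <- r_in / g
    # enforce the area budget by removing uniformly random axons (keeps the
    # per-axon radius distribution intact, stabilizes the realized density)
    budget <- target_area_fraction * domain^2
    while (sum(pi * r_out^2) > budget && length(r_out) > 1) {
      k <- sample.int(length(r_out), 1)
      r_in <- r_in[-k]; g <- g[-k]; r_out <- r_out[-k]
    }
    n_axons <- length(r_out)
    if (sum(pi * r_out^2) > 0.85 * domain^2)
      abort("requested axons exceed the achievable packing density for this domain.")
    ord <- order(r_out, decreasing = TRUE)
    r_in <- r_in[ord]; g <- g[ord]; r_out <- r_out[ord]

    # random sequential insertion at reduced radii, then grow the disks back
    # to full size under repulsive relaxation (overdamped; periodic domain)
    s0 <- min(1, sqrt(0.45 * domain^2 / sum(pi * r_out^2)))
    xs <- ys <- rep(NA_real_, n_axons)
    for (i in seq_len(n_axons)) {
      placed <- FALSE
      for (try in seq_len(400L)) {
        x <- runif(1, 0, domain); y <- runif(1, 0, domain)
        j <- which(!is.na(xs))
        if (length(j) == 0 ||
            all(periodic_diff(xs[j] - x, domain)^2 +
                periodic_diff(ys[j] - y, domain)^2 >=
                (s0 * (r_out[j] + r_out[i]))^2)) {
          xs[i] <- x; ys[i] <- y; placed <- TRUE; break
        }
      }
      if (!placed) { xs[i] <- runif(1, 0, domain); ys[i] <- runif(1, 0, domain) }
    }

    relax <- function(scale, sweeps) {
      need <- outer(r_out, r_out, "+") * scale
      for (sweep in seq_len(sweeps)) {
        dx <- periodic_diff(outer(xs, xs, "-"), domain)
        dy <- periodic_diff(outer(ys, ys, "-"), domain)
        dist <- sqrt(dx^2 + dy^2)
        diag(dist) <- Inf
        ov <- which(dist < need - 1e-12, arr.ind = TRUE)
        ov <- ov[ov[, 1] < ov[, 2], , drop = FALSE]
        if (nrow(ov) == 0) return(TRUE)
        i <- ov[, 1]; j <- ov[, 2]
        d <- dist[cbind(i, j)]
        gap <- need[cbind(i, j)] - d
        deg <- d < 1e-9                   # coincident centres: random direction
        ang <- runif(sum(deg), 0, 2 * pi)
        ux <- ifelse(deg, 0, dx[cbind(i, j)] / pmax(d, 1e-9))
        uy <- ifelse(deg, 0, dy[cbind(i, j)] / pmax(d, 1e-9))
        ux[deg] <- cos(ang); uy[deg] <- sin(ang)
        fx <- 0.3 * gap * ux; fy <- 0.3 * gap * uy
        idx <- c(i, j)
        px_push <- rowsum(c(fx, -fx), idx)
        py_push <- rowsum(c(fy, -fy), idx)
        who <- as.integer(rownames(px_push))
        xs[who] <<- (xs[who] + px_push[, 1]) %% domain
        ys[who] <<- (ys[who] + py_push[, 1]) %% domain
      }
      FALSE
    }

    relax(s0, 200L)
    for (s in seq(s0, 1, length.out = 80L)[-1]) relax(s, 150L)
    relax(1, max_relax)

    # drop axons that could not be separated
    dx <- periodic_diff(outer(xs, xs, "-"), domain)
    dy <- periodic_diff(outer(ys, ys, "-"), domain)
    dist <- sqrt(dx^2 + dy^2); diag(dist) <- Inf
    bad <- rep(FALSE, n_axons)
    repeat {
      ov <- which(dist < outer(r_out, r_out, "+") - 1e-9 &
                    !outer(bad, bad, "|"), arr.ind = TRUE)
      if (nrow(ov) == 0) break
      worst <- table(c(ov[, 1], ov[, 2]))
      bad[as.integer(names(worst)[which.max(worst)])] <- TRUE
    }
    keep <- !bad
    if (sum(keep) < 0.9 * n_axons)
      abort(sprintf("only %d of %d axons could be placed; reduce n_axons or enlarge the domain.",
                    sum(keep), n_axons))
    ax <- tibble(x = xs[keep], y = ys[keep],
                 radius_outer = r_out[keep], radius_inner = r_in[keep],
                 g_ratio = g[keep])

    if (dropout > 0) {
      n_drop <- round(dropout * nrow(ax))
      ax <- ax[-sample.int(nrow(ax), n_drop), , drop = FALSE]
    }

    labels <- rasterize_axons(ax, domain, px)
    structure(
      list(labels = labels, axons = ax, px = px, domain = domain,
           delta_chi = delta_chi, tissues = tissues, dropout = dropout),
      class = "axon_substrate"
    )
  })
}

# paint inner/outer disks onto the periodic pixel grid
rasterize_axons <- function(axons, domain, px) {
  n <- as.integer(round(domain / px))
  labels <- matrix(LBL_EXTRA, n, n)
  cx <- (seq_len(n) - 0.5) * px
  for (k in seq_len(nrow(axons))) {
    r <- axons$radius_outer[k]
    ix <- which(abs(periodic_diff(cx - axons$x[k], domain)) <= r + px)
    iy <- which(abs(periodic_diff(cx - axons$y[k], domain)) <= r + px)
    if (!length(ix) || !length(iy)) next
    ddx <- periodic_diff(cx[ix] - axons$x[k], domain)
    ddy <- periodic_diff(cx[iy] - axons$y[k], domain)
    d2 <- outer(ddx^2, ddy^2, "+")
    sub <- labels[ix, iy, drop = FALSE]
    sub[d2 <= r^2] <- LBL_MYELIN
    sub[d2 <= axons$radius_inner[k]^2] <- LBL_INTRA
    labels[ix, iy] <- sub
  }
  labels
}

#' Build a substrate from an explicit label grid
#'
#' Escape hatch for custom geometries (e.g., a single solid cylinder for
#' validation): wraps a label matrix (0 = extra-axonal, 1 = intra-axonal,
#' 2 = myelin) in an `axon_substrate` object usable by [field_map()] and the
#' Monte Carlo engine.
#'
#' @param labels Integer matrix of compartment labels.
#' @param px Pixel size in um.
#' @param delta_chi Myelin susceptibility shift in ppm.
#' @param tissues Compartment table.
#' @return An `axon_substrate`.
#' @export
substrate_from_labels <- function(labels, px = 0.05, delta_chi = -0.1,
                                  tissues = wm_compartments("3T")) {
  stopifnot(is.matrix(labels), nrow(labels) == ncol(labels))
  structure(
    list(labels = labels, axons = tibble(), px = px,
         domain = nrow(labels) * px, delta_chi = delta_chi,
         tissues = tissues, dropout = 0),
    class = "axon_substrate"
  )
}

#' @export
print.axon_substrate <- function(x, ...) {
  vf <- volume_and_water_fractions(x)
  cat(sprintf("axon substrate: %d axons, %.3g x %.3g um^2 at %.3g um/px, MVF %.1f%%, dropout %.0f%%\n",
              nrow(x$axons), x$domain, x$domain, x$px, 100 * vf$MVF,
              100 * x$dropout))
  invisible(x)
}

#' Myelin volume and water fractions
#'
#' `volume_and_water_fractions()` measures the myelin volume fraction (MVF) as
#' the myelin pixel fraction of the substrate grid and converts it to a myelin
#' water fraction (MWF) given the effective myelin proton density.
#' `myelin_water_fraction()` is the bare arithmetic
#' `MWF = pd * MVF / (pd * MVF + (1 - MVF))`.
#'
#' @param substrate An `axon_substrate`.
#' @param myelin_pd Effective myelin proton density relative to the water
#'   compartments, in (0, 1] (default one half).
#' @param mvf Myelin volume fraction (for the bare arithmetic form).
#' @return One-row tibble with `MVF`, `MWF` (and intra-/extra-axonal volume
#'   fractions), or a numeric MWF for `myelin_water_fraction()`.
#' @export
#' @examples
#' myelin_water_fraction(0.303, 0.5)  # 0.179
volume_and_water_fractions <- function(substrate, myelin_pd = 0.5) {
  if (myelin_pd <= 0 || myelin_pd > 1) abort("`myelin_pd` must be in (0, 1].")
  n <- length(substrate$labels)
  mvf <- sum(substrate$labels == LBL_MYELIN) / n
  tibble(MVF = mvf,
         IVF = sum(substrate$labels == LBL_INTRA) / n,
         EVF = sum(substrate$labels == LBL_EXTRA) / n,
         MWF = myelin_water_fraction(mvf, myelin_pd))
}

#' @rdname volume_and_water_fractions
#' @export
myelin_water_fraction <- function(mvf, myelin_pd = 0.5) {
  myelin_pd * mvf / (myelin_pd * mvf + (1 - mvf))
}
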