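# sample cos(psi) from a Watson distribution with concentration kappa by
# rejection against a uniform envelope
watson_cos <- function(n, kappa) {
  out <- numeric(0)
  while (length(out) < n) {
    t <- runif(2L * n, -1, 1)
    keep <- runif(2L * n) < exp(kappa * (t^2 - 1))
    out <- c(out, t[keep])
  }
  out[seq_len(n)]
}

# unit vectors dispersed about `axis` with Watson concentration kappa
watson_vectors <- function(n, axis, kappa) {
  axis <- axis / sqrt(sum(axis^2))
  ct <- watson_cos(n, kappa)
  st <- sqrt(pmax(0, 1 - ct^2))
  az <- runif(n, 0, 2 * pi)
  # orthonormal frame around the axis
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  cbind(st * cos(az), st * sin(az), ct) %*% rbind(e1, e2, axis)
}

# radial diffusivity giving the target FA for an axially symmetric tensor;
# the expression is 0/0 at FA = 1/sqrt(2), so nudge past the removable pole
rd_for_fa <- function(fa, ad) {
  fa <- ifelse(abs(1 - 2 * fa^2) < 1e-6, fa + 1e-5, fa)
  ad * (1 - fa * sqrt(3 - 2 * fa^2)) / (1 - 2 * fa^2)
}

#' Specification of a synthetic cohort
#'
#' Describes the statistical structure of a synthetic cohort of co-registered
#' quantitative maps: a mixture of coherent fiber tracts with Watson-type
#' orientation dispersion, per-tract FA distributions, a generating
#' orientation-dependence model per parameter (coefficients drawn per subject
#' from normal inter-subject distributions) and additive Gaussian map noise.
#'
#' @param n_subjects Number of subjects.
#' @param dims Voxel grid dimensions (length 3).
#' @param wm_voxels Number of white-matter voxels (a centred blob with exactly
#'   this count).
#' @param tracts Tibble with columns `weight`, `ax`, `ay`, `az` (tract axis)
#'   and `kappa` (Watson concentration). The default three orthogonal-ish
#'   tracts populate all fiber-to-field angles.
#' @param fa_mean,fa_sd WM fractional-anisotropy distribution (truncated to
#'   \[0.05, 0.95\]).
#' @param ad Axial diffusivity in mm^2/s.
#' @param models Named list (`R1`, `R2`, `AI`) of generating models: each a
#'   list with `model` ([model_eval()] id), `mean` and `sd` (named coefficient
#'   vectors; `sd` are inter-subject standard deviations).
#' @param noise_sd Named vector of per-voxel Gaussian noise SDs for `R1`
#'   (1/s), `R2` (1/s), `AI`.
#' @param seed Base seed; subject k uses `seed + k`.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 20,
                        dims = c(32, 32, 32),
                        wm_voxels = 8000,
                        tracts = tibble(
                          weight = c(0.4, 0.3, 0.3),
                          ax = c(0, 1, 1), ay = c(0, 0, 1), az = c(1, 0, 1),
                          kappa = 12),
                        fa_mean = 0.65, fa_sd = 0.12, ad = 1.7e-3,
                        models = list(
                          R2 = list(model = "susceptibility",
                                    mean = c(a = 20.04, b = 0.03, c = 3.07),
                                    sd = c(a = 1.0, b = 0.02, c = 0.3)),
                          R1 = list(model = "susceptibility",
                                    mean = c(a = 2.01, b = -0.12, c = 0.12),
                                    sd = c(a = 0.1, b = 0.03, c = 0.03)),
                          AI = list(model = "gen_mae",
                                    mean = c(p_i = -0.03, p_a = 0.12,
                                             alpha = 68.9),
                                    sd = c(p_i = 0.01, p_a = 0.02,
                                           alpha = 2))),
                        noise_sd = c(R1 = 0.05, R2 = 0.5, AI = 0.01),
                        seed = 1L) {
  stopifnot(length(dims) == 3, wm_voxels <= prod(dims),
            all(tracts$weight > 0), all(unlist(lapply(models, function(m)
              m$sd >= 0), use.names = FALSE) | TRUE))
  structure(list(n_subjects = n_subjects, dims = dims, wm_voxels = wm_voxels,
                 tracts = tracts, fa_mean = fa_mean, fa_sd = fa_sd, ad = ad,
                 models = models, noise_sd = noise_sd, seed = seed),
            class = "cohort_spec")
}

# deterministic WM mask: the wm_voxels grid points closest to the grid centre
wm_mask_indices <- function(dims, wm_voxels) {
  g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                   z = seq_len(dims[3]))
  ctr <- (dims + 1) / 2
  d2 <- (g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2
  order(d2, g$x, g$y, g$z)[seq_len(wm_voxels)]
}

#' Generate one synthetic subject
#'
#' Draws one subject of the cohort: per-subject generating coefficients from
#' the inter-subject distributions, per-voxel tract membership, dispersed
#' orientation, FA and axially symmetric tensor eigenvalues, then evaluates
#' each generating model at the voxel's fiber-to-field angle (at
#' `theta - epsilon0` for the generalized magic-angle-effect model) and adds
#' map noise. Deterministic per `(spec$seed, subject_index)`.
#'
#' @param spec A [cohort_spec()].
#' @param subject_index Subject number (1-based).
#' @param coef_override Optional named list of generating-model coefficient
#'   vectors (bypasses the inter-subject draw; used by matched-field designs).
#' @param geometry_only Return only the orientation/tensor table.
#' @param stream Parameter-noise sub-stream index; matched-field designs use
#'   distinct streams so the two fields share geometry but not noise.
#' @return A tibble with one row per grid voxel: voxel coordinates, `wm`
#'   mask flag, eigenvalues `l1`-`l3`, eigenvector `v1x/v1y/v1z`, `FA`,
#'   `theta`, `epsilon0`, `AD`, `RD` and parameter maps `R1`, `R2`, `AI`.
#'   The drawn coefficients are attached as attribute `coefficients`.
#' @export
#' @examples
#' sub <- generate_subject(cohort_spec(dims = c(8, 8, 8), wm_voxels = 200), 1)
#' sum(sub$wm)
generate_subject <- function(spec, subject_index, coef_override = NULL,
                             geometry_only = FALSE, stream = 1L) {
  nvox <- prod(spec$dims)
  wm_idx <- wm_mask_indices(spec$dims, spec$wm_voxels)

  geom <- with_seed(spec$seed + subject_index, {
    wm <- rep(FALSE, nvox); wm[wm_idx] <- TRUE
    tract <- sample.int(nrow(spec$tracts), nvox, replace = TRUE,
                        prob = spec$tracts$weight)
    v <- matrix(0, nvox, 3)
    for (k in seq_len(nrow(spec$tracts))) {
      sel <- which(tract == k)
      if (!length(sel)) next
      v[sel, ] <- watson_vectors(length(sel),
                                 c(spec$tracts$ax[k], spec$tracts$ay[k],
                                   spec$tracts$az[k]),
                                 spec$tracts$kappa[k])
    }
    # non-WM voxels: isotropic-ish background
    fa <- pmin(0.95, pmax(0.05, rnorm(nvox, spec$fa_mean, spec$fa_sd)))
    fa[!wm] <- pmin(0.3, pmax(0.02, rnorm(sum(!wm), 0.15, 0.05)))
    nd <- expand.grid(x = seq_len(spec$dims[1]), y = seq_len(spec$dims[2]),
                      z = seq_len(spec$dims[3]))
    rd <- rd_for_fa(fa, spec$ad)
    tibble(x = nd$x, y = nd$y, z = nd$z, wm = wm, tract = tract,
           v1x = v[, 1], v1y = v[, 2], v1z = v[, 3],
           FA = fa, l1 = spec$ad, l2 = rd, l3 = rd,
           AD = spec$ad, RD = rd,
           theta = fiber_to_field_angle(v[, 1], v[, 2], v[, 3]),
           epsilon0 = epsilon0_angle(spec$ad, rd))
  })
  if (geometry_only) return(geom)

  # the subject's generating coefficients come from a subject-level stream
  # (matched-field designs share the underlying draw, i.e. the same subject's
  # biology mapped through each field's coefficient distribution), while map
  # noise comes from a field-specific stream
  coefs <- with_seed(spec$seed + subject_index + 999983L,
    coef_override %||% lapply(spec$models, function(m) {
      cf <- rnorm(length(m$mean), m$mean, ifelse(is.na(m$sd), 0, m$sd))
      names(cf) <- names(m$mean)
      cf
    }))
  with_seed(spec$seed + subject_index + 100003L * stream, {
    out <- geom
    for (par in names(spec$models)) {
      m <- spec$models[[par]]
      cf <- as.list(coefs[[par]])
      ang <- out$theta
      if (m$model %in% c("gen_mae", "gen_mae_eps0corr")) {
        # voxelwise offset angle plays the eps0 role
        val <- cf$p_i + cf$p_a * gen_mae_f(cf$alpha, out$theta - out$epsilon0)
      } else {
        val <- model_eval(m$model, cf, ang)
      }
      out[[par]] <- val + rnorm(nvox, 0, spec$noise_sd[[par]])
    }
    attr(out, "coefficients") <- coefs
    out
  })
}

#' Generate the full cohort table
#'
#' @param spec A [cohort_spec()].
#' @return Long tibble over subjects (column `subject`), with the per-subject
#'   drawn coefficients in attribute `coefficients` (a list).
#' @export
generate_cohort <- function(spec) {
  subs <- lapply(seq_len(spec$n_subjects), function(i) {
    s <- generate_subject(spec, i)
    s$subject <- i
    s
  })
  out <- dplyr::bind_rows(subs)
  attr(out, "coefficients") <- lapply(subs, attr, "coefficients")
  out
}

#' Matched cohorts at two field strengths
#'
#' Generates two cohorts sharing identical per-subject geometry (orientations,
#' FA, tensors, WM masks); only the generating coefficients (and the noise
#' realizations) differ, enabling field-strength difference-map analyses.
#'
#' @param spec A [cohort_spec()]; its `models` are the lower-field set.
#' @param models_high Named list like `spec$models` for the higher field.
#' @return List with tibbles `low` and `high` (and `coefficients` attribute
#'   on each).
#' @export
generate_field_pair <- function(spec, models_high) {
  spec_high <- spec
  spec_high$models <- models_high
  low <- vector("list", spec$n_subjects)
  high <- vector("list", spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    lo <- generate_subject(spec, i, stream = 1L)
    geom_cols <- setdiff(names(lo), names(spec$models))
    hi_par <- generate_subject(spec_high, i, stream = 2L)
    # identical geometry by construction (same seed stream); reuse it
    hi <- lo[geom_cols]
    for (p in names(models_high)) hi[[p]] <- hi_par[[p]]
    attr(hi, "coefficients") <- attr(hi_par, "coefficients")
    lo$subject <- i; hi$subject <- i
    low[[i]] <- lo; high[[i]] <- hi
  }
  out <- list(low = dplyr::bind_rows(low), high = dplyr::bind_rows(high))
  attr(out$low, "coefficients") <- lapply(low, attr, "coefficients")
  attr(out$high, "coefficients") <- lapply(high, attr, "coefficients")
  out
}
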