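# Synthetic reflection intensities and per-image observations for an
# orthorhombic cell, feeding the merging-statistics stage with known
# ground truth.

#' Wilson-distributed model intensities
#'
#' One intensity per symmetry-unique reflection: a Wilson fall-off
#' `scale * exp(-2 B s^2)` (s = 1/(2d)) times a unit-mean exponential
#' modulation per reflection (acentric Wilson statistics).
#'
#' @param cell cell edges `c(a, b, c)`, Angstrom (default the orthorhombic
#'   cell 55.7, 158.1, 67.7).
#' @param space_group "P212121" (default) or "P222".
#' @param d_min high-resolution limit, Angstrom.
#' @param b_factor Wilson B, Angstrom^2.
#' @param scale overall scale.
#' @param modulate multiply by exponential random structure-factor
#'   modulation (TRUE) or keep the smooth Wilson envelope (FALSE).
#' @param seed RNG seed.
#' @return data frame h, k, l, d, I with cell/space-group attributes.
#' @export
wilson_intensities <- function(cell = c(55.7, 158.1, 67.7),
                               space_group = "P212121", d_min = 2.5,
                               b_factor = 47.4, scale = 1e4,
                               modulate = TRUE, seed = 1) {
  refl <- unique_reflections(cell, space_group, d_min = d_min)
  s2 <- (1 / (2 * refl$d))^2
  env <- scale * exp(-2 * b_factor * s2)
  refl$I <- if (modulate)
    with_seed(seed, env * stats::rexp(nrow(refl), 1)) else env
  attr(refl, "cell") <- cell[1:3]
  attr(refl, "space_group") <- space_group
  refl
}

#' Generate per-image reflection observations
#'
#' Each image observes a random subset of the model reflections with a
#' multiplicative per-image scale (log-normal, SD `scale_sd` on the log
#' scale) and additive Gaussian noise with SD
#' `noise_sd * sqrt(max(I, 1))`; the recorded sigma estimate equals that
#' noise SD.
#'
#' @param model_intensities data frame from [wilson_intensities()] (columns
#'   h, k, l, I; positive intensities).
#' @param n_images number of images (>= 2; a half-set split is impossible
#'   otherwise).
#' @param scale_sd per-image log-normal scale SD (0 = all scales 1).
#' @param noise_sd relative noise level (0 = noise-free).
#' @param obs_fraction probability that an image observes a given
#'   reflection.
#' @param seed RNG seed.
#' @return a [reflection_obs()] object.
#' @export
generate_reflection_observations <- function(model_intensities, n_images,
                                             scale_sd = 0.1,
                                             noise_sd = 0.1,
                                             obs_fraction = 0.3,
                                             seed = 1) {
  mi <- model_intensities
  stopifnot(all(c("h", "k", "l", "I") %in% names(mi)))
  if (any(mi$I <= 0)) stop("model intensities must be positive",
                           call. = FALSE)
  if (n_images < 2) stop("n_images must be >= 2 (half-set split impossible)",
                         call. = FALSE)
  check_fraction(obs_fraction, "obs_fraction")
  n_refl <- nrow(mi)
  with_seed(seed, {
    hit <- which(stats::runif(n_refl * n_images) < obs_fraction)
    image_id <- (hit - 1L) %/% n_refl + 1L
    refl <- (hit - 1L) %% n_refl + 1L
    scales <- if (scale_sd > 0) stats::rlnorm(n_images, 0, scale_sd) else
      rep(1, n_images)
    I_true <- mi$I[refl] * scales[image_id]
    sig <- noise_sd * sqrt(pmax(mi$I[refl], 1))
    I_obs <- I_true + if (noise_sd > 0)
      stats::rnorm(length(I_true), 0, sig) else 0
    df <- data.frame(h = mi$h[refl], k = mi$k[refl], l = mi$l[refl],
                     I = I_obs, sigma = pmax(sig, 1e-12),
                     image_id = image_id)
    reflection_obs(df,
                   cell = attr(mi, "cell") %||% c(55.7, 158.1, 67.7),
                   space_group = attr(mi, "space_group") %||% "P212121")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
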