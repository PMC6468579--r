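#' Generate two cofractionation profiles with a target correlation
#'
#' Builds two densitometry profiles across gradient fractions whose
#' population Pearson correlation equals `target_r`, by mixing a shared
#' latent compartment profile `z ~ N(0, 1)` with marker-specific noise:
#' `x_m = a z + e_m`, `e_m ~ N(0, noise_sd)` independently per marker,
#' with the mixing weight solving the correlation identity
#' `a^2 / (a^2 + noise_sd^2) = |target_r|`, i.e.
#' `a = noise_sd sqrt(|target_r| / (1 - |target_r|))`.
#' A negative `target_r` flips the sign of `a` in the second profile. The
#' latent scores are mapped affinely to positive band intensities, which
#' leaves the correlation untouched.
#'
#' @param params a [fraction_profile_params()] object.
#' @param markers character vector of two marker labels.
#' @return data.frame in long format: `marker`, `fraction_index`,
#'   `intensity` (2 x `n_fractions` rows).
#' @export
generate_fraction_profiles <- function(params,
                                       markers = c("target", "reference")) {
  stopifnot(inherits(params, "fraction_profile_params"))
  if (length(markers) != 2L) stop("exactly two marker labels are required")
  r <- params$target_r; s <- params$noise_sd; n <- params$n_fractions
  with_seed(params$seed, offset = 707L, {
    z <- rnorm(n)
    if (abs(r) == 1) {
      x1 <- z
      x2 <- sign(r) * z
    } else {
      a <- s * sqrt(abs(r) / (1 - abs(r)))   # 0 when r = 0: independent
      x1 <- a * z + rnorm(n, 0, s)
      x2 <- (if (r < 0) -a else a) * z + rnorm(n, 0, s)
    }
    scale_to_band <- function(x) 100 + 25 * x
    data.frame(marker = rep(markers, each = n),
               fraction_index = rep(seq_len(n), 2L),
               intensity = c(scale_to_band(x1), scale_to_band(x2)))
  })
}

#' Spread a long fraction-profile table into per-marker vectors
#'
#' @param profiles data.frame with `marker`, `fraction_index`, `intensity`
#'   (as written by [generate_fraction_profiles()] or read from CSV).
#' @return Named list of numeric vectors, ordered by `fraction_index`.
#' @export
profile_vectors <- function(profiles) {
  req <- c("marker", "fraction_index", "intensity")
  if (!is.data.frame(profiles) || !all(req %in% names(profiles)))
    stop("`profiles` needs columns marker, fraction_index, intensity")
  lapply(split(profiles, profiles$marker), function(p) {
    p$intensity[order(p$fraction_index)]
  })
}
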