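#' Parameters for one synthetic cell
#'
#' Bundles every knob of the synthetic live-cell generator: image geometry,
#' organelle content, punctum seeding and motion, optics and noise. Defaults
#' emulate confocal time-lapse imaging of a cultured cell expressing a
#' punctate marker together with labeled ER and mitochondria: 80 nm pixels
#' (typical sampling with a 63x/1.4 NA objective), a dense tubular ER whose
#' 100 nm neighbourhood covers roughly half of the cytoplasm, and puncta
#' seeded ER-associated with probability `p_assoc`.
#'
#' @param image_shape integer (rows, cols); each side must be >= 64 px.
#' @param pixel_size_nm physical pixel size, nm per pixel.
#' @param n_frames number of time points (>= 1).
#' @param n_puncta number of puncta seeded in the cell.
#' @param p_assoc probability in `[0, 1]` that a punctum is seeded
#'   organelle-associated (within `assoc_radius_nm` of `assoc_target`).
#' @param assoc_target `"er"` or `"mito"`: organelle used for associated
#'   seeding and tethering.
#' @param assoc_radius_nm placement distance for associated puncta, nm.
#' @param diffusion_step_sd_nm per-frame isotropic displacement SD of free
#'   puncta, nm/frame. Associated puncta move with their organelle plus a
#'   tethered residual (see [simulate_puncta_tracks()]).
#' @param organelle_motion_sd_nm per-frame SD of the rigid jitter applied to
#'   each whole organelle mask, nm/frame.
#' @param psf_sigma_nm Gaussian PSF sigma, nm.
#' @param noise_poisson_scale photons per intensity unit for shot noise
#'   (`0` disables Poisson noise).
#' @param noise_gaussian_sd additive Gaussian read-noise SD, intensity units.
#' @param mito_region_count number of elongated mitochondrial blobs (may be
#'   0 for a mitochondria-free cell).
#' @param er_nodes_per_kpx density of ER network nodes per 1000 cytoplasm
#'   pixels; controls how much of the cytoplasm the ER web covers.
#' @param seed integer seed; identical parameters and seed give bit-identical
#'   output from every generator.
#' @return An object of class `cell_params` (a validated list).
#' @seealso [generate_cell_geometry()], [simulate_puncta_tracks()],
#'   [render_timelapse()]
#' @export
cell_params <- function(image_shape = c(192L, 192L),
                        pixel_size_nm = 80,
                        n_frames = 10L,
                        n_puncta = 25L,
                        p_assoc = 0.45,
                        assoc_target = c("er", "mito"),
                        assoc_radius_nm = 100,
                        diffusion_step_sd_nm = 40,
                        organelle_motion_sd_nm = 30,
                        psf_sigma_nm = 130,
                        noise_poisson_scale = 1,
                        noise_gaussian_sd = 2,
                        mito_region_count = 12L,
                        er_nodes_per_kpx = 25,
                        seed = 1L) {
  assoc_target <- match.arg(assoc_target)
  if (length(image_shape) != 2L || any(!is.finite(image_shape)))
    stop("`image_shape` must be two finite numbers (rows, cols)")
  image_shape <- as.integer(image_shape)
  if (any(image_shape < 64L))
    stop("degenerate `image_shape`: each side must be >= 64 px")
  stop_if_not_scalar_number(pixel_size_nm, "pixel_size_nm", positive = TRUE)
  stop_if_not_scalar_number(n_frames, "n_frames")
  if (n_frames < 1) stop("`n_frames` must be >= 1")
  stop_if_not_scalar_number(n_puncta, "n_puncta", nonneg = TRUE)
  stop_if_not_scalar_number(p_assoc, "p_assoc")
  if (p_assoc < 0 || p_assoc > 1) stop("`p_assoc` must be in [0, 1]")
  stop_if_not_scalar_number(assoc_radius_nm, "assoc_radius_nm", positive = TRUE)
  stop_if_not_scalar_number(diffusion_step_sd_nm, "diffusion_step_sd_nm",
                            nonneg = TRUE)
  stop_if_not_scalar_number(organelle_motion_sd_nm, "organelle_motion_sd_nm",
                            nonneg = TRUE)
  stop_if_not_scalar_number(psf_sigma_nm, "psf_sigma_nm", positive = TRUE)
  stop_if_not_scalar_number(noise_poisson_scale, "noise_poisson_scale",
                            nonneg = TRUE)
  stop_if_not_scalar_number(noise_gaussian_sd, "noise_gaussian_sd",
                            nonneg = TRUE)
  stop_if_not_scalar_number(mito_region_count, "mito_region_count",
                            nonneg = TRUE)
  stop_if_not_scalar_number(er_nodes_per_kpx, "er_nodes_per_kpx",
                            positive = TRUE)
  stop_if_not_scalar_number(seed, "seed")
  structure(list(
    image_shape = image_shape, pixel_size_nm = pixel_size_nm,
    n_frames = as.integer(n_frames), n_puncta = as.integer(n_puncta),
    p_assoc = p_assoc, assoc_target = assoc_target,
    assoc_radius_nm = assoc_radius_nm,
    diffusion_step_sd_nm = diffusion_step_sd_nm,
    organelle_motion_sd_nm = organelle_motion_sd_nm,
    psf_sigma_nm = psf_sigma_nm,
    noise_poisson_scale = noise_poisson_scale,
    noise_gaussian_sd = noise_gaussian_sd,
    mito_region_count = as.integer(mito_region_count),
    er_nodes_per_kpx = er_nodes_per_kpx,
    seed = as.integer(seed)), class = "cell_params")
}

#' Parameters for synthetic immunogold fields
#'
#' Defaults reproduce the study conditions of a quantitative pre-embedding
#' immunogold experiment: 41 micrographs of 11.125 um^2 each, a cluster
#' density of 0.796 clusters/um^2 and 60.61% of clusters associated with
#' mitochondria.
#'
#' @param image_area_um2 imaged area per micrograph, um^2.
#' @param n_images number of micrographs.
#' @param cluster_density expected gold-cluster density, clusters/um^2; the
#'   per-image count is Poisson(`cluster_density * image_area_um2`).
#' @param assoc_fraction probability that a cluster is placed associated with
#'   a mitochondrial region.
#' @param mito_region_count mitochondrial profiles per image.
#' @param mito_region_area_fraction fraction of the image area covered by
#'   mitochondrial profiles.
#' @param assoc_distance_um reach of the association rule: a cluster within
#'   this distance of a region outline (or inside it) counts as associated.
#' @param seed integer seed.
#' @return An object of class `gold_field_params`.
#' @seealso [generate_gold_field()], [quantify_group()]
#' @export
gold_field_params <- function(image_area_um2 = 11.125,
                              n_images = 41L,
                              cluster_density = 0.796,
                              assoc_fraction = 0.6061,
                              mito_region_count = 6L,
                              mito_region_area_fraction = 0.15,
                              assoc_distance_um = 0.03,
                              seed = 1L) {
  stop_if_not_scalar_number(image_area_um2, "image_area_um2", positive = TRUE)
  stop_if_not_scalar_number(n_images, "n_images", positive = TRUE)
  stop_if_not_scalar_number(cluster_density, "cluster_density", nonneg = TRUE)
  stop_if_not_scalar_number(assoc_fraction, "assoc_fraction")
  if (assoc_fraction < 0 || assoc_fraction > 1)
    stop("`assoc_fraction` must be in [0, 1]")
  stop_if_not_scalar_number(mito_region_count, "mito_region_count",
                            nonneg = TRUE)
  if (assoc_fraction > 0 && mito_region_count == 0)
    stop("assoc_fraction > 0 requires at least one mitochondrial region")
  stop_if_not_scalar_number(mito_region_area_fraction,
                            "mito_region_area_fraction", nonneg = TRUE)
  if (mito_region_area_fraction >= 0.8)
    stop("`mito_region_area_fraction` must be < 0.8")
  stop_if_not_scalar_number(assoc_distance_um, "assoc_distance_um",
                            nonneg = TRUE)
  stop_if_not_scalar_number(seed, "seed")
  structure(list(
    image_area_um2 = image_area_um2, n_images = as.integer(n_images),
    cluster_density = cluster_density, assoc_fraction = assoc_fraction,
    mito_region_count = as.integer(mito_region_count),
    mito_region_area_fraction = mito_region_area_fraction,
    assoc_distance_um = assoc_distance_um,
    seed = as.integer(seed)), class = "gold_field_params")
}

#' Parameters for correlated cofractionation profiles
#'
#' Generates two density-gradient densitometry profiles whose population
#' Pearson correlation equals `target_r`. The default 12 fractions emulate
#' 24 collected gradient fractions paired two-by-two onto 12 gel lanes.
#'
#' @param n_fractions number of gradient fractions (>= 3).
#' @param target_r target Pearson correlation in `[-1, 1]`.
#' @param noise_sd SD of the marker-specific (independent) component,
#'   intensity units. Must be > 0 unless `|target_r| = 1`.
#' @param seed integer seed.
#' @return An object of class `fraction_profile_params`.
#' @seealso [generate_fraction_profiles()], [pearson_with_p()]
#' @export
fraction_profile_params <- function(n_fractions = 12L,
                                    target_r = 0.633,
                                    noise_sd = 1,
                                    seed = 1L) {
  stop_if_not_scalar_number(n_fractions, "n_fractions")
  if (n_fractions < 3) stop("`n_fractions` must be >= 3")
  stop_if_not_scalar_number(target_r, "target_r")
  if (abs(target_r) > 1) stop("`target_r` must be in [-1, 1]")
  stop_if_not_scalar_number(noise_sd, "noise_sd", nonneg = TRUE)
  if (noise_sd == 0 && abs(target_r) < 1)
    stop("noise_sd = 0 forces |r| = 1; use noise_sd > 0 for |target_r| < 1")
  stop_if_not_scalar_number(seed, "seed")
  structure(list(n_fractions = as.integer(n_fractions), target_r = target_r,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "fraction_profile_params")
}
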