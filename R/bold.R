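#' BOLD time-series objects
#'
#' A `bold_series` holds a 4D scalar volume (x, y, z, t) with its repetition
#' time (s), voxel size (mm) and a 3D logical brain mask. At least 3 volumes
#' are required and all in-mask values must be finite.
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param tr Repetition time in seconds.
#' @param voxel_size Numeric length-3, mm.
#' @param brain_mask 3D logical array; defaults to all TRUE.
#' @return A `bold_series` object.
#' @export
bold_series <- function(data, tr, voxel_size = c(1, 1, 1), brain_mask = NULL) {
  d <- dim(data)
  if (length(d) != 4L) stop("'data' must be a 4D array", call. = FALSE)
  if (d[4] < 3L) stop("need at least 3 volumes", call. = FALSE)
  stopifnot_scalar(tr, "tr")
  if (tr <= 0) stop("'tr' must be positive", call. = FALSE)
  if (is.null(brain_mask)) brain_mask <- array(TRUE, dim = d[1:3])
  if (!identical(dim(brain_mask), d[1:3]))
    stop("'brain_mask' must match the spatial grid", call. = FALSE)
  if (!all(is.finite(data[rep(brain_mask, d[4])])))
    stop("non-finite values inside the brain mask", call. = FALSE)
  structure(
    list(data = data, tr = as.numeric(tr), voxel_size = as.numeric(voxel_size),
         brain_mask = brain_mask),
    class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "BOLD series: %d x %d x %d grid, %d volumes, TR %.3g s, %d mask voxels\n",
    d[1], d[2], d[3], d[4], x$tr, sum(x$brain_mask)))
  invisible(x)
}

n_timepoints <- function(series) dim(series$data)[4]

# In-mask voxel time-courses as a t x V matrix (V = mask voxels, in
# which(mask) order).
mask_matrix <- function(series) {
  d <- dim(series$data)
  m <- matrix(series$data, prod(d[1:3]), d[4])
  t(m[which(series$brain_mask), , drop = FALSE])
}

# Write a t x V matrix back into a copy of `series` at the mask voxels.
set_mask_matrix <- function(series, tc) {
  d <- dim(series$data)
  m <- matrix(series$data, prod(d[1:3]), d[4])
  m[which(series$brain_mask), ] <- t(tc)
  series$data <- array(m, dim = d)
  series
}

#' Community covariance specification for the BOLD generator
#'
#' Encodes the generative model for synthetic region time-courses: each
#' community c has a latent standard-normal signal s_c(t); region i in
#' community c has signal a_i * s_c(t) + sigma * eps_i(t); each voxel adds
#' independent noise with sd `region_noise_sd`. Two regions of one community
#' therefore correlate (in the many-volume limit, ignoring voxel noise) at
#' a^2 / (a^2 + sigma^2), and regions of different communities at 0.
#'
#' @param assignment Integer vector mapping region id to community id
#'   (position = region id).
#' @param signal_gain Latent-signal loading a, scalar or per region (>= 0).
#' @param noise_sd Region-level noise sd sigma (> 0).
#' @param region_noise_sd Voxel-level noise sd (> 0).
#' @param extra_latents Optional list of planted shared components, each
#'   `list(regions = c(i, j), gain = g)`; used by [simulate_paired_study()]
#'   to raise the correlation of a region pair.
#' @return A `community_spec` object.
#' @export
community_spec <- function(assignment, signal_gain = 1, noise_sd = 1,
                           region_noise_sd = 0.5, extra_latents = list()) {
  assignment <- as.integer(assignment)
  if (any(is.na(assignment)))
    stop("every region needs a community assignment", call. = FALSE)
  if (any(signal_gain < 0)) stop("gains must be >= 0", call. = FALSE)
  if (noise_sd <= 0 || region_noise_sd <= 0)
    stop("noise sds must be > 0", call. = FALSE)
  structure(
    list(assignment = assignment, signal_gain = signal_gain,
         noise_sd = noise_sd, region_noise_sd = region_noise_sd,
         extra_latents = extra_latents),
    class = "community_spec")
}

#' Simulate a BOLD series with community-structured region covariance
#'
#' Draws latent community signals, region signals and voxel noise per the
#' model in [community_spec()]. All draws are standard-normal white noise:
#' the generator targets the covariance structure downstream connectivity
#' methods consume, not hemodynamics or scanner physics.
#'
#' @param atlas A `label_atlas`; every region must be assigned a community.
#' @param spec A `community_spec`.
#' @param n_volumes Number of time points.
#' @param tr Repetition time (s).
#' @param seed Integer seed; identical seeds give identical series.
#' @return A `bold_series` whose mask is the atlas foreground.
#' @export
simulate_bold <- function(atlas, spec, n_volumes = 300L, tr = 2,
                          seed = 1L) {
  r <- n_regions(atlas)
  if (length(spec$assignment) < r)
    stop("spec assigns ", length(spec$assignment), " regions; atlas has ", r,
         call. = FALSE)
  gains <- rep(spec$signal_gain, length.out = r)
  with_seed(seed, {
    n_comm <- max(spec$assignment)
    latent <- matrix(rnorm(n_volumes * n_comm), n_volumes, n_comm)
    region_sig <- latent[, spec$assignment[seq_len(r)], drop = FALSE] *
      rep(gains, each = n_volumes) +
      matrix(rnorm(n_volumes * r, sd = spec$noise_sd), n_volumes, r)
    for (ex in spec$extra_latents) {
      u <- rnorm(n_volumes, sd = 1)
      for (ri in ex$regions)
        region_sig[, ri] <- region_sig[, ri] + ex$gain * u
    }
    lab <- atlas$labels
    mask <- lab > 0L
    vlab <- lab[which(mask)]
    tc <- region_sig[, vlab, drop = FALSE] +
      matrix(rnorm(n_volumes * length(vlab), sd = spec$region_noise_sd),
             n_volumes, length(vlab))
    d <- dim(lab)
    dat <- array(0, dim = c(d, n_volumes))
    m <- matrix(dat, prod(d), n_volumes)
    m[which(mask), ] <- t(tc)
    bold_series(array(m, dim = c(d, n_volumes)), tr = tr,
                voxel_size = atlas$voxel_size, brain_mask = mask)
  })
}

#' Region-mean time-courses of a BOLD series
#'
#' @param series A `bold_series`.
#' @param atlas A `label_atlas` on the same grid.
#' @return A t x R matrix of unweighted region means.
#' @export
region_timecourses <- function(series, atlas) {
  lab <- atlas$labels
  idx <- which(lab > 0L)
  vlab <- lab[idx]
  d <- dim(series$data)
  m <- matrix(series$data, prod(d[1:3]), d[4])[idx, , drop = FALSE]
  out <- t(rowsum(m, vlab) / as.vector(table(vlab)))
  colnames(out) <- sort(unique(vlab))
  out
}
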