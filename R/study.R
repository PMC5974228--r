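#' Simulate a paired two-group, two-session BOLD study
#'
#' Generates a full study layout: `n_control + n_experimental` subjects, each
#' with a pre and a post resting-state series drawn from `base_spec`. Control
#' pre/post and experimental pre are exchangeable draws; only the
#' experimental post session carries the planted modulation, implemented by
#' adding one shared latent component to the two regions of every planted
#' edge, with its gain solved so the expected region-mean correlation of that
#' pair rises by `delta_r`. Adding a latent (rather than editing covariances
#' directly) keeps every generated series a valid stationary time series.
#'
#' @param atlas A `label_atlas`.
#' @param base_spec A `community_spec` describing the unmodulated state.
#' @param planted_edges Integer matrix or data.frame with two columns (region
#'   i, region j); may be empty for a null study.
#' @param delta_r Target correlation increase on each planted edge.
#' @param n_control,n_experimental Group sizes.
#' @param n_volumes,tr Series length and repetition time (s).
#' @param seed Integer master seed.
#' @return A `study_set`: list with `subjects` (data.frame: subject, group,
#'   session), `series` (list of `bold_series`, same order), `atlas`,
#'   `planted_edges`, `delta_r`.
#' @export
simulate_paired_study <- function(atlas, base_spec, planted_edges = NULL,
                                  delta_r = 0, n_control = 12L,
                                  n_experimental = 13L, n_volumes = 300L,
                                  tr = 2, seed = 1L) {
  planted_edges <- normalize_edges(planted_edges, n_regions(atlas))
  post_spec <- base_spec
  if (nrow(planted_edges) > 0L && delta_r != 0) {
    post_spec$extra_latents <- c(
      base_spec$extra_latents,
      apply(planted_edges, 1L, function(e)
        list(regions = as.integer(e),
             gain = planted_gain(atlas, base_spec, e[1], e[2], delta_r)),
        simplify = FALSE))
  }
  groups <- c(rep("control", n_control), rep("experimental", n_experimental))
  ids <- sprintf("s%02d", seq_along(groups))
  subjects <- data.frame(
    subject = rep(ids, each = 2L),
    group = rep(groups, each = 2L),
    session = rep(c("pre", "post"), length(ids)),
    stringsAsFactors = FALSE)
  sub_seeds <- with_seed(seed,
    sample.int(.Machine$integer.max - 1L, nrow(subjects)))
  series <- vector("list", nrow(subjects))
  for (k in seq_len(nrow(subjects))) {
    spec_k <- if (subjects$group[k] == "experimental" &&
                  subjects$session[k] == "post") post_spec else base_spec
    series[[k]] <- simulate_bold(atlas, spec_k, n_volumes = n_volumes,
                                 tr = tr, seed = sub_seeds[k])
  }
  structure(
    list(subjects = subjects, series = series, atlas = atlas,
         planted_edges = planted_edges, delta_r = delta_r),
    class = "study_set")
}

#' @export
print.study_set <- function(x, ...) {
  tab <- table(x$subjects$group) / 2L
  cat(sprintf(
    "Paired study: %d control + %d experimental subjects, 2 sessions each\n",
    tab[["control"]], tab[["experimental"]]))
  if (nrow(x$planted_edges))
    cat(sprintf("  %d planted edge(s), delta_r = %.3g (experimental post)\n",
                nrow(x$planted_edges), x$delta_r))
  invisible(x)
}

normalize_edges <- function(edges, r) {
  if (is.null(edges) || NROW(edges) == 0L)
    return(matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("i", "j"))))
  edges <- as.matrix(edges)[, 1:2, drop = FALSE]
  storage.mode(edges) <- "integer"
  if (any(edges < 1L) || any(edges > r) || any(edges[, 1] == edges[, 2]))
    stop("planted edges must reference distinct valid region ids",
         call. = FALSE)
  dimnames(edges) <- list(NULL, c("i", "j"))
  edges
}

# Gain g of a shared latent added to regions i and j so that their expected
# region-mean correlation becomes r0 + delta_r, where r0 is the base-model
# value. Accounts for voxel-noise attenuation via the regions' voxel counts.
planted_gain <- function(atlas, spec, i, j, delta_r) {
  r <- n_regions(atlas)
  gains <- rep(spec$signal_gain, length.out = r)
  sizes <- tabulate(atlas$labels[atlas$labels > 0L], r)
  v_i <- gains[i]^2 + spec$noise_sd^2 + spec$region_noise_sd^2 / sizes[i]
  v_j <- gains[j]^2 + spec$noise_sd^2 + spec$region_noise_sd^2 / sizes[j]
  cov0 <- if (spec$assignment[i] == spec$assignment[j])
    gains[i] * gains[j] else 0
  r_target <- cov0 / sqrt(v_i * v_j) + delta_r
  if (abs(r_target) >= 1)
    stop(sprintf("target correlation %.3f out of (-1,1) on edge (%d,%d)",
                 r_target, i, j), call. = FALSE)
  # solve (cov0 + g^2) / sqrt((v_i + g^2)(v_j + g^2)) = r_target for g^2,
  # using the symmetric approximation v = sqrt(v_i v_j)
  v <- sqrt(v_i * v_j)
  g2 <- (r_target * v - cov0) / (1 - r_target)
  if (g2 < 0)
    stop("negative delta_r beyond the base correlation is not supported",
         call. = FALSE)
  sqrt(g2)
}

#' Write a study to disk as NIfTI volumes plus a manifest table
#'
#' @param study A `study_set`.
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the manifest data.frame (subject, group, session, path).
#' @export
write_study <- function(study, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_atlas_nifti(study$atlas, file.path(outdir, "atlas.nii.gz"))
  paths <- character(nrow(study$subjects))
  for (k in seq_len(nrow(study$subjects))) {
    paths[k] <- file.path(outdir, sprintf(
      "%s_%s.nii.gz", study$subjects$subject[k], study$subjects$session[k]))
    write_bold_nifti(study$series[[k]], paths[k])
  }
  manifest <- cbind(study$subjects, path = paths)
  utils::write.table(manifest, file.path(outdir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read a study manifest
#' @param path Path to a tab-separated manifest (subject, group, session, path).
#' @return Data.frame with the four columns.
#' @export
read_manifest <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject", "group", "session", "path")
  if (!all(need %in% names(m)))
    stop("manifest needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  m
}
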