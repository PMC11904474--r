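#' Canonical resting-state network names
#'
#' The seven networks of the widely used cortical parcellation: visual,
#' somatomotor, dorsal attention, ventral attention, limbic, frontoparietal
#' control and default mode.  Names are keyed by the short codes used in
#' profile column names.
#'
#' @return named character vector (codes -> names).
#' @export
network_names <- function() {
  c(vis = "visual", som = "somatomotor", dan = "dorsal-attention",
    van = "ventral-attention", lim = "limbic",
    fpc = "frontoparietal-control", dmn = "default-mode")
}

#' Network atlas container
#'
#' @param labels integer label `volume_image` with exactly 7 nonzero labels
#'   (0 = background).
#' @param names named character vector mapping label numbers (as names) to
#'   network names; defaults to labels 1..7 in [network_names()] order.
#' @return a `network_atlas`.
#' @export
network_atlas <- function(labels,
                          names = setNames(network_names(), 1:7)) {
  labs <- sort(unique(as.vector(labels$data)))
  labs <- labs[labs != 0]
  if (length(labs) != 7L)
    stop("network_atlas: exactly 7 nonzero labels are required")
  if (!all(as.character(labs) %in% base::names(names)))
    stop("network_atlas: every label must be named")
  structure(list(labels = labels, names = names[as.character(labs)]),
            class = "network_atlas")
}

#' Binary mask of one network
#' @param atlas `network_atlas`.
#' @param network network name (e.g. `"dorsal-attention"`) or label number.
#' @return binary `volume_image`.
#' @export
atlas_network_mask <- function(atlas, network) {
  lab <- if (is.numeric(network)) network
         else as.numeric(names(atlas$names)[match(network, atlas$names)])
  if (is.na(lab)) stop(sprintf("atlas_network_mask: unknown network '%s'",
                               network))
  volume_image(array(as.numeric(atlas$labels$data == lab),
                     dim(atlas$labels$data)),
               atlas$labels$transform, "binary-mask")
}

#' Crop a network mask by the composite lesion
#'
#' The seed is the network mask minus the composite lesion.  A seed smaller
#' than `min_seed_voxels` is flagged unusable: downstream FC for that
#' network is reported as missing, never zero.
#'
#' @param network_mask,composite_lesion binary `volume_image`s.
#' @param min_seed_voxels minimum usable seed size (default 10 voxels).
#' @return binary `volume_image` with a logical `"usable"` attribute.
#' @export
crop_network <- function(network_mask, composite_lesion,
                         min_seed_voxels = 10L) {
  stop_unless_same_grid(network_mask,
                        list(composite_lesion = composite_lesion))
  seed <- volume_image(
    array(as.numeric(network_mask$data != 0 & composite_lesion$data == 0),
          dim(network_mask$data)),
    network_mask$transform, "binary-mask")
  attr(seed, "usable") <- sum(seed$data) >= min_seed_voxels
  seed
}

#' Mean BOLD time series over a seed
#'
#' @param bold `bold_series`.
#' @param seed binary `volume_image`.
#' @return numeric vector of length T (unweighted voxel mean per timepoint).
#' @export
seed_timeseries <- function(bold, seed) {
  stop_unless_same_grid(bold, list(seed = seed))
  if (sum(seed$data != 0) == 0L) stop("seed_timeseries: seed is empty")
  seed_mean_series(bold, seed)
}

#' Effective number of timepoints after bandpass filtering
#'
#' Bandpass filtering leaves only the fraction `(high - low) / Nyquist` of
#' the sampled spectrum, reducing the effective sample size available to a
#' correlation estimate proportionally:
#' `T_eff = T * (high - low) / (1 / (2 * TR)) = 2 * T * TR * (high - low)`.
#' Under the null, `atanh(r) * sqrt(T_eff - 3)` is then approximately
#' standard normal.
#'
#' @param n_timepoints number of sampled timepoints T.
#' @param repetition_time TR in seconds.
#' @param low_hz,high_hz band edges in Hz.
#' @return scalar effective sample size.
#' @export
effective_timepoints <- function(n_timepoints, repetition_time,
                                 low_hz = BAND_LOW_HZ,
                                 high_hz = BAND_HIGH_HZ) {
  teff <- 2 * n_timepoints * repetition_time * (high_hz - low_hz)
  if (teff <= 4)
    stop("effective_timepoints: too few effective timepoints in this band")
  teff
}

#' Voxelwise connectivity z-map for one seed regressor
#'
#' For every in-brain voxel, the voxel time series is regressed on an
#' intercept and the seed regressor.  Under the default `"fisher-z"`
#' variant the slope is converted to the correlation-equivalent Fisher
#' z-statistic `z = atanh(r) * sqrt(T_eff - 3)` with `r` clipped to
#' `|r| <= 1 - 1e-7`, where `T_eff` accounts for the bandpass (see
#' [effective_timepoints()]).  The `"spatial-z"` variant instead
#' standardizes the regression slopes across in-brain voxels.
#'
#' @param bold preprocessed (bandpassed) `bold_series`.
#' @param regressor numeric vector of length T with positive variance.
#' @param t_eff effective sample size; if `NULL`, computed from the band
#'   recorded by [bandpass()] (or the default band) and the TR.
#' @param variant `"fisher-z"` (default) or `"spatial-z"`.
#' @return z-map `volume_image`; voxels outside the brain are 0.  The count
#'   of zero-variance voxels (set to z = 0) is stored in the
#'   `"n_zero_variance"` attribute.
#' @export
fc_map <- function(bold, regressor, t_eff = NULL,
                   variant = c("fisher-z", "spatial-z")) {
  variant <- match.arg(variant)
  tdim <- n_timepoints(bold)
  if (length(regressor) != tdim)
    stop("fc_map: regressor length must equal the number of timepoints")
  if (sd(regressor) == 0) stop("fc_map: regressor has zero variance")
  if (is.null(t_eff)) {
    band <- attr(bold, "preprocessing")$band
    if (is.null(band)) band <- c(BAND_LOW_HZ, BAND_HIGH_HZ)
    t_eff <- effective_timepoints(tdim, bold$repetition_time,
                                  band[1], band[2])
  }
  d <- dim(bold$data)[1:3]
  inbrain <- if (is.null(bold$brain_mask)) array(TRUE, d)
             else bold$brain_mask$data != 0
  vox <- which(inbrain)
  x <- flatten_bold(bold, vox)                      # T x V
  xc <- sweep(x, 2, colMeans(x))
  rc <- regressor - mean(regressor)
  ss_x <- colSums(xc^2)
  zero_var <- ss_x == 0
  ss_x[zero_var] <- 1
  num <- as.numeric(crossprod(rc, xc))              # cov * (T-1)
  r <- num / sqrt(sum(rc^2) * ss_x)
  r[zero_var] <- 0
  zvals <- if (variant == "fisher-z") {
    r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
    atanh(r) * sqrt(t_eff - 3)
  } else {
    beta <- num / sum(rc^2)
    beta[zero_var] <- 0
    (beta - mean(beta)) / sd(beta)
  }
  zvals[zero_var] <- 0
  zarr <- array(0, d)
  zarr[vox] <- zvals
  out <- volume_image(zarr, bold$transform, "zmap")
  attr(out, "t_eff") <- t_eff
  attr(out, "variant") <- variant
  attr(out, "n_zero_variance") <- sum(zero_var)
  out
}

#' Tumor-region FC with one network
#'
#' The arithmetic mean of the connectivity z-map over the PET-segmented
#' tumor voxels.
#'
#' @param zmap z-map `volume_image`.
#' @param pet_mask binary `volume_image`.
#' @return scalar FC z-score.
#' @export
tumor_network_fc <- function(zmap, pet_mask) {
  stop_unless_same_grid(zmap, list(pet_mask = pet_mask))
  sel <- pet_mask$data != 0
  if (!any(sel)) stop("tumor_network_fc: tumor mask is empty")
  mean(zmap$data[sel])
}

#' Whole-brain FC from per-network values
#'
#' The arithmetic mean of the available (non-missing) network FC values.
#'
#' @param fc_z numeric vector of per-network FC z-scores, `NA` = missing.
#' @return scalar mean, or `NA` if all entries are missing.
#' @export
whole_brain_fc <- function(fc_z) {
  if (all(is.na(fc_z))) return(NA_real_)
  mean(fc_z, na.rm = TRUE)
}

#' Lesion-to-network proximity
#'
#' Network nodes are the face-connected components of the network mask with
#' at least `min_node_voxels` voxels.  The proximity is the mean Euclidean
#' distance, in world mm, between the PET lesion's center of gravity and
#' the node centroids.
#'
#' @param pet_mask,network_mask binary `volume_image`s.
#' @param min_node_voxels minimum node size (default 5 voxels).
#' @return scalar distance in mm, or `NA` if no node survives the filter.
#' @export
proximity <- function(pet_mask, network_mask, min_node_voxels = 5L) {
  stop_unless_same_grid(pet_mask, list(network_mask = network_mask))
  if (sum(pet_mask$data != 0) == 0L) stop("proximity: PET mask is empty")
  if (sum(network_mask$data != 0) == 0L)
    stop("proximity: network mask is empty")
  comp <- label_components(network_mask)
  sizes <- tabulate(comp$data[comp$data != 0])
  keep <- which(sizes >= min_node_voxels)
  if (!length(keep)) return(NA_real_)
  cog <- mask_cog(pet_mask)
  dists <- vapply(keep, function(l) {
    idx <- which(comp$data == l, arr.ind = TRUE)
    cen <- colMeans(world_coords(network_mask, idx))
    sqrt(sum((cen - cog)^2))
  }, numeric(1))
  mean(dists)
}

#' Per-subject tumor-to-network FC profile
#'
#' Runs the full estimator for each of the 7 networks: crop the network
#' mask by the composite lesion, average the BOLD series over the cropped
#' seed, compute the voxelwise z-map, and average it over the PET tumor
#' mask.  Adds whole-brain FC (mean over available networks), per-network
#' proximity, tumor volume, TBR statistics and lobe.
#'
#' @param bold preprocessed `bold_series`.
#' @param atlas `network_atlas`.
#' @param lesion_set `lesion_mask_set` (provides PET mask and composite).
#' @param tbr TBR `volume_image`.
#' @param lobe_template optional label `volume_image`.
#' @param lobe_names optional label-to-name map.
#' @param min_seed_voxels minimum usable seed size (default 10).
#' @param min_node_voxels minimum proximity node size (default 5).
#' @param variant z-score variant, see [fc_map()].
#' @return one-row `data.frame` with columns `fc_vis ... fc_dmn`, `fc_mean`,
#'   `prox_vis ... prox_dmn`, `vol_pet_ml`, `tbr_mean`, `tbr_max`, `lobe`,
#'   `hemisphere`; seed voxel counts are attached as the
#'   `"seed_voxel_counts"` attribute.
#' @export
subject_fc_profile <- function(bold, atlas, lesion_set, tbr,
                               lobe_template = NULL, lobe_names = NULL,
                               min_seed_voxels = 10L, min_node_voxels = 5L,
                               variant = "fisher-z") {
  stop_unless_same_grid(bold, list(atlas = atlas$labels,
                                   composite = lesion_set$composite,
                                   tbr = tbr))
  codes <- names(network_names())
  nets <- network_names()
  fc <- prox <- setNames(rep(NA_real_, 7L), codes)
  seed_counts <- setNames(integer(7L), codes)
  pet_mask <- lesion_set$pet_mask
  for (i in seq_along(nets)) {
    nm <- atlas_network_mask(atlas, nets[i])
    seed <- crop_network(nm, lesion_set$composite, min_seed_voxels)
    seed_counts[i] <- sum(seed$data)
    prox[i] <- proximity(pet_mask, nm, min_node_voxels)
    if (!attr(seed, "usable")) next   # missing, not zero
    reg <- seed_timeseries(bold, seed)
    if (sd(reg) == 0) next
    zmap <- fc_map(bold, reg, variant = variant)
    fc[i] <- tumor_network_fc(zmap, pet_mask)
  }
  summ <- pet_summary(tbr, pet_mask, lobe_template, lobe_names)
  prof <- as.data.frame(c(as.list(setNames(fc, paste0("fc_", codes))),
                          list(fc_mean = whole_brain_fc(fc)),
                          as.list(setNames(prox, paste0("prox_", codes))),
                          list(vol_pet_ml = summ$volume_ml,
                               tbr_mean = summ$tbr_mean,
                               tbr_max = summ$tbr_max,
                               lobe = summ$lobe,
                               hemisphere = summ$hemisphere)))
  attr(prof, "seed_voxel_counts") <- seed_counts
  attr(prof, "variant") <- variant
  prof
}
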