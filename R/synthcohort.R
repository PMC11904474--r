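## Seed fan-out: one user seed deterministically spawns independent
## substreams per component so modules can be re-run in isolation.
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483563)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Parameters for the synthetic imaging generator
#'
#' @param grid_shape 3 integers, voxels per axis (each >= 8).
#' @param voxel_size mm per axis.
#' @param n_timepoints number of BOLD timepoints T (>= 50).
#' @param repetition_time TR in seconds.
#' @param n_networks number of networks (default 7).
#' @param coupling named numeric vector of tumor-to-network coupling weights
#'   alpha, keyed by network name or label; unlisted networks couple with 0.
#' @param noise_sd standard deviation of the additive white voxel noise.
#' @param seed integer RNG seed; fans out to per-component substreams.
#' @return a `sim_imaging_params` list.
#' @export
sim_imaging_params <- function(grid_shape = c(32, 32, 32),
                               voxel_size = c(2, 2, 2),
                               n_timepoints = 200L,
                               repetition_time = 2,
                               n_networks = 7L,
                               coupling = NULL,
                               noise_sd = 1,
                               seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L),
            n_timepoints >= 50L, repetition_time > 0, noise_sd > 0,
            n_networks >= 1L)
  if (!is.null(coupling)) {
    ok <- names(coupling) %in% c(network_names(), as.character(seq_len(n_networks)))
    if (is.null(names(coupling)) || !all(ok))
      stop("sim_imaging_params: coupling must be named by network name or label")
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size = voxel_size,
                 n_timepoints = as.integer(n_timepoints),
                 repetition_time = repetition_time,
                 n_networks = as.integer(n_networks),
                 coupling = coupling, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "sim_imaging_params")
}

parcel_radius <- function(d) max(1L, floor(min(d) / 12))

ellipsoid_mask <- function(d, center, radii) {
  i <- slice.index(array(0, d), 1)
  j <- slice.index(array(0, d), 2)
  k <- slice.index(array(0, d), 3)
  ((i - center[1]) / radii[1])^2 + ((j - center[2]) / radii[2])^2 +
    ((k - center[3]) / radii[3])^2 <= 1
}

#' Synthetic network atlas, lobe template and brain mask
#'
#' Places `n_networks` disjoint parcels inside an ellipsoidal brain, each
#' made of two spherical components (so proximity "nodes" are exercised),
#' and partitions the brain into 8 lobes (4 per hemisphere: frontal,
#' parietal, temporal, occipital).
#'
#' @param params `sim_imaging_params`.
#' @return list with `atlas` (a `network_atlas`), `brain_mask`,
#'   `lobe_template` (label `volume_image`) and `lobe_names`.
#' @export
make_atlas <- function(params) {
  d <- params$grid_shape
  tr4 <- vox_transform(params$voxel_size)
  center <- (d + 1) / 2
  brain_radii <- 0.45 * d
  brain <- ellipsoid_mask(d, center, brain_radii)
  r_p <- parcel_radius(d)
  n_comp <- 2L * params$n_networks
  # candidate centers: brain shrunk so parcels stay inside
  cand <- which(ellipsoid_mask(d, center, pmax(brain_radii - r_p - 1, 1)))
  if (length(cand) < n_comp)
    stop("make_atlas: grid too small to place the network parcels")
  centers <- with_seed(substream_seed(params$seed, "atlas"), {
    chosen <- matrix(0, 0, 3)
    tries <- 0L
    while (nrow(chosen) < n_comp && tries < 20000L) {
      tries <- tries + 1L
      v <- cand[sample.int(length(cand), 1L)]
      p <- arrayInd(v, d)
      if (nrow(chosen) == 0L ||
          min(sqrt(rowSums(sweep(chosen, 2, as.numeric(p))^2))) >= 2 * r_p + 1)
        chosen <- rbind(chosen, as.numeric(p))
    }
    if (nrow(chosen) < n_comp)
      stop("make_atlas: grid too small to place the network parcels")
    chosen
  })
  lab <- array(0L, d)
  for (c_i in seq_len(n_comp)) {
    net <- ((c_i - 1L) %/% 2L) + 1L
    sph <- ellipsoid_mask(d, centers[c_i, ], rep(r_p, 3)) & brain
    lab[sph] <- net
  }
  lobe_names <- c("1" = "frontal-left",  "2" = "frontal-right",
                  "3" = "parietal-left", "4" = "parietal-right",
                  "5" = "temporal-left", "6" = "temporal-right",
                  "7" = "occipital-left","8" = "occipital-right")
  i <- slice.index(array(0, d), 1)
  j <- slice.index(array(0, d), 2)
  k <- slice.index(array(0, d), 3)
  quadrant <- ifelse(j >= center[2],
                     ifelse(k >= center[3], 1L, 3L),   # frontal / temporal
                     ifelse(k >= center[3], 2L, 4L))   # parietal / occipital
  lobes <- array(0L, d)
  lobes[brain] <- (2L * (quadrant - 1L) + ifelse(i > center[1], 2L, 1L))[brain]
  atlas <- if (params$n_networks == 7L)
    network_atlas(volume_image(lab, tr4, "label"))
  else volume_image(lab, tr4, "label")
  list(atlas = atlas,
       brain_mask = volume_image(array(as.numeric(brain), d), tr4,
                                 "binary-mask"),
       lobe_template = volume_image(lobes, tr4, "label"),
       lobe_names = lobe_names)
}

#' Synthetic ellipsoidal tumor overlapping one network parcel
#'
#' The tumor is centered between the first component of the target network
#' and the brain interior, with a radius one voxel larger than the parcel
#' radius, so it overlaps the parcel partially and extends beyond it.
#'
#' @param atlas_set output of [make_atlas()].
#' @param params `sim_imaging_params`.
#' @param target_network network name whose parcel the tumor overlaps.
#' @return binary `volume_image`.
#' @export
simulate_tumor_mask <- function(atlas_set, params,
                                target_network = "dorsal-attention") {
  labels <- if (inherits(atlas_set$atlas, "network_atlas"))
    atlas_set$atlas$labels else atlas_set$atlas
  lab <- if (inherits(atlas_set$atlas, "network_atlas"))
    as.numeric(names(atlas_set$atlas$names)[
      match(target_network, atlas_set$atlas$names)])
  else as.numeric(target_network)
  d <- dim(labels$data)
  comp <- label_components(volume_image(
    array(as.numeric(labels$data == lab), d), labels$transform,
    "binary-mask"))
  idx <- which(comp$data == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("simulate_tumor_mask: target network is empty")
  pcen <- colMeans(idx)
  r_p <- parcel_radius(d)
  center <- (d + 1) / 2
  # shift toward the brain center so the overlap is partial
  dir <- center - pcen
  dir <- if (all(dir == 0)) c(1, 0, 0) else dir / sqrt(sum(dir^2))
  tcen <- pcen + dir * r_p
  tum <- ellipsoid_mask(d, tcen, rep(r_p + 1, 3)) &
    (atlas_set$brain_mask$data != 0)
  volume_image(array(as.numeric(tum), d), labels$transform, "binary-mask")
}

## Latent bandlimited network time courses: Gaussian white series,
## bandpassed to the analysis band, scaled to zero mean and unit variance.
## A padding margin is generated and trimmed to suppress filter edge
## transients.
latent_timecourses <- function(tdim, repetition_time, n_networks) {
  pad <- tdim
  raw <- matrix(rnorm((tdim + 2 * pad) * n_networks), ncol = n_networks)
  s <- apply(raw, 2, bandpass_series, repetition_time = repetition_time)
  s <- s[pad + seq_len(tdim), , drop = FALSE]
  s <- sweep(s, 2, colMeans(s))
  sweep(s, 2, apply(s, 2, sd), "/")
}

#' Simulate a resting-state BOLD series with planted network structure
#'
#' Every network parcel voxel carries its network's latent bandlimited time
#' course plus white noise; tumor voxels carry the coupling-weighted sum of
#' the latent courses plus white noise (tumor membership overrides parcel
#' membership); remaining in-brain voxels are pure noise; voxels outside
#' the brain are zero.
#'
#' @param atlas_set output of [make_atlas()].
#' @param tumor_mask binary `volume_image` (nonempty).
#' @param params `sim_imaging_params`; `params$coupling` sets the alphas.
#' @return list with `bold` (`bold_series`) and `truth` (latent signal
#'   matrix `signals` T x K and the coupling vector `coupling`).
#' @export
simulate_bold <- function(atlas_set, tumor_mask, params) {
  labels <- if (inherits(atlas_set$atlas, "network_atlas"))
    atlas_set$atlas$labels else atlas_set$atlas
  stop_unless_same_grid(labels, list(tumor_mask = tumor_mask,
                                     brain_mask = atlas_set$brain_mask))
  if (sum(tumor_mask$data != 0) == 0L)
    stop("simulate_bold: tumor mask is empty")
  k <- params$n_networks
  alpha <- setNames(numeric(k), as.character(seq_len(k)))
  if (!is.null(params$coupling)) {
    key <- names(params$coupling)
    if (inherits(atlas_set$atlas, "network_atlas")) {
      byname <- match(key, atlas_set$atlas$names)
      key[!is.na(byname)] <- names(atlas_set$atlas$names)[byname[!is.na(byname)]]
    }
    alpha[key] <- params$coupling
  }
  tdim <- params$n_timepoints
  out <- with_seed(substream_seed(params$seed, "bold"), {
    s <- latent_timecourses(tdim, params$repetition_time, k)
    d <- params$grid_shape
    inbrain <- which(atlas_set$brain_mask$data != 0)
    x <- matrix(rnorm(tdim * length(inbrain), sd = params$noise_sd),
                nrow = tdim)
    labvec <- labels$data[inbrain]
    tumvec <- tumor_mask$data[inbrain] != 0
    for (net in seq_len(k)) {
      sel <- labvec == net & !tumvec
      if (any(sel)) x[, sel] <- x[, sel] + s[, net]
    }
    if (any(tumvec)) {
      tum_sig <- as.numeric(s %*% alpha)
      x[, tumvec] <- x[, tumvec] + tum_sig
    }
    arr <- array(0, c(d, tdim))
    flat <- matrix(arr, prod(d), tdim)
    flat[inbrain, ] <- t(x)
    list(arr = array(flat, c(d, tdim)), s = s)
  })
  bold <- bold_series(out$arr, params$repetition_time, labels$transform,
                      brain_mask = atlas_set$brain_mask)
  list(bold = bold, truth = list(signals = out$s, coupling = alpha))
}

#' Simulate a PET activity volume with a tumor hotspot
#'
#' In-brain background activity has mean `background_activity`; tumor
#' voxels have mean `background_activity * hotspot_tbr`; voxels outside the
#' brain are zero.  With `noise_sd = 0` the standardize-then-segment round
#' trip at any threshold <= `hotspot_tbr` recovers the tumor mask exactly.
#'
#' @param tumor_mask,brain_mask binary `volume_image`s.
#' @param hotspot_tbr desired tumor-to-brain ratio of the hotspot (> 0).
#' @param params `sim_imaging_params` (for the RNG substream).
#' @param background_activity reference activity level (arbitrary units).
#' @param noise_sd additive Gaussian noise SD in activity units (default 0).
#' @return activity `volume_image`.
#' @export
simulate_pet <- function(tumor_mask, brain_mask, hotspot_tbr, params,
                         background_activity = 100, noise_sd = 0) {
  stop_unless_same_grid(tumor_mask, list(brain_mask = brain_mask))
  if (hotspot_tbr <= 0) stop("simulate_pet: hotspot_tbr must be > 0")
  d <- dim(tumor_mask$data)
  act <- array(0, d)
  inb <- brain_mask$data != 0
  act[inb] <- background_activity
  act[inb & tumor_mask$data != 0] <- background_activity * hotspot_tbr
  if (noise_sd > 0)
    act[inb] <- pmax(act[inb] + with_seed(
      substream_seed(params$seed, "pet"),
      rnorm(sum(inb), sd = noise_sd)), 0)
  volume_image(act, tumor_mask$transform, "activity")
}

#' Simulate structural lesion masks around a tumor
#'
#' The contrast-enhancing (CE) mask is the tumor plus a random subset of
#' its one-voxel dilation shell (so CE is contained in the dilated tumor);
#' the FLAIR mask is the two-voxel dilation (so FLAIR contains the tumor
#' neighborhood and is at least as large as CE); the resection cavity is,
#' with probability `cavity_prob`, a small sphere displaced from the tumor.
#'
#' @param tumor_mask binary `volume_image` (nonempty).
#' @param brain_mask binary `volume_image`.
#' @param params `sim_imaging_params`.
#' @param cavity_prob probability that a cavity exists (default 0.5).
#' @param ce_keep_prob probability that a shell voxel joins the CE mask.
#' @return list with `ce_mask`, `flair_mask`, `cavity_mask`.
#' @export
simulate_structural_masks <- function(tumor_mask, brain_mask, params,
                                      cavity_prob = 0.5,
                                      ce_keep_prob = 0.7) {
  if (sum(tumor_mask$data != 0) == 0L)
    stop("simulate_structural_masks: tumor mask is empty")
  d <- dim(tumor_mask$data)
  with_seed(substream_seed(params$seed, "structural"), {
    dil1 <- dilate_mask(tumor_mask, 1L)
    shell <- which(dil1$data != 0 & tumor_mask$data == 0)
    ce <- tumor_mask$data != 0
    if (length(shell))
      ce[shell[runif(length(shell)) < ce_keep_prob]] <- TRUE
    flair <- dilate_mask(tumor_mask, 2L)$data != 0
    cavity <- array(FALSE, d)
    if (runif(1) < cavity_prob) {
      idx <- which(tumor_mask$data != 0, arr.ind = TRUE)
      cen <- colMeans(idx)
      ext <- max(1, max(apply(idx, 2, function(v) diff(range(v)))) / 2)
      cavity <- ellipsoid_mask(d, cen - c(ext + 2, 0, 0), rep(2, 3)) &
        brain_mask$data != 0
    }
    list(ce_mask = volume_image(array(as.numeric(ce), d),
                                tumor_mask$transform, "binary-mask"),
         flair_mask = volume_image(array(as.numeric(flair & brain_mask$data != 0 |
                                                    tumor_mask$data != 0), d),
                                   tumor_mask$transform, "binary-mask"),
         cavity_mask = volume_image(array(as.numeric(cavity), d),
                                    tumor_mask$transform, "binary-mask"))
  })
}

# ---- Survival cohort generator ---------------------------------------------

#' Parameters for the synthetic survival cohort
#'
#' Survival times follow a proportional-hazards exponential model
#' `h(t | x) = baseline_hazard * exp(sum beta_j x_j)` with the FC values
#' among the covariates; censoring is independent exponential, calibrated
#' so that roughly `censor_rate` of subjects are censored.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param log_hr_per_unit_fc length-7 numeric: planted log hazard ratio per
#'   FC z-score unit, in [network_names()] order.  Default: -0.105
#'   (HR 0.90) for the dorsal attention network, 0 elsewhere.
#' @param baseline_hazard events per month (> 0).
#' @param censor_rate target censored fraction in [0, 1).
#' @param covariate_spec list of clinical covariates, each a list with
#'   `name`, `sampler` (function of n) and `log_hr`.
#' @param seed integer RNG seed.
#' @return a `sim_cohort_params` list.
#' @export
sim_cohort_params <- function(n_subjects = 82L,
                              log_hr_per_unit_fc =
                                setNames(c(0, 0, log(0.90), 0, 0, 0, 0),
                                         names(network_names())),
                              baseline_hazard = 0.05,
                              censor_rate = 0.2,
                              covariate_spec = default_covariate_spec(),
                              seed = 1L) {
  stopifnot(n_subjects >= 2L, baseline_hazard > 0,
            censor_rate >= 0, censor_rate < 1,
            length(log_hr_per_unit_fc) == 7L)
  structure(list(n_subjects = as.integer(n_subjects),
                 log_hr_per_unit_fc = log_hr_per_unit_fc,
                 baseline_hazard = baseline_hazard,
                 censor_rate = censor_rate,
                 covariate_spec = covariate_spec,
                 seed = as.integer(seed)),
            class = "sim_cohort_params")
}

#' Default clinical covariate specification
#'
#' Age (years, roughly 26-81 around a median of 53), ECOG performance
#' score (0-3), MGMT promoter methylation (binary) and extent of resection
#' (ordinal 0-3), with modest planted log hazard ratios.
#'
#' @return list of covariate specs for [sim_cohort_params()].
#' @export
default_covariate_spec <- function() {
  list(
    list(name = "age", sampler = function(n) pmin(pmax(rnorm(n, 53, 12), 26), 81),
         log_hr = 0.02),
    list(name = "ecog",
         sampler = function(n) sample(0:3, n, TRUE, prob = c(.59, .34, .06, .01)),
         log_hr = 0.3),
    list(name = "mgmt_methylated", sampler = function(n) rbinom(n, 1, 0.6),
         log_hr = -0.4),
    list(name = "resection_extent",
         sampler = function(n) sample(0:3, n, TRUE, prob = c(.04, .22, .11, .63)),
         log_hr = -0.1))
}

#' Simulate correlated per-subject FC profiles
#'
#' FC z-scores share a subject-level factor (overall connectivity) on top
#' of network-specific variation: `fc_jk = m_k + u_j + e_jk` with
#' `u ~ N(0, sd_subject^2)` and `e ~ N(0, sd_network^2)`.  Defaults place
#' the network means in the 3.5-6.2 z-score range with total per-network
#' SD near 3, matching the magnitudes seen in glioma cohorts.
#'
#' @param n number of subjects.
#' @param means length-7 network means (z-score units).
#' @param sd_subject SD of the shared subject factor.
#' @param sd_network SD of the network-specific residual.
#' @return n x 7 matrix with columns `fc_vis ... fc_dmn`.
#' @export
simulate_fc_profiles <- function(n,
                                 means = c(4.5, 5.0, 6.0, 6.2, 3.5, 5.8, 6.0),
                                 sd_subject = 2.5, sd_network = 2.0) {
  u <- rnorm(n, 0, sd_subject)
  fc <- sweep(matrix(rnorm(n * 7, 0, sd_network), n, 7), 1, u, `+`)
  fc <- sweep(fc, 2, means, `+`)
  colnames(fc) <- paste0("fc_", names(network_names()))
  fc
}

#' Simulate a survival cohort with planted proportional hazards
#'
#' @param params `sim_cohort_params`.
#' @param fc_profiles optional n x 7 matrix of FC covariates (columns
#'   `fc_vis ... fc_dmn`); if `NULL`, drawn by [simulate_fc_profiles()].
#' @return list with `cohort` (`data.frame`: `id`, `os_months`, `event`,
#'   clinical covariates, FC columns) and `truth` (planted log-HRs and
#'   baseline hazard).
#' @export
simulate_cohort <- function(params, fc_profiles = NULL) {
  n <- params$n_subjects
  with_seed(substream_seed(params$seed, "cohort"), {
    fc <- if (is.null(fc_profiles)) simulate_fc_profiles(n)
          else as.matrix(fc_profiles)
    if (ncol(fc) != 7L)
      stop("simulate_cohort: fc_profiles must have 7 columns")
    if (is.null(colnames(fc)))
      colnames(fc) <- paste0("fc_", names(network_names()))
    covs <- lapply(params$covariate_spec, function(sp) sp$sampler(n))
    names(covs) <- vapply(params$covariate_spec, `[[`, "", "name")
    beta_cov <- vapply(params$covariate_spec, `[[`, 0, "log_hr")
    lp <- as.numeric(fc %*% params$log_hr_per_unit_fc)
    if (length(covs))
      lp <- lp + as.numeric(as.matrix(as.data.frame(covs)) %*% beta_cov)
    # Cox estimates are invariant to covariate location shifts, so the
    # linear predictor is centered to keep the baseline hazard on scale
    rate <- params$baseline_hazard * exp(lp - mean(lp))
    t_event <- rexp(n, rate)
    if (params$censor_rate > 0) {
      c_rate <- params$baseline_hazard *
        params$censor_rate / (1 - params$censor_rate)
      t_cens <- rexp(n, c_rate)
    } else t_cens <- rep(Inf, n)
    event <- as.integer(t_event <= t_cens)
    if (all(event == 0L))
      warning("simulate_cohort: all subjects censored at this censor_rate")
    cohort <- data.frame(id = sprintf("S%03d", seq_len(n)),
                         os_months = pmin(t_event, t_cens),
                         event = event)
    if (length(covs)) cohort <- cbind(cohort, as.data.frame(covs))
    cohort <- cbind(cohort, as.data.frame(fc))
    list(cohort = cohort,
         truth = list(log_hr_per_unit_fc = params$log_hr_per_unit_fc,
                      covariate_log_hr = setNames(beta_cov, names(covs)),
                      baseline_hazard = params$baseline_hazard,
                      censor_rate = params$censor_rate))
  })
}

# ---- Whole synthetic subject / cohort bundles ------------------------------

#' Generate one fully synthetic imaging subject
#'
#' Builds the atlas, tumor, BOLD, PET and structural masks for a single
#' subject on one shared grid, with per-subject RNG substreams.
#'
#' @param params `sim_imaging_params` (its `seed` is combined with
#'   `subject_id`).
#' @param subject_id integer subject index.
#' @param target_network network the tumor overlaps.
#' @param hotspot_tbr PET hotspot tumor-to-brain ratio.
#' @param pet_noise_sd PET noise SD (activity units).
#' @return list with `bold`, `pet`, `brain_mask`, `ce_mask`, `flair_mask`,
#'   `cavity_mask`, `atlas`, `lobe_template`, `lobe_names`, `tumor_mask`,
#'   `truth`, `id`.
#' @export
simulate_subject <- function(params, subject_id = 1L,
                             target_network = "dorsal-attention",
                             hotspot_tbr = 2.0, pet_noise_sd = 0) {
  sp <- params
  sp$seed <- substream_seed(params$seed, sprintf("subject%06d", subject_id))
  atl <- make_atlas(sp)
  tumor <- simulate_tumor_mask(atl, sp, target_network)
  sim <- simulate_bold(atl, tumor, sp)
  pet <- simulate_pet(tumor, atl$brain_mask, hotspot_tbr, sp,
                      noise_sd = pet_noise_sd)
  struct <- simulate_structural_masks(tumor, atl$brain_mask, sp)
  c(list(id = sprintf("S%03d", subject_id), bold = sim$bold, pet = pet,
         brain_mask = atl$brain_mask, atlas = atl$atlas,
         lobe_template = atl$lobe_template, lobe_names = atl$lobe_names,
         tumor_mask = tumor, truth = sim$truth),
    struct)
}

#' Write a synthetic subject to disk as NIfTI volumes
#'
#' @param subject output of [simulate_subject()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_subject <- function(subject, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_bold(subject$bold, file.path(dir, "bold.nii.gz"))
  for (nm in c("pet", "brain_mask", "ce_mask", "flair_mask", "cavity_mask",
               "tumor_mask", "lobe_template")) {
    write_volume(subject[[nm]], file.path(dir, paste0(nm, ".nii.gz")))
  }
  labels <- if (inherits(subject$atlas, "network_atlas"))
    subject$atlas$labels else subject$atlas
  write_volume(labels, file.path(dir, "atlas.nii.gz"))
  invisible(dir)
}

#' Read a synthetic subject written by [write_subject()]
#'
#' @param dir subject directory.
#' @param repetition_time TR in seconds.
#' @return subject list as produced by [simulate_subject()] (without truth).
#' @export
read_subject <- function(dir, repetition_time = 2) {
  brain <- read_volume(file.path(dir, "brain_mask.nii.gz"), "binary-mask")
  list(id = basename(dir),
       bold = read_bold(file.path(dir, "bold.nii.gz"),
                        repetition_time = repetition_time,
                        brain_mask = brain),
       pet = read_volume(file.path(dir, "pet.nii.gz"), "activity"),
       brain_mask = brain,
       ce_mask = read_volume(file.path(dir, "ce_mask.nii.gz"), "binary-mask"),
       flair_mask = read_volume(file.path(dir, "flair_mask.nii.gz"),
                                "binary-mask"),
       cavity_mask = read_volume(file.path(dir, "cavity_mask.nii.gz"),
                                 "binary-mask"),
       atlas = network_atlas(read_volume(file.path(dir, "atlas.nii.gz"),
                                         "label")),
       lobe_template = read_volume(file.path(dir, "lobe_template.nii.gz"),
                                   "label"))
}
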