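# Small in-code fixtures shared across test files.

# A tiny grid with a handful of marked voxels, 2 mm voxels by default.
tiny_mask <- function(d = c(8, 8, 8), on = list(c(4, 4, 4)), voxel = c(2, 2, 2)) {
  a <- array(0, d)
  for (v in on) a[v[1], v[2], v[3]] <- 1
  volume_image(a, vox_transform(voxel), "binary-mask")
}

empty_mask <- function(d = c(8, 8, 8), voxel = c(2, 2, 2)) {
  volume_image(array(0, d), vox_transform(voxel), "binary-mask")
}

# Ball mask around a center (voxel units).
ball_mask <- function(d, center, r, voxel = c(2, 2, 2)) {
  i <- slice.index(array(0, d), 1)
  j <- slice.index(array(0, d), 2)
  k <- slice.index(array(0, d), 3)
  a <- array(as.numeric((i - center[1])^2 + (j - center[2])^2 +
                          (k - center[3])^2 <= r^2), d)
  volume_image(a, vox_transform(voxel), "binary-mask")
}

# BOLD series whose voxel time series are supplied by a generator function
# f(i, j, k) -> numeric vector of length tdim.
synthetic_bold <- function(d = c(6, 6, 6), tdim = 80, tr = 2, f = NULL,
                           brain = NULL) {
  if (is.null(f)) f <- function(i, j, k) rnorm(tdim)
  a <- array(0, c(d, tdim))
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    a[i, j, k, ] <- f(i, j, k)
  bold_series(a, tr, vox_transform(), brain_mask = brain)
}

# Small imaging parameter set used by most generator tests.
small_params <- function(seed = 1, ...) {
  sim_imaging_params(grid_shape = c(24, 24, 24), n_timepoints = 120,
                     seed = seed, ...)
}

# One small coupled subject plus its preprocessed BOLD and lesion set,
# reused by connectivity tests.
small_subject_bundle <- function(seed = 1, coupling = c("dorsal-attention" = 2),
                                 fwhm = 0) {
  p <- small_params(seed = seed, coupling = coupling)
  s <- simulate_subject(p, subject_id = 1, hotspot_tbr = 2.0)
  bold <- preprocess_bold(s$bold, fwhm_mm = fwhm)
  tbr <- standardize_tbr(s$pet, s$brain_mask, dilate_mask(s$tumor_mask, 1))
  seg <- segment_pet(tbr)
  lesions <- compose_lesion(seg$mask, s$ce_mask, s$flair_mask, s$cavity_mask)
  list(subject = s, bold = bold, tbr = tbr, lesions = lesions, params = p)
}
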