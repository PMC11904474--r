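#' Volumetric image container
#'
#' A `volume_image` holds a 3D scalar grid together with its voxel-to-world
#' affine transform (mm).  It is the common currency of the pipeline: PET
#' activity, standardized tumor-to-brain-ratio (TBR) images, connectivity
#' z-maps, binary masks and integer label volumes (atlases, lobe templates)
#' are all `volume_image`s on one shared grid.
#'
#' @param data 3D numeric or integer array.
#' @param transform 4x4 voxel-to-world affine (mm); voxel indices are
#'   0-based, NIfTI style.  Defaults to 2 mm isotropic voxels at the origin.
#' @param kind one of `"activity"`, `"tbr"`, `"zmap"`, `"binary-mask"`,
#'   `"label"`.
#' @return A `volume_image` object.
#' @export
volume_image <- function(data, transform = vox_transform(), kind = "activity") {
  kind <- match.arg(kind, c("activity", "tbr", "zmap", "binary-mask", "label"))
  if (length(dim(data)) != 3L)
    stop("volume_image: 'data' must be a 3D array")
  if (!is.matrix(transform) || any(dim(transform) != c(4L, 4L)))
    stop("volume_image: 'transform' must be a 4x4 matrix")
  if (kind == "binary-mask" && !all(data %in% c(0, 1)))
    stop("volume_image: binary-mask values must be 0 or 1")
  if (kind == "tbr" && any(data < 0))
    stop("volume_image: tbr values must be >= 0")
  structure(list(data = data, transform = transform, kind = kind),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image> %s  %s  voxel %s mm\n", x$kind,
              paste(dim(x$data), collapse = "x"),
              paste(signif(voxel_sizes(x), 3), collapse = "x")))
  invisible(x)
}

#' Build a voxel-to-world affine from voxel sizes
#'
#' @param voxel_size length-3 numeric, mm per axis.
#' @param origin world coordinates (mm) of voxel (0,0,0).
#' @return 4x4 affine matrix.
#' @export
vox_transform <- function(voxel_size = c(2, 2, 2), origin = c(0, 0, 0)) {
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0), length(origin) == 3L)
  m <- diag(4)
  diag(m)[1:3] <- voxel_size
  m[1:3, 4] <- origin
  m
}

#' Voxel sizes (mm) of a volume or BOLD series
#' @param x a `volume_image` or `bold_series`.
#' @return length-3 numeric, mm per axis.
#' @export
voxel_sizes <- function(x) {
  m <- x$transform[1:3, 1:3]
  sqrt(colSums(m^2))
}

#' Voxel volume in milliliters
#' @param x a `volume_image` or `bold_series`.
#' @return scalar, mL per voxel.
#' @export
voxel_volume_ml <- function(x) abs(det(x$transform[1:3, 1:3])) / 1000

#' Volume (mL) of a binary mask
#' @param mask binary `volume_image`.
#' @return scalar, mL.
#' @export
mask_volume_ml <- function(mask) sum(mask$data != 0) * voxel_volume_ml(mask)

#' Do two volumes share grid shape and transform?
#' @param a,b `volume_image` or `bold_series` objects.
#' @param tol numeric tolerance on the affines.
#' @return logical scalar.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  da <- dim(a$data); db <- dim(b$data)
  identical(da[1:3], db[1:3]) && max(abs(a$transform - b$transform)) <= tol
}

stop_unless_same_grid <- function(ref, others) {
  for (nm in names(others)) {
    if (is.null(others[[nm]])) next
    if (!same_grid(ref, others[[nm]]))
      stop(sprintf("grid mismatch: '%s' is not on the reference grid", nm))
  }
  invisible(TRUE)
}

#' World coordinates (mm) of voxel indices
#'
#' @param x a `volume_image` or `bold_series`.
#' @param idx integer matrix with one (i,j,k) 1-based voxel index per row.
#' @return numeric matrix of world coordinates, one row per voxel.
#' @export
world_coords <- function(x, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3L)
  hom <- cbind(idx - 1, 1)          # NIfTI affines act on 0-based indices
  t(x$transform %*% t(hom))[, 1:3, drop = FALSE]
}

#' Center of gravity of a binary mask in world mm
#' @param mask binary `volume_image`.
#' @return length-3 numeric (mm).
#' @export
mask_cog <- function(mask) {
  idx <- which(mask$data != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask_cog: mask is empty")
  colMeans(world_coords(mask, idx))
}

#' 4D resting-state BOLD container
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param repetition_time repetition interval in seconds.
#' @param transform 4x4 voxel-to-world affine (mm).
#' @param brain_mask binary `volume_image` on the same spatial grid.
#' @return A `bold_series` object.
#' @export
bold_series <- function(data, repetition_time, transform = vox_transform(),
                        brain_mask = NULL) {
  if (length(dim(data)) != 4L)
    stop("bold_series: 'data' must be a 4D array")
  if (dim(data)[4] < 50L)
    stop("bold_series: at least 50 timepoints are required")
  if (!is.numeric(repetition_time) || repetition_time <= 0)
    stop("bold_series: repetition_time must be > 0")
  obj <- structure(list(data = data, repetition_time = repetition_time,
                        transform = transform, brain_mask = brain_mask),
                   class = "bold_series")
  if (!is.null(brain_mask) && !same_grid(obj, brain_mask))
    stop("bold_series: brain_mask is not on the BOLD spatial grid")
  obj
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_series> %s voxels x %d timepoints, TR %.3g s\n",
              paste(d[1:3], collapse = "x"), d[4], x$repetition_time))
  invisible(x)
}

n_timepoints <- function(bold) dim(bold$data)[4]

## Flatten the 4D array to a T x V matrix over the given voxel indices
## (linear indices into the spatial grid); inverse of `unflatten_bold`.
flatten_bold <- function(bold, vox_idx) {
  d <- dim(bold$data)
  nvox <- prod(d[1:3])
  m <- matrix(bold$data, nrow = nvox, ncol = d[4])
  t(m[vox_idx, , drop = FALSE])
}

unflatten_bold <- function(bold, vox_idx, mat, fill = 0) {
  d <- dim(bold$data)
  out <- matrix(fill, nrow = prod(d[1:3]), ncol = d[4])
  out[vox_idx, ] <- t(mat)
  array(out, dim = d)
}

# ---- NIfTI I/O -------------------------------------------------------------

#' Read a NIfTI volume
#' @param path file path (.nii or .nii.gz).
#' @param kind volume kind, see [volume_image()].
#' @return `volume_image`.
#' @export
read_volume <- function(path, kind = "activity") {
  img <- RNifti::readNifti(path)
  m <- RNifti::xform(img)
  attributes(m) <- list(dim = dim(m))
  volume_image(array(as.vector(img), dim = dim(img)[1:3]),
               transform = m, kind = kind)
}

#' Write a NIfTI volume
#' @param vol `volume_image`.
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- voxel_sizes(vol)   # must precede the xform setters
  RNifti::sform(img) <- structure(vol$transform, code = 2L)
  RNifti::qform(img) <- structure(vol$transform, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 4D BOLD NIfTI
#' @param path file path.
#' @param repetition_time seconds; if `NULL`, taken from the NIfTI header.
#' @param brain_mask optional binary `volume_image`.
#' @return `bold_series`.
#' @export
read_bold <- function(path, repetition_time = NULL, brain_mask = NULL) {
  img <- RNifti::readNifti(path)
  if (is.null(repetition_time))
    repetition_time <- RNifti::pixdim(img)[4]
  m <- RNifti::xform(img)
  attributes(m) <- list(dim = dim(m))
  bold_series(array(as.vector(img), dim = dim(img)),
              repetition_time = repetition_time,
              transform = m,
              brain_mask = brain_mask)
}

#' Write a 4D BOLD NIfTI
#' @param bold `bold_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bold <- function(bold, path) {
  img <- RNifti::asNifti(bold$data)
  RNifti::pixdim(img) <- c(voxel_sizes(bold), bold$repetition_time)
  RNifti::sform(img) <- structure(bold$transform, code = 2L)
  RNifti::qform(img) <- structure(bold$transform, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---- Binary-mask morphology ------------------------------------------------

#' Dilate a binary mask
#'
#' Face-connected (6-neighborhood) dilation, iterated `voxels` times.
#'
#' @param mask binary `volume_image`.
#' @param voxels number of dilation iterations.
#' @return binary `volume_image`.
#' @export
dilate_mask <- function(mask, voxels = 1L) {
  stopifnot(voxels >= 0L)
  a <- mask$data != 0
  d <- dim(a)
  for (it in seq_len(voxels)) {
    out <- a
    out[-1, , ]    <- out[-1, , ]    | a[-d[1], , ]
    out[-d[1], , ] <- out[-d[1], , ] | a[-1, , ]
    out[, -1, ]    <- out[, -1, ]    | a[, -d[2], ]
    out[, -d[2], ] <- out[, -d[2], ] | a[, -1, ]
    out[, , -1]    <- out[, , -1]    | a[, , -d[3]]
    out[, , -d[3]] <- out[, , -d[3]] | a[, , -1]
    a <- out
  }
  volume_image(array(as.numeric(a), d), mask$transform, "binary-mask")
}

#' Connected components of a binary mask
#'
#' Labels face-connected (6-neighborhood) components.
#'
#' @param mask binary `volume_image`.
#' @return integer label `volume_image` (0 = background, components 1..n).
#' @export
label_components <- function(mask) {
  d <- dim(mask$data)
  lab <- array(0L, d)
  fg <- which(mask$data != 0)
  if (length(fg) == 0L)
    return(volume_image(lab, mask$transform, "label"))
  nxy <- d[1] * d[2]
  in_fg <- array(FALSE, d); in_fg[fg] <- TRUE
  cur <- 0L
  for (s in fg) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      v <- queue
      queue <- integer(0)
      # decode linear indices (1-based) to coordinates
      k <- (v - 1L) %/% nxy
      rem <- (v - 1L) %% nxy
      j <- rem %/% d[1]
      i <- rem %% d[1]
      for (off in 1:6) {
        ii <- i; jj <- j; kk <- k
        if (off == 1) ii <- i - 1L else if (off == 2) ii <- i + 1L
        else if (off == 3) jj <- j - 1L else if (off == 4) jj <- j + 1L
        else if (off == 5) kk <- k - 1L else kk <- k + 1L
        ok <- ii >= 0L & ii < d[1] & jj >= 0L & jj < d[2] & kk >= 0L & kk < d[3]
        if (!any(ok)) next
        nb <- 1L + ii[ok] + jj[ok] * d[1] + kk[ok] * nxy
        nb <- nb[in_fg[nb] & lab[nb] == 0L]
        if (length(nb)) {
          nb <- unique(nb)
          lab[nb] <- cur
          queue <- c(queue, nb)
        }
      }
    }
  }
  volume_image(lab, mask$transform, "label")
}
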