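#' Standardize a PET volume to tumor-to-brain ratios
#'
#' Divides every voxel by the mean tracer activity of the unaffected brain,
#' i.e. the brain mask minus an exclusion mask (typically the composite
#' lesion dilated by one voxel, to guard against partial-volume
#' contamination of the reference).
#'
#' @param pet activity `volume_image`.
#' @param brain_mask binary `volume_image`.
#' @param exclusion_mask binary `volume_image` removed from the reference
#'   region, or `NULL` for none.
#' @return TBR `volume_image`; the reference mean is stored in the
#'   `"reference_mean"` attribute.
#' @export
standardize_tbr <- function(pet, brain_mask, exclusion_mask = NULL) {
  stop_unless_same_grid(pet, list(brain_mask = brain_mask,
                                  exclusion_mask = exclusion_mask))
  ref <- brain_mask$data != 0
  if (!is.null(exclusion_mask)) ref <- ref & exclusion_mask$data == 0
  if (!any(ref))
    stop("standardize_tbr: reference region (brain minus exclusion) is empty")
  ref_mean <- mean(pet$data[ref])
  if (ref_mean <= 0)
    stop("standardize_tbr: reference mean activity must be > 0")
  out <- volume_image(pmax(pet$data / ref_mean, 0), pet$transform, "tbr")
  attr(out, "reference_mean") <- ref_mean
  out
}

#' Segment the metabolically active tumor on a TBR image
#'
#' Thresholds the TBR image at `threshold` (inclusive: a voxel exactly at
#' the threshold is tumor, matching a definition of 1.6 "or more").
#'
#' @param tbr TBR `volume_image`.
#' @param threshold TBR cutoff (default 1.6).
#' @return list with `mask` (binary `volume_image`) and `volume_ml`.
#' @export
segment_pet <- function(tbr, threshold = 1.6) {
  if (tbr$kind != "tbr")
    stop("segment_pet: input must be a TBR image (kind 'tbr')")
  mask <- volume_image(array(as.numeric(tbr$data >= threshold), dim(tbr$data)),
                       tbr$transform, "binary-mask")
  vol <- mask_volume_ml(mask)
  if (vol == 0)
    warning("segment_pet: no voxel reaches the threshold; empty tumor mask")
  list(mask = mask, volume_ml = vol)
}

#' Compose the four lesion masks into a lesion mask set
#'
#' The composite is the voxelwise union of the PET-avid tumor, the
#' contrast-enhancing lesion, the FLAIR hyperintensity and the resection
#' cavity.
#'
#' @param pet_mask,ce_mask,flair_mask,cavity_mask binary `volume_image`s on
#'   one grid.
#' @return a `lesion_mask_set`: the four masks, their union `composite`, and
#'   `volumes_ml`.
#' @export
compose_lesion <- function(pet_mask, ce_mask, flair_mask, cavity_mask) {
  masks <- list(pet_mask = pet_mask, ce_mask = ce_mask,
                flair_mask = flair_mask, cavity_mask = cavity_mask)
  stop_unless_same_grid(pet_mask, masks[-1])
  comp <- array(as.numeric(pet_mask$data != 0 | ce_mask$data != 0 |
                           flair_mask$data != 0 | cavity_mask$data != 0),
                dim(pet_mask$data))
  composite <- volume_image(comp, pet_mask$transform, "binary-mask")
  if (sum(comp) == 0)
    warning("compose_lesion: all lesion masks are empty")
  out <- c(masks, list(composite = composite))
  out$volumes_ml <- vapply(out[c("pet_mask", "ce_mask", "flair_mask",
                                 "cavity_mask", "composite")],
                           mask_volume_ml, numeric(1))
  structure(out, class = "lesion_mask_set")
}

#' @export
print.lesion_mask_set <- function(x, ...) {
  cat("<lesion_mask_set> volumes (mL):\n")
  print(round(x$volumes_ml, 2))
  invisible(x)
}

#' Assign the tumor to a lobe by maximal volumetric overlap
#'
#' Returns the lobe label with the largest voxel overlap with the PET mask.
#' Exact ties are broken deterministically in favor of the lower template
#' label and flagged.  The hemisphere is the sign of the world-space x
#' coordinate of the PET mask's center of gravity relative to the template
#' midline (by default world +x = right, the neurological convention).
#'
#' @param pet_mask binary `volume_image`.
#' @param lobe_template integer label `volume_image` (0 = background).
#' @param lobe_names optional named character vector mapping labels to names.
#' @param x_positive_right if `FALSE`, world +x is interpreted as left.
#' @return list with `lobe`, `hemisphere`, `overlaps` (voxel counts per
#'   lobe), `tie` flag.
#' @export
assign_lobe <- function(pet_mask, lobe_template, lobe_names = NULL,
                        x_positive_right = TRUE) {
  stop_unless_same_grid(pet_mask, list(lobe_template = lobe_template))
  labs <- sort(unique(as.vector(lobe_template$data)))
  labs <- labs[labs != 0]
  counts <- vapply(labs, function(l)
    sum(pet_mask$data != 0 & lobe_template$data == l), numeric(1))
  names(counts) <- if (!is.null(lobe_names)) lobe_names[as.character(labs)]
                   else as.character(labs)
  if (all(counts == 0)) {
    warning("assign_lobe: tumor mask overlaps no lobe; unassigned")
    return(list(lobe = "unassigned", hemisphere = NA_character_,
                overlaps = counts, tie = FALSE))
  }
  win <- which.max(counts)   # first maximum = lowest label wins on ties
  tie <- sum(counts == counts[win]) > 1L
  if (tie)
    warning("assign_lobe: exact overlap tie; lowest template label reported")
  cog <- mask_cog(pet_mask)
  mid <- mean(range(world_coords(pet_mask,
           cbind(c(1, dim(pet_mask$data)[1]), 1, 1))[, 1]))
  right <- (cog[1] > mid) == x_positive_right
  list(lobe = names(counts)[win],
       hemisphere = if (right) "right" else "left",
       overlaps = counts, tie = tie)
}

#' Per-subject PET tumor summary
#'
#' @param tbr TBR `volume_image`.
#' @param pet_mask binary `volume_image` (the segmented tumor).
#' @param lobe_template optional label `volume_image` for lobe assignment.
#' @param lobe_names optional label-to-name map, see [assign_lobe()].
#' @return list with `volume_ml`, `tbr_mean`, `tbr_max`, `lobe`,
#'   `hemisphere`.
#' @export
pet_summary <- function(tbr, pet_mask, lobe_template = NULL,
                        lobe_names = NULL) {
  stop_unless_same_grid(tbr, list(pet_mask = pet_mask))
  sel <- pet_mask$data != 0
  if (!any(sel)) stop("pet_summary: tumor mask is empty")
  loc <- if (!is.null(lobe_template))
    assign_lobe(pet_mask, lobe_template, lobe_names)
  else list(lobe = NA_character_, hemisphere = NA_character_)
  list(volume_ml = mask_volume_ml(pet_mask),
       tbr_mean = mean(tbr$data[sel]),
       tbr_max = max(tbr$data[sel]),
       lobe = loc$lobe, hemisphere = loc$hemisphere)
}
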