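#' Apply the ROI retention rule to an atlas and an omnibus mask
#'
#' A parcel from the atlas is retained for pattern-similarity analysis when
#' it (1) contains at least `min_voxels` voxels -- a floor below which a
#' multi-voxel pattern is too impoverished to correlate -- and (2) has at
#' least a `min_overlap` fraction of its voxels inside the omnibus
#' significance mask (voxels showing condition differences in the
#' univariate F-test, supplied as an input volume). Both boundaries are
#' inclusive. Label 0 is background and never an ROI.
#'
#' @param atlas Integer-labelled parcellation volume (array or flat vector).
#' @param omnibus_mask Binary volume on the same grid.
#' @param min_voxels Minimum parcel size in voxels.
#' @param min_overlap Minimum fraction of parcel voxels inside the mask.
#' @param names Optional named character vector mapping label to region name.
#' @return Data frame ordered by label: `label`, `name`, `n_voxels`,
#'   `overlap_fraction`, `retained`.
#' @export
select_rois <- function(atlas, omnibus_mask, min_voxels = 100L,
                        min_overlap = 0.25, names = NULL) {
  a <- as.integer(as.vector(atlas))
  m <- as.vector(omnibus_mask) != 0
  if (length(a) != length(m)) stop("select_rois: atlas and mask grids differ")
  if (any(a < 0, na.rm = TRUE)) stop("select_rois: atlas labels must be non-negative integers")
  labs <- sort(unique(a[a > 0]))
  if (length(labs) == 0L) stop("select_rois: atlas contains no labelled voxels")
  n_vox <- as.vector(table(factor(a[a > 0], levels = labs)))
  in_mask <- as.vector(tapply(m[a > 0], factor(a[a > 0], levels = labs), sum))
  overlap <- in_mask / n_vox
  data.frame(
    label = labs,
    name = if (is.null(names)) paste0("roi_", labs) else unname(names[as.character(labs)]),
    n_voxels = n_vox,
    overlap_fraction = overlap,
    retained = n_vox >= min_voxels & overlap >= min_overlap
  )
}
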