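# Optional structural MRI backdrop: NIfTI volumes (single .nii or .hdr/.img
# pair), used only for visualization. No resampling; voxel indices are
# 0-based and the affine maps voxel to world mm.

#' Read a structural anatomy volume
#'
#' @param path a `.nii`(.gz) file or the `.hdr` member of an `.hdr`/`.img` pair.
#' @return object of class `tms_anatomy` with `data` (voxel array), `affine`
#'   (4 x 4 voxel-to-world transform, 0-based indexing) and `space`.
#' @export
read_anatomy <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (grepl("\\.hdr$", path, ignore.case = TRUE)) {
    img <- sub("\\.hdr$", ".img", path, ignore.case = TRUE)
    if (!file.exists(img))
      stop(sprintf("missing pair member: '%s' has no matching .img file", path))
  }
  vol <- RNifti::readNifti(path)
  affine <- structure(RNifti::xform(vol), class = NULL)
  if (abs(det(affine[1:3, 1:3])) < 1e-12)
    stop("non-invertible affine in anatomy volume")
  structure(list(data = as.array(vol), affine = unclass(affine),
                 space = "scanner"),
            class = "tms_anatomy")
}

#' Voxel to world coordinates
#'
#' @param anatomy a `tms_anatomy`.
#' @param voxel n x 3 matrix of 0-based voxel indices.
#' @return n x 3 matrix of world coordinates (mm).
#' @export
voxel_to_world <- function(anatomy, voxel) {
  v <- as_points3(voxel)
  out <- cbind(v, 1) %*% t(anatomy$affine)
  out[, 1:3, drop = FALSE]
}
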