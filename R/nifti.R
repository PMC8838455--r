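# NIfTI plumbing: baseline stacks are stored as 4D volumes (X, Y, 1, T),
# masks and parametric maps as single-slice 3D volumes (X, Y, 1).

# read a single-slice volume as an X x Y matrix, tolerating readers that
# drop trailing singleton dimensions
read_slice_nifti <- function(path) {
  vol <- as.array(RNifti::readNifti(path))
  d <- dim(vol)
  matrix(as.numeric(vol), d[1], d[2]) # drop image-header attributes
}

#' Read / write a baseline stack as 4D NIfTI
#'
#' @param stack An `mrf_stack`.
#' @param path `.nii` or `.nii.gz` path.
#' @param mask_path Optional path for the brain mask (3D NIfTI).
#' @return `path` invisibly (`write_stack_nifti`); an `mrf_stack`
#'   (`read_stack_nifti`).
#' @export
write_stack_nifti <- function(stack, path, mask_path = NULL) {
  stopifnot(inherits(stack, "mrf_stack"))
  d <- dim(stack$data)
  RNifti::writeNifti(array(stack$data, c(d[1], d[2], 1L, d[3])), path)
  if (!is.null(mask_path)) {
    RNifti::writeNifti(array(stack$brain_mask, c(d[1], d[2], 1L)), mask_path)
  }
  invisible(path)
}

#' @rdname write_stack_nifti
#' @export
read_stack_nifti <- function(path, mask_path = NULL) {
  vol <- as.array(RNifti::readNifti(path))
  if (length(dim(vol)) != 4L) abort("expected a 4D (X, Y, Z, T) volume.")
  mask <- if (!is.null(mask_path)) read_slice_nifti(mask_path) else NULL
  baseline_stack(array(vol, dim(vol)[c(1, 2, 4)]), brain_mask = mask)
}

#' Write parametric maps as NIfTI volumes
#'
#' Writes `<prefix>_t1.nii.gz` and `<prefix>_t2s.nii.gz` (values in ms).
#'
#' @param maps An `mrf_maps` or `mrf_match`.
#' @param prefix Output path prefix.
#' @return Character vector of the two paths, invisibly.
#' @export
write_maps_nifti <- function(maps, prefix) {
  p1 <- paste0(prefix, "_t1.nii.gz")
  p2 <- paste0(prefix, "_t2s.nii.gz")
  d <- dim(maps$t1_map)
  RNifti::writeNifti(array(maps$t1_map, c(d, 1L)), p1)
  RNifti::writeNifti(array(maps$t2s_map, c(d, 1L)), p2)
  invisible(c(p1, p2))
}

#' Read a pair of parametric maps from NIfTI
#' @param t1_path,t2s_path Paths to 3D NIfTI volumes in ms.
#' @return An `mrf_maps`.
#' @export
read_maps_nifti <- function(t1_path, t2s_path) {
  parametric_maps(read_slice_nifti(t1_path), read_slice_nifti(t2s_path))
}

#' Write a binary mask as 3D NIfTI
#' @param mask `X x Y` binary matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_nifti <- function(mask, path) {
  RNifti::writeNifti(array(as.numeric(mask != 0), c(dim(mask), 1L)), path)
  invisible(path)
}

#' @rdname write_mask_nifti
#' @param ... passed through.
#' @export
read_mask_nifti <- function(path, ...) {
  (read_slice_nifti(path) != 0) + 0L
}
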