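# Volumetric I/O and mask geometry. Voxel indexing is 0-based with respect
# to the affine (NIfTI convention); world coordinates are reached only
# through the affine.

#' Read a NIfTI volume
#'
#' @param path file path to a `.nii`/`.nii.gz` image.
#' @return array (3D or 4D) with the voxel-to-world transform attached as
#'   attribute `"affine"`.
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attr(arr, "affine") <- unclass(RNifti::xform(img))[1:4, 1:4]
  arr
}

#' Write a NIfTI volume
#'
#' @param vol 3D or 4D array.
#' @param path output `.nii` path.
#' @param affine 4x4 voxel-to-world transform (defaults to the array's
#'   `"affine"` attribute, else identity).
#' @return invisibly, `path`.
#' @export
writeVolume <- function(vol, path, affine = NULL) {
  if (is.null(affine)) affine <- attr(vol, "affine")
  if (is.null(affine)) affine <- diag(4)
  img <- RNifti::asNifti(array(as.numeric(vol), dim(vol)))
  RNifti::pixdim(img) <- sqrt(colSums(affine[1:3, 1:3]^2))
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

volumeAffine <- function(vol) {
  a <- attr(vol, "affine")
  if (is.null(a)) diag(4) else a
}

#' Construct a binary volume mask
#'
#' @param data logical/0-1 3D array.
#' @param affine 4x4 voxel-to-world transform.
#' @param space space label.
#' @return a [VolumeMask-class].
#' @export
volumeMask <- function(data, affine = diag(4), space = "study") {
  new("VolumeMask", data = array(as.logical(data), dim(data)),
      affine = affine, space = space)
}

leftRightAxis <- function(affine) {
  w <- abs(affine[1, 1:3])
  j <- which.max(w)
  if (sum(w > 0.5 * max(w)) > 1L)
    stop("ambiguous affine orientation: no single left-right voxel axis")
  j
}

#' Mirror a volume about the midsagittal plane
#'
#' The voxel axis most aligned with the world left-right direction is
#' identified from the affine, the data are reversed along it, and the
#' affine is updated so world coordinates are preserved up to reflection.
#' Applying the flip twice restores data and affine exactly. Used to map
#' right-hemisphere lesions onto the left so all subjects share a lesioned
#' hemisphere.
#'
#' @param vol 3D or 4D array (time last), affine in attribute `"affine"`
#'   or supplied.
#' @param affine optional 4x4 transform overriding the attribute.
#' @return array of the same shape with updated `"affine"` attribute.
#' @export
flipMidsagittal <- function(vol, affine = NULL) {
  if (is.null(affine)) affine <- volumeAffine(vol)
  d <- dim(vol)
  if (!length(d) %in% c(3L, 4L)) stop("vol must be a 3D or 4D array")
  j <- leftRightAxis(affine)
  idx <- lapply(seq_along(d), function(k)
    if (k == j) rev(seq_len(d[k])) else seq_len(d[k]))
  out <- do.call(`[`, c(list(vol), idx, list(drop = FALSE)))
  dim(out) <- d
  newAff <- affine
  newAff[1:3, j] <- -affine[1:3, j]
  newAff[1:3, 4] <- affine[1:3, 4] + affine[1:3, j] * (d[j] - 1)
  attr(out, "affine") <- newAff
  out
}

#' @describeIn flipMidsagittal flip a [VolumeMask-class].
#' @param mask a [VolumeMask-class].
#' @export
flipMaskMidsagittal <- function(mask) {
  flipped <- flipMidsagittal(maskArray(mask) * 1, maskAffine(mask))
  volumeMask(flipped > 0.5, attr(flipped, "affine"), mask@space)
}

#' Lesion overlap map
#'
#' Voxelwise count of subjects lesioned at each voxel.
#'
#' @param masks list of [VolumeMask-class] (or binary arrays) sharing shape
#'   and affine.
#' @return integer 3D array of counts with attribute `"affine"`.
#' @export
lesionOverlap <- function(masks) {
  if (!length(masks)) stop("no masks supplied")
  arrs <- lapply(masks, function(m)
    if (is(m, "VolumeMask")) maskArray(m) * 1L else array(as.integer(m > 0),
                                                          dim(m)))
  affs <- lapply(masks, function(m)
    if (is(m, "VolumeMask")) maskAffine(m) else volumeAffine(m))
  d <- dim(arrs[[1]])
  for (i in seq_along(arrs)) {
    if (!identical(dim(arrs[[i]]), d))
      stop("lesion masks differ in shape")
    if (max(abs(affs[[i]] - affs[[1]])) > 1e-6)
      stop("lesion masks differ in affine")
  }
  out <- Reduce(`+`, arrs)
  attr(out, "affine") <- affs[[1]]
  out
}

#' Mask of the most extreme fraction of loadings
#'
#' Selects exactly `ceiling(fraction * n_valid)` voxels with the most
#' extreme values under the chosen sign rule: `"positive"` ranks by value,
#' `"negative"` by negated value, `"absolute"` by magnitude. Ties are broken
#' by voxel index order (column-major, ascending). Used for the "extreme
#' 10%" analysis masks and "dominant 5%" display masks of network loadings.
#'
#' @param loadings numeric 3D array (or vector) of per-voxel loadings.
#' @param fraction proportion in (0, 1).
#' @param sign `"absolute"` (default), `"positive"`, or `"negative"`.
#' @param validMask optional logical array/vector restricting the eligible
#'   voxels (e.g. in-brain); defaults to all finite voxels.
#' @param affine 4x4 transform for the returned mask.
#' @return a [VolumeMask-class] when `loadings` is 3D, else a logical
#'   vector.
#' @export
topFractionMask <- function(loadings, fraction,
                            sign = c("absolute", "positive", "negative"),
                            validMask = NULL, affine = NULL) {
  sign <- match.arg(sign)
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  if (is.null(affine)) affine <- volumeAffine(loadings)
  v <- as.vector(loadings)
  valid <- if (is.null(validMask)) is.finite(v) else
    as.vector(validMask) & is.finite(v)
  vv <- v[valid]
  if (!length(vv)) stop("no valid voxels")
  if (max(vv) - min(vv) < .Machine$double.eps^0.5 * max(1, abs(max(vv))))
    stop("loading map is constant over valid voxels")
  key <- switch(sign, positive = vv, negative = -vv, absolute = abs(vv))
  if (sign == "positive" && !any(vv > 0))
    stop("no positive loadings under sign = 'positive'")
  if (sign == "negative" && !any(vv < 0))
    stop("no negative loadings under sign = 'negative'")
  n <- ceiling(fraction * length(vv))
  take <- order(-key, seq_along(key))[seq_len(n)]  # ties by voxel index
  sel <- logical(length(v))
  sel[which(valid)[take]] <- TRUE
  if (length(dim(loadings)) == 3L)
    volumeMask(array(sel, dim(loadings)), affine)
  else sel
}

#' Dice similarity coefficient
#'
#' `2|A intersect B| / (|A| + |B|)`, a spatial-overlap index in \[0, 1\];
#' symmetric in its arguments.
#'
#' @param a,b [VolumeMask-class] objects or binary arrays of the same shape.
#' @return numeric scalar in \[0, 1\].
#' @export
dice <- function(a, b) {
  av <- if (is(a, "VolumeMask")) maskArray(a) else a > 0
  bv <- if (is(b, "VolumeMask")) maskArray(b) else b > 0
  if (!identical(dim(av), dim(bv))) stop("masks differ in shape")
  if (is(a, "VolumeMask") && is(b, "VolumeMask") &&
      max(abs(maskAffine(a) - maskAffine(b))) > 1e-6)
    stop("masks differ in affine")
  na <- sum(av); nb <- sum(bv)
  if (na + nb == 0L) stop("both masks are empty")
  2 * sum(av & bv) / (na + nb)
}
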