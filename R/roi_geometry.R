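#' A 3D voxel mask
#'
#' Boolean occupancy grid with physical voxel size and an explicit B0
#' axis. The scanner's main field direction is never inferred from the
#' image orientation: it must be stated (default: third array axis).
#'
#' @param grid A 3D logical (or 0/1 numeric) array.
#' @param voxel_size Length-3 numeric, mm per axis (default 1 mm
#'   isotropic).
#' @param b0_axis Which array axis (1, 2 or 3) points along B0.
#' @param label Optional region name (e.g. "femoral intra-bone graft").
#' @return An object of class `voxel_mask`.
#' @export
voxel_mask <- function(grid, voxel_size = c(1, 1, 1), b0_axis = 3L,
                       label = NULL) {
  if (length(dim(grid)) != 3L) {
    stop("`grid` must be a 3D array", call. = FALSE)
  }
  grid <- array(as.logical(grid), dim = dim(grid))
  if (anyNA(grid)) stop("`grid` contains NA", call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0),
            b0_axis %in% 1:3)
  structure(list(grid = grid, voxel_size = voxel_size,
                 b0_axis = as.integer(b0_axis), label = label),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("<voxel_mask>%s %s, %d voxels, voxel %s mm, B0 axis %d\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              paste(dim(x$grid), collapse = "x"), sum(x$grid),
              paste(x$voxel_size, collapse = "x"), x$b0_axis))
  invisible(x)
}

n_voxels <- function(mask) sum(mask$grid)

check_same_grid <- function(a, b) {
  if (!identical(dim(a$grid), dim(b$grid)) ||
      !isTRUE(all.equal(a$voxel_size, b$voxel_size))) {
    stop("masks/volumes are not on the same grid", call. = FALSE)
  }
}

#' ROI-mean decay curve from per-echo volumes
#'
#' Averages the signal over the mask voxels in each echo volume,
#' producing the ROI-level curve the abbreviated paradigm fits (ROI
#' averaging before fitting, not voxel-wise mapping).
#'
#' @param volumes List of 3D numeric arrays, one per echo, same grid as
#'   `mask`, ordered as `schedule$all_tes`.
#' @param mask A non-empty `voxel_mask`.
#' @param schedule An `echo_schedule` (or preset name) whose pooled echo
#'   count matches `length(volumes)`.
#' @return A `decay_curve` at the schedule's pooled echo times.
#' @export
roi_mean_curve <- function(volumes, mask, schedule) {
  stopifnot(inherits(mask, "voxel_mask"))
  schedule <- as_schedule(schedule)
  if (length(volumes) != length(schedule$all_tes)) {
    stop("need one volume per echo time (", length(schedule$all_tes),
         ")", call. = FALSE)
  }
  if (n_voxels(mask) == 0L) stop("empty mask", call. = FALSE)
  idx <- which(mask$grid)
  sig <- vapply(volumes, function(v) {
    if (!identical(dim(v), dim(mask$grid))) {
      stop("volume grid does not match mask grid", call. = FALSE)
    }
    mean(v[idx])
  }, numeric(1))
  decay_curve(schedule$all_tes, sig, schedule)
}

# Integer lattice offsets within a Euclidean ball of radius `radius_mm`,
# excluding the origin, for the given anisotropic voxel size.
ball_offsets <- function(radius_mm, voxel_size) {
  r <- floor(radius_mm / voxel_size)
  off <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  d2 <- (off$dx * voxel_size[1])^2 + (off$dy * voxel_size[2])^2 +
        (off$dz * voxel_size[3])^2
  off[d2 <= radius_mm^2 + 1e-9 & d2 > 0, , drop = FALSE]
}

#' Grow the graft/bone interface shell around an ROI
#'
#' Dilates the mask by a Euclidean ball of physical radius `radius_mm`
#' (2 mm by default, i.e. 2 voxels at 1 mm isotropic) and removes the
#' original voxels, yielding the interface shell used to assess
#' tendon-to-bone healing around intra-bone graft ROIs. The result is
#' disjoint from the input by construction. Dilation is 3D by default;
#' `in_plane` restricts growth to the two axes orthogonal to the B0 axis.
#'
#' @param graft A non-empty `voxel_mask`.
#' @param radius_mm Dilation radius (mm), >= the smallest voxel dimension.
#' @param in_plane If TRUE, dilate only within slices.
#' @return A `voxel_mask` of the interface shell.
#' @export
grow_interface <- function(graft, radius_mm = 2, in_plane = FALSE) {
  stopifnot(inherits(graft, "voxel_mask"))
  if (n_voxels(graft) == 0L) stop("empty mask", call. = FALSE)
  if (radius_mm < min(graft$voxel_size)) {
    stop("`radius_mm` must be at least one voxel", call. = FALSE)
  }
  off <- ball_offsets(radius_mm, graft$voxel_size)
  if (in_plane) off <- off[off[[graft$b0_axis]] == 0, , drop = FALSE]
  dm <- dim(graft$grid)
  seeds <- which(graft$grid, arr.ind = TRUE)
  dil <- array(FALSE, dm)
  for (k in seq_len(nrow(off))) {
    i <- seeds[, 1] + off$dx[k]
    j <- seeds[, 2] + off$dy[k]
    l <- seeds[, 3] + off$dz[k]
    ok <- i >= 1 & i <= dm[1] & j >= 1 & j <= dm[2] & l >= 1 & l <= dm[3]
    dil[cbind(i[ok], j[ok], l[ok])] <- TRUE
  }
  dil[graft$grid] <- FALSE
  voxel_mask(dil, graft$voxel_size, graft$b0_axis,
             label = if (!is.null(graft$label)) {
               paste(graft$label, "interface")
             })
}

#' Orientation of an ROI relative to B0
#'
#' Computes the centroid of the mask in each slice perpendicular to the
#' slice axis (default: the B0 axis, so centroids live in the x-y plane),
#' fits a 3D line through the centroids by total least squares (principal
#' axis of the centroid cloud), and returns the angle between that line
#' and the B0 direction, folded into [0, 90] degrees. This is the angle
#' relevant to the magic-angle dependence of T2* in ordered collagen.
#'
#' @param mask A `voxel_mask` spanning at least 2 slices along the slice
#'   axis.
#' @param slice_axis Axis along which slices are taken (default: the
#'   mask's B0 axis).
#' @return Angle in degrees, in [0, 90].
#' @export
angle_to_b0 <- function(mask, slice_axis = mask$b0_axis) {
  stopifnot(inherits(mask, "voxel_mask"))
  vox <- which(mask$grid, arr.ind = TRUE)
  if (nrow(vox) == 0L) stop("empty mask", call. = FALSE)
  slices <- sort(unique(vox[, slice_axis]))
  if (length(slices) < 2L) {
    stop("mask must span >= 2 slices along axis ", slice_axis,
         call. = FALSE)
  }
  cent <- t(vapply(slices, function(s) {
    colMeans(vox[vox[, slice_axis] == s, , drop = FALSE])
  }, numeric(3)))
  # physical coordinates (mm)
  cent <- sweep(cent, 2, mask$voxel_size, `*`)
  dir <- stats::prcomp(cent, center = TRUE)$rotation[, 1]
  b0 <- c(0, 0, 0); b0[mask$b0_axis] <- 1
  cosang <- abs(sum(dir * b0)) / sqrt(sum(dir^2))
  acos(min(max(cosang, -1), 1)) * 180 / pi
}

#' Dice similarity coefficient between two masks
#'
#' 2|A n B| / (|A| + |B|); 1 for identical masks, 0 for disjoint ones.
#' Used to quantify intra-rater ROI placement reliability.
#'
#' @param a,b `voxel_mask` objects on the same grid, not both empty.
#' @return Dice coefficient in [0, 1].
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "voxel_mask"), inherits(b, "voxel_mask"))
  check_same_grid(a, b)
  na <- n_voxels(a); nb <- n_voxels(b)
  if (na + nb == 0L) stop("both masks are empty", call. = FALSE)
  2 * sum(a$grid & b$grid) / (na + nb)
}

#' Intra-rater relative error between two repeated estimates
#'
#' Symmetric relative percent difference per parameter:
#' |x1 - x2| / mean(x1, x2) x 100, for the corrected T2s* and f_bw
#' obtained from two independent ROI placements of the same region.
#'
#' @param est1,est2 `corrected_estimate` objects (or lists with positive
#'   scalar `t2s` and `f_bw`).
#' @return Named numeric vector with elements `t2s_pct` and `f_bw_pct`.
#' @export
intra_rater_error <- function(est1, est2) {
  vals <- function(e) {
    if (is.null(e$t2s) || is.null(e$f_bw)) {
      stop("estimates must carry `t2s` and `f_bw`", call. = FALSE)
    }
    c(e$t2s, e$f_bw)
  }
  v1 <- vals(est1); v2 <- vals(est2)
  if (any(v1 <= 0) || any(v2 <= 0)) {
    stop("estimates must be positive", call. = FALSE)
  }
  out <- abs(v1 - v2) / ((v1 + v2) / 2) * 100
  names(out) <- c("t2s_pct", "f_bw_pct")
  out
}

#' Read / write voxel masks and volumes as NIfTI
#'
#' Masks are stored as 0/1 volumes; the image affine is preserved on
#' read/write but all internal coordinates are voxel-indexed. The B0 axis
#' is metadata supplied by the caller, never inferred from the header.
#'
#' @param path NIfTI file path (.nii or .nii.gz).
#' @param voxel_size,b0_axis,label See [voxel_mask()]; `voxel_size`
#'   defaults to the header's pixdim.
#' @return `read_mask_nifti` returns a `voxel_mask`; `write_mask_nifti`
#'   and `write_volume_nifti` return `path` invisibly;
#'   `read_volume_nifti` returns a 3D numeric array with attribute
#'   `voxel_size`.
#' @export
read_mask_nifti <- function(path, voxel_size = NULL, b0_axis = 3L,
                            label = NULL) {
  img <- RNifti::readNifti(path)
  if (is.null(voxel_size)) {
    voxel_size <- RNifti::pixdim(img)[1:3]
  }
  voxel_mask(array(as.array(img) > 0.5, dim = dim(img)[1:3]),
             voxel_size = voxel_size, b0_axis = b0_axis, label = label)
}

#' @rdname read_mask_nifti
#' @param mask A `voxel_mask`.
#' @export
write_mask_nifti <- function(mask, path) {
  stopifnot(inherits(mask, "voxel_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$grid), dim(mask$grid)),
                         pixdim = mask$voxel_size)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_mask_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim = dim(img)[1:3])
  attr(out, "voxel_size") <- RNifti::pixdim(img)[1:3]
  out
}

#' @rdname read_mask_nifti
#' @param volume A 3D numeric array.
#' @export
write_volume_nifti <- function(volume, path, voxel_size = c(1, 1, 1)) {
  img <- RNifti::asNifti(volume, pixdim = voxel_size)
  RNifti::writeNifti(img, path)
  invisible(path)
}
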