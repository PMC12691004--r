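# ROI construction and DVH computation. All masks live on the CT grid.

shift_array <- function(a, dx, dy, dz, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, dim = d)
  sx <- seq_len(d[1]); sy <- seq_len(d[2]); sz <- seq_len(d[3])
  fx <- sx - dx; fy <- sy - dy; fz <- sz - dz
  okx <- fx >= 1 & fx <= d[1]; oky <- fy >= 1 & fy <= d[2]; okz <- fz >= 1 & fz <= d[3]
  out[sx[okx], sy[oky], sz[okz]] <- a[fx[okx], fy[oky], fz[okz]]
  out
}

# 6-connected component labelling by minimum-label propagation with raster
# sweeps (forward/backward along each axis until stable), which converges in
# a handful of passes on anatomical shapes.
label_components_6 <- function(mask) {
  d <- dim(mask)
  lab <- array(0, dim = d)
  lab[mask] <- which(mask)
  sweep_axis <- function(lab, axis, forward) {
    n <- d[axis]
    idx <- if (forward) 2:n else (n - 1):1
    for (i in idx) {
      j <- if (forward) i - 1 else i + 1
      cur <- slice_get(lab, axis, i); prv <- slice_get(lab, axis, j)
      mcur <- slice_get(mask, axis, i); mprv <- slice_get(mask, axis, j)
      upd <- mcur & mprv & prv > 0 & (cur == 0 | prv < cur)
      if (any(upd)) {
        cur[upd] <- prv[upd]
        lab <- slice_set(lab, axis, i, cur)
      }
    }
    lab
  }
  repeat {
    old <- lab
    for (axis in 1:3) {
      lab <- sweep_axis(lab, axis, TRUE)
      lab <- sweep_axis(lab, axis, FALSE)
    }
    if (identical(old, lab)) break
  }
  lab
}

slice_get <- function(a, axis, i) {
  d <- dim(a)
  m <- switch(axis, a[i, , , drop = FALSE], a[, i, , drop = FALSE],
              a[, , i, drop = FALSE])
  dim(m) <- d[-axis]
  m
}
slice_set <- function(a, axis, i, v) {
  switch(axis, a[i, , ] <- v, a[, i, ] <- v, a[, , i] <- v)
  a
}

# Fill internal holes slice-wise: background connected to the slice border
# stays background, everything else becomes foreground. Boolean propagation
# with in-plane raster sweeps.
fill_holes_slicewise <- function(mask) {
  d <- dim(mask)
  bg <- !mask
  outside <- array(FALSE, dim = d)
  outside[1, , ] <- bg[1, , ]; outside[d[1], , ] <- bg[d[1], , ]
  outside[, 1, ] <- outside[, 1, ] | bg[, 1, ]
  outside[, d[2], ] <- outside[, d[2], ] | bg[, d[2], ]
  repeat {
    old <- outside
    for (i in 2:d[1]) outside[i, , ] <- outside[i, , ] | (outside[i - 1, , ] & bg[i, , ])
    for (i in (d[1] - 1):1) outside[i, , ] <- outside[i, , ] | (outside[i + 1, , ] & bg[i, , ])
    for (i in 2:d[2]) outside[, i, ] <- outside[, i, ] | (outside[, i - 1, ] & bg[, i, ])
    for (i in (d[2] - 1):1) outside[, i, ] <- outside[, i, ] | (outside[, i + 1, ] & bg[, i, ])
    if (identical(old, outside)) break
  }
  !outside
}

#' Segment the patient body from a CT grid
#'
#' Thresholds the CT at `hu_threshold`, keeps the largest 6-connected 3-D
#' component and fills internal holes per slice (so low-density interior
#' structures such as lung stay inside the body).
#'
#' @param ct an [image_grid()] in HU.
#' @param hu_threshold threshold in HU separating body from air (default -300).
#' @return A [structure_mask()] named "body".
#' @export
build_body_mask <- function(ct, hu_threshold = -300) {
  stopifnot(is_image_grid(ct))
  fg <- ct$values > hu_threshold
  if (!any(fg)) stop("no body found above ", hu_threshold, " HU")
  lab <- label_components_6(fg)
  tab <- tabulate(lab[lab > 0])
  keep <- lab == which.max(tab)
  structure_mask("body", fill_holes_slicewise(keep), ct)
}

#' Exact anisotropic squared Euclidean distance transform
#'
#' For every voxel, the squared distance (mm^2) from its centre to the centre
#' of the nearest voxel where `from` is TRUE. Computed by the separable 1-D
#' transform applied per axis, each axis evaluated as an exact minimum over
#' all shifts (vectorised over the rest of the array).
#'
#' @param from logical 3-D array of source voxels.
#' @param spacing voxel spacing in mm per axis.
#' @param max_mm optional cap: distances beyond it are left at Inf, which
#'   bounds the per-axis shift range and speeds up shallow transforms.
#' @return Numeric array of squared distances (Inf where no source exists or
#'   beyond `max_mm`).
#' @export
distance_sq_mm <- function(from, spacing, max_mm = Inf) {
  d <- dim(from)
  f <- array(Inf, dim = d)
  f[from] <- 0
  for (axis in 1:3) {
    n <- d[axis]
    if (n == 1) next
    s2 <- spacing[axis]^2
    kmax <- min(n - 1, if (is.finite(max_mm)) ceiling(max_mm / spacing[axis]) else n - 1)
    g <- f
    for (k in seq_len(kmax)) {
      pen <- s2 * k^2
      sh <- c(0, 0, 0); sh[axis] <- k
      g <- pmin(g, shift_array(f, sh[1], sh[2], sh[3], fill = Inf) + pen)
      sh[axis] <- -k
      g <- pmin(g, shift_array(f, sh[1], sh[2], sh[3], fill = Inf) + pen)
    }
    f <- g
  }
  f
}

#' Build the 5 mm subcutaneous skin layer
#'
#' Voxels inside the body whose centre lies within `depth_mm` (anisotropic
#' Euclidean distance, voxel centre to voxel centre) of the nearest non-body
#' voxel. A body thinner than `depth_mm` everywhere saturates to the whole
#' body.
#'
#' @param body a body [structure_mask()].
#' @param spacing voxel spacing in mm per axis.
#' @param depth_mm depth of the subcutaneous layer (default 5 mm).
#' @return A [structure_mask()] named "skin5mm".
#' @export
build_skin5mm <- function(body, spacing, depth_mm = 5) {
  b <- mask_array(body)
  if (!any(b)) return(structure_mask("skin5mm", array(FALSE, dim(b))))
  d2 <- distance_sq_mm(!b, spacing, max_mm = depth_mm + max(spacing))
  structure_mask("skin5mm", b & d2 <= depth_mm^2 + 1e-9)
}

#' Resample a dose grid onto the CT grid by trilinear interpolation
#'
#' Dose is interpolated at every CT voxel centre; CT voxels outside the dose
#' grid's extent get 0 Gy. Trilinear interpolation reproduces affine dose
#' fields exactly.
#'
#' @param dose an [image_grid()] of dose in Gy (its own grid).
#' @param ct the reference CT [image_grid()].
#' @return An [image_grid()] of dose on the CT grid.
#' @export
resample_dose_to_ct <- function(dose, ct) {
  stopifnot(is_image_grid(dose), is_image_grid(ct))
  dd <- dim(dose$values); dc <- dim(ct$values)
  # continuous voxel index of each CT-axis coordinate in the dose grid
  idx <- lapply(1:3, function(a) {
    (grid_axis_mm(ct, a) - dose$origin[a]) / dose$spacing[a] + 1
  })
  if (all(idx[[1]] < 1 | idx[[1]] > dd[1]) ||
      all(idx[[2]] < 1 | idx[[2]] > dd[2]) ||
      all(idx[[3]] < 1 | idx[[3]] > dd[3]))
    stop("no overlap between dose and CT extents")
  lo <- lapply(1:3, function(a) pmin(pmax(floor(idx[[a]]), 1), dd[a] - 1))
  fr <- lapply(1:3, function(a) idx[[a]] - lo[[a]])
  inb <- lapply(1:3, function(a) idx[[a]] >= 1 - 1e-9 & idx[[a]] <= dd[a] + 1e-9)
  # clamp fractional part at the borders so exact-edge samples stay exact
  fr <- lapply(1:3, function(a) pmin(pmax(fr[[a]], 0), 1))
  X <- array(0, dim = dc)
  v <- dose$values
  ax <- lo[[1]]; ay <- lo[[2]]; az <- lo[[3]]
  fx <- fr[[1]]; fy <- fr[[2]]; fz <- fr[[3]]
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    w <- outer(outer(if (cx) fx else 1 - fx, if (cy) fy else 1 - fy),
               if (cz) fz else 1 - fz)
    X <- X + w * v[ax + cx, ay + cy, az + cz, drop = FALSE]
  }
  inside <- outer(outer(inb[[1]], inb[[2]], "&"), inb[[3]], "&")
  X[!inside] <- 0
  image_grid(X, ct$spacing, ct$origin, ct$frame_id)
}

#' Build the dose-guided skin ROI (skin layer receiving >= 10% of prescription)
#'
#' The intersection of the subcutaneous skin layer with the region receiving
#' at least `fraction` of the prescription dose (5 Gy for the standard 50 Gy
#' prescription). The dose threshold is inclusive.
#'
#' @param skin5mm skin-layer [structure_mask()].
#' @param dose_on_ct dose [image_grid()] already resampled to the CT grid.
#' @param prescription prescription dose in Gy.
#' @param fraction threshold as a fraction of prescription, in (0, 1].
#' @return A [structure_mask()] named "v5gy".
#' @export
build_v5gy_roi <- function(skin5mm, dose_on_ct, prescription, fraction = 0.10) {
  if (fraction <= 0 || fraction > 1) stop("invalid fraction: must be in (0,1]")
  s <- mask_array(skin5mm)
  if (!identical(dim(s), dim(dose_on_ct$values))) stop("grid mismatch")
  structure_mask("v5gy", s & dose_on_ct$values >= fraction * prescription)
}

#' Assemble the full ROI set for one patient
#'
#' @param ct CT [image_grid()].
#' @param dose_on_ct dose on the CT grid.
#' @param ptv PTV [structure_mask()].
#' @param prescription prescription dose in Gy.
#' @param hu_threshold body threshold in HU.
#' @param depth_mm skin-layer depth in mm.
#' @return List with masks body, skin5mm, ptv, ptv100_region, isodose5, v5gy.
#' @export
build_roi_set <- function(ct, dose_on_ct, ptv, prescription = 50,
                          hu_threshold = -300, depth_mm = 5) {
  body <- build_body_mask(ct, hu_threshold)
  skin <- build_skin5mm(body, ct$spacing, depth_mm)
  iso5 <- structure_mask("isodose5", dose_on_ct$values >= 0.10 * prescription)
  v5 <- build_v5gy_roi(skin, dose_on_ct, prescription)
  ptv100 <- structure_mask("ptv100_region",
                           mask_array(ptv) & dose_on_ct$values >= prescription)
  list(body = body, skin5mm = skin, ptv = ptv, ptv100_region = ptv100,
       isodose5 = iso5, v5gy = v5)
}

#' Dose-volume histogram features for the skin layer and PTV
#'
#' Computes the 12 DVH parameters used as the `dvh` feature block: absolute
#' volumes (cc) of the skin layer receiving >= 5, 10, ..., 50 Gy, and the PTV
#' sub-volumes receiving >= 100% and >= 105% of the prescription dose. All
#' thresholds are inclusive.
#'
#' @param dose_on_ct dose [image_grid()] on the CT grid.
#' @param rois list with at least `skin5mm` and `ptv` masks (see
#'   [build_roi_set()]).
#' @param prescription prescription dose in Gy (default 50).
#' @return Named numeric vector of 12 DVH features (cc).
#' @export
compute_dvh_features <- function(dose_on_ct, rois, prescription = 50) {
  vv <- voxel_volume_cc(dose_on_ct)
  skin <- mask_array(rois$skin5mm); ptv <- mask_array(rois$ptv)
  if (!identical(dim(skin), dim(dose_on_ct$values)) ||
      !identical(dim(ptv), dim(dose_on_ct$values))) stop("grid mismatch")
  dsk <- dose_on_ct$values[skin]
  dpt <- dose_on_ct$values[ptv]
  lv <- seq(5, 50, by = 5)
  v <- vapply(lv, function(x) vv * sum(dsk >= x), 0)
  names(v) <- paste0("dvh_skin5mm_V", lv, "Gy")
  c(v,
    dvh_ptv100 = vv * sum(dpt >= prescription),
    dvh_ptv105 = vv * sum(dpt >= 1.05 * prescription))
}
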