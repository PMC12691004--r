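#' Axis-aligned 3-D scalar grid
#'
#' The basic spatial container of the package: a 3-D array of scalar values
#' (HU for CT, Gy for dose) on an axis-aligned grid, with voxel spacing in mm
#' per axis and the world-mm coordinate of the centre of voxel (1,1,1) as the
#' origin. Grids are restricted to identity orientation; oblique acquisitions
#' are rejected at the I/O boundary.
#'
#' @param values 3-D numeric array, all values finite.
#' @param spacing numeric length-3, mm per axis (x, y, z), all positive.
#' @param origin numeric length-3, world mm of the centre of voxel (1,1,1).
#' @param frame_id character scalar identifying the frame of reference.
#' @return An object of class `image_grid`.
#' @export
image_grid <- function(values, spacing, origin = c(0, 0, 0),
                       frame_id = "frame-1") {
  if (length(dim(values)) != 3L) stop("values must be a 3-D array")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive reals")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite reals")
  if (any(!is.finite(values))) stop("grid values must be finite")
  structure(
    list(values = values, spacing = as.numeric(spacing),
         origin = as.numeric(origin), frame_id = as.character(frame_id)),
    class = "image_grid"
  )
}

#' @export
print.image_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<image_grid %dx%dx%d, spacing (%g, %g, %g) mm, origin (%g, %g, %g)>\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

is_image_grid <- function(x) inherits(x, "image_grid")

#' Volume of one voxel in cubic centimetres
#'
#' @param grid an [image_grid()].
#' @return Scalar voxel volume in cc (`prod(spacing)/1000`).
#' @export
voxel_volume_cc <- function(grid) {
  stopifnot(is_image_grid(grid))
  prod(grid$spacing) / 1000
}

#' World-mm coordinates of voxel centres along one axis
#'
#' @param grid an [image_grid()].
#' @param axis 1, 2 or 3.
#' @return Numeric vector of voxel-centre coordinates in mm.
#' @export
grid_axis_mm <- function(grid, axis) {
  stopifnot(is_image_grid(grid), axis %in% 1:3)
  grid$origin[axis] + (seq_len(dim(grid$values)[axis]) - 1) * grid$spacing[axis]
}

#' Named binary mask congruent with a reference grid
#'
#' @param name structure name.
#' @param mask logical or 0/1 array.
#' @param ref optional reference [image_grid()]; if given, shapes must match.
#' @return An object of class `structure_mask` whose `$mask` is logical.
#' @export
structure_mask <- function(name, mask, ref = NULL) {
  if (is.numeric(mask)) {
    if (!all(mask %in% c(0, 1))) stop("mask values must be 0/1")
    mask <- array(mask != 0, dim = dim(mask))
  }
  if (!is.logical(mask) || length(dim(mask)) != 3L)
    stop("mask must be a 3-D logical (or 0/1) array")
  if (!is.null(ref)) {
    stopifnot(is_image_grid(ref))
    if (!identical(dim(mask), dim(ref$values)))
      stop("mask shape must equal reference grid shape")
  }
  structure(list(name = as.character(name), mask = mask),
            class = "structure_mask")
}

is_structure_mask <- function(x) inherits(x, "structure_mask")

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask '%s', %d voxels>\n", x$name, sum(x$mask)))
  invisible(x)
}

mask_array <- function(x) {
  if (is_structure_mask(x)) x$mask else x
}
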