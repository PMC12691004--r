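# Minimal DICOM reader/writer (explicit VR, little endian) covering the three
# RT objects the pipeline consumes: CT image slices, RT-DOSE grids and
# RT-STRUCT contour sets. This is a purpose-built subset codec: it writes
# standards-shaped files for the synthetic cohort and reads the same subset
# back; it is not a general DICOM toolkit.

UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

uint16_le <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
uint32_le <- function(x) {
  # writeBin has no unsigned 32-bit; values used here stay < 2^31
  writeBin(as.integer(x), raw(), size = 4, endian = "little")
}

pad_even <- function(b, pad = as.raw(0x20)) {
  if (length(b) %% 2 == 1) c(b, pad) else b
}

# --- element constructors (raw byte encodings) -------------------------------

el_raw <- function(group, elem, vr, bytes) {
  long <- vr %in% c("OB", "OW", "OF", "SQ", "UN", "UT")
  hdr <- c(uint16_le(group), uint16_le(elem), charToRaw(vr))
  if (long) {
    c(hdr, as.raw(c(0, 0)), uint32_le(length(bytes)), bytes)
  } else {
    if (length(bytes) > 65534) stop("value too long for short VR")
    c(hdr, uint16_le(length(bytes)), bytes)
  }
}

el_str <- function(group, elem, vr, s) {
  pad <- if (vr == "UI") as.raw(0) else as.raw(0x20)
  el_raw(group, elem, vr, pad_even(charToRaw(paste(s, collapse = "\\")), pad))
}

el_us <- function(group, elem, v) el_raw(group, elem, "US", uint16_le(v))

el_ds <- function(group, elem, v) {
  el_str(group, elem, "DS", format(v, digits = 12, trim = TRUE, scientific = FALSE))
}

el_is <- function(group, elem, v) el_str(group, elem, "IS", format(as.integer(v)))

el_sq <- function(group, elem, items) {
  body <- raw(0)
  for (it in items) {
    content <- do.call(c, it)
    body <- c(body, uint16_le(0xFFFE), uint16_le(0xE000),
              uint32_le(length(content)), content)
  }
  el_raw(group, elem, "SQ", body)
}

dcm_uid <- function(...) paste0("2.25.", paste(..., sep = "."))

dcm_write_file <- function(path, dataset_elems, sop_class, sop_instance) {
  meta <- list(
    el_raw(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    el_str(0x0002, 0x0002, "UI", sop_class),
    el_str(0x0002, 0x0003, "UI", sop_instance),
    el_str(0x0002, 0x0010, "UI", UID_EXPLICIT_LE),
    el_str(0x0002, 0x0012, "UI", "2.25.999.1")
  )
  meta_body <- do.call(c, meta)
  group_len <- el_raw(0x0002, 0x0000, "UL", uint32_le(length(meta_body)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(group_len, meta_body, do.call(c, dataset_elems)), con)
  invisible(path)
}

# --- generic parser -----------------------------------------------------------

LONG_VRS <- c("OB", "OW", "OF", "SQ", "UN", "UT")

parse_elements <- function(bytes, pos, end) {
  out <- list()
  while (pos < end) {
    grp <- readBin(bytes[pos:(pos + 1)], "integer", size = 2, signed = FALSE,
                   endian = "little")
    ele <- readBin(bytes[(pos + 2):(pos + 3)], "integer", size = 2,
                   signed = FALSE, endian = "little")
    vr <- rawToChar(bytes[(pos + 4):(pos + 5)])
    if (vr %in% LONG_VRS) {
      len <- readBin(bytes[(pos + 8):(pos + 11)], "integer", size = 4,
                     endian = "little")
      vstart <- pos + 12
    } else {
      len <- readBin(bytes[(pos + 6):(pos + 7)], "integer", size = 2,
                     signed = FALSE, endian = "little")
      vstart <- pos + 8
    }
    if (len < 0) stop("undefined element lengths are not supported")
    key <- sprintf("%04X%04X", grp, ele)
    if (vr == "SQ") {
      out[[key]] <- list(vr = vr, items = parse_sequence(bytes, vstart, vstart + len))
    } else {
      val <- if (len > 0) bytes[vstart:(vstart + len - 1)] else raw(0)
      out[[key]] <- list(vr = vr, value = val)
    }
    pos <- vstart + len
  }
  out
}

parse_sequence <- function(bytes, pos, end) {
  items <- list()
  while (pos < end) {
    grp <- readBin(bytes[pos:(pos + 1)], "integer", size = 2, signed = FALSE,
                   endian = "little")
    ele <- readBin(bytes[(pos + 2):(pos + 3)], "integer", size = 2,
                   signed = FALSE, endian = "little")
    if (grp != 0xFFFE || ele != 0xE000) stop("malformed sequence item")
    len <- readBin(bytes[(pos + 4):(pos + 7)], "integer", size = 4,
                   endian = "little")
    if (len < 0) stop("undefined item lengths are not supported")
    items[[length(items) + 1]] <- parse_elements(bytes, pos + 8, pos + 8 + len)
    pos <- pos + 8 + len
  }
  items
}

dcm_read_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 132 || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM file: ", path)
  parse_elements(bytes, 133, length(bytes) + 1)
}

ds_str <- function(ds, key) {
  e <- ds[[key]]
  if (is.null(e)) return(NULL)
  trimws(gsub("\\x00", "", rawToChar(e$value), useBytes = TRUE))
}

ds_nums <- function(ds, key) {
  s <- ds_str(ds, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

ds_us <- function(ds, key) {
  e <- ds[[key]]
  if (is.null(e)) return(NULL)
  readBin(e$value, "integer", size = 2, signed = FALSE, endian = "little")
}

# --- CT series ----------------------------------------------------------------

#' Write an image grid as a DICOM CT series (one file per slice)
#'
#' Pixel values are stored as unsigned 16-bit with rescale slope 1 and
#' intercept -1024, i.e. stored = HU + 1024. HU values must therefore lie in
#' [-1024, 64511].
#'
#' @param grid an [image_grid()] of CT values in HU.
#' @param directory output directory (created if missing).
#' @param patient_id identifier written into file names.
#' @return Invisibly, the vector of file paths written.
#' @export
write_ct_series <- function(grid, directory, patient_id = "anon") {
  stopifnot(is_image_grid(grid))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  d <- dim(grid$values)
  stored <- round(grid$values) + 1024
  if (any(stored < 0 | stored > 65535)) stop("HU out of storable range")
  series_uid <- dcm_uid("11", patient_id)
  zs <- grid_axis_mm(grid, 3)
  paths <- character(d[3])
  for (iz in seq_len(d[3])) {
    slice <- stored[, , iz]
    elems <- list(
      el_str(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.2"),
      el_str(0x0008, 0x0018, "UI", dcm_uid("12", patient_id, iz)),
      el_str(0x0008, 0x0060, "CS", "CT"),
      el_str(0x0020, 0x000D, "UI", dcm_uid("10", patient_id)),
      el_str(0x0020, 0x000E, "UI", series_uid),
      el_is(0x0020, 0x0013, iz),
      el_ds(0x0020, 0x0032, c(grid$origin[1], grid$origin[2], zs[iz])),
      el_ds(0x0020, 0x0037, c(1, 0, 0, 0, 1, 0)),
      el_str(0x0020, 0x0052, "UI", grid$frame_id),
      el_us(0x0028, 0x0002, 1),
      el_us(0x0028, 0x0010, d[2]),  # Rows
      el_us(0x0028, 0x0011, d[1]),  # Columns
      el_ds(0x0028, 0x0030, c(grid$spacing[2], grid$spacing[1])),
      el_ds(0x0018, 0x0050, grid$spacing[3]),
      el_us(0x0028, 0x0100, 16), el_us(0x0028, 0x0101, 16),
      el_us(0x0028, 0x0102, 15), el_us(0x0028, 0x0103, 0),
      el_ds(0x0028, 0x1052, -1024),
      el_ds(0x0028, 0x1053, 1),
      el_raw(0x7FE0, 0x0010, "OW",
             writeBin(as.integer(slice), raw(), size = 2, endian = "little"))
    )
    paths[iz] <- file.path(directory, sprintf("ct_%s_%03d.dcm", patient_id, iz))
    dcm_write_file(paths[iz], elems, "1.2.840.10008.5.1.4.1.1.2",
                   dcm_uid("12", patient_id, iz))
  }
  invisible(paths)
}

#' Read a DICOM CT series from a directory
#'
#' Slices are sorted by their z position (ImagePositionPatient) regardless of
#' file order; pixel values are converted to HU with the per-file rescale
#' slope and intercept.
#'
#' @param directory directory containing `.dcm` CT slices of one series.
#' @return An [image_grid()] in HU.
#' @export
read_ct_series <- function(directory) {
  files <- list.files(directory, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) < 2) stop("inconsistent series: need >= 2 CT slices")
  slices <- lapply(files, dcm_read_file)
  mods <- vapply(slices, function(s) ds_str(s, "00080060"), "")
  slices <- slices[mods == "CT"]
  if (length(slices) < 2) stop("inconsistent series: need >= 2 CT slices")
  uids <- vapply(slices, function(s) ds_str(s, "0020000E"), "")
  if (length(unique(uids)) != 1) stop("multiple series in directory")
  orient <- ds_nums(slices[[1]], "00200037")
  if (!is.null(orient) && any(abs(orient - c(1, 0, 0, 0, 1, 0)) > 1e-6))
    stop("oblique acquisitions are not supported")
  zs <- vapply(slices, function(s) ds_nums(s, "00200032")[3], 0)
  if (anyDuplicated(zs)) stop("inconsistent series: duplicate slice positions")
  ord <- order(zs)
  slices <- slices[ord]; zs <- zs[ord]
  dz <- diff(zs)
  if (length(dz) && (max(dz) - min(dz)) > 1e-4 * max(dz))
    stop("inconsistent series: missing slices (non-uniform spacing)")
  rows <- ds_us(slices[[1]], "00280010")
  cols <- ds_us(slices[[1]], "00280011")
  ps <- ds_nums(slices[[1]], "00280030")  # row spacing, col spacing
  vals <- array(0, dim = c(cols, rows, length(slices)))
  for (i in seq_along(slices)) {
    slope <- ds_nums(slices[[i]], "00281053"); if (is.null(slope)) slope <- 1
    inter <- ds_nums(slices[[i]], "00281052"); if (is.null(inter)) inter <- 0
    px <- readBin(slices[[i]][["7FE00010"]]$value, "integer",
                  n = rows * cols, size = 2, signed = FALSE, endian = "little")
    vals[, , i] <- matrix(px, nrow = cols, ncol = rows) * slope + inter
  }
  ipp <- ds_nums(slices[[1]], "00200032")
  image_grid(vals, spacing = c(ps[2], ps[1], if (length(dz)) dz[1] else
                               ds_nums(slices[[1]], "00180050")),
             origin = c(ipp[1], ipp[2], zs[1]),
             frame_id = ds_str(slices[[1]], "00200052"))
}

# --- RT-DOSE ------------------------------------------------------------------

#' Write an image grid as a DICOM RT-DOSE file
#'
#' Dose is stored as unsigned 32-bit integers with a DoseGridScaling chosen so
#' the maximum dose maps to 1e6 stored units (or scaling 1 for an all-zero
#' grid); the quantisation step is therefore max(dose)/1e6 Gy.
#'
#' @param grid an [image_grid()] of dose in Gy (non-negative).
#' @param path output file path.
#' @param scaling optional explicit DoseGridScaling in Gy per stored unit.
#' @return Invisibly, `path`.
#' @export
write_rtdose <- function(grid, path, scaling = NULL) {
  stopifnot(is_image_grid(grid))
  if (any(grid$values < 0)) stop("dose must be non-negative")
  d <- dim(grid$values)
  if (is.null(scaling)) {
    mx <- max(grid$values)
    scaling <- if (mx > 0) mx / 1e6 else 1
  }
  stored <- as.integer(round(grid$values / scaling))
  offsets <- (seq_len(d[3]) - 1) * grid$spacing[3]
  elems <- list(
    el_str(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.481.2"),
    el_str(0x0008, 0x0018, "UI", dcm_uid("22", basename(path))),
    el_str(0x0008, 0x0060, "CS", "RTDOSE"),
    el_str(0x0020, 0x0052, "UI", grid$frame_id),
    el_ds(0x0020, 0x0032, grid$origin),
    el_ds(0x0020, 0x0037, c(1, 0, 0, 0, 1, 0)),
    el_us(0x0028, 0x0002, 1),
    el_is(0x0028, 0x0008, d[3]),
    el_us(0x0028, 0x0010, d[2]),
    el_us(0x0028, 0x0011, d[1]),
    el_ds(0x0028, 0x0030, c(grid$spacing[2], grid$spacing[1])),
    el_us(0x0028, 0x0100, 32), el_us(0x0028, 0x0101, 32),
    el_us(0x0028, 0x0102, 31), el_us(0x0028, 0x0103, 0),
    el_ds(0x3004, 0x000C, offsets),
    el_ds(0x3004, 0x000E, scaling),
    el_raw(0x7FE0, 0x0010, "OW",
           writeBin(stored, raw(), size = 4, endian = "little"))
  )
  dcm_write_file(path, elems, "1.2.840.10008.5.1.4.1.1.481.2",
                 dcm_uid("22", basename(path)))
  invisible(path)
}

#' Read a DICOM RT-DOSE file
#'
#' @param file path to an RT-DOSE file.
#' @return An [image_grid()] of dose in Gy; its grid may differ from the CT's.
#' @export
read_rtdose <- function(file) {
  ds <- dcm_read_file(file)
  if (!identical(ds_str(ds, "00080060"), "RTDOSE")) stop("not an RTDOSE file")
  scaling <- ds_nums(ds, "3004000E")
  if (is.null(scaling)) stop("unscaled dose: DoseGridScaling absent")
  rows <- ds_us(ds, "00280010"); cols <- ds_us(ds, "00280011")
  nfr <- as.integer(ds_str(ds, "00280008"))
  ps <- ds_nums(ds, "00280030")
  offsets <- ds_nums(ds, "3004000C")
  dz <- if (length(offsets) > 1) diff(offsets)[1] else 1
  stored <- readBin(ds[["7FE00010"]]$value, "integer", n = rows * cols * nfr,
                    size = 4, endian = "little")
  vals <- array(stored * scaling, dim = c(cols, rows, nfr))
  ipp <- ds_nums(ds, "00200032")
  image_grid(vals, spacing = c(ps[2], ps[1], dz),
             origin = c(ipp[1], ipp[2], ipp[3] + offsets[1]),
             frame_id = ds_str(ds, "00200052"))
}

# --- RT-STRUCT ----------------------------------------------------------------

#' Write contours as a DICOM RT-STRUCT file
#'
#' @param contours named list; each entry is a list of planar contours, each a
#'   list with `z` (slice position, mm) and `xy` (n x 2 matrix of world-mm
#'   vertices of a closed polygon, last vertex not repeated).
#' @param path output file path.
#' @param frame_id frame-of-reference UID shared with the CT.
#' @return Invisibly, `path`.
#' @export
write_rtstruct <- function(contours, path, frame_id = "frame-1") {
  roi_items <- list(); cont_items <- list()
  for (i in seq_along(contours)) {
    roi_items[[i]] <- list(
      el_is(0x3006, 0x0022, i),
      el_str(0x3006, 0x0026, "LO", names(contours)[i])
    )
    cs <- lapply(contours[[i]], function(ct) {
      pts <- cbind(ct$xy, ct$z)
      list(
        el_str(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
        el_is(0x3006, 0x0046, nrow(pts)),
        el_ds(0x3006, 0x0050, as.vector(t(pts)))
      )
    })
    cont_items[[i]] <- list(
      el_sq(0x3006, 0x0040, cs),
      el_is(0x3006, 0x0084, i)
    )
  }
  elems <- list(
    el_str(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.481.3"),
    el_str(0x0008, 0x0018, "UI", dcm_uid("33", basename(path))),
    el_str(0x0008, 0x0060, "CS", "RTSTRUCT"),
    el_str(0x0020, 0x0052, "UI", frame_id),
    el_sq(0x3006, 0x0020, roi_items),
    el_sq(0x3006, 0x0039, cont_items)
  )
  dcm_write_file(path, elems, "1.2.840.10008.5.1.4.1.1.481.3",
                 dcm_uid("33", basename(path)))
  invisible(path)
}

#' Even-odd point-in-polygon test
#'
#' Crossing-number (ray casting) test for many points against one polygon.
#' A point is inside when a ray to +x crosses the boundary an odd number of
#' times; edges are treated half-open so vertices are counted once.
#'
#' @param px,py point coordinates (equal-length vectors).
#' @param poly n x 2 matrix of polygon vertices (closed implicitly).
#' @return Logical vector, TRUE for points inside.
#' @export
point_in_polygon <- function(px, py, poly) {
  inside <- logical(length(px))
  n <- nrow(poly)
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Read a DICOM RT-STRUCT file and rasterize onto a reference grid
#'
#' Each closed planar contour is rasterized on its CT slice with even-odd
#' fill: a voxel belongs to the structure iff its centre lies inside the
#' polygon; several contours on one slice combine by even-odd parity, so an
#' inner ring carves a hole.
#'
#' @param file path to an RT-STRUCT file.
#' @param ref reference [image_grid()] (the CT).
#' @return Named list of [structure_mask()] objects.
#' @export
read_rtstruct <- function(file, ref) {
  stopifnot(is_image_grid(ref))
  ds <- dcm_read_file(file)
  if (!identical(ds_str(ds, "00080060"), "RTSTRUCT")) stop("not an RTSTRUCT file")
  rois <- ds[["30060020"]]$items
  names_by_num <- list()
  for (it in rois) {
    names_by_num[[ds_str(it, "30060022")]] <- ds_str(it, "30060026")
  }
  xs <- grid_axis_mm(ref, 1); ys <- grid_axis_mm(ref, 2); zs <- grid_axis_mm(ref, 3)
  ctr <- expand.grid(x = xs, y = ys)
  d <- dim(ref$values)
  out <- list()
  for (it in ds[["30060039"]]$items) {
    num <- ds_str(it, "30060084")
    nm <- names_by_num[[num]]
    mask <- array(FALSE, dim = d)
    for (ct in it[["30060040"]]$items) {
      pts <- matrix(ds_nums(ct, "30060050"), ncol = 3, byrow = TRUE)
      z <- pts[1, 3]
      iz <- which.min(abs(zs - z))
      if (abs(zs[iz] - z) > ref$spacing[3] / 2 + 1e-9)
        stop("unaligned contour: z = ", z)
      inside <- point_in_polygon(ctr$x, ctr$y, pts[, 1:2, drop = FALSE])
      mask[, , iz] <- xor(mask[, , iz], matrix(inside, d[1], d[2]))
    }
    out[[nm]] <- structure_mask(nm, mask, ref)
  }
  out
}

# --- cohort layout ------------------------------------------------------------

#' Write a synthetic cohort to the on-disk exchange layout
#'
#' One directory per patient (CT series, RT-DOSE, RT-STRUCT), a cohort-level
#' `clinical.csv` of the clinical records and labels, and a `manifest.json`.
#'
#' @param cohort a cohort produced by [generate_cohort()] with `images = TRUE`.
#' @param directory output directory.
#' @return Invisibly, `directory`.
#' @export
write_dicom_cohort <- function(cohort, directory) {
  if (is.null(cohort$patients)) stop("cohort has no image data; generate with images = TRUE")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  for (p in cohort$patients) {
    pid <- p$clinical$patient_id
    pdir <- file.path(directory, pid)
    write_ct_series(p$ct, file.path(pdir, "CT"), patient_id = pid)
    write_rtdose(p$dose, file.path(pdir, "dose.dcm"))
    write_rtstruct(p$contours, file.path(pdir, "struct.dcm"),
                   frame_id = p$ct$frame_id)
  }
  utils::write.csv(cohort$clinical, file.path(directory, "clinical.csv"),
                   row.names = FALSE)
  manifest <- list(
    n_patients = nrow(cohort$clinical),
    prescription_dose = cohort$config$prescription_dose,
    seed = cohort$config$seed,
    patients = cohort$clinical$patient_id
  )
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(directory)
}
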