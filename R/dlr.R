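# Frozen convolutional feature extractor: the 13 convolutional layers of the
# standard 16-layer VGG topology (3x3 kernels, stride 1, padding 1, ReLU,
# 2x2 max-pooling after layers 2, 4, 7, 10 and 13), with global average
# pooling (GAP) after every convolutional layer. Per-layer GAP vectors are
# concatenated to 64+64+128+128+256+256+256+512*6 = 4224 features per slice;
# per-patient vectors are the mean over eligible slices.
#
# Convolution is evaluated as nine shifted matrix products against BLAS, so
# no deep-learning runtime is required. Weights are frozen; the default mode
# draws them once from a seeded He-scaled normal, and externally trained
# weights can be supplied as a list of arrays in the same layout.

run_with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Configuration of the convolutional feature extractor
#'
#' @param layer_channels output channels of the 13 convolutional layers.
#' @param pool_after indices of layers followed by 2x2 max-pooling.
#' @param input_size square input edge in pixels (default 512).
#' @param weights_mode "seeded-random" (default) or "external".
#' @param norm_mean,norm_sd per-channel normalisation constants applied after
#'   intensity scaling (defaults leave the scaled image unchanged).
#' @return List of class `extractor_config`.
#' @export
extractor_config <- function(layer_channels = c(64, 64, 128, 128, 256, 256, 256,
                                                512, 512, 512, 512, 512, 512),
                             pool_after = c(2, 4, 7, 10, 13),
                             input_size = 512,
                             weights_mode = c("seeded-random", "external"),
                             norm_mean = c(0, 0, 0), norm_sd = c(1, 1, 1)) {
  stopifnot(length(layer_channels) == 13)
  structure(list(layer_channels = layer_channels, pool_after = pool_after,
                 input_size = input_size,
                 weights_mode = match.arg(weights_mode),
                 norm_mean = norm_mean, norm_sd = norm_sd),
            class = "extractor_config")
}

#' Build a frozen extractor
#'
#' @param config an [extractor_config()].
#' @param seed integer seed for the random frozen weights.
#' @param weights optional external weights: a list of 13 entries, each a list
#'   with `w` (array 3 x 3 x c_in x c_out) and `b` (length c_out).
#' @return List of class `dlr_extractor`.
#' @export
build_extractor <- function(config = extractor_config(), seed = 1,
                            weights = NULL) {
  ch <- config$layer_channels
  cin <- c(3, ch[-13])
  layers <- vector("list", 13)
  if (config$weights_mode == "external") {
    if (is.null(weights)) stop("external weights_mode requires weights")
    for (l in 1:13) {
      w <- weights[[l]]$w
      stopifnot(identical(dim(w), c(3L, 3L, as.integer(cin[l]),
                                    as.integer(ch[l]))))
      layers[[l]] <- list(w = w, b = weights[[l]]$b)
    }
  } else {
    layers <- run_with_seed(seed, {
      lapply(1:13, function(l) {
        sd_he <- sqrt(2 / (9 * cin[l]))
        list(w = array(stats::rnorm(9 * cin[l] * ch[l], sd = sd_he),
                       dim = c(3, 3, cin[l], ch[l])),
             b = rep(0, ch[l]))
      })
    })
  }
  # pre-flatten each (dy,dx) kernel tap to a c_in x c_out matrix for GEMM
  taps <- lapply(layers, function(ly) {
    lapply(1:9, function(k) {
      dy <- (k - 1) %% 3 - 1; dx <- (k - 1) %/% 3 - 1
      matrix(ly$w[dy + 2, dx + 2, , ], dim(ly$w)[3], dim(ly$w)[4])
    })
  })
  structure(list(config = config, layers = layers, taps = taps, seed = seed),
            class = "dlr_extractor")
}

conv3x3 <- function(x, taps, bias) {
  d <- dim(x)
  h <- d[1]; w <- d[2]; cin <- d[3]
  cout <- ncol(taps[[1]])
  xp <- array(0, dim = c(h + 2, w + 2, cin))
  xp[2:(h + 1), 2:(w + 1), ] <- x
  out <- matrix(rep(bias, each = h * w), h * w, cout)
  for (k in 1:9) {
    dy <- (k - 1) %% 3 - 1; dx <- (k - 1) %/% 3 - 1
    xs <- xp[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx), , drop = FALSE]
    dim(xs) <- c(h * w, cin)
    out <- out + xs %*% taps[[k]]
  }
  out[out < 0] <- 0  # ReLU
  array(out, dim = c(h, w, cout))
}

maxpool2 <- function(x) {
  d <- dim(x)
  if (d[1] < 2 || d[2] < 2) return(x)  # map already collapsed
  i <- seq(1, d[1] - 1, by = 2); j <- seq(1, d[2] - 1, by = 2)
  pmax(x[i, j, , drop = FALSE], x[i + 1, j, , drop = FALSE],
       x[i, j + 1, , drop = FALSE], x[i + 1, j + 1, , drop = FALSE])
}

gap2d <- function(x) colMeans(matrix(x, prod(dim(x)[1:2]), dim(x)[3]))

#' Input-design descriptor for slice preparation
#'
#' @param name one of "original", "skin5mm", "ptv100", "v5gy".
#' @param roi [structure_mask()] for masked designs; `original` takes none.
#' @return List of class `input_design`.
#' @export
input_design <- function(name = c("original", "skin5mm", "ptv100", "v5gy"),
                         roi = NULL) {
  name <- match.arg(name)
  if (name == "original" && !is.null(roi)) stop("original design takes no ROI")
  if (name != "original" && is.null(roi)) stop("masked designs require an ROI")
  structure(list(name = name, roi = roi), class = "input_design")
}

#' Prepare one CT slice as network input
#'
#' HU values are windowed to [-1000, 1000] and scaled to [0, 1]; for masked
#' designs, pixels outside the ROI slice are set to the background fill 0
#' after scaling. The slice is centre-padded with background to the
#' configured input size, replicated to 3 channels, then the per-channel
#' normalisation constants are applied.
#'
#' @param ct_slice matrix of HU values for one axial slice.
#' @param design an [input_design()]; for masked designs pass the matching
#'   2-D `roi_slice`.
#' @param config an [extractor_config()].
#' @param roi_slice logical matrix congruent with `ct_slice` (masked designs).
#' @return Array input_size x input_size x 3.
#' @export
prepare_slice <- function(ct_slice, design, config = extractor_config(),
                          roi_slice = NULL) {
  s <- config$input_size
  x <- pmin(pmax(ct_slice, -1000), 1000)
  x <- (x + 1000) / 2000
  if (design$name != "original") {
    if (is.null(roi_slice)) stop("masked design requires roi_slice")
    if (!any(roi_slice)) stop("empty roi slice")
    x[!roi_slice] <- 0
  }
  d <- dim(x)
  if (any(d > s)) stop("shape mismatch: slice larger than input size")
  canvas <- matrix(0, s, s)
  r0 <- (s - d[1]) %/% 2; c0 <- (s - d[2]) %/% 2
  canvas[(r0 + 1):(r0 + d[1]), (c0 + 1):(c0 + d[2])] <- x
  out <- array(0, dim = c(s, s, 3))
  for (ch in 1:3) out[, , ch] <- (canvas - config$norm_mean[ch]) / config$norm_sd[ch]
  out
}

#' Extract the 4224-dimensional per-slice deep feature vector
#'
#' Runs the frozen forward pass and applies global average pooling to each of
#' the 13 post-activation maps, concatenating in layer order.
#'
#' @param extractor a [build_extractor()] object.
#' @param input array input_size x input_size x 3 from [prepare_slice()].
#' @return Named numeric vector, length `sum(layer_channels)` (4224 for the
#'   default topology).
#' @export
extract_slice_features <- function(extractor, input) {
  cfg <- extractor$config
  s <- cfg$input_size
  if (!identical(dim(input), c(as.integer(s), as.integer(s), 3L)))
    stop("shape mismatch: expected ", s, "x", s, "x3 input")
  x <- input
  feats <- vector("list", 13)
  for (l in 1:13) {
    x <- conv3x3(x, extractor$taps[[l]], extractor$layers[[l]]$b)
    g <- gap2d(x)
    names(g) <- paste0("conv", l, "_", seq_along(g))
    feats[[l]] <- g
    if (l %in% cfg$pool_after) x <- maxpool2(x)
  }
  unlist(feats)
}

#' Average slice-level deep features into a patient-level vector
#'
#' @param slice_vectors matrix (slices x features) or list of equal-length
#'   named vectors; at least one slice.
#' @return Element-wise mean vector.
#' @export
aggregate_patient <- function(slice_vectors) {
  if (is.list(slice_vectors)) slice_vectors <- do.call(rbind, slice_vectors)
  if (is.null(slice_vectors) || nrow(slice_vectors) < 1)
    stop("no eligible slices")
  colMeans(slice_vectors)
}

#' Patient-level deep features for one input design
#'
#' Slice eligibility: masked designs require an ROI area of at least
#' `min_roi_pixels` on the slice; the `original` design uses slices within
#' the body's axial extent (all slices when no body mask is given).
#'
#' @param ct CT [image_grid()].
#' @param extractor a [build_extractor()].
#' @param design an [input_design()].
#' @param body optional body [structure_mask()] for the `original` design.
#' @param min_roi_pixels eligibility threshold for masked designs (default 16).
#' @return Named numeric vector `dlr_<design>_conv<L>_<c>` of length 4224
#'   (default topology), plus attribute `n_slices` used.
#' @export
extract_dlr <- function(ct, extractor, design, body = NULL,
                        min_roi_pixels = 16) {
  d <- dim(ct$values)
  roi <- if (!is.null(design$roi)) mask_array(design$roi)
  eligible <- vapply(seq_len(d[3]), function(iz) {
    if (design$name == "original") {
      if (is.null(body)) TRUE else any(mask_array(body)[, , iz])
    } else sum(roi[, , iz]) >= min_roi_pixels
  }, TRUE)
  if (!any(eligible)) stop("no eligible slices")
  vecs <- lapply(which(eligible), function(iz) {
    extract_slice_features(
      extractor,
      prepare_slice(ct$values[, , iz], design, extractor$config,
                    roi_slice = if (!is.null(roi)) roi[, , iz]))
  })
  out <- aggregate_patient(vecs)
  names(out) <- paste0("dlr_", design$name, "_", names(out))
  attr(out, "n_slices") <- sum(eligible)
  out
}
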