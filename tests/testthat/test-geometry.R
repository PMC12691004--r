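# ROI construction and DVH computation.

test_that("body mask recovers a thresholdable phantom and fills internal lung", {
  e <- make_ellipse_ct()
  body <- build_body_mask(e$grid)
  expect_identical(body$mask, e$mask)

  # carve a -750 HU 'lung' inside: hole fill must keep it in the body
  v <- e$grid$values
  v[13:17, 13:17, 3:6] <- -750
  body2 <- build_body_mask(image_grid(v, e$grid$spacing))
  expect_identical(body2$mask, e$mask)

  expect_error(build_body_mask(image_grid(array(-1000, c(4, 4, 4)), c(1, 1, 1))),
               "no body")
})

test_that("largest-component selection matches brute-force component sizes", {
  set.seed(7)
  d <- c(14, 14, 6)
  for (rep in 1:4) {
    m <- array(runif(prod(d)) < 0.25, d)
    lab <- dosederm:::label_components_6(m)
    # oracle: flood fill with a queue
    oracle <- array(0L, d); cur <- 0L
    nb <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
    for (start in which(m)) {
      if (oracle[start] > 0) next
      cur <- cur + 1L
      queue <- arrayInd(start, d)
      oracle[start] <- cur
      while (nrow(queue)) {
        v <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
        for (k in 1:6) {
          w <- v + nb[k, ]
          if (all(w >= 1) && all(w <= d) && m[w] && oracle[w] == 0) {
            oracle[w] <- cur
            queue <- rbind(queue, w)
          }
        }
      }
    }
    # same partition: labels co-vary one-to-one
    expect_true(all((lab > 0) == (oracle > 0)))
    tab <- table(lab[lab > 0], oracle[oracle > 0])
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
})

test_that("skin layer matches the all-pairs distance oracle on a digital sphere", {
  sph <- make_sphere(r_mm = 10, spacing = c(1, 1, 1))
  skin <- build_skin5mm(structure_mask("body", sph), c(1, 1, 1), depth_mm = 5)
  d <- dim(sph)
  pts_in <- arrayInd(which(sph), d)
  pts_out <- arrayInd(which(!sph), d)
  dmin2 <- vapply(seq_len(nrow(pts_in)), function(i) {
    min(colSums((t(pts_out) - pts_in[i, ])^2))
  }, 0)
  oracle <- array(FALSE, d)
  oracle[which(sph)[dmin2 <= 25 + 1e-9]] <- TRUE
  expect_identical(skin$mask, oracle)
})

test_that("skin layer respects anisotropic spacing and saturates on thin bodies", {
  sph <- make_sphere(r_mm = 12, spacing = c(2, 2, 2.5))
  skin <- build_skin5mm(structure_mask("b", sph), c(2, 2, 2.5), depth_mm = 5)
  d <- dim(sph)
  pts_in <- arrayInd(which(sph), d)
  pts_out <- arrayInd(which(!sph), d)
  w <- c(2, 2, 2.5)
  dmin2 <- vapply(seq_len(nrow(pts_in)), function(i) {
    min(colSums(((t(pts_out) - pts_in[i, ]) * w)^2))
  }, 0)
  expect_identical(skin$mask[sph], dmin2 <= 25 + 1e-9)

  # slab thinner than the depth saturates to the whole body
  slab <- array(FALSE, c(10, 10, 5)); slab[, , 3] <- TRUE
  sk <- build_skin5mm(structure_mask("b", slab), c(1, 1, 1), depth_mm = 5)
  expect_identical(sk$mask, slab)

  empty <- array(FALSE, c(4, 4, 4))
  expect_equal(sum(build_skin5mm(structure_mask("b", empty), c(1, 1, 1))$mask), 0)
})

test_that("dose resampling is exact on identical grids and affine fields", {
  set.seed(3)
  ct <- image_grid(array(0, c(10, 9, 5)), c(2, 2, 2.5), origin = c(1, 2, 3))
  dose_same <- image_grid(array(runif(10 * 9 * 5) * 50, c(10, 9, 5)),
                          ct$spacing, ct$origin)
  expect_equal(resample_dose_to_ct(dose_same, ct)$values, dose_same$values)

  # affine field a*x reproduced exactly by trilinear interpolation
  dg <- image_grid(array(0, c(30, 30, 8)), c(3, 3, 4), origin = c(-5, -4, -2))
  xs <- grid_axis_mm(dg, 1)
  dg$values <- array(rep(0.3 * xs, times = 30 * 8), dim(dg$values))
  out <- resample_dose_to_ct(dg, ct)
  expect_equal(out$values,
               array(rep(0.3 * grid_axis_mm(ct, 1), times = 9 * 5),
                     dim(ct$values)),
               tolerance = 1e-10)
})

test_that("dose resampling matches the trilinear formula voxel by voxel", {
  set.seed(9)
  dose <- image_grid(array(runif(8 * 7 * 6) * 50, c(8, 7, 6)),
                     spacing = c(3.1, 2.7, 3.3), origin = c(0.4, -1.2, 0.9))
  ct <- image_grid(array(0, c(9, 9, 5)), c(2, 2, 2.5), origin = c(1.1, 0.3, 1.7))
  out <- resample_dose_to_ct(dose, ct)
  tri <- function(p) {
    ijk <- (p - dose$origin) / dose$spacing + 1
    if (any(ijk < 1) || any(ijk > dim(dose$values))) return(0)
    lo <- pmin(pmax(floor(ijk), 1), dim(dose$values) - 1)
    f <- ijk - lo
    v <- 0
    for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
      w <- prod(ifelse(c(cx, cy, cz) == 1, f, 1 - f))
      v <- v + w * dose$values[lo[1] + cx, lo[2] + cy, lo[3] + cz]
    }
    v
  }
  idx <- arrayInd(seq_len(prod(dim(ct$values))), dim(ct$values))
  expected <- vapply(seq_len(nrow(idx)), function(i) {
    tri(ct$origin + (idx[i, ] - 1) * ct$spacing)
  }, 0)
  expect_equal(as.vector(out$values), expected, tolerance = 1e-10)
  expect_error(resample_dose_to_ct(
    image_grid(array(1, c(3, 3, 3)), c(1, 1, 1), origin = c(500, 500, 500)), ct),
    "no overlap")
})

test_that("dose-guided skin ROI is the inclusive-threshold conjunction", {
  e <- make_ellipse_ct()
  skin <- build_skin5mm(build_body_mask(e$grid), e$grid$spacing)
  zero <- image_grid(array(0, dim(e$grid$values)), e$grid$spacing)
  expect_equal(sum(build_v5gy_roi(skin, zero, 50)$mask), 0)
  full <- image_grid(array(50, dim(e$grid$values)), e$grid$spacing)
  expect_identical(build_v5gy_roi(skin, full, 50)$mask, skin$mask)

  # half-space field: count equals the brute-force conjunction
  hs <- zero
  xs <- grid_axis_mm(e$grid, 1)
  hs$values <- array(rep(ifelse(xs >= 30, 6, 4), times = 30 * 8),
                     dim(hs$values))
  roi <- build_v5gy_roi(skin, hs, 50)
  expect_equal(sum(roi$mask), sum(skin$mask & hs$values >= 5))
  expect_error(build_v5gy_roi(skin, hs, 50, fraction = 0), "invalid fraction")
  expect_error(build_v5gy_roi(skin, hs, 50, fraction = 1.2), "invalid fraction")
})

test_that("DVH features follow step, gradient and saturation dose fields", {
  d <- c(10, 10, 1)
  vox_cc <- prod(c(1, 1, 10)) / 1000   # 0.01 cc voxels
  mask <- structure_mask("skin5mm", array(TRUE, d))
  ptv <- structure_mask("ptv", array(TRUE, d))
  rois <- list(skin5mm = mask, ptv = ptv)
  step <- image_grid(array(10, d), c(1, 1, 10))
  f <- compute_dvh_features(step, rois, prescription = 50)
  expect_equal(unname(f["dvh_skin5mm_V5Gy"]), 1.0)
  expect_equal(unname(f["dvh_skin5mm_V10Gy"]), 1.0)
  expect_equal(unname(f["dvh_skin5mm_V15Gy"]), 0)

  # linear 0 -> 50 Gy gradient: V_x ~ (1 - x/50) * volume
  grad <- image_grid(array(seq(0, 50, length.out = 100), d), c(1, 1, 10))
  fg <- compute_dvh_features(grad, rois, 50)
  lv <- seq(5, 50, 5)
  expect_equal(unname(fg[1:10]), (1 - lv / 50) * 100 * vox_cc,
               tolerance = 0.03)

  sat <- image_grid(array(1.05 * 50, d), c(1, 1, 10))
  fs <- compute_dvh_features(sat, rois, 50)
  expect_equal(unname(fs["dvh_ptv100"]), 100 * vox_cc)
  expect_equal(unname(fs["dvh_ptv105"]), 100 * vox_cc)
  expect_error(compute_dvh_features(step, list(skin5mm = structure_mask(
    "s", array(TRUE, c(3, 3, 1))), ptv = ptv), 50), "grid mismatch")
})

test_that("DVH is non-increasing in dose level on random fields and ROI nesting holds", {
  set.seed(21)
  for (rep in 1:6) {
    d <- c(12, 12, 4)
    dose <- image_grid(array(pmax(rnorm(prod(d), 25, 18), 0), d), c(2, 2, 2.5))
    rois <- list(skin5mm = structure_mask("s", array(runif(prod(d)) < 0.5, d)),
                 ptv = structure_mask("p", array(runif(prod(d)) < 0.3, d)))
    f <- compute_dvh_features(dose, rois, 50)
    expect_true(all(diff(f[1:10]) <= 1e-12))
    expect_true(all(f >= 0))
  }
  co <- generate_cohort(cohort_config(n_patients = 10, grid_shape = c(48, 48, 10),
                                      seed = 2), images = TRUE)
  p <- co$patients[[3]]
  rs <- build_roi_set(p$ct, p$dose_on_ct, p$ptv, 50)
  expect_true(all(rs$v5gy$mask <= rs$skin5mm$mask))
  expect_true(all(rs$skin5mm$mask <= rs$body$mask))
  expect_true(all(rs$ptv100_region$mask <= rs$ptv$mask))
  expect_identical(rs$v5gy$mask, rs$skin5mm$mask & rs$isodose5$mask)
})

test_that("halving resolution changes DVH volumes by under 5% on smooth fields", {
  e <- make_ellipse_ct(dims = c(40, 40, 10), spacing = c(1.5, 1.5, 2),
                       semi = c(26, 22, 9))
  skin <- build_skin5mm(build_body_mask(e$grid), e$grid$spacing)
  xs <- grid_axis_mm(e$grid, 1)
  dose <- image_grid(array(rep(50 * plogis((xs - 20) / 8), times = 40 * 10),
                           dim(e$grid$values)), e$grid$spacing)
  f1 <- compute_dvh_features(dose, list(skin5mm = skin, ptv = skin), 50)
  # coarsen by 2 in x: take every other voxel, voxel volume doubles
  sub <- seq(1, 40, 2)
  g2 <- image_grid(e$grid$values[sub, , , drop = FALSE], c(3, 1.5, 2))
  skin2 <- build_skin5mm(build_body_mask(g2), g2$spacing)
  dose2 <- image_grid(dose$values[sub, , , drop = FALSE], c(3, 1.5, 2))
  f2 <- compute_dvh_features(dose2, list(skin5mm = skin2, ptv = skin2), 50)
  lv <- paste0("dvh_skin5mm_V", c(10, 20, 30), "Gy")
  expect_true(all(abs(f2[lv] - f1[lv]) / f1[lv] < 0.05))
})
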