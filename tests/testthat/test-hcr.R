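# Handcrafted radiomics: discretisation, the 105-feature contract, texture
# matrix oracles and invariance properties.

test_that("fixed-bin-width discretisation matches direct binning", {
  m <- array(TRUE, c(3, 3, 1))
  cst <- discretize(array(7, c(3, 3, 1)), m, hcr_params(25))
  expect_equal(cst$n_levels, 1)

  v <- array(c(0, 25, 50, 0, 25, 50, 0, 25, 50), c(3, 3, 1))
  d <- discretize(v, m, hcr_params(25))
  expect_equal(sort(unique(d$levels[m])), c(1, 2, 3))

  set.seed(5)
  img <- array(rnorm(4 * 4 * 4, 0, 60), c(4, 4, 4))
  mk <- array(runif(64) < 0.7, c(4, 4, 4))
  dd <- discretize(img, mk, hcr_params(10))
  oracle <- floor((img[mk] - min(img[mk])) / 10) + 1
  expect_equal(tabulate(dd$levels[mk]), tabulate(oracle))
  expect_error(discretize(img, array(FALSE, c(4, 4, 4))), "empty ROI")
})

test_that("extractor returns exactly 105 named features with the family counts", {
  set.seed(2)
  img <- array(rnorm(10^3, 40, 20), c(10, 10, 10))
  mask <- make_sphere(4, c(1, 1, 1), pad = 1)[1:10, 1:10, 1:10]
  f <- extract_hcr(img, mask, hcr_params(10), spacing = c(1, 1, 1))
  expect_length(f, 105)
  expect_identical(names(f), hcr_feature_names())
  expect_false(anyDuplicated(names(f)) > 0)
  fam <- table(sub("^hcr_([a-z]+)_.*", "\\1", names(f)))
  expect_equal(fam[["shape"]], 14)
  expect_equal(fam[["firstorder"]], 18)
  expect_equal(fam[["glcm"]], 22)
  expect_equal(fam[["glrlm"]], 16)
  expect_equal(fam[["glszm"]], 16)
  expect_equal(fam[["gldm"]], 14)
  expect_equal(fam[["ngtdm"]], 5)
  expect_true(all(is.finite(f)))
  expect_error(extract_hcr(img, array(c(TRUE, rep(FALSE, 999)), c(10, 10, 10)),
                           spacing = c(1, 1, 1)), "roi too small")
})

test_that("constant ROI degenerates to zero variance/entropy/contrast/busyness", {
  img <- array(12, c(6, 6, 4))
  mask <- array(TRUE, c(6, 6, 4))
  f <- extract_hcr(img, mask, hcr_params(25), spacing = c(1, 1, 1))
  expect_equal(unname(f["hcr_firstorder_Variance"]), 0)
  expect_equal(unname(f["hcr_firstorder_Entropy"]), 0)
  expect_equal(unname(f["hcr_glcm_Contrast"]), 0)
  expect_equal(unname(f["hcr_ngtdm_Busyness"]), 0)
  expect_equal(unname(f["hcr_glcm_JointEntropy"]), 0)
  expect_true(all(is.finite(f)))
})

test_that("GLCM contrast on a checkerboard matches hand-enumerated co-occurrences", {
  # 4x4 two-level checkerboard slice; horizontal offset: every adjacent pair
  # crosses levels, so p(1,2) = p(2,1) = 1/2 and contrast = 1
  cb <- outer(1:4, 1:4, function(i, j) (i + j) %% 2)
  img <- array(cb * 25, c(4, 4, 1))
  mask <- array(TRUE, c(4, 4, 1))
  dsc <- discretize(img, mask, hcr_params(25))
  P <- dosederm:::glcm_from_direction(dsc$levels, 2, c(1, 0, 0))
  expect_equal(sum(P), 24)          # 12 ordered pairs, symmetrised
  expect_equal(P[1, 1] + P[2, 2], 0)
  fe <- dosederm:::glcm_features_one(P)
  expect_equal(unname(fe["Contrast"]), 1)
  expect_equal(unname(fe["MaximumProbability"]), 0.5)

  # 3-D checkerboard: the 7 odd-parity directions see contrast 1, the 6
  # even-parity diagonals see 0, so the direction average is 7/13
  cb3 <- array(0, c(6, 6, 6))
  idx <- arrayInd(1:216, c(6, 6, 6))
  cb3[] <- (rowSums(idx) %% 2) * 25
  f3 <- extract_hcr(cb3, array(TRUE, c(6, 6, 6)), hcr_params(25), c(1, 1, 1))
  expect_equal(unname(f3["hcr_glcm_Contrast"]), 7 / 13, tolerance = 1e-12)
})

test_that("run-length matrix reproduces hand-enumerated runs", {
  lv <- array(NA_integer_, c(6, 1, 1))
  lv[, 1, 1] <- c(1L, 1L, 2L, 2L, 2L, 1L)
  P <- dosederm:::glrlm_from_direction(lv, 2, c(1, 0, 0), c(6, 1, 1))
  expected <- matrix(0, 2, 3)
  expected[1, 2] <- 1  # run of level 1, length 2
  expected[2, 3] <- 1  # run of level 2, length 3
  expected[1, 1] <- 1  # trailing single level-1 voxel
  expect_equal(P, expected)
})

test_that("size-zone labelling finds connected equal-level zones", {
  lv <- array(NA_integer_, c(4, 4, 1))
  lv[, , 1] <- matrix(c(1, 1, 2, 2,
                        1, 1, 2, 2,
                        3, 3, 1, 1,
                        3, 3, 1, 1), 4, 4, byrow = TRUE)
  z <- dosederm:::glszm_zones(lv, c(4, 4, 1))
  # zones: level-1 block of 4 touches the second level-1 block diagonally
  # (26-connectivity) -> one zone of 8; level 2 zone of 4; level 3 zone of 4
  expect_equal(nrow(z), 3)
  expect_equal(sort(z$size), c(4, 4, 8))
  expect_equal(z$size[z$level == 1], 8)
})

test_that("adding a constant shifts first-order location but not texture", {
  set.seed(8)
  img <- array(rnorm(8^3, 0, 40), c(8, 8, 8))
  mask <- array(runif(512) < 0.8, c(8, 8, 8))
  f0 <- extract_hcr(img, mask, hcr_params(15), c(1, 1, 1))
  f1 <- extract_hcr(img + 100, mask, hcr_params(15), c(1, 1, 1))
  expect_equal(unname(f1["hcr_firstorder_Mean"]),
               unname(f0["hcr_firstorder_Mean"]) + 100)
  tex <- grep("^hcr_(glcm|glrlm|glszm|gldm|ngtdm)_", names(f0), value = TRUE)
  expect_equal(f1[tex], f0[tex], tolerance = 1e-12)
  expect_equal(unname(f1["hcr_glcm_JointEntropy"]),
               unname(f0["hcr_glcm_JointEntropy"]))
})

test_that("90-degree in-plane rotation leaves direction-averaged features unchanged", {
  set.seed(13)
  img <- array(rnorm(9 * 9 * 5, 30, 25), c(9, 9, 5))
  mask <- array(runif(9 * 9 * 5) < 0.7, c(9, 9, 5))
  mask[5, 5, 3] <- TRUE
  rot <- function(a) {
    out <- array(a[1], dim = c(dim(a)[2], dim(a)[1], dim(a)[3]))
    for (z in seq_len(dim(a)[3])) out[, , z] <- t(a[dim(a)[1]:1, , z])
    out
  }
  f0 <- extract_hcr(img, mask, hcr_params(20), c(1, 1, 2))
  f1 <- extract_hcr(rot(img), rot(mask), hcr_params(20), c(1, 1, 2))
  keep <- grep("^hcr_(firstorder|glcm|glrlm|glszm|gldm|ngtdm)_", names(f0),
               value = TRUE)
  expect_equal(f1[keep], f0[keep], tolerance = 1e-10)
})

test_that("all 105 outputs stay finite on fuzzed inputs", {
  set.seed(77)
  for (rep in 1:8) {
    d <- c(sample(5:9, 1), sample(5:9, 1), sample(3:6, 1))
    img <- array(rnorm(prod(d), runif(1, -200, 200), runif(1, 1, 80)), d)
    mask <- array(runif(prod(d)) < runif(1, 0.4, 0.9), d)
    if (sum(mask) < 8) mask[seq_len(8)] <- TRUE
    f <- extract_hcr(img, mask, hcr_params(sample(c(5, 25), 1)),
                     spacing = c(runif(1, 0.8, 2), runif(1, 0.8, 2), 2.5))
    expect_true(all(is.finite(f)))
    expect_length(f, 105)
  }
})
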