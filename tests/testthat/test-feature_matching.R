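test_that("ncc matches its closed form and degeneracy contract", {
  set.seed(1)
  a <- array(rnorm(27), c(3, 3, 3))
  expect_equal(as.numeric(ncc(a, a)), 1)
  expect_equal(as.numeric(ncc(a, 2 * a + 3)), 1)    # affine invariance
  expect_equal(as.numeric(ncc(c(1, -1, 1, -1), c(1, 1, -1, -1))), 0)
  const <- array(5, c(3, 3, 3))
  r <- ncc(a, const)
  expect_equal(as.numeric(r), 0)
  expect_true(attr(r, "degenerate"))
  expect_error(ncc(a, array(0, c(2, 3, 3))), "shape")
  expect_error(ncc(1, 2), "2 voxels")
  for (i in 1:50) {
    set.seed(i)
    x <- rnorm(20); y <- rnorm(20)
    expect_true(abs(as.numeric(ncc(x, y))) <= 1)
    expect_equal(as.numeric(ncc(x, y)), cor(x, y), tolerance = 1e-12)
  }
})

test_that("feature selection ranks by block variance and honours the mask", {
  # constant image: nothing selectable
  flat <- image3d(array(7, c(16, 16, 16)))
  expect_equal(nrow(selectFeaturePoints(flat, blockSpec(B = c(2, 2, 2)),
                                        fraction = 1)), 0)
  # constant background + one textured cube: all selections inside the cube
  set.seed(5)
  dat <- array(0, c(24, 24, 24))
  dat[7:17, 7:17, 7:17] <- rnorm(11^3)
  img <- image3d(dat)
  spec <- blockSpec(B = c(2, 2, 2), W = c(1, 1, 1))
  sel <- selectFeaturePoints(img, spec, fraction = 0.05)
  expect_gt(nrow(sel), 0)
  expect_true(all(sel >= 4 & sel <= 18))  # blocks overlap the cube
  # brute-force variance oracle agrees on the ranking
  B <- spec$B
  oracleVar <- function(c0) var(as.vector(
    dat[(c0[1] - 1):(c0[1] + 3) + B[1] - 1, (c0[2] - 1):(c0[2] + 3) +
          B[2] - 1, (c0[3] - 1):(c0[3] + 3) + B[3] - 1]))
  all <- selectFeaturePoints(img, spec, fraction = 1)
  vOr <- apply(all + 1 - B[1], 1, function(ijk)
    var(as.vector(dat[ijk[1]:(ijk[1] + 2 * B[1]),
                      ijk[2]:(ijk[2] + 2 * B[2]),
                      ijk[3]:(ijk[3] + 2 * B[3])])))
  expect_true(all(diff(vOr) <= 1e-9))  # returned in decreasing variance
  # mask restriction
  mask <- labelImage(array(0, c(24, 24, 24)))
  mask@data[1:12, , ] <- 1
  selm <- selectFeaturePoints(img, spec, fraction = 1, mask = mask)
  expect_true(all(selm[, 1] <= 11))
  # min-spacing thinning
  selt <- selectFeaturePoints(img, spec, fraction = 1, minSpacing = 4)
  dmin <- min(dist(selt))
  expect_gte(dmin, 4)
})

test_that("block matching recovers an exact integer translation", {
  ph <- makePhantom(phantomSpec(size = c(32, 32, 32), deformMax = 0,
                                seed = 2))
  pre <- imgData(ph$preop)
  fix <- array(0, dim(pre))
  fix[4:32, , ] <- pre[1:29, , ]
  fixed <- image3d(fix, spacing(ph$preop), origin(ph$preop))
  spec <- blockSpec(B = c(2, 2, 2), W = c(4, 4, 4))
  pts <- selectFeaturePoints(ph$preop, spec, fraction = 0.2,
                             mask = ph$labels, minSpacing = 2,
                             margin = spec$B + spec$W)
  ms <- blockMatch(ph$preop, fixed, pts, spec)
  d <- displacements(ms)
  expect_true(all(abs(d[, 1] - 3) < 1e-9))
  expect_true(all(abs(d[, 2:3]) < 1e-9))
  expect_true(all(confidences(ms) > 1 - 1e-9))
  # cost-bound instrumentation: exactly prod(2W+1) evaluations per point
  expect_true(all(attr(ms, "nccEvaluations") == prod(2 * spec$W + 1)))
})

test_that("block matching is invariant to affine intensity rescaling", {
  ph <- makePhantom(phantomSpec(size = c(24, 24, 24), deformMax = 2,
                                seed = 3))
  spec <- blockSpec(B = c(2, 2, 2), W = c(3, 3, 3))
  pts <- selectFeaturePoints(ph$preop, spec, fraction = 0.1,
                             mask = ph$labels, minSpacing = 2,
                             margin = spec$B + spec$W)
  m1 <- blockMatch(ph$preop, ph$intraop, pts, spec)
  rescale <- function(img, a, b) image3d(a * imgData(img) + b,
                                         spacing(img), origin(img))
  m2 <- blockMatch(rescale(ph$preop, 2.5, 10),
                   rescale(ph$intraop, 0.3, -7), pts, spec)
  expect_identical(matchPoints(m1), matchPoints(m2))
  expect_equal(displacements(m1), displacements(m2))
  expect_equal(confidences(m1), confidences(m2), tolerance = 1e-12)
})

test_that("degenerate windows and W = 0 behave per contract", {
  ph <- makePhantom(phantomSpec(size = c(24, 24, 24), deformMax = 0,
                                seed = 4))
  spec0 <- blockSpec(B = c(2, 2, 2), W = c(0, 0, 0))
  pts <- selectFeaturePoints(ph$preop, spec0, fraction = 0.1,
                             mask = ph$labels, minSpacing = 3)
  ms <- blockMatch(ph$preop, ph$preop, pts, spec0)
  expect_true(all(displacements(ms) == 0))
  expect_true(all(attr(ms, "nccEvaluations") == 1))
  # constant fixed image: undefined NCC everywhere, all matches dropped
  const <- image3d(array(1, c(24, 24, 24)))
  ms2 <- blockMatch(ph$preop, const, pts, blockSpec(B = c(2, 2, 2),
                                                    W = c(2, 2, 2)))
  expect_equal(nMatches(ms2), 0)
  # geometry mismatch is a contract error
  other <- image3d(imgData(ph$preop), spacing = c(2, 1, 1))
  expect_error(blockMatch(ph$preop, other, pts, spec0), "geometry")
})

test_that("matches serialize to CSV and back", {
  dir <- withr::local_tempdir()
  ph <- makePhantom(phantomSpec(size = c(24, 24, 24), deformMax = 2,
                                seed = 5))
  spec <- blockSpec(B = c(2, 2, 2), W = c(3, 3, 3))
  pts <- selectFeaturePoints(ph$preop, spec, fraction = 0.05,
                             mask = ph$labels, minSpacing = 3,
                             margin = spec$B + spec$W)
  ms <- blockMatch(ph$preop, ph$intraop, pts, spec)
  p <- file.path(dir, "m.csv")
  writeMatches(ms, p)
  back <- readMatches(p)
  expect_equal(matchPoints(back), unname(matchPoints(ms)))
  expect_equal(displacements(back), unname(displacements(ms)))
  expect_equal(confidences(back), confidences(ms))
})
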