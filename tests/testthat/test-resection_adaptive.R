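test_that("BCC meshing fills a cube mask with valid labelled tetrahedra", {
  mask <- labelImage(array(1, c(12, 12, 12)))
  mesh <- bccMesh(mask, 3)
  expect_true(all(tetVolumes(mesh) > 0))
  V <- vertices(mesh)
  # hull within one cell of the (voxel-extended) cube surface
  expect_true(all(V >= -0.5 - 3 & V <= 11.5 + 3))
  # interior coverage: centroids populate the cube
  expect_gt(nrow(tets(mesh)), 100)
  # sphere-in-cube two-label mask keeps both labels
  lab2 <- array(1, c(12, 12, 12))
  ii <- as.matrix(expand.grid(1:12, 1:12, 1:12))
  lab2[ii[rowSums((ii - 6.5)^2) <= 9, ]] <- 2
  mesh2 <- bccMesh(labelImage(lab2), 2)
  expect_setequal(unique(tetLabels(mesh2)), c(1L, 2L))
  # empty mask errors
  expect_error(bccMesh(labelImage(array(0, c(6, 6, 6))), 2), "foreground")
  expect_error(bccMesh(mask, 50), "cellSize|centroid")
})

test_that("mask dilation grows every label by the requested radius", {
  lab <- array(0, c(9, 9, 9))
  lab[5, 5, 5] <- 2
  d1 <- dilateMask(labelImage(lab), 1)
  expect_equal(sum(imgData(d1) == 2), 27)
  d2 <- dilateMask(labelImage(lab), 2)
  expect_equal(sum(imgData(d2) == 2), 125)
})

test_that("resection detection finds a carved cavity and nothing else", {
  ext <- 47
  ph <- makePhantom(phantomSpec(size = c(48, 48, 48), deformMax = 0,
                                seed = 5,
                                resection = list(center = c(30.5, 23.5,
                                                            23.5),
                                                 radius = 8)))
  mesh <- bccMesh(ph$labels, 3)
  U0 <- matrix(0, nrow(vertices(mesh)), 3)
  rem <- detectResectionElements(mesh, U0, ph$intraop)
  V <- vertices(mesh)
  Tm <- tets(mesh)
  cen <- (V[Tm[, 1], ] + V[Tm[, 2], ] + V[Tm[, 3], ] + V[Tm[, 4], ]) / 4
  inCav <- which(colSums((t(cen) - c(30.5, 23.5, 23.5))^2) <= 64)
  dice <- 2 * length(intersect(rem, inCav)) / (length(rem) + length(inCav))
  expect_gte(dice, 0.85)
  # growth is monotone in the outer iteration count
  sets <- lapply(1:4, function(k)
    detectResectionElements(mesh, U0, ph$intraop,
                            resectionConfig(maxOuterIter = k)))
  for (k in 2:4) expect_true(all(sets[[k - 1]] %in% sets[[k]]))
  # no-cavity phantom: empty set
  ph2 <- makePhantom(phantomSpec(size = c(48, 48, 48), deformMax = 0,
                                 seed = 5))
  mesh2 <- bccMesh(ph2$labels, 3)
  rem2 <- detectResectionElements(mesh2, matrix(0, nrow(vertices(mesh2)),
                                                3), ph2$intraop)
  expect_length(rem2, 0)
  # intraop with no sub-threshold voxels under the mesh: empty set
  bright <- image3d(imgData(ph2$intraop) + 100, spacing(ph2$intraop))
  rem3 <- detectResectionElements(mesh2, matrix(0, nrow(vertices(mesh2)),
                                                3), bright,
                                  resectionConfig(bgThreshold = 50))
  expect_length(rem3, 0)
})

test_that("only the larger of two disjoint background pockets is collected", {
  lab <- array(0, c(36, 36, 36))
  lab[3:34, 3:34, 3:34] <- 1
  mask <- labelImage(lab)
  img <- array(60, c(36, 36, 36))
  ii <- as.matrix(expand.grid(1:36, 1:36, 1:36))
  img[ii[rowSums((ii - 12)^2) <= 49, ]] <- 0   # pocket A, radius 7
  img[ii[rowSums((ii - 26)^2) <= 16, ]] <- 0   # pocket B, radius 4
  intra <- image3d(img)
  mesh <- bccMesh(mask, 3)
  rem <- detectResectionElements(mesh, matrix(0, nrow(vertices(mesh)), 3),
                                 intra, resectionConfig(bgThreshold = 30))
  V <- vertices(mesh)
  Tm <- tets(mesh)
  cen <- (V[Tm[, 1], ] + V[Tm[, 2], ] + V[Tm[, 3], ] + V[Tm[, 4], ]) / 4
  inA <- colSums((t(cen) - 11)^2) <= 49
  inB <- colSums((t(cen) - 25)^2) <= 16
  expect_gt(sum(rem %in% which(inA)), 0)
  expect_equal(sum(rem %in% which(inB)), 0)
})

test_that("element removal compacts the mesh and reports removed volume", {
  mesh <- bccMesh(labelImage(array(1, c(10, 10, 10))), 3)
  # empty removal is the identity up to compaction
  same <- removeElements(mesh, integer(0))
  expect_equal(vertices(same), vertices(mesh))
  expect_identical(tets(same), tets(mesh))
  expect_equal(attr(same, "removedVolume"), 0)
  rem <- c(3L, 10L, 40L)
  red <- removeElements(mesh, rem)
  expect_equal(nrow(tets(red)), nrow(tets(mesh)) - 3)
  expect_equal(attr(red, "removedVolume"),
               sum(tetVolumes(mesh)[rem]), tolerance = 1e-9)
  expect_true(all(tetVolumes(red) > 0))
  expect_error(removeElements(mesh, seq_len(nrow(tets(mesh)))), "empty")
  expect_error(removeElements(mesh, 10^6L), "range")
})

test_that("field composition has the zero field as identity", {
  ph <- makePhantom(phantomSpec(size = c(16, 16, 16), deformMax = 2,
                                seed = 6))
  z <- denseField(array(0, c(16, 16, 16, 3)), ph$preop)
  expect_equal(fieldValues(composeFields(z, ph$truth)),
               fieldValues(ph$truth))
  expect_equal(fieldValues(composeFields(ph$truth, z)),
               fieldValues(ph$truth))
})

test_that("a single adaptive iteration without resection equals one pass", {
  ph <- makePhantom(phantomSpec(size = c(32, 32, 32), deformMax = 2,
                                seed = 8))
  spec <- blockSpec(B = c(2, 2, 2), W = c(3, 3, 3))
  scfg <- solverConfig(nR = 2, fR = 0.1)
  acfg <- adaptiveConfig(nIter = 1, solver = scfg, spec = spec,
                         cellSize = 6, fraction = 0.5, minSpacing = 3)
  res <- suppressWarnings(adaptiveRegister(ph$preop, ph$labels, ph$intraop,
                                           acfg))
  mesh <- bccMesh(ph$labels, 6)
  reg <- suppressWarnings(registerImages(
    ph$preop, ph$intraop, mesh, spec = spec, cfg = scfg, fraction = 0.5,
    mask = ph$labels, minSpacing = 3))
  expect_identical(fieldValues(res$field), fieldValues(reg$field))
  expect_identical(imgData(res$warped), imgData(reg$warped))
  expect_equal(res$report[[1]]$nRemoved, 0)
})

test_that("adaptive registration of identical images is a null map", {
  ph <- makePhantom(phantomSpec(size = c(32, 32, 32), deformMax = 0,
                                seed = 9))
  res <- suppressWarnings(adaptiveRegister(
    ph$preop, ph$labels, ph$preop,
    adaptiveConfig(nIter = 2, spec = blockSpec(B = c(2, 2, 2),
                                               W = c(3, 3, 3)),
                   cellSize = 6, fraction = 0.5, minSpacing = 3)))
  expect_lte(max(sqrt(rowSums(fieldValues(res$field)^2))), 0.5)
})

test_that("meshes at every adaptive iteration keep positive volumes", {
  ph <- makePhantom(phantomSpec(size = c(32, 32, 32), deformMax = 5,
                                seed = 10))
  # re-mesh OFF exercises the displaced-initial-mesh path too
  for (remesh in c(TRUE, FALSE)) {
    res <- suppressWarnings(adaptiveRegister(
      ph$preop, ph$labels, ph$intraop,
      adaptiveConfig(nIter = 3, spec = blockSpec(B = c(2, 2, 2),
                                                 W = c(5, 5, 5)),
                     cellSize = 6, remesh = remesh, fraction = 0.7,
                     minSpacing = 3, margin = c(2, 2, 2))))
    expect_length(res$report, 3)   # no iteration raised a validity error
    expect_true(all(is.finite(fieldValues(res$field))))
  }
})
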