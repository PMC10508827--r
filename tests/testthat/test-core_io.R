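test_that("NIfTI and NRRD image round-trips preserve data and geometry", {
  dir <- withr::local_tempdir()
  for (ext in c("nii.gz", "nii", "nrrd")) {
    img <- makeTestImage(c(9, 7, 5), spacing = c(0.5, 1.25, 2),
                         origin = c(-3, 4, 5.5), seed = 42)
    path <- file.path(dir, paste0("img.", ext))
    writeImage(img, path)
    back <- readImage(path)
    expect_equal(imgData(back), imgData(img), tolerance = 0)
    expect_equal(spacing(back), spacing(img))
    expect_equal(origin(back), origin(img))
    # overwrite succeeds
    writeImage(img, path)
    expect_equal(imgData(readImage(path)), imgData(img))
  }
})

test_that("randomized image round-trips are exact over many draws", {
  dir <- withr::local_tempdir()
  for (seed in 1:100) {
    set.seed(seed)
    d <- sample(2:6, 3, replace = TRUE)
    img <- image3d(array(rnorm(prod(d)), d), runif(3, 0.2, 3),
                   rnorm(3, sd = 10))
    ext <- c("nii.gz", "nrrd")[seed %% 2 + 1]
    path <- file.path(dir, paste0("r", seed, ".", ext))
    writeImage(img, path)
    back <- readImage(path)
    expect_identical(imgData(back), imgData(img))
    # NIfTI-1 stores geometry as float32; NRRD round-trips doubles exactly
    tol <- if (ext == "nrrd") 1e-12 else 1e-6
    expect_equal(spacing(back), spacing(img), tolerance = tol)
    expect_equal(origin(back), origin(img), tolerance = tol)
  }
})

test_that("label images round-trip as integers without float promotion", {
  dir <- withr::local_tempdir()
  set.seed(3)
  lab <- labelImage(array(sample(0:3, 60, TRUE), c(5, 4, 3)))
  for (ext in c("nii.gz", "nrrd")) {
    path <- file.path(dir, paste0("lab.", ext))
    writeImage(lab, path)
    back <- readImage(path, label = TRUE)
    expect_s4_class(back, "LabelImage")
    expect_identical(imgData(back), imgData(lab))
  }
  hdr <- RNifti::niftiHeader(file.path(dir, "lab.nii.gz"))
  expect_equal(hdr$datatype, 8L)  # int32 on disk
})

test_that("unreadable or mis-dimensioned images raise informative errors", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.nrrd")
  writeLines("not an image", bad)
  expect_error(readImage(bad), "NRRD")
  truncated <- file.path(dir, "trunc.nrrd")
  img <- makeTestImage(c(6, 6, 6))
  writeImage(img, truncated)
  raw <- readBin(truncated, "raw", n = file.size(truncated))
  writeBin(raw[1:150], truncated)
  expect_error(readImage(truncated), "trunc")
  expect_error(readImage(file.path(dir, "missing.nii.gz")), "exist")
  expect_error(readImage(file.path(dir, "odd.xyz")), "extension")
  expect_error(writeImage(img, file.path(dir, "no", "img.nii.gz")),
               "directory")
})

test_that("world/index mapping is exactly invertible on lattice points", {
  img <- image3d(array(0, c(7, 6, 5)), c(0.7, 1.3, 2.1), c(-5, 3, 0.5))
  ijk <- as.matrix(expand.grid(0:6, 0:5, 0:4))
  back <- worldToIndex(img, indexToWorld(img, ijk))
  expect_equal(back, unname(ijk), tolerance = 1e-12)
})

test_that("tet meshes round-trip through VTK legacy files", {
  dir <- withr::local_tempdir()
  # single tet
  m1 <- tetMesh(unitTet, matrix(1:4, 1), 3L)
  p <- file.path(dir, "one.vtk")
  writeMesh(m1, p)
  b1 <- readMesh(p)
  expect_equal(vertices(b1), vertices(m1), tolerance = 1e-12)
  expect_identical(tets(b1), tets(m1))
  expect_identical(tetLabels(b1), tetLabels(m1))
  # two labels
  m2 <- twoTetMesh()
  m2@labels <- c(1L, 2L)
  writeMesh(m2, p)
  expect_identical(tetLabels(readMesh(p)), c(1L, 2L))
  # randomized round trips
  for (seed in 1:100) {
    set.seed(seed)
    mesh <- bccMesh(labelImage(array(1, c(4, 4, 4)),
                               spacing = runif(3, 0.5, 2)),
                    cellSize = runif(1, 1.2, 2.5))
    writeMesh(mesh, p)
    back <- readMesh(p)
    expect_equal(vertices(back), vertices(mesh), tolerance = 1e-9)
    expect_identical(tets(back), tets(mesh))
    expect_identical(tetLabels(back), tetLabels(mesh))
  }
})

test_that("non-tetrahedral cells are rejected", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "hex.vtk")
  writeLines(c("# vtk DataFile Version 3.0", "hex", "ASCII",
               "DATASET UNSTRUCTURED_GRID", "POINTS 8 double",
               apply(expand.grid(0:1, 0:1, 0:1), 1, paste, collapse = " "),
               "CELLS 1 9", "8 0 1 2 3 4 5 6 7", "CELL_TYPES 1", "12"), p)
  expect_error(readMesh(p), "non-tetrahedral")
})

test_that("mesh validity enforces positive volumes and vertex bounds", {
  expect_error(tetMesh(unitTet, matrix(c(1, 2, 3, 3), 1)), "degenerate")
  m <- twoTetMesh()
  # constructor reorients rather than rejecting negative volume
  flipped <- tetMesh(vertices(m), tets(m)[, c(1, 2, 4, 3)], tetLabels(m))
  expect_true(all(tetVolumes(flipped) > 0))
  expect_error(tetMesh(rbind(unitTet, unitTet[1, , drop = FALSE]),
                       matrix(1:4, 1)), "duplicate")
})
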