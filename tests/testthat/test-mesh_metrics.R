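test_that("isotropic sizing equals the brute-force k-th distance", {
  set.seed(1)
  verts <- matrix(rnorm(60, sd = 10), ncol = 3)
  pts <- matrix(rnorm(90, sd = 10), ncol = 3)
  fld <- sizingIsotropic(verts, pts, k = 5, minSpacing = 1e-6)
  oracle <- apply(verts, 1, function(v)
    sort(sqrt(colSums((t(pts) - v)^2)))[5])
  expect_equal(fld@spacing, oracle, tolerance = 1e-12)
  # k = 1 with one point at distance 5
  f1 <- sizingIsotropic(c(0, 0, 0), c(3, 4, 0), k = 1)
  expect_equal(f1@spacing, 5)
  # coincident vertex clamps to minSpacing
  f2 <- sizingIsotropic(c(1, 1, 1), c(1, 1, 1), k = 1, minSpacing = 0.25)
  expect_equal(f2@spacing, 0.25)
  expect_error(sizingIsotropic(verts, pts[1:3, ], k = 5), "at least")
})

test_that("MVEE solves symmetric cases and always contains its input", {
  # octahedron vertices -> unit ball
  oct <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  e <- mvee(oct, tol = 1e-6)
  expect_lt(max(abs(e@center)), 1e-3)
  expect_lt(max(abs(e@M - diag(3))), 1e-3)
  # points on a sphere of radius r at q
  set.seed(2)
  q <- c(5, -2, 7)
  P <- matrix(rnorm(60), ncol = 3)
  P <- sweep(P / sqrt(rowSums(P^2)) * 3, 2, q, `+`)
  e2 <- mvee(P, tol = 1e-7)
  expect_lt(max(abs(e2@center - q)), 1e-4)
  expect_lt(max(abs(e2@M - diag(3) / 9)), 1e-5)
  # containment contract on random sets
  for (i in 1:40) {
    set.seed(i)
    X <- matrix(rnorm(3 * sample(4:20, 1)), ncol = 3)
    ee <- mvee(X)
    m <- max(apply(X, 1, function(x)
      t(x - ee@center) %*% ee@M %*% (x - ee@center)))
    expect_lte(m, 1 + 1e-5)
  }
})

test_that("MVEE volume is invariant under rigid motion", {
  set.seed(3)
  X <- matrix(rnorm(30), ncol = 3)
  v0 <- ellipsoidVolume(mvee(X, tol = 1e-7))
  for (i in 1:10) {
    set.seed(i + 100)
    qr <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(qr) < 0) qr[, 1] <- -qr[, 1]
    Xr <- X %*% t(qr) + matrix(rnorm(3), nrow(X), 3, byrow = TRUE)
    expect_equal(ellipsoidVolume(mvee(Xr, tol = 1e-7)), v0,
                 tolerance = 1e-3)
  }
})

test_that("degenerate coplanar inputs are regularised and flagged", {
  X <- cbind(matrix(rnorm(20), ncol = 2), 0)[, c(1, 3, 2)]  # plane y = 0
  X <- matrix(c(rnorm(10), rep(0, 10), rnorm(10)), ncol = 3)
  e <- mvee(X)
  expect_true(e@degenerate)
  expect_true(all(eigen(e@M, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
})

test_that("anisotropic metric is centred at the vertex and scales with a", {
  v <- c(1, 2, 3)
  # axis points at radius 2: the reflected set is the octahedron, whose
  # enclosing ellipsoid is the sphere of radius 2
  P <- sweep(rbind(c(2, 0, 0), c(0, 2, 0), c(0, 0, 2)), 2, v, `+`)
  M1 <- metricAnisotropic(v, P, k = 3, a = 1)
  expect_lt(max(abs(M1 - diag(3) / 4)), 1e-3)
  expect_equal(attr(M1, "center"), v)
  # inflation is an exact 1/a^2 scaling
  M15 <- metricAnisotropic(v, P, k = 3, a = 1.5)
  expect_equal(M15, M1 / 1.5^2, ignore_attr = TRUE)
  # containment of the k nearest points at any inflation
  set.seed(5)
  P2 <- matrix(rnorm(45, sd = 3), ncol = 3)
  for (a in c(1, 1.2, 1.5)) {
    M <- metricAnisotropic(v, P2, k = 5, a = a)
    d2 <- colSums((t(P2) - v)^2)
    near <- P2[order(d2)[1:5], ]
    vals <- apply(near, 1, function(p)
      t(p - v) %*% M %*% (p - v) * a^2)
    expect_true(all(vals <= 1 + 1e-5))
  }
  # all-coincident fallback
  Mc <- metricAnisotropic(v, matrix(rep(v, 6), ncol = 3, byrow = TRUE),
                          k = 5, a = 1, minSpacing = 0.5)
  expect_true(attr(Mc, "degenerate"))
  expect_equal(Mc, diag(3) / 0.25, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("metric fields export to VTK point data and read back", {
  dir <- withr::local_tempdir()
  set.seed(6)
  verts <- matrix(rnorm(30, sd = 5), ncol = 3)
  pts <- matrix(rnorm(60, sd = 5), ncol = 3)
  iso <- sizingIsotropic(verts, pts, k = 3)
  p <- file.path(dir, "iso.vtk")
  exportMetric(iso, p)
  back <- readMetric(p)
  expect_equal(back@spacing, iso@spacing, tolerance = 1e-9)
  expect_equal(back@vertices, iso@vertices, tolerance = 1e-9)
  aniso <- metricFieldAnisotropic(verts, pts, k = 4, a = 1.2)
  p2 <- file.path(dir, "aniso.vtk")
  exportMetric(aniso, p2)
  back2 <- readMetric(p2)
  expect_equal(back2@tensors, aniso@tensors, tolerance = 1e-9)
  # empty field is a contract error
  empty <- new("MetricField", vertices = matrix(0, 0, 3),
               type = "isotropic", spacing = numeric(0),
               tensors = array(0, c(0, 0, 0)))
  expect_error(exportMetric(empty, file.path(dir, "e.vtk")), "empty")
})

test_that("isotropic and anisotropic sizing agree on a spherical cloud", {
  v <- c(0, 0, 0)
  P <- rbind(c(2.5, 0, 0), c(0, 2.5, 0), c(0, 0, 2.5))
  iso <- sizingIsotropic(matrix(v, 1), P, k = 3)
  M <- metricAnisotropic(v, P, k = 3, a = 1)
  # tensor radius = 1/sqrt(eigenvalue) equals the k-th distance
  radii <- 1 / sqrt(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(mean(radii), iso@spacing, tolerance = 1e-3)
})
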