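
# Small consistent system: mesh, matches at interior points, optional U*.
smallSystem <- function(seed = 1, nPts = 40) {
  set.seed(seed)
  ph <- makePhantom(phantomSpec(size = c(16, 16, 16), deformMax = 0,
                                seed = seed))
  mesh <- bccMesh(ph$labels, 5)
  V <- vertices(mesh)
  Ustar <- cbind(sin(V[, 1] / 6), cos(V[, 2] / 5) - 1, V[, 3] / 40)
  pts <- V[sample(nrow(V), nPts, replace = TRUE), ] +
    matrix(runif(nPts * 3, -0.5, 0.5), ncol = 3)
  bi <- suppressWarnings(buildInterpolation(mesh, pts))
  w <- runif(length(bi$kept), 0.5, 1)
  list(mesh = mesh, K = assembleStiffness(mesh), H = bi$H,
       S = matchStiffness(w), w = w, Ustar = Ustar,
       D = as.numeric(bi$H %*% as.vector(t(Ustar))))
}

test_that("solveInterpolation honours its contracts", {
  s <- smallSystem(1)
  # homogeneous system
  expect_equal(solveInterpolation(s$K, s$H, s$S, rep(0, length(s$D))),
               rep(0, nrow(s$K)))
  # K -> 0 limit reproduces the least-squares solution on matched d.o.f.
  U <- solveInterpolation(s$K * 1e-10, s$H, s$S, s$D)
  expect_equal(as.numeric(s$H %*% U), s$D, tolerance = 1e-4)
  # pseudo-inverse oracle comparison of the fit itself
  Hd <- as.matrix(s$H)
  Sd <- diag(rep(s$w, each = 3))
  Uopt <- MASS::ginv(t(Hd) %*% Sd %*% Hd) %*% (t(Hd) %*% Sd %*% s$D)
  rOpt <- as.numeric(t(Hd %*% Uopt - s$D) %*% Sd %*% (Hd %*% Uopt - s$D))
  rOurs <- sum(blockError(U, s$H, s$S, s$D))
  expect_lt(rOurs - rOpt, 1e-6 * sum(s$D^2))
  # fixed point of the relaxed system: F = K U_prev with D = H U_prev
  Uprev <- as.vector(t(s$Ustar))
  F <- as.numeric(s$K %*% Uprev)
  Ufp <- solveInterpolation(s$K, s$H, s$S,
                            as.numeric(s$H %*% Uprev), F = F)
  expect_equal(Ufp, Uprev, tolerance = 1e-6)
})

test_that("indefinite systems raise a conditioning error", {
  s <- smallSystem(2)
  suppressWarnings(
    expect_error(solveInterpolation(-s$K, s$H, s$S * 1e-12, s$D),
                 "positive definite"))
})

test_that("blockError ranks mismatching blocks and scales with S", {
  s <- smallSystem(3)
  U <- as.vector(t(s$Ustar))
  xi <- blockError(U, s$H, s$S, s$D)
  expect_equal(xi, rep(0, length(xi)), tolerance = 1e-20)
  # corrupt one block by +10 mm: it attains the max error
  k <- 7L
  D2 <- s$D
  D2[(3 * k - 2):(3 * k)] <- D2[(3 * k - 2):(3 * k)] + 10
  xi2 <- blockError(U, s$H, s$S, D2)
  expect_equal(which.max(xi2), k)
  # homogeneity: scaling S scales xi, ranking unchanged
  xi3 <- blockError(U, s$H, s$S * 2.5, D2)
  expect_equal(xi3, 2.5 * xi2, tolerance = 1e-12)
  expect_equal(order(-xi3), order(-xi2))
})

test_that("register degenerates to pure interpolation and is deterministic", {
  s <- smallSystem(4)
  cfg0 <- solverConfig(nR = 0, fR = 0, relaxMaxIter = 0,
                       stiffnessScale = 1)
  r1 <- robustRegister(s$K, s$H, s$S, s$D, cfg0)
  expect_equal(r1$U, solveInterpolation(s$K, s$H, s$S, s$D),
               tolerance = 1e-12)
  r2 <- robustRegister(s$K, s$H, s$S, s$D, cfg0)
  expect_identical(r1$U, r2$U)            # bit-identical reruns
  expect_identical(r1$log, r2$log)
})

test_that("relaxation residual is monotonically non-increasing", {
  s <- smallSystem(5)
  # noisy targets so the relaxation has real work to do
  set.seed(55)
  D <- s$D + rnorm(length(s$D), sd = 0.3)
  r <- robustRegister(s$K, s$H, s$S, D,
                      solverConfig(nR = 0, fR = 0, relaxTol = 1e-8,
                                   relaxMaxIter = 40))
  res <- vapply(Filter(function(l) l$phase == "relax", r$log),
                `[[`, numeric(1), "residual")
  expect_true(all(diff(res) <= 1e-8 * res[-length(res)] + 1e-12))
})

test_that("rejection schedule discards exactly floor(fR n) worst matches", {
  # enough matches that the fit cannot absorb the outliers
  s <- smallSystem(6, nPts = 400)
  n <- nrow(s$H) / 3
  set.seed(66)
  bad <- sample(n, 20)
  D <- s$D
  for (k in bad) D[(3 * k - 2):(3 * k)] <- D[(3 * k - 2):(3 * k)] +
    runif(3, 5, 8)
  cfg <- solverConfig(nR = 4, fR = 0.25)
  r <- robustRegister(s$K, s$H, s$S, D, cfg)
  rejected <- unlist(lapply(r$log, `[[`, "rejected"))
  expect_equal(length(rejected), floor(0.25 * n))
  expect_equal(sum(!r$active), floor(0.25 * n))
  # most rejected ids are the corrupted ones
  expect_gte(mean(bad %in% rejected), 0.9)
  # per-iteration counts follow the schedule (remainder in the last round)
  perIter <- vapply(Filter(function(l) l$phase == "reject", r$log),
                    function(l) length(l$rejected), integer(1))
  expect_equal(sum(perIter), floor(0.25 * n))
  expect_true(all(perIter[-length(perIter)] == floor(floor(0.25 * n) / 4)))
})

test_that("nodal fields rasterise correctly to dense fields", {
  ph <- makePhantom(phantomSpec(size = c(16, 16, 16), deformMax = 0,
                                seed = 7))
  mesh <- bccMesh(ph$labels, 5)
  N <- nrow(vertices(mesh))
  # U = 0 -> zero field
  f0 <- nodalToDense(mesh, matrix(0, N, 3), ph$preop)
  expect_true(all(fieldValues(f0) == 0))
  # constant U -> constant inside the hull, zero outside
  fc <- nodalToDense(mesh, matrix(rep(c(1, 2, 3), each = N), N, 3),
                     ph$preop)
  vals <- fieldValues(fc)
  inside <- rowSums(abs(vals)) > 0
  expect_gt(sum(inside), 0)
  expect_equal(unique(round(vals[inside, 1], 9)), 1)
  expect_equal(unique(round(vals[inside, 3], 9)), 3)
  # vertex-coincident voxels carry the nodal values
  set.seed(8)
  m2 <- tetMesh(rbind(c(2, 2, 2), c(6, 2, 2), c(2, 6, 2), c(2, 2, 6)),
                matrix(1:4, 1))
  U2 <- matrix(rnorm(12), 4, 3)
  fr <- nodalToDense(m2, U2, ph$preop)
  for (v in 1:4) {
    ijk <- vertices(m2)[v, ] + 1
    expect_equal(fr@u[ijk[1], ijk[2], ijk[3], ], U2[v, ], tolerance = 1e-9)
  }
  # extension band continues the boundary values outward
  fe <- nodalToDense(mesh, matrix(rep(c(1, 2, 3), each = N), N, 3),
                     ph$preop, extend = 2)
  expect_gt(sum(rowSums(abs(fieldValues(fe))) > 0), sum(inside))
})

test_that("warpImage implements backward warping with boundary zeros", {
  ph <- makePhantom(phantomSpec(size = c(24, 24, 24), deformMax = 0,
                                seed = 9))
  img <- ph$preop
  zero <- denseField(array(0, c(24, 24, 24, 3)), img)
  expect_equal(imgData(warpImage(img, zero)), imgData(img))
  # constant displacement equals an integer shift away from the border
  u <- denseField(array(rep(c(1, 0, 0), each = 24^3), c(24, 24, 24, 3)),
                  img)
  w <- warpImage(img, u, order = 1)
  expect_equal(imgData(w)[2:24, , ], imgData(img)[1:23, , ],
               tolerance = 1e-12)
  expect_true(all(imgData(w)[1, , ] == 0))
  # nearest-neighbour label warp stays within the input label set
  lw <- warpImage(ph$labels, u)
  expect_s4_class(lw, "LabelImage")
  expect_true(all(imgData(lw) %in% imgData(ph$labels)))
  expect_error(warpImage(img, denseField(array(0, c(12, 24, 24, 3)),
                                         image3d(array(0, c(12, 24, 24)))) ,
                         order = 1), "geometry")
})
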