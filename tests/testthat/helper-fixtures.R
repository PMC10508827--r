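# Shared fixtures and independent pure-R oracles.

# Small textured image with reproducible content.
makeTestImage <- function(dim = c(12, 10, 8), spacing = c(1, 1, 1),
                          origin = c(0, 0, 0), seed = 1) {
  set.seed(seed)
  image3d(array(rnorm(prod(dim)), dim), spacing, origin)
}

# Unit right tetrahedron.
unitTet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))

twoTetMesh <- function() {
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  tetMesh(V, rbind(c(1, 2, 3, 4), c(2, 3, 4, 5)), c(1L, 1L))
}

# Brute-force directed/symmetric Hausdorff (double loop, independent of the
# packaged scan).
bruteHausdorff <- function(A, B) {
  h <- function(X, Y)
    max(apply(X, 1, function(x)
      min(sqrt((Y[, 1] - x[1])^2 + (Y[, 2] - x[2])^2 +
                 (Y[, 3] - x[3])^2))))
  max(h(A, B), h(B, A))
}

# Element stiffness by 4-point Gauss quadrature with numerically
# differentiated shape functions — an independent route to V B' C B.
quadratureStiffness <- function(X, E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  C <- diag(c(rep(lam + 2 * mu, 3), rep(mu, 3)))
  C[1:3, 1:3][upper.tri(diag(3)) | lower.tri(diag(3))] <- lam
  # shape functions in barycentric form evaluated at world x via solve
  shape <- function(x) {
    M <- rbind(1, t(X))        # 4 x 4: [1; coords] columns per vertex
    as.numeric(solve(M, c(1, x)))
  }
  gradShape <- function(x, h = 1e-6) {
    g <- matrix(0, 4, 3)
    for (ax in 1:3) {
      e <- numeric(3); e[ax] <- h
      g[, ax] <- (shape(x + e) - shape(x - e)) / (2 * h)
    }
    g
  }
  Bmat <- function(g) {
    B <- matrix(0, 6, 12)
    for (v in 1:4) {
      c0 <- 3 * (v - 1)
      b <- g[v, ]
      B[1, c0 + 1] <- b[1]; B[2, c0 + 2] <- b[2]; B[3, c0 + 3] <- b[3]
      B[4, c0 + 1] <- b[2]; B[4, c0 + 2] <- b[1]
      B[5, c0 + 2] <- b[3]; B[5, c0 + 3] <- b[2]
      B[6, c0 + 1] <- b[3]; B[6, c0 + 3] <- b[1]
    }
    B
  }
  vol <- abs(det(rbind(X[2, ] - X[1, ], X[3, ] - X[1, ],
                       X[4, ] - X[1, ]))) / 6
  a <- (5 - sqrt(5)) / 20
  b <- (5 + 3 * sqrt(5)) / 20
  qp <- rbind(c(b, a, a, a), c(a, b, a, a), c(a, a, b, a), c(a, a, a, b))
  Ke <- matrix(0, 12, 12)
  for (q in 1:4) {
    x <- as.numeric(qp[q, ] %*% X)
    B <- Bmat(gradShape(x))
    Ke <- Ke + (vol / 4) * t(B) %*% C %*% B
  }
  Ke
}

# Rigid-body basis (3 translations + 3 infinitesimal rotations) for vertex
# set V, as columns of a 3N x 6 matrix.
rigidBasis <- function(V) {
  N <- nrow(V)
  basis <- matrix(0, 3 * N, 6)
  for (ax in 1:3) basis[seq(ax, 3 * N, by = 3), ax] <- 1
  om <- diag(3)
  for (r in 1:3) {
    w <- om[r, ]
    rot <- t(apply(V, 1, function(x)
      c(w[2] * x[3] - w[3] * x[2], w[3] * x[1] - w[1] * x[3],
        w[1] * x[2] - w[2] * x[1])))
    basis[, 3 + r] <- as.vector(t(rot))
  }
  basis
}
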