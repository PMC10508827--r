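#' Construct a material table
#'
#' @param labels integer tissue labels.
#' @param E Young's moduli in Pa (recycled).
#' @param nu Poisson ratios (recycled).
#' @return a \linkS4class{MaterialTable}.
#' @export
materialTable <- function(labels, E, nu) {
  new("MaterialTable", labels = as.integer(labels),
      E = rep_len(as.numeric(E), length(labels)),
      nu = rep_len(as.numeric(nu), length(labels)))
}

#' Default brain materials
#'
#' Defaults of this package (not measured values): brain parenchyma
#' (label 1) E = 3000 Pa, nu = 0.45; tumour (label 2) E = 9000 Pa,
#' nu = 0.45. Only the stiffness ratios matter to the registration solution
#' once the regularization scale is fixed.
#'
#' @return a \linkS4class{MaterialTable}.
#' @export
defaultMaterials <- function() {
  materialTable(c(1L, 2L), c(3000, 9000), c(0.45, 0.45))
}

setMethod("show", "MaterialTable", function(object) {
  cat("MaterialTable:\n")
  for (i in seq_along(object@labels))
    cat(sprintf("  label %d: E = %g Pa, nu = %g\n", object@labels[i],
                object@E[i], object@nu[i]))
})

# 6x6 isotropic Hooke matrix in Voigt order (xx, yy, zz, xy, yz, zx).
hookeMatrix <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  C <- diag(c(rep(lam + 2 * mu, 3), rep(mu, 3)))
  C[1:3, 1:3][upper.tri(diag(3)) | lower.tri(diag(3))] <- lam
  C
}

# Constant strain-displacement matrix B (6 x 12) of the linear tetrahedron
# with vertex coordinates in the rows of X (4 x 3). d.o.f. order:
# (u1x, u1y, u1z, u2x, ...).
tetBMatrix <- function(X) {
  J <- rbind(X[2, ] - X[1, ], X[3, ] - X[1, ], X[4, ] - X[1, ])
  g <- solve(J)                       # columns: gradients of N2..N4
  grads <- rbind(-colSums(t(g)), t(g))  # 4 x 3, gradient of each shape fn
  B <- matrix(0, 6, 12)
  for (v in 1:4) {
    c0 <- 3 * (v - 1)
    b <- grads[v, ]
    B[1, c0 + 1] <- b[1]
    B[2, c0 + 2] <- b[2]
    B[3, c0 + 3] <- b[3]
    B[4, c0 + 1] <- b[2]; B[4, c0 + 2] <- b[1]
    B[5, c0 + 2] <- b[3]; B[5, c0 + 3] <- b[2]
    B[6, c0 + 1] <- b[3]; B[6, c0 + 3] <- b[1]
  }
  B
}

#' Element stiffness of a 4-node linear tetrahedron
#'
#' K_e = V B' C B with the constant strain-displacement matrix B of the
#' linear tetrahedron and the isotropic Hooke matrix C(E, nu); symmetric
#' positive semidefinite with the 6 rigid-body modes as null space.
#'
#' @param X 4 x 3 matrix of vertex coordinates, mm.
#' @param E Young's modulus, Pa.
#' @param nu Poisson ratio, in (-1, 0.5).
#' @return 12 x 12 symmetric matrix (d.o.f. blocked per vertex x, y, z).
#' @export
elementStiffness <- function(X, E, nu) {
  X <- as.matrix(X)
  vol <- det(rbind(X[2, ] - X[1, ], X[3, ] - X[1, ], X[4, ] - X[1, ])) / 6
  if (abs(vol) <= 1e-12)
    stop(sprintf("degenerate tetrahedron (volume %.3g mm^3)", vol),
         call. = FALSE)
  B <- tetBMatrix(X)
  Ke <- abs(vol) * crossprod(B, hookeMatrix(E, nu) %*% B)
  (Ke + t(Ke)) / 2
}

#' Assemble the global stiffness matrix
#'
#' Scatter-adds every element stiffness into the sparse symmetric 3N x 3N
#' matrix K. D.o.f. ordering: vertex-blocked (x1, y1, z1, x2, ...).
#'
#' @param mesh a \linkS4class{TetMesh}.
#' @param materials a \linkS4class{MaterialTable} covering every tet label.
#' @return a sparse symmetric \code{Matrix::dsCMatrix}; attribute
#'   "provenance" records vertex/element counts and the material table.
#' @export
assembleStiffness <- function(mesh, materials = defaultMaterials()) {
  stopifnot(is(mesh, "TetMesh"), is(materials, "MaterialTable"))
  lab <- mesh@labels
  mi <- match(lab, materials@labels)
  if (anyNA(mi))
    stop(sprintf("no material for tissue label(s): %s",
                 paste(sort(unique(lab[is.na(mi)])), collapse = ", ")),
         call. = FALSE)
  m <- nrow(mesh@tets)
  N <- nrow(mesh@vertices)
  ii <- integer(144L * m)
  jj <- integer(144L * m)
  xx <- numeric(144L * m)
  pos <- 0L
  idx12 <- function(verts) as.vector(t(cbind(3L * verts - 2L,
                                             3L * verts - 1L, 3L * verts)))
  # cache Hooke matrices per material row
  for (e in seq_len(m)) {
    verts <- mesh@tets[e, ]
    Ke <- elementStiffness(mesh@vertices[verts, ], materials@E[mi[e]],
                           materials@nu[mi[e]])
    dof <- idx12(verts)
    ii[pos + 1:144] <- rep(dof, times = 12)
    jj[pos + 1:144] <- rep(dof, each = 12)
    xx[pos + 1:144] <- as.vector(Ke)
    pos <- pos + 144L
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(3L * N, 3L * N))
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2, uplo = "U")
  attr(K, "provenance") <- list(nVertices = N, nTets = m,
                                materials = materials)
  K
}

#' Barycentric interpolation matrix from mesh d.o.f. to point d.o.f.
#'
#' For each world point inside some tetrahedron, emits a 3-row block with
#' the four barycentric weights on the containing tet's vertex blocks
#' (weights >= -1e-9, renormalised to sum exactly 1). Points outside every
#' tet are dropped and reported.
#'
#' @param mesh a \linkS4class{TetMesh}.
#' @param points n x 3 matrix of world coordinates, mm.
#' @return list with \code{H} (sparse 3k x 3N), \code{kept} (indices of the
#'   located points), \code{tet} (1-based containing tet per kept point) and
#'   \code{weights} (k x 4 barycentric weights).
#' @export
buildInterpolation <- function(mesh, points) {
  stopifnot(is(mesh, "TetMesh"))
  points <- matrix(as.numeric(points), ncol = 3)
  N <- nrow(mesh@vertices)
  loc <- cpp_locate_points(mesh@vertices, mesh@tets - 1L, points, 1e-9)
  kept <- which(loc[, 1] >= 0)
  if (length(kept) < nrow(points))
    warning(sprintf("%d of %d points lie outside the mesh and were dropped",
                    nrow(points) - length(kept), nrow(points)),
            call. = FALSE)
  k <- length(kept)
  tet <- as.integer(loc[kept, 1]) + 1L
  w <- loc[kept, 2:5, drop = FALSE]
  w <- pmax(w, 0)
  w <- w / rowSums(w)
  ii <- integer(12L * k)
  jj <- integer(12L * k)
  xx <- numeric(12L * k)
  for (q in seq_len(k)) {
    verts <- mesh@tets[tet[q], ]
    r0 <- 3L * (q - 1L)
    p0 <- 12L * (q - 1L)
    for (ax in 1:3) {
      ii[p0 + (ax - 1L) * 4L + 1:4] <- r0 + ax
      jj[p0 + (ax - 1L) * 4L + 1:4] <- 3L * (verts - 1L) + ax
      xx[p0 + (ax - 1L) * 4L + 1:4] <- w[q, ]
    }
  }
  H <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(3L * k, 3L * N))
  list(H = H, kept = kept, tet = tet, weights = w)
}

#' Block-matching stiffness matrix S
#'
#' Sparse block-diagonal 3n x 3n matrix whose k-th 3x3 block is w_k I3 with
#' w_k = max(confidence_k, 0)^2: matches with higher NCC confidence get
#' proportionally higher weight; negative-correlation matches get zero.
#'
#' @param weights numeric(n) non-negative per-match weights.
#' @return a sparse diagonal Matrix.
#' @export
matchStiffness <- function(weights) {
  Matrix::Diagonal(x = rep(as.numeric(weights), each = 3L))
}
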