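#' Isotropic k-th-closest-point mesh sizing
#'
#' Sets the local spacing at each vertex to the Euclidean distance to its
#' k-th nearest registration point (so that, at ideal spacing, each vertex
#' cell complex holds about k registration points), clamped below by
#' \code{minSpacing} to avoid zero sizing at vertices coincident with a
#' registration point.
#'
#' @param verts N x 3 matrix of mesh vertex coordinates, mm.
#' @param points n x 3 matrix of registration points, mm (n >= k).
#' @param k which nearest neighbour defines the spacing (>= 1).
#' @param minSpacing lower clamp, mm.
#' @return a \linkS4class{MetricField} (isotropic).
#' @export
sizingIsotropic <- function(verts, points, k = 5L, minSpacing = 0.5) {
  verts <- rbindable(verts)
  points <- rbindable(points)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (nrow(points) < k)
    stop(sprintf("need at least k = %d registration points, got %d", k,
                 nrow(points)), call. = FALSE)
  sp <- apply(verts, 1, function(v) {
    d2 <- (points[, 1] - v[1])^2 + (points[, 2] - v[2])^2 +
      (points[, 3] - v[3])^2
    sqrt(sort(d2, partial = k)[k])
  })
  new("MetricField", vertices = verts, type = "isotropic",
      spacing = pmax(sp, minSpacing), tensors = array(0, c(0, 0, 0)))
}

#' Minimum-volume enclosing ellipsoid (Khachiyan algorithm)
#'
#' Barycentric coordinate-descent on the lifted points [x; 1]: at each step
#' the point with the largest Mahalanobis value gets its weight increased
#' until the dual gap is below \code{tol}. Every input point then satisfies
#' (x - c)' M (x - c) <= 1 + tol. Degenerate (coplanar/collinear) inputs
#' are regularised by an isotropic jitter of 1e-6 x bounding-box diagonal
#' added to the moment matrix and flagged in the result.
#'
#' @param points n x 3 matrix, n >= 4 for a full-rank result.
#' @param tol convergence tolerance (default 1e-6).
#' @param maxIter iteration cap (default 1e5).
#' @return an \linkS4class{Ellipsoid}.
#' @export
mvee <- function(points, tol = 1e-6, maxIter = 1e5) {
  P <- rbindable(points)
  n <- nrow(P)
  if (n < 1) stop("need at least one point", call. = FALSE)
  d <- 3
  Q <- t(cbind(P, 1))                       # (d+1) x n
  u <- rep(1 / n, n)
  it <- 0
  repeat {
    X <- Q %*% (u * t(Q))                   # (d+1) x (d+1) moment matrix
    Xi <- tryCatch(solve(X), error = function(e) NULL)
    if (is.null(Xi)) break                  # rank-deficient: regularise below
    m <- colSums(Q * (Xi %*% Q))            # Mahalanobis values
    j <- which.max(m)
    maxM <- m[j]
    if (maxM <= (d + 1) * (1 + tol) || it >= maxIter) break
    step <- (maxM - d - 1) / ((d + 1) * (maxM - 1))
    u <- (1 - step) * u
    u[j] <- u[j] + step
    it <- it + 1
  }
  ctr <- as.numeric(t(P) %*% u)
  cov <- t(P) %*% (u * P) - tcrossprod(ctr)
  degenerate <- FALSE
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  bbox <- max(apply(P, 2, function(x) diff(range(x))), 1e-12)
  if (min(ev) <= 1e-12 * max(abs(ev), 1)) {
    cov <- cov + diag(3) * (1e-6 * bbox)^2
    degenerate <- TRUE
  }
  M <- solve(cov) / d
  M <- (M + t(M)) / 2
  # rescale so the farthest input point lies exactly on the boundary:
  # containment then holds to machine precision while the volume stays
  # within the dual gap of optimal
  Pc <- P - matrix(ctr, n, 3, byrow = TRUE)
  maxc <- max(rowSums((Pc %*% M) * Pc))
  if (maxc > 1) M <- M / maxc
  new("Ellipsoid", center = ctr, M = M, degenerate = degenerate)
}

#' Ellipsoid volume
#'
#' @param e an \linkS4class{Ellipsoid}.
#' @return volume in mm^3: (4 pi / 3) / sqrt(det M).
#' @export
ellipsoidVolume <- function(e) {
  (4 * pi / 3) / sqrt(det(e@M))
}

setMethod("show", "Ellipsoid", function(object) {
  cat(sprintf("Ellipsoid centred at (%.3g, %.3g, %.3g), volume %.4g mm^3%s\n",
              object@center[1], object@center[2], object@center[3],
              ellipsoidVolume(object),
              if (object@degenerate) " (regularised)" else ""))
})

#' Anisotropic vertex metric from the k closest registration points
#'
#' Takes the k registration points nearest to the vertex, adds their point
#' reflections 2v - p through the vertex (so the bounding ellipsoid is
#' centred at the vertex by symmetry), fits the minimum-volume enclosing
#' ellipsoid, and inflates it by the constant a (semi-axes scaled by a,
#' i.e. M <- M / a^2). The returned tensor's centre is exactly the vertex
#' by construction.
#'
#' @param vertex numeric(3), mm.
#' @param points n x 3 registration points, mm (n >= k).
#' @param k number of nearest points used (default 5).
#' @param a inflation constant >= 1 (default 1.2).
#' @param tol MVEE tolerance.
#' @param minSpacing fallback isotropic radius when all k points coincide
#'   with the vertex.
#' @return 3 x 3 SPD metric tensor; attribute "degenerate" as in
#'   \code{\link{mvee}}.
#' @export
metricAnisotropic <- function(vertex, points, k = 5L, a = 1.2, tol = 1e-6,
                              minSpacing = 0.5) {
  vertex <- as.numeric(vertex)
  points <- rbindable(points)
  if (a < 1) stop("inflation constant a must be >= 1", call. = FALSE)
  if (nrow(points) < k)
    stop(sprintf("need at least k = %d registration points", k),
         call. = FALSE)
  d2 <- (points[, 1] - vertex[1])^2 + (points[, 2] - vertex[2])^2 +
    (points[, 3] - vertex[3])^2
  nearest <- points[order(d2)[seq_len(k)], , drop = FALSE]
  if (max(d2[order(d2)[seq_len(k)]]) <= 1e-24) {
    # all k points coincide with the vertex: isotropic clamp tensor
    return(structure(diag(3) / (a * minSpacing)^2, degenerate = TRUE))
  }
  refl <- sweep(-nearest, 2, 2 * vertex, `+`)
  e <- mvee(rbind(nearest, refl), tol = tol)
  M <- e@M / a^2
  structure((M + t(M)) / 2, degenerate = e@degenerate, center = vertex)
}

#' Anisotropic metric field over mesh vertices
#'
#' \code{\link{metricAnisotropic}} applied to every vertex.
#'
#' @inheritParams sizingIsotropic
#' @inheritParams metricAnisotropic
#' @return a \linkS4class{MetricField} (anisotropic).
#' @export
metricFieldAnisotropic <- function(verts, points, k = 5L, a = 1.2,
                                   tol = 1e-6, minSpacing = 0.5) {
  verts <- rbindable(verts)
  tens <- array(0, c(3, 3, nrow(verts)))
  for (i in seq_len(nrow(verts)))
    tens[, , i] <- metricAnisotropic(verts[i, ], points, k, a, tol,
                                     minSpacing)
  new("MetricField", vertices = verts, type = "anisotropic",
      spacing = numeric(0), tensors = tens)
}

setMethod("show", "MetricField", function(object) {
  cat(sprintf("MetricField (%s) on %d vertices\n", object@type,
              nrow(object@vertices)))
})

#' Export / read a metric field (VTK legacy point data)
#'
#' Writes a VTK legacy ASCII polydata file with the vertices as points and
#' either a scalar "spacing" array or a 6-component symmetric-tensor
#' "metric" field array (order xx, yy, zz, xy, yz, xz) — the hand-off
#' format for external metric-driven remeshers.
#'
#' @param field a \linkS4class{MetricField} with >= 1 vertex.
#' @param path output path.
#' @export
exportMetric <- function(field, path) {
  stopifnot(is(field, "MetricField"))
  n <- nrow(field@vertices)
  if (n == 0L) stop("empty metric field", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  V <- field@vertices
  writeLines(c("# vtk DataFile Version 3.0", "mesh sizing metric", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.17g %.17g %.17g", V[, 1], V[, 2], V[, 3]), con)
  writeLines(sprintf("POINT_DATA %d", n), con)
  if (field@type == "isotropic") {
    writeLines(c("SCALARS spacing double 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.17g", field@spacing), con)
  } else {
    writeLines(c("FIELD metricField 1", sprintf("metric 6 %d double", n)),
               con)
    tt <- field@tensors
    writeLines(sprintf("%.17g %.17g %.17g %.17g %.17g %.17g",
                       tt[1, 1, ], tt[2, 2, ], tt[3, 3, ],
                       tt[1, 2, ], tt[2, 3, ], tt[1, 3, ]), con)
  }
  invisible(NULL)
}

#' @rdname exportMetric
#' @return \code{readMetric}: the \linkS4class{MetricField} read back.
#' @export
readMetric <- function(path) {
  tok <- scan(path, what = "character", quiet = TRUE)
  i <- match("POINTS", toupper(tok))
  if (is.na(i)) stop(sprintf("'%s' is not a VTK point-data file", path),
                     call. = FALSE)
  n <- as.integer(tok[i + 1L])
  V <- matrix(as.numeric(tok[(i + 3L):(i + 2L + 3L * n)]), ncol = 3,
              byrow = TRUE)
  j <- which(toupper(tok) == "SCALARS" & c(tolower(tok[-1]), "") == "spacing")
  if (length(j)) {
    start <- j[1] + 6L   # SCALARS spacing double 1 LOOKUP_TABLE default
    sp <- as.numeric(tok[start:(start + n - 1L)])
    return(new("MetricField", vertices = V, type = "isotropic",
               spacing = sp, tensors = array(0, c(0, 0, 0))))
  }
  pd <- which(toupper(tok) == "POINT_DATA")[1]
  j <- which(tolower(tok) == "metric" & seq_along(tok) > pd)
  if (!length(j)) stop(sprintf("no metric arrays in '%s'", path),
                       call. = FALSE)
  start <- j[1] + 4L     # metric 6 <n> double
  vals <- matrix(as.numeric(tok[start:(start + 6L * n - 1L)]), ncol = 6,
                 byrow = TRUE)
  tens <- array(0, c(3, 3, n))
  tens[1, 1, ] <- vals[, 1]; tens[2, 2, ] <- vals[, 2]
  tens[3, 3, ] <- vals[, 3]
  tens[1, 2, ] <- tens[2, 1, ] <- vals[, 4]
  tens[2, 3, ] <- tens[3, 2, ] <- vals[, 5]
  tens[1, 3, ] <- tens[3, 1, ] <- vals[, 6]
  new("MetricField", vertices = V, type = "anisotropic",
      spacing = numeric(0), tensors = tens)
}
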