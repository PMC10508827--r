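#' Solver configuration
#'
#' @param nR number of outlier-rejection iterations (>= 0).
#' @param fR total fraction of matches to discard, in [0, 1).
#' @param relaxTol relative-change threshold ||U_{i+1} - U_i|| / ||U_{i+1}||
#'   ending the final relaxation loop.
#' @param relaxMaxIter cap on relaxation iterations.
#' @param linearTol required relative residual of each inner linear solve.
#' @param stiffnessScale dimensionless factor multiplying K, or "auto" to
#'   set trace(scale K) / trace(H' S H) = \code{autoRatio}.
#' @param autoRatio target stiffness/data trace ratio for "auto".
#' @return a list of class "SolverConfig".
#' @export
solverConfig <- function(nR = 5L, fR = 0.25, relaxTol = 1e-3,
                         relaxMaxIter = 50L, linearTol = 1e-8,
                         stiffnessScale = "auto", autoRatio = 10) {
  if (fR < 0 || fR >= 1) stop("fR must lie in [0, 1)", call. = FALSE)
  if (nR < 0) stop("nR must be >= 0", call. = FALSE)
  if (relaxTol <= 0 || linearTol <= 0)
    stop("tolerances must be > 0", call. = FALSE)
  structure(list(nR = as.integer(nR), fR = fR, relaxTol = relaxTol,
                 relaxMaxIter = as.integer(relaxMaxIter),
                 linearTol = linearTol, stiffnessScale = stiffnessScale,
                 autoRatio = autoRatio),
            class = "SolverConfig")
}

# Resolve the dimensionless stiffness scale (see solverConfig).
resolveStiffnessScale <- function(cfg, K, H, S) {
  if (identical(cfg$stiffnessScale, "auto")) {
    trK <- sum(Matrix::diag(K))
    trHSH <- sum(Matrix::rowSums(H^2) * Matrix::diag(S))
    if (trK <= 0) return(1)
    cfg$autoRatio * trHSH / trK
  } else as.numeric(cfg$stiffnessScale)
}

# Factor A = K + H'SH (symmetric sparse Cholesky); conditioning error with a
# smallest-eigenvalue estimate when the system is not positive definite.
factorSystem <- function(A, linearTol) {
  A <- Matrix::forceSymmetric(A)
  ch <- tryCatch(Matrix::Cholesky(A, LDL = FALSE, perm = TRUE),
                 error = function(e) e)
  if (inherits(ch, "error")) {
    lmin <- tryCatch({
      if (nrow(A) <= 600)
        min(eigen(as.matrix(A), symmetric = TRUE, only.values = TRUE)$values)
      else NA_real_
    }, error = function(e) NA_real_)
    stop(sprintf(
      "system K + H'SH is not positive definite (smallest eigenvalue ~ %s); too few or degenerate matches",
      format(lmin)), call. = FALSE)
  }
  ch
}

solveWith <- function(ch, A, b, linearTol) {
  x <- as.numeric(Matrix::solve(ch, b))
  res <- sqrt(sum((as.numeric(A %*% x) - b)^2))
  nb <- sqrt(sum(b^2))
  if (nb > 0 && res / nb > linearTol)
    stop(sprintf("linear solve did not reach the residual tolerance (%.3g > %.3g)",
                 res / nb, linearTol), call. = FALSE)
  x
}

#' Solve the interpolation / relaxed registration system
#'
#' Solves (K + H'SH) U = H'SD (+ F) for the nodal displacement vector U.
#' With F = NULL this is the pure interpolation formulation; a non-zero F
#' is the external-force relaxation used by \code{\link{robustRegister}}.
#'
#' @param K sparse 3N x 3N stiffness matrix (already scaled).
#' @param H sparse 3n x 3N interpolation matrix.
#' @param S sparse 3n x 3n match-weight matrix.
#' @param D numeric(3n) stacked match displacements, mm.
#' @param F optional numeric(3N) external force.
#' @param linearTol relative residual bound for the solve.
#' @return numeric(3N) nodal displacements, mm.
#' @export
solveInterpolation <- function(K, H, S, D, F = NULL, linearTol = 1e-8) {
  A <- K + Matrix::crossprod(H, S %*% H)
  b <- as.numeric(Matrix::crossprod(H, S %*% D))
  if (!is.null(F)) b <- b + as.numeric(F)
  ch <- factorSystem(A, linearTol)
  solveWith(ch, Matrix::forceSymmetric(A), b, linearTol)
}

#' Per-block model-vs-match error
#'
#' xi_k = (H_k U - D_k)' S_k (H_k U - D_k): the S-weighted squared mismatch
#' between the displacement interpolated from the current mesh solution and
#' the block-matching target, per match.
#'
#' @param U numeric(3N) nodal displacements.
#' @param H,S,D as in \code{\link{solveInterpolation}}.
#' @return numeric(n) per-match errors.
#' @export
blockError <- function(U, H, S, D) {
  r <- as.numeric(H %*% U) - D
  wr <- as.numeric(S %*% r)
  colSums(matrix(r * wr, nrow = 3L))
}

#' Robust registration with iterative fractional outlier rejection
#'
#' Runs the printed outlier-rejection algorithm: nR iterations of
#' \{F <- K U; solve (K + H'SH) U = H'SD + F; compute xi; reject the
#' scheduled number of highest-xi active matches; restrict S, H, D to the
#' active set\}, followed by the relaxation loop \{F <- K U; solve\} until
#' the relative change of U drops below relaxTol or relaxMaxIter is hit.
#' In total floor(fR n) matches are rejected: floor(fR n / nR) per
#' iteration, remainder in the last. Ties in xi break toward lower
#' confidence, then lower match index.
#'
#' @param K sparse 3N x 3N stiffness matrix (unscaled; the configured
#'   stiffness scale is applied internally).
#' @param H sparse 3n x 3N interpolation matrix for all n candidate matches.
#' @param S sparse 3n x 3n weight matrix.
#' @param D numeric(3n) stacked displacements, mm.
#' @param cfg a \code{\link{solverConfig}}.
#' @param confidence optional numeric(n) NCC confidences for tie-breaking
#'   (defaults to the S block weights).
#' @return list with \code{U} (numeric 3N), \code{active} (logical(n) of
#'   surviving matches), \code{log} (per-iteration data.frame-free list:
#'   phase, rejected ids, S-weighted residual, relative change) and
#'   \code{stiffnessScale} (the resolved scale).
#' @export
robustRegister <- function(K, H, S, D, cfg = solverConfig(),
                           confidence = NULL) {
  n <- nrow(H) / 3L
  if (n < 1) stop("no matches to register", call. = FALSE)
  if (is.null(confidence)) confidence <- sqrt(Matrix::diag(S)[3 * 1:n])
  scale <- resolveStiffnessScale(cfg, K, H, S)
  Ks <- K * scale
  totalReject <- floor(cfg$fR * n)
  perIter <- if (cfg$nR > 0) floor(totalReject / cfg$nR) else 0L
  active <- rep(TRUE, n)
  U <- numeric(nrow(K))
  log <- list()
  rows3 <- function(ids) as.vector(rbind(3L * ids - 2L, 3L * ids - 1L,
                                         3L * ids))
  for (it in seq_len(cfg$nR)) {
    ids <- which(active)
    if (length(ids) == 0L)
      stop("all matches rejected; cannot continue", call. = FALSE)
    r3 <- rows3(ids)
    Ha <- H[r3, , drop = FALSE]
    Sa <- S[r3, r3, drop = FALSE]
    Da <- D[r3]
    Fi <- as.numeric(Ks %*% U)
    A <- Ks + Matrix::crossprod(Ha, Sa %*% Ha)
    b <- as.numeric(Matrix::crossprod(Ha, Sa %*% Da)) + Fi
    ch <- factorSystem(A, cfg$linearTol)
    U <- solveWith(ch, Matrix::forceSymmetric(A), b, cfg$linearTol)
    xi <- blockError(U, Ha, Sa, Da)
    nrej <- if (it == cfg$nR) totalReject - perIter * (cfg$nR - 1L)
            else perIter
    nrej <- min(nrej, length(ids) - 1L)
    rejected <- integer(0)
    if (nrej > 0L) {
      ord <- order(-xi, confidence[ids], ids)
      rejected <- ids[ord[seq_len(nrej)]]
      active[rejected] <- FALSE
    }
    log[[length(log) + 1L]] <-
      list(phase = "reject", iter = it, rejected = rejected,
           residual = sum(xi), nActive = sum(active))
  }
  # relaxation toward the approximation formulation
  ids <- which(active)
  r3 <- rows3(ids)
  Ha <- H[r3, , drop = FALSE]
  Sa <- S[r3, r3, drop = FALSE]
  Da <- D[r3]
  A <- Ks + Matrix::crossprod(Ha, Sa %*% Ha)
  ch <- factorSystem(A, cfg$linearTol)
  As <- Matrix::forceSymmetric(A)
  if (cfg$nR == 0L && cfg$relaxMaxIter == 0L) {
    U <- solveWith(ch, As, as.numeric(Matrix::crossprod(Ha, Sa %*% Da)),
                   cfg$linearTol)
    log[[length(log) + 1L]] <- list(phase = "relax", iter = 0L,
                                    rejected = integer(0),
                                    residual = sum(blockError(U, Ha, Sa, Da)),
                                    relChange = NA_real_,
                                    nActive = sum(active))
  }
  b0 <- as.numeric(Matrix::crossprod(Ha, Sa %*% Da))
  for (it in seq_len(cfg$relaxMaxIter)) {
    Uprev <- U
    U <- solveWith(ch, As, b0 + as.numeric(Ks %*% Uprev), cfg$linearTol)
    rel <- sqrt(sum((U - Uprev)^2)) / max(sqrt(sum(U^2)), 1e-300)
    log[[length(log) + 1L]] <-
      list(phase = "relax", iter = it, rejected = integer(0),
           residual = sum(blockError(U, Ha, Sa, Da)), relChange = rel,
           nActive = sum(active))
    if (rel < cfg$relaxTol) break
  }
  list(U = U, active = active, log = log, stiffnessScale = scale)
}

#' Rasterise a nodal field to a dense displacement field
#'
#' Every voxel centre inside some tetrahedron gets the barycentric
#' interpolation of the nodal displacements. With \code{extend > 0} the
#' field is then extrapolated outward by that many voxels (iterative
#' 6-neighbour mean fill), so surface structures just outside the mesh
#' hull — which sits up to half a cell inside the object for a
#' centroid-rule BCC mesh — still move with the object; voxels beyond the
#' extension band get zero displacement.
#'
#' @param mesh a \linkS4class{TetMesh}.
#' @param U N x 3 matrix (or 3N vector) of nodal displacements, mm.
#' @param ref an \linkS4class{Image3D} defining the output grid.
#' @param extend extrapolation band width in voxels (0 = none).
#' @return a \linkS4class{DenseField}.
#' @export
nodalToDense <- function(mesh, U, ref, extend = 0L) {
  if (is.null(dim(U))) U <- matrix(U, ncol = 3, byrow = TRUE)
  stopifnot(nrow(U) == nrow(mesh@vertices))
  dense <- cpp_nodal_to_dense(mesh@vertices, mesh@tets - 1L, U,
                              imgDim(ref), spacing(ref), origin(ref))
  for (i in seq_len(extend))
    dense <- cpp_extend_field(dense, imgDim(ref))
  denseField(dense[, 1:3, drop = FALSE], ref)
}

# Extension band covering the hull's deficit against the object surface:
# half the cell edge implied by the median element volume, plus one voxel.
defaultExtendVoxels <- function(mesh, ref) {
  cell <- (12 * stats::median(tetVolumes(mesh)))^(1 / 3)
  as.integer(ceiling(cell / (2 * min(spacing(ref)))) + 1L)
}

#' Warp an image by a dense displacement field (backward)
#'
#' out(x) = img(x - u(x)) with nearest-neighbour (order 0, for label
#' images) or trilinear (order 1) sampling; out-of-bounds samples get 0.
#'
#' @param img the image to resample.
#' @param field a \linkS4class{DenseField} with the output geometry.
#' @param order 0 (nearest) or 1 (trilinear); default 0 for
#'   \linkS4class{LabelImage} input, else 1.
#' @return an image of the same class as \code{img}.
#' @export
warpImage <- function(img, field, order = if (is(img, "LabelImage")) 0L
                      else 1L) {
  stopifnot(is(img, "Image3D"), is(field, "DenseField"))
  if (!sameGeometry(img, field))
    stop("field geometry does not match the image", call. = FALSE)
  out <- cpp_warp_image(as.vector(img@data), imgDim(img), spacing(img),
                        origin(img), fieldValues(field), as.integer(order))
  dat <- array(out, imgDim(img))
  if (is(img, "LabelImage") && order == 0L)
    labelImage(dat, spacing(img), origin(img))
  else image3d(dat, spacing(img), origin(img))
}

#' End-to-end physics-based non-rigid registration
#'
#' Feature selection on the floating image, block matching against the
#' fixed image, FE assembly on the mesh, robust solve with outlier
#' rejection, and rasterisation of the result: the complete pipeline for a
#' single (non-adaptive) registration pass.
#'
#' @param floating,fixed \linkS4class{Image3D}s sharing geometry.
#' @param mesh \linkS4class{TetMesh} of the floating image's brain mask.
#' @param materials \linkS4class{MaterialTable}.
#' @param spec \code{\link{blockSpec}}.
#' @param cfg \code{\link{solverConfig}}.
#' @param fraction,mask,minSpacing feature-selection parameters
#'   (see \code{\link{selectFeaturePoints}}).
#' @param minConfidence block-matching confidence threshold.
#' @param margin feature-selection border margin in voxels (default B + W,
#'   guaranteeing every point admits the full search range; pass spec$B to
#'   keep near-border features at the cost of a truncated search there).
#' @param matches optional precomputed \linkS4class{MatchSet} (skips
#'   selection/matching; used to inject corrupted matches in experiments).
#' @return list with \code{nodal} (\linkS4class{NodalField}), \code{field}
#'   (\linkS4class{DenseField}), \code{warped} (floating warped into the
#'   fixed space), \code{matches} (\linkS4class{MatchSet} used),
#'   \code{kept} (matches inside the mesh), \code{active} (post-rejection
#'   survivors among kept), \code{log} and \code{stiffnessScale}.
#' @export
registerImages <- function(floating, fixed, mesh,
                           materials = defaultMaterials(),
                           spec = blockSpec(), cfg = solverConfig(),
                           fraction = 0.05, mask = NULL, minSpacing = 3,
                           minConfidence = 0.5, margin = NULL,
                           matches = NULL) {
  if (is.null(matches)) {
    if (is.null(margin)) margin <- spec$B + spec$W
    pts <- selectFeaturePoints(floating, spec, fraction = fraction,
                               mask = mask, minSpacing = minSpacing,
                               margin = margin)
    matches <- blockMatch(floating, fixed, pts, spec, minConfidence)
  }
  if (nMatches(matches) == 0L)
    stop("block matching produced no matches", call. = FALSE)
  interp <- buildInterpolation(mesh, matchWorld(matches))
  if (length(interp$kept) == 0L)
    stop("no match points lie inside the mesh", call. = FALSE)
  kept <- subsetMatches(matches, interp$kept)
  S <- matchStiffness(matchWeights(kept))
  D <- as.vector(t(displacements(kept)))
  K <- assembleStiffness(mesh, materials)
  sol <- robustRegister(K, interp$H, S, D, cfg, confidences(kept))
  U <- matrix(sol$U, ncol = 3, byrow = TRUE)
  field <- nodalToDense(mesh, U, floating,
                        extend = defaultExtendVoxels(mesh, floating))
  list(nodal = new("NodalField", mesh = mesh, u = U),
       field = field,
       warped = warpImage(floating, field, order = 1L),
       matches = matches, kept = interp$kept, active = sol$active,
       log = sol$log, stiffnessScale = sol$stiffnessScale)
}
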