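#' Block / search-window specification
#'
#' Half-extents, in voxels, of the matching block B and of the integer
#' displacement search range W. W is a displacement range, not a window that
#' must contain the block, so no component-wise ordering between B and W is
#' required.
#'
#' @param B integer(3) block half-extent per axis (>= 1).
#' @param W integer(3) search half-range per axis (>= 0).
#' @return a list of class "BlockSpec".
#' @export
blockSpec <- function(B = c(3, 3, 3), W = c(5, 5, 5)) {
  B <- as.integer(rep_len(B, 3L))
  W <- as.integer(rep_len(W, 3L))
  if (any(B < 1L)) stop("block half-extents must be >= 1", call. = FALSE)
  if (any(W < 0L)) stop("window half-extents must be >= 0", call. = FALSE)
  structure(list(B = B, W = W), class = "BlockSpec")
}

#' Select feature (registration) points by local intensity variance
#'
#' Candidate centres are all voxels whose block fits inside the image (and,
#' if a mask is given, whose centre voxel is foreground). Candidates are
#' ranked by the sample variance of the intensities in the block; the top
#' \code{fraction} are kept and then greedily thinned (highest variance
#' first) so that no two selected centres are closer than \code{minSpacing}
#' voxels. Blocks with (numerically) zero variance are never selected.
#'
#' @param img floating \linkS4class{Image3D}.
#' @param spec a \code{\link{blockSpec}}.
#' @param fraction proportion in (0, 1] of candidates to keep by variance.
#' @param mask optional \linkS4class{LabelImage}; centres restricted to
#'   mask > 0.
#' @param minSpacing minimum Euclidean distance between selected centres, in
#'   voxels (0 disables thinning).
#' @param varThreshold optional absolute variance threshold; candidates at
#'   or below it are excluded before ranking (default: the degeneracy
#'   tolerance only).
#' @param margin integer(3) minimum distance of centres from the image
#'   border, in voxels; defaults to B. Block matching requires every point
#'   to admit the full search range, so the registration pipeline selects
#'   with margin B + W.
#' @return n x 3 integer matrix of 0-based voxel indices, ordered by
#'   decreasing block variance.
#' @export
selectFeaturePoints <- function(img, spec = blockSpec(), fraction = 0.05,
                                mask = NULL, minSpacing = 0,
                                varThreshold = NULL, margin = spec$B) {
  stopifnot(is(img, "Image3D"), inherits(spec, "BlockSpec"))
  if (fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]", call. = FALSE)
  d <- imgDim(img)
  B <- spec$B
  margin <- pmax(as.integer(rep_len(margin, 3L)), B)
  if (any(2L * margin + 1L > d))
    stop("no candidate block fits inside the image", call. = FALSE)
  ranges <- lapply(1:3, function(a) margin[a]:(d[a] - margin[a] - 1L))  # 0-based
  centers <- as.matrix(expand.grid(i = ranges[[1]], j = ranges[[2]],
                                   k = ranges[[3]]))
  if (!is.null(mask)) {
    if (!sameGeometry(img, mask))
      stop("mask geometry does not match the image", call. = FALSE)
    keep <- mask@data[centers + 1L] > 0
    centers <- centers[keep, , drop = FALSE]
  }
  if (nrow(centers) == 0L)
    stop("no candidate block fits inside the image/mask", call. = FALSE)
  storage.mode(centers) <- "integer"
  mv <- cpp_block_variance(as.vector(img@data), dim(img@data), B, centers)
  # degeneracy tolerance: constant blocks give variance ~ rounding noise
  tol <- 1e-12 * (1 + mv[, 1]^2)
  if (!is.null(varThreshold)) tol <- pmax(tol, varThreshold)
  ok <- mv[, 2] > tol
  centers <- centers[ok, , drop = FALSE]
  v <- mv[ok, 2]
  if (nrow(centers) == 0L) return(centers)
  ord <- order(-v, centers[, 3], centers[, 2], centers[, 1])
  nkeep <- ceiling(fraction * nrow(centers))
  sel <- centers[ord[seq_len(nkeep)], , drop = FALSE]
  if (minSpacing > 0 && nrow(sel) > 1L)
    sel <- greedyThin(sel, minSpacing)
  sel
}

# Greedy spacing filter: keep points in the given (variance) order, dropping
# any point within minSpacing of an already-kept one.
greedyThin <- function(pts, minSpacing) {
  kept <- matrix(0L, nrow(pts), 3)
  nk <- 0L
  ms2 <- minSpacing^2
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    if (nk == 0L) {
      nk <- 1L
      kept[1, ] <- p
      next
    }
    d2 <- (kept[1:nk, 1] - p[1])^2 + (kept[1:nk, 2] - p[2])^2 +
      (kept[1:nk, 3] - p[3])^2
    if (all(d2 >= ms2)) {
      nk <- nk + 1L
      kept[nk, ] <- p
    }
  }
  kept[seq_len(nk), , drop = FALSE]
}

#' Normalized cross-correlation of two equally shaped blocks
#'
#' \code{sum((a - mean(a)) (b - mean(b))) / sqrt(sum((a - mean(a))^2)
#' sum((b - mean(b))^2))}, invariant to affine intensity rescaling of either
#' block. When either block has zero variance the NCC is undefined: the
#' value 0 is returned with attribute \code{degenerate = TRUE}.
#'
#' @param a,b numeric arrays/vectors of identical shape with >= 2 elements.
#' @return correlation in [-1, 1] with logical attribute "degenerate".
#' @export
ncc <- function(a, b) {
  if (length(a) != length(b) || !identical(dim(a), dim(b)))
    stop("blocks must have identical shape", call. = FALSE)
  if (length(a) < 2L) stop("blocks must have >= 2 voxels", call. = FALSE)
  ac <- as.vector(a) - mean(a)
  bc <- as.vector(b) - mean(b)
  va <- sum(ac^2)
  vb <- sum(bc^2)
  if (va <= 0 || vb <= 0)
    return(structure(0, degenerate = TRUE))
  structure(max(-1, min(1, sum(ac * bc) / sqrt(va * vb))),
            degenerate = FALSE)
}

#' Block matching with exhaustive integer-voxel search
#'
#' For each registration point, every integer displacement d with
#' |d_axis| <= W_axis is evaluated with NCC between the floating block and
#' the displaced fixed block (the paper-stated per-point cost bound
#' O(BxByBz x WxWyWz): exactly prod(2W+1) NCC evaluations, each over
#' prod(2B+1) voxels). The argmax-NCC displacement is converted to mm; ties
#' break toward the smaller displacement norm, then lexicographic
#' (dz, dy, dx). Matches with undefined NCC everywhere or confidence below
#' \code{minConfidence} are dropped. Each surviving match carries the
#' isotropic S weight max(confidence, 0)^2.
#'
#' @param floating,fixed \linkS4class{Image3D}s with identical geometry.
#' @param points n x 3 matrix of 0-based voxel indices (from
#'   \code{\link{selectFeaturePoints}}); every point must admit a full block.
#' @param spec a \code{\link{blockSpec}}.
#' @param minConfidence NCC threshold below which matches are dropped.
#' @return a \linkS4class{MatchSet}; attribute "nccEvaluations" holds the
#'   per-point NCC evaluation count (instrumentation of the cost bound).
#' @export
blockMatch <- function(floating, fixed, points, spec = blockSpec(),
                       minConfidence = 0.5) {
  stopifnot(is(floating, "Image3D"), is(fixed, "Image3D"))
  if (!sameGeometry(floating, fixed))
    stop("floating and fixed images must share geometry", call. = FALSE)
  points <- matrix(as.integer(points), ncol = 3)
  d <- imgDim(floating)
  B <- spec$B
  bad <- points[, 1] < B[1] | points[, 2] < B[2] | points[, 3] < B[3] |
    points[, 1] >= d[1] - B[1] | points[, 2] >= d[2] - B[2] |
    points[, 3] >= d[3] - B[3]
  if (any(bad))
    stop(sprintf("%d points do not admit a full block", sum(bad)),
         call. = FALSE)
  res <- cpp_block_match(as.vector(floating@data), as.vector(fixed@data),
                         d, B, spec$W, points)
  keep <- res[, 6] == 0 & res[, 4] >= minConfidence
  disp <- sweep(res[keep, 1:3, drop = FALSE], 2, spacing(floating), `*`)
  conf <- res[keep, 4]
  ms <- new("MatchSet",
            points = points[keep, , drop = FALSE],
            displacements = disp,
            confidences = conf,
            weights = pmax(conf, 0)^2,
            provenance = list(spec = spec, spacing = spacing(floating),
                              origin = origin(floating), dim = d,
                              minConfidence = minConfidence))
  attr(ms, "nccEvaluations") <- res[, 5]
  ms
}

#' MatchSet accessors
#'
#' @param x a \linkS4class{MatchSet}.
#' @name MatchSet-accessors
NULL

#' @rdname MatchSet-accessors
#' @export
setMethod("matchPoints", "MatchSet", function(x) x@points)

#' @rdname MatchSet-accessors
#' @export
setMethod("displacements", "MatchSet", function(x) x@displacements)

#' @rdname MatchSet-accessors
#' @export
setMethod("confidences", "MatchSet", function(x) x@confidences)

#' @rdname MatchSet-accessors
#' @export
setMethod("matchWeights", "MatchSet", function(x) x@weights)

#' @rdname MatchSet-accessors
#' @export
nMatches <- function(x) nrow(x@points)

setMethod("show", "MatchSet", function(object) {
  n <- nMatches(object)
  cat(sprintf("MatchSet: %d matches\n", n))
  if (n > 0)
    cat(sprintf("  confidence [%.3f, %.3f], max |d| = %.3g mm\n",
                min(object@confidences), max(object@confidences),
                sqrt(max(rowSums(object@displacements^2)))))
})

#' Match world coordinates
#'
#' World positions (mm) of the match block centres in the floating image.
#'
#' @param x a \linkS4class{MatchSet}.
#' @return n x 3 matrix, mm.
#' @export
matchWorld <- function(x) {
  sweep(sweep(matrix(as.numeric(x@points), ncol = 3), 2,
              x@provenance$spacing, `*`), 2, x@provenance$origin, `+`)
}

#' Serialize / read a MatchSet as CSV
#'
#' Columns: i, j, k (0-based voxel index), dx, dy, dz (mm), confidence.
#'
#' @param x a \linkS4class{MatchSet}.
#' @param path CSV path.
#' @export
writeMatches <- function(x, path) {
  df <- data.frame(i = x@points[, 1], j = x@points[, 2], k = x@points[, 3],
                   dx = x@displacements[, 1], dy = x@displacements[, 2],
                   dz = x@displacements[, 3], confidence = x@confidences)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(NULL)
}

#' @rdname writeMatches
#' @param spacing,origin geometry of the floating image the points live on.
#' @export
readMatches <- function(path, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  df <- utils::read.csv(path)
  conf <- df$confidence
  new("MatchSet",
      points = unname(as.matrix(df[, c("i", "j", "k")])),
      displacements = unname(as.matrix(df[, c("dx", "dy", "dz")])),
      confidences = conf, weights = pmax(conf, 0)^2,
      provenance = list(spacing = spacing, origin = origin))
}

#' Restrict a MatchSet to a subset of matches
#'
#' @param x a \linkS4class{MatchSet}.
#' @param keep logical or integer index over matches.
#' @return the restricted \linkS4class{MatchSet}.
#' @export
subsetMatches <- function(x, keep) {
  new("MatchSet", points = x@points[keep, , drop = FALSE],
      displacements = x@displacements[keep, , drop = FALSE],
      confidences = x@confidences[keep], weights = x@weights[keep],
      provenance = x@provenance)
}
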