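#' Hausdorff distance between point sets
#'
#' H(A, B) = max[h(A, B), h(B, A)] with the directed distance
#' h(A, B) = max_a min_b ||a - b||. The default is the untrimmed (100%)
#' variant; \code{percentile} < 100 replaces each directed max by the
#' corresponding quantile of the min-distances (e.g. 95 for the trimmed
#' variant used in earlier work).
#'
#' @param A,B non-empty n x 3 / m x 3 matrices of points, mm.
#' @param percentile directed-distance percentile in (0, 100].
#' @return list-free numeric: H(A, B) in mm, with attributes "hAB" and
#'   "hBA" carrying the two directed distances.
#' @export
hausdorff <- function(A, B, percentile = 100) {
  A <- rbindable(A)
  B <- rbindable(B)
  if (nrow(A) == 0L || nrow(B) == 0L)
    stop("Hausdorff distance requires non-empty point sets", call. = FALSE)
  if (percentile <= 0 || percentile > 100)
    stop("percentile must lie in (0, 100]", call. = FALSE)
  dAB <- cpp_min_dists(A, B)
  dBA <- cpp_min_dists(B, A)
  directed <- function(d) {
    if (percentile >= 100) max(d)
    else sort(d)[ceiling(percentile / 100 * length(d))]
  }
  hAB <- directed(dAB)
  hBA <- directed(dBA)
  structure(max(hAB, hBA), hAB = hAB, hBA = hBA)
}

#' Canny edge points of a 3-D image
#'
#' Full-volume 3-D Canny: Gaussian smoothing, central-difference gradient
#' (in mm), non-maximum suppression along the local gradient direction
#' (trilinear magnitude sampling at a unit voxel step), and hysteresis with
#' 26-connectivity. Thresholds are fractions of the maximum gradient
#' magnitude. A constant image yields an empty set.
#'
#' @param img an \linkS4class{Image3D}.
#' @param low,high hysteresis thresholds as fractions of the maximum
#'   gradient magnitude, 0 < low <= high.
#' @param sigma Gaussian smoothing in mm (default: 1 voxel).
#' @return k x 3 matrix of edge-voxel world coordinates, mm.
#' @export
cannyPoints <- function(img, low = 0.1, high = 0.2,
                        sigma = min(spacing(img))) {
  stopifnot(is(img, "Image3D"))
  if (!(low > 0) || high < low)
    stop("thresholds must satisfy high >= low > 0", call. = FALSE)
  d <- imgDim(img)
  sp <- spacing(img)
  sm <- array(cpp_gauss_smooth(as.vector(img@data), d, sigma / sp), d)
  grad <- function(axis) {
    n <- d[axis]
    idxP <- pmin(seq_len(n) + 1L, n)
    idxM <- pmax(seq_len(n) - 1L, 1L)
    den <- (idxP - idxM) * sp[axis]
    if (axis == 1) (sm[idxP, , , drop = FALSE] - sm[idxM, , , drop = FALSE]) / den
    else if (axis == 2) sweep(sm[, idxP, , drop = FALSE] -
                              sm[, idxM, , drop = FALSE], 2, den, `/`)
    else aperm(sweep(aperm(sm[, , idxP, drop = FALSE] -
                           sm[, , idxM, drop = FALSE], c(3, 1, 2)), 1, den,
                     `/`), c(2, 3, 1))
  }
  gx <- grad(1)
  gy <- grad(2)
  gz <- grad(3)
  mag <- sqrt(gx^2 + gy^2 + gz^2)
  mmax <- max(mag)
  # a constant image leaves only smoothing round-off in the gradients
  if (mmax <= 1e-10 * (max(abs(sm)) + 1)) return(matrix(numeric(0), 0, 3))
  keep <- cpp_canny_nms(as.vector(mag), as.vector(gx), as.vector(gy),
                        as.vector(gz), d, sp)
  strong <- keep & (as.vector(mag) >= high * mmax)
  cand <- keep & (as.vector(mag) >= low * mmax)
  final <- cpp_hysteresis(strong, cand, d)
  idx <- which(array(final, d), arr.ind = TRUE) - 1L
  if (nrow(idx) == 0L) return(matrix(numeric(0), 0, 3))
  indexToWorld(img, idx)
}

#' Canny/Hausdorff evaluation of a registration
#'
#' Extracts Canny edge points from the pre-op image, maps each point
#' p -> p + u(p) into the intra-op space (u sampled trilinearly from the
#' dense field), extracts Canny points from the intra-op image, and
#' reports the Hausdorff distance between the two sets. This is a relative
#' comparison instrument for registration methods, not a clinical accuracy
#' measure, and the report labels it as such.
#'
#' @param preop,intraop \linkS4class{Image3D}s sharing geometry.
#' @param field a \linkS4class{DenseField} (the registration result).
#' @param low,high,sigma Canny parameters, see \code{\link{cannyPoints}}.
#' @param percentile Hausdorff percentile, see \code{\link{hausdorff}}.
#' @return list: \code{hd}, \code{hAB}, \code{hBA} (mm), \code{nPre},
#'   \code{nIntra} (set sizes), \code{note} (the relative-use caveat).
#' @export
evaluateRegistration <- function(preop, intraop, field, low = 0.1,
                                 high = 0.2, sigma = min(spacing(preop)),
                                 percentile = 100) {
  stopifnot(is(preop, "Image3D"), is(intraop, "Image3D"),
            is(field, "DenseField"))
  if (!sameGeometry(preop, intraop) || !sameGeometry(preop, field))
    stop("preop, intraop and field must share geometry", call. = FALSE)
  ptsPre <- cannyPoints(preop, low, high, sigma)
  if (nrow(ptsPre) == 0L)
    stop("no Canny edge points in the pre-operative image", call. = FALSE)
  ptsIntra <- cannyPoints(intraop, low, high, sigma)
  if (nrow(ptsIntra) == 0L)
    stop("no Canny edge points in the intra-operative image",
         call. = FALSE)
  mapped <- ptsPre + sampleField(field, ptsPre)
  hd <- hausdorff(mapped, ptsIntra, percentile)
  list(hd = as.numeric(hd), hAB = attr(hd, "hAB"), hBA = attr(hd, "hBA"),
       nPre = nrow(ptsPre), nIntra = nrow(ptsIntra),
       note = "relative comparison only; not a clinical accuracy measure")
}

#' Landmark registration errors
#'
#' error_i = ||(p_i + u(p_i)) - q_i|| for index-corresponding landmark
#' pairs (p_i in the floating image, q_i in the fixed image).
#'
#' @param landmarksFloat,landmarksFixed equal-length n x 3 matrices, mm.
#' @param field a \linkS4class{DenseField}.
#' @return list: \code{errors} (numeric(n), mm), \code{min}, \code{max},
#'   \code{mean}.
#' @export
landmarkErrors <- function(landmarksFloat, landmarksFixed, field) {
  P <- rbindable(landmarksFloat)
  Q <- rbindable(landmarksFixed)
  if (nrow(P) != nrow(Q))
    stop("landmark sets must have equal length", call. = FALSE)
  mapped <- P + sampleField(field, P)
  err <- sqrt(rowSums((mapped - Q)^2))
  list(errors = err, min = min(err), max = max(err), mean = mean(err))
}
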