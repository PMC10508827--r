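#' Specification of a synthetic brain-shift phantom
#'
#' Describes an ellipsoidal "brain" (label 1) with an embedded spherical
#' "tumour" (label 2), a textured pre-op intensity image, a smooth
#' ground-truth deformation, and the simulated intra-op image (the warped
#' pre-op, optionally with a resection cavity carved out at intensity 0).
#'
#' @param size integer(3) image size in voxels.
#' @param spacing numeric(3) voxel size, mm.
#' @param seed RNG seed; identical specs give bit-identical phantoms.
#' @param textureScale correlation length of the intensity texture, mm.
#' @param deformMax peak ground-truth displacement magnitude, mm.
#' @param deformCenters list of lists with elements \code{center} (mm),
#'   \code{radius} (mm) and \code{direction} (3-vector); NULL gives one
#'   default bump centred between brain centre and boundary.
#' @param resection optional list(center (mm), radius (mm)) carving an
#'   intra-op cavity.
#' @param noiseSd additive white intensity noise on the pre-op image.
#' @return a list of class "PhantomSpec".
#' @export
phantomSpec <- function(size = c(64, 64, 64), spacing = c(1, 1, 1),
                        seed = 1L, textureScale = 3, deformMax = 4,
                        deformCenters = NULL, resection = NULL,
                        noiseSd = 0) {
  size <- as.integer(rep_len(size, 3L))
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (deformMax < 0) stop("deformMax must be >= 0", call. = FALSE)
  ext <- (size - 1) * spacing
  if (is.null(deformCenters))
    deformCenters <- list(list(center = ext * 0.5,
                               radius = 0.9 * min(ext),
                               direction = c(1, 0.5, 0.25)))
  for (dc in deformCenters)
    if (dc$radius <= 0) stop("deform radius must be > 0", call. = FALSE)
  if (!is.null(resection) && resection$radius <= 0)
    stop("resection radius must be > 0", call. = FALSE)
  structure(list(size = size, spacing = spacing, seed = as.integer(seed),
                 textureScale = textureScale, deformMax = deformMax,
                 deformCenters = deformCenters, resection = resection,
                 noiseSd = noiseSd),
            class = "PhantomSpec")
}

withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic brain-shift phantom
#'
#' Builds (a) the label image: an ellipsoidal brain mask (semi-axes 0.42 of
#' the world extent) with a spherical tumour of radius 0.12 min-extent;
#' (b) the pre-op image: per-label base intensity (background 0, brain 60,
#' tumour 120) plus band-limited Gaussian texture (amplitude 12, correlation
#' length \code{textureScale}) plus optional white noise; (c) the
#' ground-truth dense field: a sum of radial Gaussian bumps
#' d * exp(-||x - c||^2 / (2 r^2)), unattenuated on the brain and tapered
#' smoothly (cosine-squared over a shell of 0.3 normalised radius) to zero
#' outside it, rescaled so the peak magnitude equals
#' \code{deformMax}; (d) the intra-op image: the pre-op warped backward by
#' the truth field, with the resection sphere (if any) set to 0 afterwards
#' so the cavity is an intra-op-space sphere.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @return list with \code{preop} (\linkS4class{Image3D}), \code{labels}
#'   (\linkS4class{LabelImage}), \code{truth} (\linkS4class{DenseField}),
#'   \code{intraop} (\linkS4class{Image3D}) and \code{spec}.
#' @export
makePhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  d <- spec$size
  sp <- spec$spacing
  ext <- (d - 1) * sp
  ctr <- ext / 2
  ax <- seq_len(d[1]) - 1
  ay <- seq_len(d[2]) - 1
  az <- seq_len(d[3]) - 1
  X <- array(ax * sp[1], d)
  Y <- aperm(array(ay * sp[2], d[c(2, 1, 3)]), c(2, 1, 3))
  Z <- aperm(array(az * sp[3], d[c(3, 2, 1)]), c(3, 2, 1))
  semi <- 0.42 * ext
  inBrain <- ((X - ctr[1]) / semi[1])^2 + ((Y - ctr[2]) / semi[2])^2 +
    ((Z - ctr[3]) / semi[3])^2 <= 1
  tumourC <- ctr + c(0.15, 0, 0) * ext
  tumourR <- 0.12 * min(ext)
  inTumour <- (X - tumourC[1])^2 + (Y - tumourC[2])^2 +
    (Z - tumourC[3])^2 <= tumourR^2
  if (any(inTumour & !inBrain))
    stop("tumour sphere extends outside the brain", call. = FALSE)
  lab <- array(0, d)
  lab[inBrain] <- 1
  lab[inTumour] <- 2
  labels <- labelImage(lab, sp, c(0, 0, 0))

  base <- array(0, d)
  base[inBrain] <- 60
  base[inTumour] <- 120
  tex <- withSeed(spec$seed, array(stats::rnorm(prod(d)), d))
  sig <- spec$textureScale / sp
  tex <- array(cpp_gauss_smooth(as.vector(tex), d, sig), d)
  tex <- tex / stats::sd(tex) * 12
  pre <- base + tex * inBrain
  if (spec$noiseSd > 0)
    pre <- pre + withSeed(spec$seed + 1L,
                          array(stats::rnorm(prod(d), sd = spec$noiseSd), d))
  preop <- image3d(pre, sp, c(0, 0, 0))

  u <- array(0, c(d, 3L))
  if (spec$deformMax > 0) {
    for (dc in spec$deformCenters) {
      g <- exp(-((X - dc$center[1])^2 + (Y - dc$center[2])^2 +
                 (Z - dc$center[3])^2) / (2 * dc$radius^2))
      dir <- dc$direction / sqrt(sum(dc$direction^2))
      for (c in 1:3) u[, , , c] <- u[, , , c] + g * dir[c]
    }
    # smooth analytic taper: 1 throughout the brain ellipsoid, C^1 cosine
    # decay to 0 over a shell of ~0.3 normalised radius outside it, so the
    # field is unattenuated on the tissue and vanishes in the far background
    rho <- sqrt(((X - ctr[1]) / semi[1])^2 + ((Y - ctr[2]) / semi[2])^2 +
                ((Z - ctr[3]) / semi[3])^2)
    shell <- 0.3
    taper <- ifelse(rho <= 1, 1,
                    ifelse(rho >= 1 + shell, 0,
                           cos((rho - 1) / shell * pi / 2)^2))
    for (c in 1:3) u[, , , c] <- u[, , , c] * taper
    mag <- sqrt(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2)
    mmax <- max(mag)
    if (mmax <= 0) stop("degenerate deformation specification",
                        call. = FALSE)
    u <- u * (spec$deformMax / mmax)
  }
  truth <- new("DenseField", u = u, spacing = sp, origin = c(0, 0, 0))

  intra <- warpImage(preop, truth, order = 1L)
  if (!is.null(spec$resection)) {
    rc <- spec$resection$center
    brainAt <- function(p) {
      sum(((p - ctr) / semi)^2) <= 1
    }
    if (!brainAt(rc))
      stop("resection sphere centre lies outside the brain", call. = FALSE)
    cav <- (X - rc[1])^2 + (Y - rc[2])^2 + (Z - rc[3])^2 <=
      spec$resection$radius^2
    dat <- imgData(intra)
    dat[cav] <- 0
    intra <- image3d(dat, sp, c(0, 0, 0))
  }
  list(preop = preop, labels = labels, truth = truth, intraop = intra,
       spec = spec)
}

#' Corrupt a fraction of matches with outlier displacements
#'
#' Replaces the displacements of a random \code{floor(fraction n)} subset
#' with uniformly random directions of fixed norm \code{magnitude} mm,
#' keeping confidences and weights; the corrupted indices are returned for
#' ground-truth scoring of outlier rejection.
#'
#' @param matches a \linkS4class{MatchSet}.
#' @param fraction proportion in [0, 1) of matches to corrupt.
#' @param magnitude outlier displacement norm, mm.
#' @param seed RNG seed.
#' @return list(matches = corrupted \linkS4class{MatchSet},
#'   ids = integer indices of corrupted matches).
#' @export
corruptMatches <- function(matches, fraction, magnitude, seed = 1L) {
  if (fraction < 0 || fraction >= 1)
    stop("fraction must lie in [0, 1)", call. = FALSE)
  n <- nMatches(matches)
  ncor <- floor(fraction * n + 1e-9)
  if (ncor == 0L) return(list(matches = matches, ids = integer(0)))
  withSeed(seed, {
    ids <- sort(sample.int(n, ncor))
    dir <- matrix(stats::rnorm(3L * ncor), ncol = 3)
    dir <- dir / sqrt(rowSums(dir^2))
    disp <- matches@displacements
    disp[ids, ] <- dir * magnitude
    list(matches = new("MatchSet", points = matches@points,
                       displacements = disp,
                       confidences = matches@confidences,
                       weights = matches@weights,
                       provenance = matches@provenance),
         ids = ids)
  })
}
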