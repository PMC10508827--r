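#' Body-centred-cubic tetrahedral mesh of a mask
#'
#' Builds the BCC lattice at the given cell size over the mask's bounding
#' box, tetrahedralises it (four tets per lattice face, each joining the
#' two adjacent body centres with a face edge) and keeps the tetrahedra
#' whose centroid falls on a foreground voxel. Each kept tet is labelled by
#' the majority mask label among its 4 vertices + centroid (nearest-voxel
#' sampling; background samples are ignored unless all five are background,
#' in which case the centroid's label is used).
#'
#' @param mask a \linkS4class{LabelImage} with >= 1 foreground voxel.
#' @param cellSize BCC cell edge length, mm.
#' @param dilate optional morphological dilation of the mask, in voxels,
#'   applied before meshing (box structuring element; labels propagate by
#'   maximum). A dilation of 1 makes the mesh hull cover the object surface
#'   so surface features receive non-zero displacement in the rasterised
#'   field.
#' @return a \linkS4class{TetMesh}.
#' @export
bccMesh <- function(mask, cellSize, dilate = 0L) {
  stopifnot(is(mask, "LabelImage"))
  if (cellSize <= 0) stop("cellSize must be > 0", call. = FALSE)
  if (dilate > 0L) mask <- dilateMask(mask, dilate)
  fg <- which(mask@data > 0, arr.ind = TRUE) - 1L
  if (nrow(fg) == 0L) stop("mask has no foreground voxels", call. = FALSE)
  lo <- origin(mask) + (apply(fg, 2, min) - 0.5) * spacing(mask)
  hi <- origin(mask) + (apply(fg, 2, max) + 0.5) * spacing(mask)
  n <- pmax(1L, as.integer(ceiling((hi - lo) / cellSize)))
  # corner lattice (n+1 per axis) and body-centre lattice (n per axis),
  # indexed on a doubled integer grid to dedupe exactly
  cornerId <- function(i, j, k) paste(2L * i, 2L * j, 2L * k)
  centerId <- function(i, j, k) paste(2L * i + 1L, 2L * j + 1L,
                                      2L * k + 1L)
  env <- new.env(hash = TRUE, parent = emptyenv())
  verts <- list()
  nv <- 0L
  getVert <- function(id, xyz) {
    v <- get0(id, envir = env, inherits = FALSE)
    if (!is.null(v)) return(v)
    nv <<- nv + 1L
    verts[[nv]] <<- xyz
    assign(id, nv, envir = env)
    nv
  }
  cornerXyz <- function(i, j, k) lo + c(i, j, k) * cellSize
  centerXyz <- function(i, j, k) lo + (c(i, j, k) + 0.5) * cellSize
  tl <- list()
  nt <- 0L
  addTet <- function(a, b, c, d) {
    nt <<- nt + 1L
    tl[[nt]] <<- c(a, b, c, d)
  }
  # faces between adjacent body centres, per axis
  for (axis in 1:3) {
    stepv <- c(0L, 0L, 0L)
    stepv[axis] <- 1L
    o1 <- c(2L, 3L, 1L)[axis]  # in-face axes
    o2 <- c(3L, 1L, 2L)[axis]
    rng <- list(seq_len(n[1]) - 1L, seq_len(n[2]) - 1L, seq_len(n[3]) - 1L)
    rng[[axis]] <- utils::head(rng[[axis]], -1L)
    if (length(rng[[axis]]) == 0L) next
    for (k in rng[[3]]) for (j in rng[[2]]) for (i in rng[[1]]) {
      c1 <- c(i, j, k)
      c2 <- c1 + stepv
      v1 <- getVert(centerId(c1[1], c1[2], c1[3]),
                    centerXyz(c1[1], c1[2], c1[3]))
      v2 <- getVert(centerId(c2[1], c2[2], c2[3]),
                    centerXyz(c2[1], c2[2], c2[3]))
      # shared face corners: fixed coordinate = c2[axis]
      base <- c1
      base[axis] <- c2[axis]
      for (e in list(c(0L, 0L, 1L, 0L), c(1L, 0L, 1L, 1L),
                     c(1L, 1L, 0L, 1L), c(0L, 1L, 0L, 0L))) {
        p1 <- base; p1[o1] <- p1[o1] + e[1]; p1[o2] <- p1[o2] + e[2]
        p2 <- base; p2[o1] <- p2[o1] + e[3]; p2[o2] <- p2[o2] + e[4]
        w1 <- getVert(cornerId(p1[1], p1[2], p1[3]),
                      cornerXyz(p1[1], p1[2], p1[3]))
        w2 <- getVert(cornerId(p2[1], p2[2], p2[3]),
                      cornerXyz(p2[1], p2[2], p2[3]))
        addTet(v1, v2, w1, w2)
      }
    }
  }
  if (nt == 0L)
    stop("cellSize too large: no tetrahedron centroid falls in the mask",
         call. = FALSE)
  V <- do.call(rbind, verts)
  Tm <- do.call(rbind, tl)
  sampleLabel <- function(P) {
    idx <- round(sweep(sweep(P, 2, origin(mask), `-`), 2, spacing(mask),
                       `/`))
    d <- imgDim(mask)
    ok <- idx[, 1] >= 0 & idx[, 2] >= 0 & idx[, 3] >= 0 &
      idx[, 1] < d[1] & idx[, 2] < d[2] & idx[, 3] < d[3]
    out <- numeric(nrow(P))
    out[ok] <- mask@data[idx[ok, , drop = FALSE] + 1L]
    out
  }
  centroid <- (V[Tm[, 1], ] + V[Tm[, 2], ] + V[Tm[, 3], ] + V[Tm[, 4], ]) / 4
  keep <- sampleLabel(centroid) > 0
  if (!any(keep))
    stop("cellSize too large: no tetrahedron centroid falls in the mask",
         call. = FALSE)
  Tm <- Tm[keep, , drop = FALSE]
  centroid <- centroid[keep, , drop = FALSE]
  samples <- cbind(sampleLabel(V[Tm[, 1], , drop = FALSE]),
                   sampleLabel(V[Tm[, 2], , drop = FALSE]),
                   sampleLabel(V[Tm[, 3], , drop = FALSE]),
                   sampleLabel(V[Tm[, 4], , drop = FALSE]),
                   sampleLabel(centroid))
  lab <- apply(samples, 1, function(s) {
    s <- s[s > 0]
    if (length(s) == 0L) return(0L)
    tab <- table(s)
    as.integer(names(tab)[which.max(tab)])
  })
  lab[lab == 0L] <- as.integer(samples[lab == 0L, 5])
  # compact to referenced vertices
  used <- sort(unique(as.vector(Tm)))
  remap <- integer(nrow(V))
  remap[used] <- seq_along(used)
  tetMesh(V[used, , drop = FALSE],
          matrix(remap[Tm], ncol = 4), as.integer(lab))
}

#' Morphological label dilation
#'
#' Box (Chebyshev-ball) dilation by \code{voxels}; labels propagate by
#' maximum, so at interfaces the higher label wins.
#'
#' @param mask a \linkS4class{LabelImage}.
#' @param voxels dilation radius in voxels.
#' @return the dilated \linkS4class{LabelImage}.
#' @export
dilateMask <- function(mask, voxels = 1L) {
  dat <- mask@data
  d <- dim(dat)
  for (r in seq_len(voxels)) {
    for (ax in 1:3) {
      n <- d[ax]
      up <- c(2:n, n)
      dn <- c(1, 1:(n - 1))
      dat <- switch(ax,
        pmax(dat, dat[up, , , drop = FALSE], dat[dn, , , drop = FALSE]),
        pmax(dat, dat[, up, , drop = FALSE], dat[, dn, , drop = FALSE]),
        pmax(dat, dat[, , up, drop = FALSE], dat[, , dn, drop = FALSE]))
      dim(dat) <- d
    }
  }
  labelImage(dat, spacing(mask), origin(mask))
}

#' Resection-detection configuration
#'
#' @param bgThreshold intensity below which an intra-op voxel counts as
#'   background, or "otsu" to derive it by Otsu's method over the mesh
#'   bounding box.
#' @param maxOuterIter cap on outer growth rounds (>= 1).
#' @param bgFraction fraction (0, 1] of a tet's 5 sample points (4 displaced
#'   vertices + displaced centroid) that must be background to flag it.
#' @return a list of class "ResectionConfig".
#' @export
resectionConfig <- function(bgThreshold = "otsu", maxOuterIter = 10L,
                            bgFraction = 0.8) {
  if (bgFraction <= 0 || bgFraction > 1)
    stop("bgFraction must lie in (0, 1]", call. = FALSE)
  if (maxOuterIter < 1) stop("maxOuterIter must be >= 1", call. = FALSE)
  structure(list(bgThreshold = bgThreshold,
                 maxOuterIter = as.integer(maxOuterIter),
                 bgFraction = bgFraction),
            class = "ResectionConfig")
}

# Otsu's threshold on a numeric vector (256-bin histogram).
otsuThreshold <- function(x) {
  r <- range(x)
  if (diff(r) <= 0) return(r[1])
  h <- graphics::hist(x, breaks = seq(r[1], r[2], length.out = 257),
                      plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[length(mu)]
  sigma2 <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sigma2[!is.finite(sigma2)] <- 0
  mids[which.max(sigma2)]
}

#' Detect resection-cavity elements
#'
#' Iterative growth of the removed submesh M_Rem: a tet is flagged when at
#' least \code{bgFraction} of its 5 sample points (4 vertices + centroid,
#' displaced by U) fall on *interior* background of the intra-op image —
#' voxels below the background threshold that are not connected to the
#' image border through background (resected tissue is background enclosed
#' by brain; the exterior is not). Round 1 seeds M_Rem with the largest face-connected component of
#' flagged tets (ties to the lower component id); later rounds add flagged
#' tets face-adjacent to the current M_Rem, until no addition or
#' \code{maxOuterIter}. Growth is monotone by construction.
#'
#' The resection region is a solid submesh, not a surface film: the seed
#' component must contain at least one tet all four of whose face
#' neighbours are also flagged. Thin chains of boundary tets (voxelisation
#' slivers at the brain surface whose vertices sample the exterior
#' background) fail this solidity test and yield an empty M_Rem.
#'
#' @param mesh a \linkS4class{TetMesh}.
#' @param U N x 3 nodal displacements, mm (0 allowed).
#' @param intraop intra-operative \linkS4class{Image3D}.
#' @param cfg a \code{\link{resectionConfig}}.
#' @return integer vector of element indices (possibly empty); attribute
#'   "threshold" carries the background threshold used.
#' @export
detectResectionElements <- function(mesh, U, intraop,
                                    cfg = resectionConfig()) {
  stopifnot(is(mesh, "TetMesh"), is(intraop, "Image3D"))
  if (is.null(dim(U))) U <- matrix(U, ncol = 3, byrow = TRUE)
  V <- mesh@vertices + U
  Tm <- mesh@tets
  thr <- cfg$bgThreshold
  if (identical(thr, "otsu")) {
    lo <- worldToIndex(intraop, matrix(apply(V, 2, min), ncol = 3))
    hi <- worldToIndex(intraop, matrix(apply(V, 2, max), ncol = 3))
    d <- imgDim(intraop)
    lo <- pmax(1L, floor(lo) + 1L)
    hi <- pmin(d, ceiling(hi) + 1L)
    sub <- intraop@data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    thr <- otsuThreshold(as.vector(sub))
  }
  # the resection region is background *enclosed by tissue*: background
  # voxels reachable from the image border (the exterior) do not count, so
  # surface tets whose vertices sample the outside never get flagged
  d <- imgDim(intraop)
  bgVox <- intraop@data < thr
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  exterior <- array(cpp_hysteresis(as.vector(border & bgVox),
                                   as.vector(bgVox), d), d)
  interiorBg <- bgVox & !exterior
  sampleBg <- function(P) {
    idx <- round(worldToIndex(intraop, P))
    ok <- idx[, 1] >= 0 & idx[, 2] >= 0 & idx[, 3] >= 0 &
      idx[, 1] < d[1] & idx[, 2] < d[2] & idx[, 3] < d[3]
    out <- logical(nrow(P))           # outside the image is exterior
    out[ok] <- interiorBg[idx[ok, , drop = FALSE] + 1L]
    out
  }
  centroid <- (V[Tm[, 1], ] + V[Tm[, 2], ] + V[Tm[, 3], ] + V[Tm[, 4], ]) / 4
  bg <- cbind(sampleBg(V[Tm[, 1], , drop = FALSE]),
              sampleBg(V[Tm[, 2], , drop = FALSE]),
              sampleBg(V[Tm[, 3], , drop = FALSE]),
              sampleBg(V[Tm[, 4], , drop = FALSE]),
              sampleBg(centroid))
  flagged <- rowMeans(bg) >= cfg$bgFraction
  if (!any(flagged))
    return(structure(integer(0), threshold = thr))
  adj <- tetFaceAdjacency(Tm)
  # seed: largest face-connected component among flagged tets
  flaggedIds <- which(flagged)
  comp <- rep(NA_integer_, nrow(Tm))
  nc <- 0L
  for (s in flaggedIds) {
    if (!is.na(comp[s])) next
    nc <- nc + 1L
    queue <- s
    comp[s] <- nc
    while (length(queue)) {
      cur <- queue[[1]]
      queue <- queue[-1]
      for (nb in adj[[cur]]) {
        if (flagged[nb] && is.na(comp[nb])) {
          comp[nb] <- nc
          queue <- c(queue, nb)
        }
      }
    }
  }
  sizes <- tabulate(comp[flaggedIds], nbins = nc)
  rem <- flaggedIds[comp[flaggedIds] == which.max(sizes)]
  # solidity: a genuine cavity has interior tets (all 4 neighbours flagged)
  solid <- any(vapply(rem, function(e) {
    nb <- adj[[e]]
    length(nb) == 4L && all(flagged[nb])
  }, logical(1)))
  if (!solid) return(structure(integer(0), threshold = thr))
  inRem <- logical(nrow(Tm))
  inRem[rem] <- TRUE
  for (it in seq_len(cfg$maxOuterIter - 1L)) {
    frontier <- unique(unlist(adj[which(inRem)]))
    add <- frontier[!inRem[frontier] & flagged[frontier]]
    if (length(add) == 0L) break
    inRem[add] <- TRUE
  }
  structure(which(inRem), threshold = thr)
}

#' Remove elements from a mesh
#'
#' Drops the given tetrahedra, compacts unreferenced vertices, and reports
#' the removed volume. If the remaining mesh splits into several
#' face-connected parts a warning names the component sizes (the solver's
#' definiteness check decides whether that is fatal).
#'
#' @param mesh a \linkS4class{TetMesh}.
#' @param rem integer element indices to remove.
#' @return the reduced \linkS4class{TetMesh}; attributes "removedVolume"
#'   (mm^3) and "vertexMap" (old index -> new index, NA if dropped).
#' @export
removeElements <- function(mesh, rem) {
  stopifnot(is(mesh, "TetMesh"))
  rem <- as.integer(rem)
  if (length(rem) && (min(rem) < 1L || max(rem) > nrow(mesh@tets)))
    stop("element indices out of range", call. = FALSE)
  keep <- setdiff(seq_len(nrow(mesh@tets)), rem)
  if (length(keep) == 0L)
    stop("removal would leave an empty mesh", call. = FALSE)
  removedVolume <- if (length(rem))
    sum(tetVolumesImpl(mesh@vertices, mesh@tets[rem, , drop = FALSE]))
  else 0
  Tm <- mesh@tets[keep, , drop = FALSE]
  used <- sort(unique(as.vector(Tm)))
  remap <- rep(NA_integer_, nrow(mesh@vertices))
  remap[used] <- seq_along(used)
  out <- tetMesh(mesh@vertices[used, , drop = FALSE],
                 matrix(remap[Tm], ncol = 4), mesh@labels[keep])
  comps <- tetComponents(out@tets)
  if (length(unique(comps)) > 1L)
    warning(sprintf("element removal disconnected the mesh into parts of sizes %s",
                    paste(sort(tabulate(comps), decreasing = TRUE),
                          collapse = ", ")), call. = FALSE)
  attr(out, "removedVolume") <- removedVolume
  attr(out, "vertexMap") <- remap
  out
}
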