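#' Adaptive-registration configuration
#'
#' @param nIter number of incremental iterations (>= 1; default 5).
#' @param solver per-iteration \code{\link{solverConfig}}.
#' @param spec per-iteration \code{\link{blockSpec}}.
#' @param cellSize BCC re-meshing cell size, mm.
#' @param remesh if FALSE, the initial mesh is reused with its vertices
#'   displaced by the running field instead of re-meshing the warped labels.
#' @param meshDilate mask dilation in voxels before meshing (see
#'   \code{\link{bccMesh}}); 1 keeps the object surface inside the hull.
#' @param margin feature-selection border margin, see
#'   \code{\link{registerImages}}.
#' @param fraction,minSpacing,minConfidence feature/matching parameters
#'   passed to \code{\link{registerImages}}.
#' @return a list of class "AdaptiveConfig".
#' @export
adaptiveConfig <- function(nIter = 5L, solver = solverConfig(),
                           spec = blockSpec(), cellSize = 8,
                           remesh = TRUE, meshDilate = 0L,
                           fraction = 0.05, minSpacing = 3,
                           minConfidence = 0.5, margin = NULL) {
  if (nIter < 1) stop("nIter must be >= 1", call. = FALSE)
  structure(list(nIter = as.integer(nIter), solver = solver, spec = spec,
                 cellSize = cellSize, remesh = isTRUE(remesh),
                 meshDilate = as.integer(meshDilate),
                 fraction = fraction, minSpacing = minSpacing,
                 minConfidence = minConfidence, margin = margin),
            class = "AdaptiveConfig")
}

#' Compose two dense displacement fields
#'
#' Returns the field of the composed backward warp: applying \code{prev}
#' then \code{inc} to an image equals one warp by the composition
#' u(x) = u_inc(x) + u_prev(x - u_inc(x)) (u_prev sampled trilinearly).
#' Composing with the zero field is the identity in either order.
#'
#' @param inc,prev \linkS4class{DenseField}s on the same grid.
#' @return the composed \linkS4class{DenseField}.
#' @export
composeFields <- function(inc, prev) {
  stopifnot(is(inc, "DenseField"), is(prev, "DenseField"))
  if (!sameGeometry(inc, prev))
    stop("fields must share geometry", call. = FALSE)
  d <- imgDim(inc)
  ijk <- as.matrix(expand.grid(i = seq_len(d[1]) - 1,
                               j = seq_len(d[2]) - 1,
                               k = seq_len(d[3]) - 1))
  xyz <- indexToWorld(inc, ijk)
  ui <- fieldValues(inc)
  # expand.grid enumerates i fastest == array linear order
  up <- sampleField(prev, xyz - ui)
  denseField(ui + up, inc)
}

#' Incremental adaptive non-rigid registration
#'
#' Runs \code{nIter} incremental passes: at each iteration the current
#' warped floating image (and its warped labels) is (re-)meshed with the
#' internal BCC mesher, resection-cavity elements are detected against the
#' fixed image and removed, a robust registration of the warped floating
#' to the fixed image yields an incremental field, and the increment is
#' composed into the running total field. Large deformations are thereby
#' split into small per-iteration ones, so every intermediate mesh is
#' rebuilt valid (no slivers or inverted elements are carried along).
#'
#' @param floating pre-op \linkS4class{Image3D}.
#' @param floatingLabels \linkS4class{LabelImage} of the floating brain.
#' @param fixed intra-op \linkS4class{Image3D}.
#' @param cfg an \code{\link{adaptiveConfig}}.
#' @param rcfg a \code{\link{resectionConfig}}.
#' @param materials a \linkS4class{MaterialTable}.
#' @return list with \code{field} (total \linkS4class{DenseField}),
#'   \code{warped} (final warped floating image), \code{labelsWarped},
#'   and \code{report} (per-iteration list: mesh sizes, matches, removed
#'   elements/volume, residuals).
#' @export
adaptiveRegister <- function(floating, floatingLabels, fixed,
                             cfg = adaptiveConfig(),
                             rcfg = resectionConfig(),
                             materials = defaultMaterials()) {
  stopifnot(is(floating, "Image3D"), is(floatingLabels, "LabelImage"),
            is(fixed, "Image3D"))
  if (!sameGeometry(floating, fixed) ||
      !sameGeometry(floating, floatingLabels))
    stop("floating, labels and fixed must share geometry", call. = FALSE)
  total <- denseField(array(0, c(imgDim(floating), 3L)), floating)
  curFloat <- floating
  curLabels <- floatingLabels
  mesh0 <- NULL
  report <- list()
  for (i in seq_len(cfg$nIter)) {
    step <- tryCatch({
      mesh <- if (cfg$remesh || is.null(mesh0)) {
        bccMesh(curLabels, cfg$cellSize, dilate = cfg$meshDilate)
      } else {
        disp <- sampleField(total, mesh0@vertices)
        tetMesh(mesh0@vertices + disp, mesh0@tets, mesh0@labels)
      }
      if (is.null(mesh0)) mesh0 <- mesh
      # register on the full mesh, then look for cavity elements with the
      # registered displacements (tets that still land on intra-op
      # background after following the brain are resected tissue)
      reg <- registerImages(curFloat, fixed, mesh, materials = materials,
                            spec = cfg$spec, cfg = cfg$solver,
                            fraction = cfg$fraction, mask = curLabels,
                            minSpacing = cfg$minSpacing,
                            minConfidence = cfg$minConfidence,
                            margin = cfg$margin)
      rem <- detectResectionElements(mesh, fieldValues(reg$nodal), fixed,
                                     rcfg)
      removedVolume <- 0
      if (length(rem) > 0L) {
        mesh <- removeElements(mesh, rem)
        removedVolume <- attr(mesh, "removedVolume")
        reg <- registerImages(curFloat, fixed, mesh, materials = materials,
                              spec = cfg$spec, cfg = cfg$solver,
                              fraction = cfg$fraction, mask = curLabels,
                              minSpacing = cfg$minSpacing,
                              minConfidence = cfg$minConfidence,
                              margin = cfg$margin, matches = reg$matches)
      }
      total <- composeFields(reg$field, total)
      # composition lets the extrapolation band of successive increments
      # creep into the background; clamp the support to a band around the
      # original and currently warped brain
      band <- defaultExtendVoxels(mesh, floating) + 2L
      supp <- labelImage((floatingLabels@data > 0) +
                           (warpImage(floatingLabels, total,
                                      order = 0L)@data > 0),
                         spacing(floating), origin(floating))
      supp <- dilateMask(supp, band)
      u <- fieldValues(total)
      u[as.vector(supp@data) == 0, ] <- 0
      total <- denseField(u, floating)
      curFloat <- warpImage(floating, total, order = 1L)
      curLabels <- warpImage(floatingLabels, total, order = 0L)
      list(iter = i, nVertices = nrow(mesh@vertices),
           nTets = nrow(mesh@tets), nMatches = nMatches(reg$matches),
           nKept = length(reg$kept), nActive = sum(reg$active),
           nRemoved = length(rem), removedVolume = removedVolume,
           maxIncrement = sqrt(max(rowSums(fieldValues(reg$field)^2))))
    }, error = function(e)
      stop(sprintf("adaptive iteration %d failed: %s", i,
                   conditionMessage(e)), call. = FALSE))
    report[[i]] <- step
  }
  list(field = total, warped = curFloat, labelsWarped = curLabels,
       report = report)
}
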