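#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib pbnrr, .registration = TRUE
NULL

#' Scalar 3-D image with axis-aligned geometry
#'
#' A voxel grid with per-axis spacing (mm) and the world position of voxel
#' (0,0,0) (mm). Voxel indices are 0-based throughout the package, so that
#' \code{world = origin + index * spacing}; oblique orientations
#' (direction cosines) are deliberately unsupported.
#'
#' @slot data 3-D numeric array of intensities.
#' @slot spacing numeric(3), voxel size in mm, all > 0.
#' @slot origin numeric(3), world coordinate of voxel (0,0,0) in mm.
#' @export
setClass("Image3D", representation(data = "array", spacing = "numeric",
                                   origin = "numeric"))

setValidity("Image3D", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("data must be a 3-D array")
  if (any(dim(d) < 1L)) return("all image dimensions must be >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be 3 finite positive values")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be 3 finite values")
  TRUE
})

#' Integer-labelled 3-D image
#'
#' Same geometry as \linkS4class{Image3D}; voxel values are non-negative
#' integer tissue labels with 0 meaning background.
#'
#' @export
setClass("LabelImage", contains = "Image3D")

setValidity("LabelImage", function(object) {
  v <- object@data
  if (any(v < 0)) return("labels must be >= 0")
  if (any(v != round(v))) return("labels must be integers")
  TRUE
})

#' Labelled tetrahedral mesh
#'
#' Vertices are world coordinates in mm; \code{tets} holds 1-based vertex
#' indices (converted from/to the 0-based VTK convention at I/O time); every
#' tetrahedron is stored with positive signed volume.
#'
#' @slot vertices N x 3 numeric matrix, mm.
#' @slot tets M x 4 integer matrix of 1-based vertex indices.
#' @slot labels integer(M) per-element tissue label.
#' @export
setClass("TetMesh", representation(vertices = "matrix", tets = "matrix",
                                   labels = "integer"))

setValidity("TetMesh", function(object) {
  V <- object@vertices
  T <- object@tets
  if (ncol(V) != 3L) return("vertices must be N x 3")
  if (ncol(T) != 4L) return("tets must be M x 4")
  if (nrow(T) != length(object@labels))
    return("labels must have one entry per tetrahedron")
  if (nrow(T) > 0L) {
    if (min(T) < 1L || max(T) > nrow(V))
      return("tet vertex indices out of range")
    vol <- tetVolumesImpl(V, T)
    if (any(vol <= 0))
      return(sprintf("%d tetrahedra have non-positive signed volume",
                     sum(vol <= 0)))
  }
  TRUE
})

#' Sparse block-matching result
#'
#' One row per surviving match: the block-centre voxel index (0-based) in the
#' floating image, the matched displacement in mm, the NCC confidence in
#' [-1, 1], and the scalar weight w such that the match's 3x3 contribution to
#' the block-matching stiffness S is w * I3 (w = max(confidence, 0)^2).
#'
#' @slot points n x 3 integer matrix of 0-based voxel indices.
#' @slot displacements n x 3 numeric matrix, mm.
#' @slot confidences numeric(n) NCC values.
#' @slot weights numeric(n) non-negative isotropic S weights.
#' @slot provenance list carrying the block/window spec and image geometry.
#' @export
setClass("MatchSet", representation(points = "matrix",
                                    displacements = "matrix",
                                    confidences = "numeric",
                                    weights = "numeric",
                                    provenance = "list"))

setValidity("MatchSet", function(object) {
  n <- nrow(object@points)
  if (ncol(object@points) != 3L || ncol(object@displacements) != 3L)
    return("points and displacements must have 3 columns")
  if (nrow(object@displacements) != n || length(object@confidences) != n ||
      length(object@weights) != n)
    return("inconsistent match count across slots")
  if (n > 0L && anyDuplicated(object@points) > 0L)
    return("duplicate match points")
  if (any(abs(object@confidences) > 1 + 1e-12))
    return("confidences must lie in [-1, 1]")
  if (any(object@weights < 0)) return("weights must be >= 0")
  TRUE
})

#' Dense displacement field
#'
#' A vector image sharing an \linkS4class{Image3D} geometry; component c of
#' the displacement (mm) at voxel (i,j,k) is \code{u[i+1, j+1, k+1, c]}.
#'
#' @slot u 4-D numeric array [nx, ny, nz, 3], mm.
#' @slot spacing,origin grid geometry as for \linkS4class{Image3D}.
#' @export
setClass("DenseField", representation(u = "array", spacing = "numeric",
                                      origin = "numeric"))

setValidity("DenseField", function(object) {
  d <- dim(object@u)
  if (length(d) != 4L || d[4] != 3L) return("u must be [nx, ny, nz, 3]")
  if (any(!is.finite(object@u))) return("field must be finite everywhere")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be 3 positive values")
  TRUE
})

#' Mesh-nodal displacement field
#'
#' @slot mesh the \linkS4class{TetMesh} the displacements live on.
#' @slot u N x 3 numeric matrix of per-vertex displacements, mm.
#' @export
setClass("NodalField", representation(mesh = "TetMesh", u = "matrix"))

setValidity("NodalField", function(object) {
  if (nrow(object@u) != nrow(object@mesh@vertices) || ncol(object@u) != 3L)
    return("u must be N x 3 for the mesh's N vertices")
  if (any(!is.finite(object@u))) return("field must be finite everywhere")
  TRUE
})

#' Tissue material table
#'
#' Maps an integer tissue label to a linear-elastic material: Young's
#' modulus E (Pa) and Poisson ratio nu (dimensionless, strictly inside
#' (-1, 0.5) so the Hooke tensor stays finite).
#'
#' @slot labels integer tissue labels.
#' @slot E numeric Young's moduli, Pa.
#' @slot nu numeric Poisson ratios.
#' @export
setClass("MaterialTable", representation(labels = "integer", E = "numeric",
                                         nu = "numeric"))

setValidity("MaterialTable", function(object) {
  n <- length(object@labels)
  if (length(object@E) != n || length(object@nu) != n)
    return("labels, E and nu must have equal length")
  if (anyDuplicated(object@labels) > 0L) return("duplicate tissue labels")
  if (any(object@E <= 0)) return("E must be > 0")
  if (any(object@nu <= -1 | object@nu >= 0.5))
    return("nu must lie strictly in (-1, 0.5)")
  TRUE
})

#' Ellipsoid as a quadratic form
#'
#' The set \{x : (x - center)' M (x - center) <= 1\} with M symmetric
#' positive definite; volume = (4 pi / 3) / sqrt(det(M)).
#'
#' @slot center numeric(3), mm.
#' @slot M 3 x 3 SPD matrix.
#' @slot degenerate logical; TRUE when the input point set was (near-)
#'   coplanar and the moment matrix was regularised.
#' @export
setClass("Ellipsoid", representation(center = "numeric", M = "matrix",
                                     degenerate = "logical"))

setValidity("Ellipsoid", function(object) {
  if (length(object@center) != 3L) return("center must be length 3")
  if (!all(dim(object@M) == c(3L, 3L))) return("M must be 3 x 3")
  if (max(abs(object@M - t(object@M))) > 1e-8 * max(1, max(abs(object@M))))
    return("M must be symmetric")
  if (any(eigen(object@M, symmetric = TRUE, only.values = TRUE)$values <= 0))
    return("M must be positive definite")
  TRUE
})

#' Per-vertex mesh-sizing field
#'
#' Either an isotropic scalar spacing (mm) per vertex or an anisotropic 3x3
#' SPD metric tensor per vertex.
#'
#' @slot vertices N x 3 matrix of the mesh vertices the field is attached to.
#' @slot type "isotropic" or "anisotropic".
#' @slot spacing numeric(N) (isotropic form; length 0 otherwise).
#' @slot tensors 3 x 3 x N array (anisotropic form; dim NULL-equivalent
#'   otherwise).
#' @export
setClass("MetricField", representation(vertices = "matrix",
                                       type = "character",
                                       spacing = "numeric",
                                       tensors = "array"))

setValidity("MetricField", function(object) {
  n <- nrow(object@vertices)
  if (!object@type %in% c("isotropic", "anisotropic"))
    return("type must be 'isotropic' or 'anisotropic'")
  if (object@type == "isotropic") {
    if (length(object@spacing) != n) return("spacing must match vertex count")
    if (any(object@spacing <= 0)) return("spacings must be > 0")
  } else {
    d <- dim(object@tensors)
    if (length(d) != 3L || d[1] != 3L || d[2] != 3L || d[3] != n)
      return("tensors must be 3 x 3 x N")
  }
  TRUE
})
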