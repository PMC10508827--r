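#' Construct a 3-D image
#'
#' @param data 3-D numeric array.
#' @param spacing numeric(3) voxel size in mm.
#' @param origin numeric(3) world position of voxel (0,0,0) in mm.
#' @return an \linkS4class{Image3D}.
#' @examples
#' img <- image3d(array(0, c(4, 4, 4)))
#' imgDim(img)
#' @export
image3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (is.null(dim(data)) || length(dim(data)) != 3L)
    stop("image data must be a 3-D array", call. = FALSE)
  new("Image3D", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a label image
#'
#' @inheritParams image3d
#' @return a \linkS4class{LabelImage}.
#' @export
labelImage <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (is.null(dim(data)) || length(dim(data)) != 3L)
    stop("label data must be a 3-D array", call. = FALSE)
  storage.mode(data) <- "double"
  new("LabelImage", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Image accessors
#'
#' @param x an \linkS4class{Image3D}.
#' @name Image3D-accessors
#' @aliases imgData spacing origin imgDim
NULL

#' @rdname Image3D-accessors
#' @export
setMethod("imgData", "Image3D", function(x) x@data)

#' @rdname Image3D-accessors
#' @export
setMethod("spacing", "Image3D", function(x) x@spacing)

#' @rdname Image3D-accessors
#' @export
setMethod("origin", "Image3D", function(x) x@origin)

#' @rdname Image3D-accessors
#' @export
setMethod("imgDim", "Image3D", function(x) dim(x@data))

#' @export
setMethod("spacing", "DenseField", function(x) x@spacing)

#' @export
setMethod("origin", "DenseField", function(x) x@origin)

#' @export
setMethod("imgDim", "DenseField", function(x) dim(x@u)[1:3])

setMethod("show", "Image3D", function(object) {
  d <- dim(object@data)
  cat(sprintf("%s %d x %d x %d, spacing (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
              class(object), d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3],
              object@origin[1], object@origin[2], object@origin[3]))
  cat(sprintf("  intensity range [%g, %g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "DenseField", function(object) {
  d <- dim(object@u)
  cat(sprintf("DenseField %d x %d x %d, max |u| = %.4g mm\n",
              d[1], d[2], d[3], sqrt(max(rowSums(matrix(object@u, ncol = 3)^2)))))
})

#' Voxel/world coordinate mapping
#'
#' Voxel indices are 0-based; the mapping is the axis-aligned affine
#' \code{world = origin + index * spacing} and is exactly invertible on the
#' voxel lattice.
#'
#' @param img an \linkS4class{Image3D} (or \linkS4class{DenseField}).
#' @param ijk n x 3 matrix (or length-3 vector) of 0-based voxel indices.
#' @param xyz n x 3 matrix (or length-3 vector) of world coordinates in mm.
#' @return the mapped coordinates as an n x 3 matrix.
#' @export
indexToWorld <- function(img, ijk) {
  ijk <- rbindable(ijk)
  sweep(sweep(ijk, 2, spacing(img), `*`), 2, origin(img), `+`)
}

#' @rdname indexToWorld
#' @export
worldToIndex <- function(img, xyz) {
  xyz <- rbindable(xyz)
  sweep(sweep(xyz, 2, origin(img), `-`), 2, spacing(img), `/`)
}

rbindable <- function(x) {
  if (is.null(dim(x))) matrix(as.numeric(x), ncol = 3) else
    matrix(as.numeric(x), ncol = ncol(x))
}

#' Dense field values
#'
#' @param x a \linkS4class{DenseField} or \linkS4class{NodalField}.
#' @return displacements: nvox x 3 (dense, voxels in array linear order) or
#'   N x 3 (nodal) matrix in mm.
#' @rdname fieldValues
#' @export
setMethod("fieldValues", "DenseField", function(x) matrix(x@u, ncol = 3))

#' @rdname fieldValues
#' @export
setMethod("fieldValues", "NodalField", function(x) x@u)

#' Construct a dense displacement field
#'
#' @param u either a 4-D array [nx, ny, nz, 3] or an nvox x 3 matrix in the
#'   linear voxel order of \code{ref}.
#' @param ref an \linkS4class{Image3D} supplying the grid geometry.
#' @return a \linkS4class{DenseField}.
#' @export
denseField <- function(u, ref) {
  d <- imgDim(ref)
  if (is.matrix(u)) u <- array(u, c(d, 3L))
  new("DenseField", u = u, spacing = spacing(ref), origin = origin(ref))
}

#' Sample a dense field at world points (trilinear)
#'
#' @param field a \linkS4class{DenseField}.
#' @param xyz n x 3 world coordinates, mm.
#' @return n x 3 displacements in mm (0 outside the grid support).
#' @export
sampleField <- function(field, xyz) {
  xyz <- rbindable(xyz)
  d <- imgDim(field)
  out <- matrix(0, nrow(xyz), 3)
  idx <- worldToIndex(field, xyz)
  for (c in 1:3) {
    comp <- field@u[, , , c, drop = TRUE]
    dim(comp) <- d
    out[, c] <- trilinearSample(comp, idx)
  }
  out
}

# Pure-R trilinear sampling at fractional 0-based indices; out-of-bounds
# corners contribute 0 (matches the C++ warping kernel).
trilinearSample <- function(vol, idx) {
  d <- dim(vol)
  i0 <- floor(idx)
  fr <- idx - i0
  acc <- numeric(nrow(idx))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    ii <- i0[, 1] + dx; jj <- i0[, 2] + dy; kk <- i0[, 3] + dz
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
         (if (dy) fr[, 2] else 1 - fr[, 2]) *
         (if (dz) fr[, 3] else 1 - fr[, 3])
    ok <- ii >= 0 & jj >= 0 & kk >= 0 & ii < d[1] & jj < d[2] & kk < d[3]
    if (any(ok)) {
      lin <- ii[ok] + d[1] * (jj[ok] + d[2] * kk[ok]) + 1
      acc[ok] <- acc[ok] + w[ok] * vol[lin]
    }
  }
  acc
}

sameGeometry <- function(a, b, tol = 1e-6) {
  all(imgDim(a) == imgDim(b)) &&
    max(abs(spacing(a) - spacing(b))) <= tol &&
    max(abs(origin(a) - origin(b))) <= tol
}
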