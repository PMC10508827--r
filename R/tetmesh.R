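#' Construct a labelled tetrahedral mesh
#'
#' Tetrahedra whose signed volume is negative under the stored vertex order
#' are reoriented (two vertices swapped) so every element has positive
#' volume; exactly degenerate elements are an error.
#'
#' @param vertices N x 3 numeric matrix, mm.
#' @param tets M x 4 matrix of 1-based vertex indices.
#' @param labels integer(M) tissue labels (default all 1).
#' @return a \linkS4class{TetMesh}.
#' @export
tetMesh <- function(vertices, tets, labels = rep(1L, nrow(tets))) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  dimnames(tets) <- NULL
  if (nrow(tets) > 0L) {
    vol <- tetVolumesImpl(vertices, tets)
    if (any(abs(vol) <= 1e-12))
      stop(sprintf("degenerate tetrahedra (|volume| <= 1e-12 mm^3): %s",
                   paste(utils::head(which(abs(vol) <= 1e-12), 5),
                         collapse = ", ")), call. = FALSE)
    flip <- vol < 0
    if (any(flip)) tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]
  }
  dup <- duplicatedVertices(vertices)
  if (any(dup))
    stop(sprintf("%d duplicate vertices within 1e-9 mm", sum(dup)),
         call. = FALSE)
  new("TetMesh", vertices = vertices, tets = tets,
      labels = as.integer(labels))
}

duplicatedVertices <- function(V, tol = 1e-9) {
  key <- paste(round(V[, 1] / tol), round(V[, 2] / tol), round(V[, 3] / tol))
  duplicated(key)
}

# Signed volumes (mm^3) of the tetrahedra of (V, T); vectorised.
tetVolumesImpl <- function(V, T) {
  a <- V[T[, 1], , drop = FALSE]
  b <- V[T[, 2], , drop = FALSE] - a
  c <- V[T[, 3], , drop = FALSE] - a
  d <- V[T[, 4], , drop = FALSE] - a
  (b[, 1] * (c[, 2] * d[, 3] - c[, 3] * d[, 2]) -
   b[, 2] * (c[, 1] * d[, 3] - c[, 3] * d[, 1]) +
   b[, 3] * (c[, 1] * d[, 2] - c[, 2] * d[, 1])) / 6
}

#' Mesh accessors
#'
#' @param x a \linkS4class{TetMesh}.
#' @name TetMesh-accessors
NULL

#' @rdname TetMesh-accessors
#' @export
setMethod("vertices", "TetMesh", function(x) x@vertices)

#' @rdname TetMesh-accessors
#' @export
setMethod("tets", "TetMesh", function(x) x@tets)

#' @rdname TetMesh-accessors
#' @export
setMethod("tetLabels", "TetMesh", function(x) x@labels)

#' @rdname TetMesh-accessors
#' @export
setMethod("tetVolumes", "TetMesh", function(x)
  tetVolumesImpl(x@vertices, x@tets))

setMethod("show", "TetMesh", function(object) {
  cat(sprintf("TetMesh: %d vertices, %d tetrahedra, labels {%s}\n",
              nrow(object@vertices), nrow(object@tets),
              paste(sort(unique(object@labels)), collapse = ", ")))
  if (nrow(object@tets) > 0L)
    cat(sprintf("  total volume %.4g mm^3\n", sum(tetVolumes(object))))
})

# Face-connected components of a tet mesh (shared triangular face).
# Returns an integer component id per element.
tetComponents <- function(T) {
  m <- nrow(T)
  if (m == 0L) return(integer(0))
  faces <- rbind(T[, c(1, 2, 3)], T[, c(1, 2, 4)], T[, c(1, 3, 4)],
                 T[, c(2, 3, 4)])
  faces <- t(apply(faces, 1, sort))
  key <- paste(faces[, 1], faces[, 2], faces[, 3])
  elem <- rep(seq_len(m), 4L)
  sp <- split(elem, key)
  parent <- seq_len(m)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (grp in sp) {
    if (length(grp) > 1L) {
      r <- find(grp[1])
      for (e in grp[-1]) {
        r2 <- find(e)
        if (r2 != r) parent[r2] <- r
      }
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  match(roots, unique(roots))
}

# Adjacency list over shared faces: for each element, the face-adjacent
# element indices.
tetFaceAdjacency <- function(T) {
  m <- nrow(T)
  faces <- rbind(T[, c(1, 2, 3)], T[, c(1, 2, 4)], T[, c(1, 3, 4)],
                 T[, c(2, 3, 4)])
  faces <- t(apply(faces, 1, sort))
  key <- paste(faces[, 1], faces[, 2], faces[, 3])
  elem <- rep(seq_len(m), 4L)
  adj <- vector("list", m)
  for (grp in split(elem, key)) {
    if (length(grp) == 2L) {
      adj[[grp[1]]] <- c(adj[[grp[1]]], grp[2])
      adj[[grp[2]]] <- c(adj[[grp[2]]], grp[1])
    }
  }
  adj
}
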