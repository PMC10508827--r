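#' Read a 3-D image
#'
#' Supports NIfTI-1 (.nii, .nii.gz) through RNifti and NRRD (.nrrd, .nhdr;
#' raw or gzip encoding, little-endian, axis-aligned geometry). Spacing and
#' origin are preserved exactly; intensities are not rescaled.
#'
#' @param path file path.
#' @param label if TRUE, return a \linkS4class{LabelImage}.
#' @return an \linkS4class{Image3D} or \linkS4class{LabelImage}.
#' @export
readImage <- function(path, label = FALSE) {
  ext <- imageFormat(path)
  if (!file.exists(path))
    stop(sprintf("image file '%s' does not exist", path), call. = FALSE)
  res <- if (ext == "nifti") readNiftiImage(path) else readNrrdImage(path)
  if (length(dim(res$data)) != 3L)
    stop(sprintf("'%s' is %d-D; only 3-D images are supported", path,
                 length(dim(res$data))), call. = FALSE)
  storage.mode(res$data) <- "double"
  if (label) labelImage(res$data, res$spacing, res$origin)
  else image3d(res$data, res$spacing, res$origin)
}

#' Write a 3-D image
#'
#' The format is chosen from the extension as in \code{\link{readImage}}.
#' \linkS4class{LabelImage} data are stored as 32-bit integers (no promotion
#' to float); other images as doubles.
#'
#' @param img an \linkS4class{Image3D}.
#' @param path output path; the parent directory must exist.
#' @export
writeImage <- function(img, path) {
  stopifnot(is(img, "Image3D"))
  if (!dir.exists(dirname(path)))
    stop(sprintf("directory '%s' does not exist", dirname(path)),
         call. = FALSE)
  isLabel <- is(img, "LabelImage")
  if (imageFormat(path) == "nifti") {
    dat <- img@data
    if (isLabel) storage.mode(dat) <- "integer"
    nim <- RNifti::asNifti(dat)
    RNifti::pixdim(nim) <- img@spacing
    m <- diag(c(img@spacing, 1))
    m[1:3, 4] <- img@origin
    nim <- RNifti::`qform<-`(nim, value = structure(m, code = 2L))
    nim <- RNifti::`sform<-`(nim, value = structure(m, code = 2L))
    RNifti::writeNifti(nim, path,
                       datatype = if (isLabel) "int32" else "double")
  } else {
    writeNrrdImage(img, path, integer = isLabel)
  }
  invisible(NULL)
}

imageFormat <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  if (grepl("\\.(nrrd|nhdr)$", path, ignore.case = TRUE)) return("nrrd")
  stop(sprintf("unrecognised image extension for '%s' (expected .nii, .nii.gz, .nrrd or .nhdr)",
               path), call. = FALSE)
}

readNiftiImage <- function(path) {
  nim <- tryCatch(RNifti::readNifti(path), error = function(e)
    stop(sprintf("failed to read NIfTI image '%s': %s", path,
                 conditionMessage(e)), call. = FALSE))
  dat <- array(as.vector(as.array(nim)), dim(nim))
  xf <- RNifti::xform(nim)
  rot <- xf[1:3, 1:3]
  if (max(abs(rot - diag(diag(rot)))) > 1e-6 * max(abs(rot)) ||
      any(diag(rot) <= 0))
    stop(sprintf("'%s' has an oblique or flipped orientation; only axis-aligned images are supported",
                 path), call. = FALSE)
  list(data = dat, spacing = diag(rot), origin = xf[1:3, 4])
}

nrrdTypes <- c(double = "double", float = "float", int = "int",
               short = "short", uchar = "uchar")

readNrrdImage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (length(magic) != 1L || !grepl("^NRRD000", magic))
    stop(sprintf("'%s' is not a NRRD file", path), call. = FALSE)
  fields <- list()
  datafile <- NULL
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L)
      stop(sprintf("truncated NRRD header in '%s'", path), call. = FALSE)
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(kv) != 3L)
      stop(sprintf("malformed NRRD header line in '%s': %s", path, line),
           call. = FALSE)
    fields[[tolower(kv[2])]] <- kv[3]
  }
  need <- function(key) {
    if (is.null(fields[[key]]))
      stop(sprintf("NRRD header of '%s' lacks field '%s'", path, key),
           call. = FALSE)
    fields[[key]]
  }
  if (as.integer(need("dimension")) != 3L)
    stop(sprintf("'%s' is not 3-D", path), call. = FALSE)
  sizes <- as.integer(strsplit(trimws(need("sizes")), "\\s+")[[1]])
  type <- trimws(need("type"))
  if (!type %in% names(nrrdTypes))
    stop(sprintf("unsupported NRRD type '%s' in '%s'", type, path),
         call. = FALSE)
  encoding <- trimws(need("encoding"))
  if (!encoding %in% c("raw", "gzip", "gz"))
    stop(sprintf("unsupported NRRD encoding '%s' in '%s'", encoding, path),
         call. = FALSE)
  spc <- c(1, 1, 1)
  org <- c(0, 0, 0)
  if (!is.null(fields[["spacings"]]))
    spc <- as.numeric(strsplit(trimws(fields[["spacings"]]), "\\s+")[[1]])
  if (!is.null(fields[["axis mins"]]))
    org <- as.numeric(strsplit(trimws(fields[["axis mins"]]), "\\s+")[[1]])
  if (!is.null(fields[["space directions"]])) {
    vecs <- parseNrrdVectors(fields[["space directions"]])
    if (any(abs(vecs - diag(diag(vecs))) > 1e-9 * max(abs(vecs))))
      stop(sprintf("'%s' has non-axis-aligned space directions", path),
           call. = FALSE)
    spc <- diag(vecs)
  }
  if (!is.null(fields[["space origin"]]))
    org <- as.numeric(parseNrrdVectors(fields[["space origin"]]))
  if (!is.null(fields[["data file"]])) {
    datafile <- file.path(dirname(path), trimws(fields[["data file"]]))
    close(con)
    on.exit(NULL)
    con <- file(datafile, "rb")
    on.exit(close(con))
  }
  bytes <- c(double = 8L, float = 4L, int = 4L, short = 2L, uchar = 1L)[type]
  nvals <- prod(sizes)
  raw <- readBin(con, "raw", n = file.size(if (is.null(datafile)) path
                                           else datafile))
  if (encoding != "raw")
    raw <- tryCatch(memDecompress(raw, type = "gzip"), error = function(e)
      stop(sprintf("NRRD data block of '%s' is truncated or corrupt",
                   path), call. = FALSE))
  if (length(raw) < nvals * bytes)
    stop(sprintf("NRRD data block of '%s' is truncated", path),
         call. = FALSE)
  what <- if (type %in% c("double", "float")) "numeric" else "integer"
  vals <- readBin(raw, what, n = nvals, size = bytes, endian = "little",
                  signed = bytes > 1L)
  list(data = array(as.double(vals), sizes), spacing = spc, origin = org)
}

parseNrrdVectors <- function(s) {
  m <- regmatches(s, gregexpr("\\(([^)]*)\\)", s))[[1]]
  vals <- lapply(m, function(v)
    as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]))
  do.call(rbind, vals)
}

writeNrrdImage <- function(img, path, integer = FALSE) {
  type <- if (integer) "int" else "double"
  d <- dim(img@data)
  hdr <- c("NRRD0004",
           sprintf("type: %s", type),
           "dimension: 3",
           sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
           sprintf("spacings: %.17g %.17g %.17g", img@spacing[1],
                   img@spacing[2], img@spacing[3]),
           sprintf("axis mins: %.17g %.17g %.17g", img@origin[1],
                   img@origin[2], img@origin[3]),
           "endian: little",
           "encoding: gzip",
           "")
  vals <- as.vector(img@data)
  raw <- if (integer) writeBin(as.integer(vals), raw(), size = 4L,
                               endian = "little")
         else writeBin(vals, raw(), size = 8L, endian = "little")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  writeBin(memCompress(raw, type = "gzip"), con)
  invisible(NULL)
}

#' Read / write a labelled tetrahedral mesh (VTK legacy ASCII)
#'
#' The on-disk format is a VTK legacy ASCII unstructured grid
#' (\code{DATASET UNSTRUCTURED_GRID}, all \code{CELL_TYPES} 10) with a
#' \code{CELL_DATA} integer \code{SCALARS label} array. Vertex indices are
#' 0-based on disk and 1-based in the returned \linkS4class{TetMesh}.
#'
#' @param path file path.
#' @return \code{readMesh}: a \linkS4class{TetMesh}.
#' @export
readMesh <- function(path) {
  if (!file.exists(path))
    stop(sprintf("mesh file '%s' does not exist", path), call. = FALSE)
  tok <- scan(path, what = "character", quiet = TRUE, comment.char = "")
  expectTok <- function(i, what) {
    if (i > length(tok) || toupper(tok[i]) != what)
      stop(sprintf("'%s' is not a VTK legacy unstructured grid (expected %s)",
                   path, what), call. = FALSE)
  }
  i <- match("DATASET", toupper(tok))
  if (is.na(i))
    stop(sprintf("'%s' is not a VTK legacy dataset", path), call. = FALSE)
  expectTok(i + 1L, "UNSTRUCTURED_GRID")
  i <- i + 2L
  expectTok(i, "POINTS")
  n <- as.integer(tok[i + 1L])
  V <- matrix(as.numeric(tok[(i + 3L):(i + 2L + 3L * n)]), ncol = 3,
              byrow = TRUE)
  i <- i + 3L + 3L * n
  expectTok(i, "CELLS")
  m <- as.integer(tok[i + 1L])
  total <- as.integer(tok[i + 2L])
  cells <- as.integer(tok[(i + 3L):(i + 2L + total)])
  i <- i + 3L + total
  expectTok(i, "CELL_TYPES")
  ctypes <- as.integer(tok[(i + 2L):(i + 1L + m)])
  if (any(ctypes != 10L))
    stop(sprintf("'%s' contains non-tetrahedral cells (VTK type %s)", path,
                 paste(unique(ctypes[ctypes != 10L]), collapse = ", ")),
         call. = FALSE)
  i <- i + 2L + m
  Tm <- matrix(0L, m, 4)
  pos <- 1L
  for (e in seq_len(m)) {
    if (cells[pos] != 4L)
      stop(sprintf("cell %d of '%s' has %d vertices; only tetrahedra are supported",
                   e, path, cells[pos]), call. = FALSE)
    Tm[e, ] <- cells[(pos + 1L):(pos + 4L)] + 1L
    pos <- pos + 5L
  }
  labels <- integer(m)
  j <- which(toupper(tok) == "CELL_DATA")
  if (length(j)) {
    k <- which(toupper(tok) == "SCALARS" & seq_along(tok) > j[1])
    if (length(k) && tolower(tok[k[1] + 1L]) == "label") {
      start <- k[1] + 5L  # SCALARS label <type> [1] LOOKUP_TABLE default
      if (toupper(tok[k[1] + 3L]) != "LOOKUP_TABLE") start <- k[1] + 6L
      labels <- as.integer(tok[start:(start + m - 1L)])
    }
  }
  tetMesh(V, Tm, labels)
}

#' @rdname readMesh
#' @param mesh a \linkS4class{TetMesh}.
#' @export
writeMesh <- function(mesh, path) {
  stopifnot(is(mesh, "TetMesh"))
  V <- mesh@vertices
  Tm <- mesh@tets - 1L
  m <- nrow(Tm)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "labelled tetrahedral mesh",
               "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(V))), con)
  writeLines(sprintf("%.17g %.17g %.17g", V[, 1], V[, 2], V[, 3]), con)
  writeLines(sprintf("CELLS %d %d", m, 5L * m), con)
  writeLines(sprintf("4 %d %d %d %d", Tm[, 1], Tm[, 2], Tm[, 3], Tm[, 4]),
             con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("10", m), con)
  writeLines(c(sprintf("CELL_DATA %d", m), "SCALARS label int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%d", mesh@labels), con)
  invisible(NULL)
}
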