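#' Triangulated surface meshes with per-vertex scalars
#'
#' A `surface_mesh` holds vertex coordinates in world mm, triangle index
#' triples (1-based), and an optional named list of per-vertex scalar maps
#' (parcel labels, myelin, curvature, ...). It stands in for the white/grey
#' matter boundary (WGB) surface from which cortical streamline seeding is
#' performed.
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @param scalars Named list of length-n numeric vectors (optional).
#' @return A `surface_mesh` object.
#' @export
surface_mesh <- function(vertices, triangles, scalars = list()) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3L)
  if (ncol(vertices) != 3L || !all(is.finite(vertices))) {
    abort("`vertices` must be a finite n x 3 matrix")
  }
  n <- nrow(vertices)
  if (any(triangles < 1L) || any(triangles > n)) {
    abort("triangle indices out of range")
  }
  degen <- triangles[, 1L] == triangles[, 2L] | triangles[, 1L] == triangles[, 3L] |
    triangles[, 2L] == triangles[, 3L]
  if (any(degen)) abort(sprintf("%d degenerate triangle(s) with repeated vertices", sum(degen)))
  if (length(scalars)) {
    stopifnot(!is.null(names(scalars)), all(lengths(scalars) == n))
  }
  structure(list(vertices = vertices, triangles = triangles, scalars = scalars),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles, scalars: %s\n",
              nrow(x$vertices), nrow(x$triangles),
              if (length(x$scalars)) paste(names(x$scalars), collapse = ", ") else "none"))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)

# --- icosphere ---------------------------------------------------------------

# Unit icosphere by repeated edge-midpoint subdivision of an icosahedron.
# Subdivision level s gives 10*4^s + 2 vertices (level 3 -> 642), the scale the
# phantom surfaces use.
icosphere <- function(subdivisions = 3L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdivisions)) {
    edge_key <- function(a, b) paste0(pmin(a, b), "_", pmax(a, b))
    mids <- new.env(parent = emptyenv())
    verts <- v
    midpoint <- function(a, b) {
      key <- edge_key(a, b)
      if (!is.null(mids[[key]])) return(mids[[key]])
      m <- (verts[a, ] + verts[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      verts <<- rbind(verts, m)
      mids[[key]] <- nrow(verts)
      nrow(verts)
    }
    nf <- matrix(0L, nrow = 4L * nrow(f), ncol = 3L)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1L]; b <- f[t, 2L]; cc <- f[t, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[4L * t - 3L, ] <- c(a, ab, ca)
      nf[4L * t - 2L, ] <- c(b, bc, ab)
      nf[4L * t - 1L, ] <- c(cc, ca, bc)
      nf[4L * t, ] <- c(ab, bc, ca)
    }
    v <- verts
    f <- nf
  }
  list(vertices = v, triangles = f)
}

# --- GIFTI-style I/O ---------------------------------------------------------

gifti_data_array <- function(doc_root, intent, datatype, mat) {
  da <- xml2::xml_add_child(doc_root, "DataArray",
    Intent = intent, DataType = datatype,
    ArrayIndexingOrder = "RowMajorOrder",
    Dimensionality = as.character(length(dim(mat))),
    Dim0 = as.character(nrow(mat)), Dim1 = as.character(ncol(mat)),
    Encoding = "ASCII", Endian = "LittleEndian"
  )
  txt <- paste(apply(mat, 1L, function(r) paste(format(r, digits = 17, scientific = FALSE, trim = TRUE), collapse = " ")),
               collapse = "\n")
  xml2::xml_add_child(da, "Data", txt)
  invisible(da)
}

#' Read and write GIFTI surface and scalar files
#'
#' Minimal GIFTI (v1.0) support with ASCII-encoded data arrays: surface
#' geometry files carry a POINTSET and a TRIANGLE array (triangle indices are
#' 0-based on disk, 1-based in R), scalar files carry one per-vertex SHAPE
#' array per map. ASCII encoding keeps the files plain text while remaining
#' valid GIFTI.
#'
#' @param mesh A [surface_mesh()].
#' @param path File path (`.surf.gii` / `.gii` conventionally).
#' @return `read_surface()` returns a [surface_mesh()] (without scalars);
#'   `read_surface_scalar()` returns a numeric vector.
#' @export
write_surface <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0", NumberOfDataArrays = "2")
  gifti_data_array(doc, "NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT32", mesh$vertices)
  gifti_data_array(doc, "NIFTI_INTENT_TRIANGLE", "NIFTI_TYPE_INT32", mesh$triangles - 1L)
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname write_surface
#' @export
read_surface <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  parse_array <- function(da) {
    n0 <- as.integer(xml2::xml_attr(da, "Dim0"))
    n1 <- as.integer(xml2::xml_attr(da, "Dim1"))
    txt <- xml2::xml_text(xml2::xml_find_first(da, ".//Data"))
    vals <- scan(text = txt, quiet = TRUE)
    matrix(vals, nrow = n0, ncol = n1, byrow = TRUE)
  }
  intents <- xml2::xml_attr(arrays, "Intent")
  pts <- parse_array(arrays[[which(intents == "NIFTI_INTENT_POINTSET")[1L]]])
  tri <- parse_array(arrays[[which(intents == "NIFTI_INTENT_TRIANGLE")[1L]]])
  surface_mesh(pts, tri + 1L)
}

#' @rdname write_surface
#' @param values Per-vertex numeric vector to write.
#' @export
write_surface_scalar <- function(values, path) {
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0", NumberOfDataArrays = "1")
  gifti_data_array(doc, "NIFTI_INTENT_SHAPE", "NIFTI_TYPE_FLOAT32",
                   matrix(as.numeric(values), ncol = 1L))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname write_surface
#' @export
read_surface_scalar <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  doc <- xml2::read_xml(path)
  da <- xml2::xml_find_first(doc, ".//DataArray")
  txt <- xml2::xml_text(xml2::xml_find_first(da, ".//Data"))
  scan(text = txt, quiet = TRUE)
}
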