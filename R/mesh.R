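#' Triangulated surface mesh
#'
#' `tri_mesh()` constructs the basic geometric container of the package: a
#' triangulated surface with vertex coordinates in millimetres, triangle
#' connectivity, and an arbitrary set of named per-vertex scalar fields
#' (e.g. mean curvature in 1/mm, TAWSS in Pa). Meshes are not required to
#' share a vertex count or correspondence: every downstream step works on
#' rendered images, never on node indices.
#'
#' @param vertices numeric n x 3 matrix of coordinates (mm).
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @param fields named list of [scalar_field()] objects (or omitted).
#' @return an object of class `mv_mesh`.
#' @export
tri_mesh <- function(vertices, faces, fields = list()) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  m <- structure(list(vertices = vertices, faces = faces, fields = list()),
                 class = "mv_mesh")
  validate_mesh(m)
  for (nm in names(fields)) m <- attach_field(m, fields[[nm]])
  m
}

validate_mesh <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (anyNA(v) || any(!is.finite(v))) stop("non-finite vertex coordinates")
  if (nrow(f) > 0) {
    if (min(f) < 1L || max(f) > nrow(v))
      stop("face index out of range (topology error)")
    if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
      stop("faces must reference 3 distinct vertices (topology error)")
  }
  for (fl in mesh$fields)
    if (length(fl$values) != nrow(v))
      stop("field '", fl$name, "' length does not match vertex count")
  invisible(mesh)
}

#' Per-vertex scalar field
#'
#' A named array of one real value per mesh vertex plus the normalization
#' range used when the field is mapped through a colormap. The range must
#' cover the data; it may be wider (e.g. a shared range across geometries).
#'
#' @param name field identifier, e.g. `"tawss"`.
#' @param values numeric vector, one finite value per vertex.
#' @param units free-text unit string (`"Pa"`, `"1/mm"`, ...).
#' @param range length-2 numeric `(min, max)` for color normalization;
#'   defaults to the data range.
#' @export
scalar_field <- function(name, values, units = "", range = NULL) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("scalar field values must be finite")
  if (is.null(range)) range <- range(values)
  if (range[1] > min(values) || range[2] < max(values))
    stop("field range must cover the data range")
  if (range[1] >= range[2] && stats::sd(values) > 0)
    stop("degenerate range for a non-constant field")
  structure(list(name = name, values = values, units = units,
                 range = as.numeric(range)),
            class = "mv_field")
}

#' @export
print.mv_mesh <- function(x, ...) {
  cat(sprintf("mv_mesh: %d vertices, %d faces, fields: %s\n",
              nrow(x$vertices), nrow(x$faces),
              if (length(x$fields)) paste(names(x$fields), collapse = ", ")
              else "<none>"))
  invisible(x)
}

#' Attach a scalar field to a mesh
#' @param mesh an `mv_mesh`.
#' @param field an `mv_field` with one value per vertex.
#' @export
attach_field <- function(mesh, field) {
  stopifnot(inherits(field, "mv_field"))
  if (length(field$values) != nrow(mesh$vertices))
    stop("field '", field$name, "' length does not match vertex count")
  mesh$fields[[field$name]] <- field
  mesh
}

## ---- welding -------------------------------------------------------------

# Merge duplicate vertices within `tol` (STL stores unindexed triangle soup).
weld_vertices <- function(vertices, faces, tol = 1e-6) {
  key <- apply(round(vertices / tol), 1L, paste, collapse = "_")
  first <- !duplicated(key)
  map <- match(key, key[first])
  newv <- vertices[first, , drop = FALSE]
  newf <- matrix(map[faces], ncol = 3L)
  keep <- newf[, 1] != newf[, 2] & newf[, 2] != newf[, 3] & newf[, 1] != newf[, 3]
  list(vertices = newv, faces = newf[keep, , drop = FALSE])
}

## ---- I/O -----------------------------------------------------------------

#' Load a surface mesh from STL, PLY, OBJ or VTK polydata
#'
#' STL input (ASCII or binary) is an unindexed triangle soup; duplicate
#' vertices are welded within `weld_tol`. PLY (ASCII) and legacy VTK
#' polydata preserve per-vertex scalar fields; OBJ carries geometry only.
#'
#' @param path file path; format inferred from the extension.
#' @param weld_tol absolute coordinate tolerance (mm) used to merge
#'   duplicated vertices for STL input.
#' @return an `mv_mesh`.
#' @export
load_mesh <- function(path, weld_tol = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = read_stl(path, weld_tol),
         ply = read_ply(path),
         obj = read_obj(path),
         vtk = read_vtk(path),
         stop("unsupported mesh format: .", ext))
}

#' Save a surface mesh as STL, PLY or VTK polydata
#'
#' @param mesh an `mv_mesh`.
#' @param path output file path.
#' @param format one of `"stl"`, `"ply"`, `"vtk"`; default from extension.
#'   STL cannot carry fields; attached fields are dropped with a warning.
#' @export
save_mesh <- function(mesh, path, format = tolower(tools::file_ext(path))) {
  validate_mesh(mesh)
  switch(format,
         stl = {
           if (length(mesh$fields))
             warning("STL cannot store per-vertex fields; fields dropped")
           write_stl(mesh, path)
         },
         ply = write_ply(mesh, path),
         vtk = write_vtk(mesh, path),
         stop("unsupported output format: ", format))
  invisible(path)
}

read_stl <- function(path, weld_tol) {
  con <- file(path, "rb")
  head80 <- readBin(con, "raw", 80L)
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  sz <- file.size(path)
  is_binary <- length(ntri) == 1L && !is.na(ntri) &&
    sz == 84 + 50 * as.numeric(ntri)
  close(con)
  if (is_binary) {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 84L)
    tris <- matrix(0, nrow = ntri * 3L, ncol = 3L)
    for (i in seq_len(ntri)) {
      rec <- readBin(con, "numeric", 12L, size = 4L, endian = "little")
      tris[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], ncol = 3L, byrow = TRUE)
      readBin(con, "raw", 2L)
    }
  } else {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
    if (!length(vl)) stop("unreadable STL file (format error): ", path)
    parts <- strsplit(trimws(vl), "\\s+")
    tris <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (nrow(tris) %% 3 != 0) stop("corrupt ASCII STL (format error)")
  }
  faces <- matrix(seq_len(nrow(tris)), ncol = 3L, byrow = TRUE)
  w <- weld_vertices(tris, faces, weld_tol)
  tri_mesh(w$vertices, w$faces)
}

write_stl <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid mvwss", con)
  for (i in seq_len(nrow(f))) {
    p <- v[f[i, ], , drop = FALSE]
    n <- cross3(p[2, ] - p[1, ], p[3, ] - p[1, ])
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
                 "    outer loop",
                 sprintf("      vertex %.9g %.9g %.9g", p[, 1], p[, 2], p[, 3]),
                 "    endloop", "  endfacet"), con)
  }
  writeLines("endsolid mvwss", con)
}

read_ply <- function(path) {
  txt <- readLines(path, warn = FALSE)
  end_h <- match("end_header", trimws(txt))
  if (is.na(end_h)) stop("unreadable PLY (format error): ", path)
  head <- trimws(txt[seq_len(end_h)])
  nv <- as.integer(sub("element vertex\\s+", "", grep("^element vertex", head, value = TRUE)))
  nf <- as.integer(sub("element face\\s+", "", grep("^element face", head, value = TRUE)))
  # vertex property names, in order
  vstart <- grep("^element vertex", head)
  fstart <- grep("^element face", head)
  props <- head[(vstart + 1):(fstart - 1)]
  props <- props[grepl("^property", props)]
  pnames <- vapply(strsplit(props, "\\s+"), function(p) p[3], character(1))
  body <- txt[(end_h + 1):length(txt)]
  vdat <- matrix(scan(text = body[seq_len(nv)], quiet = TRUE),
                 nrow = nv, byrow = TRUE)
  colnames(vdat) <- pnames
  fl <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  fdat <- t(vapply(fl, function(p) {
    if (as.integer(p[1]) != 3L) stop("non-triangular PLY face (topology error)")
    as.integer(p[2:4]) + 1L
  }, integer(3)))
  mesh <- tri_mesh(vdat[, c("x", "y", "z"), drop = FALSE], fdat)
  extras <- setdiff(pnames, c("x", "y", "z"))
  for (nm in extras)
    mesh <- attach_field(mesh, scalar_field(nm, vdat[, nm]))
  mesh
}

write_ply <- function(mesh, path) {
  v <- mesh$vertices
  extras <- names(mesh$fields)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property double x", "property double y", "property double z",
               sprintf("property double %s", extras),
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  dat <- cbind(v, do.call(cbind, lapply(mesh$fields, `[[`, "values")))
  writeLines(apply(dat, 1L, function(r) paste(sprintf("%.17g", r), collapse = " ")), con)
  writeLines(paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                   mesh$faces[, 3] - 1L), con)
}

read_obj <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", txt, value = TRUE)
  fl <- grep("^f\\s", txt, value = TRUE)
  v <- t(vapply(strsplit(trimws(vl), "\\s+"),
                function(p) as.numeric(p[2:4]), numeric(3)))
  f <- t(vapply(strsplit(trimws(fl), "\\s+"), function(p) {
    ix <- as.integer(sub("/.*", "", p[-1]))
    if (length(ix) != 3L) stop("non-triangular OBJ face (topology error)")
    ix
  }, integer(3)))
  tri_mesh(v, f)
}

read_vtk <- function(path) {
  txt <- readLines(path, warn = FALSE)
  ip <- grep("^POINTS", txt)
  if (!length(ip)) stop("unreadable VTK polydata (format error): ", path)
  nv <- as.integer(strsplit(txt[ip], "\\s+")[[1]][2])
  nums <- scan(text = txt[(ip + 1):length(txt)], quiet = TRUE, n = 3 * nv)
  v <- matrix(nums, ncol = 3L, byrow = TRUE)
  ipoly <- grep("^POLYGONS", txt)
  hd <- as.integer(strsplit(txt[ipoly], "\\s+")[[1]][2:3])
  nf <- hd[1]
  # count lines consumed by POINTS to locate POLYGONS body robustly
  fn <- scan(text = txt[(ipoly + 1):length(txt)], quiet = TRUE, n = hd[2])
  fmat <- matrix(as.integer(fn), ncol = 4L, byrow = TRUE)
  if (any(fmat[, 1] != 3L)) stop("non-triangular VTK cells (topology error)")
  mesh <- tri_mesh(v, fmat[, 2:4] + 1L)
  ipd <- grep("^POINT_DATA", txt)
  if (length(ipd)) {
    isc <- grep("^SCALARS", txt)
    isc <- isc[isc > ipd]
    for (k in isc) {
      nm <- strsplit(txt[k], "\\s+")[[1]][2]
      vals <- scan(text = txt[(k + 2):length(txt)], quiet = TRUE, n = nv)
      mesh <- attach_field(mesh, scalar_field(nm, vals))
    }
  }
  mesh
}

write_vtk <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "mvwss surface", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", nrow(v))), con)
  writeLines(apply(v, 1L, function(r) paste(sprintf("%.17g", r), collapse = " ")), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(f), 4L * nrow(f)), con)
  writeLines(paste(3L, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  if (length(mesh$fields)) {
    writeLines(sprintf("POINT_DATA %d", nrow(v)), con)
    for (fl in mesh$fields) {
      writeLines(c(sprintf("SCALARS %s double 1", fl$name),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.17g", fl$values), con)
    }
  }
}

## ---- small geometric helpers --------------------------------------------

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rotation matrix about a unit axis by `degrees` (counterclockwise looking
# down the axis toward the origin, right-handed).
rotation_matrix <- function(axis = c("x", "y", "z"), degrees) {
  axis <- match.arg(axis)
  th <- degrees * pi / 180
  c0 <- cos(th); s0 <- sin(th)
  switch(axis,
         x = matrix(c(1, 0, 0, 0, c0, s0, 0, -s0, c0), 3L),
         y = matrix(c(c0, 0, -s0, 0, 1, 0, s0, 0, c0), 3L),
         z = matrix(c(c0, s0, 0, -s0, c0, 0, 0, 0, 1), 3L))
}

#' Rigidly transform a mesh
#' @param mesh an `mv_mesh`.
#' @param rotation 3 x 3 rotation matrix (applied first).
#' @param translation length-3 offset (mm).
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  mesh$vertices <- mesh$vertices %*% t(rotation) +
    matrix(translation, nrow(mesh$vertices), 3L, byrow = TRUE)
  mesh
}

# Unit icosphere: subdivided icosahedron, radius r. Used for analytic
# curvature checks and as a generic closed test surface.
icosphere <- function(subdiv = 2L, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    mids <- new.env()
    newf <- matrix(0L, nrow = 4L * nrow(f), ncol = 3L)
    vlist <- v
    midpoint <- function(a, b) {
      k <- edge_key(a, b)
      if (!is.null(mids[[k]])) return(mids[[k]])
      m <- (vlist[a, ] + vlist[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      vlist <<- rbind(vlist, m)
      mids[[k]] <- nrow(vlist)
      nrow(vlist)
    }
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[(4 * i - 3):(4 * i), ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                           c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- vlist; f <- newf
  }
  tri_mesh(v * radius, f)
}

# Open cylinder along z of given radius/height (no caps); curvature fixture.
cylinder_mesh <- function(radius = 1, height = 4, n_axial = 20L, n_circ = 24L) {
  z <- seq(0, height, length.out = n_axial)
  th <- seq(0, 2 * pi, length.out = n_circ + 1L)[-(n_circ + 1L)]
  v <- cbind(radius * cos(rep(th, n_axial)),
             radius * sin(rep(th, n_axial)),
             rep(z, each = n_circ))
  f <- ring_strip_faces(n_axial, n_circ)
  tri_mesh(v, f)
}

# Shared triangulation of a ring strip grid: rows of n_circ vertices.
ring_strip_faces <- function(n_rows, n_circ) {
  f <- matrix(0L, nrow = 2L * (n_rows - 1L) * n_circ, ncol = 3L)
  k <- 1L
  for (i in seq_len(n_rows - 1L)) {
    base0 <- (i - 1L) * n_circ
    for (j in seq_len(n_circ)) {
      jn <- if (j == n_circ) 1L else j + 1L
      a <- base0 + j; b <- base0 + jn
      cpr <- base0 + n_circ + j; dpr <- base0 + n_circ + jn
      f[k, ] <- c(a, b, dpr); f[k + 1L, ] <- c(a, dpr, cpr)
      k <- k + 2L
    }
  }
  f
}

plane_mesh <- function(n = 12L, size = 1) {
  g <- seq(0, size, length.out = n)
  v <- cbind(rep(g, each = n), rep(g, n), 0)
  f <- matrix(0L, nrow = 2L * (n - 1L)^2, ncol = 3L)
  k <- 1L
  for (i in seq_len(n - 1L)) for (j in seq_len(n - 1L)) {
    a <- (i - 1L) * n + j
    f[k, ] <- c(a, a + n, a + n + 1L); f[k + 1L, ] <- c(a, a + n + 1L, a + 1L)
    k <- k + 2L
  }
  tri_mesh(v, f)
}
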