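#' Read a triangle mesh from OBJ, PLY or STL
#'
#' Formats are detected from the file extension unless `format` is given.
#' PLY is supported in ASCII and binary little-endian form, STL in ASCII and
#' binary form. STL carries no connectivity, so coincident vertices are welded
#' at a 1e-6 mm tolerance on load. Coordinates are passed through unchanged
#' and assumed to be millimetres.
#'
#' @param path file path.
#' @param format one of `"obj"`, `"ply"`, `"stl"`; default from extension.
#' @return A [triangle_mesh].
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop("cannot read mesh: no such file: ", path)
  format <- tolower(format %||% tools::file_ext(path))
  mesh <- switch(format,
    obj = read_obj(path),
    ply = read_ply(path),
    stl = read_stl(path),
    stop("unsupported mesh format: ", format)
  )
  if (nrow(mesh$vertices) == 0) stop("empty mesh in ", path)
  mesh
}

#' Write a triangle mesh to OBJ, PLY or STL
#'
#' @param mesh a [triangle_mesh].
#' @param path output path.
#' @param format one of `"obj"`, `"ply"`, `"stl"`; default from extension.
#' @param binary write the binary variant (PLY little-endian, STL binary).
#'   Ignored for OBJ, which is always ASCII.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, binary = FALSE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  format <- tolower(format %||% tools::file_ext(path))
  switch(format,
    obj = write_obj(mesh, path),
    ply = write_ply(mesh, path, binary),
    stl = write_stl(mesh, path, binary),
    stop("unsupported mesh format: ", format)
  )
  invisible(path)
}

#' Write a point cloud as plain-text XYZ
#'
#' One `x y z` triple per line.
#'
#' @param cloud a [point_cloud].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(cloud, path) {
  stopifnot(inherits(cloud, "point_cloud"))
  utils::write.table(format(cloud$points, digits = 9, trim = TRUE,
                            scientific = FALSE),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a plain-text XYZ point cloud
#'
#' @param path input path.
#' @return A [point_cloud].
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("cannot read point cloud: no such file: ", path)
  m <- as.matrix(utils::read.table(path))
  point_cloud(m[, 1:3, drop = FALSE])
}

`%||%` <- function(a, b) if (is.null(a) || (is.character(a) && !nzchar(a))) b else a

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(t) {
    as.numeric(t[2:4])
  }))
  faces <- NULL
  if (length(fl) > 0) {
    faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(t) {
      idx <- as.integer(vapply(strsplit(t[-1], "/"), `[`, "", 1))
      # fan-triangulate polygons
      if (length(idx) < 3) stop("face with fewer than 3 vertices in OBJ")
      cbind(idx[1], idx[seq(2, length(idx) - 1)], idx[seq(3, length(idx))])
    }))
  }
  triangle_mesh(verts, faces, drop_degenerate = TRUE)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]),
             con)
  if (nrow(mesh$faces) > 0) {
    writeLines(sprintf("f %d %d %d",
                       mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
  }
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # the header is ASCII even in binary files; read it byte-wise so the
  # connection stays positioned at the start of the payload
  read_line <- function() {
    out <- raw(0)
    repeat {
      b <- readBin(con, "raw", 1)
      if (length(b) == 0) stop("unexpected EOF in PLY header")
      if (b == as.raw(10)) break
      out <- c(out, b)
    }
    sub("\r$", "", rawToChar(out))
  }
  magic <- read_line()
  if (magic != "ply") stop("not a PLY file: ", path)
  fmt <- NULL
  elements <- list() # list of list(name, count, props = data.frame(type, name))
  cur <- NULL
  repeat {
    line <- read_line()
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "comment") next
    if (tok[1] == "format") {
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      cur$props[[length(cur$props) + 1]] <- tok[-1]
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    }
  }
  if (is.null(fmt)) stop("PLY file lacks a format line")
  ve <- elements[["vertex"]]
  fe <- elements[["face"]]
  if (is.null(ve)) stop("PLY file has no vertex element")
  if (fmt == "ascii") {
    rest <- readLines(con, warn = FALSE)
    rest <- rest[nzchar(trimws(rest))]
    vlines <- rest[seq_len(ve$count)]
    vmat <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), as.numeric))
    pn <- vapply(ve$props, function(p) p[length(p)], "")
    verts <- vmat[, match(c("x", "y", "z"), pn), drop = FALSE]
    faces <- NULL
    if (!is.null(fe) && fe$count > 0) {
      flines <- rest[ve$count + seq_len(fe$count)]
      faces <- do.call(rbind, lapply(strsplit(trimws(flines), "\\s+"), function(t) {
        n <- as.integer(t[1])
        idx <- as.integer(t[1 + seq_len(n)]) + 1L
        cbind(idx[1], idx[seq(2, n - 1)], idx[seq(3, n)])
      }))
    }
    return(triangle_mesh(verts, faces, drop_degenerate = TRUE))
  }
  if (fmt != "binary_little_endian") {
    stop("unsupported PLY format: ", fmt)
  }
  ply_size <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1, short = 2, ushort = 2,
                int16 = 2, uint16 = 2, int = 4, uint = 4, int32 = 4, uint32 = 4,
                float = 4, float32 = 4, double = 8, float64 = 8)
  read_scalar <- function(type) {
    sz <- ply_size[[type]]
    if (type %in% c("float", "float32", "double", "float64")) {
      readBin(con, "double", 1, size = sz, endian = "little")
    } else {
      readBin(con, "integer", 1, size = sz, endian = "little",
              signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
    }
  }
  pn <- vapply(ve$props, function(p) p[length(p)], "")
  pt <- vapply(ve$props, function(p) p[1], "")
  if (any(pt == "list")) stop("list properties on PLY vertices unsupported")
  verts <- matrix(NA_real_, ve$count, 3)
  xyz <- match(c("x", "y", "z"), pn)
  for (i in seq_len(ve$count)) {
    row <- vapply(pt, read_scalar, 0)
    verts[i, ] <- row[xyz]
  }
  faces <- NULL
  if (!is.null(fe) && fe$count > 0) {
    lp <- fe$props[[1]]
    if (lp[1] != "list") stop("PLY face element must be a list property")
    cnt_type <- lp[2]
    idx_type <- lp[3]
    facc <- vector("list", fe$count)
    for (i in seq_len(fe$count)) {
      n <- read_scalar(cnt_type)
      idx <- vapply(seq_len(n), function(k) read_scalar(idx_type), 0) + 1L
      facc[[i]] <- cbind(idx[1], idx[seq(2, n - 1)], idx[seq(3, n)])
    }
    faces <- do.call(rbind, facc)
  }
  triangle_mesh(verts, faces, drop_degenerate = TRUE)
}

write_ply <- function(mesh, path, binary = FALSE) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  header <- c(
    "ply",
    if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
    sprintf("element vertex %d", nv),
    "property float x", "property float y", "property float z",
    sprintf("element face %d", nf),
    "property list uchar int vertex_indices",
    "end_header"
  )
  if (!binary) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    writeLines(sprintf("%.9g %.9g %.9g",
                       mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]),
               con)
    if (nf > 0) {
      writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                         mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
    }
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con, sep = "\n")
    writeBin(as.vector(t(mesh$vertices)), con, size = 4, endian = "little")
    if (nf > 0) {
      for (i in seq_len(nf)) {
        writeBin(as.raw(3), con)
        writeBin(as.integer(mesh$faces[i, ] - 1L), con, size = 4,
                 endian = "little")
      }
    }
  }
}

read_stl <- function(path) {
  # binary STL: 80-byte header, uint32 facet count, 50 bytes per facet
  sz <- file.info(path)$size
  con <- file(path, "rb")
  head80 <- readBin(con, "raw", 80)
  nfac <- if (sz >= 84) readBin(con, "integer", 1, size = 4, endian = "little") else -1
  close(con)
  is_binary <- sz >= 84 && sz == 84 + 50 * nfac
  if (is_binary) {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 84)
    tri <- matrix(NA_real_, nfac * 3, 3)
    for (i in seq_len(nfac)) {
      vals <- readBin(con, "double", 12, size = 4, endian = "little")
      tri[3 * i - 2, ] <- vals[4:6]
      tri[3 * i - 1, ] <- vals[7:9]
      tri[3 * i, ] <- vals[10:12]
      readBin(con, "raw", 2)
    }
  } else {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
    tri <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(t) {
      as.numeric(t[2:4])
    }))
  }
  if (is.null(tri) || nrow(tri) == 0) stop("empty STL mesh in ", path)
  weld_triangle_soup(tri, tol = 1e-6)
}

# collapse coincident vertices (within tol, mm) of a triangle soup and build
# the shared-vertex mesh
weld_triangle_soup <- function(tri, tol = 1e-6) {
  key <- paste(round(tri[, 1] / tol), round(tri[, 2] / tol), round(tri[, 3] / tol))
  uid <- match(key, unique(key))
  first <- !duplicated(uid)
  verts <- tri[first, , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  triangle_mesh(verts, faces, drop_degenerate = TRUE)
}

write_stl <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(f) == 0) stop("cannot write STL for a mesh with no faces")
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- c_ - a
  nrm <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  nrm <- nrm / pmax(sqrt(rowSums(nrm^2)), 1e-30)
  if (!binary) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid occlugen", con)
    for (i in seq_len(nrow(f))) {
      writeLines(c(
        sprintf("  facet normal %.9g %.9g %.9g", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
        "    outer loop",
        sprintf("      vertex %.9g %.9g %.9g", a[i, 1], a[i, 2], a[i, 3]),
        sprintf("      vertex %.9g %.9g %.9g", b[i, 1], b[i, 2], b[i, 3]),
        sprintf("      vertex %.9g %.9g %.9g", c_[i, 1], c_[i, 2], c_[i, 3]),
        "    endloop",
        "  endfacet"
      ), con)
    }
    writeLines("endsolid occlugen", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(c(nrm[i, ], a[i, ], b[i, ], c_[i, ]), con, size = 4,
               endian = "little")
      writeBin(raw(2), con)
    }
  }
}
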