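#' Load a triangle mesh from file
#'
#' Supported dialects: Wavefront OBJ (`v`/`f` records), PLY (ascii and
#' binary little-endian, with optional per-vertex scalar properties and
#' uchar red/green/blue colors, both recovered as attribute fields),
#' binary STL, and OFF. Format is inferred from the file extension when
#' `format = "auto"`.
#'
#' Non-triangular faces are rejected unless `triangulate = TRUE`, in which
#' case polygons are fan-triangulated with a message. STL carries no
#' connectivity, so exactly coincident corner coordinates are merged on
#' read. The loaded mesh is validated; structural defects produce a warning
#' carrying the [validate_mesh()] report (attached as attribute
#' `"validation"`), never a silent repair.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"obj"`, `"ply"`, `"stl"`, `"off"`.
#' @param triangulate fan-triangulate polygonal faces instead of erroring.
#' @return a [triangle_mesh()]
#' @export
load_mesh <- function(path, format = c("auto", "obj", "ply", "stl", "off"),
                      triangulate = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- tolower(sub(".*\\.", "", basename(path)))
    if (!format %in% c("obj", "ply", "stl", "off"))
      stop("cannot infer mesh format from extension of ", basename(path))
  }
  mesh <- switch(format,
    obj = read_obj(path, triangulate),
    ply = read_ply(path, triangulate),
    stl = read_stl(path),
    off = read_off(path, triangulate)
  )
  rep <- validate_mesh(mesh)
  if (!rep$manifold || !rep$oriented) {
    warning("loaded mesh fails validation (manifold=", rep$manifold,
            ", oriented=", rep$oriented, "); see attr(mesh, 'validation')")
    attr(mesh, "validation") <- rep
  }
  mesh
}

#' Save a triangle mesh to file
#'
#' PLY can embed per-vertex attribute fields as float vertex properties;
#' when a field named `furrow_class` is present (coded valley = -1,
#' neutral = 0, ridge = +1, see [furrow_field()]) it is additionally
#' written as uchar RGB vertex colors: ridge = red, valley = blue,
#' neutral = gray. STL and OFF cannot carry vertex fields: requested
#' fields are dropped with a warning.
#'
#' @param mesh a [triangle_mesh()]
#' @param path output file path.
#' @param format one of `"auto"` (from extension), `"obj"`, `"ply"`,
#'   `"stl"`, `"off"`.
#' @param fields character vector of attribute-field names to embed
#'   (PLY only); `NULL` embeds nothing.
#' @param binary write binary PLY (little-endian) instead of ascii; STL is
#'   always binary.
#' @return the path, invisibly.
#' @export
save_mesh <- function(mesh, path, format = c("auto", "obj", "ply", "stl", "off"),
                      fields = NULL, binary = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(sub(".*\\.", "", basename(path)))
    if (!format %in% c("obj", "ply", "stl", "off"))
      stop("cannot infer mesh format from extension of ", basename(path))
  }
  if (!is.null(fields)) {
    missing_f <- setdiff(fields, names(mesh$attributes))
    if (length(missing_f))
      stop("mesh has no attribute field(s): ", paste(missing_f, collapse = ", "))
    if (format %in% c("stl", "off", "obj") && length(fields)) {
      warning(format, " cannot embed vertex fields; dropping ",
              paste(fields, collapse = ", "))
      fields <- NULL
    }
  }
  switch(format,
    obj = write_obj(mesh, path),
    ply = write_ply(mesh, path, fields = fields, binary = binary),
    stl = write_stl(mesh, path),
    off = write_off(mesh, path)
  )
  invisible(path)
}

fan_triangulate <- function(poly_list) {
  out <- lapply(poly_list, function(ix) {
    if (length(ix) == 3L) return(matrix(ix, 1L, 3L))
    cbind(ix[1], ix[2:(length(ix) - 1L)], ix[3:length(ix)])
  })
  do.call(rbind, out)
}

# ---- OBJ ----------------------------------------------------------------

read_obj <- function(path, triangulate = FALSE) {
  lines <- readLines(path, warn = FALSE)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (!length(vl)) stop("no vertex records in OBJ file ", path)
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(tok)
    as.numeric(tok[2:4])))
  polys <- lapply(strsplit(trimws(fl), "\\s+"), function(tok) {
    idx <- as.integer(sub("/.*$", "", tok[-1]))
    if (anyNA(idx)) stop("unparseable face record in OBJ file")
    if (any(idx < 0)) stop("relative (negative) OBJ indices are not supported")
    idx
  })
  sizes <- lengths(polys)
  if (any(sizes != 3L)) {
    if (!triangulate)
      stop(sum(sizes != 3L), " non-triangular faces in ", basename(path),
           "; pass triangulate = TRUE to fan-triangulate")
    message("fan-triangulating ", sum(sizes != 3L), " polygonal faces")
  }
  triangle_mesh(verts, fan_triangulate(polys),
                name = sub("\\.[^.]*$", "", basename(path)))
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# morphofold OBJ: %s", mesh$name), con)
  writeLines(sprintf("v %.9g %.9g %.9g",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  if (n_faces(mesh))
    writeLines(sprintf("f %d %d %d",
                       mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
}

# ---- OFF ----------------------------------------------------------------

read_off <- function(path, triangulate = FALSE) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (toupper(toks[1]) != "OFF") stop("missing OFF header in ", path)
  nv <- as.integer(toks[2]); nf <- as.integer(toks[3])
  pos <- 5L
  verts <- matrix(as.numeric(toks[pos:(pos + 3L * nv - 1L)]), nv, 3L, byrow = TRUE)
  pos <- pos + 3L * nv
  polys <- vector("list", nf)
  for (i in seq_len(nf)) {
    k <- as.integer(toks[pos])
    polys[[i]] <- as.integer(toks[(pos + 1L):(pos + k)]) + 1L
    pos <- pos + k + 1L
  }
  sizes <- lengths(polys)
  if (any(sizes != 3L) && !triangulate)
    stop("non-triangular faces in OFF file; pass triangulate = TRUE")
  triangle_mesh(verts, fan_triangulate(polys),
                name = sub("\\.[^.]*$", "", basename(path)))
}

write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", n_vertices(mesh), n_faces(mesh)), con)
  writeLines(sprintf("%.9g %.9g %.9g",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  if (n_faces(mesh))
    writeLines(sprintf("3 %d %d %d",
                       mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                       mesh$faces[, 3] - 1L), con)
}

# ---- STL (binary) -------------------------------------------------------

read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", n = 80L)
  if (rawToChar(header[1:5]) == "solid") {
    # could still be binary (some tools write 'solid' headers); check size
    nf_guess <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    expect <- 84 + 50 * nf_guess
    if (!is.na(nf_guess) && file.size(path) == expect) {
      nf <- nf_guess
    } else stop("ascii STL is not supported; write binary STL")
  } else {
    nf <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  }
  body <- readBin(con, "raw", n = 50L * nf)
  stride <- 50L
  tri <- matrix(0, nf, 9L)
  for (k in 1:9) {
    off <- 12L + (k - 1L) * 4L   # skip the 12-byte facet normal
    idx <- as.vector(outer(1:4 + off, (seq_len(nf) - 1L) * stride, "+"))
    tri[, k] <- readBin(body[idx], "numeric", n = nf, size = 4L, endian = "little")
  }
  corners <- rbind(tri[, 1:3, drop = FALSE], tri[, 4:6, drop = FALSE],
                   tri[, 7:9, drop = FALSE])
  key <- paste(corners[, 1], corners[, 2], corners[, 3], sep = "|")
  uk <- !duplicated(key)
  vid <- match(key, key[uk])
  verts <- corners[uk, , drop = FALSE]
  faces <- matrix(vid, nf, 3L)
  triangle_mesh(verts, faces, name = sub("\\.[^.]*$", "", basename(path)))
}

write_stl <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80L)), con)
  nf <- n_faces(mesh)
  writeBin(as.integer(nf), con, size = 4L, endian = "little")
  fn <- face_normals_raw(mesh)
  nn <- row_norms(fn)
  fn[nn > 0, ] <- fn[nn > 0, ] / nn[nn > 0]
  co <- face_corner_coords(mesh)
  block <- t(cbind(fn, co$a, co$b, co$c))   # 12 floats per face
  for (i in seq_len(nf)) {
    writeBin(as.numeric(block[, i]), con, size = 4L, endian = "little")
    writeBin(as.raw(c(0L, 0L)), con)
  }
}

# ---- PLY ----------------------------------------------------------------

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_vals <- function(raw, offsets, type, n) {
  size <- ply_type_size[[type]]
  idx <- as.vector(outer(1:size, offsets, "+"))
  what <- if (type %in% c("float", "float32", "double", "float64")) "numeric" else "integer"
  signed <- !(type %in% c("uchar", "uint8", "ushort", "uint16", "uint", "uint32"))
  vals <- readBin(raw[idx], what, n = n, size = size,
                  signed = if (size < 4L) signed else TRUE, endian = "little")
  as.numeric(vals)
}

read_ply <- function(path, triangulate = FALSE) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header (ascii lines terminated by \n)
  header <- character(0)
  repeat {
    ch <- character(0)
    repeat {
      b <- readBin(con, "raw", n = 1L)
      if (!length(b) || b == as.raw(10L)) break
      ch <- c(ch, rawToChar(b))
    }
    line <- trimws(paste(ch, collapse = ""))
    header <- c(header, line)
    if (line == "end_header") break
    if (length(header) > 1000L) stop("runaway PLY header in ", path)
  }
  if (header[1] != "ply") stop("not a PLY file: ", path)
  fmt_line <- header[startsWith(header, "format")]
  fmt <- strsplit(fmt_line, "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt)

  elements <- list()
  cur <- NULL
  for (line in header) {
    tok <- strsplit(line, "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props[[tok[5]]] <- list(list = TRUE, count_type = tok[3], type = tok[4])
      } else {
        cur$props[[tok[3]]] <- list(list = FALSE, type = tok[2])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur

  parse_ascii <- function() {
    toks <- scan(con, what = character(), quiet = TRUE)
    pos <- 1L
    out <- list()
    for (el in elements) {
      if (any(vapply(el$props, `[[`, logical(1), "list"))) {
        rows <- vector("list", el$count)
        for (i in seq_len(el$count)) {
          row <- list()
          for (pn in names(el$props)) {
            p <- el$props[[pn]]
            if (p$list) {
              k <- as.integer(toks[pos]); pos <- pos + 1L
              row[[pn]] <- as.numeric(toks[pos:(pos + k - 1L)]); pos <- pos + k
            } else {
              row[[pn]] <- as.numeric(toks[pos]); pos <- pos + 1L
            }
          }
          rows[[i]] <- row
        }
        out[[el$name]] <- rows
      } else {
        np <- length(el$props)
        block <- matrix(as.numeric(toks[pos:(pos + np * el$count - 1L)]),
                        el$count, np, byrow = TRUE)
        colnames(block) <- names(el$props)
        out[[el$name]] <- block
        pos <- pos + np * el$count
      }
    }
    out
  }

  parse_binary <- function() {
    out <- list()
    for (el in elements) {
      has_list <- any(vapply(el$props, `[[`, logical(1), "list"))
      if (!has_list) {
        sizes <- vapply(names(el$props), function(pn)
          ply_type_size[[el$props[[pn]]$type]], integer(1))
        stride <- sum(sizes)
        raw <- readBin(con, "raw", n = stride * el$count)
        block <- matrix(0, el$count, length(sizes))
        off <- 0L
        for (j in seq_along(sizes)) {
          offsets <- (seq_len(el$count) - 1L) * stride + off
          block[, j] <- ply_read_vals(raw, offsets, el$props[[j]]$type, el$count)
          off <- off + sizes[j]
        }
        colnames(block) <- names(el$props)
        out[[el$name]] <- block
      } else {
        # variable-length rows: read sequentially
        rows <- vector("list", el$count)
        for (i in seq_len(el$count)) {
          row <- list()
          for (pn in names(el$props)) {
            p <- el$props[[pn]]
            if (p$list) {
              cs <- ply_type_size[[p$count_type]]
              k <- readBin(con, "integer", n = 1L, size = cs,
                           signed = cs >= 4L, endian = "little")
              vs <- ply_type_size[[p$type]]
              what <- if (p$type %in% c("float", "float32", "double", "float64"))
                "numeric" else "integer"
              row[[pn]] <- as.numeric(readBin(con, what, n = k, size = vs,
                                              endian = "little"))
            } else {
              vs <- ply_type_size[[p$type]]
              what <- if (p$type %in% c("float", "float32", "double", "float64"))
                "numeric" else "integer"
              row[[pn]] <- as.numeric(readBin(con, what, n = 1L, size = vs,
                                              signed = vs >= 4L, endian = "little"))
            }
          }
          rows[[i]] <- row
        }
        out[[el$name]] <- rows
      }
    }
    out
  }

  data <- if (fmt == "ascii") parse_ascii() else parse_binary()
  vb <- data[["vertex"]]
  if (is.null(vb)) stop("PLY file has no vertex element")
  verts <- vb[, c("x", "y", "z"), drop = FALSE]
  extra <- setdiff(colnames(vb), c("x", "y", "z"))
  attrs <- list()
  for (pn in extra) attrs[[pn]] <- as.numeric(vb[, pn])

  fb <- data[["face"]]
  polys <- if (is.null(fb)) list() else
    lapply(fb, function(row) as.integer(row[[1]]) + 1L)
  sizes <- lengths(polys)
  if (length(sizes) && any(sizes != 3L) && !triangulate)
    stop("non-triangular faces in PLY file; pass triangulate = TRUE")
  faces <- if (length(polys)) fan_triangulate(polys) else matrix(integer(0), 0, 3)
  triangle_mesh(verts, faces, name = sub("\\.[^.]*$", "", basename(path)),
                attributes = attrs)
}

furrow_class_colors <- function(cls) {
  # valley = -1 -> blue, neutral = 0 -> gray, ridge = +1 -> red
  r <- ifelse(cls > 0.5, 220L, ifelse(cls < -0.5, 40L, 150L))
  g <- ifelse(abs(cls) <= 0.5, 150L, 40L)
  b <- ifelse(cls < -0.5, 220L, ifelse(cls > 0.5, 40L, 150L))
  cbind(r, g, b)
}

write_ply <- function(mesh, path, fields = NULL, binary = FALSE) {
  v <- n_vertices(mesh)
  scalar_fields <- fields
  with_color <- !is.null(fields) && "furrow_class" %in% fields
  header <- c(
    "ply",
    sprintf("format %s 1.0", if (binary) "binary_little_endian" else "ascii"),
    sprintf("comment morphofold: %s", mesh$name),
    sprintf("element vertex %d", v),
    "property float x", "property float y", "property float z",
    if (length(scalar_fields)) sprintf("property float %s", scalar_fields),
    if (with_color) c("property uchar red", "property uchar green",
                      "property uchar blue"),
    sprintf("element face %d", n_faces(mesh)),
    "property list uchar int vertex_indices",
    "end_header"
  )
  block <- mesh$vertices
  for (fn in scalar_fields) block <- cbind(block, mesh$attributes[[fn]])
  cols <- if (with_color) furrow_class_colors(mesh$attributes[["furrow_class"]])
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(paste(c(header, ""), collapse = "\n")), con)
    for (i in seq_len(v)) {
      writeBin(as.numeric(block[i, ]), con, size = 4L, endian = "little")
      if (with_color) writeBin(as.raw(cols[i, ]), con)
    }
    for (i in seq_len(n_faces(mesh))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(mesh$faces[i, ] - 1L), con, size = 4L, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    vlines <- apply(block, 1L, function(r) paste(sprintf("%.9g", r), collapse = " "))
    if (with_color)
      vlines <- paste(vlines, cols[, 1], cols[, 2], cols[, 3])
    writeLines(vlines, con)
    if (n_faces(mesh))
      writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                         mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  }
  invisible(path)
}
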