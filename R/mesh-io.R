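# Mesh file I/O -----------------------------------------------------------
#
# Supported interchange formats, all line-oriented ASCII:
#   vtk : legacy VTK — DATASET POLYDATA (triangles) or UNSTRUCTURED_GRID with
#         cell type 10 (tetrahedra); named POINT_DATA / CELL_DATA SCALARS
#         arrays and POINT_DATA NORMALS.
#   ply : ascii 1.0 — extra per-vertex/per-face scalar properties carry
#         fields; nx/ny/nz carry vertex normals; 4-index faces carry tets.
#   off : geometry only; fields travel in sidecar CSV (element_id,value).
# Coordinates and field values are written with "%.17g" so a write -> read ->
# write cycle is byte-identical (doubles round-trip exactly at 17 digits).
# All on-disk indices are 0-based; in-memory indices are 1-based.

fmt_num <- function(x) sprintf("%.17g", x)

guess_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("vtk", "ply", "off")) ext
  else stop("cannot guess mesh format from extension: ", path)
}

#' Read a surface or volume mesh
#'
#' The cell type found in the file selects the returned class: triangles give
#' a [surface_mesh()], tetrahedra a [volume_mesh()].  Mixed-cell files are
#' rejected — the surface and volumetric dot-mapping pipelines are distinct.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"vtk"`, `"ply"` or `"off"`.
#' @return a `surface_mesh` or `volume_mesh` with all named data arrays
#'   attached as fields.
#' @export
read_mesh <- function(path, format = c("auto", "vtk", "ply", "off")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         vtk = read_vtk(path),
         ply = read_ply(path),
         off = read_off(path))
}

#' Write a mesh to a standard format
#'
#' @param mesh a `surface_mesh` or `volume_mesh`.
#' @param path output file path.
#' @param format `"auto"` (by extension), `"vtk"`, `"ply"` or `"off"`.
#'   OFF carries no fields; write them with [write_field_csv()].
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "vtk", "ply", "off")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  validate_mesh(mesh)
  lines <- switch(format,
                  vtk = format_vtk(mesh),
                  ply = format_ply(mesh),
                  off = format_off(mesh))
  con <- file(path, open = "wb")  # binary connection: LF endings everywhere
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

split_fields <- function(mesh) {
  nv <- nrow(mesh$vertices); ne <- n_elements(mesh)
  pt <- Filter(function(f) length(f) == nv, mesh$fields)
  cl <- Filter(function(f) length(f) == ne && ne != nv, mesh$fields)
  if (nv == ne && length(mesh$fields))
    stop("ambiguous field lengths (vertex count equals element count); ",
         "attach fields explicitly after reading")
  list(point = pt, cell = cl)
}

# --- VTK legacy ASCII ----------------------------------------------------

format_vtk <- function(mesh) {
  surf <- inherits(mesh, "surface_mesh")
  v <- mesh$vertices; cells <- mesh$cells
  k <- ncol(cells)
  out <- c("# vtk DataFile Version 3.0", "dotmapr mesh", "ASCII",
           if (surf) "DATASET POLYDATA" else "DATASET UNSTRUCTURED_GRID",
           sprintf("POINTS %d double", nrow(v)),
           apply(v, 1, function(p) paste(fmt_num(p), collapse = " ")))
  cell_rows <- apply(cells - 1L, 1, function(i)
    paste(c(k, i), collapse = " "))
  if (surf) {
    out <- c(out, sprintf("POLYGONS %d %d", nrow(cells), nrow(cells) * (k + 1)),
             cell_rows)
  } else {
    out <- c(out, sprintf("CELLS %d %d", nrow(cells), nrow(cells) * (k + 1)),
             cell_rows, sprintf("CELL_TYPES %d", nrow(cells)),
             rep("10", nrow(cells)))
  }
  fl <- split_fields(mesh)
  if (length(fl$point) || !is.null(mesh$vertex_normals)) {
    out <- c(out, sprintf("POINT_DATA %d", nrow(v)))
    if (!is.null(mesh$vertex_normals))
      out <- c(out, "NORMALS normals double",
               apply(mesh$vertex_normals, 1,
                     function(p) paste(fmt_num(p), collapse = " ")))
    for (nm in names(fl$point))
      out <- c(out, sprintf("SCALARS %s double 1", nm),
               "LOOKUP_TABLE default", fmt_num(fl$point[[nm]]))
  }
  if (length(fl$cell)) {
    out <- c(out, sprintf("CELL_DATA %d", nrow(cells)))
    for (nm in names(fl$cell))
      out <- c(out, sprintf("SCALARS %s double 1", nm),
               "LOOKUP_TABLE default", fmt_num(fl$cell[[nm]]))
  }
  out
}

read_vtk <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 5 || !grepl("^# vtk DataFile", lines[1]))
    stop("not a legacy VTK file: ", path)
  if (toupper(trimws(lines[3])) != "ASCII")
    stop("only ASCII VTK supported: ", path)
  dataset <- toupper(sub("^DATASET\\s+", "", trimws(lines[4])))
  toks <- scan(text = paste(lines[-(1:4)], collapse = "\n"), what = "",
               quiet = TRUE)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function(n, what = "token") {
    if (n == 0) return(character(0))
    if (pos + n - 1L > length(toks))
      stop("VTK file truncated while reading ", what)
    r <- toks[pos:(pos + n - 1L)]; pos <<- pos + n; r
  }
  take_num <- function(n, what) {
    r <- suppressWarnings(as.numeric(take(n, what)))
    if (anyNA(r)) stop("non-numeric data while reading ", what)
    r
  }
  verts <- NULL; cells <- NULL; types <- NULL
  pt_fields <- list(); cl_fields <- list(); normals <- NULL
  n_pts <- NA_integer_; n_cells <- NA_integer_
  mode <- ""
  while (!is.na(peek())) {
    key <- toupper(peek())
    if (key == "POINTS") {
      take(1); n_pts <- as.integer(take(1)); take(1)  # type
      verts <- matrix(take_num(3 * n_pts, "POINTS"), ncol = 3, byrow = TRUE)
    } else if (key %in% c("POLYGONS", "CELLS")) {
      take(1); nc <- as.integer(take(1)); sz <- as.integer(take(1))
      raw <- as.integer(take_num(sz, key))
      rows <- vector("list", nc); i <- 1L
      for (ci in seq_len(nc)) {
        k <- raw[i]
        rows[[ci]] <- raw[(i + 1L):(i + k)]; i <- i + k + 1L
      }
      ks <- lengths(rows)
      if (length(unique(ks)) > 1)
        stop("mixed cell sizes are not supported")
      k0 <- if (nc > 0) ks[1] else if (key == "POLYGONS") 3L else 4L
      cells <- matrix(as.integer(unlist(rows)), ncol = k0, byrow = TRUE) + 1L
      n_cells <- nc
      if (key == "POLYGONS" && nc > 0 && ks[1] != 3)
        stop("unsupported cell type: ", ks[1], "-gon in POLYDATA")
    } else if (key == "CELL_TYPES") {
      take(1); nct <- as.integer(take(1))
      types <- as.integer(take_num(nct, "CELL_TYPES"))
    } else if (key == "POINT_DATA") {
      take(1); nd <- as.integer(take(1))
      if (!is.na(n_pts) && nd != n_pts)
        stop("POINT_DATA count ", nd, " does not match POINTS count ", n_pts)
      mode <- "point"
    } else if (key == "CELL_DATA") {
      take(1); nd <- as.integer(take(1))
      if (!is.na(n_cells) && nd != n_cells)
        stop("CELL_DATA count ", nd, " does not match cell count ", n_cells)
      mode <- "cell"
    } else if (key == "SCALARS") {
      take(1); nm <- take(1); take(1)  # type
      ncomp <- 1L
      if (!is.na(peek()) && !is.na(suppressWarnings(as.integer(peek()))) &&
          toupper(peek()) != "LOOKUP_TABLE")
        ncomp <- as.integer(take(1))
      if (!is.na(peek()) && toupper(peek()) == "LOOKUP_TABLE") take(2)
      n <- if (mode == "point") n_pts else n_cells
      vals <- take_num(n * ncomp, paste0("SCALARS array '", nm, "'"))
      if (ncomp != 1L) stop("multi-component scalars not supported: ", nm)
      if (mode == "point") pt_fields[[nm]] <- vals else cl_fields[[nm]] <- vals
    } else if (key == "NORMALS") {
      take(1); take(1); take(1)  # name, type
      n <- if (mode == "point") n_pts else n_cells
      vals <- matrix(take_num(3 * n, "NORMALS"), ncol = 3, byrow = TRUE)
      if (mode == "point") normals <- vals
    } else {
      stop("unsupported VTK section: ", peek())
    }
  }
  if (is.null(verts) || is.null(cells)) stop("VTK file has no geometry")
  if (dataset == "UNSTRUCTURED_GRID") {
    if (is.null(types)) stop("UNSTRUCTURED_GRID without CELL_TYPES")
    ut <- unique(types)
    if (length(ut) != 1) stop("mixed cell types are not supported")
    if (ut == 10L) {
      if (ncol(cells) != 4) stop("cell type 10 requires 4 indices per cell")
      return(volume_mesh(verts, cells, fields = c(pt_fields, cl_fields)))
    } else if (ut == 5L) {
      if (ncol(cells) != 3) stop("cell type 5 requires 3 indices per cell")
    } else stop("unsupported cell type: ", ut)
  }
  if (ncol(cells) != 3) stop("unsupported cell type in POLYDATA")
  surface_mesh(verts, cells, vertex_normals = normals,
               fields = c(pt_fields, cl_fields))
}

# --- PLY ascii 1.0 -------------------------------------------------------

format_ply <- function(mesh) {
  v <- mesh$vertices; cells <- mesh$cells; k <- ncol(cells)
  fl <- split_fields(mesh)
  has_n <- !is.null(mesh$vertex_normals)
  header <- c("ply", "format ascii 1.0", "comment dotmapr mesh",
              sprintf("element vertex %d", nrow(v)),
              "property double x", "property double y", "property double z",
              if (has_n) c("property double nx", "property double ny",
                           "property double nz"),
              sprintf("property double %s", names(fl$point)),
              sprintf("element face %d", nrow(cells)),
              "property list uchar int vertex_indices",
              sprintf("property double %s", names(fl$cell)),
              "end_header")
  vmat <- v
  if (has_n) vmat <- cbind(vmat, mesh$vertex_normals)
  for (nm in names(fl$point)) vmat <- cbind(vmat, fl$point[[nm]])
  vrows <- apply(vmat, 1, function(p) paste(fmt_num(p), collapse = " "))
  frows <- vapply(seq_len(nrow(cells)), function(i) {
    extra <- vapply(fl$cell, function(f) fmt_num(f[i]), "")
    paste(c(k, cells[i, ] - 1L, extra), collapse = " ")
  }, "")
  c(header, vrows, frows)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || trimws(lines[1]) != "ply")
    stop("not a PLY file: ", path)
  if (!grepl("^format\\s+ascii", trimws(lines[2])))
    stop("only ascii PLY supported: ", path)
  hend <- which(trimws(lines) == "end_header")[1]
  if (is.na(hend)) stop("PLY header not terminated")
  header <- trimws(lines[3:(hend - 1)])
  elems <- list(); cur <- NULL
  for (ln in header) {
    w <- strsplit(ln, "\\s+")[[1]]
    if (w[1] == "comment") next
    if (w[1] == "element") {
      cur <- w[2]
      elems[[cur]] <- list(n = as.integer(w[3]), props = character(),
                           list_prop = NA_character_)
    } else if (w[1] == "property" && !is.null(cur)) {
      if (w[2] == "list") {
        elems[[cur]]$list_prop <- w[5]
      } else {
        elems[[cur]]$props <- c(elems[[cur]]$props, w[3])
      }
    }
  }
  if (is.null(elems$vertex) || is.null(elems$face))
    stop("PLY file must contain vertex and face elements")
  body <- lines[(hend + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  nv <- elems$vertex$n; nf <- elems$face$n
  if (length(body) < nv + nf) stop("PLY file truncated")
  vprops <- elems$vertex$props
  vdat <- matrix(scan(text = paste(body[seq_len(nv)], collapse = "\n"),
                      quiet = TRUE), nrow = nv, byrow = TRUE)
  if (ncol(vdat) != length(vprops))
    stop("vertex row width does not match declared properties")
  colnames(vdat) <- vprops
  verts <- vdat[, c("x", "y", "z"), drop = FALSE]
  normals <- if (all(c("nx", "ny", "nz") %in% vprops))
    vdat[, c("nx", "ny", "nz"), drop = FALSE]
  pt_fields <- list()
  for (nm in setdiff(vprops, c("x", "y", "z", "nx", "ny", "nz")))
    pt_fields[[nm]] <- unname(vdat[, nm])
  fprops <- elems$face$props
  frows <- lapply(body[nv + seq_len(nf)], function(ln)
    scan(text = ln, quiet = TRUE))
  ks <- vapply(frows, function(r) as.integer(r[1]), 0L)
  if (length(unique(ks)) > 1) stop("mixed cell sizes are not supported")
  k <- ks[1]
  if (!(k %in% c(3L, 4L))) stop("unsupported cell type: ", k, " vertices")
  if (any(lengths(frows) != 1 + k + length(fprops)))
    stop("face row width does not match declared properties")
  fm <- matrix(unlist(frows), ncol = 1 + k + length(fprops), byrow = TRUE)
  cells <- fm[, 2:(k + 1), drop = FALSE] + 1L
  cl_fields <- list()
  for (j in seq_along(fprops)) cl_fields[[fprops[j]]] <- fm[, 1 + k + j]
  if (k == 3L)
    surface_mesh(verts, cells, vertex_normals = normals,
                 fields = c(pt_fields, cl_fields))
  else
    volume_mesh(verts, cells, fields = c(pt_fields, cl_fields))
}

# --- OFF -----------------------------------------------------------------

format_off <- function(mesh) {
  v <- mesh$vertices; cells <- mesh$cells; k <- ncol(cells)
  c("OFF", sprintf("%d %d 0", nrow(v), nrow(cells)),
    apply(v, 1, function(p) paste(fmt_num(p), collapse = " ")),
    apply(cells - 1L, 1, function(i) paste(c(k, i), collapse = " ")))
}

read_off <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", trimws(lines))]
  if (toupper(trimws(lines[1])) != "OFF") stop("not an OFF file: ", path)
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- as.integer(counts[1]); nf <- as.integer(counts[2])
  if (length(lines) < 2 + nv + nf) stop("OFF file truncated")
  verts <- matrix(scan(text = paste(lines[2 + seq_len(nv)], collapse = "\n"),
                       quiet = TRUE), nrow = nv, byrow = TRUE)[, 1:3, drop = FALSE]
  frows <- lapply(lines[2 + nv + seq_len(nf)], function(ln)
    scan(text = ln, quiet = TRUE))
  ks <- vapply(frows, function(r) as.integer(r[1]), 0L)
  if (length(unique(ks)) > 1) stop("mixed cell sizes are not supported")
  k <- ks[1]
  if (!(k %in% c(3L, 4L))) stop("unsupported cell type: ", k, " vertices")
  cells <- matrix(unlist(lapply(frows, function(r) r[2:(k + 1)])),
                  ncol = k, byrow = TRUE) + 1L
  if (k == 3L) surface_mesh(verts, cells) else volume_mesh(verts, cells)
}

# --- Sidecar CSV fields --------------------------------------------------

#' Read an element field from sidecar CSV
#'
#' Expects the header `element_id,value` with 0-based contiguous element ids.
#'
#' @param path CSV file path.
#' @param mesh optional mesh used to check the field length.
#' @param window,name passed to [element_field()].
#' @export
read_field_csv <- function(path, mesh = NULL, window = NULL, name = NULL) {
  d <- read.csv(path)
  if (!all(c("element_id", "value") %in% names(d)))
    stop("sidecar CSV must have header 'element_id,value'")
  d <- d[order(d$element_id), ]
  if (!identical(as.integer(d$element_id), seq_len(nrow(d)) - 1L))
    stop("element_id must be 0-based and contiguous")
  if (!is.null(mesh) && nrow(d) != n_elements(mesh))
    stop("field length ", nrow(d), " does not match element count ",
         n_elements(mesh))
  element_field(d$value, window %||% default_window(d$value),
                name %||% sub("\\.csv$", "", basename(path)))
}

#' Write an element field as sidecar CSV (`element_id,value`, 0-based ids)
#' @param field an [element_field()] or numeric vector.
#' @param path output CSV path.
#' @export
write_field_csv <- function(field, path) {
  v <- if (inherits(field, "element_field")) field$values else as.numeric(field)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("element_id,value",
               sprintf("%d,%s", seq_along(v) - 1L, fmt_num(v))), con, sep = "\n")
  invisible(path)
}
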