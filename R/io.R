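# Scenario CSV reader/writer and legacy ASCII VTK export.
#
# Scenario dialect: CSV with header `id,x,y[,z],type[,info]`; `info` is a
# free-form `key=value;key=value` field. Coordinates round-trip at 17
# significant digits.

.TYPE_CODES <- c(lmn = 0L, lec = 1L, mec = 2L, media = 3L)

#' Read a scenario table
#'
#' @param path CSV file with header `id,x,y[,z],type[,info]`.
#' @return list with `agents` (data.frame `id,type,x,y,z,info`) and
#'   `dimension` (2 or 3, inferred from the presence of `z`).
#' @export
read_scenario <- function(path) {
  raw <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
             check.names = FALSE),
    error = function(e) .vc_stop("vcellsim_parse_error",
                                 "cannot read scenario: %s", conditionMessage(e)))
  has_z <- "z" %in% names(raw)
  need <- c("id", "x", "y", if (has_z) "z", "type")
  if (!all(need %in% names(raw)))
    .vc_stop("vcellsim_parse_error", "scenario header must contain %s",
             paste(need, collapse = ","))
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !(raw[[col]] %in% c("", "NA")))
    if (length(bad))
      .vc_stop("vcellsim_parse_error", "row %d: non-numeric %s value '%s'",
               bad[1L], col, raw[[col]][bad[1L]])
    v
  }
  id <- suppressWarnings(as.integer(raw$id))
  if (anyNA(id))
    .vc_stop("vcellsim_parse_error", "row %d: non-integer id '%s'",
             which(is.na(id))[1L], raw$id[which(is.na(id))[1L]])
  if (anyDuplicated(id))
    .vc_stop("vcellsim_parse_error", "row %d: duplicate id %d",
             which(duplicated(id))[1L], id[which(duplicated(id))[1L]])
  x <- num("x"); y <- num("y")
  if (anyNA(x) || anyNA(y))
    .vc_stop("vcellsim_parse_error", "row %d: missing coordinate",
             which(is.na(x) | is.na(y))[1L])
  z <- if (has_z) num("z") else rep(NA_real_, length(id))
  if (has_z && anyNA(z))
    .vc_stop("vcellsim_parse_error",
             "row %d: mixed dimensionality (missing z)", which(is.na(z))[1L])
  bad_type <- which(!(raw$type %in% .CELL_TYPES))
  if (length(bad_type))
    .vc_stop("vcellsim_parse_error", "row %d: unknown type token '%s'",
             bad_type[1L], raw$type[bad_type[1L]])
  info <- if ("info" %in% names(raw)) raw$info else rep(NA_character_, length(id))
  info[info == ""] <- NA_character_
  agents <- data.frame(id = id, type = raw$type, x = x, y = y, z = z,
                       info = info, stringsAsFactors = FALSE)
  list(agents = agents, dimension = if (has_z) 3L else 2L)
}

#' @rdname read_scenario
#' @param agents a scenario data.frame (or a `"dv_state"`, in which case the
#'   alive agents are written).
#' @export
write_scenario <- function(agents, path) {
  if (inherits(agents, "dv_state")) agents <- .alive_agents(agents)
  d <- if (!all(is.na(agents$z %||% NA))) 3L else 2L
  fmt <- function(v) sprintf("%.17g", v)
  info <- agents$info %||% rep(NA_character_, nrow(agents))
  fields <- list(agents$id, fmt(agents$x), fmt(agents$y))
  if (d == 3L) fields <- c(fields, list(fmt(agents$z)))
  fields <- c(fields, list(agents$type, ifelse(is.na(info), "", info)))
  lines <- do.call(paste, c(fields, sep = ","))
  header <- if (d == 3L) "id,x,y,z,type,info" else "id,x,y,type,info"
  writeLines(c(header, lines), path)
  invisible(path)
}

.vtk_points <- function(coords) {
  if (ncol(coords) == 2L) coords <- cbind(coords, 0)
  c(sprintf("POINTS %d double", nrow(coords)),
    apply(coords, 1L, function(p) paste(sprintf("%.17g", p), collapse = " ")))
}

#' Export a mesh or the V-cells to a legacy ASCII VTK file
#'
#' `what = "mesh"` writes the Delaunay simplices as an unstructured grid
#' (VTK cell type 5 = triangle, 10 = tetrahedron) with a `cell_type` point
#' data array (lmn=0, lec=1, mec=2, media=3; -1 when no typing is known).
#' `what = "vcells"` writes the V-cell polygons (2D) or faces (3D) as
#' polydata with `generator_id` and `cell_type` cell data arrays; media and
#' hull generators are skipped (with a warning for requested-but-unbounded
#' cells).
#'
#' @param x a `"dv_mesh"` or `"dv_state"`.
#' @param path output file.
#' @param what `"mesh"` or `"vcells"`.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(x, path, what = c("mesh", "vcells")) {
  what <- match.arg(what)
  if (inherits(x, "dv_state")) {
    mesh <- x$mesh
    a <- .alive_agents(x)
    type_of <- setNames(a$type, as.character(a$id))
  } else if (inherits(x, "dv_mesh")) {
    mesh <- x
    type_of <- NULL
  } else .vc_stop("vcellsim_invalid_input", "x must be a dv_mesh or dv_state")
  header <- c("# vtk DataFile Version 3.0",
              sprintf("vcellsim %s export", what), "ASCII")
  code <- function(ids) {
    if (is.null(type_of)) rep(-1L, length(ids))
    else unname(.TYPE_CODES[type_of[as.character(ids)]])
  }
  if (what == "mesh") {
    n <- length(mesh$ids)
    idx <- setNames(seq_len(n) - 1L, as.character(mesh$ids))
    m <- nrow(mesh$simplices)
    k <- mesh$dim + 1L
    cells <- apply(mesh$simplices, 1L, function(s)
      paste(c(k, idx[as.character(s)]), collapse = " "))
    out <- c(header, "DATASET UNSTRUCTURED_GRID",
             .vtk_points(mesh$coords),
             sprintf("CELLS %d %d", m, m * (k + 1L)), cells,
             sprintf("CELL_TYPES %d", m),
             rep(if (mesh$dim == 2L) "5" else "10", m),
             sprintf("POINT_DATA %d", n),
             "SCALARS cell_type int 1", "LOOKUP_TABLE default",
             as.character(code(mesh$ids)))
  } else {
    ids <- mesh$ids
    if (!is.null(type_of)) ids <- ids[type_of[as.character(ids)] != "media"]
    polys <- list(); pids <- integer(); pcodes <- integer()
    pts <- NULL
    for (id in ids) {
      if (id %in% mesh$hull_ids) {
        warning(sprintf("skipping unbounded V-cell of generator %d", id))
        next
      }
      vc <- vcell(mesh, id)
      rings <- if (mesh$dim == 2L) list(vc$boundary) else vc$boundary
      for (ring in rings) {
        start <- if (is.null(pts)) 0L else nrow(pts)
        pts <- rbind(pts, if (mesh$dim == 2L) cbind(ring, 0) else ring)
        polys[[length(polys) + 1L]] <- c(nrow(ring), start + seq_len(nrow(ring)) - 1L)
        pids <- c(pids, id)
        pcodes <- c(pcodes, code(id))
      }
    }
    np <- length(polys)
    out <- c(header, "DATASET POLYDATA",
             .vtk_points(pts),
             sprintf("POLYGONS %d %d", np, sum(lengths(polys))),
             vapply(polys, paste, "", collapse = " "),
             sprintf("CELL_DATA %d", np),
             "SCALARS generator_id int 1", "LOOKUP_TABLE default",
             as.character(pids),
             "SCALARS cell_type int 1", "LOOKUP_TABLE default",
             as.character(pcodes))
  }
  writeLines(out, path)
  invisible(path)
}
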