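# Plain-text interchange: ASCII PLY meshes with a JSON region sidecar,
# spine-record CSV tables and vesicle-center CSV files.

#' Write a tagged mesh as ASCII PLY plus a JSON region sidecar
#'
#' The geometry goes into a standard ASCII PLY file; the region tags go into
#' `<path>.regions.json`, a JSON object mapping region names to 1-based
#' triangle-index arrays.
#'
#' @param mesh A `"tagged_mesh"`.
#' @param path Output path for the `.ply` file.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$triangles)
  header <- c("ply", "format ascii 1.0",
              "comment tagged spine mesh (um)",
              sprintf("element vertex %d", nv),
              "property float x", "property float y", "property float z",
              sprintf("element face %d", nf),
              "property list uchar int vertex_indices",
              "end_header")
  vlines <- apply(mesh$vertices, 1, function(r) {
    paste(format(r, digits = 17, scientific = FALSE, trim = TRUE),
          collapse = " ")
  })
  flines <- apply(mesh$triangles - 1L, 1, function(r) {
    paste(c(3L, r), collapse = " ")
  })
  writeLines(c(header, vlines, flines), path)
  jsonlite::write_json(mesh$regions, paste0(path, ".regions.json"))
  invisible(path)
}

#' Read a tagged mesh from ASCII PLY (+ optional region sidecar)
#'
#' Supports the ASCII PLY subset written by [write_mesh()] (float vertex
#' x/y/z properties, triangular faces). If `<path>.regions.json` exists its
#' region tags are attached.
#'
#' @param path Path to a `.ply` file.
#' @return A `"tagged_mesh"`.
#' @export
read_mesh <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || trimws(lines[1]) != "ply") {
    stop("not a PLY file: ", path, call. = FALSE)
  }
  if (!any(grepl("^format\\s+ascii", lines))) {
    stop("only ASCII PLY is supported", call. = FALSE)
  }
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) stop("malformed PLY: no end_header", call. = FALSE)
  header <- lines[seq_len(endh)]
  nv <- as.integer(sub("^element vertex\\s+", "",
                       grep("^element vertex", header, value = TRUE)[1]))
  nf <- as.integer(sub("^element face\\s+", "",
                       grep("^element face", header, value = TRUE)[1]))
  body <- lines[(endh + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  vl <- body[seq_len(nv)]
  fl <- body[nv + seq_len(nf)]
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x) {
    as.numeric(x[1:3])
  }))
  tris <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(x) {
    n <- as.integer(x[1])
    if (n != 3) stop("only triangular faces are supported", call. = FALSE)
    as.integer(x[2:4]) + 1L
  }))
  regions <- list()
  sidecar <- paste0(path, ".regions.json")
  if (file.exists(sidecar)) {
    regions <- lapply(jsonlite::read_json(sidecar, simplifyVector = TRUE),
                      as.integer)
  }
  tagged_mesh(verts, tris, regions)
}

#' Write / read a spine-record table as CSV
#'
#' Fixed, documented header: `spine_id, dendrite_id, axon_id, head_volume,
#' head_area, psd_area, neck_length, neck_diameter, neck_volume,
#' docked_vesicles, whole_spine_volume` (volumes um^3, areas um^2, lengths
#' um).
#'
#' @param records Spine-record data frame.
#' @param path CSV path.
#' @return `path` (write) or the data frame (read).
#' @export
write_spine_table <- function(records, path) {
  cols <- c("spine_id", "dendrite_id", "axon_id", "head_volume",
            "head_area", "psd_area", "neck_length", "neck_diameter",
            "neck_volume", "docked_vesicles", "whole_spine_volume")
  missing <- setdiff(cols, names(records))
  if (length(missing)) {
    stop("records lack columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(records[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spine_table
#' @export
read_spine_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read vesicle centers as CSV
#'
#' Columns `x_nm, y_nm, z_nm, terminal_id` (and `docked` ground truth when
#' present).
#'
#' @param cloud A vesicle-cloud data frame.
#' @param path CSV path.
#' @return `path` (write) or a `"vesicle_cloud"` data frame (read).
#' @export
write_vesicles <- function(cloud, path) {
  utils::write.csv(as.data.frame(cloud), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_vesicles
#' @export
read_vesicles <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(out, class = c("vesicle_cloud", "data.frame"))
}
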