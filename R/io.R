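#' Write a surface mesh as OBJ plus a JSON sidecar
#'
#' The OBJ carries vertices and faces; the sidecar (same path with
#' `.json` appended) records the spherical registration coordinates, the
#' medial-wall mask and the hemisphere labels, which OBJ cannot express.
#'
#' @param mesh a [surface_mesh].
#' @param path output OBJ path.
#' @return `path`, invisibly.
#' @export
write_mesh_obj <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  jsonlite::write_json(
    list(sphere = mesh$sphere, medial_wall = mesh$medial_wall,
         hemisphere = mesh$hemisphere),
    paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a surface mesh written by [write_mesh_obj()]
#' @param path OBJ path (sidecar expected at `path.json` if present).
#' @return A [surface_mesh].
#' @export
read_mesh_obj <- function(path) {
  lines <- readLines(path)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  verts <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(p)
    as.numeric(p[2:4])))
  faces <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(p)
    as.integer(sub("/.*", "", p[2:4]))))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    sc <- jsonlite::read_json(side, simplifyVector = TRUE)
    surface_mesh(verts, faces, sphere = matrix(unlist(sc$sphere), ncol = 3),
                 medial_wall = sc$medial_wall, hemisphere = sc$hemisphere)
  } else {
    surface_mesh(verts, faces)
  }
}

#' Write/read a subject table as TSV
#' @param subjects subject data.frame.
#' @param path file path.
#' @return `path` / the table.
#' @export
write_subjects_tsv <- function(subjects, path) {
  utils::write.table(subjects, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_subjects_tsv
#' @export
read_subjects_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$sex <- factor(tab$sex)
  tab$scanner <- factor(tab$scanner)
  tab
}

#' Write/read a vertex-map stack as CSV (one column per subject)
#' @param maps V x n matrix.
#' @param path file path.
#' @return `path` / the matrix.
#' @export
write_maps_csv <- function(maps, path) {
  utils::write.csv(as.data.frame(maps), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_maps_csv
#' @export
read_maps_csv <- function(path) {
  as.matrix(utils::read.csv(path, check.names = FALSE))
}

#' Write/read per-vertex integer labels (one label per line) with a TSV
#' label dictionary alongside.
#' @param labels integer per-vertex labels.
#' @param path label file path.
#' @param dictionary optional character vector of label names.
#' @return `path` / integer vector (dictionary in attribute
#'   `"dictionary"`).
#' @export
write_labels <- function(labels, path, dictionary = NULL) {
  writeLines(as.character(labels), path)
  if (!is.null(dictionary))
    utils::write.table(
      data.frame(label = seq_along(dictionary), name = dictionary),
      paste0(path, ".dict.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  lab <- as.integer(readLines(path))
  dict_path <- paste0(path, ".dict.tsv")
  if (file.exists(dict_path))
    attr(lab, "dictionary") <- utils::read.delim(dict_path)$name
  lab
}
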