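# CSV and mesh I/O. Record tables are comma-separated UTF-8 with a header,
# '.' decimal, booleans as 0/1, missing values empty; lengths are um in
# record tables and nm in meshes (units embedded in column names).

record_schema <- function() {
  c("cell_id", "n_flagella", "n_kinetoplasts", "n_nuclei",
    "tip_marker", "mid_marker", measurement_columns())
}

#' Read and validate a cell-record table
#'
#' Reads a CSV in the cell-record schema
#' (`cell_id,n_flagella,n_kinetoplasts,n_nuclei,tip_marker,mid_marker,`
#' `flagellum_um,cell_body_um,faz_um,kn_dist_um,kpost_dist_um,`
#' `free_flagellum_um,anterior_angle_deg`) and validates every row,
#' reporting offending rows by number: counts must be at least 1, lengths
#' non-negative, the free flagellum no longer than the flagellum, and a
#' `1F1K1N` record cannot carry both remnant markers.
#'
#' @param path CSV file path.
#' @return Validated data frame of cell records.
#' @export
read_cell_records <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) data.frame())
  if (ncol(df) == 0L) {
    warning("empty cell-record file: ", path)
    empty <- as.data.frame(setNames(rep(list(numeric(0)),
                                        length(record_schema())),
                                    record_schema()))
    empty$cell_id <- character(0)
    return(empty)
  }
  miss <- setdiff(setdiff(record_schema(), "anterior_angle_deg"), names(df))
  if (length(miss)) {
    stop("malformed header; missing columns: ", paste(miss, collapse = ", "))
  }
  if (!"anterior_angle_deg" %in% names(df)) df$anterior_angle_deg <- NA_real_
  if (nrow(df) == 0L) {
    warning("no records in ", path)
    return(df)
  }
  problems <- character(0)
  note <- function(rows, what) {
    if (length(rows)) {
      problems <<- c(problems, sprintf("row %d: %s", rows, what))
    }
  }
  num_cols <- setdiff(record_schema(), "cell_id")
  for (col in num_cols) {
    if (!is.numeric(df[[col]]) && !all(is.na(df[[col]]))) {
      bad <- which(!is.na(df[[col]]) & is.na(suppressWarnings(
        as.numeric(df[[col]]))))
      note(bad, paste0("non-numeric value in ", col))
      df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
    }
  }
  note(which(df$n_flagella < 1 | df$n_kinetoplasts < 1 | df$n_nuclei < 1),
       "F/K/N counts must be >= 1")
  len_cols <- setdiff(measurement_columns(), "anterior_angle_deg")
  for (col in len_cols) {
    note(which(!is.na(df[[col]]) & df[[col]] < 0),
         paste0("negative length in ", col))
  }
  note(which(!is.na(df$free_flagellum_um) & !is.na(df$flagellum_um) &
               df$free_flagellum_um > df$flagellum_um + 1e-9),
       "free flagellum longer than flagellum")
  is111 <- df$n_flagella == 1 & df$n_kinetoplasts == 1 & df$n_nuclei == 1
  note(which(is111 & df$tip_marker == 1 & df$mid_marker == 1),
       "1F1K1N record with both markers present")
  if (length(problems)) {
    stop("invalid cell records in ", path, ":\n  ",
         paste(problems, collapse = "\n  "))
  }
  df
}

#' Write a cell-record table
#'
#' @param records Data frame in the cell-record schema.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_records <- function(records, path) {
  cols <- intersect(record_schema(), names(records))
  write.csv(records[, cols, drop = FALSE], path, row.names = FALSE,
            quote = FALSE, na = "")
  invisible(path)
}

#' Read a triangle mesh from ASCII PLY or OBJ
#'
#' Supports ASCII PLY (vertex x/y/z properties, triangular faces) and
#' Wavefront OBJ (`v` and triangular `f` lines). Faces with more than three
#' vertices and out-of-range indices are rejected. Units are taken as nm.
#'
#' @param path Mesh file path (`.ply` or `.obj`).
#' @return A [surface_mesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") read_ply(path)
  else if (ext == "obj") read_obj(path)
  else stop("unsupported mesh format: .", ext)
}

read_ply <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || lines[1] != "ply") stop("not a PLY file")
  end_hdr <- match("end_header", trimws(lines))
  if (is.na(end_hdr)) stop("PLY header not terminated")
  hdr <- lines[seq_len(end_hdr)]
  if (!any(grepl("^format ascii", hdr))) stop("only ASCII PLY is supported")
  nv <- as.integer(sub("^element vertex ", "", grep("^element vertex ", hdr,
                                                    value = TRUE)))
  nf <- as.integer(sub("^element face ", "", grep("^element face ", hdr,
                                                  value = TRUE)))
  if (length(nv) != 1L || length(nf) != 1L) stop("malformed PLY header")
  body <- lines[(end_hdr + 1L):length(lines)]
  vert <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                                function(x) as.numeric(x[1:3])))
  face_lines <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- t(vapply(face_lines, function(x) {
    x <- as.numeric(x)
    if (x[1] != 3) stop("non-triangular PLY face (", x[1], " vertices)")
    x[2:4] + 1
  }, numeric(3)))
  surface_mesh(vert, faces)
}

read_obj <- function(path) {
  lines <- trimws(readLines(path))
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  if (!length(vl) || !length(fl)) stop("no vertices or faces in OBJ")
  vert <- do.call(rbind, lapply(strsplit(vl, "\\s+"),
                                function(x) as.numeric(x[2:4])))
  faces <- t(vapply(strsplit(fl, "\\s+"), function(x) {
    ids <- x[-1]
    if (length(ids) != 3L) {
      stop("non-triangular OBJ face (", length(ids), " vertices)")
    }
    as.integer(sub("/.*$", "", ids))
  }, integer(3)))
  surface_mesh(vert, faces)
}

#' Write a triangle mesh to ASCII PLY or OBJ
#'
#' @param mesh A [surface_mesh()].
#' @param path Output path; format chosen by extension (`.ply` or `.obj`).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices
  tr <- mesh$triangles
  if (ext == "ply") {
    hdr <- c("ply", "format ascii 1.0",
             sprintf("element vertex %d", nrow(v)),
             "property float x", "property float y", "property float z",
             sprintf("element face %d", nrow(tr)),
             "property list uchar int vertex_indices", "end_header")
    body <- c(apply(v, 1, function(p) paste(format(p, trim = TRUE,
                                                   scientific = FALSE),
                                            collapse = " ")),
              apply(tr - 1L, 1, function(f) paste(c(3, f), collapse = " ")))
    writeLines(c(hdr, body), path)
  } else if (ext == "obj") {
    writeLines(c(apply(v, 1, function(p) paste(c("v", format(p, trim = TRUE,
                                                             scientific = FALSE)),
                                               collapse = " ")),
                 apply(tr, 1, function(f) paste(c("f", f), collapse = " "))),
               path)
  } else stop("unsupported mesh format: .", ext)
  invisible(path)
}

#' Write a simulation report (or any tabular result) with a config sidecar
#'
#' Writes the table as CSV with a fixed column order and, when a scenario
#' or config is attached or supplied, a JSON sidecar (`<path>.json`)
#' recording the full resolved configuration including the seed, so the
#' run can be reproduced byte-identically.
#'
#' @param x Data frame (e.g. a `sim_report`).
#' @param path Output CSV path.
#' @param config Optional list to record; defaults to `attr(x, "scenario")`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, config = NULL) {
  if (is.null(config)) config <- attr(x, "scenario")
  df <- as.data.frame(x)
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  if (!is.null(config)) {
    jsonlite::write_json(unclass(config), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a scenario configuration from JSON or YAML
#'
#' @param path `.json` or `.yaml`/`.yml` file of [sim_scenario()] fields.
#' @return A [sim_scenario()].
#' @export
read_scenario <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required to read YAML configs")
    }
    yaml::read_yaml(path)
  } else stop("unsupported config format: .", ext)
  known <- names(formals(sim_scenario))
  do.call(sim_scenario, cfg[intersect(names(cfg), known)])
}
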