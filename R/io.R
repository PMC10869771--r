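#' Read a per-molecule transcript table
#'
#' Reads a delimited text file of detected molecules (Baysor-style output:
#' one row per molecule with its position, gene, and assigned cell). The
#' column mapping is explicit configuration so any segmenter's dialect can
#' be adapted. Rows with non-finite coordinates are dropped and counted in
#' the `"n_dropped"` attribute.
#'
#' @param path CSV file with a header row.
#' @param column_map named character vector mapping the canonical fields
#'   `x`, `y`, `gene`, `cell_id` (required) and `molecule_cluster`,
#'   `confidence` (optional) to column names in the file. Optional fields
#'   are read when their mapped column exists; mapping a missing column for
#'   a required field is a configuration error.
#' @param sep field separator.
#' @return data.frame of transcripts with canonical column names and an
#'   `"n_dropped"` attribute.
#' @export
read_transcripts <- function(path,
                             column_map = c(x = "x", y = "y", gene = "gene",
                                            cell_id = "cell_id",
                                            molecule_cluster = "molecule_cluster",
                                            confidence = "confidence"),
                             sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, sep = sep, check.names = FALSE,
                  stringsAsFactors = FALSE)
  required <- c("x", "y", "gene", "cell_id")
  for (f in required) {
    col <- column_map[[f]]
    if (is.null(col) || !col %in% names(raw))
      stop("mapped column `", if (is.null(col)) f else col,
           "` (field `", f, "`) is missing from ", path, call. = FALSE)
  }
  out <- data.frame(
    x = as.numeric(raw[[column_map[["x"]]]]),
    y = as.numeric(raw[[column_map[["y"]]]]),
    gene = as.character(raw[[column_map[["gene"]]]]),
    cell_id = as.integer(raw[[column_map[["cell_id"]]]]),
    stringsAsFactors = FALSE)
  for (f in c("molecule_cluster", "confidence")) {
    col <- column_map[f]
    if (!is.na(col) && col %in% names(raw))
      out[[f]] <- if (f == "confidence") as.numeric(raw[[col]])
                  else as.character(raw[[col]])
  }
  finite <- is.finite(out$x) & is.finite(out$y)
  dropped <- sum(!finite)
  out <- out[finite, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  out
}

#' Write a transcript table
#' @param transcripts data.frame as returned by [read_transcripts()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_transcripts <- function(transcripts, path) {
  write.csv(transcripts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-cell segmentation-statistics table
#'
#' @param path CSV file with a header row.
#' @param column_map named character vector mapping canonical fields
#'   (`cell_id`, `x`, `y` required; `n_transcripts`, `area`, `elongation`,
#'   `mean_confidence`, `type` optional) to file columns.
#' @param sep field separator.
#' @return data.frame of cells with canonical column names.
#' @export
read_cell_stats <- function(path,
                            column_map = c(cell_id = "cell_id", x = "x",
                                           y = "y",
                                           n_transcripts = "n_transcripts",
                                           area = "area",
                                           elongation = "elongation",
                                           mean_confidence = "mean_confidence",
                                           type = "type"),
                            sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, sep = sep, check.names = FALSE,
                  stringsAsFactors = FALSE)
  for (f in c("cell_id", "x", "y")) {
    col <- column_map[[f]]
    if (is.null(col) || !col %in% names(raw))
      stop("mapped column `", if (is.null(col)) f else col,
           "` (field `", f, "`) is missing from ", path, call. = FALSE)
  }
  out <- data.frame(cell_id = as.integer(raw[[column_map[["cell_id"]]]]),
                    x = as.numeric(raw[[column_map[["x"]]]]),
                    y = as.numeric(raw[[column_map[["y"]]]]),
                    stringsAsFactors = FALSE)
  numeric_fields <- c("n_transcripts", "area", "elongation", "mean_confidence")
  for (f in c(numeric_fields, "type")) {
    col <- column_map[f]
    if (!is.na(col) && col %in% names(raw))
      out[[f]] <- if (f %in% numeric_fields) as.numeric(raw[[col]])
                  else as.character(raw[[col]])
  }
  out
}

#' Write a per-cell statistics table
#' @param cells cell data.frame (or a [spatial_cell_set()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_stats <- function(cells, path) {
  if (inherits(cells, "spatial_cell_set")) cells <- cells$cells
  write.csv(cells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a count matrix as MatrixMarket + sidecar name files
#'
#' Writes `matrix.mtx`, `genes.txt` (row names) and `cells.txt` (column
#' names) into a directory, the conventional sparse exchange layout.
#'
#' @param counts gene-by-cell matrix.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "genes.txt"))
  writeLines(colnames(m), file.path(dir, "cells.txt"))
  invisible(dir)
}

#' Read a count matrix written by [write_counts_mtx()] (or a dense CSV)
#'
#' @param path directory containing `matrix.mtx`, `genes.txt`, `cells.txt`,
#'   or a dense CSV file with genes as rows (first column = gene names).
#' @return sparse `dgCMatrix`, genes x cells.
#' @export
read_counts <- function(path) {
  if (dir.exists(path)) {
    m <- Matrix::readMM(file.path(path, "matrix.mtx"))
    m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
    dimnames(m) <- list(readLines(file.path(path, "genes.txt")),
                        readLines(file.path(path, "cells.txt")))
    return(m)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix"),
              "generalMatrix")
}

#' Read a spot-position table (Visium-style)
#'
#' @param path CSV with columns mappable to `spot_id`, `x`, `y` and
#'   optionally `in_tissue` (0/1 or logical).
#' @param diameter,pitch spot diameter and center-to-center pitch (um);
#'   geometry is taken from the caller / file metadata, never assumed.
#' @param column_map field-to-column mapping.
#' @return a [spot_grid()].
#' @export
read_spot_positions <- function(path, diameter, pitch,
                                column_map = c(spot_id = "spot_id", x = "x",
                                               y = "y",
                                               in_tissue = "in_tissue")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (f in c("spot_id", "x", "y")) {
    col <- column_map[[f]]
    if (is.null(col) || !col %in% names(raw))
      stop("mapped column `", if (is.null(col)) f else col,
           "` (field `", f, "`) is missing from ", path, call. = FALSE)
  }
  in_tissue <- if (!is.na(column_map["in_tissue"]) &&
                   column_map[["in_tissue"]] %in% names(raw))
    as.logical(as.integer(raw[[column_map[["in_tissue"]]]])) else TRUE
  spot_grid(spot_id = raw[[column_map[["spot_id"]]]],
            x = as.numeric(raw[[column_map[["x"]]]]),
            y = as.numeric(raw[[column_map[["y"]]]]),
            diameter = diameter, pitch = pitch, in_tissue = in_tissue)
}

#' Write spot positions
#' @param grid a [spot_grid()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spot_positions <- function(grid, path) {
  df <- grid$spots
  df$in_tissue <- as.integer(df$in_tissue)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read landmark pairs for registration
#'
#' @param path CSV with columns `x_src`, `y_src`, `x_dst`, `y_dst`.
#' @return list of matrices `src` and `dst`.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_src", "y_src", "x_dst", "y_dst")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("landmark file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  list(src = cbind(x = df$x_src, y = df$y_src),
       dst = cbind(x = df$x_dst, y = df$y_dst))
}

#' Write landmark pairs
#' @param src,dst two-column matrices of matched points.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(src, dst, path) {
  src <- .assert_xy(src); dst <- .assert_xy(dst)
  write.csv(data.frame(x_src = src[, 1], y_src = src[, 2],
                       x_dst = dst[, 1], y_dst = dst[, 2]),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export polygons as GeoJSON
#'
#' Writes a FeatureCollection of Polygon features; one feature per entry,
#' with the list names stored as the `id` property. Rings are closed on
#' output (first vertex repeated).
#'
#' @param polygons named list of two-column vertex matrices (open rings).
#' @param path output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_polygons_geojson <- function(polygons, path) {
  feats <- lapply(seq_along(polygons), function(i) {
    ring <- .assert_xy(polygons[[i]])
    ring <- rbind(ring, ring[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(id = names(polygons)[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(k) ring[k, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read polygons from GeoJSON written by [write_polygons_geojson()]
#' @param path `.geojson` path.
#' @return named list of two-column vertex matrices (open rings).
#' @export
read_polygons_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  polys <- lapply(gj$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(v) unlist(v)))
    colnames(ring) <- c("x", "y")
    ring[-nrow(ring), , drop = FALSE]   # reopen the ring
  })
  names(polys) <- vapply(gj$features, function(f)
    as.character(f$properties$id), character(1))
  polys
}

#' Serialize / deserialize a 2D similarity transform as JSON
#' @param tf a [transform2d()].
#' @param path JSON path.
#' @return `path` (write) or a `transform2d` (read).
#' @export
write_transform_json <- function(tf, path) {
  stopifnot(inherits(tf, "transform2d"))
  jsonlite::write_json(unclass(tf)[c("theta", "scale", "tx", "ty")], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  transform2d(theta = v$theta, scale = v$scale, tx = v$tx, ty = v$ty)
}

#' Write a QC filter report as JSON
#' @param scs a filtered [spatial_cell_set()] carrying a `"qc_report"`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(scs, path) {
  rep <- attr(scs, "qc_report")
  if (is.null(rep)) stop("object carries no qc_report", call. = FALSE)
  rep$thresholds <- rep$thresholds[!vapply(rep$thresholds, is.null,
                                           logical(1))]
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
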