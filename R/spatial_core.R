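#' Segmented spatial transcriptomics dataset
#'
#' Container for a segmented imaging-based spatial transcriptomics sample:
#' a per-cell table (centroids in micrometers plus segmentation statistics),
#' optionally the per-molecule transcript table it was derived from, and a
#' gene-by-cell count matrix whose columns correspond one-to-one to the
#' cells. All coordinates are continuous positions in micrometers.
#'
#' @param cells data.frame with at least `cell_id` (positive integers, unique),
#'   `x`, `y` (centroid, um). Recognised optional columns: `n_transcripts`,
#'   `area` (um^2), `elongation` (>= 1), `mean_confidence` (in `[0, 1]`),
#'   `type`.
#' @param transcripts optional data.frame of molecules with columns `x`, `y`,
#'   `gene`, `cell_id` (0 marks noise / unassigned molecules) and optional
#'   `molecule_cluster`, `confidence`.
#' @param counts optional gene-by-cell matrix (`Matrix::dgCMatrix` or dense);
#'   column names must equal `as.character(cells$cell_id)` in order. When
#'   omitted but transcripts are present it is built with
#'   [build_count_matrix()].
#' @param polygons optional named list (names = cell ids) of two-column vertex
#'   matrices describing cell outlines.
#' @param provenance free-text tag describing the data source.
#' @return object of class `spatial_cell_set`.
#' @seealso [qc_filter()], [build_count_matrix()], [select_fov()]
#' @export
spatial_cell_set <- function(cells, transcripts = NULL, counts = NULL,
                             polygons = NULL, provenance = "") {
  cells <- as.data.frame(cells)
  need <- c("cell_id", "x", "y")
  miss <- setdiff(need, names(cells))
  if (length(miss))
    stop("cells table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(cells$cell_id))
    stop("cell ids must be unique", call. = FALSE)
  if (any(cells$cell_id <= 0))
    stop("cell ids must be positive (0 is reserved for noise molecules)",
         call. = FALSE)
  if (!all(is.finite(cells$x) & is.finite(cells$y)))
    stop("cell centroids must be finite", call. = FALSE)
  if (!is.null(transcripts)) {
    transcripts <- as.data.frame(transcripts)
    tn <- setdiff(c("x", "y", "gene", "cell_id"), names(transcripts))
    if (length(tn))
      stop("transcript table lacks column(s): ", paste(tn, collapse = ", "),
           call. = FALSE)
    if ("confidence" %in% names(transcripts)) {
      cf <- transcripts$confidence
      if (any(!is.na(cf) & (cf < 0 | cf > 1)))
        stop("transcript confidence must lie in [0, 1]", call. = FALSE)
    }
  }
  if (is.null(counts) && !is.null(transcripts))
    counts <- build_count_matrix(transcripts, cell_ids = cells$cell_id)
  if (!is.null(counts)) {
    counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                      "CsparseMatrix"), "generalMatrix")
    if (is.null(colnames(counts)) ||
        !identical(colnames(counts), as.character(cells$cell_id)))
      stop("count-matrix columns must match cell ids one-to-one",
           call. = FALSE)
    if (any(counts@x < 0)) stop("counts must be nonnegative", call. = FALSE)
  }
  structure(
    list(cells = cells, transcripts = transcripts, counts = counts,
         polygons = polygons, unit = "um", provenance = provenance),
    class = "spatial_cell_set")
}

#' @export
print.spatial_cell_set <- function(x, ...) {
  cat("<spatial_cell_set> ", nrow(x$cells), " cells",
      if (!is.null(x$transcripts)) paste0(", ", nrow(x$transcripts), " transcripts"),
      if (!is.null(x$counts)) paste0(", ", nrow(x$counts), " genes"),
      if (nzchar(x$provenance)) paste0("  [", x$provenance, "]"), "\n", sep = "")
  invisible(x)
}

#' @export
dim.spatial_cell_set <- function(x) {
  c(genes = if (is.null(x$counts)) 0L else nrow(x$counts),
    cells = nrow(x$cells))
}

# Subset a spatial_cell_set to the given cell ids, keeping transcripts of
# retained cells (plus, optionally, noise molecules passing `keep_noise`)
# and the matching count-matrix columns.
.subset_cells <- function(scs, keep_ids, keep_noise = NULL) {
  cells <- scs$cells[scs$cells$cell_id %in% keep_ids, , drop = FALSE]
  tr <- scs$transcripts
  if (!is.null(tr)) {
    keep <- tr$cell_id %in% keep_ids
    if (!is.null(keep_noise)) keep <- keep | (tr$cell_id == 0L & keep_noise)
    tr <- tr[keep, , drop = FALSE]
  }
  counts <- scs$counts
  if (!is.null(counts))
    counts <- counts[, as.character(cells$cell_id), drop = FALSE]
  polys <- scs$polygons
  if (!is.null(polys))
    polys <- polys[names(polys) %in% as.character(cells$cell_id)]
  spatial_cell_set(cells, tr, counts, polys, scs$provenance)
}

#' QC thresholds for segmented cells
#'
#' Gates applied by [qc_filter()]. The transcript threshold is a strict
#' lower bound: a cell is retained only if `n_transcripts > min_transcripts`
#' (with the default of 5, cells need at least 6 molecules). The area,
#' elongation and confidence gates are optional and off by default because
#' sensible values depend on the segmenter and tissue.
#'
#' @param min_transcripts strict lower bound on transcripts per cell.
#' @param min_area,max_area optional cell-area bounds (um^2).
#' @param max_elongation optional upper bound on the elongation ratio (>= 1).
#' @param min_confidence optional lower bound on mean segmentation
#'   confidence (in `[0, 1]`).
#' @return object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_transcripts = 5L, min_area = NULL,
                          max_area = NULL, max_elongation = NULL,
                          min_confidence = NULL) {
  if (min_transcripts < 0) stop("min_transcripts must be >= 0", call. = FALSE)
  if (!is.null(min_area) && !is.null(max_area) && min_area > max_area)
    stop("min_area exceeds max_area", call. = FALSE)
  if (!is.null(max_elongation) && max_elongation < 1)
    stop("max_elongation must be >= 1", call. = FALSE)
  if (!is.null(min_confidence) && (min_confidence < 0 || min_confidence > 1))
    stop("min_confidence must lie in [0, 1]", call. = FALSE)
  structure(list(min_transcripts = as.integer(min_transcripts),
                 min_area = min_area, max_area = max_area,
                 max_elongation = max_elongation,
                 min_confidence = min_confidence),
            class = "qc_thresholds")
}

#' Filter low-quality segmented cells
#'
#' Removes cells failing the segmentation-statistics gates: transcripts per
#' cell (strictly greater than `min_transcripts` retained), cell area,
#' elongation and mean segmentation confidence. Retained cells keep all of
#' their fields untouched; the transcript table and count-matrix columns are
#' subset consistently. A filter report (`n_in`, `n_retained`, `n_removed`,
#' per-gate removal counts) is attached as attribute `"qc_report"`.
#'
#' @param scs a [spatial_cell_set()].
#' @param thresholds a [qc_thresholds()] object.
#' @return filtered `spatial_cell_set` with a `"qc_report"` attribute.
#' @examples
#' cells <- data.frame(cell_id = 1:10, x = 1:10, y = 0, n_transcripts = 1:10)
#' scs <- spatial_cell_set(cells)
#' filtered <- qc_filter(scs, qc_thresholds(min_transcripts = 5))
#' nrow(filtered$cells)  # 5: only counts 6..10 survive the strict bound
#' @export
qc_filter <- function(scs, thresholds = qc_thresholds()) {
  stopifnot(inherits(scs, "spatial_cell_set"),
            inherits(thresholds, "qc_thresholds"))
  cells <- scs$cells
  n_in <- nrow(cells)
  gate <- function(col, test, label) {
    if (!col %in% names(cells))
      stop("qc gate on `", label, "` requires cell column `", col, "`",
           call. = FALSE)
    test(cells[[col]])
  }
  pass <- rep(TRUE, n_in)
  removed_by <- integer(0)
  apply_gate <- function(ok, label) {
    removed_by[[label]] <<- sum(!ok)
    pass <<- pass & ok
  }
  apply_gate(gate("n_transcripts",
                  function(v) v > thresholds$min_transcripts,
                  "min_transcripts"), "min_transcripts")
  if (!is.null(thresholds$min_area))
    apply_gate(gate("area", function(v) v >= thresholds$min_area, "min_area"),
               "min_area")
  if (!is.null(thresholds$max_area))
    apply_gate(gate("area", function(v) v <= thresholds$max_area, "max_area"),
               "max_area")
  if (!is.null(thresholds$max_elongation))
    apply_gate(gate("elongation",
                    function(v) v <= thresholds$max_elongation,
                    "max_elongation"), "max_elongation")
  if (!is.null(thresholds$min_confidence))
    apply_gate(gate("mean_confidence",
                    function(v) v >= thresholds$min_confidence,
                    "min_confidence"), "min_confidence")
  if (!any(pass))
    warning("qc_filter removed every cell", call. = FALSE)
  out <- .subset_cells(scs, cells$cell_id[pass], keep_noise = TRUE)
  attr(out, "qc_report") <- list(
    n_in = n_in, n_retained = sum(pass), n_removed = sum(!pass),
    removed_by_gate = as.list(removed_by),
    thresholds = unclass(thresholds))
  out
}

#' Label cells by the majority vote of their molecules
#'
#' Assigns to every cell the most frequently occurring molecule-cluster
#' label among its transcripts, emulating the usual post-segmentation
#' annotation step for transcript-clustering segmenters. Noise molecules
#' (`cell_id == 0`) and molecules without a cluster label are ignored. Ties
#' are broken deterministically by lexicographic order of the label strings.
#' Cells with no labeled molecule receive `unlabeled`.
#'
#' @param transcripts data.frame with `cell_id` and `molecule_cluster`.
#' @param cells optional cell table (or [spatial_cell_set()]); when given,
#'   the result covers exactly its cell ids. Defaults to all assigned ids
#'   seen in `transcripts`.
#' @param unlabeled value used for cells without labeled molecules.
#' @return named character vector: `cell_id` -> label.
#' @export
label_cells_by_transcript_majority <- function(transcripts, cells = NULL,
                                               unlabeled = "unlabeled") {
  if (inherits(cells, "spatial_cell_set")) cells <- cells$cells
  if (!"molecule_cluster" %in% names(transcripts))
    stop("transcripts lack a `molecule_cluster` column", call. = FALSE)
  keep <- transcripts$cell_id > 0L & !is.na(transcripts$molecule_cluster)
  tr <- transcripts[keep, c("cell_id", "molecule_cluster")]
  ids <- if (is.null(cells)) sort(unique(tr$cell_id)) else cells$cell_id
  labs <- rep(unlabeled, length(ids))
  names(labs) <- as.character(ids)
  if (nrow(tr)) {
    votes <- split(as.character(tr$molecule_cluster), tr$cell_id)
    modal <- vapply(votes, function(v) {
      tab <- table(v)
      winners <- names(tab)[tab == max(tab)]
      sort(winners)[1L]   # lexicographic tie-break
    }, character(1))
    hit <- intersect(names(modal), names(labs))
    labs[hit] <- modal[hit]
  }
  labs
}

#' Build a gene-by-cell count matrix from assigned molecules
#'
#' Entry (g, c) counts the transcripts of gene g assigned to cell c. Noise
#' molecules (`cell_id == 0`) are excluded, so the matrix total equals the
#' number of cell-assigned molecules.
#'
#' @param transcripts data.frame with `gene` and `cell_id`.
#' @param cell_ids optional full set of cell ids for the columns (cells with
#'   no molecule get an all-zero column); defaults to the assigned ids
#'   present in `transcripts`, sorted.
#' @return sparse integer `dgCMatrix`, genes x cells.
#' @export
build_count_matrix <- function(transcripts, cell_ids = NULL) {
  tr <- transcripts[transcripts$cell_id > 0L, c("gene", "cell_id")]
  if (is.null(cell_ids)) cell_ids <- sort(unique(tr$cell_id))
  genes <- sort(unique(as.character(tr$gene)))
  cid <- as.character(cell_ids)
  if (!nrow(tr) || !length(cid))
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(length(genes), length(cid)),
                                dimnames = list(genes, cid)))
  if (!all(tr$cell_id %in% cell_ids))
    stop("transcripts reference cell ids absent from `cell_ids`",
         call. = FALSE)
  i <- match(as.character(tr$gene), genes)
  j <- match(as.character(tr$cell_id), cid)
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(length(genes), length(cid)),
                       dimnames = list(genes, cid))
}

#' Field-of-view grid over a dataset's bounding box
#'
#' Splits a bounding box into `n_rows` x `n_cols` rectangular tiles indexed
#' row-major from 1 (row 1 at the bottom). The tiles partition the box:
#' points on a shared edge belong to the tile with the larger index along
#' that edge, and points on the outer maximum edges to the last tile, so
#' every point falls in exactly one tile.
#'
#' @param x a [spatial_cell_set()], a two-column point matrix/data.frame, or
#'   a numeric bbox `c(xmin, ymin, xmax, ymax)`.
#' @param n_rows,n_cols positive tile counts.
#' @return object of class `fov_grid`.
#' @export
fov_grid <- function(x, n_rows, n_cols) {
  if (inherits(x, "spatial_cell_set"))
    bbox <- c(min(x$cells$x), min(x$cells$y), max(x$cells$x), max(x$cells$y))
  else if (is.numeric(x) && length(x) == 4L) bbox <- as.numeric(x)
  else {
    p <- .assert_xy(x)
    bbox <- c(min(p[, 1]), min(p[, 2]), max(p[, 1]), max(p[, 2]))
  }
  if (n_rows < 1L || n_cols < 1L)
    stop("grid dimensions must be positive", call. = FALSE)
  if (bbox[3] <= bbox[1] || bbox[4] <= bbox[2])
    stop("bounding box is degenerate", call. = FALSE)
  structure(list(bbox = bbox, n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols)),
            class = "fov_grid")
}

#' @export
print.fov_grid <- function(x, ...) {
  cat(sprintf("<fov_grid> %d x %d tiles over [%g, %g] x [%g, %g]\n",
              x$n_rows, x$n_cols, x$bbox[1], x$bbox[3], x$bbox[2], x$bbox[4]))
  invisible(x)
}

#' Tile membership of points in a field-of-view grid
#'
#' @param grid a [fov_grid()].
#' @param points two-column matrix or data.frame with `x`, `y`.
#' @return integer vector of row-major tile indices (1-based).
#' @export
tile_index <- function(grid, points) {
  stopifnot(inherits(grid, "fov_grid"))
  p <- .assert_xy(points)
  w <- (grid$bbox[3] - grid$bbox[1]) / grid$n_cols
  h <- (grid$bbox[4] - grid$bbox[2]) / grid$n_rows
  col <- pmin(pmax(floor((p[, 1] - grid$bbox[1]) / w) + 1, 1), grid$n_cols)
  row <- pmin(pmax(floor((p[, 2] - grid$bbox[2]) / h) + 1, 1), grid$n_rows)
  as.integer((row - 1L) * grid$n_cols + col)
}

#' Select a field of view
#'
#' Returns the subset of a dataset whose cell centroids fall inside one grid
#' tile or an explicit bounding box. Transcripts of the retained cells (and
#' noise molecules located inside the region) and count-matrix columns are
#' subset consistently.
#'
#' @param scs a [spatial_cell_set()].
#' @param grid a [fov_grid()]; required for tile selection.
#' @param tile row-major tile index, or a length-2 vector `c(row, col)`.
#' @param bbox numeric `c(xmin, ymin, xmax, ymax)`; closed intervals.
#' @return `spatial_cell_set` restricted to the region.
#' @export
select_fov <- function(scs, grid = NULL, tile = NULL, bbox = NULL) {
  stopifnot(inherits(scs, "spatial_cell_set"))
  if (is.null(tile) == is.null(bbox))
    stop("supply exactly one of `tile` or `bbox`", call. = FALSE)
  if (!is.null(tile)) {
    if (is.null(grid)) stop("tile selection requires `grid`", call. = FALSE)
    if (length(tile) == 2L)
      tile <- (as.integer(tile[1]) - 1L) * grid$n_cols + as.integer(tile[2])
    if (tile < 1L || tile > grid$n_rows * grid$n_cols)
      stop("tile index ", tile, " outside the ", grid$n_rows, "x",
           grid$n_cols, " grid", call. = FALSE)
    keep <- tile_index(grid, scs$cells) == tile
    noise_keep <- if (is.null(scs$transcripts)) NULL else
      tile_index(grid, scs$transcripts) == tile
  } else {
    keep <- scs$cells$x >= bbox[1] & scs$cells$x <= bbox[3] &
      scs$cells$y >= bbox[2] & scs$cells$y <= bbox[4]
    noise_keep <- if (is.null(scs$transcripts)) NULL else
      with(scs$transcripts,
           x >= bbox[1] & x <= bbox[3] & y >= bbox[2] & y <= bbox[4])
  }
  .subset_cells(scs, scs$cells$cell_id[keep], keep_noise = noise_keep)
}
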