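#' Configuration for the synthetic kidney-tissue simulator
#'
#' Describes a circular organ section with concentric depth zones, zoned
#' cell populations with type-specific expression programs, and background
#' noise molecules. The default configuration mimics an annotated kidney
#' section qualitatively — 13 cell types across cortex / medulla / papilla
#' zones, a 200-gene panel with 3 marker genes per type, and a glomerular
#' (podocyte + glomerular-EC) plus an immune (monocyte + failed-repair PT)
#' niche — and is used in documentation and tests; it makes no claim to
#' match any real dataset.
#'
#' @param radius organ radius (um).
#' @param center organ center `c(x, y)` (um).
#' @param zones data.frame with `zone`, `depth_lo`, `depth_hi` (intervals
#'   within `[0, 1]`, 0 = capsule).
#' @param cell_types data.frame with `type`, `zone`, `intensity` (cells per
#'   um^2 within the zone).
#' @param programs genes x types matrix of mean transcript counts per cell
#'   (Poisson means).
#' @param niches data.frame with `type_a`, `type_b`, `distance` (um,
#'   intra-doublet), `n` (doublet count), `spacing` (um between doublet
#'   anchors); consumed by [make_niche_fixture()].
#' @param cell_radius disk radius (um) for scattering a cell's transcripts
#'   around its centroid; cell outlines are emitted as regular 12-gons of
#'   this radius.
#' @param noise_rate background (unassigned) molecules per um^2.
#' @param label_noise fraction of molecule-cluster labels flipped to a
#'   random other type (0 keeps labels exact).
#' @return object of class `tissue_config`.
#' @export
tissue_config <- function(radius = 1500,
                          center = c(0, 0),
                          zones = NULL,
                          cell_types = NULL,
                          programs = NULL,
                          niches = NULL,
                          cell_radius = 5,
                          noise_rate = 5e-4,
                          label_noise = 0) {
  if (is.null(zones))
    zones <- data.frame(
      zone = c("cortex", "medulla", "papilla"),
      depth_lo = c(0, 0.35, 0.7),
      depth_hi = c(0.35, 0.7, 1),
      stringsAsFactors = FALSE)
  if (is.null(cell_types))
    cell_types <- data.frame(
      type = c("Podo", "gEC", "aEC", "PT", "FR-PT", "DCT", "Mono",
               "DTL", "TAL", "CNT", "Fib", "PC", "IC"),
      zone = c(rep("cortex", 7), rep("medulla", 4), rep("papilla", 2)),
      intensity = 6e-5,
      stringsAsFactors = FALSE)
  if (is.null(programs)) {
    n_genes <- 200L
    genes <- sprintf("G%03d", seq_len(n_genes))
    programs <- matrix(0.05, nrow = n_genes, ncol = nrow(cell_types),
                       dimnames = list(genes, cell_types$type))
    for (k in seq_len(nrow(cell_types)))   # 3 dedicated markers per type
      programs[(k - 1L) * 3L + 1:3, k] <- 3
  }
  if (any(zones$depth_lo < 0) || any(zones$depth_hi > 1) ||
      any(zones$depth_lo >= zones$depth_hi))
    stop("zone depth intervals must be increasing within [0, 1]",
         call. = FALSE)
  if (!all(cell_types$zone %in% zones$zone))
    stop("cell type assigned to an unknown zone", call. = FALSE)
  if (any(cell_types$intensity < 0) || any(programs < 0))
    stop("intensities and expression programs must be nonnegative",
         call. = FALSE)
  if (!identical(colnames(programs), cell_types$type))
    stop("program columns must match cell types in order", call. = FALSE)
  if (radius <= 0 || cell_radius <= 0)
    stop("radii must be positive", call. = FALSE)
  if (is.null(niches))
    niches <- data.frame(type_a = c("Podo", "Mono"),
                         type_b = c("gEC", "FR-PT"),
                         distance = 5, n = 30, spacing = 500,
                         stringsAsFactors = FALSE)
  structure(list(radius = radius, center = center, zones = zones,
                 cell_types = cell_types, programs = programs,
                 niches = niches, cell_radius = cell_radius,
                 noise_rate = noise_rate, label_noise = label_noise),
            class = "tissue_config")
}

#' Read / write a tissue configuration as YAML
#' @param config a [tissue_config()].
#' @param path YAML path.
#' @return `path` (write) or a `tissue_config` (read).
#' @export
write_tissue_config <- function(config, path) {
  stopifnot(inherits(config, "tissue_config"))
  obj <- unclass(config)
  obj$programs <- list(genes = rownames(config$programs),
                       types = colnames(config$programs),
                       means = as.vector(config$programs))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_tissue_config
#' @export
read_tissue_config <- function(path) {
  obj <- yaml::read_yaml(path)
  pr <- matrix(unlist(obj$programs$means),
               nrow = length(obj$programs$genes),
               dimnames = list(unlist(obj$programs$genes),
                               unlist(obj$programs$types)))
  as_df <- function(l) as.data.frame(lapply(l, unlist),
                                     stringsAsFactors = FALSE)
  tissue_config(radius = obj$radius, center = unlist(obj$center),
                zones = as_df(obj$zones),
                cell_types = as_df(obj$cell_types), programs = pr,
                niches = as_df(obj$niches), cell_radius = obj$cell_radius,
                noise_rate = obj$noise_rate, label_noise = obj$label_noise)
}

# Uniform sample inside an annulus r in [r_in, r_out] around `center`.
.runif_annulus <- function(n, center, r_in, r_out) {
  r <- sqrt(runif(n, r_in^2, r_out^2))
  th <- runif(n, -pi, pi)
  cbind(x = center[1] + r * cos(th), y = center[2] + r * sin(th))
}

#' Simulate a zoned synthetic tissue
#'
#' Draws, for every configured cell type, a homogeneous Poisson number of
#' cells placed uniformly within the type's depth zone (an annulus of the
#' circular organ); draws each cell's per-gene transcript counts from the
#' type's Poisson expression program, scattering the molecules uniformly in
#' a disk of `cell_radius` around the centroid; sprinkles unassigned noise
#' molecules (`cell_id = 0`) uniformly over the organ; and records the full
#' ground truth. All randomness is a deterministic function of `seed` (a
#' fixed seed reproduces the output byte for byte).
#'
#' @param config a [tissue_config()].
#' @param seed integer seed.
#' @return object of class `synthetic_tissue`: list with `scs` (a
#'   [spatial_cell_set()]; cells carry their true `type`), `truth`
#'   (data.frame: `cell_id`, `type`, `zone`, `depth_true`), `frame` (the
#'   exact circular [organ_frame()]), `config`, `seed`.
#' @export
simulate_tissue <- function(config = tissue_config(), seed = 1L) {
  stopifnot(inherits(config, "tissue_config"))
  R <- config$radius
  ctr <- config$center
  zones <- config$zones
  types <- config$cell_types
  with_seed(seed, {
    parts <- lapply(seq_len(nrow(types)), function(k) {
      z <- zones[zones$zone == types$zone[k], ]
      r_out <- R * (1 - z$depth_lo)   # depth 0 at the capsule
      r_in <- R * (1 - z$depth_hi)
      area <- pi * (r_out^2 - r_in^2)
      if (area <= 0) stop("zone `", z$zone, "` tiles no area", call. = FALSE)
      n <- rpois(1, types$intensity[k] * area)
      if (n == 0) return(NULL)
      xy <- .runif_annulus(n, ctr, r_in, r_out)
      data.frame(x = xy[, 1], y = xy[, 2], type = types$type[k],
                 zone = types$zone[k], stringsAsFactors = FALSE)
    })
    cells <- do.call(rbind, parts)
    n_cells <- nrow(cells)
    cells$cell_id <- seq_len(n_cells)
    rr <- sqrt((cells$x - ctr[1])^2 + (cells$y - ctr[2])^2)
    cells$depth_true <- 1 - rr / R

    # per-cell per-gene transcript counts from the type's program
    genes <- rownames(config$programs)
    type_idx <- match(cells$type, colnames(config$programs))
    counts_by_cell <- lapply(seq_len(n_cells), function(i)
      rpois(length(genes), config$programs[, type_idx[i]]))
    tot <- vapply(counts_by_cell, sum, integer(1))
    gene_vec <- unlist(lapply(counts_by_cell, function(cnt)
      rep(genes, cnt)), use.names = FALSE)
    cell_vec <- rep(cells$cell_id, tot)
    n_tr <- length(gene_vec)
    # molecule positions: uniform in a disk around the centroid
    rd <- config$cell_radius * sqrt(runif(n_tr))
    th <- runif(n_tr, -pi, pi)
    tr <- data.frame(
      x = cells$x[cell_vec] + rd * cos(th),
      y = cells$y[cell_vec] + rd * sin(th),
      gene = gene_vec,
      cell_id = cell_vec,
      molecule_cluster = cells$type[cell_vec],
      confidence = runif(n_tr, 0.7, 1),
      stringsAsFactors = FALSE)
    if (config$label_noise > 0) {
      flip <- runif(n_tr) < config$label_noise
      if (any(flip))
        tr$molecule_cluster[flip] <- sample(types$type, sum(flip),
                                            replace = TRUE)
    }
    # background noise molecules, unassigned (cell_id 0), unlabeled
    n_noise <- rpois(1, config$noise_rate * pi * R^2)
    if (n_noise > 0) {
      xy <- .runif_annulus(n_noise, ctr, 0, R)
      tr <- rbind(tr, data.frame(
        x = xy[, 1], y = xy[, 2],
        gene = sample(genes, n_noise, replace = TRUE),
        cell_id = 0L,
        molecule_cluster = NA_character_,
        confidence = runif(n_noise, 0, 0.5),
        stringsAsFactors = FALSE))
    }
    rownames(tr) <- NULL

    assigned <- tr$cell_id[tr$cell_id > 0L]
    cells$n_transcripts <- tabulate(assigned, n_cells)
    cells$area <- pi * config$cell_radius^2
    cells$elongation <- 1 + rexp(n_cells, rate = 5)
    conf_sum <- vapply(split(tr$confidence[tr$cell_id > 0L], assigned),
                       mean, numeric(1))
    cells$mean_confidence <- NA_real_
    cells$mean_confidence[as.integer(names(conf_sum))] <- conf_sum

    polys <- lapply(seq_len(n_cells), function(i) {
      ang <- seq(0, 2 * pi, length.out = 13L)[-13L]
      cbind(x = cells$x[i] + config$cell_radius * cos(ang),
            y = cells$y[i] + config$cell_radius * sin(ang))
    })
    names(polys) <- as.character(cells$cell_id)

    scs <- spatial_cell_set(
      cells[, c("cell_id", "x", "y", "n_transcripts", "area", "elongation",
                "mean_confidence", "type")],
      transcripts = tr, polygons = polys,
      provenance = sprintf("synthetic tissue (seed %d)", as.integer(seed)))
    structure(list(
      scs = scs,
      truth = cells[, c("cell_id", "type", "zone", "depth_true", "x", "y")],
      frame = organ_frame(list(center = ctr, radius = R), origin = ctr),
      config = config, seed = as.integer(seed)),
      class = "synthetic_tissue")
  })
}

#' @export
print.synthetic_tissue <- function(x, ...) {
  cat(sprintf(
    "<synthetic_tissue> seed %d: %d cells, %d molecules, %d types\n",
    x$seed, nrow(x$scs$cells), nrow(x$scs$transcripts),
    length(unique(x$truth$type))))
  invisible(x)
}

#' Overlay a capture-spot grid with recorded ground-truth composition
#'
#' Lays a hexagonal (or square) spot grid over the tissue after applying
#' `transform` to the cell positions — emulating a second, spot-resolution
#' modality acquired in its own coordinate frame — and records the true
#' per-spot cell-type composition using the same nearest-spot rule as
#' [assign_to_spots()]. Landmark pairs mapping the tissue frame onto the
#' spot frame are emitted so the registration pipeline can be run end to
#' end against the recorded truth.
#'
#' @param tissue a [simulate_tissue()] result.
#' @param pitch center-to-center spot distance (um).
#' @param diameter spot diameter (um); must be <= pitch.
#' @param transform a [transform2d()] mapping tissue coordinates into the
#'   spot frame (identity by default).
#' @param layout `"hex"` or `"square"`.
#' @return object of class `synthetic_spot_panel`: list with `grid`
#'   (a [spot_grid()]), `truth_composition` (a `composition_matrix`),
#'   `transform`, `landmarks` (data.frame `x_src`, `y_src`, `x_dst`,
#'   `y_dst`), `assignments` (true spot per cell).
#' @export
simulate_spot_grid <- function(tissue, pitch = 100, diameter = 55,
                               transform = transform2d(),
                               layout = c("hex", "square")) {
  layout <- match.arg(layout)
  stopifnot(inherits(tissue, "synthetic_tissue"),
            inherits(transform, "transform2d"))
  if (diameter > pitch)
    stop("spot diameter (", diameter, ") exceeds pitch (", pitch, ")",
         call. = FALSE)
  cells_t <- apply_transform(transform, tissue$scs$cells[, c("x", "y")])
  bb <- c(min(cells_t$x), min(cells_t$y), max(cells_t$x), max(cells_t$y)) +
    pitch * c(-1, -1, 1, 1)
  if (layout == "hex") {
    row_h <- pitch * sqrt(3) / 2
    ys <- seq(bb[2], bb[4], by = row_h)
    pts <- do.call(rbind, lapply(seq_along(ys), function(r) {
      off <- if (r %% 2 == 0) pitch / 2 else 0
      xs <- seq(bb[1] + off, bb[3], by = pitch)
      cbind(xs, ys[r])
    }))
  } else {
    xs <- seq(bb[1], bb[3], by = pitch)
    ys <- seq(bb[2], bb[4], by = pitch)
    pts <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  }
  ids <- sprintf("spot_%05d", seq_len(nrow(pts)))
  organ_c <- apply_transform(transform,
                             matrix(tissue$config$center, ncol = 2))
  in_tissue <- sqrt((pts[, 1] - organ_c[1, 1])^2 +
                      (pts[, 2] - organ_c[1, 2])^2) <=
    tissue$config$radius * transform$scale + pitch / 2
  grid <- spot_grid(ids, pts[, 1], pts[, 2], diameter = diameter,
                    pitch = pitch, in_tissue = in_tissue)
  assignments <- assign_to_spots(cells_t, grid)
  truth <- spot_composition(assignments, tissue$scs$cells$type, grid = grid)
  R <- tissue$config$radius; ctr <- tissue$config$center
  lm_src <- rbind(ctr,
                  ctr + c(R / 2, 0), ctr + c(0, R / 2), ctr + c(-R / 2, R / 4))
  lm_dst <- apply_transform(transform, lm_src)
  landmarks <- data.frame(x_src = lm_src[, 1], y_src = lm_src[, 2],
                          x_dst = lm_dst[, 1], y_dst = lm_dst[, 2])
  structure(list(grid = grid, truth_composition = truth,
                 transform = transform, landmarks = landmarks,
                 assignments = assignments),
            class = "synthetic_spot_panel")
}

#' Niche fixture: planted type-pair doublets over CSR background
#'
#' Builds a cell set in which `n` doublets of the planted type pair sit at a
#' fixed intra-pair distance, with doublet anchors far apart on a jittered
#' grid, plus background types placed by complete spatial randomness over
#' the same domain. By construction the planted pair is the unique pair
#' enriched at neighborhood scales between the doublet distance and the
#' anchor spacing, which makes the fixture a positive control for
#' [neighborhood_enrichment()].
#'
#' @param n_doublets number of planted doublets.
#' @param doublet_distance intra-pair distance (um); must be smaller than
#'   `spacing`.
#' @param doublet_types length-2 character: the planted pair.
#' @param background_types character vector of CSR background types.
#' @param n_background cells per background type.
#' @param spacing distance between doublet anchors (um).
#' @param seed integer seed.
#' @return a [spatial_cell_set()] (cells only, with `type`).
#' @export
make_niche_fixture <- function(n_doublets = 30L, doublet_distance = 5,
                               doublet_types = c("Mono", "FR-PT"),
                               background_types = c("PT", "TAL"),
                               n_background = 150L, spacing = 500,
                               seed = 1L) {
  if (doublet_distance >= spacing)
    stop("doublet distance must be smaller than the anchor spacing",
         call. = FALSE)
  if (length(doublet_types) != 2L)
    stop("doublet_types must name exactly two types", call. = FALSE)
  with_seed(seed, {
    ncol_g <- max(ceiling(sqrt(n_doublets)), 1L)
    nrow_g <- max(ceiling(n_doublets / ncol_g), 1L)
    gx <- ((seq_len(n_doublets) - 1L) %% ncol_g) * spacing
    gy <- ((seq_len(n_doublets) - 1L) %/% ncol_g) * spacing
    jit <- matrix(runif(2L * n_doublets, -spacing / 10, spacing / 10),
                  ncol = 2)
    ax <- gx + jit[, 1]; ay <- gy + jit[, 2]
    th <- runif(n_doublets, -pi, pi)
    bx <- ax + doublet_distance * cos(th)
    by <- ay + doublet_distance * sin(th)
    dom <- c(-spacing / 2, -spacing / 2,
             (ncol_g - 0.5) * spacing, (nrow_g - 0.5) * spacing)
    bg <- do.call(rbind, lapply(background_types, function(tp)
      data.frame(x = runif(n_background, dom[1], dom[3]),
                 y = runif(n_background, dom[2], dom[4]),
                 type = tp, stringsAsFactors = FALSE)))
    doublets <- if (n_doublets > 0) rbind(
      data.frame(x = ax, y = ay, type = doublet_types[1],
                 stringsAsFactors = FALSE),
      data.frame(x = bx, y = by, type = doublet_types[2],
                 stringsAsFactors = FALSE)) else NULL
    cells <- rbind(doublets, bg)
    cells$cell_id <- seq_len(nrow(cells))
    spatial_cell_set(cells[, c("cell_id", "x", "y", "type")],
                     provenance = sprintf("niche fixture (seed %d)",
                                          as.integer(seed)))
  })
}

#' Write every file a simulated tissue emits, in the package's dialects
#'
#' Emits `transcripts.csv`, `cells.csv`, the MatrixMarket counts directory
#' `counts/`, `polygons.geojson`, and the ground-truth bundle
#' (`truth_cells.csv` + `truth.json`). When a spot panel is supplied, also
#' `spot_positions.csv`, `landmarks.csv`, `transform.json` and
#' `truth_composition.csv`.
#'
#' @param tissue a [simulate_tissue()] result.
#' @param dir output directory (created).
#' @param panel optional [simulate_spot_grid()] result.
#' @return `dir`, invisibly.
#' @export
write_tissue_bundle <- function(tissue, dir, panel = NULL) {
  stopifnot(inherits(tissue, "synthetic_tissue"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_transcripts(tissue$scs$transcripts, file.path(dir, "transcripts.csv"))
  write_cell_stats(tissue$scs, file.path(dir, "cells.csv"))
  write_counts_mtx(tissue$scs$counts, file.path(dir, "counts"))
  write_polygons_geojson(tissue$scs$polygons,
                         file.path(dir, "polygons.geojson"))
  write.csv(tissue$truth, file.path(dir, "truth_cells.csv"),
            row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(seed = tissue$seed, radius = tissue$config$radius,
         center = tissue$config$center,
         n_cells = nrow(tissue$scs$cells),
         n_transcripts = nrow(tissue$scs$transcripts)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(panel)) {
    write_spot_positions(panel$grid, file.path(dir, "spot_positions.csv"))
    write.csv(panel$landmarks, file.path(dir, "landmarks.csv"),
              row.names = FALSE, quote = FALSE)
    write_transform_json(panel$transform, file.path(dir, "transform.json"))
    write_composition_csv(panel$truth_composition,
                          file.path(dir, "truth_composition.csv"),
                          what = "counts")
  }
  invisible(dir)
}
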