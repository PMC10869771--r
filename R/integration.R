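#' 2D similarity transform
#'
#' Rotation by `theta`, isotropic scaling by `scale`, then translation:
#' `p' = scale * R(theta) p + (tx, ty)`. Reflections are deliberately not
#' representable; [fit_similarity_transform()] rejects landmark sets that
#' demand one.
#'
#' @param theta rotation (radians, counterclockwise).
#' @param scale isotropic scale (> 0).
#' @param tx,ty translation (um).
#' @return object of class `transform2d`.
#' @export
transform2d <- function(theta = 0, scale = 1, tx = 0, ty = 0) {
  if (scale <= 0) stop("scale must be positive", call. = FALSE)
  structure(list(theta = theta, scale = scale, tx = tx, ty = ty),
            class = "transform2d")
}

#' @export
print.transform2d <- function(x, ...) {
  cat(sprintf(
    "<transform2d> theta = %.6g rad, scale = %.6g, t = (%.6g, %.6g)",
    x$theta, x$scale, x$tx, x$ty))
  if (!is.null(attr(x, "rms")))
    cat(sprintf("  [landmark RMS %.3g]", attr(x, "rms")))
  cat("\n")
  invisible(x)
}

#' Apply a 2D transform to points
#' @param tf a [transform2d()].
#' @param points two-column matrix or data.frame with `x`, `y`.
#' @return transformed coordinates, same shape as the input.
#' @export
apply_transform <- function(tf, points) {
  stopifnot(inherits(tf, "transform2d"))
  df <- is.data.frame(points)
  p <- .assert_xy(points)
  ct <- cos(tf$theta); st <- sin(tf$theta)
  xn <- tf$scale * (ct * p[, 1] - st * p[, 2]) + tf$tx
  yn <- tf$scale * (st * p[, 1] + ct * p[, 2]) + tf$ty
  if (df) {
    out <- points
    out$x <- xn; out$y <- yn
    out
  } else cbind(x = xn, y = yn)
}

#' Invert a 2D similarity transform
#' @param tf a [transform2d()].
#' @return the inverse `transform2d`.
#' @export
invert_transform <- function(tf) {
  stopifnot(inherits(tf, "transform2d"))
  s <- 1 / tf$scale
  th <- -tf$theta
  ct <- cos(th); st <- sin(th)
  transform2d(theta = th, scale = s,
              tx = -s * (ct * tf$tx - st * tf$ty),
              ty = -s * (st * tf$tx + ct * tf$ty))
}

#' Compose two transforms (`tf2` after `tf1`)
#' @param tf1,tf2 [transform2d()] objects.
#' @return the composite `transform2d`.
#' @export
compose_transforms <- function(tf2, tf1) {
  stopifnot(inherits(tf1, "transform2d"), inherits(tf2, "transform2d"))
  t12 <- apply_transform(tf2, cbind(tf1$tx, tf1$ty))
  transform2d(theta = tf1$theta + tf2$theta, scale = tf1$scale * tf2$scale,
              tx = t12[1], ty = t12[2])
}

#' Fit a least-squares similarity (or rigid) transform from landmarks
#'
#' Finds the rotation, optional isotropic scale, and translation minimizing
#' the sum of squared residuals between transformed source landmarks and
#' their destination partners. In 2D the orientation-preserving similarity
#' fit is the complex linear regression `dst ~ a * src + b` with
#' `a = scale * exp(i * theta)`, which is solved in closed form. The
#' orientation-reversing (reflected) model is fitted alongside; when it
#' explains the landmarks strictly better the configuration is rejected
#' with an error, since reflections are forbidden by contract.
#'
#' @param src,dst two-column matrices or data.frames of matched landmarks
#'   (>= 2 non-coincident pairs; >= 3 recommended).
#' @param allow_scale fit the scale (`TRUE`) or constrain it to 1 (rigid).
#' @return a [transform2d()] with attribute `"rms"` (root-mean-square
#'   landmark residual).
#' @export
fit_similarity_transform <- function(src, dst, allow_scale = TRUE) {
  s <- .assert_xy(src); d <- .assert_xy(dst)
  if (nrow(s) != nrow(d))
    stop("landmark lists have different lengths", call. = FALSE)
  if (nrow(s) < 2L)
    stop("need at least 2 landmark pairs", call. = FALSE)
  zs <- complex(real = s[, 1], imaginary = s[, 2])
  zd <- complex(real = d[, 1], imaginary = d[, 2])
  zs_c <- zs - mean(zs); zd_c <- zd - mean(zd)
  denom <- sum(Mod(zs_c)^2)
  if (denom == 0)
    stop("degenerate landmark configuration: source points coincide",
         call. = FALSE)
  a_proper <- sum(zd_c * Conj(zs_c)) / denom
  a_mirror <- sum(zd_c * zs_c) / denom   # model dst ~ a * Conj(src) + b
  rss <- function(fit) sum(Mod(zd_c - fit)^2)
  rss_p <- rss(a_proper * zs_c)
  rss_m <- rss(a_mirror * Conj(zs_c))
  tol <- 1e-9 * max(sum(Mod(zd_c)^2), 1)
  if (rss_m < rss_p - tol)
    stop("landmarks indicate a reflection, which similarity registration ",
         "forbids; check the landmark pairing", call. = FALSE)
  theta <- Arg(a_proper)
  scale <- if (allow_scale) Mod(a_proper) else 1
  if (scale <= 0)
    stop("degenerate landmark configuration: zero fitted scale",
         call. = FALSE)
  a <- complex(modulus = scale, argument = theta)
  b <- mean(zd) - a * mean(zs)
  tf <- transform2d(theta = theta, scale = scale, tx = Re(b), ty = Im(b))
  resid <- zd - (a * zs + b)
  attr(tf, "rms") <- sqrt(mean(Mod(resid)^2))
  tf
}

#' Crop a dataset to a rectangular or polygonal region
#'
#' Retains cells (with their transcripts and count-matrix columns), spots,
#' or raw points whose positions lie inside the region. Consistent with
#' [select_fov()] bbox semantics: closed intervals.
#'
#' @param x a [spatial_cell_set()], [spot_grid()], or data.frame with
#'   `x`, `y`.
#' @param bbox numeric `c(xmin, ymin, xmax, ymax)`.
#' @param polygon two-column vertex matrix (open simple ring).
#' @return cropped object of the same class; warns when the region misses
#'   all of the data.
#' @export
crop_region <- function(x, bbox = NULL, polygon = NULL) {
  if (is.null(bbox) == is.null(polygon))
    stop("supply exactly one of `bbox` or `polygon`", call. = FALSE)
  inside <- function(px, py) {
    if (!is.null(bbox))
      px >= bbox[1] & px <= bbox[3] & py >= bbox[2] & py <= bbox[4]
    else points_in_polygon(cbind(px, py), polygon)
  }
  if (inherits(x, "spatial_cell_set")) {
    keep <- inside(x$cells$x, x$cells$y)
    if (!any(keep)) warning("crop region contains no cells", call. = FALSE)
    noise_keep <- if (is.null(x$transcripts)) NULL else
      inside(x$transcripts$x, x$transcripts$y)
    return(.subset_cells(x, x$cells$cell_id[keep], keep_noise = noise_keep))
  }
  if (inherits(x, "spot_grid")) {
    keep <- inside(x$spots$x, x$spots$y)
    if (!any(keep)) warning("crop region contains no spots", call. = FALSE)
    out <- x
    out$spots <- x$spots[keep, , drop = FALSE]
    rownames(out$spots) <- NULL
    return(out)
  }
  p <- as.data.frame(x)
  keep <- inside(p$x, p$y)
  if (!any(keep)) warning("crop region contains no points", call. = FALSE)
  p[keep, , drop = FALSE]
}

#' Spot grid (Visium-style capture array)
#'
#' @param spot_id unique spot identifiers.
#' @param x,y spot center positions (um).
#' @param diameter capture-spot diameter (um; 55 for Visium).
#' @param pitch center-to-center distance (um); must be >= diameter.
#' @param in_tissue logical flag per spot.
#' @return object of class `spot_grid`.
#' @export
spot_grid <- function(spot_id, x, y, diameter, pitch, in_tissue = TRUE) {
  if (anyDuplicated(spot_id))
    stop("spot ids must be unique", call. = FALSE)
  if (diameter > pitch)
    stop("spot diameter (", diameter, ") exceeds pitch (", pitch, ")",
         call. = FALSE)
  spots <- data.frame(spot_id = as.character(spot_id), x = as.numeric(x),
                      y = as.numeric(y),
                      in_tissue = rep_len(as.logical(in_tissue),
                                          length(spot_id)),
                      stringsAsFactors = FALSE)
  structure(list(spots = spots, diameter = diameter, pitch = pitch),
            class = "spot_grid")
}

#' @export
print.spot_grid <- function(x, ...) {
  cat(sprintf(
    "<spot_grid> %d spots (%d in tissue), diameter %g um, pitch %g um\n",
    nrow(x$spots), sum(x$spots$in_tissue), x$diameter, x$pitch))
  invisible(x)
}

#' Assign points to their nearest capture spot
#'
#' Nearest-center assignment of cell centroids or transcripts to spots,
#' after both are in the same (registered) frame. By default there is no
#' distance cutoff — every point gets the closest spot; pass `max_distance`
#' (e.g. `pitch / 2`) to leave points between spots unassigned. Ties are
#' broken by the smallest spot id.
#'
#' @param points two-column matrix or data.frame with `x`, `y`.
#' @param grid a [spot_grid()].
#' @param max_distance optional cutoff (um).
#' @return character vector of spot ids (`NA` where unassigned), with
#'   attribute `"n_unassigned"`.
#' @export
assign_to_spots <- function(points, grid, max_distance = NULL) {
  stopifnot(inherits(grid, "spot_grid"))
  if (!nrow(grid$spots)) stop("spot grid is empty", call. = FALSE)
  p <- .assert_xy(points)
  ord <- order(grid$spots$spot_id)   # ties resolve to the smallest id
  sp <- grid$spots[ord, , drop = FALSE]
  nn <- .nearest_among(p, cbind(sp$x, sp$y))
  ids <- sp$spot_id[nn$index]
  if (!is.null(max_distance)) ids[nn$dist > max_distance] <- NA_character_
  attr(ids, "n_unassigned") <- sum(is.na(ids))
  ids
}

#' Per-spot cell-type composition
#'
#' Tabulates, per spot, the count and proportion of each cell type among
#' the cells assigned to it — the directly measured composition that
#' sequencing-based spot data can only estimate by deconvolution. Spots
#' with no assigned cell are flagged empty and carry `NA` proportions.
#'
#' @param assignments spot ids per cell (from [assign_to_spots()]); `NA`
#'   entries are dropped.
#' @param type_labels parallel vector of cell-type labels.
#' @param grid optional [spot_grid()]; when given, all grid spots appear in
#'   the result (empty ones included).
#' @return object of class `composition_matrix`: list with `counts`
#'   (spots x types integer matrix), `proportions` (row-normalized; `NA`
#'   rows for empty spots), `n_cells` (per spot), `empty` (logical).
#' @export
spot_composition <- function(assignments, type_labels, grid = NULL) {
  if (length(assignments) != length(type_labels))
    stop("assignments and type_labels lengths differ", call. = FALSE)
  keep <- !is.na(assignments)
  if (any(keep & is.na(type_labels)))
    stop("every assigned cell needs a type label", call. = FALSE)
  spots <- if (!is.null(grid)) sort(grid$spots$spot_id) else
    sort(unique(assignments[keep]))
  types <- sort(unique(as.character(type_labels[keep])))
  counts <- table(factor(assignments[keep], levels = spots),
                  factor(as.character(type_labels[keep]), levels = types))
  counts <- matrix(as.integer(counts), nrow = length(spots),
                   dimnames = list(spots, types))
  n_cells <- rowSums(counts)
  props <- sweep(counts, 1, n_cells, "/")
  props[n_cells == 0, ] <- NA_real_
  structure(list(counts = counts, proportions = props,
                 n_cells = n_cells, empty = n_cells == 0),
            class = "composition_matrix")
}

#' @export
print.composition_matrix <- function(x, ...) {
  cat(sprintf(
    "<composition_matrix> %d spots x %d types, %d cells, %d empty spots\n",
    nrow(x$counts), ncol(x$counts), sum(x$counts), sum(x$empty)))
  invisible(x)
}

#' Write / read a composition matrix as CSV
#' @param comp a [spot_composition()] result.
#' @param path CSV path.
#' @param what `"proportions"` or `"counts"`.
#' @return `path` (write) or a matrix (read).
#' @export
write_composition_csv <- function(comp, path, what = c("proportions",
                                                       "counts")) {
  what <- match.arg(what)
  m <- comp[[what]]
  df <- data.frame(spot_id = rownames(m), m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_composition_csv
#' @export
read_composition_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}

#' Benchmark externally predicted spot compositions
#'
#' Compares a predicted spots x types proportion table (e.g. the output of
#' a deconvolution tool) against the directly measured composition, by
#' Pearson correlation. Three scopes are always computed and named:
#' `pooled` (one r over all spot x type entries), `per_type` (one r per
#' cell type across spots), and `per_spot` (one r per spot across types).
#' Types whose measured or predicted vector is constant get `NA` with an
#' explanatory reason. Spots present in only one table are dropped and
#' counted. When type names differ between the tables an explicit
#' `label_map` is required; no fuzzy matching is ever attempted.
#'
#' @param measured a `composition_matrix` or a spots x types proportion
#'   matrix with dimnames.
#' @param predicted spots x types matrix or data.frame (spot ids as row
#'   names or first column).
#' @param label_map optional two-column data.frame (`from`, `to`) renaming
#'   predicted type columns onto measured type names.
#' @return object of class `benchmark_report`: list with `pooled` (single
#'   r), `per_type` and `per_spot` data.frames, `n_spots_used`,
#'   `n_spots_dropped_measured`, `n_spots_dropped_predicted`.
#' @export
benchmark_predictions <- function(measured, predicted, label_map = NULL) {
  if (inherits(measured, "composition_matrix"))
    measured <- measured$proportions
  measured <- as.matrix(measured)
  if (is.data.frame(predicted)) {
    if (!is.null(predicted[["spot_id"]])) {
      rn <- as.character(predicted[["spot_id"]])
      predicted <- as.matrix(predicted[, setdiff(names(predicted),
                                                 "spot_id"), drop = FALSE])
      rownames(predicted) <- rn
    } else predicted <- as.matrix(predicted)
  }
  if (!is.null(label_map)) {
    mm <- match(colnames(predicted), label_map$from)
    hit <- !is.na(mm)
    colnames(predicted)[hit] <- label_map$to[mm[hit]]
  }
  shared_types <- intersect(colnames(measured), colnames(predicted))
  if (!length(shared_types))
    stop("no shared cell types; supply an explicit label_map",
         call. = FALSE)
  shared_spots <- intersect(rownames(measured), rownames(predicted))
  if (!length(shared_spots))
    stop("no overlapping spots between measured and predicted tables",
         call. = FALSE)
  m <- measured[shared_spots, shared_types, drop = FALSE]
  q <- predicted[shared_spots, shared_types, drop = FALSE]
  ok_rows <- !apply(is.na(m), 1, any)
  m <- m[ok_rows, , drop = FALSE]; q <- q[ok_rows, , drop = FALSE]
  safe_cor <- function(u, v) {
    if (length(u) < 2) return(list(r = NA_real_, reason = "fewer than 2 entries"))
    if (sd(u) == 0 || sd(v) == 0)
      return(list(r = NA_real_, reason = "zero variance"))
    list(r = cor(u, v), reason = "")
  }
  pooled <- safe_cor(as.vector(m), as.vector(q))
  per_type <- do.call(rbind, lapply(shared_types, function(tp) {
    s <- safe_cor(m[, tp], q[, tp])
    data.frame(type = tp, r = s$r, reason = s$reason,
               stringsAsFactors = FALSE)
  }))
  per_spot <- do.call(rbind, lapply(rownames(m), function(sp) {
    s <- safe_cor(m[sp, ], q[sp, ])
    data.frame(spot_id = sp, r = s$r, reason = s$reason,
               stringsAsFactors = FALSE)
  }))
  structure(list(
    pooled = pooled$r, pooled_reason = pooled$reason,
    per_type = per_type, per_spot = per_spot,
    n_spots_used = nrow(m),
    n_spots_dropped_measured = nrow(measured) - length(shared_spots),
    n_spots_dropped_predicted = nrow(predicted) - length(shared_spots)),
    class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf(
    "<benchmark_report> pooled r = %.4f over %d spots (dropped: %d measured-only, %d predicted-only)\n",
    x$pooled, x$n_spots_used, x$n_spots_dropped_measured,
    x$n_spots_dropped_predicted))
  invisible(x)
}
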