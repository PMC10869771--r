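#' Organ reference frame: tissue boundary plus origin
#'
#' The organ coordinate system expresses the position of a cell by its
#' normalized depth (0 at the outer boundary / capsule, 1 at a user-chosen
#' origin, e.g. the papilla center of a kidney section) and its angle around
#' that origin. The frame holds the outer boundary — a simple closed polygon
#' or an exact parametric circle — and the origin, which must lie strictly
#' inside the boundary. The origin is always supplied by the user:
#' [suggest_origin()] proposes the centroid of a named cell type but nothing
#' is ever auto-picked.
#'
#' @param boundary either a two-column vertex matrix / data.frame (an open
#'   or closed simple ring, um) or a circle given as
#'   `list(center = c(x, y), radius = R)`.
#' @param origin length-2 numeric, strictly inside the boundary.
#' @return object of class `organ_frame`.
#' @export
organ_frame <- function(boundary, origin) {
  origin <- as.numeric(origin)
  if (length(origin) != 2L || !all(is.finite(origin)))
    stop("origin must be a finite (x, y) pair", call. = FALSE)
  if (is.list(boundary) && !is.data.frame(boundary) &&
      all(c("center", "radius") %in% names(boundary))) {
    center <- as.numeric(boundary$center)
    radius <- as.numeric(boundary$radius)
    if (radius <= 0) stop("circle radius must be positive", call. = FALSE)
    if (sqrt(sum((origin - center)^2)) >= radius)
      stop("origin must lie strictly inside the boundary", call. = FALSE)
    out <- list(kind = "circle", center = center, radius = radius,
                origin = origin)
  } else {
    ring <- .assert_xy(boundary)
    if (nrow(ring) > 1 && all(ring[1, ] == ring[nrow(ring), ]))
      ring <- ring[-nrow(ring), , drop = FALSE]
    if (nrow(ring) < 3L)
      stop("boundary polygon needs at least 3 vertices", call. = FALSE)
    if (!.is_simple_polygon(ring))
      stop("boundary polygon must be simple (non-self-intersecting)",
           call. = FALSE)
    if (.polygon_area(ring) < 0) ring <- ring[nrow(ring):1, , drop = FALSE]
    if (!.point_in_polygon(origin[1], origin[2], ring))
      stop("origin must lie strictly inside the boundary", call. = FALSE)
    out <- list(kind = "polygon", ring = ring, origin = origin)
  }
  structure(out, class = "organ_frame")
}

#' @export
print.organ_frame <- function(x, ...) {
  if (x$kind == "circle")
    cat(sprintf("<organ_frame> circle r = %g at (%g, %g), origin (%g, %g)\n",
                x$radius, x$center[1], x$center[2], x$origin[1], x$origin[2]))
  else
    cat(sprintf("<organ_frame> polygon with %d vertices, origin (%g, %g)\n",
                nrow(x$ring), x$origin[1], x$origin[2]))
  invisible(x)
}

# Shoelace signed area of an open ring (positive = counterclockwise).
.polygon_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# Even-odd crossing test for a single point against an open ring.
.point_in_polygon <- function(px, py, ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  j <- c(n, seq_len(n - 1L))
  cross <- ((y > py) != (y[j] > py)) &
    (px < (x[j] - x) * (py - y) / (y[j] - y) + x)
  sum(cross) %% 2L == 1L
}

#' Point-in-polygon test
#' @param points two-column matrix or data.frame with `x`, `y`.
#' @param ring open simple ring (two-column matrix).
#' @return logical vector (even-odd rule; boundary points implementation-
#'   defined at machine precision).
#' @export
points_in_polygon <- function(points, ring) {
  p <- .assert_xy(points)
  ring <- .assert_xy(ring)
  vapply(seq_len(nrow(p)),
         function(i) .point_in_polygon(p[i, 1], p[i, 2], ring), logical(1))
}

# Proper-intersection test between non-adjacent edges; O(m^2), adequate for
# the boundary sizes this package handles.
.is_simple_polygon <- function(ring) {
  n <- nrow(ring)
  seg <- cbind(ring, ring[c(2:n, 1L), , drop = FALSE])
  orient <- function(ax, ay, bx, by, cx, cy)
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  for (i in seq_len(n - 1L)) {
    for (k in (i + 1L):n) {
      if (k == i + 1L || (i == 1L && k == n)) next  # adjacent edges share a vertex
      a <- seg[i, 1:2]; b <- seg[i, 3:4]; c <- seg[k, 1:2]; d <- seg[k, 3:4]
      o1 <- orient(a[1], a[2], b[1], b[2], c[1], c[2])
      o2 <- orient(a[1], a[2], b[1], b[2], d[1], d[2])
      o3 <- orient(c[1], c[2], d[1], d[2], a[1], a[2])
      o4 <- orient(c[1], c[2], d[1], d[2], b[1], b[2])
      if (o1 != o2 && o3 != o4) return(FALSE)
    }
  }
  TRUE
}

#' Suggest an origin from the centroid of a named cell type
#'
#' Convenience for picking the organ origin (e.g. the papilla center via the
#' innermost cell population): returns the centroid of the named type. The
#' caller still passes the result to [organ_frame()] explicitly.
#'
#' @param scs a [spatial_cell_set()] with a `type` column.
#' @param type cell-type name.
#' @return length-2 numeric `c(x, y)`.
#' @export
suggest_origin <- function(scs, type) {
  cells <- if (inherits(scs, "spatial_cell_set")) scs$cells else scs
  sel <- cells$type == type
  if (!any(sel, na.rm = TRUE))
    stop("no cells of type `", type, "`", call. = FALSE)
  c(mean(cells$x[sel], na.rm = TRUE), mean(cells$y[sel], na.rm = TRUE))
}

#' Estimate the tissue boundary of a point cloud (alpha shape)
#'
#' Computes the outer ring of the alpha shape of the points: an edge between
#' two points at distance <= 2*alpha is a boundary edge when one of the two
#' discs of radius alpha through both points is empty of other points. With
#' `alpha = Inf` the empty-disc test degenerates to the half-plane test and
#' the result is exactly the convex hull. If the requested alpha produces a
#' broken or overly tight ring (a ring is required to enclose at least 99%
#' of the points), alpha is grown by 1.5x and the estimate retried; the
#' convex hull is the final fallback (with a warning).
#'
#' @param points two-column matrix or data.frame with `x`, `y` (um).
#' @param alpha disc radius (um). Default: 3x the median nearest-neighbor
#'   spacing of the points — scale-adaptive and overridable.
#' @return two-column matrix: counterclockwise open ring, with attributes
#'   `"alpha"` (value actually used) and `"coverage"` (fraction of points
#'   enclosed).
#' @export
estimate_boundary <- function(points, alpha = NULL) {
  p <- unique(.assert_xy(points))
  if (nrow(p) < 3L)
    stop("boundary estimation needs at least 3 distinct points",
         call. = FALSE)
  hull_idx <- chull(p)
  if (length(hull_idx) < 3L)
    stop("points are collinear; boundary undefined", call. = FALSE)
  hull <- p[rev(hull_idx), , drop = FALSE]   # chull is clockwise; reverse
  if (is.null(alpha)) {
    nn <- .nearest_among(p, p, exclude_index = seq_len(nrow(p)))
    alpha <- 3 * median(nn$dist)
  }
  if (!is.finite(alpha)) {
    attr(hull, "alpha") <- Inf
    attr(hull, "coverage") <- 1
    return(hull)
  }
  for (try in 1:6) {
    ring <- .alpha_ring(p, alpha)
    if (!is.null(ring)) {
      inside <- points_in_polygon(p, ring)
      on_ring <- paste(p[, 1], p[, 2]) %in% paste(ring[, 1], ring[, 2])
      coverage <- mean(inside | on_ring)
      if (coverage >= 0.99) {
        if (.polygon_area(ring) < 0) ring <- ring[nrow(ring):1, , drop = FALSE]
        attr(ring, "alpha") <- alpha
        attr(ring, "coverage") <- coverage
        return(ring)
      }
    }
    alpha <- alpha * 1.5
  }
  warning("alpha-shape estimation fell back to the convex hull",
          call. = FALSE)
  attr(hull, "alpha") <- Inf
  attr(hull, "coverage") <- 1
  hull
}

# Boundary edges of the alpha shape via the empty-disc test, assembled into
# the outer ring; returns NULL when no clean single ring exists at this
# alpha. Candidate edges and disc-emptiness checks are restricted with a
# uniform grid hash of cell size 2*alpha.
.alpha_ring <- function(p, alpha) {
  n <- nrow(p)
  cs <- 2 * alpha
  gx <- floor(p[, 1] / cs); gy <- floor(p[, 2] / cs)
  key <- paste(gx, gy)
  cell_of <- split(seq_len(n), key)
  neighbors <- function(i) {
    ks <- as.vector(outer(gx[i] + (-1:1), gy[i] + (-1:1), paste))
    unlist(cell_of[ks], use.names = FALSE)
  }
  a2 <- alpha^2
  edges <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- neighbors(i)
    cand <- cand[cand > i]
    if (!length(cand)) next
    dx <- p[cand, 1] - p[i, 1]; dy <- p[cand, 2] - p[i, 2]
    d2 <- dx * dx + dy * dy
    cand <- cand[d2 <= 4 * a2 & d2 > 0]
    if (!length(cand)) next
    keep <- logical(length(cand))
    near_i <- neighbors(i)
    for (k in seq_along(cand)) {
      j <- cand[k]
      mx <- (p[i, 1] + p[j, 1]) / 2; my <- (p[i, 2] + p[j, 2]) / 2
      ex <- p[j, 1] - p[i, 1]; ey <- p[j, 2] - p[i, 2]
      el <- sqrt(ex^2 + ey^2)
      h <- sqrt(max(a2 - (el / 2)^2, 0))
      # the two disc centers at distance h from the midpoint, perpendicular
      cxs <- mx + c(-1, 1) * h * (-ey / el)
      cys <- my + c(-1, 1) * h * (ex / el)
      others <- setdiff(union(near_i, neighbors(j)), c(i, j))
      empty <- vapply(1:2, function(s) {
        if (!length(others)) return(TRUE)
        dd <- (p[others, 1] - cxs[s])^2 + (p[others, 2] - cys[s])^2
        all(dd >= a2 * (1 - 1e-9))
      }, logical(1))
      keep[k] <- any(empty)
    }
    edges[[i]] <- cand[keep]
  }
  ei <- rep(seq_len(n), lengths(edges))
  ej <- unlist(edges, use.names = FALSE)
  if (length(ei) < 3L) return(NULL)
  # walk the boundary graph; every vertex on a clean ring has degree 2
  adj <- split(c(ej, ei), c(ei, ej))
  deg <- lengths(adj)
  verts <- as.integer(names(adj))
  if (any(deg != 2L)) return(NULL)
  start <- verts[which.min(p[verts, 1])]
  ring_idx <- integer(0)
  prev <- NA_integer_; cur <- start
  repeat {
    ring_idx <- c(ring_idx, cur)
    nx <- adj[[as.character(cur)]]
    nxt <- if (is.na(prev)) nx[1] else nx[nx != prev][1]
    if (is.na(nxt)) return(NULL)
    prev <- cur; cur <- nxt
    if (cur == start) break
    if (length(ring_idx) > length(verts)) return(NULL)
  }
  if (length(ring_idx) < length(verts)) return(NULL)  # multiple components
  p[ring_idx, , drop = FALSE]
}

#' Transform points into organ coordinates (depth, angle)
#'
#' For each point p, the ray from the origin through p is cast to its first
#' boundary intersection b; the depth is `|p - b| / |origin - b|`, i.e. 0 on
#' the boundary and 1 at the origin, and the angle is the inclination of
#' p - origin with respect to the positive x axis, in (-pi, pi]. A point at
#' the origin gets depth 1 and angle 0 by convention. Points outside the
#' boundary are clamped to depth 0 and flagged in the `outside` column.
#'
#' `method = "nearest"` instead uses the boundary point nearest to p, with
#' depth `|p - b| / |origin - b|` for that b; it is provided for comparison
#' and does not share the ray method's guarantees.
#'
#' @param points two-column matrix or data.frame with `x`, `y`.
#' @param frame an [organ_frame()].
#' @param method `"ray"` (default) or `"nearest"`.
#' @return data.frame with columns `depth` (in `[0, 1]`), `angle`
#'   (radians in `(-pi, pi]`), `outside` (logical).
#' @examples
#' fr <- organ_frame(list(center = c(0, 0), radius = 1), origin = c(0, 0))
#' organ_transform(cbind(0.25, 0), fr)$depth  # 0.75
#' @export
organ_transform <- function(points, frame, method = c("ray", "nearest")) {
  method <- match.arg(method)
  stopifnot(inherits(frame, "organ_frame"))
  p <- .assert_xy(points)
  o <- frame$origin
  dx <- p[, 1] - o[1]; dy <- p[, 2] - o[2]
  r <- sqrt(dx^2 + dy^2)
  angle <- ifelse(r == 0, 0, atan2(dy, dx))
  if (frame$kind == "circle") {
    if (method == "nearest") {
      # nearest boundary point lies on the ray through the circle center
      cx <- p[, 1] - frame$center[1]; cy <- p[, 2] - frame$center[2]
      rc <- sqrt(cx^2 + cy^2)
      bx <- frame$center[1] + ifelse(rc == 0, frame$radius, cx / rc * frame$radius)
      by <- frame$center[2] + ifelse(rc == 0, 0, cy / rc * frame$radius)
      num <- sqrt((p[, 1] - bx)^2 + (p[, 2] - by)^2)
      den <- sqrt((o[1] - bx)^2 + (o[2] - by)^2)
      depth <- ifelse(r == 0, 1, num / den)
      outside <- rc > frame$radius
    } else {
      # first ray/circle intersection: t along the unit ray direction
      oc <- o - frame$center
      ux <- ifelse(r == 0, 1, dx / r); uy <- ifelse(r == 0, 0, dy / r)
      b <- ux * oc[1] + uy * oc[2]
      t <- -b + sqrt(pmax(b^2 - (sum(oc^2) - frame$radius^2), 0))
      outside <- r > t
      depth <- ifelse(r == 0, 1, 1 - r / t)
    }
  } else {
    ring <- frame$ring
    m <- nrow(ring)
    ax <- ring[, 1]; ay <- ring[, 2]
    bx <- ring[c(2:m, 1L), 1]; by <- ring[c(2:m, 1L), 2]
    ex <- bx - ax; ey <- by - ay
    if (method == "nearest") {
      res <- vapply(seq_len(nrow(p)), function(i) {
        if (r[i] == 0) return(c(1, FALSE))
        tt <- pmin(pmax(((p[i, 1] - ax) * ex + (p[i, 2] - ay) * ey) /
                          (ex^2 + ey^2), 0), 1)
        qx <- ax + tt * ex; qy <- ay + tt * ey
        dd <- (p[i, 1] - qx)^2 + (p[i, 2] - qy)^2
        k <- which.min(dd)
        den <- sqrt((o[1] - qx[k])^2 + (o[2] - qy[k])^2)
        c(sqrt(dd[k]) / den, !.point_in_polygon(p[i, 1], p[i, 2], ring))
      }, numeric(2))
      depth <- res[1, ]; outside <- as.logical(res[2, ])
      depth[outside] <- 0
    } else {
      res <- vapply(seq_len(nrow(p)), function(i) {
        if (r[i] == 0) return(c(1, FALSE))
        # ray o + t*(p-o); edge a + u*e, u in [0, 1): each vertex counted once
        den <- ex * dy[i] - ey * dx[i]
        u <- ifelse(abs(den) < .Machine$double.xmin, NA_real_,
                    (dx[i] * (ay - o[2]) - dy[i] * (ax - o[1])) / den)
        t <- if (abs(dx[i]) >= abs(dy[i])) (ax + u * ex - o[1]) / dx[i]
             else (ay + u * ey - o[2]) / dy[i]
        ok <- !is.na(u) & u >= 0 & u < 1 & t > 0
        if (!any(ok)) return(c(0, TRUE))
        tstar <- min(t[ok])
        c(max(1 - 1 / tstar, 0), tstar < 1 - 1e-12)
      }, numeric(2))
      depth <- res[1, ]; outside <- as.logical(res[2, ])
      depth[outside] <- 0
    }
  }
  depth <- pmin(pmax(depth, 0), 1)
  n_out <- sum(outside)
  out <- data.frame(depth = depth, angle = angle, outside = outside)
  attr(out, "n_outside") <- n_out
  out
}

#' Depth-binned composition profile
#'
#' Bins depth values into equal-width bins over `[0, 1]` and tabulates, per
#' bin, the count and within-bin proportion of each category (cell type or
#' gene). Empty bins are reported with count 0 and proportion `NA` — they
#' never propagate NaN downstream.
#'
#' @param depth numeric depth values in `[0, 1]` (e.g. from
#'   [organ_transform()]).
#' @param category parallel vector of category labels.
#' @param n_bins number of equal-width depth bins (>= 1).
#' @return object of class `depth_profile`: a long data.frame with columns
#'   `bin`, `depth_lo`, `depth_hi`, `category`, `count`, `proportion`, plus
#'   attribute `"breaks"`.
#' @export
depth_profile <- function(depth, category, n_bins = 10L) {
  if (n_bins < 1L) stop("n_bins must be >= 1", call. = FALSE)
  if (length(depth) != length(category))
    stop("depth and category lengths differ", call. = FALSE)
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  bin <- findInterval(depth, breaks, rightmost.closed = TRUE)
  bin <- pmin(pmax(bin, 1L), n_bins)
  cats <- sort(unique(as.character(category)))
  tab <- table(factor(bin, levels = seq_len(n_bins)),
               factor(as.character(category), levels = cats))
  totals <- rowSums(tab)
  prop <- sweep(tab, 1, totals, "/")
  prop[totals == 0, ] <- NA_real_
  out <- data.frame(
    bin = rep(seq_len(n_bins), times = length(cats)),
    depth_lo = rep(breaks[-length(breaks)], times = length(cats)),
    depth_hi = rep(breaks[-1], times = length(cats)),
    category = rep(cats, each = n_bins),
    count = as.vector(tab),
    proportion = as.vector(prop),
    stringsAsFactors = FALSE)
  attr(out, "breaks") <- breaks
  class(out) <- c("depth_profile", "data.frame")
  out
}
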