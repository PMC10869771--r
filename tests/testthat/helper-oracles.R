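# Independent brute-force oracles used to check the package's operations.
# These deliberately share no code with the implementation paths they test.

# Per-cell modal molecule-cluster label by explicit histogram, ties broken
# lexicographically.
oracle_majority <- function(transcripts, ids, unlabeled = "unlabeled") {
  out <- setNames(rep(unlabeled, length(ids)), as.character(ids))
  for (id in ids) {
    v <- transcripts$molecule_cluster[transcripts$cell_id == id &
                                        transcripts$cell_id > 0]
    v <- v[!is.na(v)]
    if (!length(v)) next
    counts <- vapply(unique(v), function(u) sum(v == u), integer(1))
    best <- names(counts)[counts == max(counts)]
    out[as.character(id)] <- sort(best)[1]
  }
  out
}

# All-pairs nearest distance from each row of `a` to rows of `b`.
oracle_nearest <- function(a, b, self = FALSE) {
  vapply(seq_len(nrow(a)), function(i) {
    d <- sqrt((b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2)
    if (self) d[i] <- Inf
    min(d)
  }, numeric(1))
}

# Count of unordered cell pairs of each type pair within `radius`, by full
# O(n^2) enumeration. Returns a named vector "A|B" (A <= B).
oracle_pair_counts <- function(x, y, type, radius) {
  n <- length(x)
  out <- new.env()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if ((x[i] - x[j])^2 + (y[i] - y[j])^2 <= radius^2) {
        key <- paste(sort(c(type[i], type[j])), collapse = "|")
        out[[key]] <- (if (is.null(out[[key]])) 0L else out[[key]]) + 1L
      }
    }
  }
  unlist(as.list(out))
}

# Shoelace polygon area (absolute).
oracle_polygon_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y) / 2)
}

# Even-odd point-in-polygon, written independently (angle-sum free form).
oracle_in_polygon <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

# Small random cell table helper.
random_cells <- function(n, types, extent = 1000, seed = 1) {
  spatialniche:::with_seed(seed, data.frame(
    cell_id = seq_len(n),
    x = runif(n, 0, extent), y = runif(n, 0, extent),
    type = sample(types, n, replace = TRUE),
    stringsAsFactors = FALSE))
}

# CSR two-type fixture used for enrichment calibration.
csr_two_types <- function(n_per_type = 500, extent = 2000, seed = 1) {
  spatialniche:::with_seed(seed, data.frame(
    x = runif(2 * n_per_type, 0, extent),
    y = runif(2 * n_per_type, 0, extent),
    type = rep(c("A", "B"), each = n_per_type),
    stringsAsFactors = FALSE))
}

cli_script <- function() {
  system.file("cli", "spatialniche", package = "spatialniche")
}

run_cli <- function(...) {
  res <- suppressWarnings(system2("Rscript", c(cli_script(), ...),
                                  stdout = TRUE, stderr = TRUE))
  list(status = attr(res, "status") %||% 0L, output = res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
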