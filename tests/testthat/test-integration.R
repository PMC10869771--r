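test_that("similarity fit: identity landmarks give the identity with zero residual", {
  src <- cbind(c(0, 4, 1, -2), c(0, 0, 3, 2))
  tf <- fit_similarity_transform(src, src)
  expect_equal(tf$theta, 0, tolerance = 1e-12)
  expect_equal(tf$scale, 1, tolerance = 1e-12)
  expect_equal(c(tf$tx, tf$ty), c(0, 0), tolerance = 1e-12)
  expect_equal(attr(tf, "rms"), 0, tolerance = 1e-12)
})

test_that("similarity fit recovers a known transform to 1e-6", {
  truth <- transform2d(theta = 30 * pi / 180, scale = 1.2, tx = 10, ty = -5)
  src <- cbind(c(0, 10, 3, -6, 4), c(0, 2, 8, 5, -7))
  dst <- apply_transform(truth, src)
  tf <- fit_similarity_transform(src, dst)
  expect_equal(tf$theta, truth$theta, tolerance = 1e-6)
  expect_equal(tf$scale, truth$scale, tolerance = 1e-6)
  expect_equal(tf$tx, truth$tx, tolerance = 1e-6)
  expect_equal(tf$ty, truth$ty, tolerance = 1e-6)
  expect_lt(attr(tf, "rms"), 1e-6)
  # transform round-trip: applying the fit reproduces the destinations
  expect_equal(apply_transform(tf, src), dst, tolerance = 1e-9)
})

test_that("rigid fit constrains scale to 1; reflected landmarks are rejected", {
  truth <- transform2d(theta = -0.4, scale = 1, tx = 3, ty = 9)
  src <- cbind(c(0, 5, -2), c(1, 4, 6))
  tf <- fit_similarity_transform(src, apply_transform(truth, src),
                                 allow_scale = FALSE)
  expect_equal(tf$scale, 1)
  expect_equal(tf$theta, truth$theta, tolerance = 1e-9)

  mirrored <- cbind(-src[, 1], src[, 2])
  expect_error(fit_similarity_transform(src, mirrored), "reflection")
  expect_error(fit_similarity_transform(cbind(c(1, 1), c(2, 2)),
                                        cbind(c(0, 1), c(0, 1))),
               "coincide")
  expect_error(fit_similarity_transform(src[1:2, ], src), "lengths")
})

test_that("transform algebra: inverse and composition round-trip", {
  tf <- transform2d(theta = 0.8, scale = 1.7, tx = -4, ty = 11)
  p <- cbind(c(1, -3, 0.5), c(2, 0, -6))
  expect_equal(apply_transform(invert_transform(tf), apply_transform(tf, p)),
               p, ignore_attr = TRUE, tolerance = 1e-12)
  tf2 <- transform2d(theta = -0.3, scale = 0.5, tx = 2, ty = 2)
  expect_equal(apply_transform(compose_transforms(tf2, tf), p),
               apply_transform(tf2, apply_transform(tf, p)),
               tolerance = 1e-12)
  expect_error(transform2d(scale = -1), "positive")
})

test_that("transforms serialize to JSON and back", {
  tf <- transform2d(theta = 0.51, scale = 1.23, tx = 10.25, ty = -5.5)
  f <- withr::local_tempfile(fileext = ".json")
  write_transform_json(tf, f)
  back <- read_transform_json(f)
  expect_equal(unclass(back), unclass(tf))
})

test_that("crop_region agrees with point-in-region oracles", {
  cells <- random_cells(200, "T", extent = 100, seed = 30)
  scs <- spatial_cell_set(cells)
  # full-extent bbox is the identity
  full <- crop_region(scs, bbox = c(0, 0, 100, 100))
  expect_equal(full$cells, cells, ignore_attr = TRUE)
  # left half of the extent
  half <- crop_region(scs, bbox = c(0, 0, 50, 100))
  expect_setequal(half$cells$cell_id, cells$cell_id[cells$x <= 50])
  # polygon region vs an independent even-odd oracle
  tri <- rbind(c(0, 0), c(100, 0), c(0, 100))
  got <- crop_region(scs, polygon = tri)
  want <- vapply(seq_len(nrow(cells)),
                 function(i) oracle_in_polygon(cells$x[i], cells$y[i], tri),
                 logical(1))
  expect_setequal(got$cells$cell_id, cells$cell_id[want])
  expect_warning(crop_region(scs, bbox = c(500, 500, 600, 600)), "no cells")
  expect_error(crop_region(scs), "exactly one")
})

test_that("spot grids validate geometry and crop like cells", {
  expect_error(spot_grid(1:3, 1:3, 1:3, diameter = 60, pitch = 50),
               "exceeds pitch")
  expect_error(spot_grid(c(1, 1), 1:2, 1:2, diameter = 55, pitch = 100),
               "unique")
  g <- spot_grid(sprintf("s%02d", 1:9), rep(1:3, 3), rep(1:3, each = 3),
                 diameter = 0.5, pitch = 1)
  cropped <- crop_region(g, bbox = c(1, 1, 2, 3))
  expect_equal(nrow(cropped$spots), 6)
  expect_s3_class(cropped, "spot_grid")
})

test_that("nearest-spot assignment: exact hits, id tie-break, oracle agreement", {
  g <- spot_grid(c("s3", "s7"), x = c(0, 10), y = c(0, 0),
                 diameter = 5, pitch = 10)
  expect_equal(assign_to_spots(cbind(0, 0), g), "s3", ignore_attr = TRUE)
  # equidistant point resolves to the smallest spot id
  expect_equal(assign_to_spots(cbind(5, 3), g), "s3", ignore_attr = TRUE)

  tissue <- simulate_tissue(tissue_config(radius = 400), seed = 31)
  panel <- simulate_spot_grid(tissue, pitch = 80, diameter = 55)
  pts <- spatialniche:::with_seed(32, cbind(runif(100, -400, 400),
                                            runif(100, -400, 400)))
  got <- assign_to_spots(pts, panel$grid)
  sp <- panel$grid$spots
  want <- vapply(seq_len(nrow(pts)), function(i) {
    d <- (sp$x - pts[i, 1])^2 + (sp$y - pts[i, 2])^2
    sp$spot_id[which.min(d)]
  }, character(1))
  expect_equal(unname(got), want, ignore_attr = TRUE)
})

test_that("assignment honors max_distance and joint rigid invariance", {
  g <- spot_grid(1:2, x = c(0, 100), y = c(0, 0), diameter = 10, pitch = 100)
  ids <- assign_to_spots(rbind(c(1, 0), c(49, 0)), g, max_distance = 20)
  expect_equal(unname(ids), c("1", NA), ignore_attr = TRUE)
  expect_equal(attr(ids, "n_unassigned"), 1)
  expect_error(assign_to_spots(cbind(0, 0),
                               spot_grid(character(0), numeric(0),
                                         numeric(0), 55, 100)), "empty")
  # moving points and grid by the same rigid transform leaves assignments fixed
  tissue <- simulate_tissue(tissue_config(radius = 300), seed = 33)
  panel <- simulate_spot_grid(tissue, pitch = 90)
  pts <- as.matrix(tissue$scs$cells[, c("x", "y")])
  a0 <- assign_to_spots(pts, panel$grid)
  tf <- transform2d(theta = 0.6, tx = 40, ty = -25)
  g2 <- panel$grid
  g2$spots[, c("x", "y")] <- apply_transform(tf, g2$spots[, c("x", "y")])
  a1 <- assign_to_spots(apply_transform(tf, pts), g2)
  expect_equal(a1, a0)
})

test_that("spot composition normalizes counts and flags empty spots", {
  assignments <- c("s1", "s1", "s1", "s1", NA)
  types <- c("PT", "PT", "PT", "TAL", "PT")
  g <- spot_grid(c("s1", "s2"), x = c(0, 100), y = c(0, 0),
                 diameter = 55, pitch = 100)
  comp <- spot_composition(assignments, types, grid = g)
  expect_equal(comp$proportions["s1", c("PT", "TAL")],
               c(PT = 0.75, TAL = 0.25))
  expect_true(comp$empty["s2"])
  expect_true(all(is.na(comp$proportions["s2", ])))
  expect_equal(sum(comp$counts), 4)   # NA assignment dropped
  expect_error(spot_composition(c("s1"), c("PT", "TAL")), "lengths")
})

test_that("registration + binning recovers the generator's composition exactly", {
  tissue <- simulate_tissue(tissue_config(radius = 500), seed = 34)
  truth_tf <- transform2d(theta = 15 * pi / 180, scale = 1, tx = 30, ty = 20)
  panel <- simulate_spot_grid(tissue, pitch = 100, diameter = 55,
                              transform = truth_tf)
  fit <- fit_similarity_transform(
    cbind(panel$landmarks$x_src, panel$landmarks$y_src),
    cbind(panel$landmarks$x_dst, panel$landmarks$y_dst))
  moved <- apply_transform(fit, tissue$scs$cells[, c("x", "y")])
  ids <- assign_to_spots(moved, panel$grid)
  comp <- spot_composition(ids, tissue$scs$cells$type, grid = panel$grid)
  expect_identical(comp$counts, panel$truth_composition$counts)
  # composition conservation: every cell lands in exactly one spot
  expect_equal(sum(comp$counts), nrow(tissue$scs$cells))
})

test_that("benchmarking: identity gives r = 1, shuffles match a direct oracle", {
  tissue <- simulate_tissue(tissue_config(radius = 400), seed = 35)
  panel <- simulate_spot_grid(tissue, pitch = 100)
  comp <- panel$truth_composition
  measured <- comp$proportions[!comp$empty, , drop = FALSE]
  rep <- benchmark_predictions(comp, measured)
  expect_equal(rep$pooled, 1)
  expect_true(all(abs(rep$per_type$r[rep$per_type$reason == ""] - 1) < 1e-12))

  shuffled <- spatialniche:::with_seed(
    36, measured[sample(nrow(measured)), , drop = FALSE])
  rownames(shuffled) <- rownames(measured)
  rep2 <- benchmark_predictions(comp, shuffled)
  expect_equal(rep2$pooled, cor(as.vector(measured), as.vector(shuffled)))
})

test_that("benchmarking handles constant columns, label maps, and disjoint spots", {
  measured <- matrix(c(0.2, 0.5, 0.9, 0.8, 0.5, 0.1), ncol = 2,
                     dimnames = list(c("s1", "s2", "s3"), c("PT", "TAL")))
  pred <- matrix(c(0.3, 0.3, 0.3, 0.7, 0.7, 0.7), ncol = 2,
                 dimnames = list(c("s1", "s2", "s3"),
                                 c("prox_tubule", "thick_limb")))
  expect_error(benchmark_predictions(measured, pred), "label_map")
  map <- data.frame(from = c("prox_tubule", "thick_limb"),
                    to = c("PT", "TAL"))
  rep <- benchmark_predictions(measured, pred, label_map = map)
  expect_true(all(is.na(rep$per_type$r)))
  expect_match(rep$per_type$reason[1], "zero variance")

  pred2 <- measured; rownames(pred2) <- c("x1", "x2", "x3")
  expect_error(benchmark_predictions(measured, pred2), "overlapping")
  # partially overlapping spots are dropped and counted
  pred3 <- measured[1:2, , drop = FALSE] + 0.01
  rep3 <- benchmark_predictions(measured, pred3)
  expect_equal(rep3$n_spots_used, 2)
  expect_equal(rep3$n_spots_dropped_measured, 1)
})

test_that("spot positions and composition tables round-trip as CSV", {
  tissue <- simulate_tissue(tissue_config(radius = 300), seed = 37)
  panel <- simulate_spot_grid(tissue, pitch = 100)
  f <- withr::local_tempfile(fileext = ".csv")
  write_spot_positions(panel$grid, f)
  back <- read_spot_positions(f, diameter = 55, pitch = 100)
  expect_equal(back$spots$spot_id, panel$grid$spots$spot_id)
  expect_equal(back$spots$x, panel$grid$spots$x, tolerance = 1e-12)
  expect_equal(back$spots$in_tissue, panel$grid$spots$in_tissue)

  g <- withr::local_tempfile(fileext = ".csv")
  write_composition_csv(panel$truth_composition, g, what = "counts")
  m <- read_composition_csv(g)
  expect_equal(unname(m), unname(panel$truth_composition$counts))
})
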