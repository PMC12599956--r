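test_that("randomization preserves sizes, ids and fixed border pixels", {
  g <- generate_tissue(synth_spec(n_cells = 200, width = 160, height = 160, seed = 3))
  tis <- g$tissue
  rs <- randomization_spec(n_random = 3, seed = 7)
  r1 <- randomize_tissue(tis, rs, 1)

  # per-cell area correlation source vs randomization
  a0 <- lengths(giantcell:::label_pixels(tis$labels, tis$cell_ids))
  a1 <- lengths(giantcell:::label_pixels(r1$labels, r1$cell_ids))
  expect_gte(cor(a0, a1), 0.95)

  # same cell ids, exact pixel identity for every fixed border cell
  expect_identical(r1$cell_ids, tis$cell_ids)
  for (id in tis$border_ids)
    expect_identical(which(r1$labels == id), which(tis$labels == id))

  # determinism: (tissue, spec, k) fully determines the member
  expect_identical(randomize_tissue(tis, rs, 2)$labels,
                   randomize_tissue(tis, rs, 2)$labels)
  expect_false(identical(randomize_tissue(tis, rs, 1)$labels,
                         randomize_tissue(tis, rs, 2)$labels))
})

test_that("sepal mode constrains orientation changes to +-pi/6", {
  g <- generate_tissue(synth_spec(n_cells = 80, width = 128, height = 128,
                                  anisotropy = 2, seed = 5))
  rs <- randomization_spec(n_random = 1, orient_range = c(-pi / 6, pi / 6), seed = 2)
  r1 <- randomize_tissue(g$tissue, rs, 1)
  f0 <- compute_features(g$tissue, visibility = FALSE)
  f1 <- compute_features(r1, visibility = FALSE)
  idx <- match(f0$id, f1$id)
  elong <- f0$major_axis / f0$minor_axis > 1.8 & !f0$is_border
  dth <- abs(f1$orientation_rad[idx] - f0$orientation_rad)
  dth <- pmin(dth, pi - dth)   # orientation is defined modulo pi
  # rasterization adds estimator noise; allow a modest margin
  expect_lt(quantile(dth[elong], 0.9), pi / 6 + 0.12)
})

test_that("reconstruction is the identity in the zero-noise limit", {
  g <- small_synth(seed = 19)
  rs <- randomization_spec(position_noise = 0, seed = 1)
  rec <- reconstruct_tissue(g$tissue, rs, 1)
  expect_identical(rec$labels, g$tissue$labels)
})

test_that("reconstruction centroid displacement is bounded", {
  g <- small_synth(seed = 23)
  rs <- randomization_spec(position_noise = 5, seed = 4)
  rec <- reconstruct_tissue(g$tissue, rs, 1)
  f0 <- compute_features(g$tissue, visibility = FALSE)
  f1 <- compute_features(rec, visibility = FALSE)
  idx <- match(f0$id, f1$id)
  d <- sqrt((f1$centroid_x[idx] - f0$centroid_x)^2 +
            (f1$centroid_y[idx] - f0$centroid_y)^2)
  # anchor noise is at most 5*sqrt(2) um; competition can shift centroids
  # by a further few pixels
  expect_lt(max(d[!f0$is_border]), 5 * sqrt(2) + 3)
})

test_that("reconstruction approximately preserves giant contacts", {
  # pooled over fixtures and ensemble members: a single fixture carries
  # only ~12 giant contacts, so per-fixture ratios fluctuate by ~1/12
  # from sampling alone; the preservation property concerns the mean
  rel <- vapply(c(29, 31, 47), function(sd) {
    g <- generate_tissue(synth_spec(n_cells = 150, width = 128, height = 128,
                                    seed = sd))
    pp <- plant_pattern(g$tissue, g$table, "clustered", k = 16, seed = 2,
                        boost = 10, area_floor = 50)
    n0 <- sum(giantcell:::giant_counts_raster(g$tissue, pp$giants)) / 2
    rs <- randomization_spec(position_noise = 5, seed = 9)
    nr <- vapply(1:8, function(k) {
      rec <- reconstruct_tissue(g$tissue, rs, k)
      sum(giantcell:::giant_counts_raster(rec, pp$giants)) / 2
    }, 0)
    (mean(nr) - n0) / n0
  }, 0)
  expect_lt(abs(mean(rel)), 0.10)
})

test_that("oversegmentation is a partition with the expected granularity", {
  g <- small_synth(seed = 31, n_cells = 40, wh = 80)
  os <- oversegment(g$tissue, fragment_radius = 3)
  # union of fragments = source pixels, fragments disjoint (a relabeling)
  expect_identical(os$tissue$labels > 0L, g$tissue$labels > 0L)
  for (fid in os$tissue$cell_ids) {
    parent <- os$parent[[as.character(fid)]]
    expect_true(all(g$tissue$labels[os$tissue$labels == fid] == parent))
  }
  # huge radius -> partition is the identity
  os2 <- oversegment(g$tissue, fragment_radius = 200)
  expect_equal(length(os2$tissue$cell_ids), length(g$tissue$cell_ids))
  expect_error(oversegment(g$tissue, fragment_radius = 0.5), "exceed")
})

test_that("fragment count of a disk matches area/(pi r^2) within factor 2", {
  m <- disk_mask(28)
  tis <- labeled_tissue(m, 1)
  set.seed(6)
  os <- oversegment(tis, fragment_radius = 4)
  nfrag <- length(os$tissue$cell_ids)
  expected <- sum(m) / (pi * 16)
  expect_gt(nfrag, expected / 2)
  expect_lt(nfrag, expected * 2)
})

test_that("cut_and_merge realizes giants of the requested number and size", {
  # template of unit fragments: a 10x10 grid, every pixel its own fragment
  lab <- matrix(seq_len(100L), 10, 10)
  oseg <- list(tissue = labeled_tissue(lab, 1),
               parent = setNames(rep(1L, 100), 1:100))
  cm <- cut_and_merge(oseg, giant_areas = 5, seed = 3)
  expect_length(cm$giants, 1)
  expect_equal(sum(cm$tissue$labels == cm$giants), 5)
  # contiguity of the realized giant
  seeds <- matrix(0L, 10, 10)
  seeds[which(cm$tissue$labels == cm$giants)[1]] <- 1L
  grown <- giantcell:::cpp_fill_within(seeds, cm$tissue$labels)
  expect_equal(sum(grown == 1L), 5)

  # realistic template: counts preserved, giants disjoint, stomata excluded
  g <- generate_tissue(synth_spec(n_cells = 60, width = 96, height = 96,
                                  n_stomata = 2, seed = 41))
  os <- oversegment(g$tissue, fragment_radius = 3)
  stoma_ids <- g$table$id[g$table$cell_type == "stoma"]
  targets <- c(400, 300, 250)
  cm2 <- cut_and_merge(os, targets, seed = 5, exclude_parents = stoma_ids)
  expect_length(cm2$giants, 3)
  areas <- vapply(cm2$giants, function(id) sum(cm2$tissue$labels == id), 0)
  frag_max <- max(lengths(giantcell:::label_pixels(os$tissue$labels, os$tissue$cell_ids)))
  expect_true(all(areas >= sort(targets, decreasing = TRUE) - 1e-9))
  expect_true(all(areas - sort(targets, decreasing = TRUE) < frag_max))
  # no giant pixel may come from a stoma fragment
  for (id in cm2$giants)
    expect_false(any(g$tissue$labels[cm2$tissue$labels == id] %in% stoma_ids))
})
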