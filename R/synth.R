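# Synthetic segmented-tissue generator.
#
# Space-filling tessellations are grown from seed points as an Apollonius
# (additively-weighted-by-rate) partition: each pixel joins the seed with
# the smallest distance/radius ratio, radii being drawn from a log-normal
# body with an optional heavy tail. This emulates the statistical structure
# the analysis assumes (heterogeneous convex-ish cells, minority of very
# large cells, small-cell clusters around stomata) without attempting
# puzzle-piece pavement-cell morphology.

#' Specification of a synthetic tissue
#'
#' @param n_cells number of pavement-cell seeds (>= 4).
#' @param width,height raster size in pixels.
#' @param pixel_size micrometres per pixel.
#' @param area_sdlog log-sd of the log-normal body of relative cell areas.
#' @param tail_fraction fraction of cells drawn from the heavy tail.
#' @param tail_scale multiplicative area factor of tail cells.
#' @param anisotropy cell elongation factor along y (1 = isotropic).
#' @param n_stomata number of stomatal clusters (one small near-circular
#'   cell surrounded by 3-6 small neighbors).
#' @param pattern spatial arrangement of the tail (large) cells:
#'   `"random"`, `"clustered"` or `"dispersed"`.
#' @param seed RNG seed; the same spec and seed reproduce the raster
#'   bit-exactly.
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(n_cells = 150, width = 128, height = 128, pixel_size = 1,
                       area_sdlog = 0.35, tail_fraction = 0.03, tail_scale = 10,
                       anisotropy = 1, n_stomata = 0, pattern = "random",
                       seed = 1) {
  if (n_cells < 4) stop("config error: n_cells must be >= 4")
  if (width * height < 16 * n_cells)
    stop("config error: raster too small for n_cells")
  pattern <- match.arg(pattern, c("random", "clustered", "dispersed"))
  structure(list(n_cells = n_cells, width = width, height = height,
                 pixel_size = pixel_size, area_sdlog = area_sdlog,
                 tail_fraction = tail_fraction, tail_scale = tail_scale,
                 anisotropy = anisotropy, n_stomata = n_stomata,
                 pattern = pattern, seed = seed),
            class = "synth_spec")
}

# select which seeds carry tail (large-cell) radii, by seed position
select_tail_seeds <- function(xy, k, pattern) {
  n <- nrow(xy)
  if (k == 0L) return(integer(0))
  if (pattern == "random") return(sample.int(n, k))
  if (pattern == "clustered") {
    center <- xy[sample.int(n, 1L), ]
    d <- sqrt((xy[, 1] - center[1])^2 + (xy[, 2] - center[2])^2)
    return(order(d)[seq_len(k)])
  }
  # dispersed: greedy max-min distance
  sel <- sample.int(n, 1L)
  while (length(sel) < k) {
    d <- apply(xy, 1, function(p)
      min(sqrt((xy[sel, 1] - p[1])^2 + (xy[sel, 2] - p[2])^2)))
    d[sel] <- -Inf
    sel <- c(sel, which.max(d))
  }
  sel
}

#' Generate a synthetic labeled tissue
#'
#' @param spec a [synth_spec()].
#' @param visibility forwarded to [compute_features()] (off by default:
#'   the generator is called in hot loops).
#' @return list with `tissue` (a [labeled_tissue()]) and `table` (cell
#'   table with `cell_type` filled: `"stoma"` for stomatal guard-cell
#'   analogues, `"pavement"` otherwise).
#' @export
generate_tissue <- function(spec, visibility = FALSE) {
  set.seed(spec$seed)
  W <- spec$width; H <- spec$height
  n <- spec$n_cells
  # relative areas: log-normal body, heavy tail on selected seeds
  rel <- rlnorm(n, meanlog = 0, sdlog = spec$area_sdlog)
  # seed positions by dart throwing (min spacing ~ body cell radius)
  r0 <- sqrt(W * H / (pi * n))
  xy <- matrix(NA_real_, n, 2)
  placed <- 0L
  guard <- 0L
  while (placed < n && guard < 20000L) {
    guard <- guard + 1L
    p <- c(runif(1, 1, H), runif(1, 1, W))
    if (placed == 0L ||
        min((xy[seq_len(placed), 1] - p[1])^2 + (xy[seq_len(placed), 2] - p[2])^2) > (0.9 * r0)^2) {
      placed <- placed + 1L
      xy[placed, ] <- p
    }
  }
  if (placed < n) {  # relax spacing for the remainder
    xy[(placed + 1L):n, ] <- cbind(runif(n - placed, 1, H), runif(n - placed, 1, W))
  }
  n_tail <- round(spec$tail_fraction * n)
  tail_idx <- select_tail_seeds(xy, n_tail, spec$pattern)
  rel[tail_idx] <- rel[tail_idx] * spec$tail_scale
  types <- rep("pavement", n)
  # stomatal clusters: one small near-circular cell plus 3-6 small satellites
  if (spec$n_stomata > 0L) {
    med_rel <- median(rel)
    for (s in seq_len(spec$n_stomata)) {
      c0 <- c(runif(1, 0.15 * H, 0.85 * H), runif(1, 0.15 * W, 0.85 * W))
      rs <- r0 * 0.55
      nsat <- sample(3:6, 1L)
      ang <- runif(1, 0, 2 * pi) + seq(0, 2 * pi, length.out = nsat + 1L)[-(nsat + 1L)]
      sat <- cbind(c0[1] + 1.7 * rs * sin(ang), c0[2] + 1.7 * rs * cos(ang))
      xy <- rbind(xy, c0, sat)
      rel <- c(rel, med_rel * 0.30, rep(med_rel * 0.45, nsat))
      types <- c(types, "stoma", rep("pavement", nsat))
    }
  }
  ntot <- length(rel)
  rad <- sqrt(rel)
  # Apollonius growth: pixel -> argmin distance / radius
  rr <- rep(seq_len(H), times = W)
  cc <- rep(seq_len(W), each = H)
  best <- rep(Inf, W * H)
  bestid <- integer(W * H)
  for (i in seq_len(ntot)) {
    d <- sqrt((rr - xy[i, 1])^2 + ((cc - xy[i, 2]) * spec$anisotropy)^2) / rad[i]
    upd <- d < best
    best[upd] <- d[upd]
    bestid[upd] <- i
  }
  lab <- matrix(bestid, H, W)
  lab <- enforce_contiguity(lab, xy)
  tissue <- labeled_tissue(lab, spec$pixel_size)
  assert_pixel_conservation(tissue)
  tab <- compute_features(tissue, visibility = visibility)
  tab$cell_type <- types[tab$id]
  list(tissue = tissue, table = tab)
}

# keep, for every label, only the component containing the pixel nearest its
# seed; orphan pixels are reassigned to the nearest surviving label
enforce_contiguity <- function(lab, xy) {
  H <- nrow(lab)
  seeds <- matrix(0L, H, ncol(lab))
  for (i in sort(unique(lab[lab > 0L]))) {
    pos <- which(lab == i)
    pr <- (pos - 1L) %% H + 1L
    pc <- (pos - 1L) %/% H + 1L
    j <- which.min((pr - xy[i, 1])^2 + (pc - xy[i, 2])^2)
    seeds[pos[j]] <- i
  }
  grown <- cpp_fill_within(seeds, lab)
  if (any(grown == 0L)) {
    grown <- cpp_fill_nearest(grown, matrix(TRUE, H, ncol(lab)))
  }
  grown
}

#' Plant a giant-cell pattern by cell selection
#'
#' Flags `k` eligible cells as giants without altering geometry. Eligible
#' cells are non-stomatal, non-border cells with area above `area_floor`.
#' `"random"` samples uniformly; `"clustered"` samples sequentially with
#' probability boosted by factor `1 + boost` for candidates adjacent to an
#' already-selected giant (`boost = Inf` forces a single connected clump on
#' a connected tissue); `"dispersed"` rejects candidates adjacent to
#' selected giants while feasible, and returns a partial pattern with a
#' warning otherwise.
#'
#' @param tissue a [labeled_tissue()].
#' @param table its cell table.
#' @param mode `"random"`, `"clustered"` or `"dispersed"`.
#' @param k number of giants to plant.
#' @param seed RNG seed.
#' @param boost adjacency weight boost for `"clustered"`.
#' @param area_floor minimum eligible area in square micrometres.
#' @param graph optional precomputed [build_adjacency()] result.
#' @return list with `giants` (id vector) and `table` (cell table with
#'   `cell_type = "giant"` written for the selected cells).
#' @export
plant_pattern <- function(tissue, table, mode = c("random", "clustered", "dispersed"),
                          k, seed = 1, boost = 10, area_floor = 0, graph = NULL) {
  mode <- match.arg(mode)
  set.seed(seed)
  eligible <- table$id[!table$is_border &
                         (is.na(table$cell_type) | table$cell_type != "stoma") &
                         table$area_um2 > area_floor]
  if (k > length(eligible)) stop("k exceeds number of eligible cells")
  if (k == 0L) return(list(giants = integer(0), table = table))
  if (mode == "random") {
    giants <- sample(eligible, k)
  } else {
    if (is.null(graph)) graph <- build_adjacency(tissue)
    adj <- lapply(setNames(as.list(tissue$cell_ids), tissue$cell_ids),
                  function(id) graph_neighbors(graph, id))
    giants <- sample(eligible, 1L)
    while (length(giants) < k) {
      cand <- setdiff(eligible, giants)
      near <- vapply(cand, function(id) any(adj[[as.character(id)]] %in% giants), NA)
      if (mode == "clustered") {
        if (is.infinite(boost)) {
          pool <- if (any(near)) cand[near] else cand
          pick <- if (length(pool) == 1L) pool else sample(pool, 1L)
        } else {
          w <- 1 + boost * near
          pick <- if (length(cand) == 1L) cand else sample(cand, 1L, prob = w)
        }
      } else {  # dispersed
        pool <- cand[!near]
        if (length(pool) == 0L) {
          warning(sprintf("dispersed pattern infeasible beyond %d giants (requested %d)",
                          length(giants), k))
          break
        }
        pick <- if (length(pool) == 1L) pool else sample(pool, 1L)
      }
      giants <- c(giants, pick)
    }
  }
  giants <- sort(giants)
  table$cell_type[table$id %in% giants] <- "giant"
  list(giants = giants, table = table)
}
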