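# Shape- and size-preserving tissue randomization (the spatial null model).
#
# The published randomization engine's internals are not public; this module
# implements the documented behaviour with an explicit stand-in algorithm:
# each movable cell's pixel mask is rotated and re-anchored at a random free
# location (placement in descending area order, rejection sampling with an
# overlap cap), and remaining free pixels are then assigned to the nearest
# placed cell by multi-source BFS competition. Sizes and shapes are
# approximately, not exactly, preserved - mirroring the artifact profile of
# the original method (slightly more convex shapes, noisier edges).

#' Specification of a randomization ensemble
#'
#' @param n_random ensemble size (default 400).
#' @param orient_range range (radians, length 2) of the rotation applied to
#'   each cell relative to its original orientation. The default
#'   `c(-pi, pi)` shuffles orientations freely; anisotropic tissues (sepal
#'   mode) use `c(-pi/6, pi/6)` to maintain tissue anisotropy.
#' @param fix_border keep incomplete cells at the raster border fixed
#'   (cropped-image mode).
#' @param fix_background treat the background as a single fixed cell and
#'   randomize every cell, including those at the tissue edge
#'   (whole-tissue mode, used for time-resolved data).
#' @param position_noise reconstruction mode only: maximum uniform centroid
#'   noise in micrometres per axis (default 5).
#' @param overlap_cap maximum fraction of a cell's pixels that may be lost
#'   to already-placed cells before an anchor is rejected.
#' @param max_tries anchor rejection-sampling budget per cell.
#' @param anchor_mode `"uniform"` (default) samples anchors uniformly over
#'   the free region; `"permute"` shuffles cells onto a random permutation
#'   of the original cell centroids (with growing jitter on retries), so
#'   anchor density follows cell density.
#' @param smooth_iters 3x3 majority-label smoothing passes applied to the
#'   competition-filled image (the error-correction step: removes
#'   thread-like spurious contacts; off by default: the synthetic
#'   tessellations used here are already smooth-walled).
#' @param seed base seed; member `k` of the ensemble is fully determined by
#'   `(tissue, spec, k)`.
#' @return object of class `randomization_spec`.
#' @export
randomization_spec <- function(n_random = 400, orient_range = c(-pi, pi),
                               fix_border = TRUE, fix_background = FALSE,
                               position_noise = 5, overlap_cap = 0.25,
                               max_tries = 40, anchor_mode = c("uniform", "permute"),
                               smooth_iters = 0, seed = 1) {
  anchor_mode <- match.arg(anchor_mode)
  if (n_random < 1) stop("config error: n_random must be >= 1")
  if (length(orient_range) != 2 || diff(orient_range) < 0 ||
      orient_range[1] < -pi || orient_range[2] > pi)
    stop("config error: orient_range must be within (-pi, pi]")
  structure(list(n_random = n_random, orient_range = orient_range,
                 fix_border = fix_border, fix_background = fix_background,
                 position_noise = position_noise, overlap_cap = overlap_cap,
                 max_tries = max_tries, anchor_mode = anchor_mode,
                 smooth_iters = smooth_iters, seed = seed),
            class = "randomization_spec")
}

# deterministic per-member seed below 2^31
member_seed <- function(seed, k) {
  (abs(seed) %% 100000L) * 20011L + k * 7919L + 13L
}

# core placement + competition engine shared by randomize and reconstruct
place_and_fill <- function(tissue, spec, anchors = NULL, angles = NULL) {
  lab <- tissue$labels
  nr <- nrow(lab); nc <- ncol(lab)
  fixed_ids <- if (spec$fix_border) tissue$border_ids else integer(0)
  movable <- setdiff(tissue$cell_ids, fixed_ids)
  if (length(movable) == 0L) stop("no movable cells")
  px <- label_pixels(lab, movable)
  areas <- lengths(px)
  ord <- order(areas, decreasing = TRUE)

  claim <- matrix(0L, nr, nc)
  fixed_mask <- matrix(FALSE, nr, nc)
  if (length(fixed_ids)) fixed_mask[lab %in% fixed_ids] <- TRUE
  if (spec$fix_background) fixed_mask[lab == 0L] <- TRUE
  claim[fixed_mask] <- -1L

  rel <- vector("list", length(ord))
  anc <- vector("list", length(ord))
  ths <- numeric(length(ord))
  for (i in seq_along(ord)) {
    id <- movable[ord[i]]
    pos <- px[[ord[i]]]
    prr <- (pos - 1L) %% nr + 1L
    pcc <- (pos - 1L) %/% nr + 1L
    rel[[i]] <- cbind(prr - mean(prr), pcc - mean(pcc))
    anc[[i]] <- anchors[[as.character(id)]]
    ths[i] <- angles[[as.character(id)]]
  }
  claim <- cpp_place_cells(claim, rel, as.integer(movable[ord]), ths, anc,
                           spec$overlap_cap)
  filled <- cpp_fill_nearest(claim, claim > 0L)
  out <- lab
  out[!fixed_mask] <- filled[!fixed_mask]
  if (spec$smooth_iters > 0L)
    out <- cpp_majority_smooth(out, fixed_mask, as.integer(spec$smooth_iters))
  out
}

#' Generate one randomized equivalent tissue
#'
#' Member `k` of the ensemble defined by `spec`: every non-fixed cell is
#' rotated by a uniform draw from `spec$orient_range` (relative to its
#' original orientation) and re-anchored at a random free location; the
#' remaining space is re-filled by nearest-cell competition, so per-cell
#' sizes are approximately preserved. Fixed cells (image-border cells, or
#' the background in whole-tissue mode) occupy identical pixels in every
#' member.
#'
#' @param tissue a [labeled_tissue()].
#' @param spec a [randomization_spec()].
#' @param k member index (1-based); `(tissue, spec, k)` fully determines
#'   the output.
#' @return a [labeled_tissue()] with the same cell ids as the source.
#' @export
randomize_tissue <- function(tissue, spec, k = 1L) {
  set.seed(member_seed(spec$seed, k))
  lab <- tissue$labels
  nr <- nrow(lab)
  fixed_ids <- if (spec$fix_border) tissue$border_ids else integer(0)
  movable <- setdiff(tissue$cell_ids, fixed_ids)
  fixed_mask_bg <- spec$fix_background & lab == 0L
  free_pool <- which(!(lab %in% fixed_ids) & !fixed_mask_bg)
  anchors <- list(); angles <- list()
  if (identical(spec$anchor_mode, "uniform")) {
    for (id in movable) {
      pick <- free_pool[sample.int(length(free_pool), spec$max_tries, replace = TRUE)]
      anchors[[as.character(id)]] <- cbind((pick - 1L) %% nr + 1L,
                                           (pick - 1L) %/% nr + 1L)
      angles[[as.character(id)]] <- runif(1, spec$orient_range[1], spec$orient_range[2])
    }
  } else {
    px <- label_pixels(lab, movable)
    cen <- t(vapply(px, function(pos) c(mean((pos - 1L) %% nr + 1L),
                                        mean((pos - 1L) %/% nr + 1L)), c(0, 0)))
    perm <- sample.int(length(movable))
    jit <- c(0, 2^(seq_len(spec$max_tries - 1L) / 6))  # growing retry jitter (px)
    for (i in seq_along(movable)) {
      base <- cen[perm[i], ]
      anchors[[as.character(movable[i])]] <-
        cbind(base[1] + jit * runif(spec$max_tries, -1, 1),
              base[2] + jit * runif(spec$max_tries, -1, 1))
      angles[[as.character(movable[i])]] <- runif(1, spec$orient_range[1], spec$orient_range[2])
    }
  }
  out <- labeled_tissue(place_and_fill(tissue, spec, anchors, angles),
                        tissue$pixel_size)
  assert_pixel_conservation(out)
  stopifnot(identical(out$cell_ids, tissue$cell_ids))
  out
}

#' Reconstruct a tissue through the randomization engine
#'
#' Control for shape artifacts: identical to [randomize_tissue()] except
#' that each cell keeps its orientation and is anchored at its original
#' centroid plus uniform noise of at most `spec$position_noise` micrometres
#' per axis, so the output carries the same class of competition artifacts
#' as a randomization while preserving the spatial arrangement.
#'
#' @inheritParams randomize_tissue
#' @export
reconstruct_tissue <- function(tissue, spec, k = 1L) {
  set.seed(member_seed(spec$seed + 500000L, k))
  lab <- tissue$labels
  nr <- nrow(lab)
  fixed_ids <- if (spec$fix_border) tissue$border_ids else integer(0)
  movable <- setdiff(tissue$cell_ids, fixed_ids)
  px <- label_pixels(lab, movable)
  noise_px <- spec$position_noise / tissue$pixel_size
  anchors <- list(); angles <- list()
  for (i in seq_along(movable)) {
    id <- movable[i]
    pos <- px[[i]]
    cr <- mean((pos - 1L) %% nr + 1L)
    cc <- mean((pos - 1L) %/% nr + 1L)
    anchors[[as.character(id)]] <- cbind(cr + runif(spec$max_tries, -noise_px, noise_px),
                                         cc + runif(spec$max_tries, -noise_px, noise_px))
    angles[[as.character(id)]] <- 0
  }
  out <- labeled_tissue(place_and_fill(tissue, spec, anchors, angles),
                        tissue$pixel_size)
  assert_pixel_conservation(out)
  out
}

#' Generate a randomization ensemble
#'
#' @inheritParams randomize_tissue
#' @param reconstruct generate reconstructions instead of randomizations.
#' @return object of class `randomization_ensemble`: list with `members`
#'   (list of [labeled_tissue()]), `spec`, and `source` reference.
#' @export
randomize_ensemble <- function(tissue, spec, reconstruct = FALSE) {
  gen <- if (reconstruct) reconstruct_tissue else randomize_tissue
  members <- lapply(seq_len(spec$n_random), function(k) gen(tissue, spec, k))
  structure(list(members = members, spec = spec,
                 source_dim = dim(tissue$labels)),
            class = "randomization_ensemble")
}

#' Over-segment a tissue into small fragments
#'
#' Partitions every cell into contiguous fragments of characteristic radius
#' `fragment_radius` (geodesic Voronoi regions of a Poisson-disk sample
#' inside the cell mask; the dart-throwing spacing 1.41 r is derived from
#' the saturated random-sequential-adsorption density so that mean fragment
#' area is about pi r^2). Cells smaller than one fragment are kept whole.
#'
#' @param tissue a [labeled_tissue()].
#' @param fragment_radius characteristic fragment radius in micrometres;
#'   must exceed the pixel size.
#' @return list with `tissue` (fragment-labeled [labeled_tissue()]) and
#'   `parent` (named integer vector: fragment id -> source cell id).
#' @export
oversegment <- function(tissue, fragment_radius) {
  ps <- tissue$pixel_size
  if (fragment_radius <= ps) stop("fragment_radius must exceed pixel_size")
  r_px <- fragment_radius / ps
  d2 <- (1.41 * r_px)^2
  lab <- tissue$labels
  nr <- nrow(lab)
  px <- label_pixels(lab, tissue$cell_ids)
  seeds <- matrix(0L, nr, ncol(lab))
  parent <- integer(0)
  nxt <- 1L
  for (i in seq_along(tissue$cell_ids)) {
    pos <- sample(px[[i]])
    prr <- (pos - 1L) %% nr + 1L
    pcc <- (pos - 1L) %/% nr + 1L
    keep <- 1L
    for (j in seq_along(pos)[-1L]) {
      if (min((prr[keep] - prr[j])^2 + (pcc[keep] - pcc[j])^2) > d2)
        keep <- c(keep, j)
    }
    for (j in keep) {
      seeds[pos[j]] <- nxt
      parent[nxt] <- tissue$cell_ids[i]
      nxt <- nxt + 1L
    }
  }
  frag <- cpp_fill_within(seeds, lab)
  if (any(frag == 0L & lab > 0L)) frag <- cpp_fill_within(frag, lab)
  frag[lab == 0L] <- 0L
  names(parent) <- seq_along(parent)
  list(tissue = labeled_tissue(frag, ps), parent = parent)
}

#' Cut-and-Merge random giant pattern
#'
#' Creates a random giant-cell pattern on an over-segmented template while
#' preserving giant sizes and numbers: each target giant is seeded at a
#' random eligible fragment and merged with random neighboring fragments
#' until its target area is reached (realized areas overshoot by less than
#' one fragment).
#'
#' @param oseg result of [oversegment()].
#' @param giant_areas target giant areas in square micrometres.
#' @param seed RNG seed.
#' @param exclude_parents source cell ids whose fragments may not be
#'   absorbed (e.g. stomata).
#' @param max_retries position re-draws per giant before giving up.
#' @return list with `tissue` (re-labeled [labeled_tissue()]) and `giants`
#'   (ids of the realized giant cells).
#' @export
cut_and_merge <- function(oseg, giant_areas, seed = 1, exclude_parents = integer(0),
                          max_retries = 50L) {
  set.seed(seed)
  ft <- oseg$tissue
  ps2 <- ft$pixel_size^2
  farea <- lengths(label_pixels(ft$labels, ft$cell_ids)) * ps2
  if (sum(giant_areas) >= sum(farea)) stop("giant areas exceed tissue area")
  ct <- cpp_contacts(ft$labels, 4L)
  adj <- split(c(ct$b, ct$a), c(ct$a, ct$b))
  eligible0 <- ft$cell_ids[!(oseg$parent[as.character(ft$cell_ids)] %in% exclude_parents)]
  used <- integer(0)
  giants_frags <- list()
  for (g in order(giant_areas, decreasing = TRUE)) {
    target <- giant_areas[g]
    done <- FALSE
    for (try in seq_len(max_retries)) {
      pool <- setdiff(eligible0, used)
      if (length(pool) == 0L) break
      cur <- if (length(pool) == 1L) pool else sample(pool, 1L)
      tot <- farea[as.character(cur)]
      ok <- TRUE
      while (tot < target) {
        nb <- unique(unlist(adj[as.character(cur)]))
        nb <- setdiff(intersect(nb, eligible0), c(cur, used))
        if (length(nb) == 0L) { ok <- FALSE; break }
        add <- if (length(nb) == 1L) nb else sample(nb, 1L)
        cur <- c(cur, add)
        tot <- tot + farea[as.character(add)]
      }
      if (ok) {
        giants_frags[[g]] <- cur
        used <- c(used, cur)
        done <- TRUE
        break
      }
    }
    if (!done) stop("cut_and_merge: could not realize giant of area ", target)
  }
  lab <- ft$labels
  base <- max(ft$cell_ids)
  giant_ids <- base + seq_along(giant_areas)
  for (g in seq_along(giant_areas)) {
    lab[lab %in% giants_frags[[g]]] <- giant_ids[g]
  }
  list(tissue = labeled_tissue(lab, ft$pixel_size), giants = giant_ids)
}
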