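# Cell-size distribution comparison: 1-Wasserstein distances, permutation
# tests, classical MDS (PCoA) embedding, per-replicate normalization, and
# giant-cell density/area summaries.

#' 1-Wasserstein distance between two empirical distributions
#'
#' The integral of the absolute difference between the two quantile
#' functions, computed exactly on the merged sorted support (samples may
#' have different sizes). For equal sample sizes this reduces to the mean
#' absolute difference of the sorted samples.
#'
#' @param a,b nonempty numeric samples.
#' @export
wasserstein_1d <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  x <- sort(c(a, b))
  n <- length(x)
  # empirical CDFs evaluated just below each gap of the merged support
  Fa <- findInterval(x[-n], sort(a)) / length(a)
  Fb <- findInterval(x[-n], sort(b)) / length(b)
  sum(abs(Fa - Fb) * diff(x))
}

#' Permutation test on the 1-Wasserstein distance
#'
#' Labels of the pooled sample are permuted; the p-value is the proportion
#' of permuted statistics at least as large as the observed one, with
#' add-one smoothing in numerator and denominator.
#'
#' @param a,b numeric samples.
#' @param n_perm number of permutations (>= 99).
#' @param seed RNG seed.
#' @return list with `statistic` (observed distance) and `p_value`.
#' @export
wasserstein_test <- function(a, b, n_perm = 999, seed = 1) {
  if (n_perm < 99) stop("n_perm must be >= 99")
  obs <- wasserstein_1d(a, b)
  pool <- c(a, b)
  if (length(unique(pool)) == 1L)
    return(list(statistic = obs, p_value = 1))
  na <- length(a)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(length(pool), na)
    wasserstein_1d(pool[idx], pool[-idx])
  }, 0)
  list(statistic = obs, p_value = (1 + sum(perm >= obs)) / (n_perm + 1))
}

#' Classical multidimensional scaling (principal coordinates)
#'
#' Double-centers the squared distance matrix and takes the top
#' eigenvectors scaled by the square roots of their eigenvalues. Signs
#' follow a fixed convention (largest-magnitude loading of each coordinate
#' positive). A warning with the eigenvalue report is raised when large
#' negative eigenvalues indicate a heavily non-Euclidean input.
#'
#' @param D symmetric distance matrix (zero diagonal) or `dist`.
#' @param dims number of output dimensions.
#' @return list with `coords` (n x dims), `eigenvalues`, and `shepard`
#'   (data.frame of input vs embedded Euclidean distances for the
#'   linearity check).
#' @export
pcoa_embed <- function(D, dims = 2) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (any(abs(D - t(D)) > 1e-8) || any(diag(D) != 0))
    stop("D must be symmetric with zero diagonal")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  if (any(e$values < -1e-6 * max(abs(e$values), 1)) &&
      min(e$values) < -0.1 * max(e$values))
    warning("heavily non-Euclidean distances; eigenvalues: ",
            paste(signif(e$values, 3), collapse = ", "))
  dims <- min(dims, n)
  coords <- sapply(seq_len(dims), function(k) {
    v <- e$vectors[, k] * sqrt(max(e$values[k], 0))
    if (abs(min(v)) > abs(max(v))) v <- -v
    v
  })
  coords <- matrix(coords, nrow = n)
  rownames(coords) <- rownames(D)
  emb <- as.matrix(stats::dist(coords))
  ut <- upper.tri(D)
  list(coords = coords, eigenvalues = e$values,
       shepard = data.frame(input = D[ut], embedded = emb[ut]))
}

#' Normalize cell-size samples by their replicate mean
#'
#' Each replicate is divided by its own mean cell area so that every
#' replicate has mean 1, making distributions comparable across
#' developmental stages and organs of different absolute scale.
#'
#' @param samples named list of numeric samples (one per replicate).
#' @export
normalize_by_mean <- function(samples) {
  lapply(samples, function(x) {
    if (length(x) == 0L) stop("empty sample")
    m <- mean(x)
    if (m == 0) stop("zero mean sample")
    x / m
  })
}

# classical pooled-variance two-sample t statistic and two-tailed p
pooled_t_test <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  if (!is.finite(t)) t <- 0
  list(t = t, df = nx + ny - 2,
       p = 2 * stats::pt(-abs(t), df = nx + ny - 2))
}

#' Giant-cell density, area fraction and between-genotype t-tests
#'
#' @param tables_by_group named list (per genotype) of lists of typed cell
#'   tables (one per replicate).
#' @param segmented_areas_by_group same structure: total segmented area of
#'   each replicate in square micrometres.
#' @return list with `summary` (data.frame per replicate: group, density in
#'   giants per mm^2, giant area fraction) and `tests` (data.frame of
#'   pairwise equal-variance two-tailed t-tests on densities; skipped with
#'   a message when a group has a single replicate).
#' @export
giant_density_and_area <- function(tables_by_group, segmented_areas_by_group) {
  rows <- list()
  for (g in names(tables_by_group)) {
    tabs <- tables_by_group[[g]]
    segs <- segmented_areas_by_group[[g]]
    for (r in seq_along(tabs)) {
      gid <- giant_ids(tabs[[r]])
      garea <- sum(tabs[[r]]$area_um2[tabs[[r]]$id %in% gid])
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, replicate = r,
        density_per_mm2 = length(gid) / (segs[r] / 1e6),
        area_fraction = garea / segs[r])
    }
  }
  summary <- do.call(rbind, rows)
  groups <- names(tables_by_group)
  tests <- NULL
  if (length(groups) >= 2L) {
    pr <- utils::combn(groups, 2)
    tl <- list()
    for (j in seq_len(ncol(pr))) {
      x <- summary$density_per_mm2[summary$group == pr[1, j]]
      y <- summary$density_per_mm2[summary$group == pr[2, j]]
      if (length(x) < 2L || length(y) < 2L) {
        message("single replicate in pair ", pr[1, j], " vs ", pr[2, j],
                ": t-test skipped")
        next
      }
      tt <- pooled_t_test(x, y)
      tl[[length(tl) + 1L]] <- data.frame(group1 = pr[1, j], group2 = pr[2, j],
                                          t = tt$t, df = tt$df, p = tt$p)
    }
    if (length(tl)) tests <- do.call(rbind, tl)
  }
  list(summary = summary, tests = tests)
}
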