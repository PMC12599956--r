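# Spatial observables on a selected cell population and the
# randomization-based one-sided hypothesis test.

#' Giant-neighbor counts per giant cell
#'
#' For each giant cell not at the image border (border giants are excluded
#' as counted centers but still count as neighbors of interior giants),
#' counts the adjacent giant cells; the mean over counted giants is the
#' headline clustering statistic.
#'
#' @param graph an [build_adjacency()] result.
#' @param giants giant cell ids (subset of `graph$nodes`).
#' @param border_ids ids excluded as centers (typically
#'   `tissue$border_ids`).
#' @return list with `counts` (named per counted giant), `mean` (`NA` with
#'   `undefined = TRUE` if no countable giant), `n_counted`,
#'   `n_excluded_border`.
#' @export
giant_neighbor_stats <- function(graph, giants, border_ids = integer(0)) {
  if (!all(giants %in% graph$nodes)) stop("giants must be graph nodes")
  counted <- setdiff(giants, border_ids)
  e <- graph$edges
  gg <- e$a %in% giants & e$b %in% giants
  counts <- setNames(integer(length(counted)), counted)
  if (any(gg)) {
    tb <- table(c(e$a[gg], e$b[gg]))
    hit <- intersect(names(tb), names(counts))
    counts[hit] <- as.integer(tb[hit])
  }
  if (length(counted) == 0L) {
    return(list(counts = counts, mean = NA_real_, undefined = TRUE,
                n_counted = 0L, n_excluded_border = length(intersect(giants, border_ids))))
  }
  list(counts = counts, mean = mean(counts), undefined = FALSE,
       n_counted = length(counted),
       n_excluded_border = length(intersect(giants, border_ids)))
}

#' Additional spatial observables on the giant population
#'
#' @inheritParams giant_neighbor_stats
#' @return list with `min_sp` (per countable giant, the minimum
#'   shortest-path length in the cell network to another giant; 1 means in
#'   contact; `NA` and excluded when there is a single giant),
#'   `fraction_in_contact` (fraction of counted giants with at least one
#'   giant neighbor) and `cluster_sizes` (connected-component sizes of the
#'   giant-induced subgraph, all giants included).
#' @export
extra_observables <- function(graph, giants, border_ids = integer(0)) {
  counted <- setdiff(giants, border_ids)
  g <- graph$graph
  min_sp <- setNames(rep(NA_real_, length(counted)), counted)
  if (length(giants) >= 2L && length(counted) >= 1L) {
    D <- igraph::distances(g, v = as.character(counted), to = as.character(giants))
    for (i in seq_along(counted)) {
      d <- D[i, setdiff(colnames(D), as.character(counted[i]))]
      min_sp[i] <- if (length(d)) min(d) else NA_real_
    }
  }
  ns <- giant_neighbor_stats(graph, giants, border_ids)
  frac <- if (ns$n_counted > 0L) mean(ns$counts >= 1L) else NA_real_
  sub <- igraph::induced_subgraph(g, as.character(giants))
  cl <- igraph::components(sub)$csize
  list(min_sp = min_sp, fraction_in_contact = frac,
       cluster_sizes = sort(cl, decreasing = TRUE))
}

#' One-sided (or two-sided) randomization test
#'
#' The p-value is the fraction of null values that are the same as or more
#' extreme than the observed statistic (ties count as extreme). If no null
#' value is as extreme, the p-value is floored at `1 / n_random` and
#' reported as `p < 1/n_random`.
#'
#' @param observed observed statistic.
#' @param null_sample numeric vector of null statistics (one per random
#'   image).
#' @param direction `"greater"`, `"less"` or `"two-sided"`.
#' @param statistic statistic name carried in the result.
#' @param n_excluded_border bookkeeping: border cells excluded as centers.
#' @return object of class `null_test_result` with fields `observed`,
#'   `null_sample`, `p_value`, `floored`, `n_random`, `direction`,
#'   `statistic`, `n_excluded_border`.
#' @export
null_test <- function(observed, null_sample, direction = c("greater", "less", "two-sided"),
                      statistic = "statistic", n_excluded_border = NA_integer_) {
  direction <- match.arg(direction)
  if (length(null_sample) == 0L) stop("empty null sample")
  if (is.na(observed)) stop("observed statistic undefined")
  n <- length(null_sample)
  k <- switch(direction,
    greater = sum(null_sample >= observed),
    less = sum(null_sample <= observed),
    `two-sided` = min(n, 2L * min(sum(null_sample >= observed),
                                  sum(null_sample <= observed))))
  floored <- k == 0L
  p <- if (floored) 1 / n else k / n
  structure(list(observed = observed, null_sample = null_sample,
                 p_value = p, floored = floored, n_random = n,
                 direction = direction, statistic = statistic,
                 n_excluded_border = n_excluded_border),
            class = "null_test_result")
}

#' @export
print.null_test_result <- function(x, ...) {
  ptxt <- if (x$floored) sprintf("p < %.4g", 1 / x$n_random)
          else sprintf("p = %.4g", x$p_value)
  cat(sprintf("null test (%s, %s): observed = %.4g, null mean = %.4g [n_random = %d], %s\n",
              x$statistic, x$direction, x$observed, mean(x$null_sample),
              x$n_random, ptxt))
  invisible(x)
}

#' Pooled randomization test over replicates
#'
#' Pools replicates the way the null model is built: the observed statistic
#' is taken over the union of countable giants across replicates, and the
#' k-th null value is the same statistic over the union of randomization k
#' of every replicate (index pairing keeps exactly `n_random` null values).
#'
#' @param observed_counts list (one element per replicate) of per-giant
#'   observed neighbor counts (numeric vectors; zero-length allowed).
#' @param null_counts list (one per replicate) of lists (one per
#'   randomization) of per-giant counts.
#' @param direction,statistic passed to [null_test()].
#' @return a [null_test()] result.
#' @export
pooled_null_test <- function(observed_counts, null_counts,
                             direction = "greater",
                             statistic = "mean_giant_neighbors") {
  nr <- unique(vapply(null_counts, length, 0L))
  if (length(nr) != 1L) stop("mismatched n_random across replicates")
  obs_all <- unlist(observed_counts, use.names = FALSE)
  if (length(obs_all) == 0L) stop("no countable giants in any replicate")
  nulls <- vapply(seq_len(nr), function(k) {
    mean(unlist(lapply(null_counts, `[[`, k), use.names = FALSE))
  }, 0)
  null_test(mean(obs_all), nulls, direction = direction, statistic = statistic)
}

#' Run the full randomization null test on one or more replicates
#'
#' Convenience driver: builds the adjacency graph of each replicate,
#' extracts per-giant neighbor counts, generates the randomization ensemble
#' per replicate, recomputes the counts on every member (giants keep their
#' label ids), and runs the pooled one-sided test.
#'
#' @param tissues list of [labeled_tissue()] replicates.
#' @param giants_list list of giant-id vectors, one per replicate.
#' @param spec a [randomization_spec()]; member seeds are offset per
#'   replicate so replicates get independent ensembles.
#' @param direction test direction (default `"greater"`: clustering).
#' @param connectivity,min_contact forwarded to [build_adjacency()].
#' @return a [null_test()] result.
#' @export
pooled_randomization_test <- function(tissues, giants_list, spec,
                                      direction = "greater",
                                      connectivity = 4, min_contact = 2) {
  stopifnot(length(tissues) == length(giants_list))
  obs <- list(); nul <- list()
  for (r in seq_along(tissues)) {
    tis <- tissues[[r]]
    giants <- giants_list[[r]]
    obs[[r]] <- giant_counts_raster(tis, giants, connectivity, min_contact)
    rspec <- spec
    rspec$seed <- spec$seed + 1000L * r
    nul[[r]] <- lapply(seq_len(spec$n_random), function(k) {
      rt <- randomize_tissue(tis, rspec, k)
      giant_counts_raster(rt, giants, connectivity, min_contact)
    })
  }
  pooled_null_test(obs, nul, direction = direction)
}

# fast raster path: per-giant neighbor counts without building an igraph
giant_counts_raster <- function(tissue, giants, connectivity = 4, min_contact = 2) {
  ct <- cpp_contacts(tissue$labels, as.integer(connectivity))
  keep <- ct$count >= min_contact
  a <- ct$a[keep]; b <- ct$b[keep]
  gg <- a %in% giants & b %in% giants
  counted <- setdiff(giants, tissue$border_ids)
  counts <- setNames(integer(length(counted)), counted)
  if (any(gg)) {
    tb <- table(c(a[gg], b[gg]))
    hit <- intersect(names(tb), names(counts))
    counts[hit] <- as.integer(tb[hit])
  }
  counts
}
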