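# Cell-type assignment and the giant-cell size-threshold rule.

#' Giant-cell size threshold from a pooled reference sample
#'
#' The threshold is built from a reference genotype expected to contain
#' (almost) no giant cells: it is the average of the cell-size value at the
#' given percentile (nearest-rank convention on the sorted pooled sample)
#' and the cell-size value immediately above it. Cells with area strictly
#' greater than the threshold classify as giant.
#'
#' @param pooled_reference_areas pooled reference cell areas (square
#'   micrometres), e.g. all pavement cells of several replicates.
#' @param percentile percentile used (default 99.3, i.e. under 0.7 percent
#'   of reference pavement cells exceed the threshold).
#' @return object of class `giant_threshold` with fields `value`,
#'   `percentile`, `convention` (`"nearest-rank"`), `n_reference`.
#' @export
giant_size_threshold <- function(pooled_reference_areas, percentile = 99.3) {
  x <- sort(pooled_reference_areas)
  n <- length(x)
  if (n < 2L) stop("need at least 2 reference values")
  rank <- ceiling(percentile / 100 * n)
  rank <- min(max(rank, 1L), n)
  v1 <- x[rank]
  above <- x[x > v1]
  if (length(above) == 0L)
    stop("percentile value is the sample maximum: no value immediately above")
  v2 <- min(above)
  structure(list(value = (v1 + v2) / 2, percentile = percentile,
                 convention = "nearest-rank", n_reference = n),
            class = "giant_threshold")
}

#' @export
print.giant_threshold <- function(x, ...) {
  cat(sprintf("giant_threshold: %.4g um^2 (%.4gth percentile, %s, n = %d)\n",
              x$value, x$percentile, x$convention, x$n_reference))
  invisible(x)
}

#' Default rule-based stoma classifier
#'
#' The original pipeline used a trained quadratic-kernel SVM; this package
#' exposes a pluggable classifier interface instead (any function mapping a
#' cell table to a character vector of `"stoma"`/`"pavement"`). The default
#' transparent rule classifies a cell as stoma iff its area is below
#' `area_cap` and its circularity above `circularity_floor`.
#'
#' @param area_cap maximum stoma area (square micrometres).
#' @param circularity_floor minimum stoma circularity.
#' @return a classifier function.
#' @export
rule_classifier <- function(area_cap = 150, circularity_floor = 0.7) {
  function(table) {
    ifelse(table$area_um2 < area_cap & table$circularity > circularity_floor,
           "stoma", "pavement")
  }
}

#' Assign cell types and flag giant cells
#'
#' @param table a cell table with computed features.
#' @param threshold a [giant_size_threshold()] (or `NULL` to skip giant
#'   flagging).
#' @param classifier function(table) -> character vector in
#'   `{"stoma","pavement"}`; default [rule_classifier()].
#' @return the table with `cell_type` set to `"stoma"`, `"pavement"` or
#'   `"giant"` (giant-flagged pavement; stomata are never giant).
#' @export
assign_types <- function(table, threshold = NULL, classifier = rule_classifier()) {
  need <- c("area_um2", "circularity")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing features: ", paste(miss, collapse = ", "))
  type <- classifier(table)
  if (!all(type %in% c("stoma", "pavement")))
    stop("classifier must return 'stoma' or 'pavement'")
  if (!is.null(threshold)) {
    type[type == "pavement" & table$area_um2 > threshold$value] <- "giant"
  }
  table$cell_type <- type
  table
}

#' Giant-flagged cell ids of a typed table
#' @param table a typed cell table.
#' @export
giant_ids <- function(table) table$id[!is.na(table$cell_type) & table$cell_type == "giant"]

#' Select a comparison cell population
#'
#' Selects pavement cells (giant-flagged cells included only in
#' `mode = "giant"`) whose total area approximately equals a target:
#' `"giant"` returns all giant-flagged cells; `"mid"` adds pavement cells
#' ranked by closeness of their area to `mid_anchor` until the total area
#' reaches the target; `"small"` adds cells in ascending area order;
#' `"random"` adds uniformly sampled pavement cells with area above
#' `area_floor`. Greedy accumulation stops at the first set whose total
#' area is at least the target (overshoot reported).
#'
#' @param table a typed cell table.
#' @param mode `"giant"`, `"mid"`, `"small"` or `"random"`.
#' @param target_total_area target total area (square micrometres); by
#'   convention the area occupied by the giant population.
#' @param area_floor minimum area for `"random"` eligibility.
#' @param mid_anchor anchor area for `"mid"` (default 5000).
#' @param seed RNG seed for `"random"`.
#' @return integer vector of selected ids, with attributes `total_area`
#'   and `overshoot`.
#' @export
select_population <- function(table, mode = c("giant", "mid", "small", "random"),
                              target_total_area = NULL, area_floor = 0,
                              mid_anchor = 5000, seed = 1) {
  mode <- match.arg(mode)
  pav <- table[!is.na(table$cell_type) & table$cell_type != "stoma", ]
  if (nrow(pav) == 0L) stop("no pavement cells available")
  if (mode == "giant") {
    ids <- giant_ids(table)
    sel <- pav[pav$id %in% ids, ]
    return(structure(sel$id, total_area = sum(sel$area_um2), overshoot = 0))
  }
  stopifnot(!is.null(target_total_area))
  nong <- pav[pav$cell_type == "pavement", ]
  ord <- switch(mode,
    mid = order(abs(nong$area_um2 - mid_anchor)),
    small = order(nong$area_um2),
    random = { set.seed(seed)
               sample(which(nong$area_um2 > area_floor)) })
  areas <- nong$area_um2[ord]
  cum <- cumsum(areas)
  if (length(cum) == 0L || max(cum) < target_total_area)
    stop(sprintf("target unreachable: achieved total %.4g of %.4g",
                 if (length(cum)) max(cum) else 0, target_total_area))
  nsel <- which(cum >= target_total_area)[1L]
  sel <- nong$id[ord[seq_len(nsel)]]
  structure(sort(sel), total_area = cum[nsel],
            overshoot = cum[nsel] - target_total_area)
}
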