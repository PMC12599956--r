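# Shape feature extraction from labeled rasters.
#
# Perimeters are estimated from the marching-squares contour of each cell
# mask (midpoint rule on the 0.5 level set), not from pixel-edge counts:
# pixel-edge perimeters overestimate smooth boundaries by up to sqrt(2),
# which destabilizes lobeyness.

# marching-squares segment table; edges coded 1=top, 2=right, 3=bottom, 4=left
.ms_segments <- list(
  c(4L, 3L), c(3L, 2L), c(4L, 2L), c(1L, 2L),
  c(1L, 4L, 3L, 2L), c(1L, 3L), c(1L, 4L), c(1L, 4L),
  c(1L, 3L), c(1L, 2L, 3L, 4L), c(1L, 2L), c(4L, 2L),
  c(3L, 2L), c(4L, 3L), integer(0))

# All closed contours of a logical mask, in pixel-center coordinates
# (row, col); the mask is implicitly padded with background.
marching_contours <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  P <- matrix(FALSE, nr + 2L, nc + 2L)
  P[2:(nr + 1L), 2:(nc + 1L)] <- mask
  tl <- P[1:(nr + 1L), 1:(nc + 1L)]
  tr <- P[1:(nr + 1L), 2:(nc + 2L)]
  br <- P[2:(nr + 2L), 2:(nc + 2L)]
  bl <- P[2:(nr + 2L), 1:(nc + 1L)]
  cs <- 8L * tl + 4L * tr + 2L * br + 1L * bl
  hit <- which(cs > 0L & cs < 15L)
  if (length(hit) == 0L) return(list())
  bi <- (hit - 1L) %% (nr + 1L) + 1L   # block row (padded top-left corner)
  bj <- (hit - 1L) %/% (nr + 1L) + 1L
  segs_per <- lengths(.ms_segments)[cs[hit]] %/% 2L
  bi <- rep(bi, segs_per); bj <- rep(bj, segs_per)
  codes <- unlist(lapply(cs[hit], function(k) .ms_segments[[k]]))
  e1 <- codes[seq(1L, length(codes), 2L)]
  e2 <- codes[seq(2L, length(codes), 2L)]
  # doubled coordinates of edge midpoints keep keys integral
  edge_r <- function(i, e) 2L * i + c(0L, 1L, 2L, 1L)[e]
  edge_c <- function(j, e) 2L * j + c(1L, 2L, 1L, 0L)[e]
  k1 <- edge_r(bi, e1) * 1e6 + edge_c(bj, e1)
  k2 <- edge_r(bi, e2) * 1e6 + edge_c(bj, e2)
  ns <- length(k1)
  upts <- unique(c(k1, k2))
  i1 <- match(k1, upts); i2 <- match(k2, upts)
  inc <- split(rep(seq_len(ns), 2L), c(i1, i2))  # segments incident to a point
  used <- logical(ns)
  loops <- list()
  for (s0 in seq_len(ns)) {
    if (used[s0]) next
    pts <- integer(0)
    s <- s0; pt <- i1[s0]
    repeat {
      used[s] <- TRUE
      pts <- c(pts, pt)
      pt <- if (i1[s] == pt) i2[s] else i1[s]
      nxt <- inc[[as.character(pt)]]
      nxt <- nxt[!used[nxt]]
      if (length(nxt) == 0L) break
      s <- nxt[1L]
    }
    key <- upts[pts]
    rr <- (key %/% 1e6) / 2 - 1
    cc <- (key %% 1e6) / 2 - 1
    loops[[length(loops) + 1L]] <- cbind(r = rr, c = cc)
  }
  loops
}

# circular moving-average smoothing of a closed contour: suppresses the
# staircase bias of raster contours (a raw marching contour overestimates
# smooth perimeters by several percent on diagonal boundaries)
smooth_contour <- function(p, w = 3L) {
  n <- nrow(p)
  if (n <= w) return(p)
  h <- w %/% 2L
  idx <- outer(seq_len(n), -h:h, function(i, d) ((i + d - 1L) %% n) + 1L)
  cbind(r = rowMeans(matrix(p[idx, 1], n)), c = rowMeans(matrix(p[idx, 2], n)))
}

polygon_area <- function(p) {
  x <- p[, 2]; y <- p[, 1]
  n <- nrow(p)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

polygon_perimeter <- function(p, closed = TRUE) {
  q <- if (closed) rbind(p, p[1, , drop = FALSE]) else p
  sum(sqrt(rowSums(diff(q)^2)))
}

# minimum-area bounding rectangle of a point set (rotating calipers)
min_rect_area <- function(pts) {
  h <- grDevices::chull(pts[, 2], pts[, 1])
  hp <- pts[h, , drop = FALSE]
  n <- nrow(hp)
  if (n < 3L) {
    return(0)
  }
  hq <- rbind(hp, hp[1, , drop = FALSE])
  best <- Inf
  for (i in seq_len(n)) {
    dv <- hq[i + 1L, ] - hq[i, ]
    len <- sqrt(sum(dv^2))
    if (len < 1e-12) next
    u <- dv / len; v <- c(-u[2], u[1])
    a <- hp %*% cbind(u, v)
    area <- diff(range(a[, 1])) * diff(range(a[, 2]))
    if (area < best) best <- area
  }
  best
}

hull_perimeter <- function(pts) {
  h <- grDevices::chull(pts[, 2], pts[, 1])
  polygon_perimeter(pts[h, , drop = FALSE])
}

# fraction of sampled contour-point pairs whose connecting segment stays
# inside the mask; deterministic even subsampling of at most `n_points`
# contour vertices (the definition is only verbal in the field, see vignette)
mask_visibility <- function(mask, contour, centroid_rc, n_points = 100L) {
  np <- nrow(contour)
  idx <- unique(round(seq(1L, np, length.out = min(n_points, np))))
  p <- contour[idx, , drop = FALSE]
  # pull sample endpoints half a pixel inward so contour vertices (which sit
  # on the 0.5 level, outside pixel centers) do not round to background
  dirs <- cbind(centroid_rc[1] - p[, 1], centroid_rc[2] - p[, 2])
  nn <- sqrt(rowSums(dirs^2)); nn[nn < 1e-9] <- 1
  p <- p + 0.75 * dirs / nn
  n <- nrow(p)
  if (n < 2L) return(1)
  pr <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  d <- sqrt((p[pr[, 1], 1] - p[pr[, 2], 1])^2 + (p[pr[, 1], 2] - p[pr[, 2], 2])^2)
  ns <- pmax(2L, ceiling(d / 0.7))
  tt <- (sequence(ns) - 1) / rep(ns - 1L, ns)
  g <- rep(seq_len(nrow(pr)), ns)
  rr <- p[pr[g, 1], 1] + tt * (p[pr[g, 2], 1] - p[pr[g, 1], 1])
  cc <- p[pr[g, 1], 2] + tt * (p[pr[g, 2], 2] - p[pr[g, 1], 2])
  ri <- pmin(pmax(round(rr) + 1L, 1L), nrow(mask))
  ci <- pmin(pmax(round(cc) + 1L, 1L), ncol(mask))
  inside <- mask[cbind(ri, ci)]
  bad <- rowsum(as.integer(!inside), g) > 0L
  mean(!bad)
}

#' Per-cell shape features
#'
#' Computes one record per cell: physical area and perimeter, centroid,
#' principal-axis orientation and lengths (from second moments, with the
#' 1/12 pixel-variance correction), circularity (4*pi*A/P^2), lobeyness
#' (contour perimeter / convex-hull perimeter; 1 for convex shapes),
#' rectangularity (area / minimum-area bounding-rectangle area) and
#' visibility (fraction of contour point pairs seeing each other inside the
#' cell). Single-pixel cells get a degenerate-shape fallback (unit-square
#' perimeter) and are flagged in the `degenerate` attribute.
#'
#' @param tissue a [labeled_tissue()].
#' @param visibility compute the (relatively expensive) visibility feature?
#' @param n_visibility_points maximum number of contour points sampled.
#' @return a cell table: `data.frame` with the columns documented in
#'   [write_cell_table()], one row per cell id.
#' @export
compute_features <- function(tissue, visibility = TRUE, n_visibility_points = 100L) {
  lab <- tissue$labels
  ps <- tissue$pixel_size
  ids <- tissue$cell_ids
  px <- label_pixels(lab, ids)
  nr <- nrow(lab)
  out <- vector("list", length(ids))
  degen <- logical(length(ids))
  for (i in seq_along(ids)) {
    pos <- px[[i]]
    rr <- (pos - 1L) %% nr + 1L
    cc <- (pos - 1L) %/% nr + 1L
    r0 <- min(rr); c0 <- min(cc)
    sub <- matrix(FALSE, max(rr) - r0 + 1L, max(cc) - c0 + 1L)
    sub[cbind(rr - r0 + 1L, cc - c0 + 1L)] <- TRUE
    npix <- length(pos)
    area <- npix * ps^2
    cen_r <- mean(rr) - 1; cen_c <- mean(cc) - 1   # 0-based pixel coords
    # second moments (+1/12 pixel variance)
    vr <- if (npix > 1) stats::var(rr) * (npix - 1) / npix + 1 / 12 else 1 / 12
    vc <- if (npix > 1) stats::var(cc) * (npix - 1) / npix + 1 / 12 else 1 / 12
    vrc <- if (npix > 1) stats::cov(rr, cc) * (npix - 1) / npix else 0
    ev <- eigen(matrix(c(vr, vrc, vrc, vc), 2), symmetric = TRUE)
    major <- 4 * sqrt(max(ev$values[1], 0)) * ps
    minor <- 4 * sqrt(max(ev$values[2], 0)) * ps
    vec <- ev$vectors[, 1]
    ang <- atan2(vec[1], vec[2])   # x = col, y = row (y down)
    if (ang <= -pi / 2) ang <- ang + pi
    if (ang > pi / 2) ang <- ang - pi
    if (npix == 1L) {
      degen[i] <- TRUE
      per <- 4 * ps
      lob <- 1; rect <- 1; vis <- 1
      circ <- 4 * pi * area / per^2
    } else {
      loops <- marching_contours(sub)
      outer <- loops[[which.max(vapply(loops, polygon_area, 0))]]
      outer <- smooth_contour(outer)
      per_px <- polygon_perimeter(outer)
      per <- per_px * ps
      circ <- 4 * pi * area / per^2
      lob <- per_px / hull_perimeter(outer)
      rect <- polygon_area(outer) / min_rect_area(outer)
      vis <- if (visibility) {
        mask_visibility(sub, outer, c(cen_r - r0 + 1, cen_c - c0 + 1),
                        n_visibility_points)
      } else NA_real_
    }
    out[[i]] <- data.frame(
      id = ids[i], area_um2 = area, perimeter_um = per,
      centroid_x = cen_c * ps, centroid_y = cen_r * ps,
      orientation_rad = ang, major_axis = major, minor_axis = minor,
      circularity = circ, lobeyness = lob, rectangularity = rect,
      visibility = vis, cell_type = NA_character_, ploidy = NA_real_,
      is_border = ids[i] %in% tissue$border_ids)
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  attr(tab, "degenerate_ids") <- ids[degen]
  tab
}

#' Read / write cell tables
#'
#' Cell tables are plain CSV with the fixed header
#' `id,area_um2,perimeter_um,centroid_x,centroid_y,orientation_rad,major_axis,minor_axis,circularity,lobeyness,rectangularity,visibility,cell_type,ploidy,is_border`.
#'
#' @param table a cell table data.frame.
#' @param path CSV path.
#' @export
write_cell_table <- function(table, path) {
  write.csv(table[, cell_table_columns()], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(cell_table_columns(), names(tab))
  if (length(miss)) stop("cell table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$id)) stop("duplicate cell ids")
  tab
}

cell_table_columns <- function() {
  c("id", "area_um2", "perimeter_um", "centroid_x", "centroid_y",
    "orientation_rad", "major_axis", "minor_axis", "circularity",
    "lobeyness", "rectangularity", "visibility", "cell_type", "ploidy",
    "is_border")
}
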