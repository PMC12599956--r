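# Fixture builders and independent oracles. Everything is generated in
# code at test time; no binary fixtures.

# four equal square cells in a 2x2 arrangement (6x6 raster)
four_block_tissue <- function() {
  lab <- matrix(0L, 6, 6)
  lab[1:3, 1:3] <- 1L; lab[1:3, 4:6] <- 2L
  lab[4:6, 1:3] <- 3L; lab[4:6, 4:6] <- 4L
  labeled_tissue(lab, 1)
}

# horizontal strip tissue: cell i occupies rows, strips stacked vertically;
# adjacency is a path graph 1-2-3-...-n
strip_tissue <- function(n, strip_h = 4, width = 12) {
  lab <- matrix(0L, n * strip_h, width)
  for (i in seq_len(n)) lab[((i - 1) * strip_h + 1):(i * strip_h), ] <- i
  labeled_tissue(lab, 1)
}

disk_mask <- function(r, pad = 2L) {
  n <- 2L * (r + pad) + 1L
  ctr <- r + pad + 1L
  m <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if ((i - ctr)^2 + (j - ctr)^2 <= r^2) m[i, j] <- 1L
  m
}

plus_mask <- function(arm = 10L, w = 11L) {
  L <- w + 2L * arm
  m <- matrix(0L, L + 4L, L + 4L)
  c0 <- (L + 4L - w) %/% 2L + 1L
  m[c0:(c0 + w - 1L), 3:(L + 2L)] <- 1L
  m[3:(L + 2L), c0:(c0 + w - 1L)] <- 1L
  m
}

# brute-force pixel-pair adjacency oracle: scans every pixel pair
brute_adjacency <- function(labels, connectivity = 4, min_contact = 1) {
  offs <- list(c(0, 1), c(1, 0))
  if (connectivity == 8) offs <- c(offs, list(c(1, 1), c(1, -1)))
  acc <- new.env()
  nr <- nrow(labels); nc <- ncol(labels)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    a <- labels[i, j]
    if (a <= 0) next
    for (o in offs) {
      ii <- i + o[1]; jj <- j + o[2]
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      b <- labels[ii, jj]
      if (b <= 0 || b == a) next
      key <- paste(min(a, b), max(a, b))
      acc[[key]] <- (acc[[key]] %||% 0L) + 1L
    }
  }
  keys <- ls(acc)
  cnt <- vapply(keys, function(k) acc[[k]], 0L)
  keep <- cnt >= min_contact
  if (!any(keep)) return(data.frame(a = integer(0), b = integer(0), weight = integer(0)))
  ab <- do.call(rbind, strsplit(keys[keep], " "))
  out <- data.frame(a = as.integer(ab[, 1]), b = as.integer(ab[, 2]),
                    weight = unname(cnt[keep]))
  out[order(out$a, out$b), ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# union-find oracle for connected-component sizes of the giant subgraph
uf_cluster_sizes <- function(edges_a, edges_b, nodes) {
  parent <- setNames(nodes, nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (i in seq_along(edges_a)) {
    ra <- find(as.character(edges_a[i])); rb <- find(as.character(edges_b[i]))
    if (ra != rb) parent[[ra]] <- rb
  }
  sort(as.integer(table(vapply(as.character(nodes), find, ""))), decreasing = TRUE)
}

# independent RK4 integrator of the deterministic chemical system
rk4_chemistry <- function(A0, T0, C0, p, t_end, dt) {
  f <- function(x) {
    A <- x[1]; Tt <- x[2]
    hillA <- p$V_A * A^p$n_A / (p$K_A^p$n_A + A^p$n_A)
    hillT <- p$V_T * A^p$n_T / (p$K_T^p$n_T + A^p$n_T)
    c(p$P_A + hillA - p$G_A * A, hillT - p$G_T * Tt, p$P_C)
  }
  x <- c(A0, T0, C0)
  for (i in seq_len(round(t_end / dt))) {
    k1 <- f(x); k2 <- f(x + dt / 2 * k1)
    k3 <- f(x + dt / 2 * k2); k4 <- f(x + dt * k3)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  x
}

# brute-force shortest centroid chord of a convex polygon (dense scan)
brute_min_chord <- function(poly, n_ang = 3600) {
  cen <- giantcell:::poly_centroid(poly)
  n <- nrow(poly)
  best <- Inf
  for (a in seq(0, pi, length.out = n_ang)) {
    u <- c(cos(a), sin(a))
    ts <- c()
    for (e in seq_len(n)) {
      j <- if (e == n) 1L else e + 1L
      E <- poly[j, ] - poly[e, ]
      P <- poly[e, ] - cen
      den <- E[1] * u[2] - E[2] * u[1]
      if (abs(den) < 1e-14) next
      s <- (P[2] * u[1] - P[1] * u[2]) / den
      tt <- (P[2] * E[1] - P[1] * E[2]) / den
      if (s >= 0 && s < 1) ts <- c(ts, tt)
    }
    tn <- ts[ts <= 0]; tp <- ts[ts > 0]
    if (length(tn) && length(tp)) best <- min(best, min(tp) - max(tn))
  }
  best
}

# random convex polygon (points on a noisy ellipse, ordered by angle)
random_convex_poly <- function(nv = 8, seed = 1) {
  set.seed(seed)
  ang <- sort(runif(nv, 0, 2 * pi))
  r <- runif(1, 1, 3); b <- runif(1, 0.5, 1.5)
  pts <- cbind(r * cos(ang), b * r * sin(ang))
  pts[grDevices::chull(pts), , drop = FALSE]
}

# small synthetic tissue shared by several tests
small_synth <- function(seed = 11, n_cells = 80, wh = 96, ...) {
  generate_tissue(synth_spec(n_cells = n_cells, width = wh, height = wh,
                             seed = seed, ...))
}
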