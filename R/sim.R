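# Stochastic, cell-autonomous simulator of giant-cell fate commitment in a
# growing, dividing polygonal tissue.
#
# Chemistry: chemical Langevin equations for the ATML1 concentration
# (constitutive production + Hill self-activation - linear degradation),
# its Target (Hill activation by ATML1 - linear degradation) and a Timer
# (constant production). Noise amplitude is c0 * sqrt(sum(|terms|)/eps_i)
# with eps_i = E0 * E_i(t) the effective cell size, integrated with a
# Heun predictor-corrector under the Ito convention (noise evaluated at
# the step's start state). Cells double ploidy at the Timer S-phase
# threshold; post-S cells whose Target exceeds the commitment threshold
# enter an absorbing endoreduplication state and stop dividing; all other
# cells divide at the Timer division threshold by the shortest wall
# through the cell centroid. Growth is kinematic: an anisotropic
# exponential map about the fixed tissue center of mass, with dilution of
# the modeled variables.

#' Simulation parameters
#'
#' Defaults are the shipped calibration (see `inst/params/` and
#' `scripts/calibrate.R`): ATML1 fluctuation-driven with occasional high
#' excursions, on the order of 8 giant cells per cropped tissue at the
#' final time.
#'
#' @param P_A,V_A,K_A,n_A,G_A ATML1 production, self-activation prefactor,
#'   half-max concentration, Hill exponent, degradation rate.
#' @param V_T,K_T,n_T,G_T Target activation prefactor, half-max, Hill
#'   exponent, degradation rate.
#' @param P_C Timer production rate (sets the cell-cycle duration
#'   ~ theta_CD / P_C time units).
#' @param theta_CS,theta_CD Timer thresholds for S-phase and for
#'   division/endocycle reset (0 < theta_CS < theta_CD).
#' @param theta_T Target concentration threshold for commitment to
#'   endoreduplication (checked after S-phase).
#' @param E0 effective cell-area scale in eps_i = E0 * E_i(t).
#' @param c0 noise prefactor of the chemical Langevin amplitude.
#' @param k_radial,k_axial exponential growth rates transverse/along the
#'   tissue axis (per time unit); unequal rates give anisotropic growth.
#' @param dt integration time step (default 0.1).
#' @param t_end stop time (default 135).
#' @param t_select selection time for first-arising giants (default 55).
#' @param n_rings hexagonal rings of the initial template (2 -> 19 cells).
#' @param dilute_timer subject the Timer to growth dilution as well.
#' @param eps_floor lower bound on the effective cell area entering the
#'   noise amplitude (the chemical Langevin approximation degrades for
#'   vanishing system size; the floor prevents a noise runaway in
#'   transiently small cells).
#' @param min_div_area minimum cell area for division; smaller cells at
#'   the division threshold postpone division until grown.
#' @param seed RNG seed.
#' @export
sim_params <- function(P_A = 0.1, V_A = 1.3, K_A = 0.7, n_A = 4, G_A = 1,
                       V_T = 1, K_T = 1.2, n_T = 4, G_T = 0.2,
                       P_C = 0.03, theta_CS = 0.5, theta_CD = 1,
                       theta_T = 0.6, E0 = 1, c0 = 0.3,
                       k_radial = 0.0066, k_axial = 0.0132,
                       dt = 0.1, t_end = 135, t_select = 55,
                       n_rings = 2, dilute_timer = FALSE,
                       eps_floor = 1.0, min_div_area = 0.3, seed = 1) {
  p <- list(P_A = P_A, V_A = V_A, K_A = K_A, n_A = n_A, G_A = G_A,
            V_T = V_T, K_T = K_T, n_T = n_T, G_T = G_T, P_C = P_C,
            theta_CS = theta_CS, theta_CD = theta_CD, theta_T = theta_T,
            E0 = E0, c0 = c0, k_radial = k_radial, k_axial = k_axial,
            dt = dt, t_end = t_end, t_select = t_select, n_rings = n_rings,
            dilute_timer = dilute_timer, eps_floor = eps_floor,
            min_div_area = min_div_area, seed = seed)
  rates <- unlist(p[c("P_A", "V_A", "G_A", "V_T", "G_T", "P_C",
                      "k_radial", "k_axial")])
  if (any(rates < 0)) stop("rates must be >= 0")
  if (!(theta_CS > 0 && theta_CS < theta_CD)) stop("need 0 < theta_CS < theta_CD")
  if (dt <= 0) stop("dt must be > 0")
  if (n_A < 1 || n_T < 1) stop("Hill exponents must be >= 1")
  structure(p, class = "sim_params")
}

# ---- polygon helpers (convex polygons throughout) ----

poly_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]; n <- nrow(p)
  sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y) / 2
}

poly_centroid <- function(p) {
  x <- p[, 1]; y <- p[, 2]; n <- nrow(p)
  j <- c(2:n, 1)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

# Sutherland-Hodgman clip of convex polygon p by halfplane (q - m) . nrm <= 0
clip_halfplane <- function(p, m, nrm) {
  n <- nrow(p)
  d <- (p[, 1] - m[1]) * nrm[1] + (p[, 2] - m[2]) * nrm[2]
  out <- matrix(0, n + 4, 2); k <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (d[i] <= 0) { k <- k + 1L; out[k, ] <- p[i, ] }
    if ((d[i] <= 0) != (d[j] <= 0)) {
      t <- d[i] / (d[i] - d[j])
      k <- k + 1L
      out[k, ] <- p[i, ] + t * (p[j, ] - p[i, ])
    }
  }
  out[seq_len(k), , drop = FALSE]
}

#' Initialize the simulation state
#'
#' Builds a small polygonal patch: a jittered hexagonal lattice turned into
#' a bounded Voronoi tessellation (convex cells of slightly unequal areas,
#' mean area 1). ATML1 is uniform on [0,1), Target on [0,0.1); the Timer is
#' set in correlation with cell area (rank fraction of area times the
#' division threshold, with +-10 percent multiplicative noise); all cells
#' start diploid (2C) and uncommitted.
#'
#' @param params a [sim_params()].
#' @return object of class `sim_state`.
#' @export
init_simulation <- function(params) {
  R <- params$n_rings
  s <- sqrt(2 / sqrt(3))   # lattice spacing for unit mean cell area
  ax <- unlist(lapply(-R:R, function(q) seq(max(-R, -q - R), min(R, -q + R))))
  qq <- rep(-R:R, times = vapply(-R:R, function(q)
    length(seq(max(-R, -q - R), min(R, -q + R))), 0L))
  cx <- s * (qq + ax / 2)
  cy <- s * (sqrt(3) / 2) * ax
  n <- length(cx)
  cx <- cx + rnorm(n, 0, 0.12 * s)
  cy <- cy + rnorm(n, 0, 0.12 * s)
  pad <- 0.65 * s
  box <- rbind(c(min(cx) - pad, min(cy) - pad), c(max(cx) + pad, min(cy) - pad),
               c(max(cx) + pad, max(cy) + pad), c(min(cx) - pad, max(cy) + pad))
  polys <- vector("list", n)
  for (i in seq_len(n)) {
    p <- box
    for (j in seq_len(n)) {
      if (i == j) next
      m <- c((cx[i] + cx[j]) / 2, (cy[i] + cy[j]) / 2)
      p <- clip_halfplane(p, m, c(cx[j] - cx[i], cy[j] - cy[i]))
      if (nrow(p) < 3L) stop("degenerate Voronoi cell in initial template")
    }
    polys[[i]] <- p
  }
  areas <- vapply(polys, poly_area, 0)
  com <- c(0, 0)
  for (i in seq_len(n)) com <- com + areas[i] * poly_centroid(polys[[i]])
  com <- com / sum(areas)
  rk <- rank(areas, ties.method = "random")
  verts <- do.call(rbind, polys)
  vidx <- split(seq_len(nrow(verts)), rep(seq_len(n), vapply(polys, nrow, 0L)))
  state <- list(
    verts = verts, vidx = vidx,
    areas = areas,
    id = seq_len(n), parent = rep(NA_integer_, n), next_id = n + 1L,
    A = runif(n, 0, 1), T = runif(n, 0, 0.1),
    C = params$theta_CD * (rk / n) * (1 + runif(n, -0.1, 0.1)),
    ploidy = rep(2, n), post_S = rep(FALSE, n), committed = rep(FALSE, n),
    commit_time = rep(NA_real_, n), divisions = rep(0L, n),
    last_div_time = rep(0, n),
    com = com, time = 0)
  class(state) <- "sim_state"
  state
}

#' Cell polygons of a simulation state
#'
#' @param state a `sim_state`.
#' @param i optional cell index; omit for the full list.
#' @export
sim_polygons <- function(state, i = NULL) {
  if (!is.null(i)) return(state$verts[state$vidx[[i]], , drop = FALSE])
  lapply(state$vidx, function(ix) state$verts[ix, , drop = FALSE])
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("sim_state: t = %.1f, %d cells, %d committed, ploidy 2C..%gC, total area %.3g\n",
              x$time, length(x$id), sum(x$committed), max(x$ploidy), sum(x$areas)))
  invisible(x)
}

# drift terms of the chemical Langevin equations
.drift <- function(A, T, p) {
  hillA <- p$V_A * A^p$n_A / (p$K_A^p$n_A + A^p$n_A)
  hillT <- p$V_T * A^p$n_T / (p$K_T^p$n_T + A^p$n_T)
  list(fA = p$P_A + hillA - p$G_A * A,
       fT = hillT - p$G_T * T,
       fC = p$P_C,
       sA = p$P_A + hillA + p$G_A * A,    # sum of |terms| (all nonnegative)
       sT = hillT + p$G_T * T,
       sC = p$P_C)
}

#' One chemical integration step (Heun, Ito)
#'
#' @param state a `sim_state`.
#' @param params a [sim_params()].
#' @export
langevin_step <- function(state, params) {
  p <- params
  if (p$dt * max(p$G_A, p$G_T) > 1)
    warning("dt * max degradation rate > 1: integration may be unstable")
  eps <- pmax(p$E0 * state$areas, p$eps_floor)
  A <- state$A; T <- state$T; C <- state$C
  d0 <- .drift(A, T, p)
  n <- length(A)
  sq <- sqrt(p$dt)
  gA <- p$c0 * sqrt(d0$sA / eps); dWA <- sq * rnorm(n)
  gT <- p$c0 * sqrt(d0$sT / eps); dWT <- sq * rnorm(n)
  gC <- p$c0 * sqrt(d0$sC / eps); dWC <- sq * rnorm(n)
  A1 <- pmax(A + d0$fA * p$dt + gA * dWA, 0)
  T1 <- pmax(T + d0$fT * p$dt + gT * dWT, 0)
  d1 <- .drift(A1, T1, p)
  state$A <- pmax(A + 0.5 * (d0$fA + d1$fA) * p$dt + gA * dWA, 0)
  state$T <- pmax(T + 0.5 * (d0$fT + d1$fT) * p$dt + gT * dWT, 0)
  state$C <- pmax(C + d0$fC * p$dt + gC * dWC, 0)
  state
}

#' One kinematic growth step with dilution
#'
#' Displaces every vertex away from the (fixed) tissue center of mass with
#' exponential rates `k_radial` (x) and `k_axial` (y), then multiplies the
#' modeled variables by the per-cell area ratio before/after (dilution).
#'
#' @inheritParams langevin_step
#' @export
grow_and_dilute <- function(state, params) {
  fx <- exp(params$k_radial * params$dt)
  fy <- exp(params$k_axial * params$dt)
  com <- state$com
  state$verts <- cbind(com[1] + (state$verts[, 1] - com[1]) * fx,
                       com[2] + (state$verts[, 2] - com[2]) * fy)
  ratio <- 1 / (fx * fy)            # area_before / area_after, exact (affine)
  state$areas <- state$areas / ratio
  state$A <- state$A * ratio
  state$T <- state$T * ratio
  if (params$dilute_timer) state$C <- state$C * ratio
  state
}

#' Divide a convex cell polygon by the shortest wall through its centroid
#'
#' Scans chord orientations at 1 degree resolution, keeps the chord of
#' minimal length through the polygon centroid (ties broken by an RNG
#' draw), and partitions the polygon; daughter areas sum exactly to the
#' mother area (polygon arithmetic).
#'
#' @param poly convex polygon (n x 2 matrix, vertices in order).
#' @return list of two polygons.
#' @export
divide_cell <- function(poly) {
  cen <- poly_centroid(poly)
  n <- nrow(poly)
  angs <- seq(0, pi - pi / 180, by = pi / 180)
  ex <- poly[c(2:n, 1), 1] - poly[, 1]
  ey <- poly[c(2:n, 1), 2] - poly[, 2]
  px <- poly[, 1] - cen[1]
  py <- poly[, 2] - cen[2]
  best_len <- rep(NA_real_, length(angs))
  hits <- vector("list", length(angs))
  for (a in seq_along(angs)) {
    u <- c(cos(angs[a]), sin(angs[a]))
    den <- ex * u[2] - ey * u[1]
    s <- (py * u[1] - px * u[2]) / den
    tpar <- (py * ex - px * ey) / den          # position along the line
    ok <- is.finite(s) & s >= 0 & s < 1
    if (sum(ok) < 2L) next
    tn <- tpar[ok & tpar <= 0]; tp <- tpar[ok & tpar > 0]
    if (length(tn) == 0L || length(tp) == 0L) next
    t1 <- max(tn); t2 <- min(tp)
    best_len[a] <- t2 - t1
    hits[[a]] <- list(u = u, edges = which(ok), t1 = t1, t2 = t2, tpar = tpar)
  }
  cand <- which(best_len <= min(best_len, na.rm = TRUE) + 1e-12)
  a <- if (length(cand) == 1L) cand else sample(cand, 1L)
  h <- hits[[a]]
  e1 <- h$edges[which(abs(h$tpar[h$edges] - h$t1) < 1e-9)][1]
  e2 <- h$edges[which(abs(h$tpar[h$edges] - h$t2) < 1e-9)][1]
  P1 <- cen + h$t1 * h$u
  P2 <- cen + h$t2 * h$u
  walk <- function(from, to) {
    idx <- integer(0); i <- from
    repeat {
      i <- if (i == n) 1L else i + 1L
      idx <- c(idx, i)
      if (i == to) break
    }
    idx
  }
  d1 <- rbind(P1, poly[walk(e1, e2), , drop = FALSE], P2)
  d2 <- rbind(P2, poly[walk(e2, e1), , drop = FALSE], P1)
  dedupe <- function(p) {
    n2 <- nrow(p)
    keep <- rowSums((p - p[c(2:n2, 1), , drop = FALSE])^2) > 1e-18
    p[keep, , drop = FALSE]
  }
  list(dedupe(d1), dedupe(d2))
}

#' Cell-cycle events: S-phase, commitment, endocycle reset, division
#'
#' Applied once per time step after chemistry and growth: (i) cells whose
#' Timer crosses the S-phase threshold double their ploidy once; (ii)
#' post-S cells whose Target exceeds the commitment threshold commit to
#' endoreduplication (absorbing); (iii) at the division threshold,
#' committed cells reset their Timer to U[0, 0.5) and continue endocycling
#' while uncommitted cells divide by the shortest centroid wall, daughters
#' inheriting the mother's ATML1 and Target concentrations, drawing
#' independent U[0, 0.5) Timers, and returning to 2C.
#'
#' @inheritParams langevin_step
#' @export
cycle_events <- function(state, params) {
  p <- params
  s_hit <- state$C >= p$theta_CS & !state$post_S
  state$ploidy[s_hit] <- state$ploidy[s_hit] * 2
  state$post_S[s_hit] <- TRUE
  commit_hit <- state$post_S & !state$committed & state$T >= p$theta_T
  state$committed[commit_hit] <- TRUE
  state$commit_time[commit_hit] <- state$time
  d_hit <- state$C >= p$theta_CD
  endo <- d_hit & state$committed
  if (any(endo)) {
    state$C[endo] <- runif(sum(endo), 0, 0.5)
    state$post_S[endo] <- FALSE
  }
  div <- which(d_hit & !state$committed & state$areas >= p$min_div_area)
  for (i in div) {
    dd <- divide_cell(state$verts[state$vidx[[i]], , drop = FALSE])
    j <- length(state$id) + 1L
    n0 <- nrow(state$verts)
    state$verts <- rbind(state$verts, dd[[1]], dd[[2]])
    state$vidx[[i]] <- n0 + seq_len(nrow(dd[[1]]))
    state$vidx[[j]] <- n0 + nrow(dd[[1]]) + seq_len(nrow(dd[[2]]))
    state$areas[i] <- poly_area(dd[[1]])
    state$areas[j] <- poly_area(dd[[2]])
    mother <- state$id[i]
    state$id[i] <- state$next_id; state$id[j] <- state$next_id + 1L
    state$next_id <- state$next_id + 2L
    state$parent[i] <- mother; state$parent[j] <- mother
    state$A[j] <- state$A[i]
    state$T[j] <- state$T[i]
    cc <- runif(2, 0, 0.5)
    state$C[i] <- cc[1]; state$C[j] <- cc[2]
    state$ploidy[i] <- 2; state$ploidy[j] <- 2
    state$post_S[i] <- FALSE; state$post_S[j] <- FALSE
    state$committed[j] <- FALSE
    state$commit_time[j] <- NA_real_
    state$divisions[i] <- state$divisions[i] + 1L
    state$divisions[j] <- state$divisions[i]
    state$last_div_time[i] <- state$time
    state$last_div_time[j] <- state$time
  }
  state
}

#' Run the simulation
#'
#' Loops chemistry, growth and cycle events with time step `dt` until
#' `t_end`, storing deep state snapshots at the requested times.
#'
#' @param params a [sim_params()].
#' @param snapshot_times times at which to keep state snapshots (matched to
#'   the nearest step).
#' @return list with `final` (the `sim_state` at `t_end`), `snapshots`
#'   (named list keyed by requested time) and `params`.
#' @export
run_simulation <- function(params, snapshot_times = numeric(0)) {
  set.seed(params$seed)
  state <- init_simulation(params)
  snaps <- list()
  for (ts in snapshot_times[snapshot_times <= 0]) snaps[[as.character(ts)]] <- state
  nsteps <- round(params$t_end / params$dt)
  snap_steps <- round(snapshot_times / params$dt)
  for (step in seq_len(nsteps)) {
    state <- langevin_step(state, params)
    state <- grow_and_dilute(state, params)
    state$time <- step * params$dt
    state <- cycle_events(state, params)
    hitsnap <- snapshot_times[snap_steps == step]
    for (ts in hitsnap) snaps[[as.character(ts)]] <- state
  }
  list(final = state, snapshots = snaps, params = params)
}

#' Per-cell table of a simulation state
#'
#' @param state a `sim_state`.
#' @return data.frame with id, area (model units^2), chemical state,
#'   ploidy, committed flag, commit time, divisions, last division time.
#' @export
sim_cell_table <- function(state) {
  data.frame(id = state$id, area = state$areas, A = state$A, T = state$T,
             C = state$C, ploidy = state$ploidy, committed = state$committed,
             commit_time = state$commit_time, divisions = state$divisions,
             last_div_time = state$last_div_time)
}

#' Rasterize a simulation state to a labeled tissue
#'
#' Cells are rasterized by point-in-polygon tests at pixel centers; crack
#' pixels inside the tissue hull are assigned to the nearest cell. One
#' model length unit maps to `units_per_um` micrometres (default 1).
#'
#' @param state a `sim_state`.
#' @param target_px approximate pixel count of the longest tissue side.
#' @param margin background margin in pixels (keeps the tissue off the
#'   raster border so whole-tissue randomization can fix the background).
#' @return a [labeled_tissue()]; label = cell id.
#' @export
rasterize_state <- function(state, target_px = 200, margin = 3L) {
  allv <- state$verts[unlist(state$vidx), , drop = FALSE]
  xr <- range(allv[, 1]); yr <- range(allv[, 2])
  ps <- max(diff(xr), diff(yr)) / (target_px - 2 * margin)
  nc <- ceiling(diff(xr) / ps) + 2L * margin
  nr <- ceiling(diff(yr) / ps) + 2L * margin
  lab <- matrix(0L, nr, nc)
  x0 <- xr[1] - margin * ps
  y0 <- yr[1] - margin * ps
  for (i in seq_along(state$vidx)) {
    p <- state$verts[state$vidx[[i]], , drop = FALSE]
    c1 <- max(1L, floor((min(p[, 1]) - x0) / ps)); c2 <- min(nc, ceiling((max(p[, 1]) - x0) / ps) + 1L)
    r1 <- max(1L, floor((min(p[, 2]) - y0) / ps)); r2 <- min(nr, ceiling((max(p[, 2]) - y0) / ps) + 1L)
    if (c2 < c1 || r2 < r1) next
    gx <- x0 + (seq(c1, c2) - 0.5) * ps
    gy <- y0 + (seq(r1, r2) - 0.5) * ps
    X <- matrix(gx, length(gy), length(gx), byrow = TRUE)
    Y <- matrix(gy, length(gy), length(gx))
    inside <- matrix(TRUE, length(gy), length(gx))
    n <- nrow(p)
    # convex polygon: inside iff on the inner side of every edge
    ornt <- sign(poly_area(p))
    for (e in seq_len(n)) {
      j <- if (e == n) 1L else e + 1L
      cr <- (p[j, 1] - p[e, 1]) * (Y - p[e, 2]) - (p[j, 2] - p[e, 2]) * (X - p[e, 1])
      inside <- inside & (ornt * cr >= 0)
    }
    blk <- lab[r1:r2, c1:c2]
    blk[inside] <- state$id[i]
    lab[r1:r2, c1:c2] <- blk
  }
  # fill crack pixels strictly inside the tissue (convex hull of vertices)
  hull <- allv[grDevices::chull(allv), , drop = FALSE]
  zero <- which(lab == 0L)
  if (length(zero)) {
    zr <- (zero - 1L) %% nr + 1L
    zc <- (zero - 1L) %/% nr + 1L
    X <- x0 + (zc - 0.5) * ps; Y <- y0 + (zr - 0.5) * ps
    nh <- nrow(hull)
    inh <- rep(TRUE, length(zero))
    ornt <- sign(poly_area(hull))
    for (e in seq_len(nh)) {
      j <- if (e == nh) 1L else e + 1L
      cr <- (hull[j, 1] - hull[e, 1]) * (Y - hull[e, 2]) - (hull[j, 2] - hull[e, 2]) * (X - hull[e, 1])
      inh <- inh & (ornt * cr >= 0)
    }
    m <- lab
    m[zero[!inh]] <- -1L
    m <- cpp_fill_nearest(m, m > 0L)
    m[m < 0L] <- 0L
    lab <- m
  }
  labeled_tissue(lab, 1)
}

# largest all-TRUE axis-aligned rectangle of a logical matrix
# (histogram-stack method); returns c(r1, r2, c1, c2)
maximal_rectangle <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  heights <- integer(nc)
  best <- c(0L, 1L, 1L, 1L, 1L)   # area, r1, r2, c1, c2
  for (r in seq_len(nr)) {
    heights <- ifelse(mask[r, ], heights + 1L, 0L)
    stack_c <- integer(0); stack_h <- integer(0)
    for (c in seq_len(nc + 1L)) {
      h <- if (c <= nc) heights[c] else 0L
      start <- c
      while (length(stack_h) && tail(stack_h, 1) > h) {
        hh <- tail(stack_h, 1); cc <- tail(stack_c, 1)
        stack_h <- head(stack_h, -1); stack_c <- head(stack_c, -1)
        area <- hh * (c - cc)
        if (area > best[1]) best <- c(area, r - hh + 1L, r, cc, c - 1L)
        start <- cc
      }
      if (!length(stack_h) || tail(stack_h, 1) < h) {
        stack_c <- c(stack_c, start); stack_h <- c(stack_h, h)
      }
    }
  }
  best[-1]
}

#' Crop a tissue to the maximal interior rectangle
#'
#' Crops to the largest axis-aligned rectangle containing no background,
#' the cropping convention used before giant-cell classification of
#' simulated tissues.
#'
#' @param tissue a [labeled_tissue()].
#' @export
crop_max_rectangle <- function(tissue) {
  rc <- maximal_rectangle(tissue$labels > 0L)
  labeled_tissue(tissue$labels[rc[1]:rc[2], rc[3]:rc[4], drop = FALSE],
                 tissue$pixel_size)
}

#' Giant-cell set of a simulated tissue
#'
#' `"ploidy"` mode applies the size-threshold rule: the threshold is the
#' minimum area among cells of ploidy >= 16C, and every cell at or above
#' it is a giant (so all >= 16C cells are giants, and 8C cells exceeding
#' the threshold are included too). `"first_arising"` returns cells that
#' committed to endoreduplication by `t_select` and therefore stopped
#' dividing (their ids persist to the final state).
#'
#' @param table a [sim_cell_table()] (or any data.frame with `id`, `area`,
#'   `ploidy`) for `"ploidy"` mode; for `"first_arising"`, the final
#'   state's table (needs `commit_time`).
#' @param mode `"ploidy"` or `"first_arising"`.
#' @param t_select selection time for `"first_arising"`.
#' @param exclude_ids ids excluded from the threshold computation (cells
#'   clipped by the image crop, whose raster areas underestimate their
#'   size); they may still classify as giants.
#' @return integer vector of giant ids (with attribute `threshold` in
#'   `"ploidy"` mode).
#' @export
sim_giant_set <- function(table, mode = c("ploidy", "first_arising"), t_select = 55,
                          exclude_ids = integer(0)) {
  mode <- match.arg(mode)
  if (mode == "ploidy") {
    hi <- table$area[table$ploidy >= 16 & !(table$id %in% exclude_ids)]
    if (length(hi) == 0L) {
      warning("no cells of ploidy >= 16C: empty giant set")
      return(structure(integer(0), threshold = NA_real_))
    }
    thr <- min(hi)
    structure(table$id[table$area >= thr], threshold = thr)
  } else {
    table$id[table$committed & !is.na(table$commit_time) &
               table$commit_time <= t_select]
  }
}

#' Rasterized snapshot with merged per-cell attributes
#'
#' Rasterizes a simulation state (optionally cropping to the maximal
#' interior rectangle) and returns the tissue together with a table of
#' raster-measured cell areas merged with the simulated ploidy and
#' commitment attributes.
#'
#' @param state a `sim_state`.
#' @param crop crop to the maximal interior rectangle first?
#' @param target_px approximate raster size (longest side).
#' @return list with `tissue` ([labeled_tissue()]) and `table`
#'   (data.frame: id, area, ploidy, committed, commit_time; area in
#'   pixel^2 units of the raster).
#' @export
sim_snapshot <- function(state, crop = TRUE, target_px = 200) {
  tis <- rasterize_state(state, target_px = target_px)
  if (crop) tis <- crop_max_rectangle(tis)
  npx <- lengths(label_pixels(tis$labels, tis$cell_ids))
  idx <- match(tis$cell_ids, state$id)
  tab <- data.frame(id = tis$cell_ids,
                    area = as.numeric(npx) * tis$pixel_size^2,
                    ploidy = state$ploidy[idx],
                    committed = state$committed[idx],
                    commit_time = state$commit_time[idx])
  list(tissue = tis, table = tab)
}
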