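# Chemistry-only parameter set: growth off, thresholds unreachable, so
# langevin_step can be exercised in isolation.
chem_params <- function(...) {
  sim_params(k_radial = 0, k_axial = 0, theta_CS = 1e8, theta_CD = 2e8,
             theta_T = Inf, ...)
}

step_chem <- function(state, p, n) {
  for (i in seq_len(n)) state <- langevin_step(state, p)
  state
}

test_that("initial conditions respect their stated ranges and determinism", {
  p <- sim_params(seed = 3)
  set.seed(p$seed); s1 <- init_simulation(p)
  set.seed(p$seed); s2 <- init_simulation(p)
  expect_identical(s1$A, s2$A)
  expect_identical(s1$verts, s2$verts)
  expect_true(all(s1$A >= 0 & s1$A < 1))
  expect_true(all(s1$T >= 0 & s1$T < 0.1))
  expect_true(all(s1$ploidy == 2) && !any(s1$committed))
  expect_equal(length(s1$id), 19)   # two hexagonal rings
})

test_that("initial Timer correlates with cell area (Spearman > 0.8)", {
  p <- sim_params(seed = 1)
  rho <- vapply(1:50, function(s) {
    set.seed(s)
    st <- init_simulation(p)
    cor(st$areas, st$C, method = "spearman")
  }, 0)
  expect_gt(mean(rho), 0.8)
})

test_that("noise-off linear dynamics reach their fixed points", {
  p <- chem_params(c0 = 0, V_A = 0, P_A = 0.4, G_A = 0.8)
  set.seed(1); st <- init_simulation(p)
  st <- step_chem(st, p, 200)
  expect_equal(st$A, rep(p$P_A / p$G_A, length(st$A)), tolerance = 1e-4)

  # A frozen (all its rates zero) -> T converges to the Hill fixed point
  a0 <- 1.3
  p2 <- chem_params(c0 = 0, P_A = 0, V_A = 0, G_A = 0, V_T = 0.9, K_T = 1.1,
                    n_T = 4, G_T = 0.25)
  set.seed(2); st2 <- init_simulation(p2)
  st2$A <- rep(a0, length(st2$A))
  st2 <- step_chem(st2, p2, 400)
  want <- p2$V_T * a0^4 / (p2$K_T^4 + a0^4) / p2$G_T
  expect_equal(st2$T, rep(want, length(st2$T)), tolerance = 1e-4)
})

test_that("noise-off bistable stationary states equal bracketed roots", {
  p <- chem_params(c0 = 0, P_A = 0.1, V_A = 2.2, K_A = 1, n_A = 4, G_A = 1)
  f <- function(A) p$P_A + p$V_A * A^4 / (1 + A^4) - A
  # root-bracketing oracle on a fine grid
  grid <- seq(0, 5, by = 1e-3)
  sgn <- sign(f(grid))
  roots <- grid[which(diff(sgn) != 0)]
  roots <- vapply(roots, function(lo) uniroot(f, c(lo, lo + 1e-3))$root, 0)
  stable <- roots[c(1, 3)]   # outer roots of the bistable triplet
  expect_length(roots, 3)

  set.seed(3); st <- init_simulation(p)
  st$A <- rep(c(0.05, 3), length.out = length(st$A))
  st <- step_chem(st, p, 3000)
  got <- sort(unique(round(st$A, 5)))
  expect_equal(got, sort(round(stable, 5)), tolerance = 1e-3)
})

test_that("deterministic trajectories match an independent RK4 oracle", {
  p <- chem_params(c0 = 0)
  set.seed(4); st <- init_simulation(p)
  A0 <- st$A[1]; T0 <- st$T[1]; C0 <- st$C[1]
  st <- step_chem(st, p, round(135 / p$dt))
  want <- rk4_chemistry(A0, T0, C0, p, 135, 0.01)
  expect_lt(abs(st$A[1] - want[1]) / max(want[1], 1e-6), 1e-3)
  expect_lt(abs(st$T[1] - want[2]) / max(want[2], 1e-6), 1e-3)
})

test_that("growth map scales areas exactly and dilution conserves mass", {
  p <- sim_params(c0 = 0, P_A = 0, V_A = 0, G_A = 0, V_T = 0, G_T = 0, P_C = 0,
                  theta_CS = 1e8, theta_CD = 2e8)
  set.seed(5); st <- init_simulation(p)
  a0 <- sum(st$areas); prodA <- st$A * st$areas
  for (i in 1:100) st <- grow_and_dilute(st, p)
  expect_equal(sum(st$areas) / a0, exp((p$k_axial + p$k_radial) * 100 * p$dt),
               tolerance = 1e-6)
  # pure growth, rates off: concentration x area invariant per cell
  expect_equal(st$A * st$areas, prodA, tolerance = 1e-9)

  # zero rates -> identity
  p0 <- sim_params(k_radial = 0, k_axial = 0)
  set.seed(6); st0 <- init_simulation(p0)
  ar <- st0$areas; A <- st0$A
  st0 <- grow_and_dilute(st0, p0)
  expect_equal(st0$areas, ar)
  expect_equal(st0$A, A)

  # anisotropic growth: aspect ratio strictly increases
  pa <- sim_params(k_radial = 0.005, k_axial = 0.02)
  set.seed(7); sta <- init_simulation(pa)
  asp <- function(s) {
    diff(range(s$verts[, 2])) / diff(range(s$verts[, 1]))
  }
  r0 <- asp(sta)
  for (i in 1:100) sta <- grow_and_dilute(sta, pa)
  expect_gt(asp(sta), r0)
})

test_that("divide_cell: rectangle, hexagon oracle, exact area partition", {
  rect <- cbind(c(0, 2, 2, 0), c(0, 0, 1, 1))
  dd <- divide_cell(rect)
  areas <- vapply(dd, function(q) abs(giantcell:::poly_area(q)), 0)
  expect_equal(sort(areas), c(1, 1))
  # division wall is the short chord x = 1
  wall <- dd[[1]][dd[[1]][, 1] > 1 - 1e-9 & dd[[1]][, 1] < 1 + 1e-9, ]
  expect_equal(nrow(wall), 2)
  expect_equal(unname(abs(diff(wall[, 2]))), 1)

  hexp <- cbind(cos(seq(0, 2 * pi, length.out = 7)[-7]),
                sin(seq(0, 2 * pi, length.out = 7)[-7]))
  set.seed(8)
  dh <- divide_cell(hexp)
  wall_len <- sqrt(sum((dh[[1]][1, ] - dh[[1]][nrow(dh[[1]]), ])^2))
  expect_equal(wall_len, brute_min_chord(hexp), tolerance = 1e-3)

  for (s in 1:15) {
    poly <- random_convex_poly(sample(5:10, 1), seed = s)
    dd <- divide_cell(poly)
    a <- vapply(dd, function(q) abs(giantcell:::poly_area(q)), 0)
    expect_lt(abs(sum(a) - abs(giantcell:::poly_area(poly))) /
                abs(giantcell:::poly_area(poly)), 1e-9)
  }
})

test_that("cycle events: S-phase, absorbing commitment, endocycles, division", {
  p <- sim_params(seed = 1)
  set.seed(1); st <- init_simulation(p)
  n <- length(st$id)
  st$C <- rep(0.75, n)          # past theta_CS, below theta_CD
  st$T <- rep(0, n)
  st$time <- 10
  st1 <- cycle_events(st, p)
  expect_true(all(st1$ploidy == 4))
  expect_true(all(st1$post_S))
  st2 <- cycle_events(st1, p)   # no second doubling while post_S
  expect_true(all(st2$ploidy == 4))

  # committed cell over 3 endocycles: 4 -> 8 -> 16 -> 32
  st2$T <- rep(p$theta_T + 1, n)
  st2 <- cycle_events(st2, p)
  expect_true(all(st2$committed))
  for (cyc in 1:3) {
    st2$C <- rep(p$theta_CD, n)
    st2 <- cycle_events(st2, p)      # endocycle reset, post_S cleared
    expect_true(all(!st2$post_S))
    st2$C <- rep(p$theta_CS, n)
    st2 <- cycle_events(st2, p)      # next S-phase doubles again
  }
  expect_true(all(st2$ploidy == 32))
  expect_true(all(st2$committed))    # absorbing

  # uncommitted division: daughters share A and T, reset to 2C
  set.seed(2); sd <- init_simulation(p)
  sd$C <- rep(p$theta_CD + 0.1, length(sd$id))
  sd$T <- rep(0, length(sd$id))
  sd$post_S <- rep(TRUE, length(sd$id))
  sd$ploidy <- rep(4, length(sd$id))
  sd$A <- seq_along(sd$id) * 0.1
  n0 <- length(sd$id)
  sd2 <- cycle_events(sd, p)
  expect_equal(length(sd2$id), 2 * n0)
  expect_true(all(sd2$ploidy == 2))
  expect_true(all(sd2$C >= 0 & sd2$C < 0.5))
  for (i in seq_len(n0))   # daughter pairs share the mother's concentrations
    expect_equal(sd2$A[i], sd2$A[n0 + i])
})

test_that("run_simulation limits: empty loop and commitment extremes", {
  p0 <- sim_params(t_end = 0, seed = 9)
  out0 <- run_simulation(p0)
  expect_equal(out0$final$time, 0)
  expect_equal(length(out0$final$id), 19)

  pInf <- sim_params(theta_T = Inf, t_end = 40, seed = 9)
  outI <- run_simulation(pInf)
  expect_equal(sum(outI$final$committed), 0)
  expect_gt(length(outI$final$id), 19)   # pure proliferation

  p0t <- sim_params(theta_T = 0, t_end = 40, seed = 9)
  out0t <- run_simulation(p0t)
  # every cell commits at its first S-phase; nobody ever divides
  expect_equal(length(out0t$final$id), 19)
  expect_true(all(out0t$final$committed))
})

test_that("ploidy never decreases and commitment persists through time", {
  out <- run_simulation(sim_params(seed = 12, t_end = 90), snapshot_times = c(45))
  s45 <- out$snapshots[["45"]]; s90 <- out$final
  common <- intersect(s45$id, s90$id)
  i45 <- match(common, s45$id); i90 <- match(common, s90$id)
  expect_true(all(s90$ploidy[i90] >= s45$ploidy[i45]))
  expect_true(all(!(s45$committed[i45] & !s90$committed[i90])))
  committed45 <- s45$id[s45$committed]
  expect_true(all(committed45 %in% s90$id))   # committed cells never divide
  expect_equal(s90$divisions[match(committed45, s90$id)],
               s45$divisions[match(committed45, s45$id)])
})

test_that("sim_giant_set applies the ploidy size-threshold rule", {
  tab <- data.frame(id = 1:4, area = c(10, 7, 8, 3), ploidy = c(32, 16, 8, 4))
  gs <- sim_giant_set(tab, "ploidy")
  expect_equal(attr(gs, "threshold"), 7)
  expect_setequal(as.integer(gs), 1:3)   # the 8C cell above threshold included

  tab2 <- data.frame(id = 1:3, area = 1:3, ploidy = 2)
  expect_warning(gs2 <- sim_giant_set(tab2, "ploidy"), "empty giant set")
  expect_length(gs2, 0)
})

test_that("first-arising giants persist identically to the final state", {
  out <- run_simulation(sim_params(seed = 21), snapshot_times = c(55))
  tb <- sim_cell_table(out$final)
  fa <- sim_giant_set(tb, "first_arising", t_select = 55)
  expect_true(all(fa %in% out$snapshots[["55"]]$id))
  expect_true(all(fa %in% out$final$id))
  # definition: committed by t_select and never divided afterwards
  idx <- match(fa, tb$id)
  expect_true(all(tb$commit_time[idx] <= 55))
  expect_true(all(tb$last_div_time[idx] <= 55))
})

test_that("maximal rectangle crop matches a brute-force oracle", {
  brute_max_rect <- function(mask) {
    best <- 0
    nr <- nrow(mask); nc <- ncol(mask)
    for (r1 in 1:nr) for (r2 in r1:nr) for (c1 in 1:nc) for (c2 in c1:nc)
      if (all(mask[r1:r2, c1:c2])) best <- max(best, (r2 - r1 + 1) * (c2 - c1 + 1))
    best
  }
  set.seed(13)
  for (rep in 1:5) {
    mask <- matrix(runif(64) > 0.3, 8, 8)
    rc <- giantcell:::maximal_rectangle(mask)
    got <- (rc[2] - rc[1] + 1) * (rc[4] - rc[3] + 1)
    expect_true(all(mask[rc[1]:rc[2], rc[3]:rc[4]]))
    expect_equal(got, brute_max_rect(mask))
  }
})

test_that("rasterized snapshots tile, crop and carry ploidy", {
  out <- run_simulation(sim_params(seed = 31, t_end = 60))
  sn <- sim_snapshot(out$final, crop = TRUE, target_px = 150)
  expect_true(all(sn$tissue$labels > 0L))   # crop has no background
  expect_true(all(sn$table$ploidy %in% 2^(1:12)))
  expect_setequal(sn$table$id, sn$tissue$cell_ids)
  full <- sim_snapshot(out$final, crop = FALSE, target_px = 150)
  expect_gt(mean(full$tissue$labels == 0L), 0)  # margin background retained
})
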