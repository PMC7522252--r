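test_that("the weighted direction rule reproduces its closed-form cases", {
  g <- c(0, -1)
  # alignment fixed point
  expect_equal(growth_direction(g, g, W_g = 1, W_r = 0), g)
  # inertia only
  d0 <- c(sqrt(0.5), -sqrt(0.5))
  expect_equal(growth_direction(d0, g, W_g = 0, W_r = 0), d0)
  # frozen oracle: normalize((1, 0) + 0.1*(0, -1)) = (1, -0.1)/sqrt(1.01)
  expect_equal(growth_direction(c(1, 0), g, W_g = 0.1, W_r = 0),
               c(0.9950371902, -0.0995037190), tolerance = 1e-9)
  # resistance term points away from the gradient
  d <- growth_direction(c(0, -1), g, gradR = c(10, 0), W_g = 0, W_r = 1)
  expect_lt(d[1], 0)
  # sub-tolerance gradients are dropped
  expect_equal(growth_direction(d0, g, gradR = c(1e-12, 0), W_g = 0,
                                W_r = 1, grad_tol = 1e-8), d0)
  # degenerate resultant errors out
  expect_error(growth_direction(c(0, 1), g, W_g = 1, W_r = 0),
               "degenerate")
})

test_that("with gravity weight only, the tip direction converges monotonically to vertical", {
  g <- c(0, -1)
  d <- c(sin(70 * pi / 180), -cos(70 * pi / 180))   # 70 deg off vertical
  ang <- acos(pmin(1, -d[2]))
  for (i in 1:50) {
    d <- growth_direction(d, g, W_g = 0.1, W_r = 0)
    ang_new <- acos(pmin(1, -d[2]))
    expect_lt(ang_new, ang + 1e-15)
    ang <- ang_new
  }
  expect_lt(ang * 180 / pi, 2)
})

test_that("deviation sampling is uniform on [-delta, delta] and seed reproducible", {
  expect_identical(sample_deviation(0, 10), rep(0, 10))
  set.seed(99)
  x <- sample_deviation(35, 1e4)
  expect_true(all(x >= -35 & x <= 35))
  expect_lt(abs(mean(x)), 1.5)
  set.seed(123); a <- sample_deviation(35, 100)
  set.seed(123); b <- sample_deviation(35, 100)
  expect_identical(a, b)
})

test_that("the resistance gradient recovers a manufactured linear field and sign at interfaces", {
  g <- soil_grid(4, 4, 16, 16, 0.1)
  # manufactured linear field R = 3x - 2z + 7
  R_lin <- 3 * g$elem_x - 2 * g$elem_z + 7
  gr <- resistance_gradient_at(g, R_lin, 1.7, 2.3)
  expect_equal(gr, c(3, -2), tolerance = 1e-9)
  # uniform field: zero vector
  expect_equal(resistance_gradient_at(g, rep(5, g$nelem), 2, 2), c(0, 0))
  expect_error(resistance_gradient_at(g, R_lin, 9, 2), "outside")
  # two-material interface: gradient points toward the stiff side
  s <- van_genuchten()
  obs <- obstacle(center = c(3, 2), length = 1.5, width = 1, eta = 0)
  em <- rasterize_obstacles(list(obs), g)
  st <- hydrostatic_init(g, obstacle_materials(s, list(obs)), em)
  Rf <- resistance_field(g, st, obstacle_materials(s, list(obs)), em)
  gr2 <- resistance_gradient_at(g, Rf, 2.05, 2)   # soft side, stiff at +x
  expect_gt(gr2[1], 0)
})

test_that("axes emerge on schedule and laterals follow spacing, alternation and delay", {
  sim <- small_run()
  # schedule: axes at 0, 0.5, 1, 1.5, 2 are all present by t = 2.5
  expect_equal(sum(sim$roots$order == 1L), 5L)
  expect_equal(sort(sim$roots$birth[sim$roots$order == 1L]),
               c(0, 0.5, 1, 1.5, 2))
  # first axis points straight down
  expect_equal(unlist(sim$roots[1, c("dx0", "dz0")]),
               c(dx0 = 0, dz0 = -1), tolerance = 1e-12)
  # branch points on each parent sit at exact multiples of the spacing
  q <- sim$branch_points
  expect_true(all(abs(q$arc / 0.3 - round(q$arc / 0.3)) < 1e-9))
  # consecutive branch points alternate sides
  for (ax in unique(q$parent_root)) {
    sides <- q$side[q$parent_root == ax][order(q$arc[q$parent_root == ax])]
    if (length(sides) > 1)
      expect_true(all(diff(sides) != 0))
  }
  # first lateral of the first axis activates at birth + tip delay
  first_act <- min(sim$roots$birth[sim$roots$parent_root == 1L])
  expect_equal(first_act, 0 + 2.1)
  # later branch points: activation = passage + tip delay
  qa <- q[q$parent_root == 1L, ]
  qa <- qa[order(qa$arc), ]
  if (nrow(qa) > 1)
    expect_equal(qa$t_activate[-1], qa$t_created[-1] + 2.1)
})

test_that("laterals insert at the branching angle and the graph stays a forest", {
  sim <- small_run()
  lat <- sim$roots[sim$roots$parent_root > 0, ]
  expect_gt(nrow(lat), 0)
  ang <- acos(pmax(-1, pmin(1, lat$dx0 * lat$apdx + lat$dz0 * lat$apdz)))
  expect_equal(ang * 180 / pi, rep(32.55, nrow(lat)), tolerance = 1e-9)
  # forest invariant: every parent link resolves and leads to the seed
  for (r in sim$roots$root) {
    seen <- integer(0); cur <- r
    while (cur != 0L) {
      expect_false(cur %in% seen)
      seen <- c(seen, cur)
      cur <- sim$roots$parent_root[sim$roots$root == cur]
    }
  }
  # segments form chains: each parent segment id exists or is the collar
  segs <- sim$segments
  expect_true(all(segs$parent_seg %in% c(0L, segs$seg)))
})

test_that("tip kinematics: step length is E*dt and total growth sums over tips", {
  sim <- small_run()
  segs <- sim$segments
  # segment lengths never exceed the maximum elongation over one step
  expect_true(all(segs$len <= max(sim$traits$axes_table$rate) * 0.05 + 1e-9))
  # total length equals the sum over all segments (brute-force oracle)
  expect_equal(total_length(sim), sum(segs$len))
  # arc bookkeeping: per root, the tip arc equals its summed segment length
  for (r in sim$roots$root) {
    expect_equal(sim$tips$arc[sim$tips$root == r],
                 sum(segs$len[segs$root == r]), tolerance = 1e-9)
  }
})

test_that("a zero-horizon run returns the initial state only and reruns are identical", {
  cfg <- default_config()
  cfg$domain$nx <- 8; cfg$domain$nz <- 8
  cfg$time$t_end <- 0
  sim0 <- simulate_rsa(cfg)
  expect_equal(nrow(sim0$segments), 0L)
  expect_equal(length(sim0$snapshots), 1L)
  expect_equal(sim0$snapshots[[1]]$time, 0)
  # determinism: identical seed, identical geometry
  cfg2 <- default_config()
  cfg2$domain$nx <- 12; cfg2$domain$nz <- 12
  cfg2$time$t_end <- 1.5
  a <- simulate_rsa(cfg2)
  b <- simulate_rsa(cfg2)
  expect_identical(a$segments, b$segments)
  expect_identical(a$tip_log$beta, b$tip_log$beta)
})

test_that("tips halt at the domain boundary", {
  cfg <- default_config()
  cfg$domain <- list(width = 3, height = 3, nx = 12, nz = 12,
                     thickness = 0.2)
  cfg$seed_pos <- c(1.5, 2.8)
  cfg$schedule <- data.frame(time = 0, orientation = 90)
  cfg$traits <- list(delta = 0, max_order = 1L)
  cfg$time <- list(t_end = 3, dT = 0.05, output_dt = 1)
  cfg$water$coupled <- FALSE
  sim <- simulate_rsa(cfg)
  expect_true(sim$tips$halted[1])
  expect_true(all(sim$segments$z1 >= -1e-9))
})
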