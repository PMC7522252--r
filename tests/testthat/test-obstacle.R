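test_that("rasterisation follows the element-centroid rule", {
  g <- soil_grid(4, 4, 8, 8, 0.1)     # centroids at 0.25, 0.75, ...
  # axis-aligned rectangle covering exactly 4 centroids
  obs <- obstacle(center = c(2, 2), length = 1, width = 1, eta = 0)
  em <- rasterize_obstacles(list(obs), g)
  expect_equal(sum(em == 2L), 4L)
  # empty list: all substrate
  expect_equal(rasterize_obstacles(list(), g), rep(1L, g$nelem))
  # rotated rectangle: agree with a brute-force point-in-polygon test
  obs45 <- obstacle(center = c(2, 2), length = 1.6, width = 0.6, eta = 45)
  em45 <- rasterize_obstacles(list(obs45), g)
  brute <- vapply(seq_len(g$nelem), function(e) {
    p <- c(g$elem_x[e], g$elem_z[e]) - obs45$center
    a <- sum(p * obs45$u); b <- sum(p * obs45$v)
    abs(a) <= 0.8 && abs(b) <= 0.3
  }, TRUE)
  expect_equal(em45 == 2L, brute)
  # obstacle sticking out of the domain is rejected
  expect_error(rasterize_obstacles(list(obstacle(c(3.9, 2), 1, 0.2, 0)), g),
               "outside")
})

test_that("distance to the obstacle periphery matches a sampled-boundary oracle", {
  obs <- obstacle(center = c(2, 2), length = 2, width = 0.4, eta = 30)
  # dense sampling of the rectangle periphery as an independent oracle
  tseq <- seq(0, 1, length.out = 4000)
  per <- do.call(rbind, lapply(1:4, function(k) {
    a <- obs$corners[k, ]; b <- obs$corners[if (k == 4) 1 else k + 1, ]
    cbind(a[1] + tseq * (b[1] - a[1]), a[2] + tseq * (b[2] - a[2]))
  }))
  set.seed(3)
  for (i in 1:25) {
    p <- c(runif(1, 0, 4), runif(1, 0, 4))
    d <- distance_to_obstacle(p[1], p[2], list(obs))$distance
    d_oracle <- min(sqrt((per[, 1] - p[1])^2 + (per[, 2] - p[2])^2))
    expect_lt(abs(d - d_oracle), 1e-3)
  }
  # a point exactly on an edge has distance zero
  mid_edge <- (obs$corners[1, ] + obs$corners[2, ]) / 2
  expect_lt(distance_to_obstacle(mid_edge[1], mid_edge[2],
                                 list(obs))$distance, 1e-12)
  # 1 cm along the outward normal of an axis-aligned edge
  obs0 <- obstacle(center = c(2, 2), length = 2, width = 0.4, eta = 0)
  expect_equal(distance_to_obstacle(2, 3.2, list(obs0))$distance, 1,
               tolerance = 1e-12)
  # no obstacles: infinite distance
  expect_identical(distance_to_obstacle(1, 1, list())$distance, Inf)
})

test_that("the contact phase machine transitions free -> contact -> recovery -> free", {
  cs <- new_contact_state(W_oi = 5, kappa = 2)
  expect_identical(cs$phase, "free")
  cs <- update_contact_state(cs, FALSE, 0.5, c(0, -1))
  expect_identical(cs$phase, "free")
  cs <- update_contact_state(cs, TRUE, 1.0, c(0, -1))
  expect_identical(cs$phase, "contact")
  expect_equal(cs$t0, 1.0)
  cs <- update_contact_state(cs, TRUE, 1.25, c(-0.707, -0.707))
  cs <- update_contact_state(cs, FALSE, 1.5, c(-0.707, -0.707))
  expect_identical(cs$phase, "recovery")
  expect_equal(cs$t1, 1.5)
  expect_equal(cs$t2, 2.5)                      # t1 + kappa*(t1 - t0)
  expect_equal(cs$t2 - cs$t1, 2 * (cs$t1 - cs$t0))
  # mean contact direction is a unit vector
  expect_equal(sum(cs$dbar^2), 1, tolerance = 1e-12)
  # recovery expires at t2
  cs2 <- update_contact_state(cs, FALSE, 2.6, c(0, -1))
  expect_identical(cs2$phase, "free")
  expect_equal(nrow(cs2$episodes), 1L)
  expect_equal(unlist(cs2$episodes[1, ]), c(t0 = 1.0, t1 = 1.5, t2 = 2.5))
  # re-contact during recovery restarts the contact phase
  cs3 <- update_contact_state(cs, TRUE, 2.0, c(0, -1))
  expect_identical(cs3$phase, "contact")
  expect_equal(cs3$t0, 2.0)
  expect_true(is.na(cs3$t1))
  # time regression is rejected
  expect_error(update_contact_state(cs3, TRUE, 1.0, c(0, -1)),
               "regression")
})

test_that("the history weight is 1 in contact, W_oi at t1, linear to 0 at t2", {
  cs <- new_contact_state(W_oi = 5, kappa = 2)
  cs <- update_contact_state(cs, TRUE, 1.0, c(0, -1))
  expect_equal(w_o_weight(cs, 1.2), 1)
  expect_equal(w_o_weight(cs, 1.0), 1)
  cs <- update_contact_state(cs, FALSE, 1.5, c(0, -1))
  expect_equal(w_o_weight(cs, 1.5), 5)              # W_oi at t1
  expect_equal(w_o_weight(cs, 2.0), 2.5)            # midpoint: W_oi/2
  expect_equal(w_o_weight(cs, 2.5), 0)
  expect_equal(w_o_weight(cs, 3.0), 0)
  # W_o is non-increasing across the recovery window
  tt <- seq(1.5, 2.5, by = 0.05)
  ww <- vapply(tt, function(t) w_o_weight(cs, t), 0)
  expect_true(all(diff(ww) <= 1e-12))
  expect_error(w_o_weight(cs, 0.5), "precedes")
  expect_error(new_contact_state(W_oi = 1), "W_oi")
})

test_that("contact direction policy projects entering steps onto the edge tangent", {
  # eta = 0: vertical approach becomes horizontal sliding
  obs0 <- obstacle(center = c(2, 2), length = 2, width = 0.4, eta = 0)
  pos <- c(1.8, 2.2005)                          # just above the top edge
  d <- contact_direction_policy(pos, obs0, c(0.1, -0.995), 0.1)
  expect_equal(abs(d[2]), 0, tolerance = 1e-9)   # beta = 0, sliding
  expect_equal(d[1], 1)                          # forward sense kept
  # eta = 45: sliding direction has beta = 45 degrees
  obs45 <- obstacle(center = c(2, 2), length = 2, width = 0.4, eta = 45)
  edge_mid <- (obs45$corners[1, ] + obs45$corners[2, ]) / 2
  p45 <- edge_mid + 0.0005 * obs45$v
  d45 <- contact_direction_policy(p45, obs45, c(0, -1), 0.1)
  expect_equal(atan2(abs(d45[2]), abs(d45[1])) * 180 / pi, 45,
               tolerance = 1e-6)
  # a step that does not enter the obstacle is left unchanged
  d_free <- contact_direction_policy(c(1.8, 2.2005), obs0, c(0, 1), 0.1)
  expect_equal(d_free, c(0, 1))
})

test_that("a full inclined-obstacle run slides at eta, recovers with ratio kappa, and keeps endpoints outside", {
  sim <- obstacle_run()
  ep <- sim$episodes
  expect_equal(nrow(ep), 1L)
  expect_equal((ep$t2 - ep$t1) / (ep$t1 - ep$t0), 2, tolerance = 1e-12)
  bt <- beta_trajectory(sim, 1)
  # phase-1 plateau at the obstacle inclination
  contact <- bt[bt$phase == "contact", ]
  expect_gt(nrow(contact), 5)
  expect_equal(stats::median(contact$beta), 45, tolerance = 0.5)
  # W_o = 1 throughout contact
  expect_true(all(abs(contact$W_o - 1) < 1e-12))
  # monotone return toward vertical after t2
  post <- bt[bt$time > ep$t2, ]
  expect_true(all(diff(post$beta) >= -1e-9))
  expect_equal(post$beta[nrow(post)], 90, tolerance = 5)
  # no segment endpoint strictly inside the obstacle, whole trajectory
  obs <- sim$obstacles[[1]]
  inside <- point_in_obstacle(obs, sim$segments$x1, sim$segments$z1,
                              strict = TRUE)
  expect_false(any(inside))
})
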