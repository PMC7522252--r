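# minimal hand-built simulation-shaped object: one vertical axis with
# one lateral attached at arc 1.0
toy_net <- function() {
  roots <- data.frame(root = 1:2, parent_root = c(0L, 1L),
                      attach_arc = c(0, 1), attach_seg = c(0L, 1L),
                      birth = c(0, 1), order = 1:2,
                      x0 = c(5, 5), z0 = c(9, 8),
                      dx0 = c(0, 0.5), dz0 = c(-1, -0.5),
                      apdx = c(NA, 0), apdz = c(NA, -1),
                      n_bp = c(1L, 0L))
  segs <- data.frame(seg = 1:3, root = c(1L, 1L, 2L),
                     parent_seg = c(0L, 1L, 1L),
                     x0 = c(5, 5, 5), z0 = c(9, 8, 8),
                     x1 = c(5, 5, 5.5), z1 = c(8, 7, 7.5),
                     len = c(1, 1, sqrt(0.5)),
                     birth = c(0.5, 1, 1.5), order = c(1L, 1L, 2L))
  tips <- data.frame(root = 1:2, x = c(5, 5.5), z = c(7, 7.5),
                     dx = c(0, 0.5), dz = c(-1, -0.5),
                     arc = c(2, sqrt(0.5)), halted = FALSE,
                     dt_pending = 0.05)
  structure(list(roots = roots, segments = segs, tips = tips,
                 config = list(seed_pos = c(5, 9)),
                 snapshots = list(), tip_log = data.frame()),
            class = "rsa_simulation")
}

test_that("total length sums segment lengths and is zero for empty systems", {
  expect_equal(total_length(data.frame(len = c(1, 1))), 2)
  expect_equal(total_length(data.frame(len = numeric(0))), 0)
  net <- toy_net()
  expect_equal(total_length(net), 2 + sqrt(0.5))
  # brute-force re-summation over a random polyline network
  set.seed(5)
  segs <- data.frame(len = sqrt(runif(40)^2 + runif(40)^2))
  acc <- 0
  for (i in seq_len(40)) acc <- acc + segs$len[i]
  expect_equal(total_length(segs), acc)
})

test_that("convex hull area handles triangles, squares and degenerate sets", {
  expect_equal(hull_area(c(0, 1, 0), c(0, 0, 1)), 0.5)
  expect_equal(hull_area(c(0, 1, 1, 0), c(0, 0, 1, 1)), 1)
  expect_equal(hull_area(c(0, 1, 2), c(0, 0, 0)), 0)    # collinear
  expect_equal(hull_area(c(0, 1), c(0, 1)), 0)          # two points
  net <- toy_net()
  expect_gt(foraging_area(net, axes = 1), 0)
  expect_error(foraging_area(structure(list(
    roots = net$roots[0, ], segments = net$segments[0, ]),
    class = "rsa_simulation")), "empty")
})

test_that("branching density is branch count over axis length", {
  net <- toy_net()
  expect_equal(branching_density(net, 1), 1 / 2)   # 1 lateral on 2 cm
  net2 <- toy_net()
  net2$roots$parent_root[2] <- 0L                  # detach: no laterals
  expect_equal(branching_density(net2, 1), 0)
})

test_that("the undirected graph has the seed/branch/tip topology and conserves length", {
  net <- toy_net()
  g <- to_undirected_graph(net)
  # one axis with one lateral: seed, 1 branch point, 2 tips = 4 nodes
  expect_equal(igraph::vcount(g), 4L)
  expect_equal(igraph::ecount(g), 3L)
  expect_equal(sum(igraph::E(g)$weight), total_length(net))
  expect_true(igraph::is_tree(g))
  kinds <- igraph::V(g)$kind
  expect_equal(sum(kinds == "tip"),
               nrow(net$tips))
  expect_equal(igraph::vcount(g),
               sum(kinds == "tip") + sum(kinds == "branch") + 1L)
})

test_that("graph statistics match enumeration oracles", {
  # 3-node path: middle node normalized betweenness = 1
  gp <- igraph::make_graph(~ a - b, b - c)
  st <- graph_stats(gp, weighted = FALSE)
  expect_equal(unname(st$betweenness["b"]), 1)
  expect_equal(st$node_connectivity, 1)
  # any tree has node connectivity 1
  gt <- to_undirected_graph(toy_net())
  expect_equal(graph_stats(gt)$node_connectivity, 1)
  # complete graph K4: all betweenness zero (direct edges everywhere)
  k4 <- igraph::make_full_graph(4)
  expect_true(all(graph_stats(k4, weighted = FALSE)$betweenness == 0))
  expect_error(graph_stats(igraph::make_graph(~ a - b, c - d)),
               "connected")
})

test_that("fan-tree length is the sum of seed-tip radii", {
  expect_equal(fan_tree_length(c(0, 0), rbind(c(1, 0), c(0, 1))), 2)
  expect_equal(fan_tree_length(c(0, 0), NULL), 0)
  expect_equal(fan_tree_length(c(1, 1), rbind(c(1, 1))), 0)  # coincident
})

test_that("the MST Steiner approximation matches brute-force spanning-tree enumeration", {
  # collinear: path length
  expect_equal(steiner_tree_length_approx(c(0, 0), rbind(c(1, 0), c(2, 0))),
               2)
  # brute force over all labelled spanning trees via Pruefer sequences
  mst_brute <- function(pts) {
    n <- nrow(pts)
    d <- as.matrix(stats::dist(pts))
    seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
    best <- Inf
    for (si in seq_len(nrow(seqs))) {
      prf <- seqs[si, ]
      deg <- rep(1L, n)
      for (v in prf) deg[v] <- deg[v] + 1L
      total <- 0
      prf_work <- prf
      deg_work <- deg
      for (v in prf_work) {
        leaf <- which(deg_work == 1L)[1]
        total <- total + d[leaf, v]
        deg_work[leaf] <- 0L
        deg_work[v] <- deg_work[v] - 1L
      }
      ends <- which(deg_work == 1L)
      total <- total + d[ends[1], ends[2]]
      best <- min(best, total)
    }
    best
  }
  set.seed(17)
  for (rep in 1:3) {
    tips <- cbind(runif(4, 0, 3), runif(4, 0, 3))
    seed <- c(runif(1, 0, 3), runif(1, 0, 3))
    pts <- rbind(seed, tips)
    expect_equal(steiner_tree_length_approx(seed, tips), mst_brute(pts),
                 tolerance = 1e-9)
  }
  # unit square with seed at a corner
  sq <- rbind(c(1, 0), c(0, 1), c(1, 1))
  expect_equal(steiner_tree_length_approx(c(0, 0), sq),
               mst_brute(rbind(c(0, 0), sq)))
})

test_that("Steiner approximation never exceeds the fan length and both bound the farthest tip", {
  set.seed(23)
  for (rep in 1:20) {
    ntip <- sample(2:8, 1)
    tips <- cbind(runif(ntip, -5, 5), runif(ntip, -5, 5))
    seed <- c(0, 0)
    st <- steiner_tree_length_approx(seed, tips)
    fan <- fan_tree_length(seed, tips)
    far <- max(sqrt(tips[, 1]^2 + tips[, 2]^2))
    expect_lte(st, fan + 1e-12)
    expect_gte(st, far - 1e-12)
    expect_gte(fan, far - 1e-12)
  }
})

test_that("beta angles map directions to degrees from horizontal", {
  sim <- obstacle_run()
  bt <- beta_trajectory(sim, 1)
  expect_true(all(bt$beta >= 0 & bt$beta <= 90))
  expect_equal(bt$beta[1], 90)                 # vertical start
  expect_error(beta_trajectory(sim, 99), "not present")
})

test_that("network indices of an RSML round-tripped system equal the in-memory ones", {
  sim <- small_run()
  path <- tempfile(fileext = ".rsml")
  write_rsml(sim, path)
  back <- rsml_as_simulation(read_rsml(path),
                             seed_pos = sim$config$seed_pos)
  expect_equal(total_length(back), total_length(sim), tolerance = 1e-9)
  expect_equal(foraging_area(back), foraging_area(sim), tolerance = 1e-9)
  expect_equal(branching_density(back, 1), branching_density(sim, 1),
               tolerance = 1e-9)
  expect_equal(steiner_tree_length_approx(sim$config$seed_pos,
                                          tip_positions(back)),
               steiner_tree_length_approx(sim$config$seed_pos,
                                          tip_positions(sim)),
               tolerance = 1e-9)
})
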