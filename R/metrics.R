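#' Total root network length
#'
#' @param x an `rsa_simulation`, or a segments data frame with a `len`
#'   column.
#' @return Total length (cm).
#' @export
total_length <- function(x) {
  segs <- if (inherits(x, "rsa_simulation")) x$segments else x
  if (is.null(segs) || nrow(segs) == 0) return(0)
  sum(segs$len)
}

#' Foraging area of an axis group
#'
#' Area of the 2D convex hull of all segment endpoints of the selected
#' axes and their descendant laterals. Degenerate (collinear) point sets
#' have zero area.
#'
#' @param sim an `rsa_simulation`.
#' @param axes integer ids of the axes to include (default: axes 1 and
#'   2, the axes that develop laterals); their whole subtrees are
#'   included.
#' @return Area (cm^2).
#' @export
foraging_area <- function(sim, axes = NULL) {
  roots <- sim$roots
  segs <- sim$segments
  if (nrow(roots) == 0) stop("empty root system")
  if (is.null(axes)) {
    ax <- roots$root[roots$order == 1L]
    axes <- utils::head(sort(ax), 2)
  }
  keep <- roots$root[roots$root %in% axes]
  repeat {
    more <- roots$root[roots$parent_root %in% keep & !(roots$root %in% keep)]
    if (length(more) == 0) break
    keep <- c(keep, more)
  }
  sel <- segs$root %in% keep
  if (!any(sel)) stop("no segments in the selected axis group")
  px <- c(segs$x0[sel], segs$x1[sel])
  pz <- c(segs$z0[sel], segs$z1[sel])
  hull_area(px, pz)
}

#' Convex hull area of a planar point set
#'
#' @param x,z point coordinates.
#' @return Hull area via the shoelace formula; 0 for degenerate sets.
#' @export
hull_area <- function(x, z) {
  if (length(x) < 3) return(0)
  idx <- grDevices::chull(x, z)
  if (length(idx) < 3) return(0)
  hx <- x[idx]; hz <- z[idx]
  abs(sum(hx * c(hz[-1], hz[1]) - c(hx[-1], hx[1]) * hz)) / 2
}

#' Branching density of an axis
#'
#' Number of lateral branch points on the axis divided by axis length.
#'
#' @param sim an `rsa_simulation`.
#' @param axis axis root id.
#' @return Density (1/cm).
#' @export
branching_density <- function(sim, axis = 1L) {
  segs <- sim$segments[sim$segments$root == axis, , drop = FALSE]
  len <- sum(segs$len)
  if (len <= 0) stop("axis has zero length")
  nb <- sum(sim$roots$parent_root == axis)
  nb / len
}

#' Root system as an undirected weighted graph
#'
#' Nodes are the seed, the branch points and the tips; edges follow the
#' root polylines with the path length between consecutive nodes as
#' weight, so the edge-weight sum equals [total_length()].
#'
#' @param sim an `rsa_simulation`.
#' @return An `igraph` undirected graph with vertex attributes `x`, `z`,
#'   `kind` (`seed`, `branch`, `tip`) and edge attribute `weight`.
#' @export
to_undirected_graph <- function(sim) {
  roots <- sim$roots
  segs <- sim$segments
  verts <- data.frame(name = "seed", x = sim$config$seed_pos[1],
                      z = sim$config$seed_pos[2], kind = "seed",
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = character(0), to = character(0),
                      weight = numeric(0))
  tip_xy <- function(r) {
    s <- segs[segs$root == r, , drop = FALSE]
    if (nrow(s) == 0) c(roots$x0[roots$root == r], roots$z0[roots$root == r])
    else c(s$x1[nrow(s)], s$z1[nrow(s)])
  }
  for (r in roots$root) {
    rlen <- sum(segs$len[segs$root == r])
    kids <- roots[roots$parent_root == r, , drop = FALSE]
    kids <- kids[order(kids$attach_arc), , drop = FALSE]
    origin <- if (roots$parent_root[roots$root == r] == 0) "seed"
    else sprintf("bp_%d", r)            # node where this root attaches
    arcs <- c(0, kids$attach_arc, rlen)
    names_chain <- c(origin,
                     sprintf("bp_%d", kids$root),
                     sprintf("tip_%d", r))
    # register branch-point vertices (attachment points of the children)
    for (ki in seq_len(nrow(kids))) {
      verts <- rbind(verts, data.frame(
        name = sprintf("bp_%d", kids$root[ki]),
        x = kids$x0[ki], z = kids$z0[ki], kind = "branch"))
    }
    txy <- tip_xy(r)
    verts <- rbind(verts, data.frame(name = sprintf("tip_%d", r),
                                     x = txy[1], z = txy[2],
                                     kind = "tip"))
    wgt <- diff(arcs)
    for (i in seq_along(wgt)) {
      if (wgt[i] <= 1e-12 && names_chain[i] == names_chain[i + 1]) next
      edges <- rbind(edges, data.frame(from = names_chain[i],
                                       to = names_chain[i + 1],
                                       weight = max(wgt[i], 0)))
    }
  }
  verts <- verts[!duplicated(verts$name), , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = verts)
  g
}

#' Graph statistics of a root network
#'
#' Node (vertex) connectivity and the mean normalized betweenness
#' centrality (each node's betweenness divided by the number of node
#' pairs excluding it, `(n-1)(n-2)/2` for undirected graphs).
#'
#' @param g an `igraph` graph (connected).
#' @param weighted use edge weights as distances for betweenness
#'   (default `TRUE` when present).
#' @return List with `node_connectivity`, `mean_betweenness`, and the
#'   per-vertex normalized `betweenness`.
#' @export
graph_stats <- function(g, weighted = TRUE) {
  if (!igraph::is_connected(g)) stop("graph must be connected")
  wts <- if (weighted && "weight" %in% igraph::edge_attr_names(g)) {
    w <- igraph::E(g)$weight
    if (any(w <= 0)) w <- pmax(w, 1e-12)
    w
  } else NA
  btw <- igraph::betweenness(g, directed = FALSE, weights = wts,
                             normalized = TRUE)
  list(node_connectivity = igraph::vertex_connectivity(g),
       mean_betweenness = mean(btw),
       betweenness = btw)
}

#' Fan-tree reference length
#'
#' Total length of the star network connecting the seed straight to
#' every tip.
#'
#' @param seed numeric length-2 seed position.
#' @param tips matrix or data frame of tip coordinates (columns x, z).
#' @return Length (cm).
#' @export
fan_tree_length <- function(seed, tips) {
  if (is.null(tips) || NROW(tips) == 0) return(0)
  tips <- as.matrix(tips)
  sum(sqrt((tips[, 1] - seed[1])^2 + (tips[, 2] - seed[2])^2))
}

#' Steiner-tree reference length (MST approximation)
#'
#' Length of the Euclidean minimum spanning tree over the seed and the
#' tips — the classic 2-approximation of the Euclidean Steiner minimal
#' tree. Never exceeds [fan_tree_length()].
#'
#' @inheritParams fan_tree_length
#' @return Length (cm).
#' @export
steiner_tree_length_approx <- function(seed, tips) {
  if (is.null(tips) || NROW(tips) == 0) return(0)
  pts <- rbind(as.numeric(seed), as.matrix(tips))
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 2) return(0)
  d <- as.matrix(stats::dist(pts))
  # Prim's algorithm
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- d[1, ]
  total <- 0
  for (k in seq_len(n - 1)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best[cand])]
    total <- total + best[j]
    in_tree[j] <- TRUE
    best <- pmin(best, d[j, ])
  }
  unname(total)
}

#' Tip coordinates of a simulation
#'
#' @param sim an `rsa_simulation`.
#' @return Matrix with columns `x`, `z` of all root tip positions.
#' @export
tip_positions <- function(sim) {
  cbind(x = sim$tips$x, z = sim$tips$z)
}

#' Growth-angle trajectory of an axis
#'
#' The growth angle `beta` is the angle between the instantaneous tip
#' direction and the horizontal (degrees; 90 = vertical), logged at
#' every growth step.
#'
#' @param sim an `rsa_simulation`.
#' @param axis axis root id.
#' @return Data frame `time`, `beta`, `phase`, `W_o`.
#' @export
beta_trajectory <- function(sim, axis = 1L) {
  if (!(axis %in% sim$roots$root)) stop("axis not present: ", axis)
  lg <- sim$tip_log[sim$tip_log$root == axis, , drop = FALSE]
  data.frame(time = lg$time, beta = lg$beta, phase = lg$phase,
             W_o = lg$W_o)
}

#' All network indices of a simulation
#'
#' @param sim an `rsa_simulation`.
#' @param axes axis group for foraging area / branching density
#'   (default the first two axes).
#' @return One-row data frame of the indices.
#' @export
network_indices <- function(sim, axes = NULL) {
  roots <- sim$roots
  if (is.null(axes)) {
    ax <- sort(roots$root[roots$order == 1L])
    axes <- utils::head(ax, 2)
  }
  fa <- if (nrow(sim$segments) > 0) foraging_area(sim, axes) else 0
  bd <- mean(vapply(axes, function(a) {
    s <- sim$segments[sim$segments$root == a, , drop = FALSE]
    if (nrow(s) == 0 || sum(s$len) <= 0) return(NA_real_)
    branching_density(sim, a)
  }, 0), na.rm = TRUE)
  tl <- total_length(sim)
  st <- if (nrow(sim$tips) > 0)
    steiner_tree_length_approx(sim$config$seed_pos, tip_positions(sim))
  else 0
  ft <- if (nrow(sim$tips) > 0)
    fan_tree_length(sim$config$seed_pos, tip_positions(sim))
  else 0
  data.frame(total_length = tl, foraging_area = fa,
             branching_density = if (is.nan(bd)) 0 else bd,
             fan_length = ft, steiner_length = st)
}
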