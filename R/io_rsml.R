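#' Write a root system to RSML
#'
#' Serialises the root architecture to the Root System Markup Language
#' (XML): one `<scene>`/`<plant>`, one `<root>` element per root with
#' nested children, polyline geometry, per-root properties (order,
#' birth time, attachment arc length, parent id) and a per-node
#' `birth_time` function annotation. Units are centimetres and days.
#' Geometry is written with 15 significant digits so a write/read round
#' trip reproduces the segment table.
#'
#' @param sim an `rsa_simulation`, or a list with `roots` and `segments`
#'   tables (plus `config$seed_pos`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rsml <- function(sim, path) {
  roots <- sim$roots
  segs <- sim$segments
  doc <- xml2::xml_new_root("rsml")
  meta <- xml2::xml_add_child(doc, "metadata")
  xml2::xml_add_child(meta, "version", "1")
  xml2::xml_add_child(meta, "unit", "cm")
  xml2::xml_add_child(meta, "resolution", "1")
  xml2::xml_add_child(meta, "time-unit", "day")
  xml2::xml_add_child(meta, "software", "rhizogrow")
  scene <- xml2::xml_add_child(doc, "scene")
  plant <- xml2::xml_add_child(scene, "plant", id = "1", label = "plant")

  num <- function(v) sprintf("%.15g", v)
  add_root <- function(parent_node, rid) {
    rrow <- roots[roots$root == rid, ]
    rsegs <- segs[segs$root == rid, , drop = FALSE]
    rn <- xml2::xml_add_child(parent_node, "root",
                              ID = as.character(rid),
                              label = sprintf("root-%d", rid))
    props <- xml2::xml_add_child(rn, "properties")
    xml2::xml_add_child(props, "order", as.character(rrow$order))
    xml2::xml_add_child(props, "birth", num(rrow$birth))
    xml2::xml_add_child(props, "attach_arc", num(rrow$attach_arc))
    xml2::xml_add_child(props, "parent_root",
                        as.character(rrow$parent_root))
    geom <- xml2::xml_add_child(rn, "geometry")
    poly <- xml2::xml_add_child(geom, "polyline")
    px <- c(rrow$x0, rsegs$x1)
    pz <- c(rrow$z0, rsegs$z1)
    births <- c(rrow$birth, rsegs$birth)
    for (i in seq_along(px))
      xml2::xml_add_child(poly, "point", x = num(px[i]), y = num(pz[i]))
    fns <- xml2::xml_add_child(rn, "functions")
    fn <- xml2::xml_add_child(fns, "function", name = "birth_time",
                              domain = "polyline")
    for (b in births)
      xml2::xml_add_child(fn, "sample", value = num(b))
    kids <- roots$root[roots$parent_root == rid]
    for (k in kids) add_root(rn, k)
  }
  top <- roots$root[roots$parent_root == 0]
  for (rid in top) add_root(plant, rid)
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a root system from RSML
#'
#' Accepts both nested (children inside their parent `<root>`) and flat
#' layouts (all roots under `<plant>` with a `parent_root` property).
#' Validates that the parent relations form a forest and that polyline
#' geometry is present.
#'
#' @param path RSML file path.
#' @return A list with `roots` and `segments` tables in the same layout
#'   as an `rsa_simulation`, suitable for [total_length()] and the
#'   other metric functions (wrap via [rsml_as_simulation()]).
#' @export
read_rsml <- function(path) {
  if (!file.exists(path)) stop("RSML file not found: ", path)
  doc <- xml2::read_xml(path)
  root_nodes <- xml2::xml_find_all(doc, ".//root")
  roots <- data.frame(root = integer(0), parent_root = integer(0),
                      attach_arc = numeric(0), attach_seg = integer(0),
                      birth = numeric(0), order = integer(0),
                      x0 = numeric(0), z0 = numeric(0),
                      dx0 = numeric(0), dz0 = numeric(0),
                      n_bp = integer(0))
  seg_list <- list()
  prop <- function(node, name, default = NA) {
    v <- xml2::xml_text(xml2::xml_find_first(
      node, sprintf("./properties/%s", name)))
    if (is.na(v) || !nzchar(v)) default else v
  }
  for (rn in root_nodes) {
    rid <- as.integer(xml2::xml_attr(rn, "ID"))
    if (is.na(rid)) stop("RSML parse error: root without ID attribute")
    # structural parent: enclosing <root>, else the parent_root property
    anc <- xml2::xml_parent(rn)
    parent_struct <- if (xml2::xml_name(anc) == "root")
      as.integer(xml2::xml_attr(anc, "ID")) else NA_integer_
    parent_prop <- suppressWarnings(as.integer(prop(rn, "parent_root",
                                                    NA)))
    parent <- if (!is.na(parent_struct)) parent_struct
    else if (!is.na(parent_prop)) parent_prop else 0L
    pts <- xml2::xml_find_all(rn, "./geometry/polyline/point")
    if (length(pts) == 0)
      stop("RSML parse error: root ", rid, " has no polyline geometry")
    px <- as.numeric(xml2::xml_attr(pts, "x"))
    pz <- as.numeric(xml2::xml_attr(pts, "y"))
    bt <- xml2::xml_find_all(
      rn, "./functions/function[@name='birth_time']/sample")
    births <- if (length(bt) == length(px))
      as.numeric(xml2::xml_attr(bt, "value"))
    else rep(as.numeric(prop(rn, "birth", 0)), length(px))
    ord <- as.integer(prop(rn, "order", 1L))
    roots[nrow(roots) + 1L, ] <-
      list(rid, parent, as.numeric(prop(rn, "attach_arc", 0)), 0L,
           births[1], ord, px[1], pz[1],
           NA_real_, NA_real_, 0L)
    if (length(px) > 1) {
      seg_list[[length(seg_list) + 1L]] <- data.frame(
        root = rid,
        x0 = px[-length(px)], z0 = pz[-length(pz)],
        x1 = px[-1], z1 = pz[-1],
        len = sqrt(diff(px)^2 + diff(pz)^2),
        birth = births[-1], order = ord)
    }
  }
  if (anyDuplicated(roots$root))
    stop("RSML parse error: duplicate root IDs: ",
         paste(unique(roots$root[duplicated(roots$root)]), collapse = ", "))
  # forest validation: follow parent links, detect cycles
  par <- stats::setNames(roots$parent_root, roots$root)
  for (r in roots$root) {
    seen <- integer(0)
    cur <- r
    while (cur != 0) {
      if (cur %in% seen)
        stop("RSML parse error: cycle in parent links involving roots ",
             paste(c(seen, cur), collapse = " -> "))
      seen <- c(seen, cur)
      if (!(cur %in% roots$root))
        stop("RSML parse error: parent id ", cur, " not present")
      cur <- par[[as.character(cur)]]
    }
  }
  segs <- if (length(seg_list)) do.call(rbind, seg_list)
  else data.frame(root = integer(0), x0 = numeric(0), z0 = numeric(0),
                  x1 = numeric(0), z1 = numeric(0), len = numeric(0),
                  birth = numeric(0), order = integer(0))
  segs$seg <- seq_len(nrow(segs))
  list(roots = roots, segments = segs)
}

#' Wrap an RSML network for the metric functions
#'
#' @param net result of [read_rsml()].
#' @param seed_pos seed position; defaults to the origin of the first
#'   top-level root.
#' @return A minimal `rsa_simulation`-shaped list.
#' @export
rsml_as_simulation <- function(net, seed_pos = NULL) {
  if (is.null(seed_pos)) {
    top <- net$roots[net$roots$parent_root == 0, , drop = FALSE]
    seed_pos <- c(top$x0[1], top$z0[1])
  }
  tips <- do.call(rbind, lapply(net$roots$root, function(r) {
    s <- net$segments[net$segments$root == r, , drop = FALSE]
    if (nrow(s) == 0)
      data.frame(root = r, x = net$roots$x0[net$roots$root == r],
                 z = net$roots$z0[net$roots$root == r])
    else data.frame(root = r, x = s$x1[nrow(s)], z = s$z1[nrow(s)])
  }))
  structure(list(roots = net$roots, segments = net$segments,
                 tips = tips, config = list(seed_pos = seed_pos),
                 snapshots = list(), tip_log = data.frame()),
            class = "rsa_simulation")
}
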