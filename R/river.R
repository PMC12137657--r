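#' Read a GeoJSON LineString collection
#'
#' Supports a FeatureCollection of LineString / MultiLineString features
#' or a bare (Multi)LineString geometry. Coordinates are returned as-is
#' (typically lon/lat); project with [project_coordinates()] before
#' distance computations.
#'
#' @param path GeoJSON file.
#' @return list of two-column coordinate matrices, one per polyline.
#' @export
read_river_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- list()
  grab <- function(geom) {
    if (is.null(geom$type)) return()
    if (geom$type == "LineString") {
      out[[length(out) + 1]] <<- do.call(rbind, lapply(geom$coordinates,
                                                       function(p) unlist(p)[1:2]))
    } else if (geom$type == "MultiLineString") {
      for (ls in geom$coordinates)
        out[[length(out) + 1]] <<- do.call(rbind, lapply(ls, function(p) unlist(p)[1:2]))
    }
  }
  if (identical(gj$type, "FeatureCollection")) {
    for (f in gj$features) grab(f$geometry)
  } else if (identical(gj$type, "Feature")) {
    grab(gj$geometry)
  } else grab(gj)
  if (length(out) == 0) stop("no LineString geometries found in ", path)
  out
}

# Nearest point on segment ab to point p; returns list(point, dist, t).
.project_on_segment <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
  q <- a + t * ab
  list(point = q, dist = sqrt(sum((p - q)^2)), t = t)
}

#' Waterway distances between localities along a river network
#'
#' Localities are snapped to the nearest point on the polyline network
#' (the snap offset is NOT added to path lengths); distances are shortest
#' paths along the network. Polyline endpoints within `snap_tol` metres
#' are fused into shared nodes so touching segments connect.
#'
#' @param localities data frame with columns `locality_id`, `x`, `y`
#'   (planar metres).
#' @param network list of two-column coordinate matrices (planar metres),
#'   e.g. projected output of [read_river_geojson()].
#' @param snap_tol endpoint fusion tolerance, metres.
#' @return symmetric matrix of along-network distances in metres, with
#'   `locality_id` dimnames.
#' @export
river_distance <- function(localities, network, snap_tol = 1) {
  stopifnot(all(c("locality_id", "x", "y") %in% names(localities)))
  # collect segments
  segs <- list()
  for (pl in network) {
    pl <- as.matrix(pl)
    if (nrow(pl) < 2) next
    for (i in seq_len(nrow(pl) - 1))
      segs[[length(segs) + 1]] <- rbind(pl[i, ], pl[i + 1, ])
  }
  if (length(segs) == 0) stop("empty river network")

  # node registry with snap-tolerance fusion
  nodes <- matrix(numeric(0), ncol = 2)
  node_id <- function(p, tol) {
    if (nrow(nodes) > 0) {
      d2 <- (nodes[, 1] - p[1])^2 + (nodes[, 2] - p[2])^2
      j <- which.min(d2)
      if (d2[j] <= tol^2) return(j)
    }
    nodes <<- rbind(nodes, p)
    nrow(nodes)
  }

  seg_from <- integer(0); seg_to <- integer(0)
  for (s in segs) {
    seg_from <- c(seg_from, node_id(s[1, ], snap_tol))
    seg_to <- c(seg_to, node_id(s[2, ], snap_tol))
  }

  # snap localities: nearest point over all segments, then split that
  # segment at the snap point (t in (0,1)) by adding a node
  n_loc <- nrow(localities)
  loc_node <- integer(n_loc)
  # per-segment split points: list of (t, node)
  splits <- vector("list", length(segs))
  for (i in seq_len(n_loc)) {
    p <- c(localities$x[i], localities$y[i])
    best <- NULL; best_seg <- NA
    for (k in seq_along(segs)) {
      pr <- .project_on_segment(p, segs[[k]][1, ], segs[[k]][2, ])
      if (is.null(best) || pr$dist < best$dist) { best <- pr; best_seg <- k }
    }
    nid <- node_id(best$point, snap_tol)
    loc_node[i] <- nid
    if (nid != seg_from[best_seg] && nid != seg_to[best_seg])
      splits[[best_seg]] <- rbind(splits[[best_seg]], c(best$t, nid))
  }

  # build edge list, splitting segments at recorded interior nodes
  ef <- integer(0); et <- integer(0); ew <- numeric(0)
  for (k in seq_along(segs)) {
    a_id <- seg_from[k]; b_id <- seg_to[k]
    a <- nodes[a_id, ]; b <- nodes[b_id, ]
    sp <- splits[[k]]
    if (is.null(sp)) {
      ef <- c(ef, a_id); et <- c(et, b_id)
      ew <- c(ew, sqrt(sum((b - a)^2)))
    } else {
      ord <- order(sp[, 1])
      chain <- c(a_id, sp[ord, 2], b_id)
      for (j in seq_len(length(chain) - 1)) {
        p1 <- nodes[chain[j], ]; p2 <- nodes[chain[j + 1], ]
        ef <- c(ef, chain[j]); et <- c(et, chain[j + 1])
        ew <- c(ew, sqrt(sum((p2 - p1)^2)))
      }
    }
  }

  g <- igraph::graph_from_edgelist(cbind(ef, et), directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = ew)
  if (igraph::vcount(g) < nrow(nodes))
    g <- igraph::add_vertices(g, nrow(nodes) - igraph::vcount(g))

  comp <- igraph::components(g)$membership
  loc_comp <- comp[loc_node]
  if (length(unique(loc_comp)) > 1)
    stop("river network is disconnected across queried localities; ",
         "components: ", paste(sort(unique(loc_comp)), collapse = ", "))

  uniq <- unique(loc_node)
  du <- igraph::distances(g, v = uniq, to = uniq, weights = ew)
  d <- du[match(loc_node, uniq), match(loc_node, uniq), drop = FALSE]
  dimnames(d) <- list(localities$locality_id, localities$locality_id)
  attr(d, "snapped") <- nodes[loc_node, , drop = FALSE]
  d
}
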