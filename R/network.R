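#' Create an empty vascular network
#'
#' A capillary graph: spatial nodes (mm, lower-left-origin frame) and
#' segments carrying diameter, capillary order and a parent-vessel flag.
#' Segment lengths are always the Euclidean distance between their end
#' nodes.
#'
#' @return an object of class `vascular_network` with `nodes`
#'   (id, x, y, kind) and `segments`
#'   (id, from, to, diameter, order, parent, length, generation).
#' @export
vascular_network <- function() {
  structure(list(
    nodes = data.frame(id = integer(), x = numeric(), y = numeric(),
                       kind = character(), stringsAsFactors = FALSE),
    segments = data.frame(id = integer(), from = integer(), to = integer(),
                          diameter = numeric(), order = integer(),
                          parent = logical(), length = numeric(),
                          generation = integer(), stringsAsFactors = FALSE)
  ), class = "vascular_network")
}

#' Add a node to a vascular network
#'
#' @param net a `vascular_network`.
#' @param x,y position (mm).
#' @param kind one of "parent", "sprout", "junction".
#' @return the network; the new node's id is in `attr(, "last_id")`.
#' @export
add_network_node <- function(net, x, y, kind = "sprout") {
  stopifnot(inherits(net, "vascular_network"),
            kind %in% c("parent", "sprout", "junction"))
  id <- nrow(net$nodes) + 1L
  net$nodes[id, ] <- list(id, x, y, kind)
  attr(net, "last_id") <- id
  net
}

#' Add a segment between two existing nodes
#'
#' @param net a `vascular_network`.
#' @param from,to node ids (must differ: no self-loops).
#' @param diameter vessel diameter (mm, > 0).
#' @param order capillary order (1 = highest calibre).
#' @param parent logical; parent-vessel segments are frozen during
#'   adaptation.
#' @param generation growth iteration at which the segment appeared.
#' @return the network; the new segment's id is in `attr(, "last_seg")`.
#' @export
add_segment <- function(net, from, to, diameter, order = 1L, parent = FALSE,
                        generation = 0L) {
  stopifnot(inherits(net, "vascular_network"), from != to, diameter > 0,
            order >= 1)
  len <- sqrt((net$nodes$x[from] - net$nodes$x[to])^2 +
                (net$nodes$y[from] - net$nodes$y[to])^2)
  id <- nrow(net$segments) + 1L
  net$segments[id, ] <- list(id, as.integer(from), as.integer(to), diameter,
                             as.integer(order), parent, len,
                             as.integer(generation))
  attr(net, "last_seg") <- id
  net
}

#' Node degrees of a vascular network
#' @param net a `vascular_network`.
#' @return integer vector over node ids.
#' @export
node_degree <- function(net) {
  tabulate(c(net$segments$from, net$segments$to), nbins = nrow(net$nodes))
}

#' Convert a vascular network to an igraph graph
#' @param net a `vascular_network`.
#' @return an `igraph` object with node/segment attributes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "vascular_network"))
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = net$segments$from, to = net$segments$to,
                   diameter = net$segments$diameter,
                   order = net$segments$order,
                   parent = net$segments$parent,
                   length = net$segments$length),
    directed = FALSE,
    vertices = data.frame(name = net$nodes$id, x = net$nodes$x,
                          y = net$nodes$y, kind = net$nodes$kind))
  g
}

#' Export a vascular network as CSV edge tables (and optionally GraphML)
#'
#' Writes `<prefix>_nodes.csv` (id,x,y,kind), `<prefix>_segments.csv`
#' (id,node_a,node_b,diameter_mm,order,parent,length_mm) and, if
#' `graphml = TRUE`, `<prefix>.graphml` with the same attributes.
#'
#' @param net a `vascular_network`.
#' @param prefix output path prefix.
#' @param graphml also write GraphML.
#' @return the prefix, invisibly.
#' @export
export_network <- function(net, prefix, graphml = FALSE) {
  stopifnot(inherits(net, "vascular_network"))
  utils::write.csv(net$nodes, paste0(prefix, "_nodes.csv"), row.names = FALSE)
  seg <- data.frame(id = net$segments$id, node_a = net$segments$from,
                    node_b = net$segments$to,
                    diameter_mm = net$segments$diameter,
                    order = net$segments$order,
                    parent = net$segments$parent,
                    length_mm = net$segments$length)
  utils::write.csv(seg, paste0(prefix, "_segments.csv"), row.names = FALSE)
  if (graphml)
    igraph::write_graph(as_igraph(net), paste0(prefix, ".graphml"),
                        format = "graphml")
  invisible(prefix)
}

#' Import a vascular network from CSV edge tables
#'
#' Inverse of [export_network()]; accepts any edge table with the same
#' columns, so an externally digitised capillary graph can be fed straight
#' into the flow and adaptation stages.
#'
#' @param prefix path prefix used at export.
#' @return a `vascular_network`.
#' @export
import_network <- function(prefix) {
  nodes <- utils::read.csv(paste0(prefix, "_nodes.csv"),
                           stringsAsFactors = FALSE)
  seg <- utils::read.csv(paste0(prefix, "_segments.csv"),
                         stringsAsFactors = FALSE)
  net <- vascular_network()
  net$nodes <- data.frame(id = as.integer(nodes$id), x = nodes$x, y = nodes$y,
                          kind = nodes$kind, stringsAsFactors = FALSE)
  net$segments <- data.frame(
    id = as.integer(seg$id), from = as.integer(seg$node_a),
    to = as.integer(seg$node_b), diameter = seg$diameter_mm,
    order = as.integer(seg$order),
    parent = if (is.null(seg$parent)) rep(FALSE, nrow(seg)) else as.logical(seg$parent),
    length = seg$length_mm,
    generation = rep(0L, nrow(seg)), stringsAsFactors = FALSE)
  net
}
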