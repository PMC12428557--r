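#' Build an RBP interaction network
#'
#' @param nodes Tibble with `rbp` and `deg` columns; `deg` is `"up"`,
#'   `"down"` or `"none"` (a logical column is accepted and mapped to
#'   `"up"`/`"none"`).
#' @param edges Tibble with columns `a`, `b` (undirected physical
#'   interactions). Edges must reference known nodes.
#' @return An `rbp_network` object.
#' @export
rbp_network <- function(nodes, edges) {
  stopifnot(all(c("rbp", "deg") %in% names(nodes)),
            all(c("a", "b") %in% names(edges)))
  if (is.logical(nodes$deg)) nodes$deg <- if_else(nodes$deg, "up", "none")
  stopifnot(all(nodes$deg %in% c("up", "down", "none")))
  bad <- setdiff(c(edges$a, edges$b), nodes$rbp)
  if (length(bad) > 0) {
    abort(sprintf("edge references unknown node(s): %s",
                  paste(utils::head(bad, 5), collapse = ", ")))
  }
  out <- list(nodes = as_tibble(nodes[, c("rbp", "deg")]),
              edges = as_tibble(edges[, c("a", "b")]))
  class(out) <- "rbp_network"
  out
}

#' Reduce an RBP network to components reachable from DEG nodes
#'
#' Keeps every differentially expressed (DEG) node, and every non-DEG node
#' connected to at least one DEG node by some path; edges are restricted to
#' the kept nodes. Idempotent.
#'
#' @param network An `rbp_network`.
#' @return The reduced `rbp_network`.
#' @export
reduce_rbp_network <- function(network) {
  stopifnot(inherits(network, "rbp_network"))
  nodes <- network$nodes
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = nodes$rbp)
  comp <- igraph::components(g)$membership
  deg_nodes <- nodes$rbp[nodes$deg != "none"]
  keep_comps <- unique(comp[names(comp) %in% deg_nodes])
  keep <- nodes$rbp %in% names(comp)[comp %in% keep_comps]
  new_nodes <- nodes[keep, , drop = FALSE]
  new_edges <- network$edges[network$edges$a %in% new_nodes$rbp &
                               network$edges$b %in% new_nodes$rbp, , drop = FALSE]
  rbp_network(new_nodes, new_edges)
}

#' @export
print.rbp_network <- function(x, ...) {
  cat(sprintf("<rbp_network> %d nodes (%d DEG), %d edges\n",
              nrow(x$nodes), sum(x$nodes$deg != "none"), nrow(x$edges)))
  invisible(x)
}

#' @export
tidy.rbp_network <- function(x, ...) x$nodes

#' @export
glance.rbp_network <- function(x, ...) {
  g <- igraph::graph_from_data_frame(x$edges, directed = FALSE,
                                     vertices = x$nodes$rbp)
  tibble(n_nodes = nrow(x$nodes),
         n_deg = sum(x$nodes$deg != "none"),
         n_edges = nrow(x$edges),
         n_components = igraph::components(g)$no)
}

#' Plot an RBP network
#'
#' @param object An `rbp_network`.
#' @param ... Unused.
#' @return A ggplot object (force-directed layout; DEG nodes ringed).
#' @export
autoplot.rbp_network <- function(object, ...) {
  g <- igraph::graph_from_data_frame(object$edges, directed = FALSE,
                                     vertices = object$nodes$rbp)
  set.seed(1L)
  xy <- igraph::layout_with_fr(g)
  nd <- object$nodes
  nd$x <- xy[, 1]; nd$y <- xy[, 2]
  ed <- object$edges
  ed$x <- nd$x[match(ed$a, nd$rbp)]; ed$y <- nd$y[match(ed$a, nd$rbp)]
  ed$xend <- nd$x[match(ed$b, nd$rbp)]; ed$yend <- nd$y[match(ed$b, nd$rbp)]
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey70") +
    ggplot2::geom_point(data = nd,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$deg), size = 4) +
    ggplot2::geom_text(data = nd,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$rbp),
                       vjust = -1.2, size = 3) +
    ggplot2::scale_colour_manual(values = c(up = "goldenrod", down = "steelblue",
                                            none = "grey50")) +
    ggplot2::theme_void()
}
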