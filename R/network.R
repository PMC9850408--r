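#' Build a colocalization network over one or more baits
#'
#' One node per bait and per retained feature, one edge bait-feature for
#' every entry at or above the PCC `floor`, labelled with its threshold
#' band. Features colocalized with several baits appear once and carry
#' multiple edges. Topology is a star per bait: feature-feature
#' correlations are not computed (quadratic cost, and the display
#' convention puts the bait at the centre anyway).
#'
#' @param results A `pica_coloc` or list of them.
#' @param floor Minimum PCC for an edge (default 0.6).
#' @param high,moderate_low Band edges passed to [classify_bands()].
#' @return A `coloc_network`: list with tibbles `nodes` (`name`, `type`)
#'   and `edges` (`bait`, `feature_mz`, `pcc`, `band`).
#' @examples
#' d <- simulate_msi(sim_config(seed = 1))$dataset
#' res <- colocalize(tic_normalize(d), bait_mz = 611.1607)
#' net <- build_network(res)
#' glance(net)
#' @export
build_network <- function(results, floor = 0.6, high = 0.9,
                          moderate_low = 0.6) {
  if (inherits(results, "pica_coloc")) results <- list(results)
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, logical(1), "pica_coloc")))
  edges <- purrr::map_dfr(results, function(res) {
    ent <- classify_bands(res, high = high, moderate_low = moderate_low)
    ent <- ent[ent$pcc >= floor, ]
    # the bait's own feature is the hub, not an edge to itself
    ent <- ent[abs(ent$feature_mz - res$bait$mz) > res$bait$tol, ]
    tibble::tibble(
      bait = sprintf("%.4f", res$bait$mz),
      feature_mz = ent$feature_mz,
      pcc = ent$pcc,
      band = as.character(ent$band)
    )
  })
  bait_nodes <- tibble::tibble(
    name = vapply(results, function(r) sprintf("%.4f", r$bait$mz), character(1)),
    type = "bait"
  )
  feat_nodes <- tibble::tibble(
    name = sprintf("%.4f", sort(unique(edges$feature_mz))),
    type = "feature"
  )
  feat_nodes <- feat_nodes[!feat_nodes$name %in% bait_nodes$name, ]
  structure(list(nodes = dplyr::bind_rows(bait_nodes, feat_nodes),
                 edges = edges, floor = floor,
                 bands = c(high = high, moderate_low = moderate_low)),
            class = "coloc_network")
}

#' @export
print.coloc_network <- function(x, ...) {
  cat(sprintf("<coloc_network> %d nodes (%d baits), %d edges (PCC >= %s)\n",
              nrow(x$nodes), sum(x$nodes$type == "bait"), nrow(x$edges),
              format(x$floor)))
  invisible(x)
}

#' @rdname build_network
#' @param x A `coloc_network`.
#' @param ... Unused.
#' @export
tidy.coloc_network <- function(x, ...) x$edges

#' @rdname build_network
#' @export
glance.coloc_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_baits = sum(x$nodes$type == "bait"),
    n_edges = nrow(x$edges),
    floor = x$floor
  )
}

as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = net$edges$bait,
                   to = sprintf("%.4f", net$edges$feature_mz),
                   pcc = net$edges$pcc, band = net$edges$band),
    directed = FALSE,
    vertices = as.data.frame(net$nodes)
  )
  g
}

#' Export a colocalization network
#'
#' `"graphml"` via igraph (node `type`, edge `pcc` and `band` attributes
#' preserved; re-importable with [igraph::read_graph()]), or
#' `"edgelist_csv"` (columns `bait`, `feature_mz`, `pcc`, `band`).
#'
#' @param net A `coloc_network`.
#' @param path Output path.
#' @param format `"graphml"` or `"edgelist_csv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "edgelist_csv")) {
  stopifnot(inherits(net, "coloc_network"))
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  } else {
    readr::write_csv(net$edges, path)
  }
  invisible(path)
}

#' @export
autoplot.coloc_network <- function(object, ...) {
  g <- as_igraph(object)
  lay <- igraph::layout_in_circle(g)  # deterministic; layout is cosmetic
  nodes <- tibble::tibble(name = igraph::V(g)$name, type = igraph::V(g)$type,
                          x = lay[, 1], y = lay[, 2])
  ed <- tibble::as_tibble(igraph::as_data_frame(g, "edges"))
  ed <- dplyr::left_join(ed, nodes[, c("name", "x", "y")],
                         by = c(from = "name"))
  ed <- dplyr::left_join(ed, nodes[, c("name", "x", "y")],
                         by = c(to = "name"), suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       colour = .data$band)) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     shape = .data$type), size = 3) +
    ggplot2::theme_void() +
    ggplot2::labs(title = "Colocalization network")
}
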