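# Per-individual centrality on posterior network draws: strength, weighted
# closeness and thresholded degree. Closeness uses the reciprocal of the
# edge weight as the path-length metric (rate -> distance), computed on the
# complete draw; degree alone is thresholded, at the group-year's minimum
# observed non-zero weight, because posterior draws put positive weight on
# every dyad.

.check_net <- function(net) stopifnot(inherits(net, "posterior_network"))

.resolve_id <- function(net, id) {
  k <- match(id, net$ids)
  if (anyNA(k)) stop("unknown id: ", paste(id[is.na(k)], collapse = ", "))
  k
}

#' Node strength
#'
#' Weighted sum of an individual's social connections (total grooming rate).
#'
#' @param net a `posterior_network` draw.
#' @param id optional id (or vector of ids); default all nodes.
#' @return Named numeric vector of strengths.
#' @export
compute_strength <- function(net, id = NULL) {
  .check_net(net)
  s <- rowSums(net$weights)
  if (is.null(id)) s else s[.resolve_id(net, id)]
}

#' Weighted closeness centrality
#'
#' The inverse of the mean weighted shortest-path length from an individual
#' to all others, where an edge of weight `w` has length `1/w`. On the
#' complete, strictly positive posterior draws every node is reachable; an
#' unreachable node raises an error.
#'
#' @inheritParams compute_strength
#' @return Named numeric vector of closeness values.
#' @examples
#' # complete 3-node network with equal weights w has closeness w everywhere
#' @export
compute_closeness <- function(net, id = NULL) {
  .check_net(net)
  W <- net$weights
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  D <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  if (any(!is.finite(D)))
    stop("network has unreachable node pairs; closeness undefined")
  n <- nrow(D)
  cl <- 1 / (rowSums(D) / (n - 1))
  names(cl) <- net$ids
  if (is.null(id)) cl else cl[.resolve_id(net, id)]
}

#' Thresholded degree centrality
#'
#' Number of incident edges with weight greater than or equal to
#' `threshold`. The analysis convention is to threshold at the group-year's
#' minimum observed non-zero edge weight (stored on the draw), so that an
#' individual's weakest real connections still count while the posterior's
#' near-zero mass on never-observed dyads does not.
#'
#' @param net a `posterior_network` draw.
#' @param threshold positive cut-off; defaults to `net$threshold`.
#' @return Named integer vector of degrees.
#' @export
compute_degree <- function(net, threshold = net$threshold) {
  .check_net(net)
  if (!is.numeric(threshold) || is.na(threshold) || threshold <= 0)
    stop("threshold must be a positive number")
  W <- net$weights
  diag(W) <- 0
  d <- rowSums(W >= threshold)
  names(d) <- net$ids
  storage.mode(d) <- "integer"
  d
}

#' Centrality table over posterior draws
#'
#' Computes strength, closeness and thresholded degree for every individual
#' in every supplied posterior network draw.
#'
#' @param networks a list of `posterior_network` draws (possibly from
#'   several group-years).
#' @return A data.frame with columns `group_year`, `draw`, `id`, `age`,
#'   `strength`, `closeness`, `degree`.
#' @export
centrality_table <- function(networks) {
  if (inherits(networks, "posterior_network")) networks <- list(networks)
  out <- lapply(networks, function(net) {
    data.frame(group_year = net$group_year, draw = net$draw,
               id = net$ids, age = net$ages,
               strength = unname(compute_strength(net)),
               closeness = unname(compute_closeness(net)),
               degree = unname(compute_degree(net)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
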