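# Conjugate Bayesian count edge model. Each dyad's grooming rate gets a
# gamma posterior updated from its bout count and the pair's combined focal
# effort; posterior network draws propagate sampling uncertainty into every
# downstream centrality and epidemic quantity (the reason a dyad seen
# together 1 of 1 times is treated very differently from one seen 100 of
# 100 times, despite the identical point estimate).

#' Fit the conjugate count edge model to a group-year
#'
#' For every unordered pair of individuals (including pairs never observed
#' grooming) with `x` bouts and combined focal effort `d = focal_i +
#' focal_j`, the grooming rate gets the conjugate gamma update
#' `Gamma(prior_shape + x, prior_rate + d)`. All dyads retain strictly
#' positive posterior support: a never-observed pair may still have
#' interacted outside the sample. The group-year's minimum observed
#' non-zero weight `x/d` is recorded as the degree threshold.
#'
#' @param obs a `group_year_obs` object (see [generate_group_year()] or
#'   [read_group_year()]).
#' @param prior_shape,prior_rate positive gamma prior hyperparameters;
#'   the weakly informative default is Gamma(0.1, 0.1).
#'
#' @return An object of class `edge_posterior`: list with `label`,
#'   `individuals`, `dyads` (data.frame: id_a, id_b, bouts, effort, shape,
#'   rate, weight_obs) and `threshold` (minimum observed non-zero weight).
#' @examples
#' obs <- generate_group_year(gen_config(group_size_range = c(10, 20),
#'                                       group_size_mean = 15), "toy")
#' post <- fit_edge_posterior(obs)
#' post$threshold
#' @export
fit_edge_posterior <- function(obs, prior_shape = 0.1, prior_rate = 0.1) {
  stopifnot(inherits(obs, "group_year_obs"))
  if (prior_shape <= 0 || prior_rate <= 0)
    stop("prior_shape and prior_rate must be positive")
  ind <- obs$individuals
  if (anyDuplicated(ind$id)) stop("individual ids must be unique")
  if (any(ind$focal_count < 1)) stop("focal counts must be >= 1")
  n <- nrow(ind)
  if (n < 2) stop("need at least two individuals")

  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  x <- rep(0L, length(i))
  if (nrow(obs$dyads) > 0) {
    unknown <- setdiff(c(obs$dyads$id_a, obs$dyads$id_b), ind$id)
    if (length(unknown) > 0)
      stop("dyads reference unknown ids: ", paste(unknown, collapse = ", "))
    if (any(obs$dyads$id_a == obs$dyads$id_b)) stop("self-dyads are not allowed")
    m <- match(key(obs$dyads$id_a, obs$dyads$id_b), key(ind$id[i], ind$id[j]))
    if (anyDuplicated(m)) stop("duplicated dyads in observation table")
    x[m] <- as.integer(obs$dyads$bouts)
  }
  d <- ind$focal_count[i] + ind$focal_count[j]
  if (any(d == 0)) stop("combined focal effort must be positive for every dyad")

  w_obs <- x / d
  nz <- w_obs[x > 0]
  structure(list(
    label = obs$label,
    individuals = ind,
    dyads = data.frame(id_a = ind$id[i], id_b = ind$id[j], bouts = x,
                       effort = d, shape = prior_shape + x,
                       rate = prior_rate + d, weight_obs = w_obs,
                       stringsAsFactors = FALSE),
    threshold = if (length(nz)) min(nz) else NA_real_),
    class = "edge_posterior")
}

#' @export
#' @method print edge_posterior
print.edge_posterior <- function(x, ...) {
  cat(sprintf(
    "Edge posterior '%s': %d individuals, %d dyads (%d with bouts), threshold %.4f\n",
    x$label, nrow(x$individuals), nrow(x$dyads), sum(x$dyads$bouts > 0),
    x$threshold))
  invisible(x)
}

#' Sample weighted networks from an edge posterior
#'
#' Draws `n_draws` independent weighted undirected networks, one gamma
#' variate per dyad per draw (dyads are independent in the edge-wise
#' conjugate model). Every draw is almost surely a complete graph with
#' strictly positive weights.
#'
#' @param post an [fit_edge_posterior()] result.
#' @param n_draws number of posterior networks (the full study design uses
#'   1000 per group-year).
#' @param rng_seed optional integer seed for reproducibility.
#'
#' @return A list of `posterior_network` objects: each has `group_year`,
#'   `draw` (index), `ids`, `ages`, `threshold` and `weights` (symmetric
#'   matrix, zero diagonal).
#' @export
draw_networks <- function(post, n_draws, rng_seed = NULL) {
  stopifnot(inherits(post, "edge_posterior"))
  if (n_draws < 1) stop("n_draws must be >= 1")
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
  n <- nrow(post$individuals)
  m <- nrow(post$dyads)
  ut <- upper.tri(matrix(0, n, n))
  lapply(seq_len(n_draws), function(k) {
    w <- rgamma(m, shape = post$dyads$shape, rate = post$dyads$rate)
    W <- matrix(0, n, n, dimnames = list(post$individuals$id, post$individuals$id))
    W[ut] <- w
    W <- W + t(W)
    structure(list(group_year = post$label, draw = k,
                   ids = post$individuals$id, ages = post$individuals$age,
                   threshold = post$threshold, weights = W),
              class = "posterior_network")
  })
}

#' @export
#' @method print posterior_network
print.posterior_network <- function(x, ...) {
  cat(sprintf("Posterior network draw %d of '%s': %d nodes, mean weight %.4f\n",
              x$draw, x$group_year, length(x$ids),
              mean(x$weights[upper.tri(x$weights)])))
  invisible(x)
}
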