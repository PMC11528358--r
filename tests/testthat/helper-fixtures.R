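# shared fixtures: hand-built networks and small generator configs

make_net <- function(W, ages = NULL, threshold = 0.01, group_year = "toy",
                     draw = 1L) {
  n <- nrow(W)
  ids <- sprintf("n%02d", seq_len(n))
  dimnames(W) <- list(ids, ids)
  structure(list(group_year = group_year, draw = draw, ids = ids,
                 ages = if (is.null(ages)) rep(10, n) else ages,
                 threshold = threshold, weights = W),
            class = "posterior_network")
}

complete_W <- function(n, w) {
  W <- matrix(w, n, n)
  diag(W) <- 0
  W
}

small_cfg <- function(n_group_years = 2, ...) {
  gen_config(n_group_years = n_group_years, group_size_range = c(10, 20),
             group_size_mean = 15, ...)
}

# observation set built by hand (no generator)
hand_obs <- function() {
  structure(list(
    label = "hand",
    individuals = data.frame(id = c("a", "b", "c"), age = c(8, 12, 20),
                             focal_count = c(10, 10, 20),
                             stringsAsFactors = FALSE),
    dyads = data.frame(id_a = c("a", "b"), id_b = c("b", "c"),
                       bouts = c(10L, 1L), stringsAsFactors = FALSE)),
    class = "group_year_obs")
}

# exact chi-square goodness-of-fit p-value of first-infection times against
# a geometric(p) law, lumping the tail beyond kmax
geom_chisq_pvalue <- function(times, p, kmax = 12) {
  stopifnot(all(times >= 1))
  n <- length(times)
  probs <- p * (1 - p)^(0:(kmax - 1))
  probs <- c(probs, 1 - sum(probs))
  obs <- c(tabulate(pmin(times, kmax + 1), nbins = kmax + 1))
  expd <- n * probs
  x2 <- sum((obs - expd)^2 / expd)
  stats::pchisq(x2, df = kmax, lower.tail = FALSE)
}

# first-infection times of the non-seeded node in a 2-node network with
# per-step transmission probability p, over n_rep independent runs
two_node_first_infection <- function(p, n_rep, si = 0.45, horizon = 80L) {
  w <- (p / si)^(1 / 0.7)  # invert p = si * w^0.7
  net <- make_net(complete_W(2, w))
  params <- epi_params(si = si, di = horizon, n_steps = horizon,
                       init_infected = 1)
  vapply(seq_len(n_rep), function(k) {
    res <- run_sis(net, params)
    ev <- res$events
    second <- ev[ev$start_step > 0, , drop = FALSE]
    if (nrow(second) == 0) NA_integer_ else min(second$start_step)
  }, integer(1))
}
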