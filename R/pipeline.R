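# End-to-end orchestration: generate (or accept) group-year observations,
# fit the edge model, draw posterior networks, compute centralities, run
# the SIS experiment over a parameter grid, and summarize with the three
# mixed models. Every stochastic stage's seed is derived from one master
# seed and recorded in the returned manifest.

#' Run the full analysis pipeline
#'
#' Composes every stage of the analysis and returns a classed experiment
#' object whose `report` has one row per parameterization: the model-1 and
#' model-2 age estimates with standard errors, the protective effect of
#' social ageing (their difference), and the model-3 high-to-average
#' contrasts at the young and old reference ages for each centrality
#' metric.
#'
#' @param config a [gen_config()] for the synthetic generator, or a list of
#'   `group_year_obs` objects (e.g. from [read_group_year()]).
#' @param n_draws posterior network draws per group-year.
#' @param grid a [parameter_grid()] data.frame (or subset).
#' @param prior_shape,prior_rate edge-model prior.
#' @param n_steps,init_infected simulator settings.
#' @param master_seed integer; seeds for generation, posterior draws and
#'   simulations are all derived from it. Defaults to the generator
#'   config's seed.
#' @param contrast_ages numeric pair (young, old) for model-3 contrasts.
#' @param keep_fits retain the fitted `lmerMod` objects (memory permitting).
#' @param out_dir optional directory; intermediate tables (observations,
#'   centralities, results, report) are written there as tab-separated
#'   text together with a manifest of seeds.
#'
#' @return An object of class `sage_experiment`: list with `report`,
#'   `grid`, `n_runs`, `manifest` (seeds and sizes), `centrality_summary`
#'   and optionally `fits`.
#' @examples
#' \donttest{
#' cfg <- gen_config(n_group_years = 2, group_size_range = c(15, 25),
#'                   group_size_mean = 20, rng_seed = 42)
#' ex <- run_pipeline(cfg, n_draws = 5,
#'                    grid = parameter_grid(si = 0.75, controls_only = TRUE),
#'                    n_steps = 100)
#' ex
#' }
#' @export
run_pipeline <- function(config, n_draws = 1000, grid = parameter_grid(),
                         prior_shape = 0.1, prior_rate = 0.1,
                         n_steps = 500L, init_infected = 0.1,
                         master_seed = NULL, contrast_ages = c(8, 18),
                         keep_fits = FALSE, out_dir = NULL) {
  if (inherits(config, "gen_config")) {
    if (is.null(master_seed)) master_seed <- config$rng_seed
    set.seed(as.integer(master_seed))
    seeds <- sample.int(.Machine$integer.max, 3)
    gen_cfg <- config
    gen_cfg$rng_seed <- seeds[1]
    study <- generate_study(gen_cfg)
  } else if (is.list(config) && all(vapply(config, inherits, logical(1),
                                           "group_year_obs"))) {
    if (is.null(master_seed)) master_seed <- 1L
    set.seed(as.integer(master_seed))
    seeds <- sample.int(.Machine$integer.max, 3)
    study <- config
  } else stop("config must be a gen_config or a list of group_year_obs")

  set.seed(seeds[2])
  edge_seeds <- sample.int(.Machine$integer.max, length(study))
  networks <- vector("list", length(study))
  for (k in seq_along(study)) {
    post <- fit_edge_posterior(study[[k]], prior_shape, prior_rate)
    networks[[k]] <- draw_networks(post, n_draws, rng_seed = edge_seeds[k])
  }
  networks <- do.call(c, networks)
  cents <- centrality_table(networks)

  results <- run_experiment(networks, grid, master_seed = seeds[3],
                            n_steps = n_steps, init_infected = init_infected)
  n_runs <- length(networks) * nrow(grid)

  report <- vector("list", nrow(grid))
  fits <- if (keep_fits) vector("list", nrow(grid)) else NULL
  for (gi in seq_len(nrow(grid))) {
    pid <- grid$param_id[gi]
    frame <- build_frame(results[results$param_id == pid, , drop = FALSE],
                         cents)
    m1 <- fit_cost_models(frame, 1)
    m2 <- fit_cost_models(frame, 2)
    m3 <- fit_cost_models(frame, 3)
    a1 <- age_estimate(m1); a2 <- age_estimate(m2)
    con <- lapply(c("strength", "closeness", "degree"), function(metric)
      age_contrast(m3, metric, ages = contrast_ages))
    report[[gi]] <- data.frame(
      param_id = pid, si = grid$si[gi], ai_max = grid$ai_max[gi],
      adi_max = grid$adi_max[gi], aci_max = grid$aci_max[gi],
      beta_age_m1 = a1[["estimate"]], se_m1 = a1[["se"]],
      beta_age_m2 = a2[["estimate"]], se_m2 = a2[["se"]],
      protective_effect = protective_effect(a1[["estimate"]],
                                            a2[["estimate"]]),
      pe_se = sqrt(a1[["se"]]^2 + a2[["se"]]^2),
      strength_young = con[[1]][1], strength_old = con[[1]][2],
      closeness_young = con[[2]][1], closeness_old = con[[2]][2],
      degree_young = con[[3]][1], degree_old = con[[3]][2],
      stringsAsFactors = FALSE)
    if (keep_fits) fits[[gi]] <- list(m1 = m1, m2 = m2, m3 = m3)
  }
  report <- do.call(rbind, c(report, list(make.row.names = FALSE)))

  cent_summary <- c(strength = mean(cents$strength),
                    closeness = mean(cents$closeness),
                    degree = mean(cents$degree))
  manifest <- list(master_seed = master_seed, stage_seeds = seeds,
                   n_group_years = length(study), n_draws = n_draws,
                   n_grid = nrow(grid), n_runs = n_runs,
                   n_steps = n_steps, init_infected = init_infected,
                   contrast_ages = contrast_ages)
  out <- structure(list(report = report, grid = grid, n_runs = n_runs,
                        manifest = manifest,
                        centrality_summary = cent_summary,
                        fits = fits),
                   class = "sage_experiment")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (obs in study)
      write_group_year(obs, file.path(out_dir, "observations", obs$label))
    write.table(cents, file.path(out_dir, "centralities.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    write.table(results, file.path(out_dir, "results.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    write.table(report, file.path(out_dir, "report.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    writeLines(paste(names(unlist(manifest)), unlist(manifest), sep = " = "),
               file.path(out_dir, "manifest.txt"))
  }
  out
}

#' @export
#' @method print sage_experiment
print.sage_experiment <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Social-ageing epidemic experiment: %d group-years x %d draws x %d parameterizations (%d runs)\n",
    x$manifest$n_group_years, x$manifest$n_draws, x$manifest$n_grid,
    x$n_runs))
  cat(sprintf("Mean centrality: strength %.3f, closeness %.2g, degree %.2f\n",
              x$centrality_summary["strength"],
              x$centrality_summary["closeness"],
              x$centrality_summary["degree"]))
  cat("Protective effect of social ageing (model 1 - model 2 age estimates):\n")
  print(format(x$report[, c("param_id", "beta_age_m1", "beta_age_m2",
                            "protective_effect", "pe_se")], digits = digits),
        row.names = FALSE)
  invisible(x)
}

#' @export
#' @method summary sage_experiment
summary.sage_experiment <- function(object, digits = 3, ...) {
  print(object, digits = digits)
  ages <- object$manifest$contrast_ages
  cat(sprintf(
    "\nModel-3 high-to-average contrasts (cost change, young = %g y, old = %g y):\n",
    ages[1], ages[2]))
  print(format(object$report[, c("param_id", "strength_young", "strength_old",
                                 "closeness_young", "closeness_old",
                                 "degree_young", "degree_old")],
               digits = digits), row.names = FALSE)
  invisible(object)
}

#' @export
coef.sage_experiment <- function(object, ...) object$report

#' @export
plot.sage_experiment <- function(x, which = c("protective", "contrasts"),
                                 ...) {
  which <- match.arg(which)
  rep <- x$report
  if (which == "protective") {
    ord <- order(rep$si, rep$param_id)
    mid <- barplot(rep$protective_effect[ord], names.arg = rep$param_id[ord],
                   las = 2, cex.names = 0.7,
                   ylab = "protective effect (cost units / year of age)",
                   main = "Protective effect of social ageing", ...)
    arrows(mid, rep$protective_effect[ord] - 2 * rep$pe_se[ord],
           mid, rep$protective_effect[ord] + 2 * rep$pe_se[ord],
           angle = 90, code = 3, length = 0.03)
    abline(h = 0, lty = 2)
  } else {
    metrics <- c("strength", "closeness", "degree")
    old <- graphics::par(mfrow = c(1, 3))
    on.exit(graphics::par(old))
    for (m in metrics) {
      y <- rep[[paste0(m, "_young")]]
      o <- rep[[paste0(m, "_old")]]
      lim <- range(c(y, o, 0))
      plot(seq_len(nrow(rep)) - 0.1, y, pch = 16, col = "darkgreen",
           ylim = lim, xlab = "parameterization", ylab = "cost change",
           main = sprintf("high -> average %s", m), xaxt = "n")
      points(seq_len(nrow(rep)) + 0.1, o, pch = 17, col = "navy")
      axis(1, at = seq_len(nrow(rep)), labels = rep$param_id, las = 2,
           cex.axis = 0.6)
      abline(h = 0, lty = 2)
    }
  }
  invisible(x)
}

#' Check the package arithmetic against its worked examples
#'
#' Evaluates the closed-form pieces of the analysis -- protective-effect
#' arithmetic, cost-to-infection conversion, infection cost at the age
#' extremes, the parameter-grid counts, the full-design run count, the
#' immunosenescence bounds and the susceptibility ratio -- against their
#' known values.
#'
#' @return A data.frame with columns `check`, `expected`, `actual`, `pass`;
#'   attribute `all_pass` summarizes it.
#' @export
validate_worked_examples <- function() {
  grid <- parameter_grid()
  f28 <- age_effect(28)
  checks <- list(
    list("protective effect (-1.09, -0.26)", -0.83,
         protective_effect(-1.09, -0.26)),
    list("protective effect (20.9, 22.1)", -1.2,
         protective_effect(20.9, 22.1)),
    list("22 cost units as infections", 4.4, cost_to_infections(22)),
    list("21.6 cost units as infections", 4.32, cost_to_infections(21.6)),
    list("39.0 cost units as infections", 7.8, cost_to_infections(39.0)),
    list("19.6 cost units as infections", 3.92, cost_to_infections(19.6)),
    list("control infection cost", 5, infection_cost(5, 0, 1, 0)),
    list("oldest, all effects on", 45, infection_cost(5, 10, 1, 2)),
    list("parameter grid size", 24, nrow(grid)),
    list("control cells", 3,
         sum(grid$ai_max == 0 & grid$adi_max == 0 & grid$aci_max == 0)),
    list("cells per transmissibility", 8, sum(grid$si == 0.45)),
    list("full-design run count", 552000, 23 * 1000 * nrow(grid)),
    list("oldest infection duration (adi on)", 15, 5 + round(10 * f28)),
    list("oldest per-step cost (aci on)", 3, 1 + 2 * f28),
    list("susceptibility ratio at si = 0.45", 1.56,
         round(transmission_probability(0.45, 0.25 * f28, 0.5) /
                 transmission_probability(0.45, 0, 0.5), 2)),
    list("transmission at unit weight", 0.45,
         transmission_probability(0.45, 0, 1)),
    list("R0 at prevalence 1/2", 2, estimate_R0(0.5)))
  out <- data.frame(
    check = vapply(checks, `[[`, character(1), 1),
    expected = vapply(checks, `[[`, numeric(1), 2),
    actual = vapply(checks, function(x) as.numeric(x[[3]]), numeric(1)),
    stringsAsFactors = FALSE)
  out$pass <- abs(out$expected - out$actual) < 1e-9
  attr(out, "all_pass") <- all(out$pass)
  out
}
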