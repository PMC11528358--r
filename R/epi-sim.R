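# Discrete-time stochastic SIS simulator with linear immunosenescence.
# Transmission along an edge of weight A uses p = (si + ai) * A^0.7, the
# exponent slightly up-weighting weak connections; infections last
# di + adi steps and accrue ci + aci cost units per infected step, with
# ai, adi, aci increasing linearly from the youngest (6 y) to the oldest
# (28 y) individuals when the corresponding immunosenescence switch is on.

#' Epidemic parameterization
#'
#' One cell of the simulation design. The baseline ("control") model has
#' all three age effects off: transmission depends only on edge weight and
#' `si`, every infection lasts `di = 5` steps at `ci = 1` cost unit per
#' step. Immunosenescence switches set the maximum age increments reached
#' at the oldest age: `ai_max = 0.25` (susceptibility), `adi_max = 10`
#' (duration, so 5--15 steps), `aci_max = 2` (severity, so 1--3 units per
#' step).
#'
#' @param si baseline per-edge transmission probability in (0, 1]; the
#'   design grid uses 0.45 (low), 0.60 (medium), 0.75 (high).
#' @param ai_max,adi_max,aci_max maximum age increments to susceptibility,
#'   infection duration (time steps) and per-step cost; 0 switches the
#'   effect off.
#' @param di baseline infection duration in time steps (>= 1).
#' @param dr duration of the dormant recovered period; 0 gives pure SIS
#'   dynamics (an individual returns to susceptible the step after
#'   recovery).
#' @param ci baseline per-step infection cost.
#' @param edge_exponent exponent applied to edge weights before the
#'   transmission product, in (0, 1].
#' @param n_steps number of simulation steps.
#' @param init_infected initial infections: a fraction in (0, 1) of the
#'   group (at least one individual) or an integer count >= 1.
#' @param age_anchors ages at which the linear age effect is 0 and 1;
#'   global anchors (6, 28) for cross-group comparability.
#' @param param_id optional label; a descriptive one is built if omitted.
#'
#' @return An object of class `epi_params`.
#' @export
epi_params <- function(si = 0.45, ai_max = 0, adi_max = 0, aci_max = 0,
                       di = 5L, dr = 0L, ci = 1, edge_exponent = 0.7,
                       n_steps = 500L, init_infected = 0.1,
                       age_anchors = c(6, 28), param_id = NULL) {
  if (si <= 0 || si > 1) stop("si must be in (0, 1]")
  if (di < 1) stop("di must be >= 1")
  if (dr < 0) stop("dr must be >= 0")
  if (ai_max < 0 || adi_max < 0) stop("age increments must be >= 0")
  if (edge_exponent <= 0 || edge_exponent > 1)
    stop("edge_exponent must be in (0, 1]")
  if (n_steps < 1) stop("n_steps must be >= 1")
  if (is.numeric(init_infected) && init_infected <= 0)
    stop("init_infected must be positive")
  stopifnot(length(age_anchors) == 2, age_anchors[1] < age_anchors[2])
  if (is.null(param_id))
    param_id <- sprintf("si%.2f_ai%d_adi%d_aci%d", si,
                        as.integer(ai_max > 0), as.integer(adi_max > 0),
                        as.integer(aci_max > 0))
  structure(list(si = si, ai_max = ai_max, adi_max = adi_max,
                 aci_max = aci_max, di = as.integer(di), dr = as.integer(dr),
                 ci = ci, edge_exponent = edge_exponent,
                 n_steps = as.integer(n_steps), init_infected = init_infected,
                 age_anchors = age_anchors, param_id = param_id),
            class = "epi_params")
}

#' @export
#' @method print epi_params
print.epi_params <- function(x, ...) {
  cat(sprintf(
    "SIS parameterization '%s': si=%.2f ai_max=%.2f adi_max=%g aci_max=%g\n",
    x$param_id, x$si, x$ai_max, x$adi_max, x$aci_max))
  cat(sprintf("  di=%d dr=%d ci=%g edge_exponent=%.2f steps=%d init=%s\n",
              x$di, x$dr, x$ci, x$edge_exponent, x$n_steps,
              format(x$init_infected)))
  invisible(x)
}

#' Linear age-effect scaling
#'
#' Fraction of the maximum age increment realized at a given age: 0 at the
#' young anchor, 1 at the old anchor, linear between and clamped outside.
#'
#' @param age age(s) in years.
#' @param anchors numeric pair (young, old); default `c(6, 28)`.
#' @return Values in `[0, 1]`.
#' @export
age_effect <- function(age, anchors = c(6, 28)) {
  pmin(pmax((age - anchors[1]) / (anchors[2] - anchors[1]), 0), 1)
}

#' Per-edge transmission probability
#'
#' `clamp((si + ai) * weight^edge_exponent, 0, 1)`: the probability that an
#' infected individual transmits to a susceptible neighbour along an edge
#' of the given weight in one time step. `ai` is the individual
#' susceptibility increment of the *receiving* individual.
#'
#' @param si baseline transmission probability.
#' @param ai susceptibility age increment of the susceptible individual.
#' @param weight non-negative edge weight.
#' @param edge_exponent weight exponent (default 0.7).
#' @return Probability in `[0, 1]`.
#' @examples
#' transmission_probability(0.45, 0, 1)     # 0.45
#' transmission_probability(0.45, 0, 0.25)  # 0.45 * 0.25^0.7
#' @export
transmission_probability <- function(si, ai, weight, edge_exponent = 0.7) {
  if (any(weight < 0)) stop("edge weights must be non-negative")
  pmin(pmax((si + ai) * weight^edge_exponent, 0), 1)
}

#' Cost of a single completed infection
#'
#' `(di + adi) * (ci + aci)`: duration times per-step severity, both with
#' their (already realized) age increments.
#'
#' @param di baseline duration (steps); `adi` age increment to duration.
#' @param adi,aci realized age increments (see [age_effect()]).
#' @param ci baseline per-step cost.
#' @return Cost in cost units.
#' @examples
#' infection_cost(5, 0, 1, 0)    # 5: the control infection
#' infection_cost(5, 10, 1, 2)   # 45: oldest individual, all effects on
#' @export
infection_cost <- function(di, adi, ci, aci) {
  if (di + adi < 1) stop("total infection duration must be >= 1")
  (di + adi) * (ci + aci)
}

#' Approximate basic reproductive ratio from endemic prevalence
#'
#' `R0 = 1 / (1 - prevalence)`, the standard SIS equilibrium relation.
#'
#' @param prevalence proportion infected at equilibrium, in `[0, 1)`.
#' @return R0 estimate(s).
#' @export
estimate_R0 <- function(prevalence) {
  if (any(prevalence < 0 | prevalence >= 1))
    stop("prevalence must be in [0, 1)")
  1 / (1 - prevalence)
}

# realized per-individual increments for a parameterization
.age_increments <- function(params, ages) {
  f <- age_effect(ages, params$age_anchors)
  list(ai = params$ai_max * f,
       adi = as.integer(round(params$adi_max * f)),
       aci = params$aci_max * f)
}

#' The full factorial parameter grid
#'
#' All combinations of the three immunosenescence switches (on/off) with
#' the transmissibility values: 8 parameterizations per `si`, 24 in total
#' at the default three transmissibilities. `di = 5`, `dr = 0`, `ci = 1`
#' are fixed; switched-on maxima are `ai_max = 0.25`, `adi_max = 10`,
#' `aci_max = 2`.
#'
#' @param si transmissibility values (default `c(0.45, 0.60, 0.75)`).
#' @param controls_only keep only the rows with every age effect off.
#' @return A data.frame with columns `param_id`, `si`, `ai_max`,
#'   `adi_max`, `aci_max` and one row per parameterization.
#' @export
parameter_grid <- function(si = c(0.45, 0.60, 0.75), controls_only = FALSE) {
  g <- expand.grid(aci = c(0, 2), adi = c(0, 10), ai = c(0, 0.25), si = si,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[order(g$si, g$ai, g$adi, g$aci), , drop = FALSE]
  out <- data.frame(
    param_id = sprintf("si%.2f_ai%d_adi%d_aci%d", g$si,
                       as.integer(g$ai > 0), as.integer(g$adi > 0),
                       as.integer(g$aci > 0)),
    si = g$si, ai_max = g$ai, adi_max = g$adi, aci_max = g$aci,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (controls_only)
    out <- out[out$ai_max == 0 & out$adi_max == 0 & out$aci_max == 0, ,
               drop = FALSE]
  out
}

#' Run one SIS simulation over one posterior network draw
#'
#' Synchronous discrete-time dynamics: each step, every susceptible
#' individual runs an independent Bernoulli trial against each step-start
#' infected neighbour with probability
#' [transmission_probability()]; on any success it becomes infected for
#' `di + adi` steps, accruing `ci + aci` cost units per infected step, then
#' returns to susceptible (after `dr` dormant steps if `dr > 0`).
#' Re-infection is possible immediately; infections ongoing at the end of
#' the run accrue only the steps served.
#'
#' @param net a `posterior_network` draw.
#' @param params an [epi_params()] object.
#' @param rng_seed optional integer seed.
#'
#' @return An object of class `sis_result`: list with `group_year`, `draw`,
#'   `param_id`, `ids`, `ages`, per-individual `cost`, `n_infections` and
#'   `infected_steps`, `per_step_cost` and `duration` (realized
#'   age-adjusted constants), `prevalence` (per-step fraction infected),
#'   `prev_eq` (mean prevalence over the final equilibrium window) and the
#'   per-infection `events` log.
#' @export
run_sis <- function(net, params, rng_seed = NULL) {
  stopifnot(inherits(net, "posterior_network"), inherits(params, "epi_params"))
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
  n <- length(net$ids)
  if (n < 1) stop("empty network")

  inc <- .age_increments(params, net$ages)
  duration <- params$di + inc$adi
  step_cost <- params$ci + inc$aci

  We <- net$weights^params$edge_exponent
  We[net$weights == 0] <- 0
  # P[i, j]: probability that infected j transmits to susceptible i
  P <- pmin((params$si + inc$ai) * We, 1)
  diag(P) <- 0

  n_init <- if (params$init_infected < 1)
    max(1L, as.integer(round(params$init_infected * n)))
  else as.integer(min(params$init_infected, n))
  seeds <- sample.int(n, n_init)

  raw <- sis_run_cpp(P, as.integer(duration), as.numeric(step_cost),
                     as.integer(seeds), params$n_steps, params$dr)
  window <- min(100L, params$n_steps)
  prev_eq <- mean(raw$prevalence[(params$n_steps - window + 1):params$n_steps])
  structure(list(group_year = net$group_year, draw = net$draw,
                 param_id = params$param_id, ids = net$ids, ages = net$ages,
                 cost = setNames(raw$cost, net$ids),
                 n_infections = setNames(raw$n_infections, net$ids),
                 infected_steps = setNames(raw$infected_steps, net$ids),
                 per_step_cost = setNames(step_cost, net$ids),
                 duration = setNames(duration, net$ids),
                 prevalence = raw$prevalence, prev_eq = prev_eq,
                 events = raw$events),
            class = "sis_result")
}

#' @export
#' @method print sis_result
print.sis_result <- function(x, ...) {
  cat(sprintf(
    "SIS run ('%s' draw %d, %s): %d individuals, %d infections, equilibrium prevalence %.3f\n",
    x$group_year, x$draw, x$param_id, length(x$ids), nrow(x$events), x$prev_eq))
  invisible(x)
}

#' Run a simulation experiment over networks and a parameter grid
#'
#' Applies every parameterization in `grid` to every posterior network
#' draw, with per-run seeds derived reproducibly from `master_seed`.
#' Results can be streamed to a file as they are produced (the full study
#' design -- 23 group-years x 1000 draws x 24 parameterizations -- is
#' 552,000 runs, which should not be held in memory at once).
#'
#' @param networks list of `posterior_network` draws.
#' @param grid a [parameter_grid()] data.frame (or subset).
#' @param master_seed integer; per-run seeds are derived from it.
#' @param n_steps,init_infected simulator overrides applied to every grid
#'   cell.
#' @param out_file optional path; per-individual rows are appended as
#'   tab-separated text and the (invisible) return value is the path.
#'
#' @return A data.frame with one row per individual per run: `group_year`,
#'   `draw`, `param_id`, `id`, `age`, `cost`, `n_infections`, `prev_eq`
#'   (or, with `out_file`, that path invisibly).
#' @export
run_experiment <- function(networks, grid, master_seed = 1L, n_steps = 500L,
                           init_infected = 0.1, out_file = NULL) {
  if (inherits(networks, "posterior_network")) networks <- list(networks)
  if (length(networks) < 1 || nrow(grid) < 1)
    stop("networks and grid must be non-empty")
  set.seed(as.integer(master_seed))
  seeds <- matrix(sample.int(.Machine$integer.max,
                             length(networks) * nrow(grid)),
                  nrow = length(networks))
  first <- TRUE
  acc <- vector("list", length(networks) * nrow(grid))
  idx <- 0L
  for (gi in seq_len(nrow(grid))) {
    params <- epi_params(si = grid$si[gi], ai_max = grid$ai_max[gi],
                         adi_max = grid$adi_max[gi], aci_max = grid$aci_max[gi],
                         n_steps = n_steps, init_infected = init_infected,
                         param_id = grid$param_id[gi])
    for (ni in seq_along(networks)) {
      res <- tryCatch(
        run_sis(networks[[ni]], params, rng_seed = seeds[ni, gi]),
        error = function(e) stop(sprintf(
          "simulation failed (network %d '%s' draw %s, param '%s'): %s",
          ni, networks[[ni]]$group_year, networks[[ni]]$draw,
          params$param_id, conditionMessage(e)), call. = FALSE))
      row <- data.frame(group_year = res$group_year, draw = res$draw,
                        param_id = res$param_id, id = res$ids,
                        age = res$ages, cost = unname(res$cost),
                        n_infections = unname(res$n_infections),
                        prev_eq = res$prev_eq, stringsAsFactors = FALSE)
      if (is.null(out_file)) {
        idx <- idx + 1L
        acc[[idx]] <- row
      } else {
        write.table(row, out_file, sep = "\t", row.names = FALSE,
                    col.names = first, append = !first, quote = FALSE)
        first <- FALSE
      }
    }
  }
  if (is.null(out_file))
    do.call(rbind, c(acc[seq_len(idx)], list(make.row.names = FALSE)))
  else invisible(out_file)
}
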