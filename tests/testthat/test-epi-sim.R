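test_that("transmission probability follows the clamped power-law product", {
  expect_equal(transmission_probability(0.45, 0, 1), 0.45)
  expect_equal(transmission_probability(0.60, 0, 0), 0)
  # 0.45 * 0.25^0.7 evaluated independently
  expect_equal(transmission_probability(0.45, 0, 0.25), 0.170518,
               tolerance = 1e-5)
  expect_equal(transmission_probability(0.9, 0.25, 5), 1)  # clamped
  expect_error(transmission_probability(0.45, 0, -1), "non-negative")
})

test_that("infection cost is duration times severity", {
  expect_equal(infection_cost(5, 0, 1, 0), 5)
  expect_equal(infection_cost(5, 10, 1, 2), 45)
  expect_equal(infection_cost(5, 5, 1, 1), 20)
  expect_error(infection_cost(0, 0, 1, 0), "duration")
})

test_that("age effects are anchored, monotone, and duration increments are whole steps", {
  expect_equal(age_effect(6), 0)
  expect_equal(age_effect(28), 1)
  expect_equal(age_effect(17), 0.5)
  expect_equal(age_effect(c(2, 40)), c(0, 1))  # clamped outside anchors
  f <- age_effect(6:28)
  expect_true(all(diff(f) > 0))
  adi <- round(10 * f)
  expect_true(all(adi == as.integer(adi)))
  expect_true(all(adi >= 0 & adi <= 10))
  expect_true(all(diff(adi) >= 0))
})

test_that("R0 approximation from equilibrium prevalence", {
  expect_equal(estimate_R0(0.5), 2)
  expect_equal(estimate_R0(0), 1)
  expect_equal(estimate_R0(2 / 3), 3)
  expect_error(estimate_R0(1), "prevalence")
})

test_that("parameter grid enumerates the full factorial design", {
  grid <- parameter_grid()
  expect_equal(nrow(grid), 24)
  expect_false(anyDuplicated(grid$param_id) > 0)
  expect_equal(sum(grid$ai_max == 0 & grid$adi_max == 0 & grid$aci_max == 0),
               3)
  for (s in c(0.45, 0.60, 0.75)) expect_equal(sum(grid$si == s), 8)
  ctrl <- parameter_grid(controls_only = TRUE)
  expect_equal(nrow(ctrl), 3)
  expect_true(all(ctrl$ai_max == 0))
})

test_that("without transmission only the seed accrues cost", {
  net <- make_net(matrix(0, 4, 4))
  res <- run_sis(net, epi_params(si = 0.45, init_infected = 1, n_steps = 50),
                 rng_seed = 3)
  expect_equal(sum(res$cost), 5)             # one infection at di * ci = 5
  expect_equal(sum(res$cost > 0), 1)
  expect_equal(sum(res$n_infections), 1)
  # prevalence * n is an integer at every step
  expect_true(all(abs(res$prevalence * 4 - round(res$prevalence * 4)) < 1e-12))
})

test_that("an isolated oldest individual with full immunosenescence pays 45 per infection", {
  net <- make_net(matrix(0, 1, 1), ages = 28)
  params <- epi_params(si = 0.45, ai_max = 0.25, adi_max = 10, aci_max = 2,
                       init_infected = 1, n_steps = 100)
  res <- run_sis(net, params, rng_seed = 5)
  expect_equal(res$events$duration_assigned, 15)
  expect_equal(unname(res$per_step_cost), 3)
  expect_equal(unname(res$cost), 45)
})

test_that("a certain edge transmits at the first step", {
  # 0.75 * 5^0.7 > 1, so the transmission probability clamps to 1
  net <- make_net(complete_W(2, 5))
  res <- run_sis(net, epi_params(si = 0.75, init_infected = 1, n_steps = 10),
                 rng_seed = 8)
  ev <- res$events[order(res$events$start_step), ]
  expect_equal(ev$start_step[1:2], c(0L, 1L))
})

test_that("two-node first-infection times follow the geometric law", {
  set.seed(424)
  times <- two_node_first_infection(p = 0.4, n_rep = 2000)
  expect_false(anyNA(times))
  expect_gt(geom_chisq_pvalue(times, 0.4), 0.001)
})

test_that("accumulated cost is conserved against the event log", {
  study <- generate_study(gen_config(n_group_years = 1, rng_seed = 71))
  net <- draw_networks(fit_edge_posterior(study[[1]]), 1, rng_seed = 2)[[1]]
  params <- epi_params(si = 0.75, ai_max = 0.25, adi_max = 10, aci_max = 2)
  res <- run_sis(net, params, rng_seed = 13)
  expect_gt(nrow(res$events), 50)
  # per-individual: cost = infected steps x per-step cost, exactly
  expect_equal(res$cost, res$infected_steps * res$per_step_cost)
  # event log re-aggregates to the per-individual tallies with no discrepancy
  served <- tapply(res$events$steps_served, res$events$individual, sum)
  idx <- as.integer(names(served))
  expect_equal(unname(res$infected_steps[idx]), unname(as.vector(served)))
  counts <- tapply(res$events$steps_served, res$events$individual, length)
  expect_equal(unname(res$n_infections[idx]), unname(as.vector(counts)))
  # completed infections serve exactly their assigned duration
  done <- res$events$start_step + res$events$duration_assigned <= params$n_steps
  expect_true(all(res$events$steps_served[done] ==
                    res$events$duration_assigned[done]))
  expect_true(all(res$events$steps_served[!done] <
                    res$events$duration_assigned[!done]))
})

test_that("expected infection cost increases with strength on a star network", {
  # two hubs differing only in spoke weight
  mk_star <- function(w, n = 6) {
    W <- matrix(0, n, n)
    W[1, 2:n] <- W[2:n, 1] <- w
    W[2:n, 2:n] <- 0.05
    diag(W) <- 0
    make_net(W)
  }
  params <- epi_params(si = 0.6, init_infected = 2, n_steps = 200)
  mean_hub_cost <- function(w, seeds) {
    mean(vapply(seeds, function(s)
      run_sis(mk_star(w), params, rng_seed = s)$cost[[1]], numeric(1)))
  }
  set.seed(99)
  expect_gt(mean_hub_cost(0.6, 1:150), mean_hub_cost(0.15, 1:150))
})

test_that("experiments are counted, streamed and reproducible", {
  study <- generate_study(small_cfg(rng_seed = 81))
  nets <- do.call(c, lapply(study, function(o)
    draw_networks(fit_edge_posterior(o), 2, rng_seed = 3)))
  grid <- parameter_grid(si = 0.75, controls_only = TRUE)
  r1 <- run_experiment(nets, grid, master_seed = 5, n_steps = 50)
  r2 <- run_experiment(nets, grid, master_seed = 5, n_steps = 50)
  expect_identical(r1, r2)
  n_ind <- sum(vapply(study, function(o) nrow(o$individuals), numeric(1)))
  expect_equal(nrow(r1), 2 * n_ind)  # 2 draws x 1 param x individuals
  # single network, single parameterization
  one <- run_experiment(nets[[1]], grid, master_seed = 5, n_steps = 50)
  expect_equal(unique(one$draw), 1)
  # streaming to disk reproduces the in-memory table
  f <- tempfile(fileext = ".tsv")
  run_experiment(nets, grid, master_seed = 5, n_steps = 50, out_file = f)
  disk <- read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(disk$cost, r1$cost)
  unlink(f)
})
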