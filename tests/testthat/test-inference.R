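# frames built directly (no simulator) so mixed-model behaviour can be
# checked against planted coefficients
plant_frame <- function(n_gy = 3, n_draws = 10, n_ind = 25,
                        cost_fun, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (gy in sprintf("g%d", seq_len(n_gy))) {
    age <- 6 + sample(0:22, n_ind, replace = TRUE)
    id <- sprintf("%s_i%02d", gy, seq_len(n_ind))
    strength <- rnorm(n_ind)       # per-individual latent centrality
    for (d in seq_len(n_draws)) {
      rows[[length(rows) + 1]] <- data.frame(
        group_year = gy, draw = d, param_id = "p", id = id, age = age,
        strength = strength + rnorm(n_ind, 0, 0.1),
        closeness = rnorm(n_ind), degree = rnorm(n_ind),
        stringsAsFactors = FALSE)
    }
  }
  frame <- do.call(rbind, rows)
  frame$cost <- cost_fun(frame)
  res <- frame[, c("group_year", "draw", "param_id", "id", "age", "cost")]
  cents <- frame[, c("group_year", "draw", "id", "strength", "closeness",
                     "degree")]
  build_frame(res, cents)
}

test_that("z-scores are computed within group-year and binned on the stated boundaries", {
  f <- plant_frame(cost_fun = function(fr) rnorm(nrow(fr)), seed = 2)
  for (gy in unique(f$group_year)) {
    z <- f$strength_z[f$group_year == gy]
    expect_equal(mean(z), 0, tolerance = 1e-10)
    expect_equal(sd(z), 1, tolerance = 1e-10)
  }
  # boundary convention, brute force over a grid against an independent rule
  z <- seq(-3, 3, by = 0.001)
  got <- sisage:::.bin_z(z)
  oracle <- ifelse(z < -1.5, "very_low",
            ifelse(z < -0.5, "low",
            ifelse(z < 0.5, "average",
            ifelse(z < 1.5, "high", "very_high"))))
  expect_false(anyNA(got))
  expect_equal(as.character(got), oracle)
  expect_equal(as.character(sisage:::.bin_z(0)), "average")
  expect_equal(as.character(sisage:::.bin_z(1.6)), "very_high")
  expect_equal(as.character(sisage:::.bin_z(-1.5)), "low")  # lower bound in
  expect_equal(levels(got)[1], "average")  # reference category
})

test_that("build_frame validates joins and variance", {
  res <- data.frame(group_year = "g", draw = 1, param_id = "p", id = "a",
                    age = 10, cost = 1, stringsAsFactors = FALSE)
  expect_error(build_frame(res, res[, c("group_year", "draw")]),
               "must both carry")
  cents <- data.frame(group_year = "g", draw = 1, id = "b", strength = 1,
                      closeness = 1, degree = 1, stringsAsFactors = FALSE)
  expect_error(build_frame(res, cents), "matching")
  # zero within-group variance is reported with the group-year name
  res2 <- data.frame(group_year = "g7", draw = c(1, 1), param_id = "p",
                     id = c("a", "b"), age = c(8, 9), cost = c(1, 2),
                     stringsAsFactors = FALSE)
  cents2 <- data.frame(group_year = "g7", draw = 1, id = c("a", "b"),
                       strength = c(1, 1), closeness = c(1, 2),
                       degree = c(1, 2), stringsAsFactors = FALSE)
  expect_error(build_frame(res2, cents2), "g7")
})

test_that("protective effect and cost conversion arithmetic", {
  expect_equal(protective_effect(-1.09, -0.26), -0.83)
  expect_equal(protective_effect(20.9, 22.1), -1.2)
  expect_equal(protective_effect(3.3, 3.3), 0)
  expect_error(protective_effect(NA, 1), "finite")
  expect_equal(cost_to_infections(22), 4.4)
  expect_equal(cost_to_infections(21.6), 4.32)
  expect_equal(round(cost_to_infections(21.6), 1), 4.3)
  expect_equal(cost_to_infections(0), 0)
  expect_error(cost_to_infections(1, di = 0), "positive")
})

test_that("model 1 recovers a planted age slope", {
  f <- plant_frame(cost_fun = function(fr)
    10 - 1 * fr$age + rnorm(nrow(fr), 0, 2), seed = 3)
  m1 <- fit_cost_models(f, 1)
  a <- age_estimate(m1)
  expect_lt(abs(a["estimate"] + 1), 2 * a["se"])
})

test_that("a null frame yields null fixed effects", {
  f <- plant_frame(cost_fun = function(fr) rnorm(nrow(fr)), seed = 4)
  m2 <- fit_cost_models(f, 2)
  co <- m2$coefficients
  nonint <- co[co$term != "(Intercept)", ]
  expect_true(all(abs(nonint$estimate) < 2.5 * nonint$se))
})

test_that("planted mediation attenuates the age estimate in model 2", {
  # cost depends only on strength; strength declines with age
  set.seed(5)
  rows <- list()
  for (gy in sprintf("g%d", 1:3)) {
    age <- 6 + sample(0:22, 30, replace = TRUE)
    id <- sprintf("%s_i%02d", gy, 1:30)
    strength <- 2 - 0.08 * age + rnorm(30, 0, 0.3)
    for (d in 1:10)
      rows[[length(rows) + 1]] <- data.frame(
        group_year = gy, draw = d, param_id = "p", id = id, age = age,
        strength = strength, closeness = rnorm(30), degree = rnorm(30),
        cost = 20 * strength + rnorm(30, 0, 1), stringsAsFactors = FALSE)
  }
  fr <- do.call(rbind, rows)
  f <- build_frame(fr[, c("group_year", "draw", "param_id", "id", "age",
                          "cost")],
                   fr[, c("group_year", "draw", "id", "strength",
                          "closeness", "degree")])
  b1 <- age_estimate(fit_cost_models(f, 1))["estimate"]
  b2 <- age_estimate(fit_cost_models(f, 2))["estimate"]
  expect_lt(b1, 0)
  expect_lt(abs(b2), abs(b1))
  expect_lt(protective_effect(b1, b2), 0)
})

test_that("model-3 contrasts recover a planted age-by-centrality interaction", {
  # the high-vs-average strength penalty doubles between ages 8 and 18;
  # cost is planted from the frame's own categories so the fit's job is
  # purely to recover the interaction coefficients
  effect <- function(age) 10 + (age - 8)  # 10 at age 8, 20 at age 18
  f <- plant_frame(n_ind = 40, n_draws = 15,
                   cost_fun = function(fr) 0, seed = 6)
  set.seed(60)
  f$cost <- (f$strength_cat == "high") * effect(f$age) +
    rnorm(nrow(f), 0, 1)
  m3 <- fit_cost_models(f, 3)
  con <- age_contrast(m3, "strength", ages = c(8, 18))
  # moving high -> average removes the penalty: about -10 young, -20 old
  expect_lt(abs(con[["age_8"]] + 10), 1.5)
  expect_lt(abs(con[["age_18"]] + 20), 1.5)
  expect_lt(abs(con[["age_18"]] / con[["age_8"]] - 2), 0.3)
  # robustness variant: average -> low is also a valid request
  alt <- age_contrast(m3, "strength", from_cat = "average", to_cat = "low")
  expect_length(alt, 2)
})

test_that("no planted interaction gives equal young and old contrasts", {
  f <- plant_frame(n_ind = 40, n_draws = 15,
                   cost_fun = function(fr) 0, seed = 7)
  set.seed(70)
  f$cost <- (f$strength_cat == "high") * 10 + rnorm(nrow(f), 0, 1)
  con <- age_contrast(fit_cost_models(f, 3), "strength", ages = c(8, 18))
  expect_lt(abs(con[["age_18"]] - con[["age_8"]]), 2)
})

test_that("model fitting guards against mixed parameterizations", {
  f <- plant_frame(cost_fun = function(fr) rnorm(nrow(fr)), seed = 8)
  f2 <- f
  f2$param_id[1] <- "other"
  expect_error(fit_cost_models(f2, 1), "param_id")
  expect_error(fit_cost_models(f, 4), "model")
})
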