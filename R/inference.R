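# Mixed-model summaries of simulation output. Model 1 regresses accumulated
# infection cost on age alone; model 2 adds the three social-centrality
# measures (z-scored within group-year, binned into five ordered categories);
# model 3 interacts age with each category. The protective effect of social
# ageing is the model-1 age coefficient minus the model-2 age coefficient:
# negative values mean age-related declines in centrality buffer infection
# cost.

.CENT_LEVELS <- c("average", "very_low", "low", "high", "very_high")

# bin a z-score: (-Inf,-1.5) very_low; [-1.5,-0.5) low; [-0.5,0.5) average;
# [0.5,1.5) high; [1.5,Inf) very_high -- reference level "average"
.bin_z <- function(z) {
  lab <- cut(z, breaks = c(-Inf, -1.5, -0.5, 0.5, 1.5, Inf),
             labels = c("very_low", "low", "average", "high", "very_high"),
             right = FALSE)
  factor(as.character(lab), levels = .CENT_LEVELS)
}

#' Build the analysis frame from simulation results and centralities
#'
#' Joins per-individual simulation costs to the matching per-draw
#' centrality records, z-scores strength, closeness and degree within
#' group-year, and bins each into five ordered categories (`very_low` <
#' -1.5 <= `low` < -0.5 <= `average` < 0.5 <= `high` < 1.5 <= `very_high`;
#' lower bounds inclusive). The reference level is `average`, so a model-3
#' `high` coefficient reads directly as the high-vs-average contrast.
#'
#' @param results a [run_experiment()] data.frame (a single
#'   parameterization, or several -- z-scores are computed once per
#'   group-year across all rows).
#' @param centralities a [centrality_table()] data.frame.
#' @return A data.frame with columns `group_year`, `draw`, `param_id`,
#'   `id`, `age`, `cost`, the three z-scores, the three category factors
#'   and `gy_sim` (group-year x simulation identifier for the random
#'   intercept).
#' @export
build_frame <- function(results, centralities) {
  need <- c("group_year", "draw", "id")
  if (!all(need %in% names(results)) || !all(need %in% names(centralities)))
    stop("results and centralities must both carry group_year, draw, id")
  frame <- merge(results,
                 centralities[, c("group_year", "draw", "id", "strength",
                                  "closeness", "degree")],
                 by = need, sort = FALSE)
  if (nrow(frame) < nrow(results))
    stop("some simulation rows had no matching centrality record")
  for (v in c("strength", "closeness", "degree")) {
    z <- numeric(nrow(frame))
    for (gy in unique(frame$group_year)) {
      k <- frame$group_year == gy
      s <- sd(frame[[v]][k])
      if (!is.finite(s) || s == 0)
        stop(sprintf("zero within-group variance in %s for group-year '%s'",
                     v, gy))
      z[k] <- (frame[[v]][k] - mean(frame[[v]][k])) / s
    }
    frame[[paste0(v, "_z")]] <- z
    frame[[paste0(v, "_cat")]] <- .bin_z(z)
  }
  frame$gy_sim <- interaction(frame$group_year, frame$draw, drop = TRUE)
  frame
}

# formula for a model number, dropping category terms with < 2 observed
# levels (can happen on very small frames)
.model_formula <- function(frame, model) {
  cats <- c("degree_cat", "strength_cat", "closeness_cat")
  usable <- cats[vapply(cats, function(v) length(unique(frame[[v]])) > 1,
                        logical(1))]
  fixed <- switch(as.character(model),
    "1" = "age",
    "2" = paste(c("age", usable), collapse = " + "),
    "3" = if (length(usable))
      paste(sprintf("age * %s", usable), collapse = " + ") else "age",
    stop("model must be 1, 2 or 3"))
  rand <- c("group_year", "id", "gy_sim")
  rand <- rand[vapply(rand, function(v) length(unique(frame[[v]])) > 1,
                      logical(1))]
  if (length(rand) == 0)
    stop("frame has no random-effect grouping with more than one level")
  if (length(rand) < 3)
    message("dropping single-level random intercepts: ",
            paste(setdiff(c("group_year", "id", "gy_sim"), rand),
                  collapse = ", "))
  as.formula(paste("cost ~", fixed, "+",
                   paste(sprintf("(1 | %s)", rand), collapse = " + ")))
}

#' Fit the summary mixed models
#'
#' Gaussian linear mixed models of accumulated infection cost with random
#' intercepts for group-year, individual id and group-year x simulation:
#' model 1 has age as the only fixed effect; model 2 adds the three
#' centrality categories; model 3 interacts age with each category.
#' Singular variance-component fits are retained with a message;
#' non-convergence is reported with the optimizer diagnostics.
#'
#' @param frame a [build_frame()] data.frame (one parameterization).
#' @param model 1, 2 or 3.
#' @return An object of class `sage_model`: list with `model` (number),
#'   `formula`, `fit` (the `lmerMod`), and `coefficients` (fixed-effect
#'   table with estimates and standard errors).
#' @export
fit_cost_models <- function(frame, model = 1) {
  if (length(unique(frame$param_id)) > 1)
    stop("frame mixes parameterizations; fit models separately per param_id")
  frame <- droplevels(frame)
  form <- .model_formula(frame, model)
  fit <- lme4::lmer(form, data = frame,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  if (lme4::isSingular(fit))
    message(sprintf("model %s: singular variance components (fit retained)",
                    model))
  conv <- fit@optinfo$conv$lme4
  msgs <- conv$messages[!grepl("singular", conv$messages)]
  if (length(msgs))
    warning(sprintf("model %s convergence: %s", model,
                    paste(msgs, collapse = "; ")))
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  structure(list(model = model, formula = form, fit = fit,
                 coefficients = data.frame(term = names(est),
                                           estimate = unname(est),
                                           se = unname(se[names(est)]),
                                           stringsAsFactors = FALSE)),
            class = "sage_model")
}

#' @export
#' @method print sage_model
print.sage_model <- function(x, digits = 4, ...) {
  cat(sprintf("Infection-cost mixed model %s\n  %s\n", x$model,
              deparse(x$formula)))
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
coef.sage_model <- function(object, ...) {
  setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Age coefficient and its standard error
#'
#' @param fit a [fit_cost_models()] result.
#' @return Named numeric vector `c(estimate, se)`.
#' @export
age_estimate <- function(fit) {
  stopifnot(inherits(fit, "sage_model"))
  k <- match("age", fit$coefficients$term)
  if (is.na(k)) stop("fit has no age term")
  c(estimate = fit$coefficients$estimate[k], se = fit$coefficients$se[k])
}

#' Protective effect of social ageing
#'
#' The model-1 age coefficient minus the model-2 age coefficient on
#' accumulated infection cost. Negative values indicate that age-related
#' differences in social centrality buffer infection cost (part of the
#' raw age effect is explained by sociality).
#'
#' @param beta_m1 age estimate from model 1 (age only).
#' @param beta_m2 age estimate from model 2 (age + centrality categories).
#' @return `beta_m1 - beta_m2`.
#' @examples
#' protective_effect(-1.09, -0.26)  # -0.83
#' @export
protective_effect <- function(beta_m1, beta_m2) {
  if (!is.finite(beta_m1) || !is.finite(beta_m2))
    stop("both age estimates must be finite")
  beta_m1 - beta_m2
}

#' Convert cost units to baseline-infection equivalents
#'
#' One baseline infection costs `di * ci` units (5 by default), so
#' `cost_units / (di * ci)` expresses a cost difference as a number of
#' baseline infections.
#'
#' @param cost_units cost difference in cost units.
#' @param di,ci baseline duration and per-step cost.
#' @return Infection equivalents.
#' @examples
#' cost_to_infections(22)    # 4.4
#' @export
cost_to_infections <- function(cost_units, di = 5, ci = 1) {
  if (di * ci <= 0) stop("di * ci must be positive")
  cost_units / (di * ci)
}

# fixed-effect contribution of a category level at a given age
.cat_pred <- function(coefs, var, level, age) {
  if (level == .CENT_LEVELS[1]) return(0)  # reference
  main <- paste0(var, level)
  b <- if (main %in% names(coefs)) coefs[[main]] else
    stop(sprintf("category '%s' absent from the fit", main))
  inter <- intersect(c(paste0("age:", main), paste0(main, ":age")),
                     names(coefs))
  if (length(inter)) b <- b + age * coefs[[inter[1]]]
  b
}

#' Age-specific centrality contrasts from model 3
#'
#' Predicted change in accumulated infection cost from moving an individual
#' from one centrality category to another (default high to average) at a
#' young and an old age (defaults 8 and 18 years), computed from the
#' model-3 fixed effects. Negative values are cost reductions.
#'
#' @param fit3 a [fit_cost_models()] result with `model = 3`.
#' @param metric `"strength"`, `"closeness"` or `"degree"`.
#' @param from_cat,to_cat category levels (`"very_low"`, `"low"`,
#'   `"average"`, `"high"`, `"very_high"`).
#' @param ages numeric pair (young, old).
#' @return Named numeric vector of the `to - from` predicted differences at
#'   each age.
#' @export
age_contrast <- function(fit3, metric = c("strength", "closeness", "degree"),
                         from_cat = "high", to_cat = "average",
                         ages = c(8, 18)) {
  stopifnot(inherits(fit3, "sage_model"))
  if (fit3$model != 3) stop("age contrasts require the model-3 fit")
  metric <- match.arg(metric)
  from_cat <- match.arg(from_cat, .CENT_LEVELS)
  to_cat <- match.arg(to_cat, .CENT_LEVELS)
  coefs <- as.list(coef(fit3))
  var <- paste0(metric, "_cat")
  out <- vapply(ages, function(a)
    .cat_pred(coefs, var, to_cat, a) - .cat_pred(coefs, var, from_cat, a),
    numeric(1))
  setNames(out, sprintf("age_%g", ages))
}
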