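# Mixed-effects models of preference: a linear model of z-scored ratings on
# z-scored item features (random intercept + random slope per feature), and a
# logistic model of binary choice on the left-minus-right differences of the
# rating and of every feature (random intercept + random delta-ratings slope).

new_prefeat_fit <- function(model, family, data, predictors) {
  sm <- coef(summary(model))
  is_logistic <- family == "logistic"
  coefs <- tibble(
    term = rownames(sm),
    estimate = unname(sm[, "Estimate"]),
    std_error = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, if (is_logistic) "z value" else "t value"]),
    df = if (is_logistic) NA_real_ else unname(sm[, "df"]),
    p_value = unname(sm[, if (is_logistic) "Pr(>|z|)" else "Pr(>|t|)"])
  )
  vc <- as.data.frame(lme4::VarCorr(model))
  msgs <- model@optinfo$conv$lme4$messages %||% character(0)
  # a boundary (singular) fit -- some random-effect variance estimated at
  # zero -- is a converged fit, not an optimiser failure
  real_msgs <- msgs[!grepl("boundary \\(singular\\)", msgs)]
  structure(
    list(
      model = model,
      family = family,
      predictors = predictors,
      coefficients = coefs,
      random_effect_variances = as_tibble(vc),
      n_observations = stats::nobs(model),
      n_participants = nlevels(factor(model@frame$participant_id)),
      converged = length(real_msgs) == 0 && model@optinfo$conv$opt == 0,
      singular = lme4::isSingular(model),
      convergence_messages = real_msgs
    ),
    class = "prefeat_fit"
  )
}

#' @export
print.prefeat_fit <- function(x, digits = 3, ...) {
  notes <- c(if (!x$converged) "convergence warnings",
             if (x$singular) "singular random effects")
  cat(sprintf("<prefeat_fit> %s mixed model: %d obs, %d participants%s\n",
              x$family, x$n_observations, x$n_participants,
              if (length(notes)) paste0("  [", paste(notes, collapse = "; "), "]")
              else ""))
  print(as.data.frame(x$coefficients), digits = digits, row.names = FALSE)
  invisible(x)
}

#' @rdname prefeat_fit_tidiers
#' @method tidy prefeat_fit
#' @export
tidy.prefeat_fit <- function(x, effects = c("fixed", "ran_pars"), ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") x$coefficients else x$random_effect_variances
}

#' Tidiers for preference model fits
#'
#' `tidy()` returns the fixed-effect table (`term`, `estimate`, `std_error`,
#' `statistic`, `df`, `p_value`) or, with `effects = "ran_pars"`, the
#' random-effect variances. `glance()` returns one-row model-level
#' diagnostics.
#'
#' @param x A `prefeat_fit` object.
#' @param effects `"fixed"` or `"ran_pars"`.
#' @param ... Unused.
#' @name prefeat_fit_tidiers
#' @method glance prefeat_fit
#' @export
glance.prefeat_fit <- function(x, ...) {
  tibble(
    family = x$family,
    n_observations = x$n_observations,
    n_participants = x$n_participants,
    logLik = as.numeric(logLik(x$model)),
    AIC = AIC(x$model),
    BIC = BIC(x$model),
    converged = x$converged
  )
}

#' Assemble the model-ready table of choice-trial deltas
#'
#' One row per kept, responded choice trial, carrying the binary response
#' (`choice_left`, 1 = left item chosen) and, for the rating and every
#' z-scored feature, the left-minus-right difference (`delta_rating`,
#' `delta_<feature>`). Trials for which the participant lacks a z-scored
#' rating of either item, or an item lacks features, are dropped with a
#' warning (the count is stored in the `n_dropped` attribute).
#'
#' @param choices Kept choice trials (`participant_id`, `left_item`,
#'   `right_item`, `choice`).
#' @param ratings Kept rating trials with a `z_rating` column (see
#'   [zscore_ratings()]); multiple ratings of an item by the same participant
#'   are averaged.
#' @param features Item feature table with `z_*` columns (see
#'   [zscore_features()]).
#' @return A tibble of deltas, one row per usable choice trial.
#' @export
build_delta_table <- function(choices, ratings, features) {
  check_columns(choices, c("participant_id", "left_item", "right_item",
                           "choice"), "choices")
  if (!"z_rating" %in% names(ratings)) {
    abort("ratings need a `z_rating` column; run zscore_ratings() first")
  }
  zcols <- grep("^z_", names(features), value = TRUE)
  if (!length(zcols)) abort("features need `z_*` columns; run zscore_features() first")

  rat <- ratings |>
    filter(!is.na(.data$z_rating)) |>
    group_by(.data$participant_id, .data$item_id) |>
    summarise(z_rating = mean(.data$z_rating), .groups = "drop")
  feat <- features |> select(all_of(c("item_id", zcols)))

  joined <- choices |>
    filter(.data$choice %in% c("left", "right")) |>
    mutate(choice_left = as.integer(.data$choice == "left")) |>
    left_join(rename(rat, zr_left = "z_rating"),
              by = c("participant_id", left_item = "item_id")) |>
    left_join(rename(rat, zr_right = "z_rating"),
              by = c("participant_id", right_item = "item_id")) |>
    left_join(feat, by = c(left_item = "item_id"),
              suffix = c("", ".left")) |>
    left_join(feat, by = c(right_item = "item_id"),
              suffix = c(".left", ".right"))

  need <- c("zr_left", "zr_right",
            paste0(zcols, ".left"), paste0(zcols, ".right"))
  ok <- complete.cases(joined[need])
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    warn(sprintf("dropped %d choice trial(s) lacking a participant rating or item features",
                 n_dropped))
    joined <- joined[ok, ]
  }
  out <- joined |> mutate(delta_rating = .data$zr_left - .data$zr_right)
  for (z in zcols) {
    out[[sub("^z_", "delta_", z)]] <-
      out[[paste0(z, ".left")]] - out[[paste0(z, ".right")]]
  }
  out <- out |>
    select(all_of(c("participant_id", "left_item", "right_item",
                    "choice_left", "delta_rating",
                    sub("^z_", "delta_", zcols))))
  attr(out, "n_dropped") <- n_dropped
  out
}

ranef_formula <- function(predictors, random) {
  bar <- if (random == "diagonal") "||" else "|"
  sprintf("(1 + %s %s participant_id)", paste(predictors, collapse = " + "), bar)
}

#' Fit the mixed-effects ratings model
#'
#' Linear mixed model of participant-wise z-scored ratings on z-scored item
#' features, all predictors entered simultaneously so each coefficient is
#' the unique contribution of its feature adjusted for all others. Every
#' fixed effect also gets a per-participant random slope, alongside a random
#' intercept. With `random = "diagonal"` (the default) random effects are
#' uncorrelated, which keeps models with many slopes estimable;
#' `random = "full"` estimates the full covariance and falls back to the
#' diagonal structure with a warning if it fails to converge. P-values use
#' the Satterthwaite degrees-of-freedom approximation.
#'
#' @param ratings Rating table with `z_rating` (see [zscore_ratings()]). If
#'   `features` is supplied it is joined by `item_id` first; alternatively
#'   pass a pre-joined table and name the `predictors`.
#' @param features Optional item feature table with `z_*` columns.
#' @param predictors Character vector of predictor columns; defaults to every
#'   `z_*` column except `z_rating`.
#' @param random Random-effect covariance structure, `"diagonal"` or
#'   `"full"`.
#' @param reml Fit by REML (default) or maximum likelihood.
#' @return A `prefeat_fit` object.
#' @export
fit_ratings_model <- function(ratings, features = NULL, predictors = NULL,
                              random = c("diagonal", "full"), reml = TRUE) {
  random <- match.arg(random)
  data <- if (!is.null(features)) {
    left_join(ratings, features, by = "item_id",
              suffix = c("", ".feature"))
  } else {
    ratings
  }
  predictors <- predictors %||%
    setdiff(grep("^z_", names(data), value = TRUE), "z_rating")
  if (!length(predictors)) abort("no predictors found (expected `z_*` columns)")
  if (length(unique(data$participant_id)) < 2L) {
    abort("at least 2 participants required")
  }
  data <- filter(data, !is.na(.data$z_rating))
  fml <- stats::as.formula(paste(
    "z_rating ~", paste(predictors, collapse = " + "), "+",
    ranef_formula(predictors, random)
  ))
  ctrl <- lme4::lmerControl(calc.derivs = FALSE)
  fit_once <- function(f) lmerTest::lmer(f, data = data, REML = reml,
                                         control = ctrl)
  model <- if (random == "full") {
    tryCatch(fit_once(fml), error = function(e) {
      warn(paste0("full random-effect covariance failed (",
                  conditionMessage(e),
                  "); refitting with diagonal structure"))
      fit_once(stats::as.formula(paste(
        "z_rating ~", paste(predictors, collapse = " + "), "+",
        ranef_formula(predictors, "diagonal")
      )))
    })
  } else {
    tryCatch(fit_once(fml), error = function(e) {
      abort(paste0("ratings model failed to fit: ", conditionMessage(e)),
            class = "prefeat_fit_error")
    })
  }
  new_prefeat_fit(model, "linear", data, predictors)
}

#' Fit the mixed-effects logistic choice model
#'
#' Logistic mixed model of the probability of choosing the left item on the
#' left-minus-right delta of the z-scored rating and of every z-scored
#' feature. Only the intercept and the `delta_rating` slope vary across
#' participants; the feature deltas enter as fixed effects, so their
#' coefficients measure the influence of features on choice over and above
#' the items' rated values.
#'
#' @param delta_table A table from [build_delta_table()].
#' @param predictors Fixed-effect columns; defaults to `delta_rating` plus
#'   every other `delta_*` column.
#' @param include_delta_rating Set `FALSE` for the supplementary variant that
#'   explains choices without adjusting for ratings (the random structure
#'   then reduces to a random intercept).
#' @param nagq Number of adaptive Gauss-Hermite quadrature points passed to
#'   [lme4::glmer()]; `0` uses the faster penalised-least-squares
#'   approximation, useful for large simulation sweeps.
#' @return A `prefeat_fit` object.
#' @export
fit_choice_model <- function(delta_table, predictors = NULL,
                             include_delta_rating = TRUE, nagq = 1L) {
  deltas <- grep("^delta_", names(delta_table), value = TRUE)
  predictors <- predictors %||%
    c("delta_rating", setdiff(deltas, "delta_rating"))
  if (!include_delta_rating) {
    predictors <- setdiff(predictors, "delta_rating")
  }
  if (!length(predictors)) abort("no delta predictors found")
  if (length(unique(delta_table$choice_left)) < 2L) {
    abort("binary response must contain both classes")
  }
  re <- if (include_delta_rating) {
    "(1 + delta_rating | participant_id)"
  } else {
    "(1 | participant_id)"
  }
  fml <- stats::as.formula(paste(
    "choice_left ~", paste(predictors, collapse = " + "), "+", re
  ))
  model <- tryCatch(
    lme4::glmer(fml, data = delta_table, family = stats::binomial(),
                nAGQ = nagq,
                control = lme4::glmerControl(calc.derivs = FALSE)),
    error = function(e) {
      # PIRLS divergence is the classic symptom of (quasi-)separated choices
      if (grepl("pwrssUpdate|PIRLS", conditionMessage(e))) {
        abort(paste0("complete or quasi-complete separation suspected ",
                     "(the deviance iteration diverged); add response noise ",
                     "or more trials"),
              class = "prefeat_separation_error")
      }
      abort(paste0("choice model failed to fit: ", conditionMessage(e)),
            class = "prefeat_fit_error")
    }
  )
  fe <- lme4::fixef(model)
  se <- sqrt(diag(as.matrix(stats::vcov(model))))
  if (any(abs(fe) > 10 & se > 25)) {
    abort(paste0("complete or quasi-complete separation suspected ",
                 "(a coefficient diverged); add response noise or more trials"),
          class = "prefeat_separation_error")
  }
  new_prefeat_fit(model, "logistic", delta_table, predictors)
}

#' Fit the supplementary model variants
#'
#' Two alternative specifications discussed alongside the headline models:
#' * `"ratings_with_choice"` -- the ratings model with an additional
#'   choice-derived covariate, the participant's Colley rating of the item
#'   (computed from their binary choices), entered as a fixed effect with a
#'   random slope like every other predictor;
#' * `"choices_without_ratings"` -- the choice model with `delta_rating`
#'   omitted, so feature deltas absorb rating-correlated variance.
#'
#' @param data A `prefeat_data` list from [preprocess_behavior()], or any
#'   list with elements `ratings` (with `z_rating`), `choices` and
#'   `features` (with `z_*` columns).
#' @param variant Which variant to fit.
#' @param ... Passed on to [fit_ratings_model()] or [fit_choice_model()].
#' @return A `prefeat_fit` object.
#' @export
fit_variant_models <- function(data,
                               variant = c("ratings_with_choice",
                                           "choices_without_ratings"),
                               ...) {
  variant <- match.arg(variant)
  if (is.null(data$choices)) abort("variant models require choice data")
  if (variant == "ratings_with_choice") {
    cov <- colley_item_ratings(data$choices)
    joined <- data$ratings |>
      left_join(data$features, by = "item_id", suffix = c("", ".feature")) |>
      left_join(cov, by = c("participant_id", "item_id"))
    n_missing <- sum(is.na(joined$colley_rating))
    if (n_missing > 0) {
      warn(sprintf("dropped %d rating trial(s) of items absent from the participant's choices",
                   n_missing))
      joined <- filter(joined, !is.na(.data$colley_rating))
    }
    zcols <- setdiff(grep("^z_", names(joined), value = TRUE), "z_rating")
    preds <- c(zcols, "colley_rating")
    if (sd(joined$colley_rating) < 1e-10) {
      warn("choice covariate is constant; fitting the headline ratings model")
      preds <- zcols
    }
    fit_ratings_model(joined, predictors = preds, ...)
  } else {
    dt <- build_delta_table(data$choices, data$ratings, data$features)
    fit_choice_model(dt, include_delta_rating = FALSE, ...)
  }
}
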