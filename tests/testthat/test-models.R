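# Delta-table construction and the two mixed-model families, validated by
# hand computation, invariances, and small-scale parameter recovery.

small_sim <- function(seed, n_participants = 20, n_items = 24,
                      n_choice_trials = 120, ...) {
  feats <- gen_item_features(n_items, "fractal", seed = seed + 1)
  cfg <- generator_config(n_items = n_items, n_participants = n_participants,
                          n_choice_trials = n_choice_trials, seed = seed, ...)
  sim <- gen_behavior(cfg, feats)
  sim$features <- zscore_features(feats)
  sim$ratings <- zscore_ratings(sim$ratings)
  sim
}

test_that("delta tables match manual subtraction on a hand-built example", {
  ratings <- tibble::tibble(
    participant_id = "p1", item_id = c("a", "b", "c"),
    rating = c(2, 5, 8), rt = 1
  ) |> zscore_ratings()
  features <- zscore_features(tibble::tibble(
    item_id = c("a", "b", "c"), hue = c(0.1, 0.2, 0.6)
  ))
  choices <- tibble::tibble(
    participant_id = "p1",
    left_item = c("a", "c"), right_item = c("b", "b"),
    choice = c("right", "left"), rt = 1
  )
  dt <- build_delta_table(choices, ratings, features)
  expect_equal(dt$choice_left, c(0L, 1L))
  z <- ratings$z_rating
  expect_equal(dt$delta_rating, c(z[1] - z[2], z[3] - z[2]))
  zf <- features$z_hue
  expect_equal(dt$delta_hue, c(zf[1] - zf[2], zf[3] - zf[2]))

  # an unrated item drops its trials with a warning
  choices2 <- dplyr::bind_rows(choices, tibble::tibble(
    participant_id = "p1", left_item = "d", right_item = "a",
    choice = "left", rt = 1
  ))
  expect_warning(dt2 <- build_delta_table(choices2, ratings, features),
                 "dropped 1")
  expect_equal(nrow(dt2), 2)
})

test_that("swapping display sides flips the response and negates every delta", {
  sim <- small_sim(601)
  dt <- build_delta_table(sim$choices, sim$ratings, sim$features)
  swapped <- sim$choices |>
    dplyr::mutate(tmp = left_item, left_item = right_item, right_item = tmp,
                  choice = dplyr::case_when(choice == "left" ~ "right",
                                            choice == "right" ~ "left",
                                            TRUE ~ choice)) |>
    dplyr::select(-tmp)
  dts <- build_delta_table(swapped, sim$ratings, sim$features)
  expect_equal(dts$choice_left, 1L - dt$choice_left)
  expect_equal(dts$delta_rating, -dt$delta_rating)
  expect_equal(dts$delta_hue, -dt$delta_hue)

  fit <- fit_choice_model(dt, nagq = 0L)
  fit_s <- fit_choice_model(dts, nagq = 0L)
  # identical likelihood; slopes unchanged; intercept negated
  # (up to the optimiser's convergence tolerance)
  expect_lt(abs(glance(fit)$logLik - glance(fit_s)$logLik), 0.5)
  co <- tidy(fit); cs <- tidy(fit_s)
  expect_lt(abs(cs$estimate[cs$term == "(Intercept)"] +
                  co$estimate[co$term == "(Intercept)"]), 0.01)
  expect_lt(max(abs(cs$estimate[cs$term != "(Intercept)"] -
                      co$estimate[co$term != "(Intercept)"])), 0.01)
})

test_that("the ratings model recovers generating weights at reduced scale", {
  sim <- small_sim(602, n_participants = 40, n_items = 40)
  fit <- fit_ratings_model(sim$ratings, sim$features)
  td <- dplyr::filter(tidy(fit), term != "(Intercept)")
  truth <- sim$truth$expected_rating_coefs
  expect_setequal(td$term, paste0("z_", names(truth)))
  z <- abs(td$estimate - truth[sub("^z_", "", td$term)]) / td$std_error
  expect_true(all(z < 3))
  expect_equal(glance(fit)$n_participants, 40)
})

test_that("with no noise the mixed fit collapses to ordinary least squares", {
  sim <- small_sim(603, rating_noise_sd = 1e-4, weight_sd = 0)
  joined <- dplyr::left_join(sim$ratings, sim$features, by = "item_id")
  preds <- setdiff(grep("^z_", names(joined), value = TRUE), "z_rating")
  ols <- lm(stats::reformulate(preds, "z_rating"), data = joined)
  fit <- suppressMessages(fit_ratings_model(sim$ratings, sim$features))
  td <- tidy(fit)
  expect_equal(td$estimate, unname(coef(ols)[td$term]), tolerance = 1e-3)
})

test_that("fixed effects ignore participant labels and scale with predictors", {
  sim <- small_sim(604, n_participants = 10, n_items = 16,
                   n_choice_trials = 40)
  fit <- fit_ratings_model(sim$ratings, sim$features)
  perm <- sim$ratings |>
    dplyr::mutate(participant_id = chartr("0123456789", "9876543210",
                                          participant_id))
  fit_p <- fit_ratings_model(perm, sim$features)
  expect_equal(tidy(fit)$estimate, tidy(fit_p)$estimate, tolerance = 1e-6)

  doubled <- dplyr::mutate(sim$features, z_hue = z_hue * 2)
  fit_d <- fit_ratings_model(sim$ratings, doubled)
  est <- function(f, term) tidy(f)$estimate[tidy(f)$term == term]
  expect_equal(est(fit_d, "z_hue"), est(fit, "z_hue") / 2, tolerance = 1e-3)
})

test_that("the choice model recovers weights and is null-calibrated", {
  sim <- small_sim(605, n_participants = 30, n_choice_trials = 150,
                   choice_feature_weights = c(sharpness = 0.25))
  dt <- build_delta_table(sim$choices, sim$ratings, sim$features)
  fit <- fit_choice_model(dt, nagq = 0L)
  td <- dplyr::filter(tidy(fit), term != "(Intercept)")
  truth <- sim$truth$expected_choice_coefs
  z <- abs(td$estimate - truth[td$term]) / td$std_error
  expect_true(all(z < 3))
  expect_gt(td$estimate[td$term == "delta_sharpness"], 0)
})

test_that("a fair-coin chooser yields a null choice model", {
  sim <- small_sim(606, n_participants = 20, n_choice_trials = 120,
                   frac_random_choosers = 1)
  dt <- build_delta_table(sim$choices, sim$ratings, sim$features)
  fit <- fit_choice_model(dt, nagq = 0L)
  td <- tidy(fit)
  expect_true(all(abs(td$estimate) / td$std_error < 3))
})

test_that("complete separation raises a structured error", {
  sim <- small_sim(607, n_participants = 8, n_choice_trials = 80)
  dt <- build_delta_table(sim$choices, sim$ratings, sim$features) |>
    dplyr::mutate(choice_left = as.integer(delta_rating > 0))
  expect_error(
    suppressWarnings(suppressMessages(fit_choice_model(dt, nagq = 0L))),
    class = "prefeat_separation_error"
  )
})

test_that("variant models behave as specified", {
  sim <- small_sim(608, n_participants = 16, n_items = 16,
                   n_choice_trials = 100)
  data <- list(ratings = sim$ratings, choices = sim$choices,
               features = sim$features)

  # both variants run on the same synthetic set
  va <- suppressWarnings(fit_variant_models(data, "ratings_with_choice"))
  vb <- fit_variant_models(data, "choices_without_ratings", nagq = 0L)
  expect_s3_class(va, "prefeat_fit")
  expect_true("colley_rating" %in% tidy(va)$term)
  expect_false("delta_rating" %in% tidy(vb)$term)

  # omitting delta ratings lets feature deltas absorb utility variance
  dt <- build_delta_table(sim$choices, sim$ratings, sim$features)
  headline <- fit_choice_model(dt, nagq = 0L)
  est <- function(f, t) tidy(f)$estimate[tidy(f)$term == t]
  expect_gt(est(vb, "delta_hue"), est(headline, "delta_hue") + 0.2)

  # a constant choice covariate degenerates to the headline ratings model:
  # every pair is chosen once in each display order, so each participant's
  # win matrix is symmetric and all Colley ratings equal 1/2
  items <- letters[1:8]
  pids <- c("p1", "p2", "p3", "p4")
  sym <- tidyr::expand_grid(participant_id = pids,
                            left_item = items, right_item = items) |>
    dplyr::filter(left_item != right_item) |>
    dplyr::mutate(choice = "left", rt = 1)
  set.seed(99)
  ratings <- tidyr::expand_grid(participant_id = pids, item_id = items) |>
    dplyr::mutate(rating = runif(32, 1, 10), rt = 1) |>
    zscore_ratings()
  feats <- zscore_features(tibble::tibble(item_id = items,
                                          hue = seq(0.1, 0.9, length.out = 8)))
  const_data <- list(ratings = ratings, choices = sym, features = feats)
  expect_warning(
    vc <- suppressMessages(fit_variant_models(const_data,
                                              "ratings_with_choice")),
    "constant"
  )
  head_fit <- suppressMessages(fit_ratings_model(ratings, feats))
  expect_equal(tidy(vc)$estimate, tidy(head_fit)$estimate, tolerance = 1e-6)
})
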