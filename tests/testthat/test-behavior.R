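# The preprocessing cascade: z-scoring and the item / trial / participant
# exclusion rules.

test_that("rating z-scores are exact within participant", {
  tr <- tibble::tibble(participant_id = "p1", item_id = c("a", "b", "c"),
                       rating = c(1, 2, 3))
  expect_equal(zscore_ratings(tr)$z_rating, c(-1, 0, 1))

  const <- tibble::tibble(participant_id = "p2", item_id = c("a", "b"),
                          rating = c(5, 5))
  expect_warning(out <- zscore_ratings(const), "constant ratings")
  expect_true(all(is.na(out$z_rating)))

  set.seed(3)
  rnd <- tibble::tibble(
    participant_id = rep(c("p1", "p2"), each = 30),
    item_id = rep(sprintf("i%02d", 1:30), 2),
    rating = runif(60, 1, 10)
  )
  z <- zscore_ratings(rnd) |>
    dplyr::group_by(participant_id) |>
    dplyr::summarise(m = mean(z_rating), s = sd(z_rating))
  expect_equal(z$m, c(0, 0), tolerance = 1e-12)
  expect_equal(z$s, c(1, 1), tolerance = 1e-12)
})

test_that("feature z-scores are computed per category and match recomputation", {
  f <- tibble::tibble(
    item_id = sprintf("i%d", 1:6),
    category = rep(c("fractal", "snack"), each = 3),
    hue = c(2, 4, 6, 10, 20, 30)
  )
  out <- zscore_features(f)
  expect_equal(out$z_hue, c(-1, 0, 1, -1, 0, 1))

  set.seed(5)
  g <- tibble::tibble(item_id = sprintf("i%d", 1:20),
                      a = rnorm(20), b = runif(20))
  out2 <- zscore_features(g)
  expect_equal(out2$z_a, (g$a - mean(g$a)) / sd(g$a))
  expect_equal(out2$z_b, (g$b - mean(g$b)) / sd(g$b))

  flat <- tibble::tibble(item_id = c("x", "y"), a = c(1, 1))
  expect_error(zscore_features(flat), "`a` has zero variance")
})

test_that("item exclusion flags exactly the planted outlier", {
  set.seed(9)
  f <- tibble::tibble(item_id = sprintf("i%02d", 1:60),
                      hue = c(rnorm(59, 0, 0.01), 10))
  fz <- zscore_features(f)
  res <- exclude_items(fz, k = 3)
  expect_equal(res$removed$item_id, "i60")
  expect_equal(res$removed$feature, "hue")
  expect_equal(nrow(res$kept), 59)

  none <- exclude_items(fz, k = Inf)
  expect_equal(nrow(none$removed), 0)
  expect_equal(nrow(none$kept), 60)

  # brute-force scan agrees on an arbitrary table
  set.seed(10)
  g <- zscore_features(tibble::tibble(item_id = sprintf("i%02d", 1:40),
                                      a = rnorm(40), b = rt(40, df = 2)))
  res2 <- exclude_items(g, k = 1.5)
  manual <- g$item_id[abs(g$z_a) > 1.5 | abs(g$z_b) > 1.5]
  expect_setequal(res2$removed$item_id, manual)

  # rerunning on kept output removes nothing further (idempotence)
  again <- exclude_items(res2$kept, k = 1.5)
  expect_equal(nrow(again$removed), 0)
})

test_that("trial exclusion removes RT outliers and non-responses per the rule", {
  tr <- make_rating_trials("p1", sprintf("i%03d", 1:101), rating = 5, rt = 0.5)
  tr$rt[101] <- 10
  res <- exclude_trials(tr, k = 3)
  # oracle on the 101 values
  mu <- mean(tr$rt); s <- sd(tr$rt)
  expect_true(abs(10 - mu) > 3 * s && abs(0.5 - mu) <= 3 * s)
  expect_equal(res$removed$item_id, "i101")
  expect_equal(res$removed$reason, "rt_outlier")
  expect_equal(res$loss$fraction, 1 / 101)

  # no-response trials go regardless of RT statistics
  ch <- tibble::tibble(participant_id = "p1",
                       left_item = sprintf("L%d", 1:10),
                       right_item = sprintf("R%d", 1:10),
                       choice = c(rep("left", 8), "none", "none"),
                       rt = 0.5)
  resc <- exclude_trials(ch)
  expect_equal(sort(resc$removed$reason), c("no_response", "no_response"))
  expect_equal(resc$loss$fraction, 0.2)

  # identical RTs: zero SD, nothing removed
  same <- make_rating_trials("p1", sprintf("i%d", 1:20))
  expect_equal(nrow(exclude_trials(same)$removed), 0)
})

test_that("trial exclusion is a single pass and idempotent on clean spreads", {
  rts <- rep(c(0.48, 0.50, 0.52), length.out = 60)
  tr <- make_rating_trials("p1", sprintf("i%02d", 1:60))
  tr$rt <- rts
  tr$rt[c(10, 20)] <- 9
  first <- exclude_trials(tr)
  expect_equal(sort(first$removed$item_id), c("i10", "i20"))
  second <- exclude_trials(first$kept)
  expect_equal(nrow(second$removed), 0)
  expect_equal(first$loss$n_removed, 2L)
  expect_equal(first$loss$fraction, 2 / 60)
})

test_that("RT statistics are computed within participant and task", {
  fast <- make_rating_trials("p1", sprintf("i%d", 1:30), rt = 0.3)
  slow <- make_rating_trials("p2", sprintf("i%d", 1:30), rt = 3)
  fast$rt <- fast$rt + rep(c(-0.01, 0, 0.01), 10)
  slow$rt <- slow$rt + rep(c(-0.1, 0, 0.1), 10)
  # p2's 3 s trials are unremarkable for p2 though far beyond p1's spread
  res <- exclude_trials(dplyr::bind_rows(fast, slow))
  expect_equal(nrow(res$removed), 0)
})

test_that("participant exclusion applies the trial-loss and transitivity rules", {
  loss <- tibble::tibble(
    participant_id = c("p1", "p2", "p3"),
    task = "rating",
    fraction = c(0.31, 0.30, 0.05)
  )
  out <- exclude_participants(loss)
  expect_equal(out$participant_id, "p1") # cap is strict: > 0.30
  expect_equal(out$reason, "trial_loss_rating")

  scores <- tibble::tibble(participant_id = sprintf("p%d", 1:10),
                           transitivity_score = rep(0.2, 10))
  out2 <- exclude_participants(loss[3, ], scores)
  expect_equal(nrow(out2), 0) # identical scores: zero SD, no outliers

  few <- scores[1:2, ]
  expect_warning(exclude_participants(loss[3, ], few), "fewer than 3")
})

test_that("the full cascade keeps order items -> trials -> participants", {
  feats <- gen_item_features(30, "fractal", seed = 21)
  feats$hue[7] <- 30 # plant a feature outlier
  cfg <- generator_config(n_items = 30, n_participants = 12,
                          n_choice_trials = 100, rt_outlier_rate = 0.01,
                          no_response_rate = 0.01, seed = 77)
  sim <- gen_behavior(cfg, feats)
  prep <- preprocess_behavior(sim$ratings, sim$choices, feats)

  expect_equal(prep$report$removed_items$item_id, feats$item_id[7])
  expect_false(feats$item_id[7] %in% prep$ratings$item_id)
  expect_false(any(feats$item_id[7] %in%
                     c(prep$choices$left_item, prep$choices$right_item)))
  # fractions are exact ratios over post-item-drop trials
  loss <- prep$report$trial_loss
  expect_true(all(loss$fraction == loss$n_removed / loss$n_trials))
  expect_true(all(loss$fraction >= 0 & loss$fraction <= 1))
  # kept ratings carry per-participant z-scores
  zchk <- prep$ratings |>
    dplyr::group_by(participant_id) |>
    dplyr::summarise(m = mean(z_rating))
  expect_true(all(abs(zchk$m) < 1e-10))
})

test_that("rating-only designs skip the choice-side criteria", {
  feats <- gen_item_features(20, "fractal", seed = 31)
  cfg <- generator_config(n_items = 20, n_participants = 6,
                          n_choice_trials = 10, seed = 5)
  sim <- gen_behavior(cfg, feats)
  prep <- preprocess_behavior(sim$ratings, choices = NULL, features = feats)
  expect_null(prep$choices)
  expect_null(prep$scores)
  expect_s3_class(prep$ratings, "tbl_df")
})

test_that("exclusion reports serialise to JSON", {
  feats <- gen_item_features(20, "fractal", seed = 31)
  cfg <- generator_config(n_items = 20, n_participants = 6,
                          n_choice_trials = 10, seed = 5)
  sim <- gen_behavior(cfg, feats)
  prep <- preprocess_behavior(sim$ratings, sim$choices, feats)
  path <- withr::local_tempfile(fileext = ".json")
  write_exclusion_report(prep$report, path)
  parsed <- jsonlite::read_json(path)
  expect_named(parsed$summary,
               c("n_items_removed", "n_trials_removed", "mean_trial_loss_pct",
                 "sd_trial_loss_pct", "n_participants_removed"))
})
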