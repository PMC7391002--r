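# Behavioural preprocessing: participant-wise z-scoring of ratings,
# category-wise z-scoring of features, and the fixed exclusion cascade
# items -> trials -> participants.

check_columns <- function(df, need, what) {
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(paste0(what, " table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
}

# Task label for a trial table: explicit `task` column wins, otherwise
# inferred from the schema.
infer_task <- function(trials) {
  if ("task" %in% names(trials)) return(trials$task)
  if ("rating" %in% names(trials)) rep("rating", nrow(trials))
  else if ("choice" %in% names(trials)) rep("choice", nrow(trials))
  else abort("cannot infer task: no `task`, `rating` or `choice` column")
}

responded <- function(trials) {
  if ("rating" %in% names(trials)) !is.na(trials$rating)
  else trials$choice %in% c("left", "right")
}

#' Z-score preference ratings within participant
#'
#' Participants use different ranges of the rating scale; z-scoring each
#' participant's ratings (sample SD, `n - 1`) removes that between-participant
#' variance. Participants whose ratings are constant get missing z-scores and
#' a warning.
#'
#' @param trials A data frame of rating trials with columns `participant_id`,
#'   `item_id`, `rating` (and typically `rt`).
#' @return The input tibble with a `z_rating` column appended.
#' @examples
#' zscore_ratings(tibble::tibble(participant_id = "p1",
#'                               item_id = c("a", "b", "c"),
#'                               rating = c(1, 2, 3)))
#' @export
zscore_ratings <- function(trials) {
  check_columns(trials, c("participant_id", "rating"), "ratings")
  out <- trials |>
    group_by(.data$participant_id) |>
    mutate(z_rating = {
      r <- .data$rating[!is.na(.data$rating)]
      if (length(unique(r)) < 2L) {
        rep(NA_real_, length(.data$rating))
      } else {
        (.data$rating - mean(r)) / sd(r)
      }
    }) |>
    ungroup()
  degenerate <- out |>
    group_by(.data$participant_id) |>
    summarise(bad = all(is.na(.data$z_rating)) && any(!is.na(.data$rating)),
              .groups = "drop") |>
    filter(.data$bad)
  if (nrow(degenerate)) {
    warn(paste0("constant ratings, z-scores set to NA for participant(s): ",
                paste(degenerate$participant_id, collapse = ", ")))
  }
  out
}

#' Z-score item features within category
#'
#' Standardises each feature column across items, separately per category when
#' a `category` column is present, so regression coefficients are directly
#' comparable across features. Z-scored columns are appended with a `z_`
#' prefix.
#'
#' @param features A data frame with one row per item (`item_id`, optionally
#'   `category`, plus numeric feature columns).
#' @param cols Feature columns to standardise; defaults to every numeric
#'   column.
#' @return The input tibble with `z_<feature>` columns appended.
#' @export
zscore_features <- function(features, cols = NULL) {
  check_columns(features, "item_id", "features")
  cols <- cols %||% names(features)[vapply(features, is.numeric, logical(1))]
  cols <- setdiff(cols, c("item_id", "category"))
  if (!length(cols)) abort("no numeric feature columns to z-score")
  grouped <- if ("category" %in% names(features)) {
    sizes <- table(features$category)
    if (any(sizes < 2L)) abort("each category needs at least 2 items")
    group_by(features, .data$category)
  } else {
    if (nrow(features) < 2L) abort("at least 2 items required")
    features
  }
  for (col in cols) {
    sds <- grouped |> summarise(s = sd(.data[[col]]), .groups = "drop")
    if (any(!is.finite(sds$s) | sds$s == 0)) {
      abort(sprintf("feature `%s` has zero variance and cannot be z-scored", col))
    }
  }
  grouped |>
    mutate(across(all_of(cols), ~ (.x - mean(.x)) / sd(.x),
                  .names = "z_{.col}")) |>
    ungroup()
}

#' Remove items with outlying feature values
#'
#' Drops any item whose z-scored feature value lies more than `k` sample SDs
#' from the category mean on any feature. The reported trigger is the feature
#' with the largest absolute z-score.
#'
#' @param features A feature table carrying `z_*` columns, as produced by
#'   [zscore_features()].
#' @param k Outlier threshold in SD units (default 3).
#' @return A list with `kept` (the surviving feature rows) and `removed`
#'   (a tibble `item_id`, `feature`, `z`, `reason`).
#' @export
exclude_items <- function(features, k = 3) {
  zcols <- grep("^z_", names(features), value = TRUE)
  if (!length(zcols)) {
    abort("no `z_*` columns found; run zscore_features() first")
  }
  long <- features |>
    select(all_of(c("item_id", zcols))) |>
    tidyr::pivot_longer(all_of(zcols), names_to = "feature", values_to = "z")
  removed <- long |>
    filter(abs(.data$z) > k) |>
    group_by(.data$item_id) |>
    slice_max(abs(.data$z), n = 1L, with_ties = FALSE) |>
    ungroup() |>
    transmute(item_id = .data$item_id,
              feature = sub("^z_", "", .data$feature),
              z = .data$z,
              reason = "feature_outlier")
  list(
    kept = filter(features, !.data$item_id %in% removed$item_id),
    removed = removed
  )
}

#' Remove no-response trials and reaction-time outliers
#'
#' Within each participant and task, removes trials with no response and
#' trials whose reaction time lies more than `k` sample SDs from that
#' participant's task mean. The mean and SD are computed over responded
#' trials only. Works on rating tables (`rating` column; `NA` = no response)
#' and choice tables (`choice` column; `"none"` = no response).
#'
#' @param trials A rating or choice trial table with `participant_id` and
#'   `rt` columns.
#' @param k Outlier threshold in SD units (default 3).
#' @return A list with `kept`, `removed` (with a `reason` column:
#'   `no_response` or `rt_outlier`), and `loss`, a per-participant tibble of
#'   `n_trials`, `n_removed` and `fraction = n_removed / n_trials`.
#' @export
exclude_trials <- function(trials, k = 3) {
  check_columns(trials, c("participant_id", "rt"), "trials")
  task <- infer_task(trials)
  resp <- responded(trials)
  work <- trials |>
    mutate(.task = task, .resp = resp) |>
    group_by(.data$participant_id, .data$.task) |>
    mutate(
      .mu = mean(.data$rt[.data$.resp], na.rm = TRUE),
      .sd = sd(.data$rt[.data$.resp], na.rm = TRUE),
      .reason = dplyr::case_when(
        !.data$.resp ~ "no_response",
        is.finite(.data$.sd) & .data$.sd > 0 &
          abs(.data$rt - .data$.mu) > k * .data$.sd ~ "rt_outlier",
        TRUE ~ NA_character_
      )
    ) |>
    ungroup()
  loss <- work |>
    group_by(participant_id = .data$participant_id, task = .data$.task) |>
    summarise(n_trials = dplyr::n(),
              n_removed = sum(!is.na(.data$.reason)),
              .groups = "drop") |>
    mutate(fraction = .data$n_removed / .data$n_trials)
  removed <- work |>
    filter(!is.na(.data$.reason)) |>
    mutate(reason = .data$.reason) |>
    select(-all_of(c(".task", ".resp", ".mu", ".sd", ".reason")))
  kept <- work |>
    filter(is.na(.data$.reason)) |>
    select(-all_of(c(".task", ".resp", ".mu", ".sd", ".reason")))
  list(kept = kept, removed = removed, loss = loss)
}

#' Remove participants with excessive trial loss or extreme intransitivity
#'
#' A participant is removed when more than `trial_loss_cap` of their trials
#' were excluded in either task, or when their choice-transitivity score lies
#' beyond `k` sample SDs from the sample mean of scores. Each removed
#' participant carries exactly one primary reason; trial loss takes
#' precedence over intransitivity.
#'
#' @param loss Per-participant trial-loss table(s) as returned in the `loss`
#'   element of [exclude_trials()] (bind rating and choice tables together).
#' @param scores Optional tibble `participant_id`, `transitivity_score` from
#'   [transitivity_scores()]; omit for rating-only designs.
#' @param trial_loss_cap Maximum tolerated fraction of excluded trials
#'   (default 0.30).
#' @param k Transitivity outlier threshold in SD units (default 3).
#' @param direction `"two.sided"` flags scores far from the mean in either
#'   direction (the literal reading of the exclusion rule); `"low"` flags only
#'   abnormally low scores, the signature of random or cyclic choosers.
#' @return A tibble `participant_id`, `reason`, `value`.
#' @export
exclude_participants <- function(loss, scores = NULL, trial_loss_cap = 0.30,
                                 k = 3, direction = c("two.sided", "low")) {
  direction <- match.arg(direction)
  check_columns(loss, c("participant_id", "task", "fraction"), "trial-loss")
  by_loss <- loss |>
    filter(.data$fraction > trial_loss_cap) |>
    arrange(.data$participant_id, .data$task) |>
    distinct(.data$participant_id, .keep_all = TRUE) |>
    transmute(participant_id = .data$participant_id,
              reason = paste0("trial_loss_", .data$task),
              value = .data$fraction)
  by_trans <- NULL
  if (!is.null(scores)) {
    check_columns(scores, c("participant_id", "transitivity_score"),
                  "transitivity")
    sc <- scores |> filter(!is.na(.data$transitivity_score))
    if (nrow(sc) < 3L) {
      warn("fewer than 3 participants with transitivity scores; intransitivity criterion skipped")
    } else {
      mu <- mean(sc$transitivity_score)
      s <- sd(sc$transitivity_score)
      if (s > 0) {
        flag <- if (direction == "two.sided") {
          abs(sc$transitivity_score - mu) > k * s
        } else {
          sc$transitivity_score < mu - k * s
        }
        by_trans <- sc |>
          filter(flag) |>
          transmute(participant_id = .data$participant_id,
                    reason = "intransitivity",
                    value = .data$transitivity_score)
      }
    }
  }
  bind_rows(by_loss, by_trans) |>
    distinct(.data$participant_id, .keep_all = TRUE)
}

#' Run the full behavioural preprocessing cascade
#'
#' Applies, in fixed order: category-wise feature z-scoring, item exclusion
#' (any |z| > `k_item`), removal of trials referencing excluded items,
#' trial exclusion (no response, or RT beyond `k_rt` SDs within participant
#' and task), choice-transitivity scoring, participant exclusion (trial loss
#' above `trial_loss_cap` in either task, or a transitivity score beyond
#' `k_transitivity` SDs), and finally participant-wise z-scoring of the
#' surviving ratings. Trial-loss fractions use the trials that entered the
#' trial-exclusion stage (i.e. after item removal) as denominator, and
#' no-response trials count toward them.
#'
#' @param ratings Rating-trial table (`participant_id`, `item_id`, `rating`,
#'   `rt`).
#' @param choices Optional choice-trial table (`participant_id`, `left_item`,
#'   `right_item`, `choice`, `rt`); omit for rating-only designs, in which
#'   case the transitivity criterion is skipped.
#' @param features Item feature table (`item_id`, optionally `category`,
#'   numeric features).
#' @param k_item,k_rt,k_transitivity Outlier thresholds in SD units.
#' @param trial_loss_cap Maximum tolerated fraction of excluded trials.
#' @param transitivity_direction Passed to [exclude_participants()].
#' @param feature_cols Passed to [zscore_features()].
#' @return A list of class `prefeat_data` with elements `ratings` (kept,
#'   with `z_rating`), `choices` (kept), `features` (kept, with `z_*`
#'   columns), `scores` (transitivity) and `report` (an `exclusion_report`).
#' @export
preprocess_behavior <- function(ratings, choices = NULL, features,
                                k_item = 3, k_rt = 3,
                                trial_loss_cap = 0.30, k_transitivity = 3,
                                transitivity_direction = "two.sided",
                                feature_cols = NULL) {
  check_columns(ratings, c("participant_id", "item_id", "rating", "rt"),
                "ratings")
  if (!is.null(choices)) {
    check_columns(choices, c("participant_id", "left_item", "right_item",
                             "choice", "rt"), "choices")
    if (any(choices$left_item == choices$right_item)) {
      abort("choice trials must pair two distinct items")
    }
  }
  fz <- zscore_features(features, cols = feature_cols)
  items <- exclude_items(fz, k = k_item)
  bad_items <- items$removed$item_id

  r_in <- filter(ratings, !.data$item_id %in% bad_items)
  n_item_trials <- nrow(ratings) - nrow(r_in)
  r_ex <- exclude_trials(r_in, k = k_rt)

  c_ex <- NULL
  scores <- NULL
  if (!is.null(choices)) {
    c_in <- filter(choices, !(.data$left_item %in% bad_items |
                                .data$right_item %in% bad_items))
    n_item_trials <- n_item_trials + nrow(choices) - nrow(c_in)
    c_ex <- exclude_trials(c_in, k = k_rt)
    scores <- transitivity_scores(c_ex$kept)
  }

  loss <- bind_rows(r_ex$loss, if (!is.null(c_ex)) c_ex$loss)
  removed_participants <- exclude_participants(
    loss, scores, trial_loss_cap = trial_loss_cap,
    k = k_transitivity, direction = transitivity_direction
  )
  bad_p <- removed_participants$participant_id

  kept_ratings <- r_ex$kept |>
    filter(!.data$participant_id %in% bad_p) |>
    zscore_ratings()
  kept_choices <- if (!is.null(c_ex)) {
    filter(c_ex$kept, !.data$participant_id %in% bad_p)
  }

  report <- structure(list(
    removed_items = items$removed,
    n_item_referencing_trials_dropped = n_item_trials,
    removed_trials = bind_rows(
      rating = select(r_ex$removed, any_of(c("participant_id", "item_id",
                                             "left_item", "right_item",
                                             "rt", "reason"))),
      choice = if (!is.null(c_ex)) {
        select(c_ex$removed, any_of(c("participant_id", "item_id",
                                      "left_item", "right_item",
                                      "rt", "reason")))
      },
      .id = "task"
    ),
    trial_loss = loss,
    removed_participants = removed_participants,
    summary = list(
      n_items_removed = nrow(items$removed),
      n_trials_removed = nrow(r_ex$removed) +
        if (is.null(c_ex)) 0L else nrow(c_ex$removed),
      mean_trial_loss_pct = 100 * mean(loss$fraction),
      sd_trial_loss_pct = 100 * sd(loss$fraction),
      n_participants_removed = nrow(removed_participants)
    )
  ), class = "exclusion_report")

  structure(
    list(ratings = kept_ratings, choices = kept_choices,
         features = items$kept, scores = scores, report = report),
    class = "prefeat_data"
  )
}

#' @export
print.exclusion_report <- function(x, ...) {
  s <- x$summary
  cat("<exclusion_report>\n")
  cat(sprintf("  items removed (feature outliers): %d\n", s$n_items_removed))
  cat(sprintf("  trials removed (RT / no response): %d (mean %.2f%%, SD %.2f%% per participant-task)\n",
              s$n_trials_removed, s$mean_trial_loss_pct, s$sd_trial_loss_pct))
  cat(sprintf("  participants removed: %d\n", s$n_participants_removed))
  invisible(x)
}

#' Serialise an exclusion report to JSON
#'
#' @param report An `exclusion_report` from [preprocess_behavior()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_exclusion_report <- function(report, path) {
  stopifnot(inherits(report, "exclusion_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
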