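# Colley-matrix ratings from pairwise choices, and the SD-of-ratings
# transitivity score used to screen out random or cyclic choosers.

#' Build a win-count matrix from one participant's choices
#'
#' @param choices Choice trials for a single participant (`left_item`,
#'   `right_item`, `choice`); trials with `choice == "none"` are ignored.
#' @param items Optional character vector fixing the item set and order;
#'   defaults to all items appearing in the trials.
#' @return An `n x n` integer matrix `wins` with `wins[i, j]` the number of
#'   times item `i` was chosen over item `j` (zero diagonal). Repeated pairs
#'   accumulate.
#' @export
choice_graph <- function(choices, items = NULL) {
  check_columns(choices, c("left_item", "right_item", "choice"), "choices")
  items <- items %||% sort(unique(c(as.character(choices$left_item),
                                    as.character(choices$right_item))))
  resp <- choices |> filter(.data$choice %in% c("left", "right"))
  winner <- ifelse(resp$choice == "left", as.character(resp$left_item),
                   as.character(resp$right_item))
  loser <- ifelse(resp$choice == "left", as.character(resp$right_item),
                  as.character(resp$left_item))
  wins <- table(factor(winner, levels = items), factor(loser, levels = items))
  wins <- matrix(as.integer(wins), length(items), length(items),
                 dimnames = list(items, items))
  if (any(diag(wins) != 0)) abort("self-play detected: left_item equals right_item")
  wins
}

#' Colley ratings and the transitivity score of a choice tournament
#'
#' Solves the Colley linear system over a participant's win/loss record:
#' with `t_i` the total games, `w_i` the wins and `l_i` the losses of item
#' `i`, and `n_ij` the games between `i` and `j`,
#' \deqn{(2 + t_i)\, r_i - \sum_{j \ne i} n_{ij} r_j = 1 + (w_i - l_i)/2.}
#' The system is diagonally dominant and always nonsingular; ratings lie in
#' (0, 1) and average exactly 1/2. The transitivity score is the sample SD of
#' the ratings: a deterministic, order-consistent chooser spreads the ratings
#' out, while random or cyclic choices compress them toward 1/2.
#'
#' @param wins An `n x n` nonnegative win-count matrix (zero diagonal), e.g.
#'   from [choice_graph()].
#' @return An object of class `colley_result`: a list with `items`,
#'   `ratings`, `transitivity_score` and the `wins` matrix.
#' @examples
#' # A beats B, A beats C, B beats C
#' w <- matrix(c(0, 0, 0, 1, 0, 0, 1, 1, 0), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' colley_ratings(w)$ratings # 0.7 0.5 0.3
#' @export
colley_ratings <- function(wins) {
  wins <- as.matrix(wins)
  if (nrow(wins) != ncol(wins)) abort("`wins` must be square")
  if (any(wins < 0) || any(diag(wins) != 0)) {
    abort("`wins` must be nonnegative with a zero diagonal")
  }
  n <- nrow(wins)
  w <- rowSums(wins)
  l <- colSums(wins)
  games <- wins + t(wins)
  C <- diag(2 + w + l, nrow = n) - games
  b <- 1 + (w - l) / 2
  r <- as.numeric(solve(C, b))
  structure(
    list(items = rownames(wins) %||% as.character(seq_len(n)),
         ratings = r,
         transitivity_score = if (n > 1L) sd(r) else 0,
         wins = wins),
    class = "colley_result"
  )
}

#' @export
print.colley_result <- function(x, ...) {
  cat(sprintf("<colley_result> %d items, transitivity score %.4f\n",
              length(x$items), x$transitivity_score))
  invisible(x)
}

#' @method tidy colley_result
#' @export
tidy.colley_result <- function(x, ...) {
  tibble(item_id = x$items, rating = x$ratings) |>
    arrange(dplyr::desc(.data$rating))
}

#' Per-participant transitivity scores
#'
#' Builds each participant's choice tournament from their kept trials and
#' returns the SD of their Colley ratings. Participants with no responded
#' trials get a missing score and a warning.
#'
#' @param choices A choice-trial table (`participant_id`, `left_item`,
#'   `right_item`, `choice`).
#' @return A tibble `participant_id`, `transitivity_score`, `n_trials`.
#' @export
transitivity_scores <- function(choices) {
  check_columns(choices, c("participant_id", "left_item", "right_item",
                           "choice"), "choices")
  out <- purrr::imap_dfr(
    split(choices, choices$participant_id),
    function(df, id) {
      resp <- df$choice %in% c("left", "right")
      tibble(
        participant_id = id,
        transitivity_score = if (!any(resp)) NA_real_ else {
          colley_ratings(choice_graph(df))$transitivity_score
        },
        n_trials = sum(resp)
      )
    }
  )
  if (anyNA(out$transitivity_score)) {
    warn(paste0("no responded choice trials, transitivity score NA for: ",
                paste(out$participant_id[is.na(out$transitivity_score)],
                      collapse = ", ")))
  }
  out
}

#' Per-participant, per-item Colley ratings
#'
#' Choice-derived item values, used as a covariate in the supplementary
#' ratings-model variant that adjusts ratings for binary choices.
#'
#' @inheritParams transitivity_scores
#' @return A tibble `participant_id`, `item_id`, `colley_rating`.
#' @export
colley_item_ratings <- function(choices) {
  check_columns(choices, c("participant_id", "left_item", "right_item",
                           "choice"), "choices")
  choices |>
    group_by(.data$participant_id) |>
    dplyr::group_modify(function(df, key) {
      res <- colley_ratings(choice_graph(df))
      tibble(item_id = res$items, colley_rating = res$ratings)
    }) |>
    ungroup()
}
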