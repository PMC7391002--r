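# Synthetic stimuli and behaviour with stored ground truth, so every stage of
# the pipeline -- feature extraction, the exclusion cascade, transitivity
# screening and both model families -- can be validated end to end by
# parameter recovery, without any external data.

#' Generate a noise image with a known spectral exponent
#'
#' Shapes white Gaussian noise in the frequency domain so that spectral power
#' falls off as `f^beta`, producing a validation stimulus whose spectral
#' slope is known by construction (`beta = 0` is white noise; natural images
#' cluster near `beta = -2`). The filtered field is transformed back to the
#' spatial domain, rescaled to `[0, 1]` (an affine map, which leaves the
#' slope untouched) and replicated to RGB.
#'
#' @param beta Target spectral exponent; values outside `[-4, 1]` trigger a
#'   warning as numerically extreme.
#' @param size Image side in pixels (even, at least 64).
#' @param seed Integer seed; the same seed reproduces the image exactly.
#' @param item_id,category Metadata for the returned [stimulus_image()].
#' @return A [stimulus_image()] of `size x size` pixels.
#' @examples
#' img <- gen_spectral_image(beta = -2, size = 512, seed = 42)
#' spectral_slope(img)$slope
#' @export
gen_spectral_image <- function(beta, size = 512L, seed,
                               item_id = sprintf("beta%+.1f", beta),
                               category = "fractal") {
  if (size < 64L || size %% 2L != 0L) abort("`size` must be even and >= 64")
  if (beta < -4 || beta > 1) {
    warn(sprintf("beta = %.2f is numerically extreme (typical range [-4, 1])",
                 beta))
  }
  set.seed(seed)
  white <- matrix(rnorm(size * size), size, size)
  u <- c(0:(size / 2), -(size / 2 - 1):-1)
  f <- sqrt(outer(u^2, u^2, `+`))
  filt <- f^(beta / 2)
  filt[1, 1] <- 0  # kill DC; the mean is set by the rescale below
  shaped <- Re(stats::fft(stats::fft(white) * filt, inverse = TRUE)) / size^2
  rng <- range(shaped)
  px <- (shaped - rng[1]) / (rng[2] - rng[1])
  stimulus_image(px, item_id = item_id, category = category)
}

#' Simulation settings for synthetic behaviour
#'
#' Defaults mirror the study design this package targets: 60 items per
#' category, 240 binary-choice trials per participant (about 14% of the
#' 60 x 59 / 2 possible pairs, sampled without replacement), a continuous
#' 1--10 rating scale, and around 100 participants per sample.
#'
#' @param n_items Number of items (must match the feature table supplied to
#'   [gen_behavior()]).
#' @param n_participants Number of simulated participants.
#' @param n_choice_trials Binary-choice trials per participant.
#' @param rating_scale Length-2 numeric rating scale bounds.
#' @param weights Named vector of population utility weights on z-scored
#'   features; features not named get weight 0.
#' @param weight_sd SD of participant-level deviations around each weight
#'   (random slopes in the generating process).
#' @param rating_noise_sd SD of the trial-level Gaussian noise added to each
#'   participant-item utility.
#' @param temperature Softmax temperature of the choice rule: the probability
#'   of choosing the left item is `plogis((u_left - u_right) / temperature)`.
#'   Smaller values give more deterministic, more transitive choosers.
#' @param choice_feature_weights Named vector of direct feature effects on
#'   the choice logit (added as `sum(gamma_f * delta z_f) / temperature`),
#'   over and above the utility difference; defaults to none.
#' @param frac_random_choosers Fraction of participants who choose at random
#'   (contaminants the transitivity screen should catch).
#' @param rt_outlier_rate Per-trial probability of an implausibly slow
#'   reaction time (the RT multiplied by `rt_outlier_factor`).
#' @param no_response_rate Per-trial probability of a missing response.
#' @param rt_meanlog,rt_sdlog Log-normal reaction-time parameters (seconds).
#' @param rt_outlier_factor Multiplier applied to outlier RTs.
#' @param allow_duplicate_pairs Allow the same item pair to be sampled twice
#'   for one participant.
#' @param seed Integer seed (mandatory: every generated dataset must be
#'   reproducible).
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_items = 60L, n_participants = 100L,
                             n_choice_trials = 240L,
                             rating_scale = c(1, 10),
                             weights = c(hue = 0.4, saturation = 0,
                                         color_value = -0.3, sharpness = 0.2,
                                         spectral_slope = 0),
                             weight_sd = 0.1,
                             rating_noise_sd = 0.5,
                             temperature = 0.5,
                             choice_feature_weights = NULL,
                             frac_random_choosers = 0,
                             rt_outlier_rate = 0,
                             no_response_rate = 0,
                             rt_meanlog = log(1.2), rt_sdlog = 0.3,
                             rt_outlier_factor = 8,
                             allow_duplicate_pairs = FALSE,
                             seed) {
  if (missing(seed) || is.null(seed)) abort("`seed` is mandatory")
  rates <- c(frac_random_choosers, rt_outlier_rate, no_response_rate)
  if (any(rates < 0 | rates > 1)) abort("rates must lie in [0, 1]")
  if (length(rating_scale) != 2L || diff(rating_scale) <= 0) {
    abort("`rating_scale` must be an increasing length-2 numeric")
  }
  if (temperature <= 0) abort("`temperature` must be positive")
  structure(
    list(n_items = as.integer(n_items),
         n_participants = as.integer(n_participants),
         n_choice_trials = as.integer(n_choice_trials),
         rating_scale = rating_scale, weights = weights,
         weight_sd = weight_sd, rating_noise_sd = rating_noise_sd,
         temperature = temperature,
         choice_feature_weights = choice_feature_weights,
         frac_random_choosers = frac_random_choosers,
         rt_outlier_rate = rt_outlier_rate,
         no_response_rate = no_response_rate,
         rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
         rt_outlier_factor = rt_outlier_factor,
         allow_duplicate_pairs = allow_duplicate_pairs,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Generate a synthetic item feature table
#'
#' Draws raw feature values with realistic locations and spreads for the
#' requested category: the five visual features for all categories, plus
#' market features (calories, product weight, price) for snacks and
#' configural features (fWHR, eye distance, nose--eyes distance) for faces.
#'
#' @param n_items Number of items.
#' @param category `"fractal"`, `"snack"` or `"face"`.
#' @param seed Integer seed.
#' @return A tibble of raw (not yet z-scored) features, one row per item.
#' @export
gen_item_features <- function(n_items = 60L, category = c("fractal", "snack",
                                                          "face"), seed) {
  category <- match.arg(category)
  if (missing(seed)) abort("`seed` is mandatory")
  set.seed(seed)
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  out <- tibble(
    item_id = sprintf("%s%03d", substr(category, 1, 2), seq_len(n_items)),
    category = category,
    hue = clamp(rnorm(n_items, 0.35, 0.15), 0, 1),
    saturation = clamp(rnorm(n_items, 0.50, 0.18), 0, 1),
    color_value = clamp(rnorm(n_items, 0.55, 0.15), 0, 1),
    sharpness = exp(rnorm(n_items, log(0.08), 0.4)),
    spectral_slope = rnorm(n_items, -2, 0.35)
  )
  if (category == "snack") {
    out <- out |> mutate(
      calories = clamp(rnorm(n_items, 480, 120), 100, 900),
      product_weight = clamp(rnorm(n_items, 60, 25), 10, 200),
      price = clamp(rnorm(n_items, 5, 2), 1, 10)
    )
  } else if (category == "face") {
    out <- out |> mutate(
      fwhr = clamp(rnorm(n_items, 1.10, 0.08), 0.8, 1.5),
      eye_distance = clamp(rnorm(n_items, 0.42, 0.04), 0.25, 0.6),
      nose_eyes_distance = clamp(rnorm(n_items, 0.40, 0.05), 0.2, 0.6)
    )
  }
  out
}

#' Generate synthetic ratings and choices with known ground truth
#'
#' Each participant's latent utility for an item is a weighted sum of the
#' item's z-scored features plus Gaussian noise,
#' `u_pi = sum_f w_pf z_f(i) + eps`, with participant weights scattered
#' around the population weights. Ratings are an affine map of utility onto
#' the rating scale (clipped at the scale ends; the map is chosen so that
#' three utility SDs span half the scale, making clipping rare). Choice
#' trials sample item pairs uniformly without within-participant duplicates
#' (unless allowed), randomise the left/right display, and choose left with
#' probability `plogis((u_left - u_right + sum_f gamma_f delta z_f) /
#' temperature)`. Contaminants are injected per the config: random choosers,
#' slow-RT outlier trials and missing responses. Reaction times are
#' log-normal.
#'
#' The returned `truth` element stores everything a recovery test needs,
#' including the coefficients the two model families should recover *on the
#' scale they are fitted on*: because ratings are z-scored per participant,
#' the generating weights map onto fitted coefficients via each
#' participant's realised rating SD, and `truth$expected_rating_coefs` /
#' `truth$expected_choice_coefs` carry those implied values (averaged over
#' uncontaminated participants).
#'
#' @param config A [generator_config()].
#' @param features An item feature table, e.g. from [gen_item_features()].
#' @return A list with `ratings`, `choices` and `truth`.
#' @export
gen_behavior <- function(config, features) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  fz <- zscore_features(features)
  zcols <- grep("^z_", names(fz), value = TRUE)
  fnames <- sub("^z_", "", zcols)
  Z <- as.matrix(fz[zcols])
  n_items <- nrow(Z)
  if (n_items != config$n_items) {
    warn(sprintf("feature table has %d items; config says %d (using the table)",
                 n_items, config$n_items))
  }
  P <- config$n_participants
  K <- length(fnames)

  w <- setNames(numeric(K), fnames)
  known <- intersect(names(config$weights), fnames)
  w[known] <- config$weights[known]
  Wp <- matrix(rep(w, each = P), P, K, dimnames = list(NULL, fnames)) +
    matrix(rnorm(P * K, 0, config$weight_sd), P, K)

  U <- Z %*% t(Wp) +
    matrix(rnorm(n_items * P, 0, config$rating_noise_sd), n_items, P)

  scale <- config$rating_scale
  mid <- mean(scale)
  u_centre <- mean(U)
  b <- (diff(scale) / 2) / (3 * sd(U))
  R <- pmin(pmax(mid + b * (U - u_centre), scale[1]), scale[2])

  pid <- sprintf("p%03d", seq_len(P))
  items <- fz$item_id
  n_rc <- round(config$frac_random_choosers * P)
  random_choosers <- if (n_rc > 0) sample(pid, n_rc) else character(0)

  draw_rt <- function(n) {
    rt <- rlnorm(n, config$rt_meanlog, config$rt_sdlog)
    out <- runif(n) < config$rt_outlier_rate
    rt[out] <- rt[out] * config$rt_outlier_factor
    list(rt = rt, outlier = out)
  }

  # ratings: every participant rates every item once
  ratings <- tidyr::expand_grid(participant_id = pid, item_id = items) |>
    mutate(rating = as.vector(R), task = "rating")
  rr <- draw_rt(nrow(ratings))
  nr <- runif(nrow(ratings)) < config$no_response_rate
  ratings <- ratings |>
    mutate(rt = ifelse(nr, NA_real_, rr$rt),
           rating = ifelse(nr, NA_real_, .data$rating))

  # choices: sampled pairs, randomised display side
  pairs <- t(utils::combn(n_items, 2L))
  if (config$n_choice_trials > nrow(pairs) && !config$allow_duplicate_pairs) {
    abort(sprintf("n_choice_trials (%d) exceeds the %d available pairs; set allow_duplicate_pairs = TRUE",
                  config$n_choice_trials, nrow(pairs)))
  }
  gamma <- setNames(numeric(K), fnames)
  if (!is.null(config$choice_feature_weights)) {
    gk <- intersect(names(config$choice_feature_weights), fnames)
    gamma[gk] <- config$choice_feature_weights[gk]
  }
  choice_list <- lapply(seq_len(P), function(p) {
    idx <- sample(nrow(pairs), config$n_choice_trials,
                  replace = config$allow_duplicate_pairs &&
                    config$n_choice_trials > nrow(pairs))
    a <- pairs[idx, 1]; bb <- pairs[idx, 2]
    swap <- runif(length(idx)) < 0.5
    li <- ifelse(swap, bb, a); ri <- ifelse(swap, a, bb)
    eta <- (U[li, p] - U[ri, p] +
              as.vector((Z[li, , drop = FALSE] - Z[ri, , drop = FALSE]) %*%
                          gamma)) / config$temperature
    p_left <- if (pid[p] %in% random_choosers) {
      rep(0.5, length(eta))
    } else {
      plogis(eta)
    }
    tibble(participant_id = pid[p],
           left_item = items[li], right_item = items[ri],
           choice = ifelse(rbinom(length(eta), 1, p_left) == 1,
                           "left", "right"),
           task = "choice")
  })
  choices <- bind_rows(choice_list)
  cr <- draw_rt(nrow(choices))
  cnr <- runif(nrow(choices)) < config$no_response_rate
  choices <- choices |>
    mutate(rt = ifelse(cnr, NA_real_, cr$rt),
           choice = ifelse(cnr, "none", .data$choice))

  # implied coefficients on the fitted (z-scored) scale
  clean <- !(pid %in% random_choosers)
  s_p <- apply(R, 2, sd)
  rating_coefs <- sweep(Wp, 1, b / s_p, `*`)  # P x K realised slopes
  expected_rating_coefs <- colMeans(rating_coefs)
  expected_choice_coefs <- c(
    delta_rating = mean(s_p[clean]) / (b * config$temperature),
    setNames(gamma / config$temperature, paste0("delta_", fnames))
  )

  truth <- list(
    features_z = fz,
    participant_weights = as_tibble(Wp) |>
      mutate(participant_id = pid, .before = 1),
    utilities = U,
    rating_map = list(mid = mid, slope = b, u_centre = u_centre),
    expected_rating_coefs = expected_rating_coefs,
    expected_choice_coefs = expected_choice_coefs,
    contaminants = tibble(participant_id = random_choosers,
                          type = rep("random_chooser",
                                     length(random_choosers))),
    rating_rt_outliers = which(rr$outlier & !nr),
    choice_rt_outliers = which(cr$outlier & !cnr),
    config = config
  )
  list(ratings = ratings, choices = choices, truth = truth)
}

#' Generate synthetic facial landmarks with known geometry
#'
#' Produces detector-style bounding boxes and eye/nose landmarks whose
#' configural features are known by construction: the box aspect ratio is the
#' drawn fWHR, the eyes sit symmetrically about the box centre at the drawn
#' (normalised) eye distance, and the nose bottom sits the drawn normalised
#' distance below the eye midpoint. [facial_features()] recovers the drawn
#' values exactly.
#'
#' @param n_faces Number of faces.
#' @param seed Integer seed.
#' @param mean_fwhr,sd_fwhr Distribution of the width-to-height ratio.
#' @param mean_eye_distance,sd_eye_distance Distribution of eye distance
#'   (fraction of box height).
#' @param mean_nose_eyes,sd_nose_eyes Distribution of nose--eyes distance
#'   (fraction of box height).
#' @param image_size Side of the (virtual) image canvas in pixels.
#' @return A landmark tibble as consumed by [facial_features()], with the
#'   drawn feature values attached as the `truth` attribute.
#' @export
gen_landmarks <- function(n_faces, seed, mean_fwhr = 1.1, sd_fwhr = 0.08,
                          mean_eye_distance = 0.42, sd_eye_distance = 0.04,
                          mean_nose_eyes = 0.40, sd_nose_eyes = 0.05,
                          image_size = 1024L) {
  if (n_faces < 1L) abort("`n_faces` must be at least 1")
  if (missing(seed)) abort("`seed` is mandatory")
  set.seed(seed)
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  box_h <- clamp(rnorm(n_faces, 300, 15), 200, 380)
  fwhr <- clamp(rnorm(n_faces, mean_fwhr, sd_fwhr), 0.7, 1.6)
  eye_d <- clamp(rnorm(n_faces, mean_eye_distance, sd_eye_distance), 0.2, 0.7)
  nose_d <- clamp(rnorm(n_faces, mean_nose_eyes, sd_nose_eyes), 0.15, 0.7)
  box_w <- fwhr * box_h
  box_x <- pmax(1, (image_size - box_w) / 2)
  box_y <- pmax(1, (image_size - box_h) / 2)
  cx <- box_x + box_w / 2
  eye_y <- box_y + 0.38 * box_h
  half <- eye_d * box_h / 2
  out <- tibble(
    item_id = sprintf("fa%03d", seq_len(n_faces)),
    box_x = box_x, box_y = box_y, box_w = box_w, box_h = box_h,
    lex = cx - half, ley = eye_y,
    rex = cx + half, rey = eye_y,
    nx = cx, ny = eye_y + nose_d * box_h
  )
  attr(out, "truth") <- tibble(
    item_id = out$item_id, fwhr = fwhr, eye_distance = eye_d,
    nose_eyes_distance = nose_d
  )
  out
}
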