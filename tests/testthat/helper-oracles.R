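# Independent brute-force oracles and small fixture builders. These
# deliberately re-derive results by direct enumeration (explicit loops,
# elementwise system assembly) so they share no code path with the package.

# 3x3 Sobel convolution by explicit loops, reflect-edge (clamped) padding.
oracle_sobel_magnitude <- function(g) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3) # columns: -1, 0, +1
  ky <- t(kx)
  h <- nrow(g); w <- ncol(g)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      gx <- 0; gy <- 0
      for (di in -1:1) {
        for (dj in -1:1) {
          ii <- min(max(i + di, 1), h)
          jj <- min(max(j + dj, 1), w)
          gx <- gx + g[ii, jj] * kx[di + 2, dj + 2]
          gy <- gy + g[ii, jj] * ky[di + 2, dj + 2]
        }
      }
      out[i, j] <- sqrt(gx^2 + gy^2)
    }
  }
  out
}

# Radial binning by an exhaustive double loop over (u, v).
oracle_radial_average <- function(power) {
  n <- nrow(power)
  centre <- n %/% 2 + 1
  sums <- list(); counts <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == centre && j == centre) next
      f <- as.character(round(sqrt((i - centre)^2 + (j - centre)^2)))
      sums[[f]] <- (sums[[f]] %||% 0) + power[i, j]
      counts[[f]] <- (counts[[f]] %||% 0) + 1
    }
  }
  freqs <- sort(as.integer(names(sums)))
  data.frame(
    freq = freqs,
    power = vapply(as.character(freqs),
                   function(f) sums[[f]] / counts[[f]], numeric(1))
  )
}

# Colley system assembled entry by entry and solved with QR.
oracle_colley <- function(wins) {
  n <- nrow(wins)
  C <- matrix(0, n, n)
  b <- numeric(n)
  for (i in seq_len(n)) {
    wi <- sum(wins[i, ]); li <- sum(wins[, i])
    C[i, i] <- 2 + wi + li
    for (j in seq_len(n)) {
      if (j != i) C[i, j] <- -(wins[i, j] + wins[j, i])
    }
    b[i] <- 1 + (wi - li) / 2
  }
  as.numeric(qr.solve(C, b))
}

random_tournament <- function(n, seed) {
  set.seed(seed)
  wins <- matrix(rpois(n * n, lambda = runif(1, 0.1, 2)), n, n)
  diag(wins) <- 0L
  wins
}

# A uniform-colour stimulus image.
uniform_image <- function(rgb, h = 4, w = 4) {
  stimulus_image(array(rep(rgb, each = h * w), dim = c(h, w, 3)))
}

# Minimal well-formed behavioural tables for cascade tests.
make_rating_trials <- function(participants, items, rating = 5, rt = 0.5) {
  tidyr::expand_grid(participant_id = participants, item_id = items) |>
    dplyr::mutate(rating = rating, rt = rt)
}
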