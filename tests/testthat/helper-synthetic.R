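# shared synthetic fixtures, built once per test run

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- build()
  .fixtures[[key]]
}

# small space: fast enough for property loops
tiny_config <- function(...) {
  space_config(n_vertices = 60L, n_shape_dims = 6L,
               texture_shape = c(16L, 12L), n_complexion_dims = 6L,
               n_sf_bands = 3L, ...)
}

tiny_space <- function() memo("tiny", function()
  build_generative_space(tiny_config(), seed = 11L))

# the desk-scale study space used by end-to-end checks
desk_space <- function() memo("desk", function()
  build_generative_space(space_config(), seed = 7L))

# simulate one rater with a planted preference at a given SNR
planted_rater <- function(space, seed, n_trials = 1950L, snr = 2,
                          pref = NULL, noise_sd = NULL) {
  if (is.null(pref)) pref <- random_preference(space, seed = seed)
  p <- participant_spec(sprintf("r%d", seed), pref$true_shape_pref,
                        pref$true_complexion_pref, seed = seed + 10000L)
  p$noise_sd <- if (is.null(noise_sd)) noise_sd_for_snr(space, p, snr)
                else noise_sd
  stim <- synthesize_stimuli(space, n_trials, seed = seed + 20000L)
  list(participant = p, trials = simulate_ratings(p, stim, space))
}

# hand-rolled face_trials with exact coefficient-rating relations
manual_trials <- function(shape, complexion, rating,
                          viewpoint = rep_len(c(-30, 0, 30), nrow(shape))) {
  structure(list(trial_id = seq_len(nrow(shape)), viewpoint = viewpoint,
                 rating = as.integer(rating), shape = shape,
                 complexion = complexion,
                 n_shape_dims = ncol(shape), n_complexion_dims = dim(complexion)[2],
                 n_sf_bands = dim(complexion)[3]),
            class = "face_trials")
}

# independent exhaustive BH oracle: max k with p_(k) <= k q / m
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0L
  for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
  mask <- logical(m)
  if (k > 0L) mask[o[seq_len(k)]] <- TRUE
  mask
}

# independent elbow oracle: explicit point-to-chord geometry per index
elbow_oracle <- function(v) {
  n <- length(v)
  p1 <- c(1, v[1]); p2 <- c(n, v[n])
  chord <- p2 - p1
  d <- vapply(seq_len(n), function(i) {
    rel <- c(i, v[i]) - p1
    abs(chord[1] * rel[2] - chord[2] * rel[1]) / sqrt(sum(chord^2))
  }, numeric(1))
  d[d < 1e-12 * max(1, max(abs(v)))] <- 0
  which.max(d)
}

# histogram plug-in MI oracle (equal-count bins)
hist_mi_oracle <- function(x, y, n_bins = 8L) {
  bx <- cut(rank(x, ties.method = "first"), n_bins, labels = FALSE)
  by <- cut(rank(y, ties.method = "first"), n_bins, labels = FALSE)
  tab <- table(bx, by) / length(x)
  px <- rowSums(tab); py <- colSums(tab)
  sum(tab * log(tab / outer(px, py)), na.rm = TRUE)
}
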