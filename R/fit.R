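#' Fit a participant's multivariate preference model
#'
#' Reverse correlation in coefficient space: for every identity dimension j
#' (shape and complexion alike) the stimulus coefficient is regressed on the
#' rating, `coefficient_j = beta1_j + beta2_j * rating`, by robust bisquare
#' regression ([robust_simple_regression()]). The beta2 map across dimensions
#' is the participant's model of facial attractiveness; ratings enter as raw
#' integers 1..9.
#'
#' @param trials a rated `face_trials` (>= 10 trials, ratings not all equal).
#' @param participant_id,condition labels stored on the model.
#' @return a `preference_model`: `shape_beta1`/`shape_beta2` (vectors),
#'   `complexion_beta1`/`complexion_beta2` (`dims x bands` matrices),
#'   per-dimension two-tailed slope p-values in the same shapes, `method`
#'   (`"robust_linear"`), `n_trials`.
#' @export
fit_preference_model <- function(trials, participant_id = "p", condition = "") {
  stopifnot(inherits(trials, "face_trials"))
  n <- n_trials_of(trials)
  if (n < 10L) stop_invalid("need at least 10 rated trials, got %d", n)
  ratings <- trials$rating
  if (anyNA(ratings)) stop_invalid("trials carry missing ratings")
  if (length(unique(ratings)) < 2L)
    stop_invalid("degenerate design: all ratings identical")
  Y <- cbind(trials$shape, flatten_complexion(trials$complexion))
  fit <- robust_simple_regression(Y, as.numeric(ratings))
  ds <- trials$n_shape_dims
  dc <- trials$n_complexion_dims; B <- trials$n_sf_bands
  si <- seq_len(ds); ci <- ds + seq_len(dc * B)
  structure(list(
    participant_id = participant_id, condition = condition,
    method = "robust_linear",
    shape_beta1 = fit$b1[si], shape_beta2 = fit$b2[si],
    shape_p = fit$p[si],
    complexion_beta1 = matrix(fit$b1[ci], dc, B),
    complexion_beta2 = matrix(fit$b2[ci], dc, B),
    complexion_p = matrix(fit$p[ci], dc, B),
    n_trials = n, n_shape_dims = ds, n_complexion_dims = dc, n_sf_bands = B
  ), class = "preference_model")
}

#' @export
print.preference_model <- function(x, ...) {
  cat(sprintf(
    "preference_model [%s] %s%s: %d shape + %dx%d complexion dims, %d trials\n",
    x$method, x$participant_id,
    if (nzchar(x$condition)) paste0(" (", x$condition, ")") else "",
    x$n_shape_dims, x$n_complexion_dims, x$n_sf_bands, x$n_trials))
  invisible(x)
}

# beta2 concatenated in fitting order (shape, then complexion bands)
beta2_vector <- function(model) {
  c(model$shape_beta2, as.vector(model$complexion_beta2))
}

check_same_dims <- function(models) {
  ref <- models[[1]]
  for (m in models)
    if (m$n_shape_dims != ref$n_shape_dims ||
        m$n_complexion_dims != ref$n_complexion_dims ||
        m$n_sf_bands != ref$n_sf_bands)
      stop_invalid("models have mismatched dimensions")
  invisible(ref)
}

#' Map a model's beta2 to vertex space
#'
#' @param model a `preference_model`.
#' @param space the `generative_space`.
#' @return numeric vector of length `3 * n_vertices`: the per-coordinate
#'   attractiveness slope map implied by the multivariate model.
#' @export
model_vertex_map <- function(model, space) {
  drop(space$shape_basis %*% model$shape_beta2)
}

#' Map a model's complexion beta2 to down-sampled pixel space
#'
#' @inheritParams model_vertex_map
#' @param factor block-mean down-sampling factor (default 4, the same
#'   reduction the local pixel model uses).
#' @return numeric vector of length `3 * (h/factor) * (w/factor)`.
#' @export
model_pixel_map <- function(model, space, factor = 4L) {
  h <- space$texture_shape[2]; w <- space$texture_shape[1]
  acc <- 0
  for (b in seq_len(space$n_sf_bands))
    acc <- acc + drop(downsample_pixels(
      space$complexion_basis[[b]] %*% model$complexion_beta2[, b],
      h, w, factor))
  acc
}

#' Fit vertex- and pixel-level local models
#'
#' Renders every trial against a cell and regresses each vertex coordinate
#' and each down-sampled pixel channel (block-mean, factor 4; 800x600 ->
#' 200x150 at full study scale) independently on the ratings. Two-tailed
#' slope p-values are corrected by Benjamini-Hochberg FDR jointly across all
#' vertex-coordinate tests, and separately jointly across all pixel-channel
#' tests.
#'
#' @inheritParams fit_preference_model
#' @param space the `generative_space`.
#' @param cell categorical cell the trials were rendered against.
#' @param fdr_q FDR level for the masks (default 0.05).
#' @return a `local_model`: `vertex_beta2`/`vertex_p`/`vertex_mask`
#'   (`n_vertices x 3`), `pixel_beta2`/`pixel_p`/`pixel_mask`
#'   (`h/4 x w/4 x 3`), `fdr_q`.
#' @export
fit_local_model <- function(trials, space, cell, fdr_q = 0.05) {
  stopifnot(inherits(space, "generative_space"))
  n <- n_trials_of(trials)
  if (n < 10L) stop_invalid("need at least 10 rated trials")
  if (anyNA(trials$rating)) stop_invalid("trials carry missing ratings")
  if (length(unique(trials$rating)) < 2L)
    stop_invalid("degenerate design: all ratings identical")
  get_cell(space, cell)
  x <- as.numeric(trials$rating)

  Vmat <- render_vertices(space, trials, cell)
  vfit <- robust_simple_regression(Vmat, x)
  Pmat <- render_pixels_down(space, trials, cell)
  pfit <- robust_simple_regression(Pmat, x)

  V <- space$n_vertices
  h2 <- space$texture_shape[2] %/% 4L; w2 <- space$texture_shape[1] %/% 4L
  structure(list(
    vertex_beta2 = matrix(vfit$b2, V, 3),
    vertex_p = matrix(vfit$p, V, 3),
    vertex_mask = matrix(bh_mask(vfit$p, fdr_q), V, 3),
    pixel_beta2 = array(pfit$b2, c(h2, w2, 3)),
    pixel_p = array(pfit$p, c(h2, w2, 3)),
    pixel_mask = array(bh_mask(pfit$p, fdr_q), c(h2, w2, 3)),
    fdr_q = fdr_q, cell = cell, n_trials = n
  ), class = "local_model")
}

# collapse the 9 rating levels to 5 attractiveness bins: {1-2,3-4,5,6-7,8-9}
rating_to_bin <- function(rating) {
  cut(rating, breaks = c(0.5, 2.5, 4.5, 5.5, 7.5, 9.5), labels = FALSE)
}

#' Check the linearity assumption of the preference regression
#'
#' Three-step diagnostic: (1) average the rendered faces within each of 5
#' attractiveness rating bins; (2) compute the per-vertex Euclidean distance
#' of each bin average from the categorical average, giving an
#' `n_vertices x 5` distance matrix; (3) cluster the vertex distance profiles
#' with k-means (k chosen by the elbow method on within-cluster dispersion
#' over k = 1..8, 20 restarts) and report each cluster centroid's maximum
#' deviation from the straight line joining its bin-1 and bin-5 values.
#' Near-zero deviations support modeling the coefficient-rating relation
#' linearly.
#'
#' Distances are signed: each vertex's per-bin deviation is projected onto
#' that vertex's dominant direction of travel (its bin-5 minus bin-1
#' deviation), so a linear preference produces linear — not V-shaped —
#' distance profiles. Vertices whose travel direction is degenerate fall
#' back to the unsigned Euclidean distance.
#'
#' @inheritParams fit_local_model
#' @param n_bins number of rating bins (5; the 9 levels collapse as
#'   1-2, 3-4, 5, 6-7, 8-9).
#' @param k_max largest k tried for k-means.
#' @param seed seed for the k-means restarts.
#' @return a `linearity_report`: `bin_counts`, `distance_matrix`
#'   (`n_vertices x n_bins`), `k_selected`, `cluster_centroids`
#'   (`k x n_bins`), `max_deviation_from_line` and `centroid_range` per
#'   centroid, `cluster_assignment`.
#' @export
check_linearity <- function(trials, space, cell, n_bins = 5L, k_max = 8L,
                            seed = 1L) {
  stopifnot(inherits(space, "generative_space"), n_bins == 5L)
  avg <- get_cell(space, cell)$mesh
  bins <- rating_to_bin(trials$rating)
  counts <- tabulate(bins, n_bins)
  if (any(counts == 0L))
    stop_invalid("empty attractiveness bin(s): %s",
                 paste(which(counts == 0L), collapse = ", "))
  V <- space$n_vertices
  # per-bin mean deviation of each vertex from the categorical average
  dev <- lapply(seq_len(n_bins), function(b) {
    mb <- colMeans(render_vertices(space, subset_trials(trials, bins == b),
                                   cell))
    matrix(mb, V, 3) - avg
  })
  # signed distance: each vertex's deviation projected on its dominant
  # direction of travel (bin-5 minus bin-1 deviation); a linear
  # coefficient-rating relation makes every row linear in the bin drive
  u <- dev[[n_bins]] - dev[[1]]
  un <- sqrt(rowSums(u^2))
  degen <- un < .Machine$double.eps^0.5
  u <- u / ifelse(un == 0, 1, un)
  D <- vapply(dev, function(d) {
    s <- rowSums(d * u)
    ifelse(degen, sqrt(rowSums(d^2)), s)
  }, numeric(V))

  spread <- sum(apply(D, 2L, stats::var))
  if (spread < 1e-20) {
    k_sel <- 1L
    centroids <- matrix(colMeans(D), 1L)
    assign <- rep(1L, V)
  } else {
    wss <- with_seed(seed, vapply(seq_len(k_max), function(k)
      stats::kmeans(D, centers = k, nstart = 20L,
                    iter.max = 50L)$tot.withinss, numeric(1)))
    k_sel <- elbow_select(pmax(wss, 0) + 1e-12)
    km <- with_seed(seed + 1L,
                    stats::kmeans(D, centers = k_sel, nstart = 20L,
                                  iter.max = 50L))
    centroids <- km$centers
    assign <- km$cluster
  }
  line_vals <- t(vapply(seq_len(nrow(centroids)), function(i)
    seq(centroids[i, 1], centroids[i, n_bins], length.out = n_bins),
    numeric(n_bins)))
  structure(list(
    bin_counts = counts, distance_matrix = D, k_selected = k_sel,
    cluster_centroids = centroids,
    max_deviation_from_line = apply(abs(centroids - line_vals), 1L, max),
    centroid_range = apply(centroids, 1L, function(r) diff(range(r))),
    cluster_assignment = assign
  ), class = "linearity_report")
}

#' Fit a signed mutual-information preference model
#'
#' Estimates, per identity dimension, the Gaussian-copula mutual information
#' between the stimulus coefficient and the rating — sensitive to any
#' (linear or monotone nonlinear) dependence — and signs it with the slope of
#' the robust linear fit so MI and regression models are directly comparable.
#' Signed MI values occupy the beta2 slots; beta1 slots are zero.
#'
#' @inheritParams fit_preference_model
#' @return a `preference_model` with `method = "mi_signed"`.
#' @export
fit_mi_model <- function(trials, participant_id = "p", condition = "") {
  base <- fit_preference_model(trials, participant_id, condition)
  Y <- cbind(trials$shape, flatten_complexion(trials$complexion))
  mi <- gaussian_copula_mi(Y, as.numeric(trials$rating))
  signed <- mi * sign(beta2_vector(base))
  ds <- base$n_shape_dims; dc <- base$n_complexion_dims; B <- base$n_sf_bands
  base$method <- "mi_signed"
  base$shape_beta2 <- signed[seq_len(ds)]
  base$complexion_beta2 <- matrix(signed[ds + seq_len(dc * B)], dc, B)
  base$shape_beta1 <- numeric(ds)
  base$complexion_beta1 <- matrix(0, dc, B)
  base
}

#' Compare two preference models in vertex and pixel space
#'
#' Maps both models' beta2 to vertex space (shape) and down-sampled pixel
#' space (complexion), computes the Spearman rank correlation between them,
#' and calibrates it against a permutation null built by shuffling beta2
#' magnitudes across identity dimensions while holding signs fixed
#' (the null of "same signs, unrelated magnitudes").
#'
#' @param model_a,model_b `preference_model`s over the same dimensions.
#' @param space the `generative_space`.
#' @param n_perm permutation iterations (default 200).
#' @param seed integer seed.
#' @return a `model_similarity` list with per-domain (`shape`, `complexion`)
#'   `r`, `threshold` (95th percentile of the null) and `significant`.
#' @export
compare_model_similarity <- function(model_a, model_b, space, n_perm = 200L,
                                     seed = 1L) {
  check_same_dims(list(model_a, model_b))
  maps <- function(m) list(shape = model_vertex_map(m, space),
                           complexion = model_pixel_map(m, space))
  a <- maps(model_a)
  shuffle_model <- function(m) {
    v <- beta2_vector(m)
    v2 <- sign(v) * sample(abs(v))
    m$shape_beta2 <- v2[seq_len(m$n_shape_dims)]
    m$complexion_beta2 <- matrix(v2[-seq_len(m$n_shape_dims)],
                                 m$n_complexion_dims, m$n_sf_bands)
    m
  }
  b <- maps(model_b)
  obs <- list(shape = stats::cor(a$shape, b$shape, method = "spearman"),
              complexion = stats::cor(a$complexion, b$complexion,
                                      method = "spearman"))
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      bm <- maps(shuffle_model(model_b))
      c(stats::cor(a$shape, bm$shape, method = "spearman"),
        stats::cor(a$complexion, bm$complexion, method = "spearman"))
    }, numeric(2))
  })
  thr <- apply(null, 1L, stats::quantile, probs = 0.95, names = FALSE)
  structure(list(
    shape = list(r = obs$shape, threshold = thr[1],
                 significant = obs$shape > thr[1]),
    complexion = list(r = obs$complexion, threshold = thr[2],
                      significant = obs$complexion > thr[2]),
    n_perm = n_perm
  ), class = "model_similarity")
}
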