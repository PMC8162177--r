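#' Average preference models into a group model
#'
#' Elementwise mean of the beta1 and beta2 coefficients over participants;
#' all models must share dimensions and fitting method.
#'
#' @param models nonempty list of `preference_model`s.
#' @param condition label stored on the group model.
#' @return a `preference_model` whose coefficients are the group means.
#' @export
average_group_model <- function(models, condition = "group") {
  if (length(models) < 1L) stop_invalid("need at least one model")
  ref <- check_same_dims(models)
  methods <- unique(vapply(models, `[[`, character(1), "method"))
  if (length(methods) > 1L)
    stop_invalid("mixed fitting methods: %s", paste(methods, collapse = ", "))
  mean_of <- function(field)
    Reduce(`+`, lapply(models, `[[`, field)) / length(models)
  out <- ref
  out$participant_id <- sprintf("group_mean_n%d", length(models))
  out$condition <- condition
  out$shape_beta1 <- mean_of("shape_beta1")
  out$shape_beta2 <- mean_of("shape_beta2")
  out$complexion_beta1 <- mean_of("complexion_beta1")
  out$complexion_beta2 <- mean_of("complexion_beta2")
  out$shape_p <- NULL; out$complexion_p <- NULL
  out
}

#' Reconstruct attractive, average and unattractive faces
#'
#' Renders the categorical average displaced along the model's beta2
#' direction: positively amplified for the attractive face, negatively for
#' the unattractive one. The default gain corresponds to evaluating the
#' linear model at the rating extremes (4 rating steps from the scale
#' midpoint); `display_multiplier` amplifies further for visualization.
#'
#' @param space a `generative_space`.
#' @param cell cell label.
#' @param model a `preference_model`.
#' @param gain positive amplification applied to beta2 (default 4).
#' @param display_multiplier extra display amplification (default 1).
#' @return list with `attractive`, `average`, `unattractive` renders (each a
#'   `mesh` + `texture` pair) and deviation maps `vertex_displacement`
#'   (`n_vertices`, Euclidean, signed by direction of travel not applicable —
#'   nonnegative) and `pixel_delta` (`h x w x 3`).
#' @export
reconstruct_extreme_faces <- function(space, cell, model, gain = 4,
                                      display_multiplier = 1) {
  if (gain <= 0) stop_invalid("gain must be positive")
  g <- gain * display_multiplier
  mk <- function(s) render_stimulus(space, list(
    shape_coeffs = s * g * model$shape_beta2,
    complexion_coeffs = s * g * model$complexion_beta2), cell)
  attractive <- mk(1); average <- mk(0); unattractive <- mk(-1)
  list(attractive = attractive, average = average, unattractive = unattractive,
       vertex_displacement =
         sqrt(rowSums((attractive$mesh - average$mesh)^2)),
       pixel_delta = attractive$texture - average$texture,
       gain = gain, display_multiplier = display_multiplier, cell = cell)
}

# kernel-density mode per column, Silverman bandwidth, 512-point grid
kde_mode <- function(x) {
  if (length(unique(x)) == 1L) return(x[1])
  d <- stats::density(x, bw = "nrd0", n = 512L,
                      from = min(x), to = max(x))
  d$x[which.max(d$y)]
}

#' Z-score modal attractive features against the stimulus distribution
#'
#' Four steps: (1) pool every participant's highly attractive stimuli
#' (rating at or above `min_rating`; a participant with no such trials
#' contributes their top `fallback_quantile` of ratings instead);
#' (2) estimate, per identity dimension, the modal coefficient of that
#' attractive set by a Gaussian kernel density peak, and render the modal
#' attractive face; (3) compute the per-vertex-coordinate and per-pixel
#' channel mean and SD over all experimental stimuli; (4) z-score the modal
#' face against those moments. Locations with zero stimulus SD are returned
#' as `NA` and flagged, never silently zero.
#'
#' @param trials_by_participant list of rated `face_trials` (one per
#'   participant; pass a list of one if stimuli are shared).
#' @param space a `generative_space`.
#' @param cell cell label.
#' @param min_rating attractiveness cutoff defining the attractive set.
#' @param fallback_quantile per-participant rating quantile used when no
#'   trial reaches `min_rating`.
#' @return a `zscore_map`: `vertex_z` (`n_vertices x 3`), `pixel_z`
#'   (`h x w x 3`), matching `*_undefined` flags, `attractive_set_size`,
#'   `modal_shape_coeffs`, `modal_complexion_coeffs`.
#' @export
zscore_attractive_features <- function(trials_by_participant, space, cell,
                                       min_rating = 8L,
                                       fallback_quantile = 0.9) {
  stopifnot(inherits(space, "generative_space"))
  if (inherits(trials_by_participant, "face_trials"))
    trials_by_participant <- list(trials_by_participant)
  pick <- lapply(trials_by_participant, function(tr) {
    idx <- which(tr$rating >= min_rating)
    if (length(idx) == 0L)
      idx <- which(tr$rating >= stats::quantile(tr$rating, fallback_quantile))
    subset_trials(tr, idx)
  })
  n_attr <- sum(vapply(pick, n_trials_of, integer(1)))
  if (n_attr == 0L) stop_invalid("attractive set is empty under the top rule")
  attr_shape <- do.call(rbind, lapply(pick, `[[`, "shape"))
  attr_cplx <- do.call(rbind, lapply(pick, function(p)
    flatten_complexion(p$complexion)))

  modal_shape <- apply(attr_shape, 2L, kde_mode)
  modal_cplx_flat <- apply(attr_cplx, 2L, kde_mode)
  modal_cplx <- matrix(modal_cplx_flat, space$n_complexion_dims,
                       space$n_sf_bands)
  modal_face <- render_stimulus(space, list(shape_coeffs = modal_shape,
                                            complexion_coeffs = modal_cplx),
                                cell)

  all_shape <- do.call(rbind, lapply(trials_by_participant, `[[`, "shape"))
  all_cplx <- do.call(rbind, lapply(trials_by_participant, function(p)
    flatten_complexion(p$complexion)))
  avg <- get_cell(space, cell)

  # exact per-location moments via the coefficient covariance (rendering is
  # affine, so location variance = b' Cov(coeffs) b per basis row)
  mesh_mean <- avg$mesh +
    matrix(space$shape_basis %*% colMeans(all_shape), space$n_vertices, 3)
  Ss <- stats::cov(all_shape)
  mesh_var <- rowSums((space$shape_basis %*% Ss) * space$shape_basis)
  mesh_sd <- matrix(sqrt(pmax(mesh_var, 0)), space$n_vertices, 3)

  Bfull <- do.call(cbind, space$complexion_basis)
  tex_mean <- as.vector(avg$texture) + drop(Bfull %*% colMeans(all_cplx))
  Sc <- stats::cov(all_cplx)
  tex_sd <- sqrt(pmax(rowSums((Bfull %*% Sc) * Bfull), 0))

  vz <- (modal_face$mesh - mesh_mean) / mesh_sd
  vz[mesh_sd == 0] <- NA_real_
  h <- space$texture_shape[2]; w <- space$texture_shape[1]
  pz <- (as.vector(modal_face$texture) - tex_mean) / tex_sd
  pz[tex_sd == 0] <- NA_real_
  structure(list(
    vertex_z = vz, vertex_undefined = mesh_sd == 0,
    pixel_z = array(pz, c(h, w, 3)),
    pixel_undefined = array(tex_sd == 0, c(h, w, 3)),
    attractive_set_size = n_attr,
    modal_shape_coeffs = modal_shape,
    modal_complexion_coeffs = modal_cplx, cell = cell
  ), class = "zscore_map")
}

#' Sexual-dimorphism direction of an ethnicity
#'
#' The per-vertex (shape) and per-pixel (complexion) difference between the
#' female and male categorical averages, reparametrized into identity
#' coefficient space by basis projection, with a reduced dimension set
#' selected by the elbow method on the space's database eigenvalue spectrum,
#' separately for shape and for each SF band.
#'
#' @param space a `generative_space`.
#' @param ethnicity ethnicity label with both a female and a male cell.
#' @return a `dimorphism_direction`: `vertex_delta` (`n_vertices x 3`),
#'   `pixel_delta` (`h x w x 3`), `coeff_shape`, `coeff_complexion`
#'   (`dims x bands`), `reduced_shape_dims`, `reduced_complexion_dims`
#'   (one per band).
#' @export
compute_dimorphism_direction <- function(space, ethnicity) {
  f <- get_cell(space, paste(ethnicity, "female", sep = "_"))
  m <- get_cell(space, paste(ethnicity, "male", sep = "_"))
  vd <- f$mesh - m$mesh
  pd <- f$texture - m$texture
  coeff_shape <- drop(crossprod(space$shape_basis, as.vector(vd)))
  coeff_cplx <- vapply(seq_len(space$n_sf_bands), function(b)
    drop(crossprod(space$complexion_basis[[b]], as.vector(pd))),
    numeric(space$n_complexion_dims))
  structure(list(
    ethnicity = ethnicity, vertex_delta = vd, pixel_delta = pd,
    coeff_shape = coeff_shape, coeff_complexion = coeff_cplx,
    reduced_shape_dims = elbow_select(space$shape_spectrum),
    reduced_complexion_dims = vapply(seq_len(space$n_sf_bands), function(b)
      elbow_select(space$complexion_spectrum[, b]), integer(1))
  ), class = "dimorphism_direction")
}

# reduced-dimension vectors used by the cosine comparison and the
# dimorphism predictor
reduced_model_vector <- function(model, direction, domain) {
  if (domain == "shape") {
    k <- direction$reduced_shape_dims
    model$shape_beta2[seq_len(k)]
  } else {
    unlist(lapply(seq_len(model$n_sf_bands), function(b)
      model$complexion_beta2[seq_len(direction$reduced_complexion_dims[b]), b]))
  }
}

reduced_direction_vector <- function(direction, domain) {
  if (domain == "shape") {
    direction$coeff_shape[seq_len(direction$reduced_shape_dims)]
  } else {
    unlist(lapply(seq_along(direction$reduced_complexion_dims), function(b)
      direction$coeff_complexion[
        seq_len(direction$reduced_complexion_dims[b]), b]))
  }
}

#' Bootstrap cosine test of a preference model against a direction
#'
#' Computes the cosine between the model's reduced-dimension beta2 and a
#' reference direction (typically sexual dimorphism). The null of "no
#' difference" is the model's bootstrap self-similarity: trials are resampled
#' with replacement `n_boot` times, the model refitted, and the cosine of
#' each bootstrap model to the original model collected; the observed
#' model-vs-direction cosine is significantly different from the direction
#' when it falls below the 2.5th percentile of that self-similarity
#' distribution.
#'
#' @param trials the rated `face_trials` the model was fitted from.
#' @param model the fitted `preference_model`.
#' @param direction a [compute_dimorphism_direction()] result (or any
#'   object with the same fields).
#' @param domain `"shape"` or `"complexion"`.
#' @param n_boot bootstrap iterations (default 1000).
#' @param seed integer seed.
#' @return a `cosine_test`: `cosine`, `ci_low`, `ci_high` (2.5/97.5
#'   percentiles of bootstrap self-similarity), `significant`
#'   (`cosine < ci_low`), `n_boot`, `boot_cosines`.
#' @export
cosine_similarity_test <- function(trials, model, direction,
                                   domain = c("shape", "complexion"),
                                   n_boot = 1000L, seed = 1L) {
  domain <- match.arg(domain)
  v_dir <- reduced_direction_vector(direction, domain)
  if (sqrt(sum(v_dir^2)) == 0)
    stop_invalid("zero-norm reference direction")
  v_mod <- reduced_model_vector(model, direction, domain)
  obs <- cosine_similarity(v_mod, v_dir)
  n <- n_trials_of(trials)
  # bootstrap refits reuse the robust-regression settings of the full fit;
  # per-dimension regressions are independent, so only the reduced-dimension
  # columns entering the cosine need refitting
  cols <- if (domain == "shape") {
    seq_len(direction$reduced_shape_dims)
  } else {
    unlist(lapply(seq_len(model$n_sf_bands), function(b)
      (b - 1L) * model$n_complexion_dims +
        seq_len(direction$reduced_complexion_dims[b])))
  }
  Y <- if (domain == "shape") trials$shape[, cols, drop = FALSE]
       else flatten_complexion(trials$complexion)[, cols, drop = FALSE]
  x <- as.numeric(trials$rating)
  boot <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    bf <- robust_simple_regression(Y[idx, , drop = FALSE], x[idx])
    cosine_similarity(bf$b2, v_mod)
  }, numeric(1)))
  ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
  structure(list(cosine = obs, ci_low = ci[1], ci_high = ci[2],
                 significant = obs < ci[1], n_boot = n_boot,
                 domain = domain, boot_cosines = boot),
            class = "cosine_test")
}

#' @export
print.cosine_test <- function(x, ...) {
  cat(sprintf(
    "cosine test (%s): cos = %.3f, self-similarity 95%% CI [%.3f, %.3f] -> %s\n",
    x$domain, x$cosine, x$ci_low, x$ci_high,
    if (x$significant) "significantly different" else "not distinguishable"))
  invisible(x)
}
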