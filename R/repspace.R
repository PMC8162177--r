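#' Elbow selection on a ranked eigenvalue curve
#'
#' Returns the index of the point with the largest perpendicular distance to
#' the chord joining the first and last points of the curve — the elbow.
#' Ties (including an exactly linear curve, where every distance is zero)
#' resolve to the smallest index.
#'
#' @param values nonincreasing positive numeric vector, length >= 3.
#' @return 1-based integer index of the elbow.
#' @export
elbow_select <- function(values) {
  n <- length(values)
  if (n < 3L) stop_invalid("elbow selection needs at least 3 values")
  if (!all(is.finite(values)) || any(values <= 0))
    stop_invalid("eigenvalue curve must be positive and finite")
  x <- seq_len(n)
  dx <- n - 1; dy <- values[n] - values[1]
  # distance from (x_i, v_i) to the chord through the endpoints
  d <- abs(dy * (x - 1) - dx * (values - values[1])) / sqrt(dx^2 + dy^2)
  d[d < 1e-12 * max(1, max(abs(values)))] <- 0
  as.integer(which.max(d))
}

# vectorize one model in a domain: vertex map (shape) or down-sampled pixel
# map (complexion)
model_domain_vector <- function(model, space, domain) {
  if (domain == "shape") model_vertex_map(model, space)
  else model_pixel_map(model, space)
}

#' Build the attractiveness representation space over individual models
#'
#' Vectorizes each model's beta2 at vertex granularity (shape) or
#' down-sampled pixel granularity (complexion), stacks models as rows,
#' mean-centers across models and applies PCA. The number of retained
#' components is chosen by the elbow method on the eigenvalue curve.
#'
#' @param models list of >= 2 `preference_model`s with equal dimensions.
#' @param space the `generative_space`.
#' @param domain `"shape"` or `"complexion"`.
#' @param group_labels optional per-model condition labels.
#' @return an `attractiveness_space`: `loadings` (`ambient x n_components`,
#'   orthonormal), `eigenvalues`, `var_explained`, `n_kept`, `scores`
#'   (`n_models x n_kept`), `center`, `model_ids`, `group_labels`, `domain`.
#' @export
build_attractiveness_space <- function(models, space,
                                       domain = c("shape", "complexion"),
                                       group_labels = NULL) {
  domain <- match.arg(domain)
  if (length(models) < 2L) stop_invalid("need at least 2 models for a PCA")
  check_same_dims(models)
  X <- t(vapply(models, model_domain_vector, space = space, domain = domain,
                numeric(length(model_domain_vector(models[[1]], space,
                                                   domain)))))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  keepable <- ev > max(ev) * 1e-12
  ev <- ev[keepable]
  n_comp <- length(ev)
  n_kept <- if (n_comp >= 3L) elbow_select(ev) else n_comp
  structure(list(
    domain = domain,
    loadings = pc$rotation[, seq_len(n_comp), drop = FALSE],
    eigenvalues = ev,
    var_explained = ev / sum(ev),
    n_kept = as.integer(n_kept),
    scores = pc$x[, seq_len(n_kept), drop = FALSE],
    all_scores = pc$x[, seq_len(n_comp), drop = FALSE],
    center = pc$center,
    model_ids = vapply(models, `[[`, character(1), "participant_id"),
    group_labels = group_labels %||%
      vapply(models, `[[`, character(1), "condition")
  ), class = "attractiveness_space")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.attractiveness_space <- function(x, ...) {
  cat(sprintf(
    "attractiveness_space (%s): %d models, %d components (%d kept, %.1f%% var)\n",
    x$domain, nrow(x$scores), length(x$eigenvalues), x$n_kept,
    100 * sum(x$var_explained[seq_len(x$n_kept)])))
  invisible(x)
}

#' Project vectors into an attractiveness space
#'
#' @param aspace an `attractiveness_space`.
#' @param X matrix with ambient-dimension columns (one row per vector).
#' @param center subtract the model mean first (TRUE for model vectors,
#'   FALSE for stimulus residuals measured from the categorical average).
#' @param components how many leading components (default the kept set).
#' @return score matrix `nrow(X) x components`.
#' @export
space_project <- function(aspace, X, center = TRUE,
                          components = aspace$n_kept) {
  X <- as.matrix(X)
  if (center) X <- sweep(X, 2L, aspace$center)
  X %*% aspace$loadings[, seq_len(components), drop = FALSE]
}

#' Bootstrap refits of a participant's preference model
#'
#' @param trials rated `face_trials`.
#' @param n_boot number of with-replacement resamples of the trials.
#' @param seed integer seed.
#' @param participant_id,condition labels for the refits.
#' @return list of `n_boot` `preference_model`s.
#' @export
bootstrap_models <- function(trials, n_boot = 20L, seed = 1L,
                             participant_id = "p", condition = "") {
  stopifnot(n_boot >= 1)
  n <- n_trials_of(trials)
  idx <- with_seed(seed, replicate(n_boot, sample.int(n, n, replace = TRUE),
                                   simplify = FALSE))
  lapply(idx, function(i)
    fit_preference_model(subset_trials(trials, i), participant_id, condition))
}

# per-component group/participant R2 terms for a score matrix
ss_decompose <- function(scores, group, participant) {
  scores <- as.matrix(scores)
  group <- as.factor(group); participant <- as.factor(participant)
  ss_total <- colSums(scores^2)
  gm <- rowsum(scores, group) / as.vector(table(group))
  resid1 <- scores - gm[as.integer(group), , drop = FALSE]
  ss_resi1 <- colSums(resid1^2)
  pm <- rowsum(resid1, participant) / as.vector(table(participant))
  resid2 <- resid1 - pm[as.integer(participant), , drop = FALSE]
  ss_resi2 <- colSums(resid2^2)
  r2g <- 1 - ss_resi1 / ss_total
  frac2 <- ifelse(ss_resi1 > 0, ss_resi2 / ss_resi1, 1)
  list(ss_total = ss_total, ss_resi1 = ss_resi1, ss_resi2 = ss_resi2,
       r2_group = r2g,
       r2_participant = ss_resi1 / ss_total * (1 - frac2))
}

#' Decompose preference variance into group and participant shares
#'
#' Per retained component, the total sum of squares is measured from 0 (the
#' no-effect point of a beta2 score). Removing condition (group) means leaves
#' `SSresi1`; additionally removing each participant's residual mean leaves
#' `SSresi2`. The group share is `R2_group = 1 - SSresi1/SStotal` and the
#' participant share `R2_participant = SSresi1/SStotal * (1 -
#' SSresi2/SSresi1)`; the remainder is bootstrap sampling variance. Weighted
#' summaries combine components by their share of explained variance.
#'
#' @param scores score matrix (`n_models x n_components`), e.g.
#'   `aspace$scores` over bootstrap models.
#' @param group,participant per-row condition and participant labels;
#'   >= 2 groups and >= 2 participants per group.
#' @param var_weights per-component weights (e.g. `var_explained` of the
#'   kept components); normalized internally.
#' @return a `variance_decomposition` with per-component SS terms, `R2_group`,
#'   `R2_participant`, and `weighted_R2_group` / `weighted_R2_participant`.
#' @export
decompose_variance <- function(scores, group, participant,
                               var_weights = NULL) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (length(group) != n || length(participant) != n)
    stop_invalid("group/participant labels must match the score rows")
  if (anyNA(group) || anyNA(participant))
    stop_invalid("missing group or participant labels")
  if (length(unique(group)) < 2L) stop_invalid("need >= 2 groups")
  tab <- table(unique(data.frame(g = group, p = participant))$g)
  if (any(tab < 2L)) stop_invalid("need >= 2 participants per group")
  w <- var_weights %||% rep(1, ncol(scores))
  w <- w / sum(w)
  d <- ss_decompose(scores, group, participant)
  structure(c(d, list(
    weighted_R2_group = sum(w * d$r2_group),
    weighted_R2_participant = sum(w * d$r2_participant),
    var_weights = w
  )), class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf(
    "variance decomposition: weighted R2 group = %.3f, participant = %.3f (%d components)\n",
    x$weighted_R2_group, x$weighted_R2_participant, length(x$r2_group)))
  invisible(x)
}

#' Permutation thresholds for group/participant variance shares
#'
#' Group mode: participant blocks (each participant's bootstrap models move
#' together) are shuffled across conditions and `R2_group` recomputed per
#' component, giving a null of no group difference. Participant mode:
#' conditions stay fixed and models are shuffled across participants within
#' each condition, giving a null of no stable participant preference. The
#' per-component threshold is the `100 - 100*alpha/n_components` percentile
#' (one-tailed, Bonferroni over components; e.g. 99.375 for 8 components at
#' alpha 0.05); the overall threshold is the variance-weighted sum of the
#' per-component thresholds.
#'
#' @inheritParams decompose_variance
#' @param mode `"group"` or `"participant"`.
#' @param n_perm permutation iterations (>= 100).
#' @param alpha one-tailed familywise level.
#' @param seed integer seed.
#' @return a `permutation_thresholds` object: `thresholds` per component,
#'   `observed`, `significant`, `weighted_threshold`, `weighted_observed`,
#'   `weighted_significant`, `percentile`.
#' @export
permutation_thresholds <- function(scores, group, participant,
                                   mode = c("group", "participant"),
                                   n_perm = 200L, alpha = 0.05, seed = 1L,
                                   var_weights = NULL) {
  mode <- match.arg(mode)
  if (n_perm < 100L) stop_invalid("n_perm must be >= 100")
  scores <- as.matrix(scores)
  group <- as.character(group); participant <- as.character(participant)
  pmap <- unique(data.frame(p = participant, g = group,
                            stringsAsFactors = FALSE))
  if (anyDuplicated(pmap$p))
    stop_invalid("inconsistent block structure: a participant appears in several groups")
  k <- ncol(scores)
  w <- var_weights %||% rep(1, k)
  w <- w / sum(w)
  obs <- ss_decompose(scores, group, participant)
  observed <- if (mode == "group") obs$r2_group else obs$r2_participant

  null <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(i) {
      if (mode == "group") {
        newg <- stats::setNames(sample(pmap$g), pmap$p)
        d <- ss_decompose(scores, newg[participant], participant)
        d$r2_group
      } else {
        newp <- participant
        for (g in unique(group)) {
          idx <- which(group == g)
          newp[idx] <- participant[idx][sample(length(idx))]
        }
        d <- ss_decompose(scores, group, newp)
        d$r2_participant
      }
    }, numeric(k)))
  })
  pct <- 100 - 100 * alpha / k
  thr <- apply(null, 2L, stats::quantile, probs = pct / 100, names = FALSE)
  structure(list(
    mode = mode, thresholds = thr, observed = observed,
    significant = observed > thr,
    weighted_threshold = sum(w * thr),
    weighted_observed = sum(w * observed),
    weighted_significant = sum(w * observed) > sum(w * thr),
    percentile = pct, n_perm = n_perm
  ), class = "permutation_thresholds")
}

#' Classify transferred versus interactive preference features
#'
#' A location (vertex coordinate or pixel channel) of the other-ethnicity
#' group model is *transferred* when its beta2 sign matches the same
#' culture's own-ethnicity model, *interactive* when it matches the other
#' culture's own-ethnicity model, *both* when it matches both, and *neither*
#' otherwise. Zero slopes carry sign 0 and match nothing.
#'
#' @param own_same own culture, own-ethnicity group `preference_model`.
#' @param own_other own culture, other-ethnicity group model (the one being
#'   classified).
#' @param other_same other culture's own-ethnicity group model.
#' @param space the `generative_space`.
#' @return a `transfer_map` with factors `vertex_class`
#'   (length `3 * n_vertices`) and `pixel_class` (down-sampled pixel
#'   channels), levels transferred/interactive/both/neither.
#' @export
classify_transfer_interactive <- function(own_same, own_other, other_same,
                                          space) {
  check_same_dims(list(own_same, own_other, other_same))
  structure(list(
    vertex_class = sign_match_classes(model_vertex_map(own_other, space),
                                      model_vertex_map(own_same, space),
                                      model_vertex_map(other_same, space)),
    pixel_class = sign_match_classes(model_pixel_map(own_other, space),
                                     model_pixel_map(own_same, space),
                                     model_pixel_map(other_same, space))
  ), class = "transfer_map")
}

#' Per-location transferred/interactive sign rule
#'
#' @param own_other,own_same,other_same numeric vectors of per-location
#'   slopes (equal length).
#' @return factor with levels transferred/interactive/both/neither.
#' @export
sign_match_classes <- function(own_other, own_same, other_same) {
  stopifnot(length(own_other) == length(own_same),
            length(own_other) == length(other_same))
  so <- sign(own_other)
  transferred <- so != 0 & so == sign(own_same)
  interactive <- so != 0 & so == sign(other_same)
  cls <- ifelse(transferred & interactive, "both",
                ifelse(transferred, "transferred",
                       ifelse(interactive, "interactive", "neither")))
  factor(cls, levels = c("transferred", "interactive", "both", "neither"))
}
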