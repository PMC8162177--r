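#' Averageness predictor of a stimulus
#'
#' Distance of the stimulus from the center of the identity space (the
#' categorical average): the Euclidean norm of its shape coefficient vector,
#' or of its flattened complexion coefficient matrix.
#'
#' @param shape_coeffs numeric vector, or `complexion_coeffs` matrix.
#' @param complexion_coeffs complexion coefficient matrix (`dims x bands`).
#' @param domain `"shape"` or `"complexion"`.
#' @return nonnegative scalar distance.
#' @export
averageness_predictor <- function(shape_coeffs = NULL,
                                  complexion_coeffs = NULL,
                                  domain = c("shape", "complexion")) {
  domain <- match.arg(domain)
  v <- if (domain == "shape") shape_coeffs else as.vector(complexion_coeffs)
  check_finite(v, "coefficients")
  sqrt(sum(v^2))
}

#' Sexual-dimorphism predictor of a stimulus
#'
#' Scalar projection of the stimulus coefficients onto the dimorphism
#' direction, computed in the reduced dimension set of the direction.
#'
#' @param shape_coeffs,complexion_coeffs stimulus coefficients.
#' @param direction a [compute_dimorphism_direction()].
#' @param domain `"shape"` or `"complexion"`.
#' @return scalar projection `<coeffs, dir> / ||dir||`.
#' @export
dimorphism_predictor <- function(shape_coeffs = NULL,
                                 complexion_coeffs = NULL, direction,
                                 domain = c("shape", "complexion")) {
  domain <- match.arg(domain)
  d <- reduced_direction_vector(direction, domain)
  nd <- sqrt(sum(d^2))
  if (nd == 0) stop_invalid("zero-norm dimorphism direction")
  v <- if (domain == "shape") {
    shape_coeffs[seq_len(direction$reduced_shape_dims)]
  } else {
    unlist(lapply(seq_along(direction$reduced_complexion_dims), function(b)
      complexion_coeffs[seq_len(direction$reduced_complexion_dims[b]), b]))
  }
  sum(v * d) / nd
}

# per-trial predictor columns for the two alternative families
alternative_predictors <- function(trials, direction, domain) {
  n <- n_trials_of(trials)
  avgness <- if (domain == "shape") {
    sqrt(rowSums(trials$shape^2))
  } else {
    sqrt(rowSums(flatten_complexion(trials$complexion)^2))
  }
  dim_pred <- vapply(seq_len(n), function(i) {
    tr <- trial_record(trials, i)
    dimorphism_predictor(tr$shape_coeffs, tr$complexion_coeffs,
                         direction, domain)
  }, numeric(1))
  list(averageness = avgness, dimorphism = dim_pred)
}

# Gamma/log GLM fit + prediction with convergence flagging
gamma_glm_tau <- function(x_train, y_train, x_test, y_test) {
  x_train <- as.matrix(x_train); x_test <- as.matrix(x_test)
  dtr <- data.frame(y = y_train, x_train)
  dte <- data.frame(x_test); names(dte) <- names(dtr)[-1]
  fit <- tryCatch(
    stats::glm(y ~ ., data = dtr, family = stats::Gamma(link = "log"),
               control = stats::glm.control(maxit = 100, epsilon = 1e-8)),
    error = function(e) NULL, warning = function(w) NULL)
  ok <- !is.null(fit) && fit$converged
  if (!ok) return(list(tau = NA_real_, converged = FALSE, coef = NULL))
  pred <- stats::predict(fit, newdata = dte, type = "response")
  list(tau = stats::cor(y_test, pred, method = "kendall"),
       converged = TRUE, coef = stats::coef(fit))
}

#' Cross-validated prediction of held-out ratings
#'
#' k-fold cross-validation (13 folds by default: trials randomly permuted
#' into contiguous blocks) of three predictor families, separately for shape
#' and complexion. Per fold, the participant's preference model is refitted
#' on the training trials, the attractiveness space rebuilt from that model
#' plus the supplied context models of other participants, each stimulus's
#' identity residual expressed as kept-component scores, and a Gamma GLM
#' with log link fitted to the training ratings (positive, right-skewed) by
#' iteratively reweighted least squares. Held-out predictions are scored by
#' Kendall tau rank correlation with the actual ratings. The alternative
#' families replace the scores with the averageness distance and the
#' dimorphism scalar projection.
#'
#' @param trials rated `face_trials` of the target participant
#'   (>= `10 * k_folds` trials).
#' @param context_models list of other participants' `preference_model`s
#'   used to span the space in every fold.
#' @param space the `generative_space`.
#' @param direction a [compute_dimorphism_direction()] for the dimorphism
#'   predictor.
#' @param k_folds number of folds (>= 2; default 13).
#' @param seed integer seed for the fold permutation.
#' @param participant_id label carried into the result.
#' @return a `validation_result`: `tau` matrix (`k_folds x 6` families:
#'   attractiveness/averageness/dimorphism x shape/complexion), `folds`
#'   (trial assignments), `converged` flags, `glm_coefficients`.
#' @export
crossval_predict <- function(trials, context_models, space, direction,
                             k_folds = 13L, seed = 1L,
                             participant_id = "p") {
  n <- n_trials_of(trials)
  if (k_folds < 2L) stop_invalid("k_folds must be >= 2")
  if (n < 10L * k_folds)
    stop_invalid("need at least %d trials for %d folds", 10L * k_folds,
                 k_folds)
  if (any(trials$rating <= 0)) stop_invalid("ratings must be positive")
  folds <- with_seed(seed, {
    perm <- sample.int(n)
    fold_of <- integer(n)
    fold_of[perm] <- rep(seq_len(k_folds),
                         times = diff(round(seq(0, n, length.out =
                                                  k_folds + 1L))))
    fold_of
  })

  # stimulus maps in model-vectorization space do not depend on the fold
  stim_vec <- list(shape = render_vertices(space, trials),
                   complexion = render_pixels_down(space, trials))
  alts <- list(shape = alternative_predictors(trials, direction, "shape"),
               complexion = alternative_predictors(trials, direction,
                                                   "complexion"))
  fams <- c("attractiveness_shape", "averageness_shape", "dimorphism_shape",
            "attractiveness_complexion", "averageness_complexion",
            "dimorphism_complexion")
  tau <- matrix(NA_real_, k_folds, length(fams),
                dimnames = list(NULL, fams))
  converged <- matrix(TRUE, k_folds, length(fams),
                      dimnames = list(NULL, fams))
  glm_coefs <- vector("list", k_folds)

  for (f in seq_len(k_folds)) {
    test <- folds == f
    train_trials <- subset_trials(trials, !test)
    fold_model <- fit_preference_model(train_trials, participant_id)
    y_tr <- as.numeric(trials$rating[!test])
    y_te <- as.numeric(trials$rating[test])
    glm_coefs[[f]] <- list()
    for (domain in c("shape", "complexion")) {
      aspace <- build_attractiveness_space(
        c(list(fold_model), context_models), space, domain)
      sc <- space_project(aspace, stim_vec[[domain]], center = FALSE)
      preds <- list(attractiveness = sc,
                    averageness = alts[[domain]]$averageness,
                    dimorphism = alts[[domain]]$dimorphism)
      for (fam in names(preds)) {
        X <- as.matrix(preds[[fam]])
        res <- gamma_glm_tau(X[!test, , drop = FALSE], y_tr,
                             X[test, , drop = FALSE], y_te)
        col <- paste(fam, domain, sep = "_")
        tau[f, col] <- res$tau
        converged[f, col] <- res$converged
        if (fam == "attractiveness")
          glm_coefs[[f]][[domain]] <- res$coef
      }
    }
  }
  structure(list(participant_id = participant_id, tau = tau, folds = folds,
                 converged = converged, glm_coefficients = glm_coefs,
                 k_folds = k_folds, seed = seed),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  m <- colMeans(x$tau, na.rm = TRUE)
  cat(sprintf("validation_result %s (%d folds): mean Kendall tau\n",
              x$participant_id, x$k_folds))
  for (nm in names(m)) cat(sprintf("  %-26s %.3f\n", nm, m[nm]))
  invisible(x)
}

#' Compare predictor families across participants
#'
#' Per participant, the mean Kendall tau across folds of each predictor
#' family; then paired t-tests of attractiveness against averageness and
#' against dimorphism, separately for shape and complexion,
#' Bonferroni-corrected over the 4 comparisons. The pairing unit is the
#' participant (folds within a participant are dependent).
#'
#' @param results list of >= 2 `validation_result`s with complete folds.
#' @return a `predictor_comparison`: `mean_tau` (participant x family),
#'   `tests` data frame with `t`, `df`, `p`, `p_bonferroni`.
#' @export
compare_predictors <- function(results) {
  if (length(results) < 2L) stop_invalid("need >= 2 participants")
  mt <- t(vapply(results, function(r) colMeans(r$tau, na.rm = TRUE),
                 numeric(6)))
  rownames(mt) <- vapply(results, `[[`, character(1), "participant_id")
  if (anyNA(mt)) stop_invalid("incomplete fold results for some participants")
  cmp <- expand.grid(alternative = c("averageness", "dimorphism"),
                     domain = c("shape", "complexion"),
                     stringsAsFactors = FALSE)
  tests <- do.call(rbind, lapply(seq_len(nrow(cmp)), function(i) {
    a <- mt[, paste("attractiveness", cmp$domain[i], sep = "_")]
    b <- mt[, paste(cmp$alternative[i], cmp$domain[i], sep = "_")]
    if (all(a == b)) {
      data.frame(cmp[i, ], t = 0, df = length(a) - 1L, p = 1)
    } else {
      tt <- stats::t.test(a, b, paired = TRUE)
      data.frame(cmp[i, ], t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value)
    }
  }))
  tests$p_bonferroni <- pmin(tests$p * nrow(tests), 1)
  structure(list(mean_tau = mt, tests = tests),
            class = "predictor_comparison")
}

#' @export
print.predictor_comparison <- function(x, ...) {
  cat("predictor comparison (paired t over participants, Bonferroni x4):\n")
  print(x$tests, row.names = FALSE)
  invisible(x)
}
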