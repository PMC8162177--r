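#' Configure a full synthetic study run
#'
#' The four experimental conditions cross rater culture (WE, EA) with face
#' ethnicity (same, other), as in a balanced two-culture design. Each
#' simulated participant's planted preference is drawn around a
#' condition-level mean preference, so the cohort carries both a cultural
#' (group) and an idiosyncratic (participant) component.
#'
#' @param space_config a [space_config()].
#' @param n_per_condition participants per condition (>= 2).
#' @param n_trials trials per participant.
#' @param snr drive signal-to-noise ratio of every simulated rater.
#' @param group_sd dispersion of participant preferences around their
#'   condition mean (unit-norm condition means).
#' @param n_boot bootstrap models per participant for the variance
#'   decomposition.
#' @param n_perm permutation iterations for the significance thresholds.
#' @param k_folds cross-validation folds.
#' @param n_validate number of participants run through cross-validation
#'   (validation is the slowest stage; `Inf` for all).
#' @param seed master seed; all stage seeds derive from it.
#' @return a `run_config` list.
#' @export
run_config <- function(space_config = prefcorr3d::space_config(),
                       n_per_condition = 3L, n_trials = 260L, snr = 2,
                       group_sd = 0.4, n_boot = 5L, n_perm = 100L,
                       k_folds = 13L, n_validate = 4L, seed = 1L) {
  if (n_per_condition < 2L) stop_invalid("need >= 2 participants per condition")
  structure(list(space_config = space_config,
                 n_per_condition = as.integer(n_per_condition),
                 n_trials = as.integer(n_trials), snr = snr,
                 group_sd = group_sd, n_boot = as.integer(n_boot),
                 n_perm = as.integer(n_perm), k_folds = as.integer(k_folds),
                 n_validate = n_validate, seed = as.integer(seed)),
            class = "run_config")
}

condition_table <- function() {
  data.frame(
    condition = c("Western-same", "Western-other", "Eastern-same",
                  "Eastern-other"),
    culture = c("WE", "WE", "EA", "EA"),
    face_ethnicity = c("WE", "EA", "EA", "WE"),
    stringsAsFactors = FALSE)
}

#' Simulate a structured cohort of raters
#'
#' Draws one unit-norm mean preference per condition and one participant
#' preference per rater around it, simulates each rater's trials and
#' ratings at the configured signal-to-noise ratio, and fits each rater's
#' preference model.
#'
#' @param space a `generative_space`.
#' @param config a [run_config()].
#' @return list with `participants` (specs), `trials` (rated `face_trials`
#'   per participant), `models` (fitted `preference_model`s), and a
#'   `conditions` data frame (one row per participant).
#' @export
simulate_cohort <- function(space, config) {
  ct <- condition_table()
  centers <- lapply(seq_len(nrow(ct)), function(i)
    random_preference(space, seed = config$seed * 1000L + i))
  participants <- list(); trials <- list(); models <- list()
  rows <- list()
  idx <- 0L
  for (i in seq_len(nrow(ct))) for (j in seq_len(config$n_per_condition)) {
    idx <- idx + 1L
    pid <- sprintf("%s_p%02d", ct$condition[i], j)
    pref <- random_preference(space, seed = config$seed * 1000L + 100L * i + j,
                              center = centers[[i]], sd = config$group_sd)
    p <- participant_spec(pid, pref$true_shape_pref,
                          pref$true_complexion_pref,
                          culture = ct$culture[i],
                          face_ethnicity = ct$face_ethnicity[i],
                          seed = config$seed * 2000L + idx)
    p$noise_sd <- noise_sd_for_snr(space, p, config$snr)
    stim <- synthesize_stimuli(space, config$n_trials,
                               seed = config$seed * 3000L + idx)
    tr <- simulate_ratings(p, stim, space)
    participants[[pid]] <- p
    trials[[pid]] <- tr
    models[[pid]] <- fit_preference_model(tr, pid, ct$condition[i])
    rows[[idx]] <- data.frame(participant_id = pid,
                              condition = ct$condition[i],
                              culture = ct$culture[i],
                              face_ethnicity = ct$face_ethnicity[i],
                              stringsAsFactors = FALSE)
  }
  list(participants = participants, trials = trials, models = models,
       conditions = do.call(rbind, rows))
}

#' Run the full analysis pipeline on synthetic data
#'
#' End-to-end orchestration: builds the generative space, simulates the
#' cohort, fits individual models, computes group models and feature
#' analyses (dimorphism directions, cosine tests for one participant per
#' condition, z-score maps), builds the attractiveness representation
#' spaces, decomposes preference variance over bootstrap models with
#' permutation thresholds, and cross-validates rating prediction. All
#' artifacts are written under `out_dir` along with a machine-readable
#' `summary.json`. Runs are fully reproducible under the config's seed.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return the summary list, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    val <- tryCatch(expr, error = function(e)
      stop_invalid("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)))
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    val
  }

  space <- stage("space", {
    s <- build_generative_space(config$space_config, seed = config$seed)
    write_space(s, file.path(out_dir, "space"))
    s
  })

  cohort <- stage("cohort", {
    co <- simulate_cohort(space, config)
    dir.create(file.path(out_dir, "trials"), showWarnings = FALSE)
    dir.create(file.path(out_dir, "models"), showWarnings = FALSE)
    for (pid in names(co$trials)) {
      write_trials(co$trials[[pid]],
                   file.path(out_dir, "trials", paste0(pid, ".csv")))
      write_model(co$models[[pid]],
                  file.path(out_dir, "models", paste0(pid, ".json")))
    }
    co
  })
  ct <- condition_table()
  by_cond <- split(seq_len(nrow(cohort$conditions)),
                   cohort$conditions$condition)[ct$condition]

  features <- stage("features", {
    group_models <- lapply(ct$condition, function(cd)
      average_group_model(cohort$models[by_cond[[cd]]], cd))
    names(group_models) <- ct$condition
    directions <- lapply(space$ethnicities, function(e)
      compute_dimorphism_direction(space, e))
    names(directions) <- space$ethnicities
    cos_tests <- lapply(seq_len(nrow(ct)), function(i) {
      pid <- cohort$conditions$participant_id[by_cond[[ct$condition[i]]][1]]
      ctest <- cosine_similarity_test(
        cohort$trials[[pid]], cohort$models[[pid]],
        directions[[ct$face_ethnicity[i]]], domain = "shape",
        n_boot = 200L, seed = config$seed + i)
      list(participant = pid, cosine = ctest$cosine,
           ci_low = ctest$ci_low, significant = ctest$significant)
    })
    names(cos_tests) <- ct$condition
    zmaps <- lapply(ct$condition, function(cd) {
      cell <- paste0(ct$face_ethnicity[match(cd, ct$condition)], "_female")
      z <- zscore_attractive_features(cohort$trials[by_cond[[cd]]], space,
                                      cell)
      list(condition = cd, attractive_set_size = z$attractive_set_size,
           max_abs_vertex_z = max(abs(z$vertex_z), na.rm = TRUE))
    })
    names(zmaps) <- ct$condition
    list(group_models = group_models, directions = directions,
         cosine_tests = cos_tests, zscore = zmaps)
  })

  repspace <- stage("representation", {
    out <- list()
    for (domain in c("shape", "complexion")) {
      aspace <- build_attractiveness_space(
        unname(cohort$models), space, domain,
        group_labels = cohort$conditions$condition)
      boot <- list(); bgroup <- character(0); bpart <- character(0)
      for (irow in seq_len(nrow(cohort$conditions))) {
        pid <- cohort$conditions$participant_id[irow]
        bms <- bootstrap_models(cohort$trials[[pid]], config$n_boot,
                                seed = config$seed * 4000L + irow,
                                participant_id = pid,
                                condition = cohort$conditions$condition[irow])
        boot <- c(boot, bms)
        bgroup <- c(bgroup, rep(cohort$conditions$condition[irow],
                                config$n_boot))
        bpart <- c(bpart, rep(pid, config$n_boot))
      }
      bspace <- build_attractiveness_space(boot, space, domain,
                                           group_labels = bgroup)
      w <- bspace$var_explained[seq_len(bspace$n_kept)]
      dec <- decompose_variance(bspace$scores, bgroup, bpart, w)
      pg <- permutation_thresholds(bspace$scores, bgroup, bpart, "group",
                                   n_perm = config$n_perm,
                                   seed = config$seed + 7L, var_weights = w)
      pp <- permutation_thresholds(bspace$scores, bgroup, bpart,
                                   "participant", n_perm = config$n_perm,
                                   seed = config$seed + 8L, var_weights = w)
      data.table::fwrite(
        data.frame(model_id = bspace$model_ids, group = bgroup,
                   bspace$scores),
        file.path(out_dir, sprintf("scores_%s.csv", domain)))
      out[[domain]] <- list(
        n_components = length(aspace$eigenvalues), n_kept = aspace$n_kept,
        var_explained_first3 =
          sum(aspace$var_explained[seq_len(min(3L,
                                               length(aspace$eigenvalues)))]),
        var_explained_kept = sum(aspace$var_explained[seq_len(aspace$n_kept)]),
        weighted_R2_group = dec$weighted_R2_group,
        weighted_R2_participant = dec$weighted_R2_participant,
        group_significant = pg$weighted_significant,
        participant_significant = pp$weighted_significant)
    }
    out
  })

  validation <- stage("validation", {
    n_val <- min(length(cohort$models), config$n_validate)
    results <- lapply(seq_len(n_val), function(irow) {
      pid <- cohort$conditions$participant_id[irow]
      eth <- cohort$conditions$face_ethnicity[irow]
      crossval_predict(cohort$trials[[pid]],
                       unname(cohort$models[names(cohort$models) != pid]),
                       space, features$directions[[eth]],
                       k_folds = config$k_folds,
                       seed = config$seed * 5000L + irow,
                       participant_id = pid)
    })
    cmp <- if (n_val >= 2L) compare_predictors(results) else NULL
    list(mean_tau = colMeans(do.call(rbind, lapply(results, function(r)
      colMeans(r$tau, na.rm = TRUE)))),
      comparison = if (!is.null(cmp)) cmp$tests else NULL,
      n_validated = n_val)
  })

  summary <- list(
    seed = config$seed,
    space = list(n_vertices = space$n_vertices,
                 n_shape_dims = space$n_shape_dims,
                 n_complexion_dims = space$n_complexion_dims,
                 n_sf_bands = space$n_sf_bands),
    cohort = list(n_participants = nrow(cohort$conditions),
                  n_per_condition = config$n_per_condition,
                  n_trials = config$n_trials, snr = config$snr),
    features = list(
      cosine_tests = features$cosine_tests,
      zscore = features$zscore,
      reduced_shape_dims =
        features$directions[[1]]$reduced_shape_dims,
      reduced_complexion_dims =
        features$directions[[1]]$reduced_complexion_dims),
    representation = repspace,
    validation = validation)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       force = TRUE)
  invisible(summary)
}
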