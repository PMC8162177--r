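test_that("robust regression recovers exact linear relations", {
  set.seed(1)
  n <- 60L
  rating <- rep(1:9, length.out = n)
  # noiseless: c_j = 0.2 + 0.5 * rating
  Y <- cbind(0.2 + 0.5 * rating,        # exact linear
             rep(3.7, n),               # constant dimension
             0.1 - 0.25 * rating)       # negative slope
  fit <- robust_simple_regression(Y, rating)
  expect_equal(fit$b1[1], 0.2, tolerance = 1e-6)
  expect_equal(fit$b2[1], 0.5, tolerance = 1e-6)
  expect_equal(fit$b2[2], 0, tolerance = 1e-12)
  expect_equal(fit$b1[2], 3.7, tolerance = 1e-12)
  expect_equal(fit$b2[3], -0.25, tolerance = 1e-6)
  # noiseless closed form: b2 = cov(y, x) / var(x) (OLS limit)
  expect_equal(fit$b2[1], cov(Y[, 1], rating) / var(rating),
               tolerance = 1e-10)
  expect_error(robust_simple_regression(Y, rep(5, n)), "constant")
})

test_that("bisquare IRLS matches the reference M-estimator on noisy data", {
  skip_if_not_installed("MASS")
  set.seed(2)
  n <- 400L
  x <- sample(1:9, n, replace = TRUE)
  for (i in 1:5) {
    y <- 1 + 0.3 * x + rnorm(n, sd = 0.5)
    y[sample(n, 20)] <- y[sample(n, 20)] + rnorm(20, sd = 8)  # outliers
    ours <- robust_simple_regression(cbind(y), x)
    ref <- MASS::rlm(y ~ x, psi = MASS::psi.bisquare, c = 4.685,
                     maxit = 100)
    expect_equal(ours$b2[1], unname(coef(ref)[2]), tolerance = 0.02)
    expect_equal(ours$b1[1], unname(coef(ref)[1]), tolerance = 0.05)
  }
})

test_that("preference model has the declared shapes and fails on degenerate input", {
  sp <- tiny_space()
  rr <- planted_rater(sp, seed = 21L, n_trials = 400L)
  m <- fit_preference_model(rr$trials, "p21", "Western-same")
  expect_s3_class(m, "preference_model")
  expect_length(m$shape_beta2, sp$n_shape_dims)
  expect_identical(dim(m$complexion_beta2),
                   c(sp$n_complexion_dims, sp$n_sf_bands))
  expect_true(all(is.finite(m$shape_beta2)))
  expect_identical(m$method, "robust_linear")

  few <- subset_trials(rr$trials, 1:5)
  expect_error(fit_preference_model(few), "at least 10")
  const <- rr$trials; const$rating <- rep(5L, 400L)
  expect_error(fit_preference_model(const), "identical")
})

test_that("reverse regression slope matches the covariance closed form", {
  sp <- tiny_space()
  rr <- planted_rater(sp, seed = 22L, n_trials = 600L, noise_sd = 0)
  tr <- rr$trials
  m <- fit_preference_model(tr)
  ols <- drop(cov(tr$shape, tr$rating)) / var(as.numeric(tr$rating))
  # robust and OLS agree closely on clean Gaussian data
  expect_gt(cor(m$shape_beta2, ols), 0.999)
})

test_that("BH mask equals the exhaustive oracle and the local model controls FDR", {
  set.seed(3)
  for (i in 1:50) {
    m <- sample(3:50, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- runif(1, 0.01, 0.2)
    expect_identical(bh_mask(p, q), bh_oracle(p, q))
  }

  sp <- tiny_space()
  # null rater: pure-noise ratings, FDR mask should fire (almost) nowhere
  fracs <- vapply(1:4, function(s) {
    st <- synthesize_stimuli(sp, 300L, seed = 30L + s)
    p0 <- participant_spec("null", rep(0, 6), matrix(0, 6, 3), noise_sd = 1,
                           seed = 40L + s)
    tr <- simulate_ratings(p0, st, sp)
    lmod <- fit_local_model(tr, sp, "WE_female", fdr_q = 0.05)
    mean(c(lmod$vertex_mask, lmod$pixel_mask))
  }, numeric(1))
  expect_lte(mean(fracs), 0.05)
})

test_that("local model shapes match the joint test families and detect planted signal", {
  sp <- tiny_space()
  rr <- planted_rater(sp, seed = 23L, n_trials = 800L, snr = 4)
  lmod <- fit_local_model(rr$trials, sp, "WE_female")
  expect_identical(dim(lmod$vertex_p), c(60L, 3L))
  expect_identical(dim(lmod$pixel_p), c(3L, 4L, 3L))   # 12x16 grid / 4
  expect_true(all(lmod$vertex_p >= 0 & lmod$vertex_p <= 1))
  # strong planted preference: the mask finds signal
  expect_gt(mean(lmod$vertex_mask), 0.2)
  # masks only where BH-adjusted p passes
  expect_identical(as.vector(lmod$vertex_mask),
                   bh_oracle(as.vector(lmod$vertex_p), 0.05))
})

test_that("linearity check reports near-linear centroids for a linear rater", {
  sp <- tiny_space()
  rr <- planted_rater(sp, seed = 24L, n_trials = 1950L, noise_sd = 1e-8)
  rep_ <- check_linearity(rr$trials, sp, "WE_female", seed = 5L)
  expect_identical(dim(rep_$distance_matrix), c(60L, 5L))
  expect_gte(rep_$k_selected, 1L)
  # bin means of a Gaussian drive under equal-count rating bins sit ~8.5%
  # off the endpoint chord even for a perfectly linear rater (the tails
  # stretch); with bin-mean sampling noise at n = 1950 the honest bound is
  # 20% of the centroid range, and centroids must stay monotone
  rel <- rep_$max_deviation_from_line / pmax(rep_$centroid_range, 1e-12)
  expect_lt(max(rel), 0.20)
  for (i in seq_len(nrow(rep_$cluster_centroids)))
    expect_true(all(diff(rep_$cluster_centroids[i, ]) > 0) ||
                  all(diff(rep_$cluster_centroids[i, ]) < 0))

  # all ratings collapsed into one bin is a named binning error
  one <- rr$trials; one$rating <- rep(9L, 1950L)
  expect_error(check_linearity(one, sp, "WE_female"), "empty.*bin")

  # identical distance rows (zero-preference space) give a single cluster
  cfg0 <- tiny_config(shape_scale = rep(0, 6),
                      complexion_scale = matrix(0, 6, 3))
  sp0 <- build_generative_space(cfg0, seed = 3L)
  st0 <- synthesize_stimuli(sp0, 200L, seed = 4L)
  p0 <- participant_spec("n", rep(0, 6), matrix(0, 6, 3), noise_sd = 1,
                         seed = 5L)
  tr0 <- simulate_ratings(p0, st0, sp0)
  rep0 <- check_linearity(tr0, sp0, "WE_female")
  expect_identical(rep0$k_selected, 1L)
})

test_that("signed MI model agrees with the linear model on a linear rater", {
  sp <- tiny_space()
  rr <- planted_rater(sp, seed = 25L, n_trials = 1500L)
  lin <- fit_preference_model(rr$trials)
  mi <- fit_mi_model(rr$trials)
  expect_identical(mi$method, "mi_signed")
  expect_true(all(mi$shape_beta1 == 0))
  v_lin <- c(lin$shape_beta2, as.vector(lin$complexion_beta2))
  v_mi <- c(mi$shape_beta2, as.vector(mi$complexion_beta2))
  expect_gte(cor(v_lin, v_mi, method = "spearman"), 0.95)

  # strictly monotone noiseless single dimension dominates all MI values
  n <- 800L
  shape <- matrix(rnorm(n * 6), n)
  cplx <- array(rnorm(n * 6 * 3), c(n, 6, 3))
  drive <- shape[, 2]
  rating <- as.integer(ceiling(rank(drive, ties.method = "min") * 9 / n))
  tr <- manual_trials(shape, cplx, rating)
  mi2 <- fit_mi_model(tr)
  expect_identical(which.max(abs(c(mi2$shape_beta2,
                                   as.vector(mi2$complexion_beta2)))), 2L)
  # and matches the dimension ranked top by |beta2|
  lin2 <- fit_preference_model(tr)
  expect_identical(which.max(abs(lin2$shape_beta2)), 2L)

  # an independent dimension stays below its 200-shuffle null
  x_ind <- rnorm(2000)
  y <- sample(1:9, 2000, replace = TRUE)
  obs <- gaussian_copula_mi(cbind(x_ind), y)
  null <- vapply(1:200, function(i)
    gaussian_copula_mi(cbind(sample(x_ind)), y), numeric(1))
  expect_lt(obs, quantile(null, 0.95))

  # plug-in histogram oracle ranks dependence the same way
  strong <- hist_mi_oracle(drive, rating)
  weak <- hist_mi_oracle(shape[, 1], rating)
  expect_gt(strong, weak)
})

test_that("model similarity is exact for identical models and calibrated under shuffles", {
  sp <- tiny_space()
  rr <- planted_rater(sp, seed = 26L, n_trials = 600L)
  m <- fit_preference_model(rr$trials)
  self <- compare_model_similarity(m, m, sp, n_perm = 100L, seed = 1L)
  expect_equal(self$shape$r, 1, tolerance = 1e-12)
  expect_true(self$shape$significant)
  expect_true(self$complexion$significant)

  # hand fixture: Spearman equals rank-Pearson computed from scratch
  m2 <- fit_mi_model(rr$trials)
  sim <- compare_model_similarity(m, m2, sp, n_perm = 100L, seed = 2L)
  a <- drop(sp$shape_basis %*% m$shape_beta2)
  b <- drop(sp$shape_basis %*% m2$shape_beta2)
  ra <- rank(a); rb <- rank(b)
  r_hand <- sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  expect_equal(sim$shape$r, r_hand, tolerance = 1e-10)

  short <- fit_preference_model(subset_trials(
    planted_rater(tiny_space(), 27L, n_trials = 100L)$trials, 1:100))
  mm <- short; mm$n_shape_dims <- 5L
  expect_error(compare_model_similarity(m, mm, sp), "mismatch")
})
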