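test_that("elbow selection matches brute-force chord geometry", {
  expect_identical(elbow_select(c(10, 5, 1, 0.9, 0.8, 0.7)), 3L)
  expect_identical(elbow_select(c(100, 1, 0.99, 0.98)), 2L)
  # exactly linear decay: all distances zero, tie-break to the first index
  expect_identical(elbow_select(seq(9, 1, length.out = 7)), 1L)
  expect_error(elbow_select(c(2, 1)), "at least 3")
  expect_error(elbow_select(c(3, 2, -1)), "positive")

  set.seed(4)
  for (i in 1:200) {
    v <- sort(rexp(sample(3:30, 1)) + 1e-3, decreasing = TRUE)
    expect_identical(elbow_select(v), as.integer(elbow_oracle(v)))
  }
})

test_that("model PCA spans, scores and reconstructs the models", {
  sp <- tiny_space()
  models <- lapply(1:8, function(s)
    fit_preference_model(planted_rater(sp, 200L + s,
                                       n_trials = 120L)$trials,
                         sprintf("p%d", s), if (s <= 4) "A" else "B"))
  asp <- build_attractiveness_space(models, sp, "shape")
  expect_true(all(diff(asp$var_explained) <= 1e-12))
  expect_lte(asp$n_kept, length(asp$eigenvalues))
  G <- crossprod(asp$loadings)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)

  # full projection reconstructs centered model vectors to 1e-8
  X <- t(sapply(models, function(m) drop(sp$shape_basis %*% m$shape_beta2)))
  Xc <- sweep(X, 2L, asp$center)
  recon <- (Xc %*% asp$loadings) %*% t(asp$loadings)
  expect_lt(max(abs(recon - Xc)), 1e-8)

  # duplicating every model rescales eigenvalues but keeps scores
  asp2 <- build_attractiveness_space(c(models, models), sp, "shape")
  r <- asp2$eigenvalues[1] / asp$eigenvalues[1]
  expect_equal(asp2$eigenvalues / r, asp$eigenvalues[seq_along(asp2$eigenvalues)],
               tolerance = 1e-6)
  expect_equal(abs(asp2$scores[1:8, 1]), abs(asp2$scores[9:16, 1]),
               tolerance = 1e-8)
  expect_error(build_attractiveness_space(models[1], sp, "shape"),
               "at least 2")
})

test_that("groups planted around distinct centroids separate in kept-score space", {
  sp <- tiny_space()
  ca <- random_preference(sp, seed = 301L)
  cb <- random_preference(sp, seed = 302L)
  models <- list(); labels <- character(0)
  for (i in 1:6) {
    ctr <- if (i <= 3) ca else cb
    rr <- planted_rater(sp, 310L + i, n_trials = 400L,
                        pref = random_preference(sp, 320L + i, center = ctr,
                                                 sd = 0.15))
    models[[i]] <- fit_preference_model(rr$trials, sprintf("m%d", i),
                                        if (i <= 3) "A" else "B")
    labels[i] <- if (i <= 3) "A" else "B"
  }
  asp <- build_attractiveness_space(models, sp, "shape", labels)
  sc <- asp$all_scores
  mu_a <- colMeans(sc[1:3, , drop = FALSE])
  mu_b <- colMeans(sc[4:6, , drop = FALSE])
  # margin check along the centroid axis: every model on its own side
  axis <- mu_b - mu_a
  proj <- drop(sc %*% axis)
  mid <- mean(c(max(proj[1:3]), min(proj[4:6])))
  expect_true(all(proj[1:3] < mid) && all(proj[4:6] > mid))
})

test_that("bootstrap refits reproduce exact fits and honor the seed", {
  # exact linear coefficient-rating relation: any resample refits identically
  set.seed(9)
  n <- 90L
  rating <- rep(1:9, each = 10L)
  shape <- outer(rating, c(0.1, -0.2, 0.3)) +
    matrix(rep(c(1, 2, 3), each = n), n)
  cplx <- array(outer(rating, rep(0.05, 4)), c(n, 2, 2))
  tr <- manual_trials(shape, cplx, rating)
  orig <- fit_preference_model(tr)
  boots <- bootstrap_models(tr, n_boot = 5L, seed = 2L)
  for (b in boots) {
    expect_equal(b$shape_beta2, orig$shape_beta2, tolerance = 1e-6)
    expect_equal(b$complexion_beta2, orig$complexion_beta2,
                 tolerance = 1e-6)
  }
  expect_identical(bootstrap_models(tr, 3L, seed = 5L),
                   bootstrap_models(tr, 3L, seed = 5L))

  # bootstrap spread shrinks roughly as 1/sqrt(n_trials)
  sp <- tiny_space()
  sd_at <- function(n_trials) {
    rr <- planted_rater(sp, 401L, n_trials = n_trials)
    bb <- bootstrap_models(rr$trials, n_boot = 12L, seed = 3L)
    mean(apply(sapply(bb, function(m) m$shape_beta2), 1L, sd))
  }
  ratio <- sd_at(500L) / sd_at(2000L)
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 2.9)
})

test_that("variance decomposition matches hand-computed SS terms", {
  # worked 8-model fixture: 2 groups x 2 participants x 2 bootstrap models
  scores <- matrix(c(2.0, 2.2, 1.6, 1.8, -1.0, -1.2, -0.6, -0.8,
                     0.5, 0.4, -0.3, -0.4, 0.2, 0.1, -0.1, -0.2),
                   ncol = 2)
  grp <- rep(c("G1", "G2"), each = 4)
  prt <- rep(c("a", "b", "c", "d"), each = 2)
  d <- decompose_variance(scores, grp, prt, var_weights = c(0.7, 0.3))

  # independent arithmetic, written out longhand
  for (k in 1:2) {
    s <- scores[, k]
    sstot <- sum(s * s)
    g1 <- mean(s[1:4]); g2 <- mean(s[5:8])
    r1 <- s - c(rep(g1, 4), rep(g2, 4))
    ss1 <- sum(r1 * r1)
    pmeans <- c(mean(r1[1:2]), mean(r1[3:4]), mean(r1[5:6]), mean(r1[7:8]))
    r2 <- r1 - rep(pmeans, each = 2)
    ss2 <- sum(r2 * r2)
    expect_equal(d$ss_total[k], sstot, tolerance = 1e-12)
    expect_equal(d$ss_resi1[k], ss1, tolerance = 1e-12)
    expect_equal(d$ss_resi2[k], ss2, tolerance = 1e-12)
    expect_equal(d$r2_group[k], 1 - ss1 / sstot, tolerance = 1e-12)
    expect_equal(d$r2_participant[k], ss1 / sstot * (1 - ss2 / ss1),
                 tolerance = 1e-12)
  }
  expect_equal(d$weighted_R2_group,
               0.7 * d$r2_group[1] + 0.3 * d$r2_group[2], tolerance = 1e-12)

  # identity: residual share + group share + participant share = 1
  set.seed(10)
  for (i in 1:20) {
    sc <- matrix(rnorm(48), ncol = 3)
    dd <- decompose_variance(sc, rep(c("A", "B"), each = 8),
                             rep(letters[1:8], each = 2))
    lhs <- dd$ss_resi1 / dd$ss_total * (dd$ss_resi2 / dd$ss_resi1) +
      dd$r2_group + dd$r2_participant
    expect_equal(lhs, rep(1, 3), tolerance = 1e-10)
  }

  # degenerate cases
  sc_eq <- matrix(rep(c(1, -1), each = 4), ncol = 1)
  de <- decompose_variance(sc_eq, rep(c("A", "B"), each = 4),
                           rep(c("a", "b", "c", "d"), each = 2))
  expect_equal(de$r2_group[1], 1, tolerance = 1e-12)
  expect_equal(de$r2_participant[1], 0, tolerance = 1e-12)

  # identical groups, stable distinct participants: participant share wins
  ps <- rep(c(3, -3, 1, -1), each = 2)
  sc_p <- matrix(c(ps, ps), ncol = 1)
  dp <- decompose_variance(sc_p, rep(c("A", "B"), each = 8),
                           rep(letters[1:8], each = 2))
  expect_lt(abs(dp$r2_group[1]), 1e-10)
  expect_gt(dp$r2_participant[1], 0.99)

  expect_error(decompose_variance(scores, rep("G", 8), prt), ">= 2 groups")
  expect_error(decompose_variance(scores, grp, rep(c("a", "c"), each = 4)),
               ">= 2 participants")
})

test_that("permutation thresholds use Bonferroni percentiles and block shuffles", {
  set.seed(11)
  sc8 <- matrix(rnorm(40 * 8), ncol = 8)
  grp <- rep(c("A", "B"), each = 20)
  prt <- rep(sprintf("p%02d", 1:10), each = 4)
  pt <- permutation_thresholds(sc8, grp, prt, "group", n_perm = 100L,
                               seed = 1L)
  expect_equal(pt$percentile, 99.375, tolerance = 1e-9)
  sc3 <- sc8[, 1:3]
  pt3 <- permutation_thresholds(sc3, grp, prt, "participant",
                                n_perm = 100L, seed = 2L)
  expect_equal(pt3$percentile, 100 - 5 / 3, tolerance = 1e-9)
  expect_lt(abs(pt3$percentile - 98.34), 0.01)

  bad_prt <- prt; bad_prt[1] <- "p06"   # participant in two groups
  expect_error(permutation_thresholds(sc8, grp, bad_prt, "group"),
               "block structure")
})

test_that("transfer/interactive sign rule matches hand evaluation", {
  cls <- sign_match_classes(own_other = c(1, -1, -1),
                            own_same = c(1, -1, 1),
                            other_same = c(-1, -1, 1))
  expect_identical(as.character(cls), c("transferred", "both", "neither"))
  expect_identical(as.character(sign_match_classes(0, 1, 1)), "neither")
  # own_other = own_same = -other_same: all transferred, none interactive
  v <- c(0.5, -2, 1.3)
  cls2 <- sign_match_classes(v, v, -v)
  expect_true(all(cls2 == "transferred"))

  sp <- tiny_space()
  ms <- lapply(1:3, function(s)
    fit_preference_model(planted_rater(sp, 500L + s,
                                       n_trials = 60L)$trials))
  tm <- classify_transfer_interactive(ms[[1]], ms[[2]], ms[[3]], sp)
  expect_length(tm$vertex_class, 180L)
  expect_false(anyNA(tm$vertex_class))
})

test_that("planted group/participant variance shares are recovered", {
  # plant known shares directly in score space: group effect + stable
  # participant effect + bootstrap sampling noise
  set.seed(14)
  npart <- 40L; nboot <- 20L
  sd_g <- 1.0; sd_p <- 0.8; sd_e <- 0.5
  geff <- rnorm(4, 0, sd_g)
  grp_of_part <- rep(1:4, each = npart / 4L)
  peff <- rnorm(npart, 0, sd_p)
  # center participant effects within group so planted group and
  # participant shares are exactly orthogonal
  peff <- peff - ave(peff, grp_of_part)
  rows <- rep(seq_len(npart), each = nboot)
  sc <- matrix(geff[grp_of_part][rows] + peff[rows] +
                 rnorm(npart * nboot, 0, sd_e), ncol = 1)
  d <- decompose_variance(sc, grp_of_part[rows],
                          sprintf("p%02d", rows))
  tot <- sum(sc^2) / length(sc)
  share_g <- sum((geff[grp_of_part][rows])^2) / length(sc) / tot
  share_p <- sum(peff[rows]^2) / length(sc) / tot
  expect_lt(abs(d$weighted_R2_group - share_g), 0.07)
  expect_lt(abs(d$weighted_R2_participant - share_p), 0.07)
})
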