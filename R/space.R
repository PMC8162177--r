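#' Configure a generative face space
#'
#' A generative face space expresses every stimulus as a categorical average
#' (one per ethnicity-by-sex cell, at a fixed age) plus an identity residual:
#' an orthonormal basis for 3D shape over the mesh vertices and one
#' orthonormal, band-limited basis per spatial-frequency (SF) band for the
#' L*a*b* complexion map. Coefficient scales play the role of the PCA
#' eigenvalue spectrum of a morphable model and decay as a power law.
#'
#' The default sizes are a desk scale (500 vertices, 40 shape dimensions,
#' 80x60 texture, 40 complexion dimensions over 5 SF bands) on which every
#' analysis in the package runs in seconds. The full-study scale of the
#' emulated database (4,735 vertices, 467 shape dimensions, 800x600 texture,
#' 467x5 complexion dimensions) is available through [paper_scale_config()]
#' for dimension bookkeeping via [space_dim_summary()].
#'
#' @param n_vertices number of 3D mesh vertices.
#' @param n_shape_dims number of identity shape dimensions
#'   (`<= 3 * n_vertices`).
#' @param texture_shape integer pair `c(width, height)` of the complexion map.
#' @param n_complexion_dims identity complexion dimensions per SF band
#'   (`<= 3 * width * height`).
#' @param n_sf_bands number of spatial-frequency octave bands.
#' @param ethnicities,sexes labels whose crossing defines the categorical
#'   cells.
#' @param age fixed age label carried as metadata.
#' @param shape_scale per-dimension sampling scale for shape coefficients;
#'   default 1 (coefficients expressed in units of each component's natural
#'   SD, the convention under which random faces are drawn with standard
#'   normal coefficients).
#' @param complexion_scale matrix `n_complexion_dims x n_sf_bands` of
#'   sampling scales; default 1.
#' @param shape_spectrum,complexion_spectrum decreasing positive eigenvalue
#'   curves of the emulated database PCA (`complexion_spectrum` has one
#'   column per band); default the power law `j^-1.2`. The spectra rank
#'   dimension importance for elbow-based reduced-dimension selection; they
#'   do not rescale stimulus sampling.
#' @return a `space_config` list.
#' @export
space_config <- function(n_vertices = 500L, n_shape_dims = 40L,
                         texture_shape = c(80L, 60L),
                         n_complexion_dims = 40L, n_sf_bands = 5L,
                         ethnicities = c("WE", "EA"),
                         sexes = c("female", "male"),
                         age = 25L,
                         shape_scale = NULL, complexion_scale = NULL,
                         shape_spectrum = NULL, complexion_spectrum = NULL) {
  dims <- c(n_vertices, n_shape_dims, texture_shape, n_complexion_dims,
            n_sf_bands)
  if (!all(is.finite(dims)) || any(dims < 1))
    stop_invalid("all space dimensions must be positive finite integers")
  n_vertices <- as.integer(n_vertices)
  n_shape_dims <- as.integer(n_shape_dims)
  texture_shape <- as.integer(texture_shape)
  n_complexion_dims <- as.integer(n_complexion_dims)
  n_sf_bands <- as.integer(n_sf_bands)
  if (n_shape_dims > 3L * n_vertices)
    stop_invalid("n_shape_dims (%d) exceeds ambient shape dimension (%d)",
                 n_shape_dims, 3L * n_vertices)
  grid3 <- 3L * prod(texture_shape)
  if (n_complexion_dims > grid3)
    stop_invalid("n_complexion_dims (%d) exceeds ambient pixel dimension (%d)",
                 n_complexion_dims, grid3)
  if (is.null(shape_scale))
    shape_scale <- rep(1, n_shape_dims)
  if (is.null(complexion_scale))
    complexion_scale <- matrix(1, n_complexion_dims, n_sf_bands)
  complexion_scale <- as.matrix(complexion_scale)
  if (is.null(shape_spectrum))
    shape_spectrum <- seq_len(n_shape_dims)^-1.2
  if (is.null(complexion_spectrum))
    complexion_spectrum <- matrix(seq_len(n_complexion_dims)^-1.2,
                                  n_complexion_dims, n_sf_bands)
  complexion_spectrum <- as.matrix(complexion_spectrum)
  if (length(shape_spectrum) != n_shape_dims ||
      !identical(dim(complexion_spectrum),
                 c(n_complexion_dims, n_sf_bands)) ||
      any(shape_spectrum <= 0) || any(complexion_spectrum <= 0) ||
      is.unsorted(rev(shape_spectrum)))
    stop_invalid("spectra must be positive nonincreasing curves matching the dimensions")
  if (length(shape_scale) != n_shape_dims ||
      !identical(dim(complexion_scale),
                 c(n_complexion_dims, n_sf_bands)))
    stop_invalid("coefficient scale sizes do not match the requested dimensions")
  if (!all(is.finite(shape_scale)) || !all(is.finite(complexion_scale)) ||
      any(shape_scale < 0) || any(complexion_scale < 0))
    stop_invalid("coefficient scales must be finite and nonnegative")
  structure(list(
    n_vertices = n_vertices, n_shape_dims = n_shape_dims,
    texture_shape = texture_shape,
    n_complexion_dims = n_complexion_dims, n_sf_bands = n_sf_bands,
    ethnicities = ethnicities, sexes = sexes, age = age,
    shape_scale = as.numeric(shape_scale),
    complexion_scale = complexion_scale,
    shape_spectrum = as.numeric(shape_spectrum),
    complexion_spectrum = complexion_spectrum
  ), class = "space_config")
}

#' Full-study-scale configuration of the emulated face database
#'
#' @return a `space_config` at the scale of the emulated 3D face database:
#'   4,735 vertices, 467 shape dimensions, 800x600 texture and 467 complexion
#'   dimensions in each of 5 SF bands.
#' @export
paper_scale_config <- function() {
  space_config(n_vertices = 4735L, n_shape_dims = 467L,
               texture_shape = c(800L, 600L),
               n_complexion_dims = 467L, n_sf_bands = 5L)
}

#' Array shapes implied by a space configuration
#'
#' Reports, without allocating anything, the shapes of the arrays a built
#' space would contain, plus the joint test-family sizes used by the local
#' (vertex/pixel) models.
#'
#' @param config a [space_config()].
#' @return list of dimension vectors.
#' @export
space_dim_summary <- function(config) {
  stopifnot(inherits(config, "space_config"))
  w <- config$texture_shape[1]; h <- config$texture_shape[2]
  list(
    shape_basis = c(3L * config$n_vertices, config$n_shape_dims),
    complexion_basis = c(3L * w * h, config$n_complexion_dims),
    n_complexion_bases = config$n_sf_bands,
    average_mesh = c(config$n_vertices, 3L),
    average_texture = c(h, w, 3L),
    vertex_test_family = 3L * config$n_vertices,
    pixel_test_family = 3L * (w %/% 4L) * (h %/% 4L)
  )
}

# smooth scalar field over 3D points: low-order polynomial harmonics with
# seeded coefficients (deterministic given the active RNG stream)
smooth_field3d <- function(pts, amplitude = 1) {
  basis <- cbind(1, pts, pts^2, pts[, 1] * pts[, 2], pts[, 1] * pts[, 3],
                 pts[, 2] * pts[, 3])
  drop(basis %*% rnorm(ncol(basis), sd = amplitude / sqrt(ncol(basis))))
}

# smooth 2D field: a few low-frequency cosines over the texture grid
smooth_field2d <- function(h, w, amplitude = 1, n_terms = 6L) {
  yy <- matrix(seq(0, 1, length.out = h), h, w)
  xx <- matrix(seq(0, 1, length.out = w), h, w, byrow = TRUE)
  f <- matrix(0, h, w)
  for (k in seq_len(n_terms)) {
    fx <- sample(0:2, 1); fy <- sample(0:2, 1)
    ph <- runif(2, 0, 2 * pi)
    f <- f + rnorm(1, sd = amplitude / sqrt(n_terms)) *
      cos(2 * pi * fx * xx + ph[1]) * cos(2 * pi * fy * yy + ph[2])
  }
  f
}

# quasi-uniform points on a head-like ellipsoid (Fibonacci sphere)
base_mesh <- function(n_vertices) {
  i <- seq_len(n_vertices) - 0.5
  phi <- acos(1 - 2 * i / n_vertices)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = 0.8 * sin(phi) * cos(theta),
        y = 1.0 * sin(phi) * sin(theta),
        z = 0.9 * cos(phi))
}

# octave edges (radial cycles per image); band 1 = lowest SF, includes DC
band_edges <- function(h, w, n_bands) {
  fmax <- sqrt((h / 2)^2 + (w / 2)^2)
  hi <- fmax / 2^(n_bands - seq_len(n_bands))
  lo <- c(0, hi[-n_bands])
  cbind(lo = lo, hi = hi)
}

# radial-frequency map (cycles per image) of an h x w FFT grid
radial_freq <- function(h, w) {
  fy <- pmin(seq_len(h) - 1L, h - (seq_len(h) - 1L))
  fx <- pmin(seq_len(w) - 1L, w - (seq_len(w) - 1L))
  sqrt(outer(fy^2, fx^2, `+`))
}

# band-pass a real h x w image to the annulus (lo, hi]
band_pass <- function(img, lo, hi, rf = radial_freq(nrow(img), ncol(img))) {
  keep <- (rf > lo | (lo == 0 & rf == 0)) & rf <= hi
  Re(fft(fft(img) * keep, inverse = TRUE)) / length(img)
}

#' Build a synthetic generative face space
#'
#' Constructs the categorical average mesh and texture of every
#' ethnicity-by-sex cell and the orthonormal identity bases. Averages differ
#' between cells by smooth seeded deformations (shape) and tints plus smooth
#' fields (complexion). The shape basis is a column-orthonormalized Gaussian
#' matrix; each complexion band basis is built from band-pass-filtered random
#' textures and is therefore band-limited to its stated octave.
#'
#' @param config a [space_config()].
#' @param seed integer seed; identical `(config, seed)` give identical spaces.
#' @return a `generative_space` object: the config plus `cells` (named list
#'   with `mesh` `n_vertices x 3` and `texture` `h x w x 3` L*a*b* arrays),
#'   `shape_basis` (`3V x n_shape_dims`, orthonormal columns),
#'   `complexion_basis` (list of `3hw x n_complexion_dims` per band),
#'   `band_edges` (radial cycles-per-image octaves), and the seed.
#' @export
build_generative_space <- function(config = space_config(), seed = 1L) {
  stopifnot(inherits(config, "space_config"))
  with_seed(seed, {
    V <- config$n_vertices
    w <- config$texture_shape[1]; h <- config$texture_shape[2]
    base <- base_mesh(V)
    base_tex <- array(0, c(h, w, 3))
    base_tex[, , 1] <- 62 + 4 * smooth_field2d(h, w)
    base_tex[, , 2] <- 14 + 2 * smooth_field2d(h, w)
    base_tex[, , 3] <- 18 + 3 * smooth_field2d(h, w)

    cells <- list()
    for (eth in config$ethnicities) for (sx in config$sexes) {
      mesh <- base
      for (k in 1:3) mesh[, k] <- mesh[, k] + 0.08 * smooth_field3d(base)
      tex <- base_tex
      tint <- rnorm(3, sd = c(3, 1.5, 2.5))
      for (ch in 1:3)
        tex[, , ch] <- tex[, , ch] + tint[ch] + 1.5 * smooth_field2d(h, w)
      cells[[paste(eth, sx, sep = "_")]] <-
        list(ethnicity = eth, sex = sx, mesh = mesh, texture = tex)
    }

    shape_basis <- orthonormalize(
      matrix(rnorm(3L * V * config$n_shape_dims), 3L * V))

    edges <- band_edges(h, w, config$n_sf_bands)
    rf <- radial_freq(h, w)
    complexion_basis <- vector("list", config$n_sf_bands)
    for (b in seq_len(config$n_sf_bands)) {
      cols <- matrix(0, 3L * h * w, config$n_complexion_dims)
      for (j in seq_len(config$n_complexion_dims)) {
        chans <- vapply(1:3, function(ch)
          as.vector(band_pass(matrix(rnorm(h * w), h, w),
                              edges[b, 1], edges[b, 2], rf)),
          numeric(h * w))
        cols[, j] <- as.vector(chans)
      }
      complexion_basis[[b]] <- orthonormalize(cols)
    }

    structure(c(unclass(config), list(
      cells = cells, shape_basis = shape_basis,
      complexion_basis = complexion_basis, band_edges = edges,
      seed = as.integer(seed)
    )), class = "generative_space")
  })
}

#' @export
print.generative_space <- function(x, ...) {
  cat(sprintf(
    "Generative face space: %d vertices, %d shape dims, %dx%d texture,\n  %d complexion dims x %d SF bands; cells: %s (age %s); seed %d\n",
    x$n_vertices, x$n_shape_dims, x$texture_shape[1], x$texture_shape[2],
    x$n_complexion_dims, x$n_sf_bands,
    paste(names(x$cells), collapse = ", "), x$age, x$seed))
  invisible(x)
}

get_cell <- function(space, cell) {
  if (!cell %in% names(space$cells))
    stop_invalid("unknown cell '%s'; available: %s", cell,
                 paste(names(space$cells), collapse = ", "))
  space$cells[[cell]]
}

#' Synthesize random identity residuals (stimuli)
#'
#' Draws independent zero-mean Gaussian coefficients per identity dimension
#' with the space's per-dimension scales, and cycles viewpoints evenly over
#' -30, 0, +30 degrees. Coefficients are stored cell-free, so the same
#' residual set can be rendered against any categorical average.
#'
#' @param space a `generative_space`.
#' @param n_trials number of stimuli (>= 1).
#' @param seed integer seed.
#' @return a `face_trials` object: `shape` (`n x n_shape_dims`), `complexion`
#'   (`n x n_complexion_dims x n_sf_bands`), `viewpoint`, `trial_id`,
#'   `rating` (NA until rated).
#' @export
synthesize_stimuli <- function(space, n_trials, seed = 1L) {
  stopifnot(inherits(space, "generative_space"))
  if (!is.numeric(n_trials) || n_trials < 1)
    stop_invalid("n_trials must be >= 1")
  n <- as.integer(n_trials)
  with_seed(seed, {
    shape <- matrix(rnorm(n * space$n_shape_dims), n) *
      rep(space$shape_scale, each = n)
    complexion <- array(rnorm(n * space$n_complexion_dims * space$n_sf_bands),
                        c(n, space$n_complexion_dims, space$n_sf_bands))
    for (b in seq_len(space$n_sf_bands))
      complexion[, , b] <- complexion[, , b] *
        rep(space$complexion_scale[, b], each = n)
    structure(list(
      trial_id = seq_len(n),
      viewpoint = rep_len(c(-30, 0, 30), n),
      rating = rep(NA_integer_, n),
      shape = shape, complexion = complexion,
      n_shape_dims = space$n_shape_dims,
      n_complexion_dims = space$n_complexion_dims,
      n_sf_bands = space$n_sf_bands
    ), class = "face_trials")
  })
}

#' @export
print.face_trials <- function(x, ...) {
  cat(sprintf(
    "face_trials: %d trials, %d shape dims, %d complexion dims x %d bands; ratings %s\n",
    length(x$trial_id), x$n_shape_dims, x$n_complexion_dims, x$n_sf_bands,
    if (all(is.na(x$rating))) "absent" else "present"))
  invisible(x)
}

n_trials_of <- function(trials) length(trials$trial_id)

#' Subset a trial set by index
#'
#' @param trials a `face_trials`.
#' @param idx integer or logical trial index.
#' @return the subsetted `face_trials`.
#' @export
subset_trials <- function(trials, idx) {
  out <- trials
  out$trial_id <- trials$trial_id[idx]
  out$viewpoint <- trials$viewpoint[idx]
  out$rating <- trials$rating[idx]
  out$shape <- trials$shape[idx, , drop = FALSE]
  out$complexion <- trials$complexion[idx, , , drop = FALSE]
  out
}

# flatten complexion coefficients to n x (dims * bands), band-major blocks
flatten_complexion <- function(complexion) {
  d <- dim(complexion)
  matrix(complexion, d[1], d[2] * d[3])
}

#' Render one stimulus against a categorical cell
#'
#' The rendering is affine in the coefficients: mesh = cell average +
#' shape_basis %*% shape_coeffs (reshaped to vertices x 3); texture = cell
#' average + the per-band complexion bases applied to each band's
#' coefficients.
#'
#' @param space a `generative_space`.
#' @param trial either a `face_trials` row (see `trial_record()`) or a list
#'   with `shape_coeffs` and `complexion_coeffs`.
#' @param cell cell label, e.g. `"WE_female"`.
#' @return list with `mesh` (`n_vertices x 3`) and `texture` (`h x w x 3`
#'   L*a*b*).
#' @export
render_stimulus <- function(space, trial, cell) {
  stopifnot(inherits(space, "generative_space"))
  cc <- get_cell(space, cell)
  sc <- trial$shape_coeffs
  xc <- trial$complexion_coeffs
  check_finite(sc, "shape coefficients"); check_finite(xc, "complexion coefficients")
  mesh <- cc$mesh + matrix(space$shape_basis %*% sc, space$n_vertices, 3)
  w <- space$texture_shape[1]; h <- space$texture_shape[2]
  tex_vec <- as.vector(cc$texture)
  for (b in seq_len(space$n_sf_bands))
    tex_vec <- tex_vec + drop(space$complexion_basis[[b]] %*% xc[, b])
  list(mesh = mesh, texture = array(tex_vec, c(h, w, 3)))
}

#' Extract one trial's coefficient record
#'
#' @param trials a `face_trials`.
#' @param i trial index.
#' @return list with `trial_id`, `viewpoint`, `rating`, `shape_coeffs`,
#'   `complexion_coeffs`.
#' @export
trial_record <- function(trials, i) {
  stopifnot(inherits(trials, "face_trials"), i >= 1, i <= n_trials_of(trials))
  list(trial_id = trials$trial_id[i], viewpoint = trials$viewpoint[i],
       rating = trials$rating[i],
       shape_coeffs = trials$shape[i, ],
       complexion_coeffs = matrix(trials$complexion[i, , ],
                                  trials$n_complexion_dims,
                                  trials$n_sf_bands))
}

# render all trials at vertex granularity: n x 3V matrix (cell optional:
# without it, pure residual deviations from the origin)
render_vertices <- function(space, trials, cell = NULL) {
  dev <- trials$shape %*% t(space$shape_basis)
  if (!is.null(cell))
    dev <- sweep(dev, 2L, as.vector(get_cell(space, cell)$mesh), `+`)
  dev
}

# block-mean downsampling operator applied to pixel-space basis columns /
# vectors; input length 3hw, output length 3*(h/f)*(w/f)
downsample_pixels <- function(vec_or_mat, h, w, factor = 4L) {
  m <- as.matrix(vec_or_mat)
  h2 <- h %/% factor; w2 <- w %/% factor
  out <- matrix(0, 3L * h2 * w2, ncol(m))
  for (j in seq_len(ncol(m))) {
    a <- array(m[, j], c(h, w, 3))
    a <- a[seq_len(h2 * factor), seq_len(w2 * factor), , drop = FALSE]
    d <- array(0, c(h2, w2, 3))
    for (ch in 1:3) {
      x <- a[, , ch]
      x <- rowsum(x, rep(seq_len(h2), each = factor)) / factor
      x <- t(rowsum(t(x), rep(seq_len(w2), each = factor)) / factor)
      d[, , ch] <- x
    }
    out[, j] <- as.vector(d)
  }
  out
}

# down-sampled pixel deviations for all trials: n x (3 * h/4 * w/4)
render_pixels_down <- function(space, trials, cell = NULL, factor = 4L) {
  h <- space$texture_shape[2]; w <- space$texture_shape[1]
  n <- n_trials_of(trials)
  acc <- NULL
  for (b in seq_len(space$n_sf_bands)) {
    db <- downsample_pixels(space$complexion_basis[[b]], h, w, factor)
    contrib <- trials$complexion[, , b, drop = FALSE]
    dim(contrib) <- c(n, space$n_complexion_dims)
    acc <- if (is.null(acc)) contrib %*% t(db) else acc + contrib %*% t(db)
  }
  if (!is.null(cell)) {
    avg <- downsample_pixels(as.vector(get_cell(space, cell)$texture),
                             h, w, factor)
    acc <- sweep(acc, 2L, drop(avg), `+`)
  }
  acc
}

#' Specify a simulated rater
#'
#' A simulated rater carries a planted linear preference: the rating drive of
#' a stimulus is the inner product of the preference with the stimulus
#' coefficients plus Gaussian noise.
#'
#' @param participant_id character id.
#' @param true_shape_pref numeric vector, length `n_shape_dims`.
#' @param true_complexion_pref numeric matrix
#'   `n_complexion_dims x n_sf_bands`.
#' @param noise_sd nonnegative Gaussian noise SD on the drive.
#' @param culture,face_ethnicity condition labels.
#' @param seed integer seed used when simulating this rater's ratings.
#' @return a `participant_spec`.
#' @export
participant_spec <- function(participant_id, true_shape_pref,
                             true_complexion_pref, noise_sd = 0,
                             culture = "WE", face_ethnicity = "WE",
                             seed = 1L) {
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  check_finite(true_shape_pref, "true_shape_pref")
  check_finite(true_complexion_pref, "true_complexion_pref")
  structure(list(participant_id = as.character(participant_id),
                 culture = culture, face_ethnicity = face_ethnicity,
                 true_shape_pref = as.numeric(true_shape_pref),
                 true_complexion_pref = as.matrix(true_complexion_pref),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "participant_spec")
}

# the planted preference concatenated in fitting order (shape, then bands)
true_pref_vector <- function(participant) {
  c(participant$true_shape_pref, as.vector(participant$true_complexion_pref))
}

# SD of the noiseless drive under the space's sampling scales
drive_sd <- function(space, participant) {
  sqrt(sum((participant$true_shape_pref * space$shape_scale)^2) +
         sum((participant$true_complexion_pref * space$complexion_scale)^2))
}

#' Noise level giving a target drive signal-to-noise ratio
#'
#' @param space a `generative_space`.
#' @param participant a [participant_spec()].
#' @param snr target ratio of drive SD to noise SD.
#' @return noise SD such that `drive_sd / noise_sd = snr`.
#' @export
noise_sd_for_snr <- function(space, participant, snr = 2) {
  stopifnot(snr > 0)
  drive_sd(space, participant) / snr
}

#' Simulate a rater's attractiveness ratings
#'
#' Computes each stimulus's drive (planted preference inner product plus
#' Gaussian noise) and maps the drives monotonically onto the 9-point rating
#' scale by empirical quantiles into 9 equal-count bins. Tied drives share a
#' bin (ranking with `ties.method = "min"`), so a constant drive produces a
#' single rating level.
#'
#' @param participant a [participant_spec()].
#' @param stimuli a nonempty `face_trials`.
#' @param space the `generative_space` the stimuli were drawn from.
#' @return the `face_trials` with integer ratings in 1..9 filled in; the
#'   noiseless and noisy drives are attached as attributes `"drive"` and
#'   `"noisy_drive"`.
#' @export
simulate_ratings <- function(participant, stimuli, space) {
  stopifnot(inherits(participant, "participant_spec"),
            inherits(stimuli, "face_trials"))
  n <- n_trials_of(stimuli)
  if (n == 0L) stop_invalid("empty stimulus list")
  drive <- drop(stimuli$shape %*% participant$true_shape_pref) +
    drop(flatten_complexion(stimuli$complexion) %*%
           as.vector(participant$true_complexion_pref))
  noisy <- with_seed(participant$seed,
                     drive + rnorm(n, sd = participant$noise_sd))
  r <- rank(noisy, ties.method = "min")
  stimuli$rating <- as.integer(ceiling(r * 9 / n))
  attr(stimuli, "drive") <- drive
  attr(stimuli, "noisy_drive") <- noisy
  stimuli
}

#' Draw a random planted preference aligned with the space's spectrum
#'
#' Convenience generator for synthetic cohorts: a unit-norm preference with
#' independent Gaussian entries, optionally concentrated on the
#' leading (high-variance) dimensions so that fitted models have realistic
#' low-dimensional structure.
#'
#' @param space a `generative_space`.
#' @param seed integer seed.
#' @param concentrate exponent: entry SD proportional to
#'   `sqrt(spectrum)^concentrate` per dimension, concentrating the
#'   preference on leading (high-eigenvalue) dimensions (0 = isotropic).
#' @param center optional `participant_spec`-style list with
#'   `true_shape_pref`/`true_complexion_pref` around which to draw; `sd`
#'   scales the dispersion around it.
#' @param sd dispersion around `center` (ignored without a center, where the
#'   draw is unit-normalized).
#' @return list with `true_shape_pref` and `true_complexion_pref`.
#' @export
random_preference <- function(space, seed = 1L, concentrate = 1,
                              center = NULL, sd = 0.3) {
  with_seed(seed, {
    s <- rnorm(space$n_shape_dims) *
      sqrt(space$shape_spectrum)^concentrate
    cm <- matrix(rnorm(space$n_complexion_dims * space$n_sf_bands),
                 space$n_complexion_dims) *
      sqrt(space$complexion_spectrum)^concentrate
    nrm <- sqrt(sum(s^2) + sum(cm^2))
    s <- s / nrm; cm <- cm / nrm
    if (!is.null(center)) {
      s <- center$true_shape_pref + sd * s
      cm <- center$true_complexion_pref + sd * cm
    }
    list(true_shape_pref = s, true_complexion_pref = cm)
  })
}
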