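#' Write a trial table to CSV
#'
#' Columns: `trial_id`, `viewpoint`, `rating`, shape coefficients
#' `s0..s{n-1}`, complexion coefficients `c{band}_{dim}` (0-based dims).
#' Missing ratings are written as empty fields.
#'
#' @param trials a `face_trials`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  stopifnot(inherits(trials, "face_trials"))
  ds <- trials$n_shape_dims; dc <- trials$n_complexion_dims
  B <- trials$n_sf_bands
  cn <- c(paste0("s", seq_len(ds) - 1L),
          unlist(lapply(seq_len(B), function(b)
            paste0("c", b, "_", seq_len(dc) - 1L))))
  df <- data.frame(trial_id = trials$trial_id, viewpoint = trials$viewpoint,
                   rating = trials$rating)
  co <- cbind(trials$shape, flatten_complexion(trials$complexion))
  colnames(co) <- cn
  data.table::fwrite(cbind(df, co), path)
  invisible(path)
}

#' Read a trial table from CSV
#'
#' @param path CSV path written by [write_trials()] (the `rating` column may
#'   be absent).
#' @return a `face_trials`; ratings are validated as integers in 1..9 (or
#'   NA), with a row-numbered error otherwise.
#' @export
read_trials <- function(path) {
  dt <- data.table::fread(path, data.table = FALSE)
  need <- c("trial_id", "viewpoint")
  if (!all(need %in% names(dt)))
    stop_invalid("malformed trial table: missing column(s) %s",
                 paste(setdiff(need, names(dt)), collapse = ", "))
  scols <- grep("^s[0-9]+$", names(dt), value = TRUE)
  ccols <- grep("^c[0-9]+_[0-9]+$", names(dt), value = TRUE)
  if (length(scols) == 0L || length(ccols) == 0L)
    stop_invalid("malformed trial table: no coefficient columns found")
  scols <- scols[order(as.integer(sub("s", "", scols)))]
  bands <- as.integer(sub("^c([0-9]+)_.*$", "\\1", ccols))
  dims <- as.integer(sub("^c[0-9]+_([0-9]+)$", "\\1", ccols))
  B <- max(bands); dc <- max(dims) + 1L
  if (length(ccols) != B * dc)
    stop_invalid("malformed trial table: ragged complexion columns")
  n <- nrow(dt)
  rating <- if ("rating" %in% names(dt)) dt$rating else rep(NA, n)
  rating <- suppressWarnings(as.numeric(rating))
  bad <- which(!is.na(rating) &
                 (rating != round(rating) | rating < 1 | rating > 9))
  if (length(bad))
    stop_invalid("invalid rating at row(s) %s: must be an integer in 1..9",
                 paste(utils::head(bad, 5L), collapse = ", "))
  cplx <- array(0, c(n, dc, B))
  for (b in seq_len(B)) {
    cols <- paste0("c", b, "_", seq_len(dc) - 1L)
    cplx[, , b] <- as.matrix(dt[, cols])
  }
  structure(list(trial_id = as.integer(dt$trial_id),
                 viewpoint = as.numeric(dt$viewpoint),
                 rating = as.integer(rating),
                 shape = unname(as.matrix(dt[, scols])), complexion = cplx,
                 n_shape_dims = length(scols), n_complexion_dims = dc,
                 n_sf_bands = B),
            class = "face_trials")
}

# ---- numeric array CSV helpers (headerless, lossless via %.17g) ----

write_array_csv <- function(m, path) {
  data.table::fwrite(as.data.frame(as.matrix(m)), path, col.names = FALSE)
  invisible(path)
}

read_array_csv <- function(path) {
  unname(as.matrix(data.table::fread(path, header = FALSE,
                                     data.table = FALSE)))
}

#' Convert an L*a*b* array to sRGB (D65)
#'
#' Standard CIE L*a*b* -> XYZ (D65 white) -> linear RGB -> sRGB gamma,
#' clipped to \[0, 1\]. Used only for PNG previews; the numeric L*a*b*
#' arrays remain authoritative.
#'
#' @param lab array `h x w x 3` (L*, a*, b*).
#' @return array `h x w x 3` of sRGB in \[0, 1\].
#' @export
lab_to_srgb <- function(lab) {
  L <- lab[, , 1]; a <- lab[, , 2]; b <- lab[, , 3]
  fy <- (L + 16) / 116
  fx <- fy + a / 500
  fz <- fy - b / 200
  finv <- function(t) ifelse(t^3 > 0.008856, t^3, (t - 16 / 116) / 7.787)
  wp <- c(0.95047, 1, 1.08883)
  X <- wp[1] * finv(fx); Y <- wp[2] * finv(fy); Z <- wp[3] * finv(fz)
  R <- 3.2406 * X - 1.5372 * Y - 0.4986 * Z
  G <- -0.9689 * X + 1.8758 * Y + 0.0415 * Z
  B <- 0.0557 * X - 0.2040 * Y + 1.0570 * Z
  gam <- function(u) ifelse(u <= 0.0031308, 12.92 * u,
                            1.055 * pmax(u, 0)^(1 / 2.4) - 0.055)
  out <- array(0, dim(lab))
  out[, , 1] <- gam(R); out[, , 2] <- gam(G); out[, , 3] <- gam(B)
  pmin(pmax(out, 0), 1)
}

#' Write a mesh as a Wavefront OBJ
#'
#' Vertex positions only (point-cloud OBJ); an optional per-vertex scalar is
#' written as a CSV sidecar.
#'
#' @param mesh `n_vertices x 3` matrix.
#' @param path output `.obj` path.
#' @param vertex_scalar optional numeric vector of per-vertex values.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path, vertex_scalar = NULL) {
  lines <- sprintf("v %.8f %.8f %.8f", mesh[, 1], mesh[, 2], mesh[, 3])
  writeLines(c("# prefcorr3d mesh", lines), path)
  if (!is.null(vertex_scalar))
    data.table::fwrite(data.frame(vertex = seq_len(nrow(mesh)),
                                  value = vertex_scalar),
                       sub("\\.obj$", "_scalar.csv", path))
  invisible(path)
}

#' Serialize a generative space to a directory bundle
#'
#' Writes `manifest.json` (dimensions, cells, seed, scales, band edges),
#' headerless CSV arrays for the bases and cell averages, plus per-cell
#' preview OBJ meshes and sRGB PNG textures.
#'
#' @param space a `generative_space`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_space <- function(space, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    n_vertices = space$n_vertices, n_shape_dims = space$n_shape_dims,
    texture_shape = space$texture_shape,
    n_complexion_dims = space$n_complexion_dims,
    n_sf_bands = space$n_sf_bands, ethnicities = space$ethnicities,
    sexes = space$sexes, age = space$age, seed = space$seed,
    shape_scale = space$shape_scale,
    complexion_scale = space$complexion_scale,
    shape_spectrum = space$shape_spectrum,
    complexion_spectrum = space$complexion_spectrum,
    band_edges = space$band_edges, cells = names(space$cells))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  write_array_csv(space$shape_basis, file.path(dir, "shape_basis.csv"))
  for (b in seq_len(space$n_sf_bands))
    write_array_csv(space$complexion_basis[[b]],
                    file.path(dir, sprintf("complexion_basis_band%d.csv", b)))
  h <- space$texture_shape[2]; w <- space$texture_shape[1]
  for (nm in names(space$cells)) {
    cc <- space$cells[[nm]]
    write_array_csv(cc$mesh, file.path(dir, paste0(nm, "_mesh.csv")))
    write_array_csv(matrix(cc$texture, h, 3L * w),
                    file.path(dir, paste0(nm, "_texture.csv")))
    write_obj(cc$mesh, file.path(dir, paste0(nm, "_mesh.obj")))
    png::writePNG(lab_to_srgb(cc$texture),
                  file.path(dir, paste0(nm, "_texture.png")))
  }
  invisible(dir)
}

#' Read a generative space bundle
#'
#' @param dir directory written by [write_space()].
#' @return a `generative_space`.
#' @export
read_space <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  h <- manifest$texture_shape[2]; w <- manifest$texture_shape[1]
  cells <- list()
  for (nm in manifest$cells) {
    parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
    cells[[nm]] <- list(
      ethnicity = parts[1], sex = parts[2],
      mesh = read_array_csv(file.path(dir, paste0(nm, "_mesh.csv"))),
      texture = array(read_array_csv(file.path(dir,
                                               paste0(nm, "_texture.csv"))),
                      c(h, w, 3)))
  }
  structure(list(
    n_vertices = manifest$n_vertices, n_shape_dims = manifest$n_shape_dims,
    texture_shape = manifest$texture_shape,
    n_complexion_dims = manifest$n_complexion_dims,
    n_sf_bands = manifest$n_sf_bands, ethnicities = manifest$ethnicities,
    sexes = manifest$sexes, age = manifest$age,
    shape_scale = manifest$shape_scale,
    complexion_scale = as.matrix(manifest$complexion_scale),
    shape_spectrum = manifest$shape_spectrum,
    complexion_spectrum = as.matrix(manifest$complexion_spectrum),
    cells = cells,
    shape_basis = read_array_csv(file.path(dir, "shape_basis.csv")),
    complexion_basis = lapply(seq_len(manifest$n_sf_bands), function(b)
      read_array_csv(file.path(dir,
                               sprintf("complexion_basis_band%d.csv", b)))),
    band_edges = as.matrix(manifest$band_edges), seed = manifest$seed
  ), class = "generative_space")
}

#' Write a preference model as JSON
#'
#' @param model a `preference_model`.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a preference model written by [write_model()]
#'
#' @param path JSON path.
#' @return a `preference_model`.
#' @export
read_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("complexion_beta1", "complexion_beta2", "complexion_p"))
    if (!is.null(m[[f]])) {
      v <- m[[f]]
      if (!is.matrix(v))
        v <- matrix(unlist(v), m$n_complexion_dims, m$n_sf_bands)
      m[[f]] <- v
    }
  structure(m, class = "preference_model")
}
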