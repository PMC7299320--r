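#' Default class-conditional lesion texture parameters
#'
#' The phantom models lesion texture as a stationary correlated Gaussian
#' random field (smoothed white noise) added inside the lesion, with
#' separate parameters per class (FISH-positive / FISH-negative) for the
#' pre-contrast field and for the contrast-uptake field. The uptake field
#' enters both the post-contrast image and (after subtraction) the
#' subtraction image, so a class difference placed there produces the
#' strongest separation on subtraction images, a diluted one on
#' post-contrast images (overlaid on shared pre-contrast texture), and
#' the weakest on pre-contrast images, where the class difference is
#' minimal by construction.
#'
#' @return nested list `pre` / `uptake`, each with `positive` /
#'   `negative` parameter lists (`correlation_length` in pixels,
#'   `field_sd` in intensity units, `mean_shift` in intensity units).
#' @export
default_texture_params <- function() {
  list(
    pre = list(
      positive = list(correlation_length = 1.5, field_sd = 97, mean_shift = 12),
      negative = list(correlation_length = 1.5, field_sd = 90, mean_shift = 0)),
    uptake = list(
      positive = list(correlation_length = 2.15, field_sd = 140, mean_shift = 38),
      negative = list(correlation_length = 1.55, field_sd = 115, mean_shift = 0)))
}

#' Null texture parameters (no class effect)
#'
#' Both classes receive the negative-class parameters; useful for type-I
#' error and null-AUC calibration studies.
#'
#' @return parameter list as in [default_texture_params()].
#' @export
null_texture_params <- function() {
  p <- default_texture_params()
  p$pre$positive <- p$pre$negative
  p$uptake$positive <- p$uptake$negative
  p
}

#' Phantom cohort configuration
#'
#' @param n_positive,n_negative class sizes (defaults 52 / 40).
#' @param image_size `c(rows, cols)` in pixels.
#' @param lesion_radius_range min/max mean lesion radius in pixels.
#' @param background_level background intensity.
#' @param lesion_contrast pre-contrast lesion-minus-background intensity.
#' @param enhancement mean contrast uptake added inside the lesion.
#' @param texture_params class-conditional field parameters, see
#'   [default_texture_params()].
#' @param heterogeneity per-patient biological variability applied on top
#'   of the class parameters: `sd_log` / `corr_log` are log-normal
#'   jitters of the field standard deviation and correlation length,
#'   `shift_sd` an additive Gaussian jitter of the mean shift. Identical
#'   for both classes, so it widens within-class spread without creating
#'   a class effect.
#' @param noise_sd standard deviation of the independent acquisition
#'   noise added to each phase.
#' @param roi_margin dilation margin (pixels) of the seed ROI around the
#'   true lesion boundary, emulating a hand-drawn region.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(n_positive = 52L, n_negative = 40L,
                           image_size = c(96L, 96L),
                           lesion_radius_range = c(10, 16),
                           background_level = 200,
                           lesion_contrast = 50,
                           enhancement = 600,
                           texture_params = default_texture_params(),
                           heterogeneity = list(sd_log = 0.18,
                                                corr_log = 0.12,
                                                shift_sd = 18),
                           noise_sd = 20,
                           roi_margin = 5,
                           seed = 1L) {
  stopifnot(n_positive >= 0, n_negative >= 0)
  if (any(image_size < 8)) stop("phantom_config: image too small")
  if (max(lesion_radius_range) + roi_margin + 3 > min(image_size) / 2)
    stop("phantom_config: lesion radius exceeds the frame")
  structure(list(n_positive = as.integer(n_positive),
                 n_negative = as.integer(n_negative),
                 image_size = as.integer(image_size),
                 lesion_radius_range = lesion_radius_range,
                 background_level = background_level,
                 lesion_contrast = lesion_contrast,
                 enhancement = enhancement,
                 texture_params = texture_params,
                 heterogeneity = heterogeneity,
                 noise_sd = noise_sd,
                 roi_margin = roi_margin,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Stationary correlated field: white noise smoothed by a Gaussian kernel
# of width correlation_length, empirically rescaled to unit variance.
correlated_field <- function(dims, correlation_length) {
  z <- matrix(stats::rnorm(prod(dims)), dims[1], dims[2])
  if (correlation_length > 0) {
    z <- EBImage::gblur(z, sigma = correlation_length)
    z <- z / stats::sd(as.numeric(z))
  }
  z
}

# Smoothly irregular lesion mask: a disk with low-order radial modulation.
lesion_geometry <- function(dims, radius_range, roi_margin) {
  r0 <- stats::runif(1, radius_range[1], radius_range[2])
  amp <- stats::runif(3, 0, 0.12)
  pha <- stats::runif(3, 0, 2 * pi)
  max_wobble <- 1 + sum(amp)
  jitter_max <- max(0, min(dims) / 2 - r0 * max_wobble - roi_margin - 2)
  ctr <- dims / 2 + stats::runif(2, -1, 1) * min(3, jitter_max)
  radius_at <- function(theta) {
    w <- rep(1, length(theta))
    for (k in 1:3) w <- w + amp[k] * cos((k + 1) * theta + pha[k])
    r0 * w
  }
  rr <- matrix(seq_len(dims[1]), dims[1], dims[2])
  cc <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  theta <- atan2(cc - ctr[2], rr - ctr[1])
  dist <- sqrt((rr - ctr[1])^2 + (cc - ctr[2])^2)
  mask <- dist <= radius_at(theta)
  th <- seq(0, 2 * pi, length.out = 37)[-37]
  roi <- roi_polygon(cbind(ctr[1] + (radius_at(th) + roi_margin) * cos(th),
                           ctr[2] + (radius_at(th) + roi_margin) * sin(th)))
  list(mask = mask, roi = roi)
}

phantom_case <- function(config, patient_id, label) {
  dims <- config$image_size
  geo <- lesion_geometry(dims, config$lesion_radius_range, config$roi_margin)
  mask <- geo$mask
  tp <- config$texture_params
  cls <- if (label == "positive") "positive" else "negative"
  het <- config$heterogeneity
  jitter <- function(par) list(
    correlation_length = par$correlation_length * exp(stats::rnorm(1, 0, het$corr_log)),
    field_sd = par$field_sd * exp(stats::rnorm(1, 0, het$sd_log)),
    mean_shift = par$mean_shift + stats::rnorm(1, 0, het$shift_sd))
  pp <- jitter(tp$pre[[cls]]); up <- jitter(tp$uptake[[cls]])
  pre_field <- correlated_field(dims, pp$correlation_length) * pp$field_sd
  up_field <- correlated_field(dims, up$correlation_length) * up$field_sd
  pre <- config$background_level +
    (config$lesion_contrast + pp$mean_shift + pre_field) * mask +
    matrix(stats::rnorm(prod(dims), 0, config$noise_sd), dims[1], dims[2])
  post <- pre +
    (config$enhancement + up$mean_shift + up_field) * mask +
    matrix(stats::rnorm(prod(dims), 0, config$noise_sd), dims[1], dims[2])
  list(patient_id = patient_id,
       pre = slice_image(pre, "pre", patient_id),
       post = slice_image(post, "post", patient_id),
       true_mask = mask,
       seed_roi = geo$roi,
       label = label)
}

#' Generate a synthetic DCE-MRI cohort
#'
#' Emits `n_positive + n_negative` single-slice cases, each with a
#' pre-contrast image, a post-contrast image, the true lesion mask, a
#' seed ROI polygon (true boundary dilated by `roi_margin`), and the
#' class label. Identical seeds give identical cohorts.
#'
#' @param config a `phantom_config`.
#' @return list of cases (each a list with `patient_id`, `pre`, `post`,
#'   `true_mask`, `seed_roi`, `label`).
#' @export
generate_cohort <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  labels <- c(rep("positive", config$n_positive),
              rep("negative", config$n_negative))
  withr::with_seed(config$seed, {
    lapply(seq_along(labels), function(i)
      phantom_case(config, sprintf("P%03d", i), labels[i]))
  })
}

#' Deterministic fixture images
#'
#' Small, fully-masked integer images with known structure, used as
#' oracle inputs for the texture and segmentation operators.
#'
#' @param pattern one of `"constant"`, `"checkerboard"`, `"gradient"`,
#'   `"two_blob"`, `"impulse"`.
#' @param size `c(rows, cols)`, at least 2x2.
#' @param levels number of gray levels.
#' @return a `quantized_roi` with a full mask.
#' @export
make_fixture <- function(pattern = c("constant", "checkerboard", "gradient",
                                     "two_blob", "impulse"),
                         size = c(16L, 16L), levels = 256L) {
  pattern <- match.arg(pattern)
  if (any(size < 2)) stop("make_fixture: size must be >= 2x2")
  nr <- size[1]; nc <- size[2]
  top <- as.integer(levels - 1L)
  g <- switch(pattern,
    constant = matrix(as.integer(levels %/% 2), nr, nc),
    checkerboard = matrix(as.integer((outer(seq_len(nr), seq_len(nc), `+`)) %% 2L),
                          nr, nc),
    gradient = matrix(as.integer(floor((col(matrix(0, nr, nc)) - 1) /
                                         max(1, nc - 1) * top)), nr, nc),
    two_blob = {
      m <- matrix(0L, nr, nc)
      b1 <- max(2L, nr %/% 3L)            # larger blob, top-left
      m[2:(1 + b1), 2:(1 + b1)] <- top
      b2 <- max(1L, b1 %/% 2L)            # smaller blob, bottom-right
      m[(nr - b2):(nr - 1L), (nc - b2):(nc - 1L)] <- top
      m
    },
    impulse = {
      m <- matrix(0L, nr, nc)
      m[nr %/% 2L, nc %/% 2L] <- top
      m
    })
  structure(list(grid = g, mask = matrix(TRUE, nr, nc),
                 n_levels = as.integer(levels),
                 params = list(mu = NA_real_, sigma = NA_real_,
                               n_bits = as.integer(round(log2(levels))),
                               degenerate = FALSE, fixture = pattern)),
            class = "quantized_roi")
}

#' Write a phantom cohort to disk
#'
#' Per patient, the pre- and post-contrast slices are written as 32-bit
#' float TIFF, min-max scaled into the unit range the TIFF writer
#' expects; the per-image intensity range is recorded in the manifest so
#' [read_cohort()] restores the original values. The seed ROI is stored
#' as a JSON list of `[row, col]` vertices.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("write_cohort requires the 'tiff' package")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  put_plane <- function(grid, path) {
    lo <- min(grid); hi <- max(grid)
    span <- if (hi > lo) hi - lo else 1
    tiff::writeTIFF((grid - lo) / span, path, bits.per.sample = 32L)
    c(lo, hi)
  }
  rows <- lapply(cohort, function(cs) {
    paths <- file.path(dir, sprintf("%s_%s.tif", cs$patient_id,
                                    c("pre", "post")))
    r_pre <- put_plane(cs$pre$grid, paths[1])
    r_post <- put_plane(cs$post$grid, paths[2])
    roi_path <- file.path(dir, sprintf("%s_roi.json", cs$patient_id))
    jsonlite::write_json(unname(apply(cs$seed_roi$vertices, 1, as.list)),
                         roi_path, auto_unbox = TRUE, digits = NA)
    data.frame(patient_id = cs$patient_id, label = cs$label,
               pre_path = paths[1], post_path = paths[2],
               roi_path = roi_path,
               pre_lo = r_pre[1], pre_hi = r_pre[2],
               post_lo = r_post[1], post_hi = r_post[2])
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}
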