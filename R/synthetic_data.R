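## Seeded synthetic face-like corpus generator.
##
## Real face databases for age estimation are rarely redistributable, so
## the pipeline is exercised on a controllable surrogate that emulates the
## two phases of facial aging: craniofacial shape change (the face-ellipse
## aspect varies over the child groups) and skin-texture change (oriented
## wrinkle lines whose spatial frequency and contrast increase with age),
## under uneven illumination and additive pixel noise. Group sizes mirror
## the imbalanced composition of the study database (1355 images over the
## eight brackets at factor 1).

#' Specification for a synthetic corpus
#'
#' @param factor Scale factor for the per-group counts; counts are
#'   `ceiling(factor * base)` with base (200, 189, 363, 200, 158, 109, 71,
#'   65).
#' @param side Image side length S in pixels.
#' @param seed Integer seed; every image is a pure function of
#'   (seed, group, index).
#' @param aspect Face-ellipse width/height aspect per group; distinct over
#'   the first three groups (craniofacial phase).
#' @param wrinkle_freq Wrinkle spatial frequency per group (cycles per
#'   image height), strictly increasing with group index.
#' @param wrinkle_contrast Wrinkle line amplitude per group (intensity
#'   units), increasing with group index.
#' @param illum_amp Peak-to-centre amplitude of the linear illumination
#'   gradient (intensity units).
#' @param noise_sd Standard deviation of the additive Gaussian pixel noise.
#' @return List of class `"synth_spec"` (includes the resolved `counts`).
#' @export
synth_spec <- function(factor = 1, side = 100L, seed = 1L,
                       aspect = c(0.95, 0.84, 0.73, 0.70, 0.70, 0.70, 0.70, 0.70),
                       wrinkle_freq = c(2, 3, 4, 5, 7, 9, 11, 13),
                       wrinkle_contrast = c(2, 5, 8, 12, 17, 22, 28, 34),
                       illum_amp = 20, noise_sd = 3) {
  base <- c(200L, 189L, 363L, 200L, 158L, 109L, 71L, 65L)
  stopifnot(factor > 0, side >= 16,
            length(aspect) == 8, length(wrinkle_freq) == 8,
            length(wrinkle_contrast) == 8,
            all(diff(wrinkle_freq[4:8]) > 0),
            length(unique(aspect[1:3])) == 3,
            illum_amp >= 0, noise_sd >= 0)
  counts <- as.integer(ceiling(factor * base))
  structure(list(counts = counts, side = as.integer(side),
                 seed = as.integer(seed), aspect = aspect,
                 wrinkle_freq = wrinkle_freq,
                 wrinkle_contrast = wrinkle_contrast,
                 illum_amp = illum_amp, noise_sd = noise_sd),
            class = "synth_spec")
}

image_seed <- function(seed, group, index) {
  as.integer((as.double(seed) * 100003 + group * 10007 + index * 101) %%
               2147483647)
}

#' Generate one synthetic labeled face image
#'
#' Deterministic in (spec$seed, group, index): an ellipse with the group's
#' aspect on a dark background, an oriented sinusoidal wrinkle field at the
#' group's frequency and contrast inside the face, a linear illumination
#' gradient in a per-image random direction, and Gaussian pixel noise,
#' clipped to 0-255.
#'
#' @param spec A [synth_spec()].
#' @param group Age-group index 0-7.
#' @param index Image index within the group (1-based).
#' @return List with `pixels` (side x side integer matrix) and `label`.
#' @export
generate_image <- function(spec, group, index) {
  stopifnot(inherits(spec, "synth_spec"))
  if (length(group) != 1L || is.na(group) || group < 0 || group > 7) {
    stop("group must be a single index in 0..7", call. = FALSE)
  }
  g <- group + 1L
  s <- spec$side
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(image_seed(spec$seed, group, index))

  yy <- matrix(seq_len(s), s, s)               # row coordinate
  xx <- matrix(seq_len(s), s, s, byrow = TRUE) # column coordinate
  cy <- (s + 1) / 2 + stats::runif(1, -0.02, 0.02) * s
  cx <- (s + 1) / 2 + stats::runif(1, -0.02, 0.02) * s
  ry <- 0.42 * s * stats::runif(1, 0.95, 1.05)
  rx <- ry * spec$aspect[g] * stats::runif(1, 0.97, 1.03)
  inside <- ((xx - cx) / rx)^2 + ((yy - cy) / ry)^2 <= 1

  img <- matrix(60, s, s)                      # background
  img[inside] <- 170                           # skin base

  f <- spec$wrinkle_freq[g]
  cg <- spec$wrinkle_contrast[g]
  if (cg > 0) {
    ph1 <- stats::runif(1, 0, 2 * pi)
    ph2 <- stats::runif(1, 0, 2 * pi)
    # mostly-horizontal wrinkle lines plus a weaker oblique component
    w <- cg * sin(2 * pi * f * yy / s + ph1) +
      0.5 * cg * sin(2 * pi * f * (0.35 * xx + 0.65 * yy) / s + ph2)
    img[inside] <- img[inside] + w[inside]
  }
  if (spec$illum_amp > 0) {
    theta <- stats::runif(1, 0, 2 * pi)
    grad <- (cos(theta) * (xx / s - 0.5) + sin(theta) * (yy / s - 0.5)) * 2
    img <- img + spec$illum_amp * grad
  }
  if (spec$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(s * s, 0, spec$noise_sd), s, s)
  }
  list(pixels = round(pmax(pmin(img, 255), 0)), label = as.integer(group))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a full synthetic corpus
#'
#' Produces exactly `spec$counts[g]` images per group. The sample order
#' interleaves the groups deterministically (each group spread evenly by
#' fractional position), so a contiguous 80/20 block split contains every
#' group in both blocks. The manifest records all parameters, the seed and
#' the order.
#'
#' @param spec A [synth_spec()].
#' @return List of class `"synth_corpus"`: `images` (list of matrices),
#'   `labels` (integer 0-7), `manifest`.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  sched <- do.call(rbind, lapply(0:7, function(g) {
    n <- spec$counts[g + 1L]
    if (n < 1L) return(NULL)
    data.frame(group = g, index = seq_len(n),
               key = (seq_len(n) - 0.5) / n)
  }))
  sched <- sched[order(sched$key, sched$group), ]
  images <- vector("list", nrow(sched))
  labels <- integer(nrow(sched))
  for (i in seq_len(nrow(sched))) {
    im <- generate_image(spec, sched$group[i], sched$index[i])
    images[[i]] <- im$pixels
    labels[i] <- im$label
  }
  manifest <- list(counts = spec$counts, side = spec$side, seed = spec$seed,
                   aspect = spec$aspect, wrinkle_freq = spec$wrinkle_freq,
                   wrinkle_contrast = spec$wrinkle_contrast,
                   illum_amp = spec$illum_amp, noise_sd = spec$noise_sd,
                   order = paste0(sched$group, ":", sched$index),
                   total = nrow(sched))
  structure(list(images = images, labels = labels, manifest = manifest),
            class = "synth_corpus")
}

#' Write a synthetic corpus to disk
#'
#' PNG files under `<dir>/<group_dir>/img_<index>.png` in the layout
#' [load_corpus()] reads, plus `manifest.json`.
#'
#' @param corpus A `"synth_corpus"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "synth_corpus"))
  dirs <- age_group_dirs()
  for (d in dirs) dir.create(file.path(dir, d), recursive = TRUE,
                             showWarnings = FALSE)
  idx <- integer(8)
  for (i in seq_along(corpus$images)) {
    g <- corpus$labels[i] + 1L
    idx[g] <- idx[g] + 1L
    write_image(corpus$images[[i]],
                file.path(dir, dirs[g], sprintf("img_%04d.png", idx[g])))
  }
  jsonlite::write_json(corpus$manifest,
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
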