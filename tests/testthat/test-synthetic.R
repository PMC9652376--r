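test_that("image generation is a pure function of (seed, group, index)", {
  spec <- synth_spec(factor = 0.05, side = 32, seed = 9)
  a <- generate_image(spec, 4, 2)
  b <- generate_image(spec, 4, 2)
  expect_identical(a, b)
  expect_equal(a$label, 4L)
  expect_true(all(a$pixels >= 0 & a$pixels <= 255))
  c <- generate_image(spec, 4, 3)
  expect_false(identical(a$pixels, c$pixels))
  expect_error(generate_image(spec, 8, 1), "0..7")
})

test_that("image generation leaves the caller's RNG stream untouched", {
  spec <- synth_spec(factor = 0.05, side = 24, seed = 3)
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(generate_image(spec, 2, 1)); after <- runif(3)
  expect_identical(before, after)
})

test_that("a texture-free spec yields a smooth ellipse with little high-frequency energy", {
  smooth_spec <- synth_spec(factor = 0.05, side = 64, seed = 5,
                            wrinkle_contrast = rep(0, 8),
                            illum_amp = 0, noise_sd = 0)
  textured_spec <- synth_spec(factor = 0.05, side = 64, seed = 5,
                              illum_amp = 0, noise_sd = 0)
  smooth <- generate_image(smooth_spec, 7, 1)$pixels
  textured <- generate_image(textured_spec, 7, 1)$pixels
  # the texture-free image is the edge-only baseline: the ellipse boundary
  # alone accounts for its high-frequency content, and adding the wrinkle
  # field raises that band well above it
  expect_gt(fft_band_energy(textured, 8, 24),
            2 * fft_band_energy(smooth, 8, 24))
  # interior pixels away from the boundary are constant when texture is off
  expect_equal(length(unique(as.vector(smooth[28:36, 28:36]))), 1L)
})

test_that("older groups carry more high-frequency band energy than younger ones", {
  spec <- synth_spec(factor = 0.05, side = 64, seed = 6,
                     illum_amp = 0, noise_sd = 0)
  e7 <- mean(vapply(1:4, function(i)
    fft_band_energy(generate_image(spec, 7, i)$pixels, 8, 24), numeric(1)))
  e3 <- mean(vapply(1:4, function(i)
    fft_band_energy(generate_image(spec, 3, i)$pixels, 8, 24), numeric(1)))
  expect_gt(e7, e3)
})

test_that("corpus counts follow the scale factor and the default totals 1355", {
  expect_equal(sum(synth_spec()$counts), 1355)
  expect_equal(synth_spec(factor = 0.1)$counts,
               as.integer(ceiling(0.1 * c(200, 189, 363, 200, 158, 109, 71, 65))))
  corpus <- generate_corpus(synth_spec(factor = 1 / 65, side = 24, seed = 7))
  expect_equal(as.vector(table(corpus$labels)),
               synth_spec(factor = 1 / 65)$counts)
  expect_equal(corpus$manifest$total, length(corpus$images))
})

test_that("two corpus runs with the same seed give identical manifests and pixels", {
  spec <- synth_spec(factor = 1 / 65, side = 24, seed = 8)
  c1 <- generate_corpus(spec)
  c2 <- generate_corpus(spec)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$images, c2$images)
})

test_that("the interleaved order puts every group in both blocks of an 80/20 split", {
  corpus <- generate_corpus(synth_spec(factor = 0.05, side = 24, seed = 10))
  sp <- divide_block(length(corpus$labels))
  expect_setequal(unique(corpus$labels[sp$train]), 0:7)
  expect_setequal(unique(corpus$labels[sp$test]), 0:7)
})

test_that("group-conditional spectra separate a nearest-centroid classifier above chance", {
  corpus <- generate_corpus(synth_spec(factor = 0.1, side = 32, seed = 11))
  bands <- rbind(c(0.5, 2), c(2, 4), c(4, 8), c(8, 16))
  feats <- t(vapply(corpus$images, function(im) {
    log(vapply(seq_len(nrow(bands)),
               function(b) fft_band_energy(im, bands[b, 1], bands[b, 2]),
               numeric(1)) + 1)
  }, numeric(nrow(bands))))
  sp <- divide_block(nrow(feats))
  centroids <- vapply(0:7, function(g) {
    colMeans(feats[sp$train, , drop = FALSE][corpus$labels[sp$train] == g, ,
                                             drop = FALSE])
  }, numeric(ncol(feats)))
  pred <- apply(feats[sp$test, ], 1, function(v) {
    which.min(colSums((centroids - v)^2)) - 1L
  })
  acc <- mean(pred == corpus$labels[sp$test])
  expect_gt(acc, 0.125)
})

test_that("the writer produces the directory layout the loader expects", {
  dir <- withr::local_tempdir()
  corpus <- generate_corpus(synth_spec(factor = 1 / 65, side = 24, seed = 12))
  write_corpus(corpus, dir)
  expect_true(all(dir.exists(file.path(dir, age_group_dirs()))))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  expect_equal(manifest$total, length(corpus$images))
  expect_equal(manifest$seed, 12)
})
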