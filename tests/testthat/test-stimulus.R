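# independent oracle: literal double loop over checks applying the
# modulation equation to reconstructed L, M, N
reference_render <- function(spec, template, noise) {
  ny <- nrow(noise$values); nx <- ncol(noise$values)
  side <- nrow(template$check_grid)
  oy <- floor((ny - side) / 2); ox <- floor((nx - side) / 2)
  out <- matrix(NA_real_, ny, nx)
  bg <- if (spec$bipolar_modulation) -1 else 0
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    inside <- y > oy && y <= oy + side && x > ox && x <= ox + side
    LM <- if (inside) {
      v <- template$check_grid[y - oy, x - ox]
      if (spec$bipolar_modulation) 2 * v - 1 else v
    } else bg
    N <- noise$values[y, x]
    out[y, x] <- spec$mean_luminance *
      (1 + spec$noise_contrast * N +
         spec$luminance_amplitude * LM +
         spec$contrast_amplitude * spec$noise_contrast * LM * N)
  }
  kronecker(out, matrix(1, noise$check_size_px, noise$check_size_px))
}

test_that("rendered frames satisfy the modulation equation pixel by pixel", {
  specs <- list(
    stimulus_spec("LM"),
    stimulus_spec("CM"),
    stimulus_spec("LM", luminance_amplitude = 0.5, noise_contrast = 0.1),
    stimulus_spec("CM", contrast_amplitude = 0.5),
    stimulus_spec("CM", bipolar_modulation = TRUE, contrast_amplitude = 0.5,
                  noise_contrast = 0.25)
  )
  for (s in seq_along(specs)) {
    spec <- specs[[s]]
    tpl <- make_letter_template(hotv_letters[(s %% 4) + 1], 1)
    noise <- sample_noise(8, 10, check_size_px = 2, seed = 100 + s)
    fr <- render_frame(spec, tpl, noise)
    expect_equal(fr$image, reference_render(spec, tpl, noise))
    expect_true(all(fr$image >= 0 & fr$image <= 2 * spec$mean_luminance))
  }
})

test_that("direct substitutions give the expected luminances", {
  tplH <- make_letter_template("H", 1)
  noise <- sample_noise(5, 5, seed = 3)
  # no modulation: background-only values I(1 +/- n)
  fr0 <- render_frame(stimulus_spec("LM", luminance_amplitude = 0,
                                    noise_contrast = 0.2), tplH, noise)
  expect_setequal(unique(as.vector(fr0$image)), c(0.8, 1.2))
  # LM letter pixel with N = +1: 1 * (1 + 0.2 + 0.3) = 1.5
  frLM <- render_frame(stimulus_spec("LM", luminance_amplitude = 0.3), tplH,
                       noise)
  inside <- tplH$check_grid == 1 & noise$values == 1
  expect_true(all(frLM$image[inside] == 1.5))
  # CM m = 1: letter pixels at 1 +/- 0.4, background at 1 +/- 0.2
  noise30 <- sample_noise(10, 10, seed = 4)
  tpl5 <- make_letter_template("O", 1)
  frCM <- render_frame(stimulus_spec("CM", contrast_amplitude = 1), tpl5,
                       noise30)
  sup <- matrix(0, 10, 10); sup[3:7, 3:7] <- tpl5$check_grid
  expect_equal(sort(unique(frCM$image[sup == 1])), c(0.6, 1.4))
  expect_equal(sort(unique(frCM$image[sup == 0])), c(0.8, 1.2))
})

test_that("a frame carries at most four luminance levels (two when unmodulated)", {
  tpl <- make_letter_template("V", 2)
  noise <- sample_noise(20, 20, seed = 8)
  for (spec in list(stimulus_spec("LM"), stimulus_spec("CM"))) {
    fr <- render_frame(spec, tpl, noise)
    expect_lte(length(unique(as.vector(fr$image))), 4)
  }
  flat <- render_frame(stimulus_spec("LM", luminance_amplitude = 0),
                       tpl, noise)
  expect_equal(length(unique(as.vector(flat$image))), 2)
})

test_that("noise sampling is seeded, unbiased and block-constant", {
  a <- sample_noise(15, 15, seed = 42)
  b <- sample_noise(15, 15, seed = 42)
  expect_identical(a$values, b$values)
  expect_true(all(a$values %in% c(-1, 1)))
  big <- sample_noise(200, 200, seed = 7)
  expect_lt(abs(mean(big$values)), 3 / 200)  # 3 binomial SEs
  blk <- render_frame(stimulus_spec("LM", luminance_amplitude = 0),
                      make_letter_template("H", 1),
                      sample_noise(5, 5, check_size_px = 4, seed = 1))
  expect_identical(dim(blk$image), c(20L, 20L))
  for (i in 0:4) for (j in 0:4) {
    expect_equal(length(unique(as.vector(
      blk$image[i * 4 + 1:4, j * 4 + 1:4]))), 1)
  }
  expect_error(sample_noise(0, 5, seed = 1), ">= 1")
  expect_error(sample_noise(5, 5), "seed")
})

test_that("movies refresh noise every frame but are seed-reproducible", {
  spec <- stimulus_spec("CM")
  tpl <- make_letter_template("T")
  m1 <- render_movie(spec, tpl, n_frames = 2, seed = 5)
  m2 <- render_movie(spec, tpl, n_frames = 2, seed = 5)
  expect_false(identical(m1$frames[[1]]$noise$values,
                         m1$frames[[2]]$noise$values))
  expect_identical(m1$frames[[1]]$image, m2$frames[[1]]$image)
  expect_identical(m1$frames[[2]]$image, m2$frames[[2]]$image)
  one <- render_movie(spec, tpl, n_frames = 1, seed = 9)
  direct <- render_frame(spec, tpl,
                         sample_noise(30, 30, 1,
                                      seed = derive_seed(9, "frame", 1)))
  expect_identical(one$frames[[1]]$image, direct$image)
})

test_that("mean-luminance checks match the stimulus-equation expectations", {
  tpl <- make_letter_template("H")
  # CM: both regions estimate I
  cm <- render_movie(stimulus_spec("CM"), tpl, n_frames = 60, seed = 21)
  chk <- check_mean_luminance(cm)
  expect_true(chk$tolerance_pass)
  expect_lt(abs(chk$letter_region_mean - 1), 3 * chk$letter_region_se)
  # LM: letter region estimates I(1 + l)
  lm <- render_movie(stimulus_spec("LM", luminance_amplitude = 0.3), tpl,
                     n_frames = 60, seed = 22)
  chk2 <- check_mean_luminance(lm)
  expect_equal(chk2$expected_letter_mean, 1.3)
  expect_lt(abs(chk2$letter_region_mean - 1.3), 3 * chk2$letter_region_se)
  expect_lt(abs(chk2$background_mean - 1), 3 * chk2$background_se)
  # n = 0: exact means, zero spread
  quiet <- render_movie(stimulus_spec("CM", noise_contrast = 0), tpl,
                        n_frames = 2, seed = 23)
  chk3 <- check_mean_luminance(quiet)
  expect_identical(chk3$letter_region_mean, 1)
  expect_identical(chk3$background_mean, 1)
  expect_true(chk3$tolerance_pass)
})

test_that("stimulus specs enforce exclusivity and the luminance gamut", {
  expect_error(stimulus_spec("LM", contrast_amplitude = 0.5), "contrast_amplitude = 0")
  expect_error(stimulus_spec("CM", luminance_amplitude = 0.2), "luminance_amplitude = 0")
  expect_error(stimulus_spec("CM", noise_contrast = 1.5), "\\[0, 1\\]")
  # |l| + n(1 + |m|) > 1
  expect_error(stimulus_spec("LM", luminance_amplitude = 0.9,
                             noise_contrast = 0.2), "gamut")
  expect_error(stimulus_spec("CM", contrast_amplitude = 1,
                             noise_contrast = 0.6), "gamut")
  # boundary case is allowed and spans the full range exactly
  ok <- stimulus_spec("CM", contrast_amplitude = 1, noise_contrast = 0.5)
  fr <- render_frame(ok, make_letter_template("H", 1),
                     sample_noise(15, 15, seed = 2))
  expect_equal(range(fr$image), c(0, 2))
})

test_that("PNG export writes an 8-bit image plus sidecar metadata", {
  fr <- render_frame(stimulus_spec("CM"), make_letter_template("O"),
                     sample_noise(30, 30, seed = 6))
  path <- file.path(tempdir(), "frame.png")
  write_frame_png(fr, path)
  expect_true(file.exists(path))
  img <- png::readPNG(path)
  expect_identical(dim(img), c(30L, 30L))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(meta$letter, "O")
  expect_identical(meta$stimulus_type, "CM")
  expect_identical(meta$noise_seed, 6L)
  q <- quantize_frame(fr)
  expect_true(all(abs(q$image - fr$image) <= 1 / 255))
})
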