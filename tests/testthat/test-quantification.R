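make_three_pixel_field <- function() {
  g <- matrix(0L, 3, 3); r <- matrix(0L, 3, 3); mask <- matrix(0L, 3, 3)
  g[1, 1:3] <- c(10L, 20L, 30L)
  r[1, 1:3] <- c(40L, 50L, 60L)
  mask[1, 1:3] <- 7L
  list(green = channel_image(g, "green", field_id = "f", sample_id = "s"),
       red = channel_image(r, "red", field_id = "f", sample_id = "s"),
       mask = mask)
}

test_that("per-cell means and ratios follow the hand-computed arithmetic", {
  f <- make_three_pixel_field()
  m <- measure_cell(f$green, f$red, f$mask, 7L)
  expect_equal(m$green_mean, 20)
  expect_equal(m$red_mean, 50)
  expect_equal(m$ratio, 0.4)
  expect_identical(m$n_pixels, 3L)

  # uniform cell: green 100, red 200 -> ratio exactly 0.5
  mask <- matrix(0L, 6, 6); mask[3:4, 3:4] <- 1L
  m2 <- measure_field(const_image(100L, c(6L, 6L)),
                      const_image(200L, c(6L, 6L), channel = "red"), mask)
  expect_identical(m2$ratio, 0.5)

  # zero green signal is a valid ratio of 0
  m3 <- measure_field(const_image(0L, c(6L, 6L)),
                      const_image(200L, c(6L, 6L), channel = "red"), mask)
  expect_identical(m3$ratio, 0)
})

test_that("unusable cells are excluded with warnings", {
  mask <- matrix(0L, 8, 8); mask[3:4, 3:4] <- 1L; mask[6, 6] <- 2L
  g <- const_image(50L, c(8L, 8L)); r <- const_image(0L, c(8L, 8L), channel = "red")
  expect_warning(m <- measure_field(g, r, mask), "housekeeping")
  expect_identical(nrow(m), 0L)

  r2 <- const_image(100L, c(8L, 8L), channel = "red")
  expect_warning(m2 <- measure_field(g, r2, mask, min_cell_area = 3L),
                 "min_cell_area")
  expect_identical(m2$cell_id, 1L)

  # border-touching cells are excluded (their means are truncation-biased)
  mask_b <- matrix(0L, 8, 8); mask_b[1, 1:3] <- 1L; mask_b[4:5, 4:5] <- 2L
  expect_warning(m3 <- measure_field(g, r2, mask_b), "border")
  expect_identical(m3$cell_id, 2L)

  expect_error(measure_field(g, r2, matrix(0L, 4, 4)), "shape")
  expect_error(measure_field(r2, g, mask), "swapped")
})

test_that("ratios are invariant to common gain and scale with green-only gain", {
  sp <- tiny_spec(cells_per_image = 6L, red_mean_level = 8000)
  f <- render_field(draw_cell_truths(sp, 0), sp, 0)
  base <- measure_field(f$green, f$red, f$mask)

  scale_img <- function(img, c) {
    channel_image(matrix(as.integer(round(img$pixels * c)),
                         nrow(img$pixels)), img$channel, img$bit_depth,
                  img$field_id, img$sample_id)
  }
  # power-of-two common gain: exact invariance
  m4 <- measure_field(scale_img(f$green, 4), scale_img(f$red, 4), f$mask)
  expect_identical(m4$ratio, base$ratio)
  # arbitrary common gain: invariance to floating-point rounding
  m3 <- measure_field(scale_img(f$green, 3), scale_img(f$red, 3), f$mask)
  expect_equal(m3$ratio, base$ratio, tolerance = 1e-12)
  # green-only gain scales every ratio by exactly that factor
  mg <- measure_field(scale_img(f$green, 2), f$red, f$mask)
  expect_equal(mg$ratio, 2 * base$ratio, tolerance = 1e-12)
})

test_that("a common additive offset pulls every ratio toward one", {
  sp <- tiny_spec(cells_per_image = 6L, red_mean_level = 8000)
  f <- render_field(draw_cell_truths(sp, 0), sp, 0)
  base <- measure_field(f$green, f$red, f$mask)
  off <- function(img, b) channel_image(img$pixels + as.integer(b),
                                        img$channel, img$bit_depth,
                                        img$field_id, img$sample_id)
  shifted <- measure_field(off(f$green, 2000), off(f$red, 2000), f$mask)
  expect_true(all(abs(shifted$ratio - 1) < abs(base$ratio - 1)))
})

test_that("noise-free measurement recovers the generator truth", {
  # exact-arithmetic regime: constant integer levels, ratio with an exact
  # integer product -> measured ratio identical to the truth
  spx <- tiny_spec(between_cell_sd = 0, red_cell_cv = 0,
                   mean_ratio = 0.6, cells_per_image = 5L)
  tr <- draw_cell_truths(spx, 0)
  f <- render_field(tr, spx, 0)
  m <- measure_field(f$green, f$red, f$mask)
  expect_identical(m$ratio, rep(0.6, 5))

  # generic continuous draws: agreement bounded by integer quantization
  # of the detector (half a count over the red level)
  sp <- tiny_spec(between_cell_sd = 0.05, red_cell_cv = 0.1,
                  cells_per_image = 8L)
  tr2 <- draw_cell_truths(sp, 0)
  f2 <- render_field(tr2, sp, 0)
  m2 <- measure_field(f2$green, f2$red, f2$mask)
  bound <- 1.5 / min(tr2$true_red_level)
  expect_true(all(abs(m2$ratio - tr2$true_ratio[m2$cell_id]) < bound))
})

test_that("red-channel segmentation finds the rendered cells", {
  sp <- tiny_spec(cells_per_image = 5L, pixel_noise_sd = 0)
  f <- render_field(draw_cell_truths(sp, 0), sp, 0)
  seg <- segment_cells(f$red, min_cell_area = 20L)
  expect_identical(length(setdiff(unique(as.integer(seg)), 0L)), 5L)
  # segmented footprints agree with the generator mask
  expect_true(all((seg > 0) == (f$mask > 0)))

  expect_identical(max(segment_cells(const_image(100L, c(16L, 16L),
                                                 channel = "red"))), 0L)

  # a size filter drops the sub-threshold component
  r <- matrix(0L, 24, 24)
  r[3:12, 3:7] <- 4000L   # 50 px
  r[16:19, 16:17] <- 4000L  # 8 px
  seg2 <- segment_cells(channel_image(r, "red"), min_cell_area = 20L)
  expect_identical(length(setdiff(unique(as.integer(seg2)), 0L)), 1L)
})

test_that("collection selection is seeded, uniform, and handles shortfall", {
  cells <- data.frame(sample_id = "s", field_id = "f", cell_id = 1:100,
                      green_mean = 1, red_mean = 2, ratio = 0.5,
                      n_pixels = 60L)
  c1 <- select_cell_collection(cells, k = 30, seed = 5)
  c2 <- select_cell_collection(cells, k = 30, seed = 5)
  expect_identical(c1, c2)
  expect_identical(nrow(c1), 30L)
  expect_identical(anyDuplicated(c1$cell_id), 0L)
  expect_false(identical(c1$cell_id,
                         select_cell_collection(cells, k = 30, seed = 6)$cell_id))

  short <- cells[1:20, ]
  expect_warning(call <- select_cell_collection(short, k = 30, seed = 1),
                 "20 cells")
  expect_identical(nrow(call), 20L)
  expect_error(select_cell_collection(cells[0, ], k = 30, seed = 1),
               "unanalyzable")

  # uniformity: over 200 seeded resamplings each cell's inclusion
  # frequency stays inside wide binomial bounds around k/n = 0.3
  inc <- integer(100)
  for (s in 1:200) {
    picked <- select_cell_collection(cells, k = 30, seed = 1000 + s)$cell_id
    inc[picked] <- inc[picked] + 1L
  }
  freq <- inc / 200
  se <- sqrt(0.3 * 0.7 / 200)
  expect_true(all(abs(freq - 0.3) < 3.9 * se))
  expect_equal(mean(freq), 0.3)
})

test_that("sample summaries use the arithmetic mean and n-1 SD", {
  cells <- data.frame(sample_id = "s", field_id = "f", cell_id = 1:2,
                      green_mean = c(4, 6), red_mean = 10,
                      ratio = c(0.4, 0.6), n_pixels = 50L)
  s <- summarize_sample(cells, "g")
  expect_equal(s$mean_ratio, 0.5)
  expect_equal(s$sd_ratio, 0.1414213562, tolerance = 1e-9)
  expect_identical(s$n_cells, 2L)

  const <- cells; const$ratio <- 0.6
  expect_equal(summarize_sample(const, "g")$sd_ratio, 0)

  expect_warning(s1 <- summarize_sample(cells[1, ], "g"), "single-cell")
  expect_identical(s1$sd_ratio, 0)

  mixed <- rbind(cells, transform(cells, sample_id = "other"))
  expect_error(summarize_sample(mixed, "g"), "multiple samples")
})

test_that("sample mean ratios track the generator truth under noise", {
  # property: with noise on, M.R lands within 3 (cell SD / sqrt(30)) of the
  # sample's true mean in nearly all replicates
  ok <- 0L
  for (i in 1:40) {
    sp <- do.call(sample_spec, c(list(sample_id = sprintf("R%02d", i),
                                      group_label = "g",
                                      true_mean_ratio = 0.6,
                                      seed = 7000 + i), sim_template))
    s <- simulate_sample_summary(sp, k_cells = 30L)
    ok <- ok + (abs(s$mean_ratio - 0.6) <= 3 * s$sd_ratio / sqrt(30))
  }
  expect_gte(ok, 38L)
})
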