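test_that("zero-dispersion specs give exact truths; degenerate cases behave", {
  sp <- tiny_spec(between_cell_sd = 0, red_cell_cv = 0)
  tr <- draw_cell_truths(sp, 0)
  expect_equal(nrow(tr), sp$cells_per_image)
  expect_true(all(tr$true_ratio == 0.6))
  expect_true(all(tr$true_red_level == sp$red_mean_level))

  sp0 <- tiny_spec(cells_per_image = 0L)
  expect_identical(nrow(draw_cell_truths(sp0, 0)), 0L)

  expect_error(tiny_spec(between_cell_sd = 0.7), "between_cell_sd")
  expect_error(tiny_spec(image_shape = c(12L, 12L)), "cell_radius_range")
  expect_error(draw_cell_truths(sp, sp$n_images), "image_index")
})

test_that("truth draws recover the generator distribution over many cells", {
  sp <- sample_spec("LLN", "g", true_mean_ratio = 0.6, seed = 101,
                    n_images = 30L, cells_per_image = 30L,
                    between_cell_sd = 0.05, image_shape = c(192L, 192L))
  ratios <- unlist(lapply(seq_len(30) - 1L,
                          function(i) draw_cell_truths(sp, i)$true_ratio))
  expect_length(ratios, 900L)
  expect_lt(abs(mean(ratios) - 0.6), 3 * 0.05 / sqrt(900))
  # empirical SD close to the nominal between-cell SD (chi-square MC error)
  expect_lt(abs(sd(ratios) - 0.05), 4 * 0.05 / sqrt(2 * 899))
})

test_that("generation is deterministic and image streams are independent", {
  sp <- tiny_spec(pixel_noise_sd = 200)
  t1 <- draw_cell_truths(sp, 1); t2 <- draw_cell_truths(sp, 1)
  expect_identical(t1, t2)
  f1 <- render_field(t1, sp, 1); f2 <- render_field(t2, sp, 1)
  expect_identical(f1$green$pixels, f2$green$pixels)
  expect_identical(f1$mask, f2$mask)
  # different images of the same sample get different draws
  expect_false(identical(t1$true_ratio, draw_cell_truths(sp, 0)$true_ratio))
})

test_that("noise-free forward model renders exact in-cell intensities", {
  sp <- sample_spec("NF", "g", true_mean_ratio = 0.5, seed = 3,
                    n_images = 1L, cells_per_image = 1L,
                    between_cell_sd = 0, red_mean_level = 200,
                    red_cell_cv = 0, background_level = 0,
                    pixel_noise_sd = 0, image_shape = c(32L, 32L),
                    bit_depth = 8L)
  tr <- draw_cell_truths(sp, 0)
  f <- render_field(tr, sp, 0)
  inside <- f$mask == 1L
  expect_true(any(inside))
  expect_true(all(f$green$pixels[inside] == 100L))
  expect_true(all(f$red$pixels[inside] == 200L))
  expect_true(all(f$green$pixels[!inside] == 0L))

  # empty truth list: constant background, all-zero mask
  f0 <- render_field(tr[0, ], sp, 0)
  expect_true(all(f0$mask == 0L))
  expect_true(all(f0$red$pixels == 0L))
})

test_that("label mask matches analytic ellipse rasterization", {
  sp <- tiny_spec(sample_id = "E", cells_per_image = 5L, pixel_noise_sd = 0)
  tr <- draw_cell_truths(sp, 0)
  f <- render_field(tr, sp, 0)
  expect_setequal(setdiff(unique(as.integer(f$mask)), 0L), 1:5)
  h <- sp$image_shape[1]; w <- sp$image_shape[2]
  for (i in 1:5) {
    # oracle: count pixels satisfying the ellipse inequality on the full grid
    rr <- ((seq_len(h) - 1) - tr$center_row[i]) / tr$r_row[i]
    cc <- ((seq_len(w) - 1) - tr$center_col[i]) / tr$r_col[i]
    n_oracle <- sum(outer(rr^2, cc^2, `+`) <= 1)
    expect_identical(sum(f$mask == i), n_oracle)
    # rasterized area differs from pi*a*b by at most a perimeter's worth
    analytic <- pi * tr$r_row[i] * tr$r_col[i]
    expect_lt(abs(n_oracle - analytic), 2 * pi * max(tr$r_row[i], tr$r_col[i]) + 4)
  }
})

test_that("impossible placements fail with an informative error", {
  sp <- sample_spec("CRWD", "g", 0.6, seed = 9, n_images = 1L,
                    cells_per_image = 40L, image_shape = c(32L, 32L),
                    cell_radius_range = c(4, 7))
  expect_error(draw_cell_truths(sp, 0), "CRWD")
})

test_that("overflow beyond the bit depth clips with a warning", {
  sp <- sample_spec("OV", "g", 0.9, seed = 4, n_images = 1L,
                    cells_per_image = 3L, between_cell_sd = 0,
                    red_mean_level = 250, red_cell_cv = 0,
                    pixel_noise_sd = 30, image_shape = c(48L, 48L),
                    bit_depth = 8L)
  tr <- draw_cell_truths(sp, 0)
  w <- capture_warnings(f <- render_field(tr, sp, 0))
  expect_true(any(grepl("overflow", w)))
  expect_true(all(f$red$pixels <= 255L))
})

test_that("poisson noise mode is seeded and centred on the forward model", {
  sp <- tiny_spec(sample_id = "PO", noise_model = "poisson",
                  between_cell_sd = 0, red_cell_cv = 0,
                  cells_per_image = 4L)
  tr <- draw_cell_truths(sp, 0)
  f1 <- render_field(tr, sp, 0); f2 <- render_field(tr, sp, 0)
  expect_identical(f1$red$pixels, f2$red$pixels)
  inside <- f1$mask > 0
  # Poisson(20000): the in-cell mean sits within 5 SE of the rate
  expect_lt(abs(mean(f1$red$pixels[inside]) - 20000),
            5 * sqrt(20000 / sum(inside)))
})

test_that("generate_study writes a complete, exactly regenerable study", {
  specs <- c(
    lapply(1:3, function(i) tiny_spec(sprintf("A_%d", i), "grpA", 0.6,
                                      seed = i, n_images = 4L)),
    lapply(1:3, function(i) tiny_spec(sprintf("B_%d", i), "grpB", 0.62,
                                      seed = 100 + i, n_images = 4L)))
  d1 <- withr::local_tempdir()
  man <- generate_study(specs, d1)
  expect_equal(nrow(man), 2 * 3 * 4)
  expect_true(all(file.exists(file.path(d1, man$green_path))))

  # byte-identical regeneration
  d2 <- withr::local_tempdir()
  generate_study(specs, d2)
  for (p in c(man$green_path[1:4], man$mask_path[1:4])) {
    expect_identical(unname(tools::md5sum(file.path(d1, p))),
                     unname(tools::md5sum(file.path(d2, p))))
  }

  # duplicate sample ids abort before anything is written
  d3 <- withr::local_tempdir()
  expect_error(generate_study(c(specs[1], specs[1]), file.path(d3, "x")),
               "duplicate")
  expect_false(dir.exists(file.path(d3, "x")))
})

test_that("a study config mirroring the full design yields 2,020 field triples", {
  # 39 + 23 + 30 + 9 samples at 20 images each, counted without rendering
  n_samples <- c(HL = 39, NHL = 23, normal = 30, RLH = 9)
  expect_identical(sum(n_samples) * 20, 2020)
  specs <- unlist(lapply(names(n_samples), function(g) {
    group_sample_specs(g, n_samples[[g]], 0.6, 0.02, seed = 1,
                       n_images = 20L)
  }), recursive = FALSE)
  expect_length(specs, 101L)
  expect_identical(sum(vapply(specs, `[[`, integer(1), "n_images")), 2020L)
})
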