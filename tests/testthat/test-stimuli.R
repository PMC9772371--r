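## Stimulus generation: catalogue, palettes, masks, symmetry, resolution
## behaviour and the Mondrian tessellations.

test_that("the catalogue lists 13 displays with the human direction signs", {
  cat13 <- list_displays()
  expect_equal(nrow(cat13), 13)
  expect_equal(sum(is.na(cat13$human_sign)), 2)   # the two Mondrians
  expect_equal(cat13$human_sign[cat13$name == "slc"], +1)
  expect_equal(cat13$human_sign[cat13$name == "dungeon"], -1)
  ## signs agree with the embedded human statistics
  t1 <- table1_stats()
  for (d in t1$display) {
    expect_equal(cat13$human_sign[cat13$name == d], sign(t1$Md[t1$display == d]),
                 info = d)
  }
})

test_that("illusion displays contain exactly their printed luminances", {
  pal <- list(slc = c(6, 69, 145), slc_dark = c(6, 25, 145),
              slc_light = c(6, 105, 145), maniatis = c(6, 69, 145),
              whites = c(6, 69, 145), wedding_cake = c(6, 69, 145),
              dungeon = c(6, 69, 145), bullseye = c(6, 69, 145))
  for (nm in names(pal)) {
    b <- build_display(nm, resolution = 128)
    expect_equal(sort(unique(as.vector(b$image))), pal[[nm]], info = nm)
    expect_true(all(b$image[b$mask_left] == b$target_luminance), info = nm)
    expect_true(all(b$image[b$mask_right] == b$target_luminance), info = nm)
  }
})

test_that("masks mirror across the vertical midline for symmetric displays", {
  cat13 <- list_displays()
  for (nm in cat13$name[cat13$symmetric & !cat13$needs_seed]) {
    b <- build_display(nm, resolution = 192)
    expect_identical(b$mask_right, b$mask_left[, ncol(b$mask_left):1],
                     info = nm)
  }
})

test_that("target areas match the printed cm sizes", {
  cat13 <- list_displays()
  for (i in seq_len(nrow(cat13))) {
    nm <- cat13$name[i]
    b <- build_display(nm, resolution = 256,
                       seed = if (cat13$needs_seed[i]) 7 else NULL)
    frac_expected <- cat13$target_area_cm2[i] / 81
    expect_equal(sum(b$mask_left) / length(b$image), frac_expected,
                 tolerance = 0.05, info = nm)
  }
})

test_that("doubling the resolution scales masks and keeps the palette", {
  for (nm in c("slc", "whites", "dungeon", "bullseye")) {
    b1 <- build_display(nm, resolution = 128)
    b2 <- build_display(nm, resolution = 256)
    expect_equal(sum(b2$mask_left), 4 * sum(b1$mask_left),
                 tolerance = 4 * sqrt(sum(b1$mask_left)) / sum(b1$mask_left),
                 info = nm)
    expect_equal(sort(unique(as.vector(b1$image))),
                 sort(unique(as.vector(b2$image))), info = nm)
  }
})

test_that("Mondrians are seed-deterministic with the required surfaces", {
  a <- build_display("mondrian34", resolution = 128, seed = 3)
  b <- build_display("mondrian34", resolution = 128, seed = 3)
  c <- build_display("mondrian34", resolution = 128, seed = 4)
  expect_identical(a$image, b$image)
  expect_false(identical(a$image, c$image))
  expect_true(all(a$image >= 6 & a$image <= 145))
  expect_true(all(a$image[a$mask_left] == 69))
  expect_true(all(a$image[a$mask_right] == 69))
  ## 34 background surfaces: at least 30 distinct levels outside the
  ## targets (duplicates allowed only for non-adjacent surfaces)
  bg <- a$image[!(a$mask_left | a$mask_right)]
  expect_gte(length(unique(bg)), 25)
  b4 <- build_display("mondrian4", resolution = 128, seed = 3)
  bg4 <- unique(as.vector(b4$image[!(b4$mask_left | b4$mask_right)]))
  expect_lte(length(bg4), 4)
})

test_that("the Mondrian generator leaves the caller's RNG untouched", {
  set.seed(99); before <- .Random.seed
  invisible(build_display("mondrian4", resolution = 128, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("invalid build requests error clearly", {
  expect_error(build_display("nonesuch", 128), "unknown display")
  expect_error(build_display("slc", 32), "at least 64")
  expect_error(build_display("dungeon", 64), "finest")
  expect_error(build_display("mondrian4", 128), "seed")
})
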