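## Embedded human statistics and the paired / one-sample machinery.
## stats::t.test serves as the independent oracle for the formulas.

test_that("embedded human statistics are internally consistent", {
  t1 <- table1_stats()
  expect_equal(nrow(t1), 11)
  expect_true(all(t1$df == 84))
  expect_true(all(sign(t1$t) == sign(t1$Md)))
  expect_true(all(sign(t1$d) == sign(t1$Md)))
  ## printed-rounding consistency of d = Md/SDd and t = Md/SEd
  expect_true(all(abs(t1$d - t1$Md / t1$SDd) <= 0.03))
  expect_true(all(abs(t1$t - t1$Md / t1$SEd) <= 0.12 * abs(t1$t)))
})

test_that("paired_stats matches the t.test oracle to 1e-12", {
  set.seed(42)
  for (i in 1:5) {
    n <- sample(3:40, 1)
    left <- runif(n); right <- runif(n)
    got <- paired_stats(left, right)
    tt <- t.test(left, right, paired = TRUE)
    expect_equal(got$t, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(got$Md, unname(tt$estimate), tolerance = 1e-12)
    expect_equal(got$p, tt$p.value, tolerance = 1e-12)
    expect_equal(got$df, n - 1)
    expect_equal(got$SEd, got$SDd / sqrt(n), tolerance = 1e-15)
    expect_equal(got$d, got$Md / got$SDd, tolerance = 1e-15)
  }
  ## worked toy case against the closed-form numbers
  got <- paired_stats(c(0.1, 0.0, 0.2), c(0, 0, 0))
  expect_equal(got$Md, 0.1, tolerance = 1e-12)
  expect_equal(got$SDd, 0.1, tolerance = 1e-12)
  expect_equal(got$t, 0.1 / (0.1 / sqrt(3)), tolerance = 1e-12)
})

test_that("paired_stats is antisymmetric and order-invariant", {
  set.seed(1)
  left <- runif(10); right <- runif(10)
  a <- paired_stats(left, right)
  b <- paired_stats(right, left)
  expect_equal(a$Md, -b$Md)
  expect_equal(a$t, -b$t)
  expect_equal(a$d, -b$d)
  o <- sample(10)
  c <- paired_stats(left[o], right[o])
  expect_equal(a$t, c$t)
})

test_that("paired_stats rejects degenerate input", {
  expect_error(paired_stats(1, 2), "two pairs")
  expect_error(paired_stats(c(1, 2), c(0.5, 1.5)), "zero variance")
  expect_equal(paired_stats(c(0.4, 0.5), c(0.4, 0.3))$Md, 0.1)
})

test_that("one_sample_stats matches t.test and handles symmetry", {
  expect_equal(one_sample_stats(c(0.4, 0.5, 0.6), 0.5)$t, 0)
  got <- one_sample_stats(c(0.5, 0.6, 0.7), 0.5)
  tt <- t.test(c(0.5, 0.6, 0.7), mu = 0.5)
  expect_equal(got$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(got$p, tt$p.value, tolerance = 1e-12)
  expect_equal(one_sample_stats(rep(0.5, 4), 0.5)$t, 0)
})

test_that("contrast_illusion_sizes runs a paired test on magnitudes", {
  toy <- match_data(data.frame(
    participant = rep(1:2, each = 8),
    display = rep(rep(c("a", "b"), each = 4), 2),
    side = rep(c("left", "left", "right", "right"), 4),
    repetition = rep(1:2, 8),
    gray = c(130, 132, 120, 122, 140, 138, 120, 118,
             128, 126, 122, 120, 131, 129, 119, 121)))
  got <- contrast_illusion_sizes(toy, "a", "b")
  ## oracle: per-participant magnitudes computed by hand
  magA <- c(mean(c(130, 132)) - mean(c(120, 122)),
            mean(c(128, 126)) - mean(c(122, 120))) / 255
  magB <- c(mean(c(140, 138)) - mean(c(120, 118)),
            mean(c(131, 129)) - mean(c(119, 121))) / 255
  tt <- t.test(magA, magB, paired = TRUE)
  expect_equal(got$t, unname(tt$statistic), tolerance = 1e-12)
  ## identical magnitudes give t = 0
  same <- match_data(data.frame(
    participant = rep(1:3, each = 4),
    display = rep(c("a", "a", "b", "b"), 3),
    side = rep(c("left", "right"), 6),
    repetition = 1L,
    gray = rep(c(130, 120), 6)))
  expect_error(contrast_illusion_sizes(same, "a", "b"), "zero variance")
})

test_that("match_data validates and converts gray to unit lightness", {
  df <- data.frame(participant = 1, display = "slc", side = "left",
                   repetition = 1, gray = 127)
  m <- match_data(df)
  expect_equal(m$match, 127 / 255, tolerance = 1e-12)
  expect_equal(round(m$match, 3), 0.498)
  expect_error(match_data(transform(df, gray = 300)), "0, 255")
  expect_error(match_data(rbind(df, df)), "duplicate")
  expect_error(match_data(df[, -5]), "columns")
})

test_that("load_matches round-trips through CSV and accepts empty files", {
  m <- simulate_matches(observer_model("slc", n = 5), seed = 2)
  f <- tempfile(fileext = ".csv")
  write_matches(m, f)
  m2 <- load_matches(f)
  expect_equal(m2$gray, m$gray)
  expect_equal(m2$match, m$match)
  f0 <- tempfile(fileext = ".csv")
  writeLines("participant,display,side,repetition,gray", f0)
  empty <- load_matches(f0)
  expect_s3_class(empty, "match_data")
  expect_equal(nrow(empty), 0)
})
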