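## Scoreboard mechanics, checked with cheap synthetic "models" at low
## resolution; the full-resolution benchmark lives in test-acceptance.R.

test_that("direction_match applies the sign and no-effect rules", {
  expect_true(direction_match(0.10, +1))
  expect_false(direction_match(0.002, +1))          # below epsilon
  expect_false(direction_match(-0.04, +1))
  expect_true(direction_match(-0.04, -1))           # checkerboard-style
  expect_false(direction_match(0.004, +1, epsilon = 0.005))
  expect_true(direction_match(0.006, +1, epsilon = 0.005))
})

test_that("mondrian_constancy needs both displays within delta", {
  mk <- function(l, r, d) structure(
    list(display = d, model_id = "m", left = l, right = r, diff = l - r,
         raw_min = 0, raw_max = 1, params = list(), optional_tier = FALSE),
    class = "illusion_result")
  expect_true(mondrian_constancy(list(mk(0.5, 0.5, "mondrian4"),
                                      mk(0.52, 0.48, "mondrian34"))))
  expect_false(mondrian_constancy(list(mk(0.5, 0.5, "mondrian4"),
                                       mk(0.3, 0.3, "mondrian34"))))
  expect_error(mondrian_constancy(list(mk(0.5, 0.5, "mondrian4"))), "both")
})

## cheap bundles shared by the scoreboard tests
eval_bundles <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cat13 <- list_displays()
      cache <<- lapply(seq_len(nrow(cat13)), function(i) {
        build_display(cat13$name[i], 128, 8,
                      seed = if (cat13$needs_seed[i]) 1 else NULL)
      })
      names(cache) <<- cat13$name
    }
    cache
  }
})

test_that("a human-replay oracle attains the maximum scoreboard total", {
  ## the oracle returns a unit-scale map whose targets sit exactly at the
  ## human mean matches (and at 0.5 for the Mondrians)
  t1 <- table1_stats()
  oracle <- function(b) {
    v <- (b$image - 6) / (145 - 6)
    v[1, 1] <- 0; v[1, 2] <- 1     # pin the normalization range
    md <- if (b$name %in% t1$display) t1$Md[t1$display == b$name] else 0
    v[b$mask_left] <- 0.5 + md / 2
    v[b$mask_right] <- 0.5 - md / 2
    v
  }
  dt <- table2(list(replay = oracle), bundles = eval_bundles())
  expect_equal(unname(dt$totals["replay"]), 9)
  expect_equal(unname(dt$column_totals), rep(1, 9))
})

test_that("a constant-map model scores zero with error annotations", {
  dt <- table2(list(flat = function(b) matrix(1, nrow(b$image), ncol(b$image))),
               bundles = eval_bundles())
  expect_equal(unname(dt$totals["flat"]), 0)
  expect_equal(sum(!is.na(dt$results$error)), 13)
})

test_that("row and column totals are consistent with the grid", {
  dt <- table2(list(hp = function(b) highpass(b)), bundles = eval_bundles())
  expect_equal(unname(dt$totals), unname(rowSums(dt$grid)))
  expect_equal(unname(dt$column_totals), unname(colSums(dt$grid)))
})

test_that("increasing epsilon never increases a row total", {
  bundles <- eval_bundles()
  t_prev <- Inf
  for (eps in c(0, 0.005, 0.05, 0.2)) {
    dt <- table2(list(hp = function(b) highpass(b)), bundles = bundles,
                 eps = eps)
    expect_lte(unname(dt$totals["hp"]), t_prev)
    t_prev <- unname(dt$totals["hp"])
  }
})

test_that("the scoreboard is deterministic for a fixed configuration", {
  d1 <- table2(list(hp = function(b) highpass(b)), bundles = eval_bundles())
  d2 <- table2(list(hp = function(b) highpass(b)), bundles = eval_bundles())
  expect_identical(d1$grid, d2$grid)
  expect_identical(d1$results, d2$results)
})

test_that("optional-tier models carry their fidelity flag into reports", {
  b <- eval_bundles()[["slc"]]
  r <- illusion_effect(b, function(bb) dynamic_decorrelation(bb))
  expect_true(r$optional_tier)
  dt <- table2(list(dyndec = function(bb) dynamic_decorrelation(bb)),
               bundles = eval_bundles())
  expect_true(unname(dt$optional_tier["dyndec"]))
  expect_true(all(dt$results$optional_tier))
})
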