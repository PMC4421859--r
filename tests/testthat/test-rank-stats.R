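test_that("rank_transform assigns average ranks to ties", {
  expect_equal(rank_transform(c(10, 20, 30)), c(1, 2, 3))
  expect_equal(rank_transform(c(5, 5, 7)), c(1.5, 1.5, 3))
  expect_error(rank_transform(c(1, NA, 3)), "non-finite")
})

test_that("rank_transform agrees with a sort-based oracle", {
  set.seed(3)
  for (i in 1:20) {
    x <- rnorm(50)
    # Oracle: position in the sorted vector (no ties almost surely).
    oracle <- match(x, sort(x))
    expect_equal(rank_transform(x), as.numeric(oracle))
  }
})

test_that("spearman recovers perfect monotone association", {
  expect_equal(spearman(1:4, c(2, 4, 6, 8))$r, 1)
  expect_equal(spearman(1:4, c(8, 6, 4, 2))$r, -1)
  expect_error(spearman(1:5, rep(2, 5)), "Constant")
  expect_error(spearman(1:2, 2:3), "n >= 3")
})

test_that("spearman is symmetric and invariant to increasing transforms", {
  set.seed(9)
  for (i in 1:10) {
    x <- rnorm(25); y <- rnorm(25)
    a <- spearman(x, y, p_method = "t")
    expect_equal(a$r, spearman(y, x, p_method = "t")$r)
    expect_equal(a$r, spearman(exp(x), y^3 + 10 * y, p_method = "t")$r)
  }
})

test_that("spearman matches the reference implementation's estimate and p-value", {
  set.seed(17)
  for (n in c(12, 30, 80)) {
    x <- rnorm(n); y <- 0.4 * x + rnorm(n)
    mine <- spearman(x, y, p_method = "t")
    ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                            exact = FALSE))
    expect_equal(mine$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("the exact small-n p-value matches the reference exact distribution", {
  set.seed(23)
  for (n in c(6, 7, 8)) {
    x <- rnorm(n); y <- rnorm(n)
    mine <- spearman(x, y) # auto: exact for n <= 8
    expect_identical(mine$p_method, "exact")
    ref <- stats::cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("partial_spearman handles degenerate and identity cases", {
  set.seed(2)
  x <- rnorm(10); z <- rnorm(10)
  expect_equal(partial_spearman(x, x, z, p_method = "t")$r, 1)
  expect_error(partial_spearman(x, rnorm(10), x), "rank-identical")
  expect_error(partial_spearman(1:3, 3:1, c(2, 1, 3)), "n >= 4")
})

test_that("partial_spearman is symmetric and transform-invariant", {
  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(20); y <- rnorm(20); z <- rnorm(20)
    a <- partial_spearman(x, y, z, p_method = "t")
    expect_equal(a$r, partial_spearman(y, x, z, p_method = "t")$r,
                 tolerance = 1e-12)
    b <- partial_spearman(exp(x), y^3 + y, atan(z), p_method = "t")
    expect_equal(a$r, b$r, tolerance = 1e-12)
    expect_equal(a$p, b$p, tolerance = 1e-12)
  }
})

test_that("partial_spearman matches the precision-matrix oracle", {
  set.seed(41)
  for (i in 1:25) {
    x <- rnorm(30); y <- rnorm(30); z <- rnorm(30)
    mine <- partial_spearman(x, y, z, p_method = "t")$r
    R <- stats::cor(cbind(rank(x), rank(y), rank(z)))
    P <- solve(R)
    oracle <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
    expect_equal(mine, oracle, tolerance = 1e-10)
  }
})

test_that("a rank-orthogonal controller reduces the partial to the simple coefficient", {
  # z is constructed so its ranks are uncorrelated with those of x and y.
  x <- 1:8
  y <- c(2, 1, 4, 3, 6, 5, 8, 7)
  z <- c(7, 5, 1, 2, 4, 8, 6, 3)
  expect_equal(cor(rank(z), rank(x)), 0)
  expect_equal(cor(rank(z), rank(y)), 0)
  expect_equal(partial_spearman(x, y, z, p_method = "t")$r,
               spearman(x, y, p_method = "t")$r, tolerance = 1e-12)
})

test_that("p-values are calibrated under independence", {
  set.seed(55)
  reps <- 1200
  rej_s <- logical(reps); rej_p <- logical(reps)
  for (i in seq_len(reps)) {
    x <- rnorm(30); y <- rnorm(30); z <- rnorm(30)
    rej_s[i] <- spearman(x, y, p_method = "t")$p < 0.05
    rej_p[i] <- partial_spearman(x, y, z, p_method = "t")$p < 0.05
  }
  expect_gt(mean(rej_s), 0.03); expect_lt(mean(rej_s), 0.07)
  expect_gt(mean(rej_p), 0.03); expect_lt(mean(rej_p), 0.07)
})

test_that("correlation_screen ranks a rank-identical category first", {
  set.seed(6)
  n <- 40
  q <- exp(rnorm(n)); mass <- exp(rnorm(n))
  profiles <- data.frame(
    perfect = rank(q) / (n + 1),
    noise1 = runif(n), noise2 = runif(n)
  )
  out <- correlation_screen(profiles, q, mass)
  expect_equal(out$category[1], "perfect")
  expect_equal(out$r_s[out$category == "perfect"], 1)
  expect_true(out$retained[out$category == "perfect"])
})

test_that("correlation_screen drops constant categories and tiny panels", {
  set.seed(61)
  profiles <- data.frame(flat = rep(0.2, 10), ok = runif(10))
  expect_warning(
    out <- correlation_screen(profiles, rnorm(10), runif(10),
                              keep_all = TRUE),
    "constant"
  )
  expect_false("flat" %in% out$category)
  expect_error(
    correlation_screen(data.frame(a = runif(3)), rnorm(3), runif(3)),
    "Fewer than 4"
  )
})

test_that("screen q-values are a BH adjustment of the partial p-values", {
  set.seed(71)
  profiles <- as.data.frame(matrix(runif(200), nrow = 20))
  out <- correlation_screen(profiles, rnorm(20), runif(20), keep_all = TRUE)
  expect_equal(out$q_value, p.adjust(out$p_partial, method = "BH"))
})

test_that("subgroup_partial reports per-level results and skips tiny groups", {
  set.seed(81)
  n <- 30
  d <- tibble::tibble(
    x = rnorm(n), y = rnorm(n), m = rnorm(n),
    flag = rep(c(TRUE, FALSE), c(10, 20))
  )
  out <- subgroup_partial(d, "x", "y", "m", "flag", p_method = "t")
  expect_setequal(out$level, c("TRUE", "FALSE"))
  expect_equal(out$n[out$level == "TRUE"], 10L)

  d2 <- d
  d2$flag <- rep(c(TRUE, FALSE), c(3, 27))
  expect_warning(out2 <- subgroup_partial(d2, "x", "y", "m", "flag",
                                          p_method = "t"),
                 "skipped")
  expect_equal(out2$level, "FALSE")

  d3 <- d
  d3$flag <- TRUE
  out3 <- subgroup_partial(d3, "x", "y", "m", "flag", p_method = "t")
  whole <- partial_spearman(d$x, d$y, d$m, p_method = "t")
  expect_equal(out3$r_s_partial, whole$r)
})

test_that("tidy and glance produce one-row summaries of rank correlations", {
  res <- spearman(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9), p_method = "t")
  td <- tidy(res)
  expect_equal(nrow(td), 1L)
  expect_named(td, c("estimate", "p.value", "n", "method", "controlled",
                     "statistic", "df", "p.method"))
  expect_equal(td$estimate, res$r)
  expect_equal(glance(res), td)
})
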