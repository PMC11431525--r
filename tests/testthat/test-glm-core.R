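test_that("intercept-only and tiny closed-form fits are exact", {
  d <- data.frame(y = c(3, 5, 7, 9), x1 = c(1, 2, 3, 4))
  g <- gram_cache(d, "y")
  f0 <- fit_subset(g, integer(0), lambda = 2)
  expect_equal(unname(f0$coefficients), mean(d$y))
  expect_equal(f0$rss, sum((d$y - mean(d$y))^2))

  d2 <- data.frame(y = c(-1, 1), x1 = c(0, 0.5))
  f2 <- fit_subset(gram_cache(d2, "y"), integer(0), lambda = 0)
  expect_equal(f2$rss, 2)
  expect_equal(f2$neg2ll, 2 * (log(2 * pi) + 1), tolerance = 1e-12)
  expect_equal(f2$neg2ll, 5.6757541, tolerance = 1e-6)
})

test_that("Gram-based fits match a dense least-squares oracle", {
  for (s in 1:100) {
    n <- sample(20:200, 1)
    p <- sample(2:10, 1)
    d <- rand_instance(n, p, seed = 1000 + s)
    X <- as.matrix(d[pred_names(d)])
    g <- gram_cache(d, "y")
    act <- sort(sample.int(p, sample.int(p, 1)))
    f <- fit_subset(g, act, lambda = 2)
    o <- oracle_fit(X, d$y, act)
    expect_equal(unname(f$coefficients), o$coef, tolerance = 1e-8)
    expect_equal(f$rss, o$rss, tolerance = 1e-8)
    expect_equal(f$neg2ll, o$neg2ll, tolerance = 1e-8)
    expect_equal(f$q, o$neg2ll + 2 * length(act), tolerance = 1e-8)
  }
})

test_that("adding a predictor never increases rss or -2logLik", {
  for (s in 1:25) {
    d <- rand_instance(50, 6, seed = 200 + s)
    g <- gram_cache(d, "y")
    act <- sort(sample.int(6, sample.int(4, 1)))
    extra <- sample(setdiff(1:6, act), 1)
    f1 <- fit_subset(g, act, lambda = 0)
    f2 <- fit_subset(g, sort(c(act, extra)), lambda = 0)
    expect_lte(f2$rss, f1$rss + 1e-10)
    expect_lte(f2$neg2ll, f1$neg2ll + 1e-8)
  }
})

test_that("rank-deficient subsets raise an error naming the column", {
  d <- rand_instance(30, 3, seed = 7)
  d$x3 <- d$x1 + d$x2  # exactly collinear
  g <- gram_cache(d, "y")
  expect_error(fit_subset(g, 1:3, lambda = 0), "rank-deficient")
  expect_error(fit_subset(g, 1:3, lambda = 0), "column")
  # subsets avoiding the collinearity still fit
  expect_s3_class(fit_subset(g, c(1, 2), lambda = 0), "subset_fit")
})

test_that("refreshing the response updates only the outcome cross-products", {
  d <- rand_instance(40, 4, seed = 11)
  g <- gram_cache_keep(d, "y")
  y2 <- rnorm(40)
  g2 <- refresh_y(g, y2)
  d2 <- d
  d2$y <- y2
  g_direct <- gram_cache(d2, "y")
  expect_equal(g2$G, g_direct$G, tolerance = 1e-10)
  m <- g$p + 2
  expect_equal(g2$G[-m, -m], g$G[-m, -m])  # X block untouched
})

test_that("squared Wald statistics equal squared t from a dense fit", {
  for (s in 1:10) {
    d <- rand_instance(40, 4, seed = 300 + s)
    fit <- lm(y ~ ., data = d)
    tsq <- summary(fit)$coefficients[-1, "t value"]^2
    for (j in 1:4) {
      expect_equal(wald_squared(d, "y", j), unname(tsq[j]), tolerance = 1e-8)
    }
  }
})

test_that("squared Wald statistics are invariant to predictor rescaling", {
  d <- rand_instance(60, 5, seed = 42)
  w1 <- wald_squared(d, "y", "x2")
  d2 <- d
  d2$x2 <- d2$x2 * 37.5
  expect_equal(wald_squared(d2, "y", "x2"), w1, tolerance = 1e-8)
})

test_that("multi-variable Wald quadratic form matches the textbook formula", {
  d <- rand_instance(50, 4, seed = 5)
  fit <- lm(y ~ ., data = d)
  b <- coef(fit)[c("x1", "x3")]
  V <- vcov(fit)[c("x1", "x3"), c("x1", "x3")]
  expect_equal(wald_squared(d, "y", c("x1", "x3")),
               as.numeric(t(b) %*% solve(V, b)), tolerance = 1e-8)
})

test_that("standardization is idempotent and rescales slopes by column sd", {
  d <- rand_instance(50, 4, seed = 9)
  s1 <- standardize_predictors(d, "y")
  s2 <- standardize_predictors(as.data.frame(s1), "y")
  expect_equal(as.matrix(s1[pred_names(d)]), as.matrix(s2[pred_names(d)]),
               tolerance = 1e-12)
  expect_identical(s1$y, d$y)

  raw <- best_subset(d, "y", "AIC")
  std <- best_subset(as.data.frame(s1), "y", "AIC")
  expect_identical(raw$active, std$active)
  expect_equal(raw$q, std$q, tolerance = 1e-8)
  scales <- attr(s1, "scaled_scale")
  for (v in raw$terms) {
    expect_equal(std$coefficients[[v]], raw$coefficients[[v]] * scales[[v]],
                 tolerance = 1e-8)
  }
})

test_that("constant predictor columns cannot be standardized", {
  d <- data.frame(y = rnorm(10), x1 = rnorm(10), x2 = 1)
  expect_error(standardize_predictors(d, "y"), "constant")
})

test_that("dataset validation reports missing and non-numeric cells", {
  d <- data.frame(y = c(1, NA, 3), x1 = c(1, 2, 3))
  expect_error(gram_cache(d, "y"), "row 2")
  d2 <- data.frame(y = c(1, 2), x1 = c("a", "b"), stringsAsFactors = FALSE)
  expect_error(gram_cache(d2, "y"), "non-numeric")
  expect_error(gram_cache(data.frame(y = 1:3), "z"), "not found")
})
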