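test_that("exhaustive search matches an independent enumeration oracle", {
  for (s in 1:20) {
    d <- rand_instance(60, 8, seed = 400 + s)
    X <- as.matrix(d[pred_names(d)])
    lam <- sample(c(2, log(60), 5), 1)
    f <- best_subset(d, "y", "custom", lambda = lam, engine = "exhaustive")
    o <- oracle_best_subset(X, d$y, lam)
    expect_identical(f$active, o$active)
    expect_equal(f$q, o$q, tolerance = 1e-8)
  }
})

test_that("a dominating penalty empties the model; zero penalty fills it", {
  d <- rand_instance(50, 3, seed = 1)
  f <- best_subset(d, "y", "custom", lambda = 10 * 50, engine = "exhaustive")
  expect_length(f$active, 0)
  f0 <- best_subset(d, "y", "custom", lambda = 0, engine = "exhaustive")
  expect_identical(f0$active, 1:3)
})

test_that("branch-and-bound agrees with exhaustive search across penalties", {
  lams <- function(n) c(2, log(n), 2 * log(log(n)))
  for (s in 1:60) {
    n <- sample(c(40, 100, 200), 1)
    p <- sample(6:12, 1)
    d <- rand_instance(n, p, seed = 500 + s, rho = sample(c(0, 0.5, 0.9), 1))
    lam <- sample(lams(n), 1)
    bb <- best_subset(d, "y", "custom", lambda = lam, engine = "branch_and_bound")
    ex <- best_subset(d, "y", "custom", lambda = lam, engine = "exhaustive")
    expect_identical(bb$active, ex$active)
    expect_equal(bb$q, ex$q, tolerance = 1e-10)
  }
})

test_that("branch-and-bound prunes (visits fewer nodes than enumeration)", {
  d <- rand_instance(150, 12, seed = 77)
  bb <- best_subset(d, "y", "BIC", engine = "branch_and_bound")
  ex <- best_subset(d, "y", "BIC", engine = "exhaustive")
  expect_lt(bb$nodes_visited, ex$nodes_visited)
})

test_that("force-in/force-out constraints are always respected", {
  for (eng in c("exhaustive", "branch_and_bound", "forward", "backward")) {
    d <- rand_instance(60, 6, seed = 21)
    f <- best_subset(d, "y", "AIC", engine = eng,
                     force_in = "x2", force_out = c("x5", "x6"))
    expect_true(2 %in% f$active)
    expect_false(any(c(5, 6) %in% f$active))
  }
  d <- rand_instance(60, 6, seed = 21)
  expect_error(best_subset(d, "y", "AIC", force_in = "x1", force_out = "x1"),
               "disjoint")
  # constrained optimum matches the constrained oracle
  X <- as.matrix(d[pred_names(d)])
  f <- best_subset(d, "y", "AIC", engine = "exhaustive",
                   force_in = 2, force_out = c(5, 6))
  o <- oracle_best_subset(X, d$y, 2, forced_in = 2, forced_out = c(5, 6))
  expect_identical(f$active, o$active)
})

test_that("zero free variables returns the forced-in fit directly", {
  d <- rand_instance(30, 3, seed = 3)
  f <- best_subset(d, "y", "AIC", engine = "branch_and_bound",
                   force_in = c(1, 2), force_out = 3)
  expect_identical(f$active, 1:2)
  g <- gram_cache(d, "y")
  expect_equal(f$q, fit_subset(g, 1:2, 2)$q, tolerance = 1e-10)
})

test_that("greedy heuristics are exact on orthogonal designs and bounded otherwise", {
  # orthogonal columns: greedy forward recovers the exact optimum
  n <- 64
  X <- qr.Q(qr(matrix(rnorm(n * 5), n, 5))) * sqrt(n)
  colnames(X) <- paste0("x", 1:5)
  set.seed(8)
  y <- 1.5 * X[, 1] - 1 * X[, 4] + rnorm(n)
  d <- data.frame(y = y, X)
  fwd <- best_subset(d, "y", "AIC", engine = "forward")
  ex <- best_subset(d, "y", "AIC", engine = "exhaustive")
  expect_identical(fwd$active, ex$active)

  # heuristic Q is an upper bound on the exact minimum
  for (s in 1:15) {
    d <- rand_instance(60, 8, seed = 600 + s, rho = 0.7)
    ex <- best_subset(d, "y", "AIC", engine = "exhaustive")
    for (eng in c("forward", "backward")) {
      h <- best_subset(d, "y", "AIC", engine = eng)
      expect_gte(h$q, ex$q - 1e-9)
    }
  }
})

test_that("forward selection with an infinite-like penalty keeps only forced-in", {
  d <- rand_instance(50, 5, seed = 13)
  f <- best_subset(d, "y", "custom", lambda = 1e6, engine = "forward",
                   force_in = "x3")
  expect_identical(f$active, 3L)
})

test_that("selected model size is non-increasing in the penalty", {
  d <- rand_instance(120, 8, seed = 31, rho = 0.4)
  sizes <- vapply(c(0, 0.5, 1, 2, 4, 8, 16, 32, 64),
                  function(l) length(best_subset(d, "y", "custom", lambda = l,
                                                 engine = "exhaustive")$active),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("the exhaustive guard points to branch and bound", {
  d <- rand_instance(40, 3, seed = 2)
  g <- gram_cache(d, "y")
  fake <- g
  expect_error(
    subsetvi:::`.cpp_search`(g$G, g$n, 2, integer(0), integer(0), "bogus"),
    "unknown engine")
  # guard is on the number of free variables, checked in the C++ layer
  big <- rand_instance(60, 26, seed = 2)
  expect_error(best_subset(big, "y", "AIC", engine = "exhaustive"),
               "branch_and_bound")
})

test_that("tidy() and glance() summarise a fit", {
  d <- rand_instance(50, 4, seed = 17)
  f <- best_subset(d, "y", "BIC")
  td <- tidy(f)
  expect_s3_class(td, "tbl_df")
  expect_identical(td$term[1], "(Intercept)")
  gl <- glance(f)
  expect_identical(gl$criterion, "BIC")
  expect_equal(gl$q, f$q)
  expect_equal(gl$n_selected, length(f$active))
})
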