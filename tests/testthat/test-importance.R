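test_that("VI matches brute-force enumeration split by group membership", {
  for (s in 1:10) {
    d <- rand_instance(100, 6, seed = 700 + s, rho = sample(c(0, 0.6), 1))
    X <- as.matrix(d[pred_names(d)])
    lam <- sample(c(2, log(100)), 1)
    grp <- sort(sample.int(6, sample.int(2, 1)))
    rec <- variable_importance(d, "y", grp, criterion = "custom", lambda = lam,
                               engine = "exhaustive")
    o <- oracle_vi(X, d$y, lam, grp)
    expect_equal(rec$vi, o$vi, tolerance = 1e-8)
    expect_equal(rec$mvi, o$mvi, tolerance = 1e-8)
    expect_equal(rec$q_excluded, o$q_excluded, tolerance = 1e-8)
    expect_equal(rec$q_included, o$q_included, tolerance = 1e-8)
  }
})

test_that("with zero penalty VI is the likelihood-ratio statistic for one drop", {
  d <- rand_instance(80, 5, seed = 23)
  full <- lm(y ~ ., data = d)
  red <- lm(y ~ . - x2, data = d)
  n <- nrow(d)
  lrt <- n * log(sum(resid(red)^2) / sum(resid(full)^2))
  rec <- variable_importance(d, "y", "x2", criterion = "custom", lambda = 0)
  expect_equal(rec$vi, lrt, tolerance = 1e-8)
  expect_equal(rec$mvi, rec$vi)  # lambda = 0
})

test_that("mVI >= 0 and VI >= -lambda|S| for exact engines (Theorem 1 bounds)", {
  for (s in 1:40) {
    n <- sample(c(30, 80), 1)
    d <- rand_instance(n, 6, seed = 800 + s, rho = sample(c(0, 0.9), 1))
    lam <- sample(c(0, 2, log(n), 10), 1)
    grp <- sort(sample.int(6, sample.int(3, 1)))
    rec <- variable_importance(d, "y", grp, criterion = "custom", lambda = lam,
                               engine = "exhaustive")
    expect_gte(rec$mvi, -1e-8)
    expect_gte(rec$vi, -lam * length(grp) - 1e-8)
  }
})

test_that("VI sign is coupled to membership in the unconstrained optimum", {
  for (s in 1:20) {
    d <- rand_instance(70, 6, seed = 900 + s, rho = 0.5)
    opt <- best_subset(d, "y", "BIC", engine = "exhaustive")
    for (v in sample.int(6, 3)) {
      rec <- variable_importance(d, "y", v, criterion = "BIC",
                                 engine = "exhaustive")
      expect_identical(rec$selected, v %in% opt$active)
      if (rec$vi > 1e-9) expect_true(v %in% opt$active)
      if (rec$vi < -1e-9) expect_false(v %in% opt$active)
    }
  }
})

test_that("VI is invariant to standardizing the predictors", {
  d <- rand_instance(60, 5, seed = 37)
  s <- as.data.frame(standardize_predictors(d, "y"))
  for (v in c("x1", "x4")) {
    r1 <- variable_importance(d, "y", v, criterion = "BIC")
    r2 <- variable_importance(s, "y", v, criterion = "BIC")
    expect_equal(r1$vi, r2$vi, tolerance = 1e-7)
    expect_equal(r1$mvi, r2$mvi, tolerance = 1e-7)
  }
})

test_that("modified_importance validates the penalty and applies the shift", {
  d <- rand_instance(50, 4, seed = 3)
  pen <- penalty_value("BIC", n = 50)
  rec <- variable_importance(d, "y", "x1", criterion = pen)
  expect_equal(modified_importance(rec, pen), rec$vi + pen$lambda)
  expect_equal(modified_importance(rec, pen), rec$mvi)
  expect_error(modified_importance(rec, penalty_value("AIC")), "mismatch")
})

test_that("importance_table reproduces per-group records and flags selection", {
  d <- rand_instance(80, 5, seed = 57)
  tab <- importance_table(d, "y", criteria = c("AIC", "BIC"))
  expect_identical(tab$group, paste0("x", 1:5))
  for (i in c(1, 3, 5)) {
    rec <- variable_importance(d, "y", i, criterion = "AIC")
    expect_equal(tab$vi_AIC[i], rec$vi, tolerance = 1e-10)
    expect_equal(tab$mvi_AIC[i], rec$mvi, tolerance = 1e-10)
    expect_identical(tab$in_AIC[i], rec$selected)
    expect_equal(tab$wald[i], wald_squared(d, "y", i), tolerance = 1e-10)
  }
})

test_that("groupings must be disjoint, non-empty and known", {
  d <- rand_instance(50, 4, seed = 5)
  expect_error(importance_table(d, "y", groups = list(a = "x1", b = "x1")),
               "disjoint")
  expect_error(importance_table(d, "y", groups = list(a = character(0))),
               "non-empty")
  expect_error(importance_table(d, "y", groups = list(a = "nope")), "unknown")
  tab <- importance_table(d, "y", groups = list(pair = c("x1", "x2"), x4 = "x4"),
                          criteria = "AIC")
  expect_identical(tab$group, c("pair", "x4"))
  rec <- variable_importance(d, "y", c("x1", "x2"), criterion = "AIC")
  expect_equal(tab$mvi_AIC[1], rec$mvi, tolerance = 1e-10)
})

test_that("group members may not overlap the forced sets", {
  d <- rand_instance(50, 4, seed = 6)
  expect_error(variable_importance(d, "y", "x1", force_in = "x1"), "disjoint")
})

test_that("heuristic engines warn that the mVI bound is not guaranteed", {
  d <- rand_instance(50, 4, seed = 8)
  expect_warning(variable_importance(d, "y", "x1", engine = "forward"),
                 "heuristic")
})
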