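test_that("the published equation evaluates by plain linear arithmetic", {
  m <- published_concentration_model()
  zero <- c(ClogP = 0, FNSA3 = 0, FPSA3 = 0, RPCG = 0)
  expect_equal(apply_linear_model(m, zero), 6.105)
  expect_equal(apply_linear_model(m, c(ClogP = 1, FNSA3 = 0, FPSA3 = 0, RPCG = 0)),
               6.536)  # 6.105 + 0.431
  expect_equal(apply_linear_model(m, c(ClogP = 0, FNSA3 = 0, FPSA3 = 0, RPCG = 1)),
               0.772)  # 6.105 - 5.333
  expect_error(apply_linear_model(m, c(ClogP = 1)), "FNSA3")
  # linearity: f(x + y) = f(x) + f(y) - intercept
  set.seed(1)
  x <- setNames(rnorm(4), names(m$terms))
  y <- setNames(rnorm(4), names(m$terms))
  expect_equal(apply_linear_model(m, x + y),
               apply_linear_model(m, x) + apply_linear_model(m, y) - m$intercept)
  # data-frame input vectorises
  df <- as.data.frame(rbind(zero, zero))
  expect_equal(apply_linear_model(m, df), c(6.105, 6.105))
})

test_that("linear models round-trip losslessly through JSON", {
  m <- published_concentration_model()
  path <- tempfile(fileext = ".json")
  write_linear_model(m, path)
  expect_equal(read_linear_model(path), m)
})

test_that("stepwise regression recovers a noiseless single predictor exactly", {
  set.seed(21)
  X <- as.data.frame(matrix(rnorm(50 * 10), 50, 10,
                            dimnames = list(NULL, paste0("x", 1:10))))
  y <- 2 + 3 * X$x1
  m <- stepwise_mlr(X, y)
  expect_equal(names(m$terms), "x1")
  expect_equal(m$intercept, 2, tolerance = 1e-8)
  expect_equal(unname(m$terms["x1"]), 3, tolerance = 1e-8)
})

test_that("under the null the stepwise entry rate is controlled at p_enter", {
  set.seed(99)
  entered <- 0
  for (s in 1:40) {
    X <- as.data.frame(matrix(rnorm(60 * 8), 60, 8,
                              dimnames = list(NULL, paste0("x", 1:8))))
    y <- rnorm(60)
    m <- stepwise_mlr(X, y)
    entered <- entered + (length(m$terms) > 0)
  }
  # family-wise entry probability ~0.05 per run; 40 null runs should rarely
  # show more than a handful of non-empty selections
  expect_lte(entered, 7)
})

test_that("zero-variance candidates are dropped with a warning", {
  X <- data.frame(x1 = rnorm(30), flat = rep(1, 30))
  y <- 1 + 2 * X$x1 + rnorm(30, 0, 0.1)
  expect_warning(m <- stepwise_mlr(X, y), "flat")
  expect_equal(names(m$terms), "x1")
})

test_that("SVR respects the epsilon tube and is invariant to data duplication", {
  spec <- svr_spec(gamma = 0.1, epsilon = 0.2, cost = 5)
  # single training point: prediction within epsilon of its target
  one <- fit_svr(spec, data.frame(a = 1, b = 2), 3.5)
  expect_lte(abs(predict(one, data.frame(a = 1, b = 2)) - 3.5), 0.2)
  set.seed(4)
  X <- data.frame(a = rnorm(12), b = rnorm(12))
  y <- X$a - X$b + rnorm(12, 0, 0.1)
  # a cost high enough that no box constraint binds: the solution then
  # depends only on the point set, so duplicating the data changes nothing
  big <- svr_spec(gamma = 0.1, epsilon = 0.2, cost = 1e4)
  m1 <- fit_svr(big, X, y, tolerance = 1e-8)
  m2 <- fit_svr(big, rbind(X, X), c(y, y), tolerance = 1e-8)
  expect_equal(predict(m1, X), predict(m2, X), tolerance = 1e-4)
  # feature order never matters (tight optimiser tolerance so the SMO
  # iteration order cannot leak into the comparison)
  ma <- fit_svr(spec, X, y, tolerance = 1e-10)
  mb <- fit_svr(spec, X[, c("b", "a")], y, tolerance = 1e-10)
  expect_equal(predict(ma, X), predict(mb, X), tolerance = 1e-6)
  expect_error(fit_svr(spec, data.frame(a = c(1, NA)), c(1, 2)), "non-finite")
})

test_that("SVR solves the same dual problem as an independent solver", {
  skip_if_not_installed("kernlab")
  set.seed(8)
  X <- data.frame(u = rnorm(15), v = rnorm(15))
  y <- sin(X$u) + 0.3 * X$v
  # standardise with the population sd so fit_svr's internal transform is
  # the identity and both solvers optimise the identical dual problem
  Xs <- as.data.frame(lapply(X, function(col) {
    (col - mean(col)) / sqrt(mean((col - mean(col))^2))
  }))
  spec <- svr_spec(gamma = 0.5, epsilon = 0.1, cost = 10)
  mine <- predict(fit_svr(spec, Xs, y, tolerance = 1e-8), Xs)
  ref <- kernlab::ksvm(as.matrix(Xs), y, type = "eps-svr",
                       kernel = "rbfdot", kpar = list(sigma = 0.5),
                       C = 10, epsilon = 0.1, scaled = FALSE, tol = 1e-8)
  expect_equal(mine, as.vector(kernlab::predict(ref, as.matrix(Xs))),
               tolerance = 1e-4)
})

test_that("LOOCV equals the brute-force refit loop for a linear fitter", {
  set.seed(15)
  X <- data.frame(x = rnorm(5))
  y <- 1 + 2 * X$x + rnorm(5, 0, 0.3)
  lm_fitter <- function(Xtr, ytr) {
    fit <- lm(ytr ~ x, data = Xtr)
    structure(list(fit = fit), class = "lmwrap")
  }
  assign("predict.lmwrap",
         function(object, newdata, ...) unname(predict(object$fit, newdata)),
         envir = globalenv())
  on.exit(rm("predict.lmwrap", envir = globalenv()))
  rep <- loocv(lm_fitter, X, y)
  # independent oracle: explicit five separate refits
  manual <- vapply(1:5, function(i) {
    fit <- lm(y[-i] ~ x, data = X[-i, , drop = FALSE])
    unname(predict(fit, X[i, , drop = FALSE]))
  }, numeric(1))
  expect_equal(rep$predictions$predicted, manual, tolerance = 1e-12)
  expect_equal(rep$total_mse, mean((y - manual)^2), tolerance = 1e-12)
  expect_equal(rep$squared_correlation, cor(y, manual)^2, tolerance = 1e-12)
})

test_that("perfect and constant predictors give the boundary CV scores", {
  expect_equal(cv_report(1:10, 1:10)$squared_correlation, 1)
  expect_equal(cv_report(1:10, 1:10)$total_mse, 0)
  expect_warning(r <- cv_report(c(1, 2, 3), c(2, 2, 2)), "constant")
  expect_equal(r$squared_correlation, 0)
  # through-origin slope: sum(pred * y) / sum(y^2)
  r2 <- cv_report(c(1, 2, 3), c(1.1, 1.9, 3.2))
  expect_equal(r2$identity_slope,
               sum(c(1.1, 1.9, 3.2) * c(1, 2, 3)) / sum(c(1, 2, 3)^2))
})

test_that("grid search is exhaustive, deterministic and monotone in grid size", {
  set.seed(2)
  X <- data.frame(a = rnorm(14))
  y <- X$a^2 + rnorm(14, 0, 0.2)
  single <- grid_search(svr_spec(), X, y, gamma_grid = 0.5,
                        epsilon_grid = 0.1, cost_grid = 2)
  expect_equal(single$spec$gamma, 0.5)
  expect_equal(single$spec$cost, 2)
  expect_equal(nrow(single$grid), 1)
  small <- grid_search(svr_spec(), X, y, gamma_grid = c(0.1, 1),
                       epsilon_grid = 0.1, cost_grid = c(1, 5))
  large <- grid_search(svr_spec(), X, y, gamma_grid = c(0.01, 0.1, 1, 10),
                       epsilon_grid = c(0.05, 0.1), cost_grid = c(1, 5, 20))
  expect_gte(large$report$squared_correlation,
             small$report$squared_correlation)
})

test_that("grid search recovers the generating kernel width to one grid step", {
  set.seed(31)
  x <- seq(-3, 3, length.out = 30)
  centres <- c(-2, 0, 1.5)
  gamma0 <- 0.5
  y <- rowSums(vapply(centres, function(c0) exp(-gamma0 * (x - c0)^2),
                      numeric(30))) + rnorm(30, 0, 0.03)
  gs <- grid_search(svr_spec(), data.frame(x = scale(x)[, 1]), y,
                    gamma_grid = c(0.005, 0.05, 0.5, 5, 50),
                    epsilon_grid = 0.05, cost_grid = 10)
  expect_true(gs$spec$gamma %in% c(0.05, 0.5, 5))
})

test_that("deleting the load-bearing feature hurts most", {
  set.seed(12)
  X <- data.frame(A = rnorm(30), B = rnorm(30))
  y <- 2 * X$A + rnorm(30, 0, 0.2)
  imp <- descriptor_importance(svr_spec(), X, y, gamma_grid = c(0.1, 1),
                               epsilon_grid = 0.1, cost_grid = c(1, 10))
  expect_equal(nrow(imp), 2)
  expect_equal(imp$deleted[1], "A")  # sorted ascending: most important first
  expect_lt(imp$squared_correlation[imp$deleted == "A"],
            imp$squared_correlation[imp$deleted == "B"])
})

test_that("concentration tables derive -Log10 C consistently", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("id\tconcentration", "a\t0.001", "b\t1e-06"), path)
  d <- read_concentrations(path)
  expect_equal(d$neg_log_c, c(3, 6), tolerance = 1e-9)
  writeLines(c("id\tconcentration", "a\t-1"), path)
  expect_error(read_concentrations(path), "positive")
})
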