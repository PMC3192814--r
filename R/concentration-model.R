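# Metabolite concentration models: the published polarity equation,
# stepwise multiple linear regression, epsilon-SVR with LOOCV, grid search
# and descriptor-deletion importance.

#' Construct a linear concentration model
#'
#' @param intercept Numeric intercept.
#' @param terms Named numeric vector of coefficients (unique names).
#' @return Object of class `"linear_model"`.
#' @export
linear_model <- function(intercept, terms) {
  stopifnot(is.numeric(intercept), length(intercept) == 1)
  terms <- unlist(terms)
  if (length(terms) > 0 &&
      (is.null(names(terms)) || anyDuplicated(names(terms)) ||
       any(!nzchar(names(terms))))) {
    stop("model terms must have unique non-empty names")
  }
  structure(list(intercept = unname(intercept), terms = terms),
            class = "linear_model")
}

#' The published polarity equation for metabolite concentration
#'
#' The reported stepwise-regression equation linking the negative decadic
#' logarithm of metabolite concentration (mol/L) to four polarity
#' descriptors:
#' `-LogC = 6.105 + 0.431 ClogP + 15.595 FNSA3 + 16.727 FPSA3 - 5.333 RPCG`.
#' Shipped as a constant evaluator (it is a published fit, not refit here).
#'
#' @return A `"linear_model"`.
#' @export
published_concentration_model <- function() {
  linear_model(6.105, c(ClogP = 0.431, FNSA3 = 15.595,
                        FPSA3 = 16.727, RPCG = -5.333))
}

#' Evaluate a linear model on descriptor values
#'
#' @param model A `"linear_model"`.
#' @param x Named numeric vector/list, or a data frame with one column per
#'   model term (one prediction per row).
#' @return Numeric prediction(s): `intercept + sum(coefficient * value)`.
#' @export
apply_linear_model <- function(model, x) {
  stopifnot(inherits(model, "linear_model"))
  nm <- names(model$terms)
  if (is.data.frame(x)) {
    missing <- setdiff(nm, names(x))
    if (length(missing) > 0) {
      stop("missing descriptor(s): ", paste(missing, collapse = ", "))
    }
    if (length(nm) == 0) return(rep(model$intercept, nrow(x)))
    return(model$intercept +
             as.vector(as.matrix(x[, nm, drop = FALSE]) %*% model$terms))
  }
  x <- unlist(x)
  missing <- setdiff(nm, names(x))
  if (length(missing) > 0) {
    stop("missing descriptor(s): ", paste(missing, collapse = ", "))
  }
  unname(model$intercept + sum(model$terms * x[nm]))
}

#' @export
print.linear_model <- function(x, ...) {
  rhs <- if (length(x$terms) == 0) "" else paste(
    sprintf(" %+.4g * %s", x$terms, names(x$terms)), collapse = "")
  cat(sprintf("-LogC = %.4g%s\n", x$intercept, rhs))
  invisible(x)
}

#' Write/read a linear model as JSON (lossless round trip)
#'
#' @param model A `"linear_model"`.
#' @param path File path.
#' @name linear-model-io
#' @export
write_linear_model <- function(model, path) {
  jsonlite::write_json(list(intercept = model$intercept,
                            terms = as.list(model$terms)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname linear-model-io
#' @export
read_linear_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  linear_model(obj$intercept, unlist(obj$terms))
}

#' Stepwise multiple linear regression by partial-F tests
#'
#' Forward selection with backward elimination. At each forward step every
#' remaining candidate is tested by its partial F (equivalently the squared
#' t statistic of its coefficient when added to the current model); the best
#' candidate enters if its p-value clears `p_enter`. After each entry,
#' terms whose retention p-value exceeds `p_remove` are eliminated (worst
#' first). Iteration stops when no term can enter or leave.
#'
#' By default the entry p-value is Bonferroni-adjusted for the number of
#' candidates examined at that step, so the family-wise probability of
#' admitting a pure-noise candidate at any step is `p_enter` itself --
#' under a null model the expected rate of non-empty selections then
#' matches `p_enter` and support recovery is reliable even with many decoy
#' descriptors. `adjust = "none"` gives the classical per-candidate
#' behaviour.
#'
#' Constant (zero-variance) candidates are dropped with a warning before
#' selection; a candidate producing a singular fit at some step is skipped
#' at that step with a warning.
#'
#' @param X Data frame or matrix of candidate predictors (named columns).
#' @param y Numeric response (here: -Log10 concentration).
#' @param p_enter,p_remove Probability-of-F thresholds (defaults 0.05/0.10).
#' @param adjust `"bonferroni"` (default) or `"none"` multiplicity handling
#'   for the entry test.
#' @return A `"linear_model"` fitted by least squares on the selected terms,
#'   with attributes `trace` (selection history) and `fit` (the final
#'   [stats::lm()] object).
#' @export
stepwise_mlr <- function(X, y, p_enter = 0.05, p_remove = 0.10,
                         adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  X <- as.data.frame(X)
  stopifnot(nrow(X) == length(y))
  const <- vapply(X, function(col) stats::sd(col) == 0 || anyNA(col), logical(1))
  if (any(const)) {
    warning("dropping zero-variance candidate(s): ",
            paste(names(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  candidates <- names(X)
  selected <- character(0)
  trace <- list()

  term_p <- function(vars) {
    # retention p-value of each term in the model y ~ vars (1-df partial F);
    # summary.lm's perfect-fit warning is expected on noiseless data
    fit <- stats::lm(y ~ ., data = X[, vars, drop = FALSE])
    sm <- suppressWarnings(summary(fit)$coefficients)
    p <- rep(NA_real_, length(vars))
    names(p) <- vars
    hit <- intersect(vars, rownames(sm))
    p[hit] <- sm[hit, 4]
    p
  }

  repeat {
    changed <- FALSE
    remaining <- setdiff(candidates, selected)
    if (length(remaining) > 0 && length(selected) + 2 < length(y)) {
      entry_p <- vapply(remaining, function(v) {
        fit <- stats::lm(y ~ ., data = X[, c(selected, v), drop = FALSE])
        co <- suppressWarnings(summary(fit)$coefficients)
        if (!(v %in% rownames(co)) || anyNA(stats::coef(fit))) {
          warning("singular fit; skipping candidate ", v, " at this step")
          return(NA_real_)
        }
        co[v, 4]
      }, numeric(1))
      if (any(!is.na(entry_p))) {
        best <- names(which.min(entry_p))
        thr <- if (adjust == "bonferroni") p_enter / sum(!is.na(entry_p)) else p_enter
        if (entry_p[best] < thr) {
          selected <- c(selected, best)
          trace[[length(trace) + 1]] <- list(action = "enter", term = best,
                                             p = unname(entry_p[best]))
          changed <- TRUE
        }
      }
    }
    if (length(selected) > 0) {
      repeat {
        p <- term_p(selected)
        worst <- names(which.max(p))
        if (length(worst) == 1 && !is.na(p[worst]) && p[worst] > p_remove) {
          selected <- setdiff(selected, worst)
          trace[[length(trace) + 1]] <- list(action = "remove", term = worst,
                                             p = unname(p[worst]))
          changed <- TRUE
          if (length(selected) == 0) break
        } else break
      }
    }
    if (!changed) break
  }

  if (length(selected) == 0) {
    fit <- stats::lm(y ~ 1)
    model <- linear_model(mean(y), stats::setNames(numeric(0), character(0)))
  } else {
    fit <- stats::lm(y ~ ., data = X[, selected, drop = FALSE])
    cf <- stats::coef(fit)
    model <- linear_model(cf[["(Intercept)"]], cf[selected])
  }
  attr(model, "trace") <- trace
  attr(model, "fit") <- fit
  model
}

#' Specify an epsilon-SVR model
#'
#' Radial-basis-function support vector regression,
#' `k(u, v) = exp(-gamma * ||u - v||^2)`, with epsilon-insensitive loss.
#' Defaults are the published optimum of the concentration model
#' (gamma 0.01, epsilon 0.22, cost 7.9).
#'
#' @param gamma RBF kernel width (> 0).
#' @param epsilon Insensitive-tube half-width (>= 0).
#' @param cost Box constraint C (> 0).
#' @param features Optional character vector restricting which columns of a
#'   feature table the model uses.
#' @return Object of class `"svr_spec"`.
#' @export
svr_spec <- function(gamma = 0.01, epsilon = 0.22, cost = 7.9,
                     features = NULL) {
  stopifnot(gamma > 0, epsilon >= 0, cost > 0)
  structure(list(gamma = gamma, epsilon = epsilon, cost = cost,
                 features = features), class = "svr_spec")
}

.spec_features <- function(spec, X) {
  X <- as.data.frame(X)
  if (!is.null(spec$features)) {
    missing <- setdiff(spec$features, names(X))
    if (length(missing) > 0) {
      stop("feature(s) not in table: ", paste(missing, collapse = ", "))
    }
    X <- X[, spec$features, drop = FALSE]
  }
  X
}

#' Fit an epsilon-SVR model
#'
#' Features are z-standardised on the training data (centred, divided by
#' the population standard deviation) and the same transform is applied at
#' prediction time; an unscaled RBF kernel over mixed-unit features would
#' be dominated by the widest-ranging column. The population (1/n)
#' standard deviation makes the transform invariant under duplication of
#' the training set. The response is left in its own units, so `epsilon`
#' is an insensitivity band on the response scale.
#'
#' @param spec An [svr_spec()].
#' @param X Feature data frame/matrix.
#' @param y Numeric response.
#' @param tolerance Optimiser termination tolerance (forwarded to
#'   [e1071::svm()]).
#' @return Object of class `"svr_model"` with a [predict()] method.
#' @export
fit_svr <- function(spec, X, y, tolerance = 0.001) {
  stopifnot(inherits(spec, "svr_spec"))
  X <- .spec_features(spec, X)
  if (!all(is.finite(as.matrix(X))) || !all(is.finite(y))) {
    stop("non-finite feature or response values")
  }
  if (nrow(X) == 1) {
    # degenerate single-point training set: the constant predictor y sits
    # inside the epsilon tube
    return(structure(list(constant = y[1], features = names(X)),
                     class = "svr_model"))
  }
  centre <- vapply(X, mean, numeric(1))
  pop_sd <- vapply(X, function(col) sqrt(mean((col - mean(col))^2)), numeric(1))
  pop_sd[pop_sd == 0] <- 1  # constant columns pass through unchanged
  Xs <- sweep(sweep(as.matrix(X), 2, centre), 2, pop_sd, "/")
  fit <- e1071::svm(x = Xs, y = y, type = "eps-regression",
                    kernel = "radial", gamma = spec$gamma,
                    epsilon = spec$epsilon, cost = spec$cost,
                    scale = FALSE, tolerance = tolerance)
  structure(list(fit = fit, features = names(X), centre = centre,
                 pop_sd = pop_sd),
            class = "svr_model")
}

#' @export
predict.svr_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  missing <- setdiff(object$features, names(newdata))
  if (length(missing) > 0) {
    stop("feature(s) not in newdata: ", paste(missing, collapse = ", "))
  }
  newdata <- newdata[, object$features, drop = FALSE]
  if (!is.null(object$constant)) return(rep(object$constant, nrow(newdata)))
  Xs <- sweep(sweep(as.matrix(newdata), 2, object$centre), 2, object$pop_sd, "/")
  unname(stats::predict(object$fit, Xs))
}

#' Leave-one-out cross validation
#'
#' For each observation i, the model is trained on all other observations
#' and predicts y_i. The report scores held-out predictions by the squared
#' Pearson correlation with the observed response and by the plain mean of
#' squared residuals, and also records the through-origin regression slope
#' `sum(pred * y) / sum(y^2)` of predictions on observations. Constant
#' predictions make the correlation undefined; it is reported as 0 with a
#' warning.
#'
#' `spec` may be an [svr_spec()] or any function `f(X, y)` returning an
#' object with a `predict(object, newdata)` method (e.g. a linear-model
#' fitter), so the same CV machinery scores every model family.
#'
#' @param spec Model specification or fitter function.
#' @param X Feature data frame/matrix (n >= 3 rows).
#' @param y Numeric response.
#' @return Object of class `"cv_report"`: list with `squared_correlation`,
#'   `total_mse`, `identity_slope` and `predictions` (data frame
#'   `index`/`observed`/`predicted`).
#' @export
loocv <- function(spec, X, y) {
  X <- as.data.frame(X)
  n <- nrow(X)
  stopifnot(n == length(y))
  if (n < 3) stop("need n >= 3 for leave-one-out cross validation")
  fit_fun <- if (inherits(spec, "svr_spec")) {
    function(Xtr, ytr) fit_svr(spec, Xtr, ytr)
  } else if (is.function(spec)) {
    spec
  } else stop("spec must be an svr_spec or a fitter function")
  preds <- numeric(n)
  for (i in seq_len(n)) {
    m <- fit_fun(X[-i, , drop = FALSE], y[-i])
    preds[i] <- stats::predict(m, X[i, , drop = FALSE])[1]
  }
  cv_report(y, preds)
}

#' Build a cross-validation report from observed/predicted pairs
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return A `"cv_report"` (see [loocv()]).
#' @export
cv_report <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    warning("constant predictions or observations; squared correlation reported 0")
    r2 <- 0
  } else {
    r2 <- stats::cor(observed, predicted)^2
  }
  structure(list(squared_correlation = r2,
                 total_mse = mean((observed - predicted)^2),
                 identity_slope = sum(predicted * observed) / sum(observed^2),
                 predictions = data.frame(index = seq_along(observed),
                                          observed = observed,
                                          predicted = predicted)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("LOOCV: squared correlation = %.4f, total MSE = %.4f, slope through origin = %.4f (n = %d)\n",
              x$squared_correlation, x$total_mse, x$identity_slope,
              nrow(x$predictions)))
  invisible(x)
}

#' Exhaustive grid search over SVR parameters
#'
#' Evaluates every (gamma, epsilon, cost) cell by [loocv()] and returns the
#' best specification: highest squared correlation, ties broken by lower
#' total MSE, then by smaller cost. The default grids bracket the published
#' optimum (0.01, 0.22, 7.9).
#'
#' @param spec Template [svr_spec()] (carries the feature restriction).
#' @param X,y Training data.
#' @param gamma_grid,epsilon_grid,cost_grid Non-empty numeric grids.
#' @return List with `spec` (best [svr_spec()]), `report` (its
#'   `"cv_report"`) and `grid` (data frame of every cell's metrics).
#' @export
grid_search <- function(spec, X, y,
                        gamma_grid = 10^seq(-3, 1),
                        epsilon_grid = seq(0.01, 0.5, by = 0.03),
                        cost_grid = seq(0.1, 10, by = 0.3)) {
  stopifnot(length(gamma_grid) > 0, length(epsilon_grid) > 0,
            length(cost_grid) > 0)
  cells <- expand.grid(gamma = gamma_grid, epsilon = epsilon_grid,
                       cost = cost_grid, KEEP.OUT.ATTRS = FALSE)
  best <- NULL
  best_report <- NULL
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cand <- svr_spec(cells$gamma[i], cells$epsilon[i], cells$cost[i],
                     features = spec$features)
    rep_i <- suppressWarnings(loocv(cand, X, y))
    rows[[i]] <- data.frame(gamma = cand$gamma, epsilon = cand$epsilon,
                            cost = cand$cost,
                            squared_correlation = rep_i$squared_correlation,
                            total_mse = rep_i$total_mse)
    better <- is.null(best) ||
      rep_i$squared_correlation > best_report$squared_correlation ||
      (rep_i$squared_correlation == best_report$squared_correlation &&
         (rep_i$total_mse < best_report$total_mse ||
            (rep_i$total_mse == best_report$total_mse &&
               cand$cost < best$cost)))
    if (better) {
      best <- cand
      best_report <- rep_i
    }
  }
  list(spec = best, report = best_report, grid = do.call(rbind, rows))
}

#' Descriptor-deletion importance for an SVR model
#'
#' Deletes one feature at a time, re-optimises the reduced model by
#' [grid_search()] + [loocv()], and ranks features by the resulting squared
#' correlation: the lower the score after deletion, the more important the
#' deleted descriptor. Rows are sorted ascending by squared correlation
#' (most important feature first).
#'
#' @param spec Template [svr_spec()].
#' @param X,y Training data (>= 2 features).
#' @param gamma_grid,epsilon_grid,cost_grid Grids forwarded to
#'   [grid_search()]; keep them small for large feature counts.
#' @return Data frame `deleted`, `squared_correlation`, `total_mse`,
#'   `gamma`, `epsilon`, `cost`.
#' @export
descriptor_importance <- function(spec, X, y,
                                  gamma_grid = 10^seq(-2, 0),
                                  epsilon_grid = c(0.1, 0.22),
                                  cost_grid = c(1, 7.9)) {
  X <- .spec_features(spec, X)
  if (ncol(X) < 2) stop("need >= 2 features for deletion importance")
  rows <- lapply(names(X), function(feat) {
    Xr <- X[, setdiff(names(X), feat), drop = FALSE]
    gs <- grid_search(svr_spec(features = NULL), Xr, y,
                      gamma_grid = gamma_grid, epsilon_grid = epsilon_grid,
                      cost_grid = cost_grid)
    data.frame(deleted = feat,
               squared_correlation = gs$report$squared_correlation,
               total_mse = gs$report$total_mse,
               gamma = gs$spec$gamma, epsilon = gs$spec$epsilon,
               cost = gs$spec$cost, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$squared_correlation), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read/write concentration tables
#'
#' A concentration table is a TSV with columns `id` and `concentration`
#' (mol/L, > 0); `neg_log_c = -log10(concentration)` is derived on read and
#' kept consistent to numerical precision.
#'
#' @param path File path.
#' @name concentration-io
#' @export
read_concentrations <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "concentration") %in% names(d)))
  if (any(d$concentration <= 0)) stop("concentrations must be positive (mol/L)")
  d$neg_log_c <- -log10(d$concentration)
  d
}

#' @rdname concentration-io
#' @param concentrations Data frame with `id` and `concentration`.
#' @export
write_concentrations <- function(concentrations, path) {
  utils::write.table(concentrations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
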