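#' Six regression validation metrics
#'
#' For an observed vector Y and prediction vector Yhat:
#' \deqn{R^2 = 1 - \frac{\sum(Y-\hat Y)^2}{\sum(Y-\bar Y)^2},\quad
#'       RMSE = \sqrt{\tfrac1n\sum(Y-\hat Y)^2},\quad
#'       MAE = \tfrac1n\sum|Y-\hat Y|,}
#' \deqn{MAPE = \tfrac{100}{n}\sum\left|\tfrac{Y-\hat Y}{Y}\right|,\quad
#'       MSLE = \tfrac1n\sum(\ln(Y+1)-\ln(\hat Y+1))^2,\quad
#'       MedAE = \mathrm{median}|Y-\hat Y|.}
#' RMSE is reported as the square root of the mean squared error (the
#' dimensionally consistent convention); MSLE uses the natural
#' logarithm. Metrics that are undefined for the given data (MAPE with a
#' zero observation, MSLE with values at or below -1, R-squared with
#' zero-variance observations) are returned as `NA` and named in
#' `flags`, without failing the remaining metrics.
#'
#' @param observed,predicted equal-length numeric vectors.
#' @return List of class `metric_set` with `r2`, `rmse`, `mae`, `mape`
#'   (percent), `msle`, `medae` and a character vector `flags`.
#' @examples
#' compute_metrics(c(1, 2, 3), c(2, 2, 2))
#' @export
compute_metrics <- function(observed, predicted) {
  y <- as.numeric(observed); yh <- as.numeric(predicted)
  if (length(y) != length(yh) || length(y) == 0) {
    stop("observed and predicted must have equal nonzero length",
         call. = FALSE)
  }
  if (any(!is.finite(y)) || any(!is.finite(yh))) {
    stop("non-finite values in input", call. = FALSE)
  }
  err <- y - yh
  flags <- character()
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    r2 <- NA_real_
    flags <- c(flags, "r2: zero-variance observed")
  } else {
    r2 <- 1 - sum(err^2) / sst
  }
  if (any(y == 0)) {
    mape <- NA_real_
    flags <- c(flags, "mape: zero observed value")
  } else {
    mape <- 100 * mean(abs(err / y))
  }
  if (any(y <= -1) || any(yh <= -1)) {
    msle <- NA_real_
    flags <- c(flags, "msle: value <= -1")
  } else {
    msle <- mean((log(y + 1) - log(yh + 1))^2)
  }
  structure(list(r2 = r2,
                 rmse = sqrt(mean(err^2)),
                 mae = mean(abs(err)),
                 mape = mape,
                 msle = msle,
                 medae = stats::median(abs(err)),
                 flags = flags),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  v <- unlist(x[c("r2", "rmse", "mae", "mape", "msle", "medae")])
  print(round(v, 4))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Specify a prediction model for the validation harness
#'
#' Models are consumed through a fit/predict contract; the harness and
#' metrics are the tested surface, the learners' internals are not.
#' Available families: `"mean"` (constant grand-mean baseline),
#' `"linear"` (ordinary least squares), `"random_forest"`
#' (`randomForest::randomForest`) and `"mlp"` (single-hidden-layer
#' feedforward network, `nnet::nnet`, with internal feature/target
#' standardization and linear output).
#'
#' @param family model family.
#' @param params named list of hyperparameters passed to the learner
#'   (e.g. `ntree`, `mtry`, `nodesize` for the forest; `size`, `decay`,
#'   `maxit` for the network).
#' @param seed integer seed applied before each stochastic fit.
#' @return List of class `model_spec`.
#' @export
model_spec <- function(family = c("mean", "linear", "random_forest", "mlp"),
                       params = list(), seed = 1L) {
  family <- match.arg(family)
  structure(list(family = family, params = params, seed = as.integer(seed)),
            class = "model_spec")
}

# internal fit/predict dispatch; x is a numeric matrix, y numeric
fit_model <- function(spec, x, y) {
  set.seed(spec$seed)
  p <- spec$params
  switch(spec$family,
    mean = list(kind = "mean", mu = mean(y)),
    linear = {
      fit <- stats::lm.fit(cbind(1, x), y)
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0        # rank-deficient directions dropped
      list(kind = "linear", beta = beta)
    },
    random_forest = {
      args <- c(list(x = x, y = y), p)
      if (is.null(args$ntree)) args$ntree <- 500
      list(kind = "rf", fit = do.call(randomForest::randomForest, args))
    },
    mlp = {
      ctr <- colMeans(x)
      scl <- apply(x, 2, stats::sd); scl[scl == 0] <- 1
      xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
      y_ctr <- mean(y); y_scl <- stats::sd(y)
      if (y_scl == 0) y_scl <- 1
      args <- c(list(x = xs, y = (y - y_ctr) / y_scl,
                     linout = TRUE, trace = FALSE), p)
      if (is.null(args$size)) args$size <- 5
      if (is.null(args$maxit)) args$maxit <- 500
      if (is.null(args$decay)) args$decay <- 0.01
      list(kind = "mlp", fit = do.call(nnet::nnet, args),
           ctr = ctr, scl = scl, y_ctr = y_ctr, y_scl = y_scl)
    })
}

predict_model <- function(fit, x) {
  switch(fit$kind,
    mean = rep(fit$mu, nrow(x)),
    linear = as.numeric(cbind(1, x) %*% fit$beta),
    rf = as.numeric(stats::predict(fit$fit, x)),
    mlp = {
      xs <- sweep(sweep(x, 2, fit$ctr), 2, fit$scl, "/")
      as.numeric(stats::predict(fit$fit, xs)) * fit$y_scl + fit$y_ctr
    })
}

#' Leave-one-out cross-validation
#'
#' Fits the model n times, each time holding one sample out, and
#' assembles the out-of-fold predictions in input order. The fold
#' structure is deterministic; the model seed is re-applied before every
#' fold so stochastic learners are reproducible.
#'
#' @param spec a [model_spec()].
#' @param features n x p numeric matrix or data frame.
#' @param target length-n numeric response.
#' @return Length-n numeric vector of out-of-fold predictions.
#' @examples
#' loo_cv(model_spec("mean"), matrix(0, 3, 1), c(1, 2, 3))
#' @export
loo_cv <- function(spec, features, target) {
  stopifnot(inherits(spec, "model_spec"))
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  y <- as.numeric(target)
  n <- length(y)
  if (n < 2 || nrow(x) != n) {
    stop("need n >= 2 samples with matching feature rows", call. = FALSE)
  }
  preds <- numeric(n)
  for (i in seq_len(n)) {
    fit <- tryCatch(fit_model(spec, x[-i, , drop = FALSE], y[-i]),
                    error = function(e) {
                      stop("model training failed in fold ", i, ": ",
                           conditionMessage(e), call. = FALSE)
                    })
    preds[i] <- predict_model(fit, x[i, , drop = FALSE])
  }
  preds
}

#' Exhaustive grid search under leave-one-out cross-validation
#'
#' Evaluates every hyperparameter combination with [loo_cv()] and scores
#' the assembled out-of-fold predictions with [compute_metrics()]. The
#' best cell maximizes `r2` or minimizes any other selection metric;
#' ties go to the earlier grid row.
#'
#' @param family model family, as in [model_spec()].
#' @param grid data frame of candidate hyperparameter rows, or a named
#'   list of candidate values expanded via [expand.grid()].
#' @param features,target as in [loo_cv()].
#' @param selection_metric one of `"r2"`, `"rmse"`, `"mae"`, `"mape"`,
#'   `"msle"`, `"medae"` (default `"rmse"`).
#' @param seed seed forwarded to every fitted model.
#' @return List with `best_params` (named list), `best_metrics`
#'   (a `metric_set`), `best_index`, and `results` (one row per grid
#'   cell with all six metrics).
#' @export
grid_search <- function(family, grid, features, target,
                        selection_metric = "rmse", seed = 1L) {
  selection_metric <- match.arg(selection_metric,
                                c("r2", "rmse", "mae", "mape", "msle",
                                  "medae"))
  if (!is.data.frame(grid)) {
    grid <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  }
  if (nrow(grid) == 0) stop("empty hyperparameter grid", call. = FALSE)
  metric_names <- c("r2", "rmse", "mae", "mape", "msle", "medae")
  scores <- matrix(NA_real_, nrow(grid), length(metric_names),
                   dimnames = list(NULL, metric_names))
  sets <- vector("list", nrow(grid))
  failures <- character()
  for (i in seq_len(nrow(grid))) {
    spec <- model_spec(family, params = as.list(grid[i, , drop = FALSE]),
                       seed = seed)
    res <- tryCatch({
      preds <- loo_cv(spec, features, target)
      compute_metrics(target, preds)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, paste0("cell ", i, ": ",
                                     conditionMessage(res)))
      next
    }
    sets[[i]] <- res
    scores[i, ] <- unlist(res[metric_names])
  }
  if (all(is.na(scores[, selection_metric]))) {
    stop("all grid cells failed: ",
         paste(utils::head(failures, 3), collapse = "; "), call. = FALSE)
  }
  crit <- scores[, selection_metric]
  if (selection_metric == "r2") crit <- -crit
  best <- unname(which(crit == min(crit, na.rm = TRUE)))[1]  # first = grid order
  results <- cbind(grid, as.data.frame(scores))
  list(best_params = as.list(grid[best, , drop = FALSE]),
       best_metrics = sets[[best]],
       best_index = best,
       results = results)
}

#' Build an indicator feature matrix from a MET dataset
#'
#' Default encoding: one 0/1 column per genotype and per environment,
#' one row per (genotype, environment, replicate) record; every row sums
#' to 2. The encoding is an explicit design choice of this package for
#' predicting a trait from trial structure.
#'
#' @param dataset a balanced [met_dataset].
#' @param trait trait used as the prediction target.
#' @param encoding only `"onehot"` is implemented.
#' @return List with `features` (numeric matrix) and `target` (numeric
#'   vector), rows in dataset record order.
#' @export
build_feature_matrix <- function(dataset, trait, encoding = "onehot") {
  stopifnot(inherits(dataset, "met_dataset"))
  encoding <- match.arg(encoding, "onehot")
  if (!trait %in% attr(dataset, "trait_names")) {
    stop("trait '", trait, "' not in dataset", call. = FALSE)
  }
  gl <- attr(dataset, "genotype_order")
  el <- attr(dataset, "environment_order")
  gmat <- outer(dataset$genotype, gl, "==") * 1
  emat <- outer(dataset$environment, el, "==") * 1
  colnames(gmat) <- paste0("g_", gl)
  colnames(emat) <- paste0("e_", el)
  list(features = cbind(gmat, emat), target = dataset[[trait]])
}
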