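# Learner registry for the CATE stage ---------------------------------
#
# Each learner is a pair of closures (fit, predict) over a plain feature
# matrix and numeric target. Hyperparameters with more than one candidate
# are resolved by inner cross-validation restricted to the training data,
# which preserves the out-of-sample contract of sequential cross-fitting.

learner_registry <- new.env(parent = emptyenv())

register_learner <- function(name, fit, default_grid = list()) {
  assign(name, list(fit = fit, default_grid = default_grid),
         envir = learner_registry)
}

#' List registered CATE learners
#' @return Character vector of learner names accepted by [learner_spec()].
#' @export
list_learners <- function() sort(ls(learner_registry))

#' Specify a CATE learner
#'
#' @param name Registered learner name: `"penalized_linear"` (ridge
#'   regression via glmnet with internally cross-validated penalty),
#'   `"svr"` (radial-basis-kernel support vector regression),
#'   `"random_forest"` (ranger), `"mlp"` (single-hidden-layer perceptron
#'   via nnet), or `"mean"` (training-mean dummy, mainly for testing).
#' @param grid Named list of hyperparameter candidate vectors; merged over
#'   the learner's defaults. Grids with more than one combination are
#'   resolved by 5-fold inner cross-validation on the training folds.
#' @param seed Integer seed for the learner's own randomness.
#' @return A `learner_spec` object.
#' @export
learner_spec <- function(name, grid = list(), seed = 1L) {
  if (!exists(name, envir = learner_registry)) {
    abort(sprintf("Unknown learner `%s`; see list_learners().", name))
  }
  entry <- get(name, envir = learner_registry)
  full_grid <- utils::modifyList(entry$default_grid, grid)
  structure(list(name = name, grid = full_grid, seed = as.integer(seed)),
            class = "learner_spec")
}

# expand a named list of candidate vectors into a list of single settings
expand_settings <- function(grid) {
  if (length(grid) == 0) return(list(list()))
  combos <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(combos)), function(i) as.list(combos[i, , drop = FALSE]))
}

# fit a learner_spec on (X, y); returns an object with a $predict(newX)
fit_learner <- function(spec, X, y) {
  entry <- get(spec$name, envir = learner_registry)
  settings <- expand_settings(spec$grid)
  if (length(settings) > 1) {
    settings <- list(tune_by_inner_cv(entry, settings, X, y, spec$seed))
  }
  set.seed(spec$seed)
  entry$fit(X, y, settings[[1]])
}

# 5-fold inner CV over candidate settings; mean squared error objective
tune_by_inner_cv <- function(entry, settings, X, y, seed) {
  n <- nrow(X)
  k <- min(5L, n)
  set.seed(derive_seed(seed, 777L))
  fold <- sample(rep(seq_len(k), length.out = n))
  mse <- vapply(settings, function(s) {
    errs <- vapply(seq_len(k), function(f) {
      tr <- fold != f
      m <- entry$fit(X[tr, , drop = FALSE], y[tr], s)
      mean((y[!tr] - m$predict(X[!tr, , drop = FALSE]))^2)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  settings[[which.min(mse)]]
}

# --- learner implementations -----------------------------------------

register_learner("mean",
  fit = function(X, y, s) {
    mu <- mean(y)
    list(predict = function(newX) rep(mu, nrow(newX)))
  })

register_learner("penalized_linear",
  fit = function(X, y, s) {
    alpha <- s$alpha %||% 0
    if (ncol(X) < 2) {
      # glmnet needs >= 2 columns; fall back to OLS
      df <- data.frame(y = y, x = X[, 1])
      m <- stats::lm(y ~ x, data = df)
      return(list(predict = function(newX) {
        as.numeric(stats::predict(m, data.frame(x = newX[, 1])))
      }))
    }
    nfolds <- max(3, min(5, floor(nrow(X) / 3)))
    cv <- glmnet::cv.glmnet(X, y, alpha = alpha, nfolds = nfolds)
    list(predict = function(newX) {
      as.numeric(stats::predict(cv, newx = newX, s = "lambda.min"))
    })
  },
  default_grid = list(alpha = 0))

register_learner("svr",
  fit = function(X, y, s) {
    m <- e1071::svm(X, y, kernel = "radial",
                    cost = s$cost %||% 1, gamma = s$gamma %||% (1 / ncol(X)),
                    epsilon = s$epsilon %||% 0.1)
    list(predict = function(newX) as.numeric(stats::predict(m, newX)))
  },
  default_grid = list(cost = 1))

register_learner("random_forest",
  fit = function(X, y, s) {
    df <- as.data.frame(X)
    names(df) <- paste0("f", seq_len(ncol(X)))
    df$.y <- y
    m <- ranger::ranger(
      dependent.variable.name = ".y", data = df,
      num.trees = s$num.trees %||% 300,
      min.node.size = s$min.node.size %||% 5,
      seed = s$seed %||% 1, num.threads = 1
    )
    list(predict = function(newX) {
      nd <- as.data.frame(newX)
      names(nd) <- paste0("f", seq_len(ncol(newX)))
      stats::predict(m, data = nd, num.threads = 1)$predictions
    })
  },
  default_grid = list(num.trees = 300))

register_learner("mlp",
  fit = function(X, y, s) {
    m <- nnet::nnet(X, y, size = s$size %||% 8, decay = s$decay %||% 0.01,
                    linout = TRUE, maxit = s$maxit %||% 200, trace = FALSE)
    list(predict = function(newX) as.numeric(stats::predict(m, newX)))
  },
  default_grid = list(decay = 0.01))
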