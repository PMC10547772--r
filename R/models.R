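#' Model specification
#'
#' A model family plus one point of its hyperparameter grid. Families:
#' `"random-forest"` (randomForest: `ntree`, `max_depth` via `maxnodes =
#' 2^depth`), `"gradient-boosted-trees"` (xgboost: `num_parallel_tree`,
#' `max_depth`, `nrounds`), `"support-vector-machine"` (e1071::svm with
#' Platt-scaled probabilities: `cost`, `kernel`), and
#' `"gaussian-naive-bayes"` (no hyperparameters).
#'
#' @param family one of the four family names above.
#' @param ... family-specific hyperparameters.
#' @return A `model_spec` object.
#' @export
model_spec <- function(family = c("random-forest", "gradient-boosted-trees",
                                  "support-vector-machine",
                                  "gaussian-naive-bayes"), ...) {
  family <- match.arg(family)
  params <- list(...)
  defaults <- switch(family,
    "random-forest" = list(ntree = 50, max_depth = 5),
    "gradient-boosted-trees" = list(num_parallel_tree = 50, max_depth = 5,
                                    nrounds = 50),
    "support-vector-machine" = list(cost = 1, kernel = "radial"),
    "gaussian-naive-bayes" = list()
  )
  defaults[names(params)] <- params
  structure(list(family = family, params = defaults), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec ", format(x), ">\n", sep = "")
  invisible(x)
}

#' @export
format.model_spec <- function(x, ...) {
  if (!length(x$params)) return(x$family)
  paste0(x$family, " (",
         paste(names(x$params), unlist(x$params), sep = "=", collapse = ", "),
         ")")
}

#' Default hyperparameter grids
#'
#' The candidate `model_spec` list explored by [evaluate_models()]: random
#' forest with trees in \{25, 50, 100\} and depth in \{3, 5, 10\} (Gini
#' split); gradient-boosted trees with parallel trees in \{25, 50, 100\} and
#' depth in \{3, 5, 10\}; SVM with cost in \{0.5, 1, 2, 3\} and kernel in
#' \{linear, polynomial, radial, sigmoid\}; Gaussian naive Bayes. Grid order
#' is the final tie-break in [select_best_model()].
#'
#' @return List of `model_spec` objects.
#' @export
default_model_grid <- function() {
  grid <- list()
  for (nt in c(25, 50, 100)) for (d in c(3, 5, 10))
    grid[[length(grid) + 1]] <- model_spec("random-forest", ntree = nt,
                                           max_depth = d)
  for (nt in c(25, 50, 100)) for (d in c(3, 5, 10))
    grid[[length(grid) + 1]] <- model_spec("gradient-boosted-trees",
                                           num_parallel_tree = nt,
                                           max_depth = d)
  for (cc in c(0.5, 1, 2, 3))
    for (kn in c("linear", "polynomial", "radial", "sigmoid"))
      grid[[length(grid) + 1]] <- model_spec("support-vector-machine",
                                             cost = cc, kernel = kn)
  grid[[length(grid) + 1]] <- model_spec("gaussian-naive-bayes")
  grid
}

#' Reduced one-per-family candidate list
#'
#' A small candidate set for desk-scale runs: the reference best random
#' forest (50 trees, depth 5), one gradient-boosted, one radial SVM and
#' Gaussian naive Bayes.
#'
#' @return List of `model_spec` objects.
#' @export
reference_model_grid <- function() {
  list(
    model_spec("random-forest", ntree = 50, max_depth = 5),
    model_spec("gradient-boosted-trees", num_parallel_tree = 50,
               max_depth = 5, nrounds = 20),
    model_spec("support-vector-machine", cost = 1, kernel = "radial"),
    model_spec("gaussian-naive-bayes")
  )
}

#' Fit a model to a training table
#'
#' @param spec a `model_spec`.
#' @param X numeric training matrix (samples x features).
#' @param y binary labels (0/1).
#' @param seed integer seed for stochastic fitting steps.
#' @return A `fitted_model` carrying the fit, the spec and the training data
#'   (used as SHAP background).
#' @export
fit_model <- function(spec, X, y, seed = 1) {
  X <- as.matrix(X)
  yf <- factor(y, levels = c(0, 1))
  fit <- withr::with_seed(seed, switch(spec$family,
    "random-forest" = randomForest::randomForest(
      x = X, y = yf, ntree = spec$params$ntree,
      maxnodes = 2L^spec$params$max_depth, keep.inbag = TRUE
    ),
    "gradient-boosted-trees" = xgboost::xgboost(
      X, yf, objective = "binary:logistic",
      nrounds = spec$params$nrounds, max_depth = spec$params$max_depth,
      num_parallel_tree = spec$params$num_parallel_tree,
      nthreads = 1, seed = seed, verbosity = 0
    ),
    "support-vector-machine" = e1071::svm(
      x = X, y = yf, kernel = spec$params$kernel, cost = spec$params$cost,
      probability = TRUE
    ),
    "gaussian-naive-bayes" = e1071::naiveBayes(x = as.data.frame(X), y = yf)
  ))
  structure(list(fit = fit, spec = spec, features = colnames(X),
                 X_train = X, y_train = y),
            class = "fitted_model")
}

#' Positive-class probability predictions
#'
#' @param model a `fitted_model`.
#' @param X matrix of rows to score (same columns as the training table).
#' @return Numeric vector of P(class = 1) in `[0, 1]`.
#' @export
predict_prob <- function(model, X) {
  X <- as.matrix(X)[, model$features, drop = FALSE]
  p <- switch(model$spec$family,
    "random-forest" =
      stats::predict(model$fit, X, type = "prob")[, "1"],
    "gradient-boosted-trees" =
      stats::predict(model$fit, X, type = "response"),
    "support-vector-machine" = {
      pr <- stats::predict(model$fit, X, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    "gaussian-naive-bayes" =
      stats::predict(model$fit, as.data.frame(X), type = "raw")[, "1"]
  )
  unname(pmin(pmax(as.numeric(p), 0), 1))
}
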