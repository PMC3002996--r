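#' Restrict a labelled dataset to one of the four binary problems
#'
#' The four problems are: (i) up- vs. down-regulated genes; (ii)
#' down-regulated vs. un-responsive genes; (iii) up-regulated vs.
#' un-responsive genes; (iv) differential (up or down) vs. un-responsive
#' genes.
#'
#' @param X Numeric matrix genes x features (acetylation-change profiles).
#' @param y Character/factor labels in `up`, `down`, `stable`, aligned to the
#'   rows of `X`.
#' @param problem One of `"i"`, `"ii"`, `"iii"`, `"iv"`.
#' @return List with `X`, binary factor `y` (first level = positive class)
#'   and `problem`.
#' @export
make_problem <- function(X, y, problem = c("i", "ii", "iii", "iv")) {
  problem <- match.arg(problem)
  y <- as.character(y)
  stopifnot(nrow(X) == length(y))
  sel <- switch(problem,
    i = list(pos = "up", neg = "down"),
    ii = list(pos = "down", neg = "stable"),
    iii = list(pos = "up", neg = "stable"),
    iv = list(pos = c("up", "down"), neg = "stable"))
  pos <- y %in% sel$pos
  neg <- y %in% sel$neg
  if (!any(pos) || !any(neg)) {
    stop(sprintf("problem %s has an empty class", problem), call. = FALSE)
  }
  keep <- pos | neg
  yy <- factor(ifelse(pos[keep], paste(sel$pos, collapse = "+"),
                      paste(sel$neg, collapse = "+")),
               levels = c(paste(sel$pos, collapse = "+"),
                          paste(sel$neg, collapse = "+")))
  list(X = X[keep, , drop = FALSE], y = yy, problem = problem)
}

#' Balanced resamples of a binary dataset
#'
#' Each resample keeps the entire minority class and a without-replacement
#' uniform sample of the majority class of equal size, so every resample is
#' exactly 50/50 and chance accuracy is 50%. If the classes are already
#' equal the resamples are copies of the full dataset.
#'
#' @param problem A [make_problem()] result.
#' @param n_resamples Number of balanced resamples.
#' @param seed Integer seed.
#' @return List of `n_resamples` lists, each with `X` and `y`.
#' @export
balanced_resamples <- function(problem, n_resamples = 20, seed = 1L) {
  y <- problem$y
  X <- problem$X
  tab <- table(y)
  minority <- names(tab)[which.min(tab)]
  majority <- setdiff(names(tab), minority)
  i_min <- which(y == minority)
  i_maj <- which(y == majority)
  set.seed(seed)
  lapply(seq_len(n_resamples), function(b) {
    i_sub <- if (length(i_maj) > length(i_min)) {
      sample(i_maj, length(i_min))
    } else {
      i_maj
    }
    idx <- c(i_min, i_sub)
    list(X = X[idx, , drop = FALSE], y = droplevels(y[idx]))
  })
}

# --- small in-package classifiers ------------------------------------------

# diagonal linear discriminant analysis: shared diagonal covariance
fit_dlda <- function(x, y) {
  cls <- levels(y)
  mu <- sapply(cls, function(c) colMeans(x[y == c, , drop = FALSE]))
  v <- numeric(ncol(x))
  for (c in cls) {
    xc <- x[y == c, , drop = FALSE]
    v <- v + colSums(sweep(xc, 2, colMeans(xc))^2)
  }
  v <- v / (nrow(x) - length(cls))
  v[v < 1e-10] <- 1e-10
  prior <- as.numeric(table(y)[cls]) / length(y)
  list(mu = mu, v = v, prior = prior, classes = cls)
}

predict_dlda <- function(fit, x) {
  sc <- sapply(seq_along(fit$classes), function(k) {
    -0.5 * rowSums(sweep(x, 2, fit$mu[, k])^2 / rep(fit$v, each = nrow(x))) +
      log(fit$prior[k])
  })
  factor(fit$classes[max.col(sc)], levels = fit$classes)
}

# shrinkage-regularized LDA: pooled covariance shrunk toward a scaled
# identity; used as the stabilized linear scores variant
fit_slda <- function(x, y, lambda = 0.25) {
  cls <- levels(y)
  mu <- sapply(cls, function(c) colMeans(x[y == c, , drop = FALSE]))
  S <- matrix(0, ncol(x), ncol(x))
  for (c in cls) {
    xc <- sweep(x[y == c, , drop = FALSE], 2, colMeans(x[y == c, , drop = FALSE]))
    S <- S + crossprod(xc)
  }
  S <- S / (nrow(x) - length(cls))
  S <- (1 - lambda) * S + lambda * mean(diag(S)) * diag(ncol(x))
  prior <- as.numeric(table(y)[cls]) / length(y)
  list(mu = mu, Sinv = solve(S), prior = prior, classes = cls)
}

predict_slda <- function(fit, x) {
  sc <- sapply(seq_along(fit$classes), function(k) {
    m <- fit$mu[, k]
    drop(x %*% (fit$Sinv %*% m)) - 0.5 * drop(t(m) %*% fit$Sinv %*% m) +
      log(fit$prior[k])
  })
  factor(fit$classes[max.col(sc)], levels = fit$classes)
}

fit_bagged_tree <- function(x, y, n_bags = 25) {
  d <- data.frame(.y = y, x)
  fits <- lapply(seq_len(n_bags), function(b) {
    idx <- sample.int(nrow(d), replace = TRUE)
    rpart::rpart(.y ~ ., data = d[idx, , drop = FALSE], method = "class")
  })
  list(fits = fits, classes = levels(y))
}

predict_bagged_tree <- function(fit, x) {
  d <- data.frame(x)
  votes <- sapply(fit$fits, function(f) {
    as.character(predict(f, newdata = d, type = "class"))
  })
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1)
  factor(apply(votes, 1, function(v) names(which.max(table(v)))),
         levels = fit$classes)
}

#' Registry of classifiers for the cross-validation benchmark
#'
#' Returns the suite used to make the benchmark independent of any single
#' method choice: support vector machines with linear, radial-basis and
#' polynomial (degree 2 and 3) kernels; linear, quadratic, diagonal-linear
#' and shrinkage-regularized discriminant analysis; a single classification
#' tree, bagged trees and a random forest; k-nearest-neighbour with k in
#' 1, 5, 10, 15; naive Bayes; a single-hidden-layer neural network; and
#' logistic regression. Each entry documents its default hyperparameters in
#' `params` and provides `fit(x, y)` / `predict(fit, x)` closures.
#'
#' @return Named list of classifier specs (18 entries).
#' @export
classifier_registry <- function() {
  svm_spec <- function(kernel, degree = 3) {
    # coef0 = 1 gives the inhomogeneous polynomial kernel; the homogeneous
    # one (coef0 = 0) is an even function for degree 2 and cannot separate
    # sign-symmetric classes
    list(fit = function(x, y) {
      e1071::svm(x, y, kernel = kernel, degree = degree, coef0 = 1,
                 scale = FALSE, cost = 1)
    },
    predict = function(fit, x) predict(fit, x),
    params = list(kernel = kernel, degree = degree, coef0 = 1, cost = 1))
  }
  knn_spec <- function(k) {
    list(fit = function(x, y) list(x = x, y = y, k = k),
         predict = function(fit, x) {
           class::knn(fit$x, x, fit$y, k = fit$k)
         },
         params = list(k = k))
  }
  reg <- list(
    svm_linear = svm_spec("linear"),
    svm_rbf = svm_spec("radial"),
    svm_poly2 = svm_spec("polynomial", 2),
    svm_poly3 = svm_spec("polynomial", 3),
    lda = list(fit = function(x, y) MASS::lda(x, y),
               predict = function(fit, x) predict(fit, x)$class,
               params = list()),
    qda = list(fit = function(x, y) MASS::qda(x, y),
               predict = function(fit, x) predict(fit, x)$class,
               params = list()),
    dlda = list(fit = fit_dlda, predict = predict_dlda, params = list()),
    slda = list(fit = fit_slda, predict = predict_slda,
                params = list(lambda = 0.25)),
    tree = list(fit = function(x, y) {
      rpart::rpart(.y ~ ., data = data.frame(.y = y, x), method = "class")
    },
    predict = function(fit, x) {
      predict(fit, newdata = data.frame(x), type = "class")
    },
    params = list()),
    bagged_tree = list(fit = fit_bagged_tree, predict = predict_bagged_tree,
                       params = list(n_bags = 25)),
    random_forest = list(fit = function(x, y) {
      randomForest::randomForest(x, y, ntree = 100)
    },
    predict = function(fit, x) predict(fit, x),
    params = list(ntree = 100)),
    knn_1 = knn_spec(1), knn_5 = knn_spec(5), knn_10 = knn_spec(10),
    knn_15 = knn_spec(15),
    naive_bayes = list(fit = function(x, y) e1071::naiveBayes(x, y),
                       predict = function(fit, x) predict(fit, x),
                       params = list()),
    neural_net = list(fit = function(x, y) {
      nnet::nnet(x, stats::model.matrix(~ y - 1), size = 5, decay = 0.01,
                 maxit = 100, trace = FALSE, softmax = TRUE)
    },
    predict = function(fit, x) {
      pr <- predict(fit, x)
      factor(sub("^y", "", colnames(pr)[max.col(pr)]),
             levels = sub("^y", "", colnames(pr)))
    },
    params = list(size = 5, decay = 0.01, maxit = 100)),
    logistic = list(fit = function(x, y) {
      # separation warnings are expected on balanced separable resamples
      suppressWarnings(
        stats::glm(.y ~ ., data = data.frame(.y = y, x),
                   family = stats::binomial))
    },
    predict = function(fit, x) {
      pr <- predict(fit, newdata = data.frame(x), type = "response")
      # glm models P(second level); > 0.5 means the second level
      factor(ifelse(pr > 0.5, levels(fit$model$.y)[2], levels(fit$model$.y)[1]),
             levels = levels(fit$model$.y))
    },
    params = list()))
  for (nm in names(reg)) reg[[nm]]$id <- nm
  reg
}

#' Stratified repeated cross-validation accuracy on one dataset
#'
#' Splits the dataset into `folds` stratified folds (class proportions are
#' preserved inside each fold), trains the classifier fresh on each training
#' portion and pools the held-out predictions; accuracy is the pooled
#' fraction correct.
#'
#' @param dataset List with `X` and factor `y` (e.g. one balanced resample).
#' @param spec One entry of [classifier_registry()], or its name.
#' @param folds Number of CV folds.
#' @param seed Integer seed for the fold assignment.
#' @return Accuracy in `[0, 1]`.
#' @export
run_cv <- function(dataset, spec, folds = 10, seed = 1L) {
  if (is.character(spec)) {
    reg <- classifier_registry()
    if (!spec %in% names(reg)) {
      stop(sprintf("unknown classifier '%s'; registry: %s", spec,
                   paste(names(reg), collapse = ", ")), call. = FALSE)
    }
    spec <- reg[[spec]]
  }
  X <- as.matrix(dataset$X)
  y <- droplevels(as.factor(dataset$y))
  if (min(table(y)) < folds) {
    stop("each class needs at least as many rows as folds", call. = FALSE)
  }
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  correct <- 0L
  for (f in seq_len(folds)) {
    tr <- fold != f
    fit <- spec$fit(X[tr, , drop = FALSE], droplevels(y[tr]))
    pred <- spec$predict(fit, X[!tr, , drop = FALSE])
    correct <- correct + sum(as.character(pred) == as.character(y[!tr]))
  }
  correct / length(y)
}

#' Balanced repeated cross-validation benchmark over problems and classifiers
#'
#' For every requested problem, draws `n_resamples` balanced resamples and
#' computes the stratified `folds`-fold CV accuracy of every classifier on
#' each resample. The spread of the resulting accuracy vectors reflects both
#' the resampling of the majority class and the random fold splits.
#'
#' @inheritParams make_problem
#' @param problems Character vector of problem ids.
#' @param registry Classifier registry (or a named subset of it).
#' @param n_resamples Balanced resamples per problem.
#' @param folds CV folds.
#' @param seed Global seed; per-problem and per-resample sub-seeds are
#'   derived from it.
#' @return Object of class `cv_report`: data.frame with `problem`,
#'   `classifier`, `resample`, `accuracy` (one row per cell draw, i.e.
#'   `length(problems) * length(registry) * n_resamples` rows).
#' @export
full_benchmark <- function(X, y, problems = c("i", "ii", "iii", "iv"),
                           registry = classifier_registry(),
                           n_resamples = 20, folds = 10, seed = 1L) {
  rows <- list()
  for (pb in problems) {
    prob <- make_problem(X, y, pb)
    res <- balanced_resamples(prob, n_resamples,
                              seed = derive_seed(seed, paste0("resample.", pb)))
    for (b in seq_along(res)) {
      fold_seed <- derive_seed(seed, sprintf("fold.%s.%d", pb, b))
      for (nm in names(registry)) {
        acc <- run_cv(res[[b]], registry[[nm]], folds = folds,
                      seed = fold_seed)
        rows[[length(rows) + 1L]] <- data.frame(
          problem = pb, classifier = nm, resample = b, accuracy = acc,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cv_report", "data.frame")
  out
}

#' Median and IQR summary of a benchmark report
#'
#' @param object A [full_benchmark()] report.
#' @param ... Unused.
#' @return data.frame with one row per (problem, classifier) cell: `median`,
#'   `q25`, `q75`, `n`.
#' @export
summary.cv_report <- function(object, ...) {
  agg <- function(f) {
    stats::aggregate(accuracy ~ problem + classifier, data = object, FUN = f)
  }
  out <- agg(stats::median)
  names(out)[3] <- "median"
  out$q25 <- agg(function(a) stats::quantile(a, 0.25))$accuracy
  out$q75 <- agg(function(a) stats::quantile(a, 0.75))$accuracy
  out$n <- agg(length)$accuracy
  out
}
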