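#' Gaussian naive Bayes model
#'
#' Class-conditional Gaussian model over continuous pathway-score features:
#' class priors from training frequencies and per-class per-feature means
#' and variances (variances floored to avoid degenerate likelihood spikes).
#'
#' @slot priors Named numeric vector summing to 1.
#' @slot means Feature-by-class matrix of Gaussian means.
#' @slot vars Feature-by-class matrix of Gaussian variances (> 0).
#' @slot features Character vector: the feature (pathway) panel.
#' @exportClass NBModel
setClass("NBModel",
         representation(priors = "numeric", means = "matrix",
                        vars = "matrix", features = "character"))

setValidity("NBModel", function(object) {
  msg <- NULL
  if (abs(sum(object@priors) - 1) > 1e-8)
    msg <- c(msg, "priors must sum to 1")
  if (any(object@vars <= 0))
    msg <- c(msg, "variances must be positive")
  if (!identical(rownames(object@means), object@features) ||
      !identical(rownames(object@vars), object@features))
    msg <- c(msg, "feature list must match the parameter matrices")
  if (is.null(msg)) TRUE else msg
})

#' @export
setMethod("show", "NBModel", function(object) {
  cat("Gaussian naive Bayes model\n")
  cat("  classes:", paste(names(object@priors), collapse = ", "),
      sprintf("(priors %s)", paste(signif(object@priors, 3), collapse = "/")), "\n")
  cat("  features:", length(object@features), "pathway scores\n")
})

#' @describeIn trainNB class prior probabilities
#' @export
nbPriors <- function(model) model@priors

#' @describeIn trainNB feature (pathway) panel names
#' @export
nbFeatures <- function(model) model@features

#' Train a Gaussian naive Bayes subgroup classifier
#'
#' @param scores Feature-by-sample matrix (pathway enrichment scores).
#' @param labels Class labels per sample (>= 2 classes, each with >= 2
#'   samples).
#' @return An \linkS4class{NBModel}.
#' @export
trainNB <- function(scores, labels) {
  stopifnot(is.matrix(scores), ncol(scores) == length(labels))
  cls <- sort(unique(as.character(labels)))
  if (length(cls) < 2L) stop("training needs >= 2 classes")
  if (any(table(labels) < 2L)) stop("every class needs >= 2 samples")
  labels <- as.character(labels)
  means <- vars <- matrix(NA_real_, nrow(scores), length(cls),
                          dimnames = list(rownames(scores), cls))
  for (cl in cls) {
    sub <- scores[, labels == cl, drop = FALSE]
    means[, cl] <- rowMeans(sub)
    vars[, cl] <- apply(sub, 1, stats::var)
  }
  # floor relative to each feature's global spread to avoid likelihood
  # spikes when a feature is constant within a class
  gv <- apply(scores, 1, stats::var)
  floor_ <- pmax(1e-9 * gv, 1e-12)
  vars <- pmax(vars, floor_)
  priors <- table(factor(labels, levels = cls)) / length(labels)
  new("NBModel", priors = stats::setNames(as.numeric(priors), cls),
      means = means, vars = vars, features = rownames(scores))
}

#' Predict subgroups with a naive Bayes model
#'
#' Argmax of log prior plus summed log Gaussian densities; posterior
#' probabilities normalized per sample; ties broken by class order.
#'
#' @param model An \linkS4class{NBModel}.
#' @param scores Feature-by-sample matrix covering the model's features.
#' @return List with \code{labels} (named character) and \code{posterior}
#'   (class-by-sample matrix, columns summing to 1).
#' @export
predictNB <- function(model, scores) {
  miss <- setdiff(model@features, rownames(scores))
  if (length(miss))
    stop("missing feature(s) in score matrix: ", paste(miss, collapse = ", "))
  x <- scores[model@features, , drop = FALSE]
  cls <- names(model@priors)
  loglik <- vapply(cls, function(cl) {
    colSums(stats::dnorm(x, mean = model@means[, cl],
                         sd = sqrt(model@vars[, cl]), log = TRUE)) +
      log(model@priors[[cl]])
  }, numeric(ncol(x)))
  loglik <- matrix(loglik, ncol = length(cls),
                   dimnames = list(colnames(x), cls))
  post <- t(apply(loglik, 1, function(v) {
    v <- exp(v - max(v)); v / sum(v)
  }))
  labels <- cls[apply(loglik, 1, which.max)]
  list(labels = stats::setNames(labels, colnames(x)), posterior = t(post))
}

#' Stratified 10-fold cross-validation
#'
#' Deterministic stratified fold assignment under the seed, per-fold
#' train/predict, per-fold and mean accuracy. A class smaller than the fold
#' count triggers a warning and unstratified folds.
#'
#' @param scores Feature-by-sample matrix.
#' @param labels Class labels per sample (n >= 10).
#' @param seed Integer seed for the fold shuffle.
#' @param n_folds Number of folds (default 10).
#' @return List with \code{fold_accuracy} and \code{mean_accuracy}.
#' @export
cv10 <- function(scores, labels, seed = 1L, n_folds = 10L) {
  n <- ncol(scores)
  if (n < n_folds) stop("need at least as many samples as folds")
  labels <- as.character(labels)
  set.seed(seed)
  fold <- integer(n)
  if (any(table(labels) < n_folds)) {
    warning("a class is smaller than the fold count; using plain folds")
    fold <- sample(rep_len(seq_len(n_folds), n))
  } else {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  }
  acc <- vapply(seq_len(n_folds), function(f) {
    test <- fold == f
    model <- trainNB(scores[, !test, drop = FALSE], labels[!test])
    pred <- predictNB(model, scores[, test, drop = FALSE])$labels
    mean(pred == labels[test])
  }, numeric(1))
  list(fold_accuracy = acc, mean_accuracy = mean(acc), folds = fold)
}

#' Serialize / restore a naive Bayes model as JSON
#'
#' @param model An \linkS4class{NBModel}.
#' @param path Output (input) path.
#' @return \code{path} invisibly; \code{readNBModel} returns the model.
#' @export
writeNBModel <- function(model, path) {
  obj <- list(priors = as.list(model@priors),
              features = model@features,
              classes = names(model@priors),
              means = apply(model@means, 2, identity, simplify = FALSE),
              vars = apply(model@vars, 2, identity, simplify = FALSE))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeNBModel
#' @export
readNBModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- obj$classes
  feats <- obj$features
  # per-class vectors are stored in feature order
  toMat <- function(l) {
    m <- do.call(cbind, lapply(cls, function(cl) unname(unlist(l[[cl]]))))
    dimnames(m) <- list(feats, cls)
    m
  }
  new("NBModel", priors = unlist(obj$priors)[cls],
      means = toMat(obj$means), vars = toMat(obj$vars), features = feats)
}
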