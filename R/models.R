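# Linear SVM scoring functions. Training goes through libsvm (e1071) but
# the fitted model is reduced to an explicit weight vector and decision
# threshold, so scoring and serialization never require the training
# backend: s(x) = sum_k w_k x_k - b, hot spot iff s > 0 (strictly).

#' Training configuration for the SVM grid search
#'
#' @param C_grid Soft-margin cost values for the grid search.
#' @param class_weight_grid Multiplicative cost factors for the positive
#'   (hot spot) class; hot spots are the minority class in alanine-scanning
#'   data, so values > 1 penalise missed hot spots more.
#' @param seed Integer seed for every stochastic step.
#' @return Named list.
#' @export
training_config <- function(C_grid = c(0.01, 0.1, 1, 10, 100),
                            class_weight_grid = c(1, 2, 5),
                            seed = 1L) {
  stopifnot(length(C_grid) > 0, all(C_grid > 0),
            length(class_weight_grid) > 0, all(class_weight_grid > 0))
  list(C_grid = C_grid, class_weight_grid = class_weight_grid,
       seed = as.integer(seed))
}

#' Train a linear soft-margin SVM on selected features
#'
#' Fits a linear-kernel SVM (hinge loss, L2 regularization, optional
#' asymmetric class cost) on the given feature columns, which are assumed
#' already standardized. The returned model carries explicit weights and
#' threshold; its score on the training rows reproduces the backend's
#' decision values.
#'
#' @param table Labelled, standardized feature table (\code{label} column
#'   of +1/-1; both classes present).
#' @param feature_ids Character vector of feature columns to use.
#' @param C Soft-margin cost.
#' @param class_weight Cost multiplier for the +1 class.
#' @param stats Optional standardization stats (stored for scoring raw
#'   feature vectors later).
#' @return Object of class \code{hspred_svm}: list with \code{feature_ids},
#'   \code{weights}, \code{threshold}, \code{meta}.
#' @export
train_linear_svm <- function(table, feature_ids, C = 1, class_weight = 1,
                             stats = NULL) {
  X <- as.matrix(table[, feature_ids, drop = FALSE])
  if (any(!is.finite(X))) stop("non-finite feature value(s)")
  y <- table$label
  if (length(unique(y)) < 2)
    stop("training table contains a single class; cannot fit a classifier")
  yf <- factor(y, levels = c(-1, 1))
  fit <- e1071::svm(X, yf, kernel = "linear", cost = C, scale = FALSE,
                    class.weights = c("-1" = 1, "1" = class_weight))
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- fit$rho
  # libsvm orients decision values toward the first label it sees; fix the
  # sign so s > 0 means the +1 (hot spot) class
  dv <- attr(stats::predict(fit, X[1, , drop = FALSE],
                            decision.values = TRUE), "decision.values")
  if (!startsWith(colnames(dv)[1], "1")) { w <- -w; b <- -b }
  names(w) <- feature_ids
  structure(list(feature_ids = feature_ids, weights = w, threshold = b,
                 meta = list(C = C, class_weight = class_weight,
                             stats = stats)),
            class = "hspred_svm")
}

#' Decision score of a linear model
#'
#' \code{s = sum_k w_k x_k - threshold}. If the model carries
#' standardization stats, raw feature values are standardized first.
#'
#' @param model \code{hspred_svm}.
#' @param x Named numeric feature vector, or a data.frame/matrix of rows,
#'   containing at least the model's features.
#' @return Numeric score(s).
#' @export
score <- function(model, x) {
  stopifnot(inherits(model, "hspred_svm"))
  if (is.null(dim(x))) x <- as.data.frame(as.list(x))
  miss <- setdiff(model$feature_ids, colnames(x))
  if (length(miss))
    stop("missing feature component(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(as.data.frame(x)[, model$feature_ids, drop = FALSE])
  st <- model$meta$stats
  if (!is.null(st)) {
    fi <- model$feature_ids
    X <- sweep(sweep(X, 2, st$mean[fi]), 2, st$sd[fi], "/")
  }
  drop(X %*% model$weights) - model$threshold
}

#' Hot-spot call from a decision score
#'
#' Scores strictly greater than zero are predicted hot spots; a score of
#' exactly zero is a non hot spot.
#'
#' @param s Numeric score(s).
#' @return Integer vector of +1 / -1.
#' @export
classify <- function(s) ifelse(s > 0, 1L, -1L)

#' @export
print.hspred_svm <- function(x, ...) {
  cat("Linear SVM scoring function (", length(x$feature_ids),
      " features)\n", sep = "")
  print(round(x$weights, 4))
  cat("threshold:", round(x$threshold, 4),
      " C:", x$meta$C, " class weight:", x$meta$class_weight, "\n")
  invisible(x)
}

#' @export
coef.hspred_svm <- function(object, ...) {
  c(object$weights, threshold = object$threshold)
}

#' Route a mutation to its specialist classifier
#'
#' Glu mutations are scored by the Glu specialist, Arg by the Arg
#' specialist, every other mutable amino acid by the general model.
#'
#' @param ensemble \code{hspred} ensemble.
#' @param wild_type 1-letter wild-type code.
#' @return The \code{hspred_svm} to use.
#' @export
route <- function(ensemble, wild_type) {
  stopifnot(inherits(ensemble, "hspred"))
  if (wild_type %in% c("A", "G", "P"))
    stop("residue type ", wild_type, " is not a mutation candidate")
  if (!wild_type %in% mutable_amino_acids())
    stop("unknown amino-acid code: ", wild_type)
  if (wild_type == "E" && !is.null(ensemble$model_E)) return(ensemble$model_E)
  if (wild_type == "R" && !is.null(ensemble$model_R)) return(ensemble$model_R)
  ensemble$model_X
}
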