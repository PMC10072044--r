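#' Fit a linear soft-margin SVM
#'
#' L2-regularized hinge-loss (C-SVM) linear classifier fitted by dual
#' coordinate descent with deterministic cyclic sweeps, so the fit is a pure
#' function of its inputs. The bias is handled as an augmented constant
#' feature. Written in C++ because the wrapper evaluates thousands of fits
#' per run; no SVM dependency is required.
#'
#' @param X numeric matrix (rows = samples).
#' @param y two-level factor or a vector coercible to one (level 2 =
#'   positive class, mapped to +1).
#' @param cost soft-margin cost C (> 0).
#' @param max_iter maximum coordinate-descent sweeps.
#' @param tol stop when the largest projected gradient falls below this.
#' @return A list of class `linear_svm` with `coef` (length `ncol(X) + 1`,
#'   bias last) and the factor `levels`.
#' @export
svm_linear <- function(X, y, cost = 1, max_iter = 1000L, tol = 1e-6) {
  X <- as.matrix(X)
  if (!is.factor(y)) y <- factor(y)
  if (nlevels(y) != 2L) stop("svm_linear requires exactly two classes")
  ypm <- ifelse(as.integer(y) == 2L, 1, -1)
  coef <- .svm_dcd_fit(X, ypm, C = cost, max_iter = as.integer(max_iter),
                       tol = tol)
  structure(list(coef = coef, levels = levels(y)), class = "linear_svm")
}

#' Predict classes from a fitted linear SVM
#'
#' @param object a `linear_svm` fit.
#' @param newdata numeric matrix with the same columns as the training data.
#' @param type `"class"` for labels, `"decision"` for the signed margin.
#' @param ... unused.
#' @return Factor of predicted labels, or a numeric vector of decision
#'   values. Decision values of exactly 0 go to the positive class.
#' @export
predict.linear_svm <- function(object, newdata, type = c("class", "decision"),
                               ...) {
  type <- match.arg(type)
  dec <- as.numeric(.svm_decision(as.matrix(newdata), object$coef))
  if (type == "decision") return(dec)
  factor(object$levels[ifelse(dec >= 0, 2L, 1L)], levels = object$levels)
}
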