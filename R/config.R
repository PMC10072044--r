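#' Configuration for the EF-BDBA pipeline
#'
#' Collects every tunable of both stages in one validated list. Wrapper
#' defaults follow the published parameterization (`G = 500`, `NP = 30`,
#' `P1 = 0.6`, `P2 = 0.4`, `alpha = 0.9`, scaling-factor bounds 0.1/0.9);
#' filter and preprocessing knobs default to the classic conventions noted
#' below.
#'
#' @param G maximum number of wrapper generations (>= 1).
#' @param NP population size (>= 4; mutation needs three donors distinct from
#'   the target).
#' @param P1 probability of moving toward the best vulture (vs. a random
#'   move) during the exploration phase, in \[0, 1\].
#' @param P2 probability of the siege-fight update (vs. rotating flight)
#'   during the transition phase, in \[0, 1\].
#' @param alpha adaptive crossover factor parameter in (0, 1]; the crossover
#'   rate decays from `alpha` toward `alpha * 0.2384`.
#' @param f_min,f_max bounds of the inertial adaptive scaling factor F,
#'   `0 <= f_min < f_max <= 1`.
#' @param p_init per-bit inclusion probability at population initialization.
#' @param use_bavoa logical; fuse the binary African-vultures step into the
#'   first 40\% of generations (gated by the starvation rate). `FALSE` gives
#'   a pure improved-binary-DE run.
#' @param relevance_keep fraction of features kept by class relevance before
#'   the FCBF loop (quantile rule), used when `delta` is `NULL`.
#' @param delta optional absolute relevance threshold in \[0, 0.8); overrides
#'   `relevance_keep`.
#' @param n_comp number of sample draws for the complementarity estimate
#'   (clipped to the number of samples).
#' @param comp_neighbor heterogeneous nearest neighbor rule for
#'   complementarity: `"index"` (closest opposite-class sample by position in
#'   the sample order) or `"euclidean"` (closest in the two-feature subspace).
#' @param smote_k SMOTE neighbor count (classic default 5).
#' @param fisher_top_k number of top Fisher-score features intersected with
#'   the FCBF set (published default 100).
#' @param tukey_k Tukey fence multiplier (classic inner fences, 1.5).
#' @param knn_k neighbor count for KNN imputation.
#' @param svm_cost soft-margin cost C of the linear SVM fitness classifier.
#' @param cv_folds stratified cross-validation folds for the fitness (5).
#' @param seed integer seed; all randomness in a run flows from it.
#' @return A validated list of class `bdba_config`.
#' @export
bdba_config <- function(G = 500L, NP = 30L, P1 = 0.6, P2 = 0.4, alpha = 0.9,
                        f_min = 0.1, f_max = 0.9, p_init = 0.5,
                        use_bavoa = TRUE,
                        relevance_keep = 0.2, delta = NULL,
                        n_comp = 20L, comp_neighbor = c("index", "euclidean"),
                        smote_k = 5L, fisher_top_k = 100L,
                        tukey_k = 1.5, knn_k = 5L,
                        svm_cost = 1, cv_folds = 5L,
                        seed = 1L) {
  comp_neighbor <- match.arg(comp_neighbor)
  G <- as.integer(G); NP <- as.integer(NP)
  stopifnot(G >= 1L, NP >= 4L,
            P1 >= 0, P1 <= 1, P2 >= 0, P2 <= 1,
            alpha > 0, alpha <= 1,
            f_min >= 0, f_min < f_max, f_max <= 1,
            p_init > 0, p_init <= 1,
            relevance_keep > 0, relevance_keep <= 1,
            is.null(delta) || (delta >= 0 && delta < 0.8),
            n_comp >= 1L, smote_k >= 1L, fisher_top_k >= 1L,
            tukey_k > 0, knn_k >= 1L, svm_cost > 0, cv_folds >= 2L)
  structure(
    list(G = G, NP = NP, P1 = P1, P2 = P2, alpha = alpha,
         f_min = f_min, f_max = f_max, p_init = p_init,
         use_bavoa = isTRUE(use_bavoa),
         relevance_keep = relevance_keep, delta = delta,
         n_comp = as.integer(n_comp), comp_neighbor = comp_neighbor,
         smote_k = as.integer(smote_k),
         fisher_top_k = as.integer(fisher_top_k),
         tukey_k = tukey_k, knn_k = as.integer(knn_k),
         svm_cost = svm_cost, cv_folds = as.integer(cv_folds),
         seed = as.integer(seed)),
    class = "bdba_config"
  )
}

#' @export
print.bdba_config <- function(x, ...) {
  cat("bdba_config\n")
  cat("  wrapper: G=", x$G, " NP=", x$NP, " P1=", x$P1, " P2=", x$P2,
      " alpha=", x$alpha, " F in [", x$f_min, ",", x$f_max, "]\n", sep = "")
  cat("  filter: keep=", x$relevance_keep,
      if (!is.null(x$delta)) paste0(" delta=", x$delta) else "",
      " fisher_top_k=", x$fisher_top_k, " n_comp=", x$n_comp, "\n", sep = "")
  cat("  fitness: linear SVM (C=", x$svm_cost, "), ", x$cv_folds,
      "-fold stratified CV\n", sep = "")
  cat("  seed: ", x$seed, "\n", sep = "")
  invisible(x)
}
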