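#' Initialize the wrapper population
#'
#' `NP` random inclusion masks over a pool of `L` features, each bit set
#' independently with probability `p_init`. All-zero masks are repaired by
#' setting one uniformly random bit (the SVM fitness is undefined on zero
#' features).
#'
#' @param L pool size (>= 1).
#' @param NP population size (>= 4).
#' @param p_init per-bit inclusion probability.
#' @return List of `NP` 0/1 integer vectors of length `L`.
#' @export
init_population <- function(L, NP, p_init = 0.5) {
  stopifnot(L >= 1L, NP >= 4L, p_init > 0, p_init <= 1)
  lapply(seq_len(NP), function(i) {
    repair_mask(as.integer(stats::runif(L) < p_init))
  })
}

# all-zero masks get one random bit so they remain evaluable
repair_mask <- function(mask) {
  if (sum(mask) == 0L) mask[sample.int(length(mask), 1L)] <- 1L
  mask
}

# lexicographic global-best update: higher accuracy, then fewer features,
# then first-found
better_than_archive <- function(acc, num, archive) {
  is.null(archive) || acc > archive$acc ||
    (acc == archive$acc && num < archive$num)
}

#' Evolve the population over the candidate pool
#'
#' The hybrid wrapper loop: during the first 40\% of generations each
#' individual draws a starvation rate; if its magnitude is below 1 the
#' individual takes a binary vulture move ([bavoa_move()]), otherwise an
#' improved-binary-DE step (mutation, crossover); after the 40\% mark the
#' run is pure DE. Every child — from either path — competes with its parent
#' under the segmented-adaptive fitness at the current generation, which
#' keeps the verbatim sparsity-inverting binarization from destroying good
#' masks. A global-best archive (ranked by accuracy, then subset size, then
#' first found) is kept outside the population, since the beta-weighted
#' fitness is not comparable across generations.
#'
#' @param ds_pool an `ExpressionDataset` restricted to the candidate pool
#'   (see [build_pool()] and [subset_features()]).
#' @param cfg a [bdba_config()].
#' @param reseed seed the RNG from `cfg$seed` before starting (default TRUE;
#'   set FALSE when the caller manages the stream).
#' @return An object of class `RunReport`: list with `best_mask`,
#'   `best_feature_ids`, `best_acc`, `best_num`,
#'   `per_generation_best_fitness` (length `G`), `best_acc_trace`
#'   (non-decreasing), `pool_ids` and the `config` echo.
#' @export
evolve <- function(ds_pool, cfg = bdba_config(), reseed = TRUE) {
  check_two_classes(ds_pool)
  if (reseed) set.seed(cfg$seed)
  L <- n_features(ds_pool)
  if (L < 1L) stop("empty candidate pool")
  evaluate <- make_fitness_evaluator(ds_pool$values, ds_pool$labels,
                                     cost = cfg$svm_cost,
                                     folds = cfg$cv_folds)
  masks <- init_population(L, cfg$NP, cfg$p_init)
  accs <- vapply(masks, evaluate, numeric(1L))
  nums <- vapply(masks, function(m) sum(m), integer(1L))
  archive <- NULL
  for (i in seq_len(cfg$NP)) {
    if (better_than_archive(accs[i], nums[i], archive)) {
      archive <- list(mask = masks[[i]], acc = accs[i], num = nums[i])
    }
  }
  gen_best_fitness <- numeric(cfg$G)
  best_acc_trace <- numeric(cfg$G)
  for (g in seq_len(cfg$G)) {
    beta <- beta_weight(g, cfg$G)
    Fg <- scaling_factor(g, cfg$G, cfg$f_min, cfg$f_max)
    CRg <- crossover_factor(g, cfg$G, cfg$alpha)
    fit <- vapply(seq_len(cfg$NP),
                  function(i) fitness_value(accs[i], nums[i], L, beta),
                  numeric(1L))
    bavoa_gen <- cfg$use_bavoa && (g / cfg$G < 0.4)
    if (bavoa_gen) {
      first_i <- order(-fit, seq_len(cfg$NP))[1L]
      x_first <- masks[[first_i]]
      f_first <- fit[first_i]
      x_new <- if (L >= 2L) random_opposition(x_first) else x_first
    }
    new_masks <- masks
    new_accs <- accs
    new_nums <- nums
    for (i in seq_len(cfg$NP)) {
      child <- NULL
      if (bavoa_gen && abs(SR <- starvation_rate(g, cfg$G)) < 1) {
        x_best <- select_best_vulture(x_first, x_new, f_first)
        donors <- sample(setdiff(seq_len(cfg$NP), i), 2L)
        child <- bavoa_move(masks[[i]], x_best,
                            masks[[donors[1L]]], masks[[donors[2L]]],
                            SR, cfg$P1, cfg$P2)
      } else {
        donors <- sample(setdiff(seq_len(cfg$NP), i), 3L)
        u <- ibde_mutation(masks[[donors[1L]]], masks[[donors[2L]]],
                           masks[[donors[3L]]], Fg)
        child <- ibde_crossover(masks[[i]], u, CRg)
      }
      child <- repair_mask(child)
      acc_c <- tryCatch(evaluate(child), error = function(e) {
        message("evolve: evaluation failed at g=", g, ", i=", i, ": ",
                conditionMessage(e))
        NA_real_
      })
      if (is.na(acc_c)) next  # child discarded, parent kept
      num_c <- sum(child)
      if (better_than_archive(acc_c, num_c, archive)) {
        archive <- list(mask = child, acc = acc_c, num = num_c)
      }
      f_child <- fitness_value(acc_c, num_c, L, beta)
      if (f_child > fit[i]) {
        new_masks[[i]] <- child
        new_accs[i] <- acc_c
        new_nums[i] <- num_c
      }
    }
    masks <- new_masks
    accs <- new_accs
    nums <- new_nums
    gen_best_fitness[g] <- max(vapply(seq_len(cfg$NP),
      function(i) fitness_value(accs[i], nums[i], L, beta), numeric(1L)))
    best_acc_trace[g] <- archive$acc
  }
  structure(
    list(best_mask = archive$mask,
         best_feature_ids = ds_pool$feature_ids[archive$mask == 1L],
         best_acc = archive$acc,
         best_num = archive$num,
         per_generation_best_fitness = gen_best_fitness,
         best_acc_trace = best_acc_trace,
         pool_ids = ds_pool$feature_ids,
         metrics = NULL,
         biomarker_stats = NULL,
         config = cfg),
    class = "RunReport"
  )
}

#' Feature ids of the final selected subset
#'
#' Maps the global-best mask back through the pool to feature identifiers.
#'
#' @param report a `RunReport` from [evolve()] or [run_efbdba()].
#' @return Character vector of selected feature ids.
#' @export
final_subset <- function(report) {
  report$pool_ids[report$best_mask == 1L]
}

#' @export
print.RunReport <- function(x, ...) {
  cat("RunReport: ", x$best_num, " feature(s) selected from a pool of ",
      length(x$pool_ids), "\n", sep = "")
  cat("  CV accuracy of best subset: ", format(x$best_acc, digits = 4),
      "\n", sep = "")
  cat("  features: ", paste(x$best_feature_ids, collapse = ", "), "\n",
      sep = "")
  if (!is.null(x$metrics)) {
    cat("  metrics: ",
        paste(names(x$metrics), format(unname(x$metrics), digits = 4),
              sep = "=", collapse = "  "), "\n", sep = "")
  }
  invisible(x)
}

#' Run the full EF-BDBA pipeline
#'
#' Preprocessing (duplicate averaging, Tukey fences, KNN imputation,
#' z-score), ensemble filter pool construction, hybrid wrapper search, and
#' final evaluation: cross-validated metrics of the selected subset plus
#' per-feature biomarker statistics (computed on the imputed, unscaled
#' expression values, where a fold change is meaningful).
#'
#' @param ds an `ExpressionDataset` (raw).
#' @param cfg a [bdba_config()].
#' @return A `RunReport` with `metrics`, `biomarker_stats` and `filter`
#'   filled in.
#' @export
run_efbdba <- function(ds, cfg = bdba_config()) {
  set.seed(cfg$seed)
  ds_dedup <- average_duplicate_features(ds)
  ds_imputed <- knn_impute(tukey_flag_outliers(ds_dedup, k = cfg$tukey_k),
                           k = cfg$knn_k)
  ds_clean <- zscore_features(ds_imputed)
  filt <- build_pool(ds_clean, cfg)
  ds_pool <- subset_features(ds_clean, filt$pool)
  report <- evolve(ds_pool, cfg, reseed = FALSE)
  sel <- match(report$best_feature_ids, ds_clean$feature_ids)
  report$metrics <- cv_metrics(ds_clean$values[, sel, drop = FALSE],
                               ds_clean$labels, cost = cfg$svm_cost,
                               folds = cfg$cv_folds)
  report$biomarker_stats <- biomarker_stats(ds_imputed,
                                            report$best_feature_ids)
  report$filter <- filt
  report
}
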