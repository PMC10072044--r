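#' Inertial adaptive scaling factor
#'
#' Decays linearly from `f_max` at the first generation toward `f_min`:
#' `F = f_min + ((G - g + 1)/G) (f_max - f_min)`, clamped to
#' `[f_min, f_max]`. Early generations mutate aggressively (global search),
#' late ones conservatively (local search).
#'
#' @param g current generation (1..G).
#' @param G maximum generations.
#' @param f_min,f_max factor bounds.
#' @return Scaling factor F.
#' @export
scaling_factor <- function(g, G, f_min = 0.1, f_max = 0.9) {
  stopifnot(g >= 1, g <= G)
  F <- f_min + ((G - g + 1) / G) * (f_max - f_min)
  min(f_max, max(f_min, F))
}

#' Sparsity-inducing binary mutation
#'
#' Builds the mutant vector from three distinct donors: per dimension,
#' `diff = 0` if the first two donors agree, else `F * x_r1`; the inclusion
#' probability is `pr = tanh(diff)`, and a bit is set only where
#' `pr >= rand(0, 1)` **and** the third donor has the bit set. The
#' conjunction makes `support(u)` a subset of `support(x_r3)`, so mutation
#' can only shrink the candidate support — the operator that keeps selected
#' subsets small.
#'
#' @param x_r1,x_r2,x_r3 donor masks (0/1 vectors of equal length).
#' @param F scaling factor from [scaling_factor()].
#' @return Mutant 0/1 vector.
#' @export
ibde_mutation <- function(x_r1, x_r2, x_r3, F) {
  L <- length(x_r1)
  stopifnot(length(x_r2) == L, length(x_r3) == L)
  diff <- ifelse(x_r1 == x_r2, 0, F * x_r1)
  pr <- tanh(diff)
  as.integer(pr >= stats::runif(L) & x_r3 == 1L)
}

#' Adaptive crossover factor
#'
#' `CR = alpha * 2 exp(-(g/G)) / (exp(g/G) + exp(-(g/G)))`, strictly
#' decreasing from `alpha` at `g = 0` to about `0.2384 * alpha` at `g = G`
#' (0.23 for alpha = 1, 0.023 for alpha = 0.1, truncated).
#'
#' @param g current generation (0..G).
#' @param G maximum generations.
#' @param alpha crossover factor parameter in (0, 1].
#' @return Crossover rate CR.
#' @export
crossover_factor <- function(g, G, alpha = 0.9) {
  stopifnot(g >= 0, g <= G)
  gg <- g / G
  alpha * 2 * exp(-gg) / (exp(gg) + exp(-gg))
}

#' Binomial crossover
#'
#' Assembles the trial vector: each coordinate comes from the mutant with
#' probability `CR`, except one uniformly drawn coordinate `jrand` which
#' always comes from the mutant (the standard DE guarantee that the trial
#' differs from the target in at least one dimension).
#'
#' @param x target mask.
#' @param u mutant mask from [ibde_mutation()].
#' @param CR crossover rate.
#' @return Trial 0/1 vector.
#' @export
ibde_crossover <- function(x, u, CR) {
  L <- length(x)
  stopifnot(length(u) == L)
  jrand <- sample.int(L, 1L)
  take <- stats::runif(L) <= CR
  take[jrand] <- TRUE
  as.integer(ifelse(take, u, x))
}

#' Segmented fitness weight
#'
#' `beta = (floor(g/100) * 100) / G + 0.1`: constant on 100-generation
#' windows and stepping upward, so the feature-count penalty grows as the
#' search matures. Once `beta >= 0.9` the fitness drops the penalty entirely
#' and optimizes accuracy alone.
#'
#' @param g current generation.
#' @param G maximum generations.
#' @return Weight beta.
#' @export
beta_weight <- function(g, G) {
  (floor(g / 100) * 100) / G + 0.1
}

#' Segmented-adaptive fitness of a subset
#'
#' `f = acc - beta * num / L` while `beta < 0.9`, else `f = acc` (final
#' phase: accuracy only). The empty mask is invalid for the SVM and gets the
#' sentinel -1 so it always loses a selection.
#'
#' @param acc cross-validated accuracy in \[0, 1\].
#' @param num number of selected features.
#' @param L pool size.
#' @param beta weight from [beta_weight()].
#' @return Fitness value.
#' @export
fitness_value <- function(acc, num, L, beta) {
  stopifnot(L >= 1)
  if (num == 0) return(-1)
  if (beta < 0.9) acc - beta * (num / L) else acc
}

#' Greedy one-to-one selection
#'
#' Keeps the trial individual only if its fitness strictly exceeds the
#' target's (ties retain the incumbent, for stability). Both fitness values
#' must be computed at the same generation (same beta).
#'
#' @param x,v lists with elements `mask` and `fitness`.
#' @return The surviving individual.
#' @export
de_select <- function(x, v) {
  if (v$fitness > x$fitness) v else x
}
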