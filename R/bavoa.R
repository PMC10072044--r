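#' Random opposition-based learning
#'
#' Inverts exactly `floor(L/2)` uniformly chosen distinct bits of the best
#' mask. The opposite individual replaces the second-best vulture of the
#' classic algorithm: it is better with some probability yet random, which
#' helps population diversity during exploration.
#'
#' @param x_first 0/1 vector (length >= 2).
#' @return 0/1 vector at Hamming distance `floor(L/2)` from `x_first`.
#' @export
random_opposition <- function(x_first) {
  L <- length(x_first)
  stopifnot(L >= 2L)
  flip <- sample.int(L, L %/% 2L)
  x_new <- x_first
  x_new[flip] <- 1L - x_new[flip]
  x_new
}

#' Select the leading vulture
#'
#' The best-fitness mask is kept with probability equal to its (clamped)
#' fitness; otherwise the opposition-derived mask leads:
#' `x_best = x_first` if `rand(0,1) <= clamp(f_first, 0, 1)`, else `x_new`.
#' A strong incumbent therefore usually leads, while a weak one frequently
#' yields to the random opposite.
#'
#' @param x_first best-fitness mask.
#' @param x_new opposition mask from [random_opposition()].
#' @param f_first fitness of `x_first` (clamped into \[0, 1\]; the
#'   feature-count penalty can push raw fitness slightly negative).
#' @return Either `x_first` or `x_new`.
#' @export
select_best_vulture <- function(x_first, x_new, f_first) {
  p <- min(1, max(0, f_first))
  if (stats::runif(1L) <= p) x_first else x_new
}

#' Starvation rate
#'
#' Time-decaying randomized scalar deciding vulture behavior, in the
#' original formulation (the satiety/hunger model):
#' `SR = (2 rand + 1) z (1 - g/G) + t` with `z ~ U(-1, 1)`,
#' `t = h (sin^w((pi/2)(g/G)) + cos((pi/2)(g/G)) - 1)`, `h ~ U(-2, 2)` and
#' `w = 2.5`. `|SR|` shrinks toward 0 as generations advance; at `g = G` it
#' is exactly 0. Phase branching uses the magnitude `|SR|`.
#'
#' @param g current generation (1..G).
#' @param G maximum generations.
#' @param w exponent controlling the late-phase disruption (default 2.5).
#' @return Signed starvation rate.
#' @export
starvation_rate <- function(g, G, w = 2.5) {
  stopifnot(g >= 1, g <= G)
  z <- stats::runif(1L, -1, 1)
  h <- stats::runif(1L, -2, 2)
  gg <- g / G
  t <- h * (sin((pi / 2) * gg)^w + cos((pi / 2) * gg) - 1)
  (2 * stats::runif(1L) + 1) * z * (1 - gg) + t
}

#' Random-movement exploration update
#'
#' `x' = x + D * SR` with `D = (2 rand) x_r1 - x_r2` — one shared uniform
#' draw per call, matching the scalar notation of the update. Returns a
#' continuous position to be passed through [binarize_position()].
#'
#' @param x current mask.
#' @param x_r1,x_r2 two random population masks.
#' @param SR starvation rate.
#' @return Real-valued position vector.
#' @export
explore_random <- function(x, x_r1, x_r2, SR) {
  L <- length(x)
  stopifnot(length(x_r1) == L, length(x_r2) == L)
  D <- (2 * stats::runif(1L)) * x_r1 - x_r2
  x + D * SR
}

#' Best-directed exploration update
#'
#' Moves toward the leading vulture at a random distance:
#' `x' = x_best - |2 rand x_best - x| * SR` (one shared draw per call).
#'
#' @param x current mask.
#' @param x_best leading mask from [select_best_vulture()].
#' @param SR starvation rate.
#' @return Real-valued position vector.
#' @export
explore_toward_best <- function(x, x_best, SR) {
  stopifnot(length(x_best) == length(x))
  x_best - abs(2 * stats::runif(1L) * x_best - x) * SR
}

#' Transition-phase update (siege-fight or rotating flight)
#'
#' With probability `P2` the siege-fight move
#' `x' = D (SR + rand) - (x_best - x)`, `D = |2 rand x_best - x|`;
#' otherwise the rotating flight
#' `x' = x_best - (S1 + S2)` with
#' `S1 = x_best (rand x / (2 pi)) cos(x)` and
#' `S2 = x_best (rand x / (2 pi)) sin(x)` (elementwise, independent draws
#' for S1 and S2).
#'
#' @param x current mask.
#' @param x_best leading mask.
#' @param SR starvation rate.
#' @param P2 siege-fight probability.
#' @return Real-valued position vector.
#' @export
transition_update <- function(x, x_best, SR, P2) {
  stopifnot(length(x_best) == length(x))
  if (stats::runif(1L) <= P2) {
    D <- abs(2 * stats::runif(1L) * x_best - x)
    D * (SR + stats::runif(1L)) - (x_best - x)
  } else {
    S1 <- x_best * (stats::runif(1L) * x / (2 * pi)) * cos(x)
    S2 <- x_best * (stats::runif(1L) * x / (2 * pi)) * sin(x)
    x_best - (S1 + S2)
  }
}

#' Shifted-sigmoid stochastic binarization
#'
#' Maps a continuous position to a 0/1 mask: per dimension
#' `s = 1 / (1 + exp(-x - 2))` (a sigmoid shifted left by 2) and the bit is
#' set iff `rand(0,1) > s`. Note the inversion: larger positions give larger
#' `s` and therefore a *lower* probability of selection — kept exactly in
#' this form; it acts as a sparsity-inducing transfer and is counteracted by
#' parent-vs-child selection in the wrapper.
#'
#' @param x_cont real-valued position vector (finite).
#' @return 0/1 vector of the same length.
#' @export
binarize_position <- function(x_cont) {
  stopifnot(all(is.finite(x_cont)))
  s <- 1 / (1 + exp(-x_cont - 2))
  as.integer(stats::runif(length(x_cont)) > s)
}

# One full vulture move for individual mask x: pick phase from |SR|, apply
# the continuous update, binarize. Exploration chooses the best-directed
# move with probability P1, else the random move (donors x_r1, x_r2).
bavoa_move <- function(x, x_best, x_r1, x_r2, SR, P1, P2) {
  cont <- if (abs(SR) >= 0.5) {
    if (stats::runif(1L) <= P1) {
      explore_toward_best(x, x_best, SR)
    } else {
      explore_random(x, x_r1, x_r2, SR)
    }
  } else {
    transition_update(x, x_best, SR, P2)
  }
  binarize_position(cont)
}
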