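#' @useDynLib netcoop, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# 0-based edge list of an igraph object, as the C++ engine expects.
graph_edges0 <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  list(n = igraph::vcount(g),
       ei = as.integer(el[, 1L] - 1L),
       ej = as.integer(el[, 2L] - 1L))
}

rule_code <- function(rule) {
  match(rule$name, c("recolonize", "fermi", "unconditional")) - 1L
}

#' Prisoner's Dilemma payoff parameters
#'
#' The weak-dilemma parameterization used throughout: `R = 1`, `P = S = 0`,
#' `T = 1 + r`, where `r` is the cost-to-benefit ratio, and `D = T - S`
#' normalizes payoff differences in the recolonization rule.  Any values with
#' `T > R >= P >= S` are accepted.
#'
#' @param r Cost-to-benefit ratio (default 0.95).
#' @param T,R,P,S Optional explicit payoffs overriding the `r`-derived
#'   defaults.
#' @return An object of class `payoff_params`.
#' @examples
#' payoff_params(0.95)
#' @export
payoff_params <- function(r = 0.95, T = 1 + r, R = 1, P = 0, S = 0) {
  if (!(T > R && R >= P && P >= S))
    stop("payoffs must satisfy T > R >= P >= S", call. = FALSE)
  structure(list(T = T, R = R, P = P, S = S, r = r, D = T - S),
            class = "payoff_params")
}

#' @export
print.payoff_params <- function(x, ...) {
  cat(sprintf("<payoff_params> T=%g R=%g P=%g S=%g (r=%g, D=%g)\n",
              x$T, x$R, x$P, x$S, x$r, x$D))
  invisible(x)
}

#' Strategy-update rule
#'
#' @param name One of `"recolonize"` (payoff-proportional competition for
#'   each site among its occupant and neighbors), `"fermi"` (pairwise
#'   comparison with logistic imitation probability), or `"unconditional"`
#'   (copy the strictly richer best neighbor).
#' @param k Noise amplitude of the Fermi rule (default 0.1; must be > 0).
#' @return An object of class `update_rule`.
#' @export
update_rule <- function(name = c("recolonize", "fermi", "unconditional"),
                        k = 0.1) {
  name <- match.arg(name)
  if (name == "fermi" && !(is.numeric(k) && k > 0))
    stop("`k` must be > 0 for the fermi rule", call. = FALSE)
  structure(list(name = name, k = k), class = "update_rule")
}

#' Equilibrium evaluation mode
#'
#' A transient of `ceiling(transient_factor * N)` generations is discarded,
#' then the cooperation frequency is averaged over
#' `ceiling(averaging_factor * N)` consecutive generations.
#'
#' @param transient_factor Transient length as a multiple of the node count.
#' @param averaging_factor Averaging-window length as a multiple of the node
#'   count.
#' @return An object of class `evaluation_mode`.
#' @seealso [mode_a()], [mode_b()]
#' @export
evaluation_mode <- function(transient_factor, averaging_factor) {
  if (!(transient_factor > 0 && averaging_factor > 0))
    stop("both factors must be > 0", call. = FALSE)
  structure(list(transient_factor = transient_factor,
                 averaging_factor = averaging_factor),
            class = "evaluation_mode")
}

#' @rdname evaluation_mode
#' @details Mode-A discards `N` generations and averages `0.1 N`; Mode-B
#'   discards `10 N` and averages `N`.  Both yield similar distributions of
#'   the equilibrium cooperation level; Mode-A is the default because it is
#'   an order of magnitude cheaper.
#' @export
mode_a <- function() evaluation_mode(1, 0.1)

#' @rdname evaluation_mode
#' @export
mode_b <- function() evaluation_mode(10, 1)

#' Accumulated game payoffs
#'
#' Each node plays one Prisoner's Dilemma round with every neighbor and
#' payoffs add up: against a neighbor, a cooperator earns `R` (vs C) or `S`
#' (vs D), a defector earns `T` (vs C) or `P` (vs D).
#'
#' @param g An igraph object.
#' @param strategies Integer/logical vector, one per node; 1 = cooperate,
#'   0 = defect.
#' @param pp A [payoff_params()] object.
#' @return Numeric vector of per-node payoffs.
#' @export
accumulate_payoffs <- function(g, strategies, pp = payoff_params()) {
  strategies <- as.integer(strategies)
  stopifnot(length(strategies) == igraph::vcount(g),
            all(strategies %in% c(0L, 1L)))
  e <- graph_edges0(g)
  cpp_accumulate_payoffs(e$n, e$ei, e$ej, strategies, pp$T, pp$R, pp$P, pp$S)
}

#' Probability that a neighbor takes over a site
#'
#' Under the recolonization rule, neighbor `y` succeeds in placing an
#' offspring on site `x` with probability `(P_y - P_x) / (D * max(d_x, d_y))`
#' when `P_y > P_x`, and 0 otherwise (including the tie `P_y = P_x`).
#' Payoffs accumulated over at most `max(d_x, d_y)` games each bounded by
#' `D = T - S` keep the value in `[0, 1]`.
#'
#' @param p_x,p_y Payoffs of the focal site and the neighbor (vectorized).
#' @param d_x,d_y Their degrees (>= 1).
#' @param pp A [payoff_params()] object.
#' @return Takeover probabilities in `[0, 1]`.
#' @export
takeover_probability <- function(p_x, p_y, d_x, d_y, pp = payoff_params()) {
  stopifnot(all(d_x >= 1), all(d_y >= 1))
  ifelse(p_y > p_x, (p_y - p_x) / (pp$D * pmax(d_x, d_y)), 0)
}

#' Fermi imitation probability
#'
#' Probability that a learner with payoff difference `delta = P_learner -
#' P_model` adopts the model's strategy: `1 / (1 + exp(delta / k))`.
#' Equal payoffs give 1/2; the probability decreases monotonically in
#' `delta`.
#'
#' @param delta Payoff difference, learner minus model (vectorized).
#' @param k Noise amplitude (> 0).
#' @return Adoption probabilities in `(0, 1)`.
#' @export
fermi_probability <- function(delta, k = 0.1) {
  stopifnot(k > 0)
  stats::plogis(-delta / k)
}

check_strategies <- function(g, strategies) {
  strategies <- as.integer(strategies)
  stopifnot(length(strategies) == igraph::vcount(g),
            all(strategies %in% c(0L, 1L)))
  strategies
}

#' One synchronous generation of strategy updating
#'
#' All sites revise simultaneously from the payoffs and strategies of the
#' current generation.
#'
#' `step_recolonize`: site `x` keeps its strategy with probability
#' `prod_y (1 - W_y)` over neighbor takeover probabilities `W_y` (see
#' [takeover_probability()]); otherwise one neighbor is adopted with relative
#' probability `W_y / sum(W)`.
#'
#' `step_fermi`: each node picks one neighbor uniformly and adopts its
#' strategy with probability `1 / (1 + exp((P_self - P_neighbor) / k))`.
#'
#' `step_unconditional`: each node copies the neighbor with the largest
#' payoff provided that payoff strictly exceeds its own; ties among equally
#' best neighbors are broken uniformly at random.
#'
#' @inheritParams accumulate_payoffs
#' @param k Fermi noise amplitude.
#' @return The next generation's strategy vector.
#' @name game_step
NULL

#' @rdname game_step
#' @export
step_recolonize <- function(g, strategies, pp = payoff_params()) {
  strategies <- check_strategies(g, strategies)
  e <- graph_edges0(g)
  cpp_step(e$n, e$ei, e$ej, strategies, 0L, pp$T, pp$R, pp$P, pp$S, 0.1)
}

#' @rdname game_step
#' @export
step_fermi <- function(g, strategies, pp = payoff_params(), k = 0.1) {
  strategies <- check_strategies(g, strategies)
  stopifnot(k > 0)
  e <- graph_edges0(g)
  cpp_step(e$n, e$ei, e$ej, strategies, 1L, pp$T, pp$R, pp$P, pp$S, k)
}

#' @rdname game_step
#' @export
step_unconditional <- function(g, strategies, pp = payoff_params()) {
  strategies <- check_strategies(g, strategies)
  e <- graph_edges0(g)
  cpp_step(e$n, e$ei, e$ej, strategies, 2L, pp$T, pp$R, pp$P, pp$S, 0.1)
}

#' Cooperation-level estimate with sampling bookkeeping
#'
#' Holds the running aggregate of independent equilibrium evaluations of one
#' structure: `sum` of sampled cooperation levels, `num` of samples, and the
#' derived mean `avg = sum / num`.
#'
#' @param sum Sum of sampled cooperation levels.
#' @param num Number of samples (>= 1).
#' @return An object of class `coop_estimate` with fields `sum`, `num`,
#'   `avg`.
#' @export
coop_estimate <- function(sum, num) {
  stopifnot(num >= 1, sum >= 0, sum <= num + 1e-12)
  structure(list(sum = sum, num = as.integer(num), avg = sum / num),
            class = "coop_estimate")
}

#' @export
print.coop_estimate <- function(x, ...) {
  cat(sprintf("<coop_estimate> avg=%.4f (sum=%.4f over num=%d samples)\n",
              x$avg, x$sum, x$num))
  invisible(x)
}

#' Evaluate the equilibrium cooperation level of a structure
#'
#' Strategies are initialized as cooperator/defector with equal probability
#' (or forced via `init`), the game runs through the mode's transient, and
#' the cooperation frequency is averaged over the mode's averaging window.
#' Homogeneous states are absorbing under all three rules and short-circuit
#' the remaining generations analytically.
#'
#' @param g A connected igraph object.
#' @param rule An [update_rule()].
#' @param pp A [payoff_params()].
#' @param mode An [evaluation_mode()].
#' @param init Optional forced initial strategy vector (testing hook).
#' @return A [coop_estimate()] with `num = 1`.
#' @export
evaluate_cooperation <- function(g, rule = update_rule("recolonize"),
                                 pp = payoff_params(), mode = mode_a(),
                                 init = NULL) {
  n <- igraph::vcount(g)
  e <- graph_edges0(g)
  init <- if (is.null(init)) integer(0) else check_strategies(g, init)
  val <- cpp_evaluate(e$n, e$ei, e$ej, rule_code(rule),
                      pp$T, pp$R, pp$P, pp$S, rule$k,
                      as.integer(ceiling(mode$transient_factor * n)),
                      as.integer(ceiling(mode$averaging_factor * n)),
                      init)
  coop_estimate(val, 1L)
}

#' Average several independent equilibrium evaluations
#'
#' Multi-sampling narrows the spread of the noisy cooperation-level estimate
#' at a proportional computational cost.
#'
#' @inheritParams evaluate_cooperation
#' @param n_samples Number of independent evaluations (>= 1).
#' @return A [coop_estimate()] with `num = n_samples`.
#' @export
multi_sample_evaluate <- function(g, n_samples, rule = update_rule("recolonize"),
                                  pp = payoff_params(), mode = mode_a()) {
  stopifnot(n_samples >= 1)
  total <- 0
  for (i in seq_len(n_samples)) {
    total <- total + evaluate_cooperation(g, rule, pp, mode)$sum
  }
  coop_estimate(total, n_samples)
}
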