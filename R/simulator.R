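#' Simulation settings for the stationary process
#'
#' @param rate expected tie-change opportunities per actor (the rate
#'   parameter lambda of the continuous-time process; fixed, never
#'   estimated). Values of 10,000 or more are known to invite degenerate
#'   behaviour and trigger a warning.
#' @param mode `"poisson"` draws the total ministep count from
#'   Poisson(n * rate) (continuous-time semantics); `"fixed"` uses exactly
#'   `round(n * rate)` ministeps.
#' @return a `sim_settings` object.
#' @export
sim_settings <- function(rate = 36, mode = c("poisson", "fixed")) {
  mode <- match.arg(mode)
  if (!is.numeric(rate) || rate <= 0) stop("rate must be positive")
  if (rate >= 10000)
    warning("rate >= 10,000: degeneracy of the stationary process expected")
  structure(list(rate = rate, mode = mode), class = "sim_settings")
}

#' Ministep choice probabilities
#'
#' The multinomial-logit distribution over a focal actor's alternatives:
#' toggling the tie to each alter j (probability proportional to
#' exp(evaluation gain)) or doing nothing (gain 0).
#'
#' @inheritParams change_statistics
#' @return numeric vector of length n: positions 1..n-1-ish named by alter
#'   label hold toggle probabilities (the focal actor's own position is
#'   dropped), plus a final `"<keep>"` entry for the no-change alternative.
#'   Strictly positive, sums to 1.
#' @export
choice_probabilities <- function(evalfn, net, village, i) {
  i <- resolve_actor(net, i)
  d <- change_statistics(evalfn, net, village, i)
  gains <- colSums(d * evalfn$beta)
  if (any(!is.finite(gains[-i]))) {
    k <- which(!is.finite(colSums(d[, -i, drop = FALSE] * evalfn$beta)))
    bad <- rownames(d)[which(apply(!is.finite(d[, -i, drop = FALSE]), 1,
                                   any))]
    stop("non-finite evaluation gain (effect: ",
         paste(bad, collapse = ", "), ")")
  }
  g <- c(gains[-i], 0)
  names(g) <- c(colnames(d)[-i], "<keep>")
  e <- exp(g - max(g))
  e / sum(e)
}

#' One ministep
#'
#' The focal actor draws one alternative from [choice_probabilities()] and
#' applies it; the returned network differs from the input by at most one tie
#' in row `i`.
#'
#' @inheritParams choice_probabilities
#' @return the updated `directed_network`.
#' @export
ministep <- function(evalfn, net, village, i) {
  i <- resolve_actor(net, i)
  p <- choice_probabilities(evalfn, net, village, i)
  pick <- sample.int(length(p), 1, prob = p)
  nm <- names(p)[pick]
  if (nm == "<keep>") return(net)
  j <- match(nm, rownames(net))
  net[i, j] <- 1L - net[i, j]
  net
}

#' Simulate a chain of ministeps
#'
#' Runs the continuous-time process: the total number of ministeps is
#' Poisson(n * rate) (or fixed at round(n * rate)); at each ministep the
#' focal actor is drawn uniformly (rates are homogeneous because the rate
#' parameter is a fixed constant) and makes a multinomial-logit choice among
#' toggling each outgoing tie or keeping the status quo.
#'
#' @inheritParams choice_probabilities
#' @param settings a [sim_settings()] object.
#' @param return_score if `TRUE`, also return the per-chain score vector
#'   (the gradient of the chain log-likelihood in the effect weights), used
#'   by the score-function Jacobian estimate.
#' @param record_states if `TRUE` (n <= 5 only), also return the
#'   bit-encoded network state after every ministep.
#' @return the final `directed_network`, with attributes `score` and
#'   `states` when requested.
#' @export
simulate_chain <- function(evalfn, net, village, settings = sim_settings(),
                           return_score = FALSE, record_states = FALSE) {
  comp <- compile_evalfn(evalfn, village)
  n <- n_actors(net)
  nsteps <- if (settings$mode == "poisson")
    stats::rpois(1, n * settings$rate) else as.integer(round(n * settings$rate))
  res <- .simulate_chain_cpp(adj(net), comp$codes, comp$weights, comp$beta,
                             comp$hh, nsteps, score = return_score,
                             record = record_states)
  out <- directed_network(res$net, actor_labels(net),
                          attr(net, "observation_label"))
  if (return_score) {
    sc <- res$score
    names(sc) <- names(evalfn$beta)
    attr(out, "score") <- sc
  }
  if (record_states) attr(out, "states") <- res$states
  attr(out, "nsteps") <- nsteps
  out
}

#' Simulate an ensemble of independent chains
#'
#' Each replicate runs [simulate_chain()] from the same start under its own
#' RNG sub-stream (derived from the current RNG state by drawing one
#' sub-seed per replicate up front), so ensembles are reproducible for a
#' given master seed regardless of R.
#'
#' @inheritParams simulate_chain
#' @param R number of replicates (>= 1).
#' @param statistics if `TRUE` (default) compute the target statistic vector
#'   (column sums of [effect_statistics()]) for every replicate.
#' @param return_networks keep the simulated networks (default `FALSE` to
#'   save memory; the first replicate is always kept).
#' @return list with `stats` (R x K matrix or `NULL`), `scores` (R x K),
#'   `networks` (list or first network only).
#' @export
simulate_ensemble <- function(evalfn, net, village,
                              settings = sim_settings(), R = 1,
                              statistics = TRUE, return_networks = FALSE,
                              return_score = FALSE) {
  stopifnot(R >= 1)
  subseeds <- sample.int(.Machine$integer.max, R)
  K <- length(evalfn$beta)
  stats_m <- if (statistics) matrix(0, R, K,
                                    dimnames = list(NULL,
                                                    names(evalfn$beta)))
  scores <- if (return_score) matrix(0, R, K,
                                     dimnames = list(NULL,
                                                     names(evalfn$beta)))
  nets <- if (return_networks) vector("list", R)
  first <- NULL
  for (r in seq_len(R)) {
    set.seed(subseeds[r])
    sim <- simulate_chain(evalfn, net, village, settings,
                          return_score = return_score)
    if (statistics)
      stats_m[r, ] <- colSums(effect_statistics(evalfn, sim, village))
    if (return_score) scores[r, ] <- attr(sim, "score")
    if (return_networks) nets[[r]] <- sim
    if (r == 1) first <- sim
  }
  list(stats = stats_m, scores = scores,
       networks = if (return_networks) nets else list(first))
}
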