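#' Alter-choice distribution of an actor
#'
#' The probability distribution over the n-1 potential alters implied by the
#' fitted evaluation function at the observed network: the probability that
#' actor i's next tie change involves alter j, proportional to the
#' exponentiated evaluation gain of toggling the tie to j. The no-change
#' alternative is excluded from this choice set (it belongs to the
#' simulator's ministep, not to the alter-choice measure).
#'
#' @inheritParams change_statistics
#' @return named probability vector over the n-1 alters (strictly positive,
#'   sums to 1).
#' @export
alter_choice_distribution <- function(evalfn, net, village, i) {
  i <- resolve_actor(net, i)
  d <- change_statistics(evalfn, net, village, i)
  g <- colSums(d[, -i, drop = FALSE] * evalfn$beta)
  e <- exp(g - max(g))
  e / sum(e)
}

# choice distributions with and without each effect's contribution, from one
# change-statistic evaluation
choice_perturbations <- function(evalfn, net, village, i) {
  i <- resolve_actor(net, i)
  d <- change_statistics(evalfn, net, village, i)[, -i, drop = FALSE]
  contrib <- d * evalfn$beta          # K x (n-1), row k = beta_k * Delta_k
  g <- colSums(contrib)
  soft <- function(v) { e <- exp(v - max(v)); e / sum(e) }
  pi_full <- soft(g)
  K <- length(evalfn$beta)
  raw <- numeric(K)
  for (k in seq_len(K)) {
    pi_k <- soft(g - contrib[k, ])
    raw[k] <- sum(abs(pi_full - pi_k))
  }
  names(raw) <- names(evalfn$beta)
  list(pi = pi_full, raw = raw)
}

#' Raw per-effect importance for one actor
#'
#' For each effect k, the L1 distance between the alter-choice distribution
#' and the distribution obtained when k's contribution to every
#' alternative's gain is removed (its change statistics treated as zero)
#' while all other effects and weights are kept.
#'
#' @inheritParams alter_choice_distribution
#' @return named numeric vector of raw importances (one per effect).
#' @export
effect_importance <- function(evalfn, net, village, i) {
  choice_perturbations(evalfn, net, village, i)$raw
}

#' Relative importance of effects
#'
#' Per-actor normalized importances I_k(x, i) = raw_k / sum_l raw_l (each row
#' sums to 1), their across-actor averages I_k(x), and the entropy-based
#' degree of certainty R_H per actor and globally. Actors whose raw vector is
#' all zero (all weights zero) receive the uniform 1/K with a warning.
#' Importance is a deterministic function of the observed network, the
#' weights and the covariates; no simulation is involved, and parameter
#' uncertainty is not propagated.
#'
#' @inheritParams effect_statistics
#' @return an `importance_result` list: `per_actor` (n x K matrix of
#'   I_k(x, i)), `global` (K vector I_k(x)), `raw` (n x K), `r_h_actor`,
#'   `r_h` and `choice` (n x (n-1) matrix of alter-choice probabilities,
#'   columns indexed by alter rank).
#' @export
relative_importance <- function(evalfn, net, village) {
  n <- n_actors(net)
  K <- length(evalfn$beta)
  raw <- matrix(0, n, K, dimnames = list(actor_labels(net),
                                         names(evalfn$beta)))
  rh <- numeric(n)
  choice <- matrix(0, n, n - 1)
  warned <- FALSE
  for (i in seq_len(n)) {
    cp <- choice_perturbations(evalfn, net, village, i)
    raw[i, ] <- cp$raw
    choice[i, ] <- cp$pi
    rh[i] <- 1 - shannon_entropy(cp$pi) / log(n - 1)
  }
  per_actor <- raw
  zero_rows <- rowSums(raw) == 0
  if (any(zero_rows)) {
    warning(sum(zero_rows),
            " actor(s) with all-zero importance; assigned uniform 1/K")
    per_actor[zero_rows, ] <- 1 / K
  }
  per_actor[!zero_rows, ] <- raw[!zero_rows, , drop = FALSE] /
    rowSums(raw)[!zero_rows]
  structure(list(per_actor = per_actor, global = colMeans(per_actor),
                 raw = raw, r_h_actor = stats::setNames(rh,
                                                        actor_labels(net)),
                 r_h = mean(rh), choice = choice),
            class = "importance_result")
}

#' @export
print.importance_result <- function(x, ...) {
  cat("<importance_result> global I_k(x):\n")
  print(round(sort(x$global, decreasing = TRUE), 3))
  cat(sprintf("global R_H = %.3f\n", x$r_h))
  invisible(x)
}

shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Entropy-based degree of certainty
#'
#' R_H(i) = 1 - H(pi_i) / log(n - 1), where H is the Shannon entropy of
#' actor i's alter-choice distribution: 0 for a uniform distribution
#' (complete uncertainty about whom i would pick), 1 when one alter holds
#' all probability mass. The global value is the mean over actors. The
#' measure is invariant to the logarithm base.
#'
#' @inheritParams effect_statistics
#' @return list with `actor` (per-actor R_H) and `global`.
#' @export
degree_of_certainty <- function(evalfn, net, village) {
  n <- n_actors(net)
  rh <- vapply(seq_len(n), function(i) {
    p <- alter_choice_distribution(evalfn, net, village, i)
    1 - shannon_entropy(p) / log(n - 1)
  }, numeric(1))
  list(actor = stats::setNames(rh, actor_labels(net)), global = mean(rh))
}
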