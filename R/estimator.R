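#' Estimation settings
#'
#' Controls for the stochastic-approximation fit. The defaults use four
#' gain-halving subphases for the parameter phase and a 1,000-iteration
#' diagnostics phase; the diagnostics phase can be raised (e.g. to 20,000)
#' for publication-grade standard errors.
#'
#' @param subphases number of Phase-2 subphases (gain halved after each).
#' @param iterations_per_subphase base iteration count of the first subphase;
#'   later subphases grow by factor 1.5.
#' @param initial_gain Robbins-Monro step size a0 for the first subphase.
#' @param phase3_iterations simulations used for standard errors, convergence
#'   ratios and the moment Jacobian.
#' @param phase1_iterations simulations used for the initial Jacobian.
#' @param max_step cap on the parameter-update norm per iteration.
#' @param newton_steps maximum damped Newton polish steps between the
#'   parameter phase and the diagnostics phase (each uses a large ensemble;
#'   polishing stops early once the overall Mahalanobis deviation ratio
#'   falls below 0.07).
#' @return an `est_settings` object.
#' @export
est_settings <- function(subphases = 4, iterations_per_subphase = 50,
                         initial_gain = 0.2, phase3_iterations = 1000,
                         phase1_iterations = 60, max_step = 2,
                         newton_steps = 8) {
  stopifnot(subphases >= 1, iterations_per_subphase >= 1, initial_gain > 0,
            phase3_iterations >= 2, phase1_iterations >= 2, max_step > 0,
            newton_steps >= 0)
  structure(list(subphases = subphases,
                 iterations_per_subphase = iterations_per_subphase,
                 initial_gain = initial_gain,
                 phase3_iterations = phase3_iterations,
                 phase1_iterations = phase1_iterations,
                 max_step = max_step, newton_steps = newton_steps),
            class = "est_settings")
}

#' Observed target statistics
#'
#' The moment-condition targets: for every effect, the statistic summed over
#' actors at the observed network.
#'
#' @inheritParams effect_statistics
#' @return named numeric vector of length K.
#' @export
observed_targets <- function(evalfn, net, village) {
  colSums(effect_statistics(evalfn, net, village))
}

# Score-function estimate of the moment Jacobian D = dE[S]/dbeta:
# D_kl = Cov(S_k, score_l) across simulated chains.
jacobian_score <- function(stats_m, scores) {
  Sc <- scale(stats_m, scale = FALSE)
  Uc <- scale(scores, scale = FALSE)
  crossprod(Sc, Uc) / (nrow(stats_m) - 1)
}

#' Fit the stationary actor-oriented model by method of moments
#'
#' Robbins-Monro stochastic approximation: each iteration simulates one chain
#' from the observed network and updates the weights by
#' \eqn{\beta \leftarrow \beta - a D^{-1} (S_{sim} - S_{obs})}, with the gain
#' `a` halved across subphases and the Jacobian `D` estimated by the
#' score-function method. After the final subphase, diagnostics are computed
#' by [phase3_diagnostics()]. The rate parameter is a fixed constant of
#' `settings_sim`, never estimated. Out-degree starts at the logit of the
#' observed density and all other effects at zero.
#'
#' @inheritParams effect_statistics
#' @param settings_sim [sim_settings()] for the chains.
#' @param settings_est [est_settings()].
#' @param beta0 optional start values overriding the default.
#' @param seed optional integer; when given, `set.seed(seed)` is called so a
#'   refit with the same seed (sequential execution) is bit-identical.
#' @return a `saom_fit` object: estimates, standard errors, covariance,
#'   per-effect convergence t-ratios, overall maximum convergence ratio,
#'   convergence flag and the settings used.
#' @export
fit_saom <- function(evalfn, net, village, settings_sim = sim_settings(),
                     settings_est = est_settings(), beta0 = NULL,
                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- length(evalfn$beta)
  s_obs <- observed_targets(evalfn, net, village)
  if (is.null(beta0)) {
    beta0 <- stats::setNames(numeric(K), names(evalfn$beta))
    outd <- which(vapply(evalfn$effects, function(e)
      e$type == "outdegree", logical(1)))
    if (length(outd)) {
      dens <- graph_density(net)
      dens <- min(max(dens, 1 / (n_actors(net)^2)), 1 - 1 / (n_actors(net)^2))
      beta0[outd] <- stats::qlogis(dens)
    }
  }
  beta <- beta0
  # Phase 1: initial Jacobian at the start values
  ens <- simulate_ensemble(set_beta(evalfn, beta), net, village, settings_sim,
                           R = settings_est$phase1_iterations,
                           return_score = TRUE)
  D <- jacobian_score(ens$stats, ens$scores)
  # Phase 2: gain-halving subphases. For stability the update direction
  # partially diagonalizes the derivative matrix (a noisy full Jacobian can
  # throw the iterates off; the diagonal alone converges too slowly for
  # correlated statistics), and subphase re-estimates of the Jacobian are
  # blended with the previous estimate rather than adopted outright.
  stabilize <- function(D, mix = 0.2) {
    d <- diag(D)
    floorv <- 0.01 * stats::median(d[d > 0])
    if (!is.finite(floorv) || floorv <= 0) floorv <- 1
    Dm <- (1 - mix) * D + mix * diag(pmax(d, floorv), K)
    diag(Dm) <- pmax(diag(Dm), floorv)
    Dm
  }
  a <- settings_est$initial_gain
  n_iter <- settings_est$iterations_per_subphase
  sub <- 0
  attempts <- 0
  R_re <- max(settings_est$phase1_iterations, K + 10)
  while (sub < settings_est$subphases &&
         attempts < settings_est$subphases + 4) {
    attempts <- attempts + 1
    iterates <- matrix(0, n_iter, K)
    Dinv <- solve_regularized(stabilize(D))
    for (it in seq_len(n_iter)) {
      sim <- simulate_chain(set_beta(evalfn, beta), net, village,
                            settings_sim)
      s_sim <- colSums(effect_statistics(evalfn, sim, village))
      step <- a * as.numeric(Dinv %*% (s_sim - s_obs))
      nrm <- sqrt(sum(step^2))
      if (nrm > settings_est$max_step)
        step <- step * settings_est$max_step / nrm
      beta <- beta - step
      iterates[it, ] <- beta
    }
    beta <- colMeans(iterates)
    names(beta) <- names(evalfn$beta)
    # assess: a subphase only counts (and the gain only halves) once the
    # scaled deviations are in range; a far-off iterate instead refreshes
    # the Jacobian at the current point and retries with the same gain
    ens <- simulate_ensemble(set_beta(evalfn, beta), net, village,
                             settings_sim, R = R_re, return_score = TRUE)
    mdev <- colMeans(ens$stats) - s_obs
    sdev <- apply(ens$stats, 2, stats::sd)
    scaled <- max(abs(mdev / pmax(sdev, 1e-12)))
    Dnew <- jacobian_score(ens$stats, ens$scores)
    if (scaled > 2) {
      D <- Dnew
    } else {
      D <- 0.5 * D + 0.5 * Dnew
      a <- a / 2
      n_iter <- ceiling(n_iter * 1.5)
      sub <- sub + 1
    }
  }
  # Newton polish: with large ensembles the mean deviation and the
  # score-function Jacobian are precise, so a few damped Newton steps drive
  # the full (Mahalanobis) moment deviation to Monte-Carlo noise before the
  # diagnostics phase. The best iterate by overall ratio is kept.
  R_newton <- max(800, 20 * K)
  best_beta <- beta
  best_overall <- Inf
  for (np in seq_len(settings_est$newton_steps)) {
    ens <- simulate_ensemble(set_beta(evalfn, beta), net, village,
                             settings_sim, R = R_newton, return_score = TRUE)
    mdev <- colMeans(ens$stats) - s_obs
    sdev <- apply(ens$stats, 2, stats::sd)
    Sigma <- stats::cov(ens$stats)
    Sinv <- tryCatch(solve(Sigma), error = function(e) MASS::ginv(Sigma))
    overall <- sqrt(max(0, as.numeric(t(mdev) %*% Sinv %*% mdev)))
    if (overall < best_overall) {
      best_overall <- overall
      best_beta <- beta
    }
    if (overall < 0.07 && max(abs(mdev / pmax(sdev, 1e-12))) < 0.05) break
    D <- jacobian_score(ens$stats, ens$scores)
    step <- as.numeric(solve_regularized(D) %*% mdev)
    nrm <- sqrt(sum(step^2))
    if (nrm > settings_est$max_step)
      step <- step * settings_est$max_step / nrm
    beta <- beta - step
  }
  beta <- best_beta
  names(beta) <- names(evalfn$beta)
  fit <- structure(list(evalfn = set_beta(evalfn, beta), beta = beta,
                        s_obs = s_obs, net = net, village = village,
                        settings_sim = settings_sim,
                        settings_est = settings_est, seed = seed),
                   class = "saom_fit")
  phase3_diagnostics(fit, settings_est$phase3_iterations)
}

solve_regularized <- function(D) {
  K <- nrow(D)
  ridge <- 1e-8 * mean(abs(diag(D)))
  tryCatch(solve(D + diag(ridge, K)),
           error = function(e) MASS::ginv(D))
}

#' Phase-3 diagnostics: standard errors and convergence checks
#'
#' Simulates `R_iterations` chains at the fitted weights; computes per-effect
#' convergence t-ratios (mean simulated-minus-observed deviation over its
#' simulation standard deviation), the overall maximum convergence ratio
#' (Mahalanobis norm of the mean deviation), the score-function Jacobian, and
#' the parameter covariance \eqn{D^{-1} \Sigma D^{-T}}. A fit is flagged
#' converged when every |t-ratio| < 0.1 and the overall ratio < 0.15.
#'
#' @param fit a `saom_fit` (possibly from an interrupted run).
#' @param R_iterations simulations for the diagnostics.
#' @return the completed `saom_fit`.
#' @export
phase3_diagnostics <- function(fit, R_iterations = 1000) {
  ens <- simulate_ensemble(fit$evalfn, fit$net, fit$village,
                           fit$settings_sim, R = R_iterations,
                           return_score = TRUE)
  dev <- sweep(ens$stats, 2, fit$s_obs)
  mdev <- colMeans(dev)
  sdev <- apply(ens$stats, 2, stats::sd)
  tconv <- ifelse(sdev > 0, mdev / sdev, ifelse(mdev == 0, 0, Inf))
  Sigma <- stats::cov(ens$stats)
  Sinv <- tryCatch(solve(Sigma), error = function(e) {
    warning("singular simulated covariance; using generalized inverse")
    MASS::ginv(Sigma)
  })
  overall <- sqrt(max(0, as.numeric(t(mdev) %*% Sinv %*% mdev)))
  D <- jacobian_score(ens$stats, ens$scores)
  Dinv <- solve_regularized(D)
  # covariance of the moment estimator: D^-1 Sigma D^-T
  covb <- Dinv %*% Sigma %*% t(Dinv)
  covb <- (covb + t(covb)) / 2
  se <- sqrt(pmax(diag(covb), 0))
  names(se) <- names(fit$beta)
  dimnames(covb) <- list(names(fit$beta), names(fit$beta))
  fit$tconv <- stats::setNames(tconv, names(fit$beta))
  fit$overall_ratio <- overall
  fit$covariance <- covb
  fit$se <- se
  fit$jacobian <- D
  fit$sim_stats <- ens$stats
  fit$converged <- all(abs(tconv) < 0.1) && overall < 0.15
  fit$phase3_iterations <- R_iterations
  fit
}

#' @export
print.saom_fit <- function(x, ...) {
  cat(sprintf("<saom_fit> %d effects; rate = %g; %s\n", length(x$beta),
              x$settings_sim$rate,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  tab <- data.frame(estimate = round(x$beta, 3),
                    se = round(x$se, 3),
                    t_conv = round(x$tconv, 3))
  print(tab)
  cat(sprintf("overall max. convergence ratio: %.3f\n", x$overall_ratio))
  invisible(x)
}

#' Fit report as a data frame
#'
#' @param fit a `saom_fit`.
#' @return data frame with effect, estimate, standard error, two-tailed
#'   p-value (normal reference for estimate / se) and convergence t-ratio.
#' @export
fit_report <- function(fit) {
  z <- fit$beta / fit$se
  data.frame(effect = names(fit$beta), estimate = as.numeric(fit$beta),
             se = as.numeric(fit$se),
             p = 2 * stats::pnorm(-abs(z)),
             t_conv = as.numeric(fit$tconv), row.names = NULL)
}

#' Multi-parameter Wald test
#'
#' Tests whether a subset of effect weights is simultaneously zero:
#' \eqn{\chi^2 = \hat\beta_A^T (Cov_{AA})^{-1} \hat\beta_A} on |A| degrees of
#' freedom.
#'
#' @param fit a converged `saom_fit`.
#' @param effects character vector of effect names (or integer indices).
#' @return list with `chisq`, `df`, `p`.
#' @export
wald_test <- function(fit, effects) {
  idx <- if (is.character(effects)) match(effects, names(fit$beta))
         else as.integer(effects)
  if (anyNA(idx)) stop("unknown effects: ",
                       paste(effects[is.na(idx)], collapse = ", "))
  b <- fit$beta[idx]
  V <- fit$covariance[idx, idx, drop = FALSE]
  Vi <- tryCatch(solve(V), error = function(e)
    stop("singular covariance submatrix for the requested effects"))
  chisq <- as.numeric(t(b) %*% Vi %*% b)
  df <- length(idx)
  list(chisq = chisq, df = df, p = stats::pchisq(chisq, df,
                                                 lower.tail = FALSE))
}
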