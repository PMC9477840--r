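GOF_FAMILIES <- c("indegree", "outdegree", "geodesic", "triad_census",
                  "clique_census", "consanguineous_ties")

#' Auxiliary statistics for goodness-of-fit
#'
#' Fixed-layout statistic vectors per family, delegating to the census
#' operations: counts of actors per in-/out-degree value over a configured
#' range, the geodesic pair-count distribution (distances 1-5 plus pooled
#' 5+/infinity), the 16-class triad census, the maximal-clique size census
#' over a configured size range, and arc counts per consanguineal
#' relatedness class (classes fixed by the relatedness matrix).
#'
#' @param net a `directed_network`.
#' @param village the [village()] data (needed for `consanguineous_ties`).
#' @param family one of `"indegree"`, `"outdegree"`, `"geodesic"`,
#'   `"triad_census"`, `"clique_census"`, `"consanguineous_ties"`.
#' @param degree_range degree values enumerated for the degree families.
#' @param clique_range clique sizes enumerated (larger cliques pooled into
#'   the top bin).
#' @return named numeric vector with a layout that depends only on the
#'   configuration (never on the simulated network), so vectors are
#'   comparable across replicates.
#' @export
auxiliary_statistics <- function(net, village, family,
                                 degree_range = 0:(n_actors(net) - 1),
                                 clique_range = 1:8) {
  if (!family %in% GOF_FAMILIES)
    stop("unknown family '", family, "'; families: ",
         paste(GOF_FAMILIES, collapse = ", "))
  x <- adj(net)
  switch(family,
    indegree = {
      d <- colSums(x)
      stats::setNames(vapply(degree_range, function(k) sum(d == k),
                             numeric(1)),
                      paste0("in", degree_range))
    },
    outdegree = {
      d <- rowSums(x)
      stats::setNames(vapply(degree_range, function(k) sum(d == k),
                             numeric(1)),
                      paste0("out", degree_range))
    },
    geodesic = geodesic_distribution(net),
    triad_census = triad_census(net),
    clique_census = {
      cc <- clique_census(net)
      sizes <- as.integer(names(cc))
      out <- stats::setNames(numeric(length(clique_range)),
                             paste0("w", clique_range))
      top <- max(clique_range)
      for (s in seq_along(cc)) {
        bin <- min(sizes[s], top)
        if (bin %in% clique_range)
          out[paste0("w", bin)] <- out[paste0("w", bin)] + cc[s]
      }
      out
    },
    consanguineous_ties = {
      r <- village$dyads$consanguineal
      if (is.null(r)) stop("village lacks a 'consanguineal' dyad covariate")
      consanguineous_tie_distribution(net, r)
    })
}

#' Joint Mahalanobis distance test
#'
#' Distance of the observed auxiliary vector from the simulated ensemble:
#' centre = simulated mean, scatter = simulated covariance with
#' zero-variance components dropped and a generalized inverse (census
#' vectors are frequently rank-deficient). The Monte-Carlo p-value is the
#' proportion of replicates whose own (leave-in) distance is at least the
#' observed distance; p > 0.05 indicates the simulated and observed
#' distributions are compatible.
#'
#' @param observed numeric statistic vector.
#' @param simulated R x length(observed) matrix of simulated vectors (R >= 2).
#' @param tol singular-value tolerance for the generalized inverse and the
#'   zero-variance drop.
#' @return list with `mhd`, `p`, `kept` (logical vector of retained
#'   components) and `replicate_mhd`.
#' @export
mahalanobis_test <- function(observed, simulated, tol = 1e-10) {
  simulated <- as.matrix(simulated)
  if (nrow(simulated) < 2) stop("need at least 2 simulated replicates")
  if (ncol(simulated) != length(observed))
    stop("observed and simulated vectors differ in length")
  ctr <- colMeans(simulated)
  v <- apply(simulated, 2, stats::var)
  kept <- v > tol
  if (!any(kept)) {
    mhd <- if (all(abs(observed - ctr) <= tol)) 0 else Inf
    return(list(mhd = mhd, p = if (mhd == 0) 1 else 0, kept = kept,
                replicate_mhd = rep(0, nrow(simulated))))
  }
  S <- stats::cov(simulated[, kept, drop = FALSE])
  if (ncol(S) >= nrow(simulated))
    warning("fewer replicates than components; using generalized inverse")
  Sinv <- MASS::ginv(S, tol = tol)
  dev <- observed[kept] - ctr[kept]
  mhd <- as.numeric(t(dev) %*% Sinv %*% dev)
  devs <- sweep(simulated[, kept, drop = FALSE], 2, ctr[kept])
  rep_mhd <- rowSums((devs %*% Sinv) * devs)
  p <- mean(rep_mhd >= mhd - 1e-12)
  list(mhd = max(mhd, 0), p = p, kept = kept, replicate_mhd = rep_mhd)
}

#' Simulation-based goodness-of-fit
#'
#' Simulates one ensemble of stationary chains at the fitted weights (reused
#' across families) and, per auxiliary family, computes the joint
#' Mahalanobis distance of the observed vector and its Monte-Carlo p-value.
#'
#' @param fit a converged `saom_fit` (a non-converged fit is refused unless
#'   `allow_nonconverged`).
#' @param families auxiliary families to test (default all six).
#' @param R ensemble size (default 1000; raise to 20,000 for
#'   publication-grade tests).
#' @param allow_nonconverged proceed despite a non-converged fit.
#' @return named list of `gof_result` objects (one per family), each holding
#'   the observed vector, simulated means, `mhd`, `p` and `R`.
#' @export
run_gof <- function(fit, families = GOF_FAMILIES, R = 1000,
                    allow_nonconverged = FALSE) {
  if (!isTRUE(fit$converged) && !allow_nonconverged)
    stop("fit did not converge; rerun estimation or pass ",
         "allow_nonconverged = TRUE")
  bad <- setdiff(families, GOF_FAMILIES)
  if (length(bad)) stop("unknown families: ", paste(bad, collapse = ", "))
  ens <- simulate_ensemble(fit$evalfn, fit$net, fit$village,
                           fit$settings_sim, R = R, statistics = FALSE,
                           return_networks = TRUE)
  out <- list()
  for (fam in families) {
    obs <- auxiliary_statistics(fit$net, fit$village, fam)
    sim <- t(vapply(ens$networks, function(nw)
      auxiliary_statistics(nw, fit$village, fam), obs))
    mt <- mahalanobis_test(obs, sim)
    out[[fam]] <- structure(list(family = fam, observed = obs,
                                 simulated_mean = colMeans(sim),
                                 simulated = sim, mhd = mt$mhd, p = mt$p,
                                 R = R), class = "gof_result")
  }
  out
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("<gof_result> %s: MHD = %.3f, Monte-Carlo p = %.3f (R = %d)\n",
              x$family, x$mhd, x$p, x$R))
  invisible(x)
}
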