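#' Descriptive network statistics
#'
#' Basic whole-graph descriptives for a directed binary network: density,
#' the proportion of arcs that are reciprocated, weak-rule transitivity (the
#' fraction of directed two-paths i -> h -> j over distinct actors that are
#' closed by i -> j), and degree summaries. Degree standard deviations use
#' the population formula (divide by n) because the network is a census of a
#' complete population.
#'
#' @param net a `directed_network`.
#' @return `graph_density()`, `reciprocity_proportion()` and
#'   `transitivity_weak()` return a single proportion (`NaN` with a warning
#'   for an empty network where the ratio is undefined); `degree_summaries()`
#'   returns a named list.
#' @name descriptives
NULL

#' @rdname descriptives
#' @export
graph_density <- function(net) {
  n <- n_actors(net)
  sum(adj(net)) / (n * (n - 1))
}

#' @rdname descriptives
#' @export
reciprocity_proportion <- function(net) {
  x <- adj(net)
  arcs <- sum(x)
  if (arcs == 0) {
    warning("reciprocity undefined for an empty network")
    return(NaN)
  }
  sum(x * t(x)) / arcs
}

#' @rdname descriptives
#' @export
transitivity_weak <- function(net) {
  x <- adj(net)
  two_paths <- x %*% x
  diag(two_paths) <- 0            # i -> h -> i is not an (i, h, j) triple
  denom <- sum(two_paths)
  if (denom == 0) {
    warning("transitivity undefined: no directed two-paths")
    return(NaN)
  }
  sum(x * two_paths) / denom
}

#' @rdname descriptives
#' @export
degree_summaries <- function(net) {
  x <- adj(net)
  n <- nrow(x)
  outd <- rowSums(x); ind <- colSums(x)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  list(mean_degree = mean(outd), sd_out = pop_sd(outd), sd_in = pop_sd(ind),
       max_out = max(outd), max_in = max(ind), sd_formula = "population")
}

#' Triad census
#'
#' Counts of all \eqn{\binom{n}{3}} unordered actor triples classified by the
#' standard Mutual-Asymmetric-Null scheme.
#'
#' @param net a `directed_network` with at least 3 actors.
#' @return named integer vector over the 16 M-A-N codes, summing to C(n, 3).
#' @export
triad_census <- function(net) {
  if (n_actors(net) < 3) stop("triad census needs at least 3 actors")
  g <- igraph::graph_from_adjacency_matrix(adj(net), mode = "directed")
  counts <- igraph::triad_census(g)
  names(counts) <- c("003", "012", "102", "021D", "021U", "021C", "111D",
                     "111U", "030T", "030C", "201", "120D", "120U", "120C",
                     "210", "300")
  counts
}

#' Clique census
#'
#' Counts of inclusion-maximal fully mutual vertex subsets by size. A clique
#' in this directed setting is a vertex set in which every ordered pair is
#' tied in both directions; actors in no mutual dyad form size-1 cliques, so
#' every actor is covered at least once.
#'
#' @param net a `directed_network`.
#' @return named integer vector of counts indexed by clique size (1..max).
#' @export
clique_census <- function(net) {
  x <- adj(net)
  m <- x * t(x)                 # mutual-tie (undirected) adjacency
  g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected")
  cl <- igraph::max_cliques(g)
  sizes <- vapply(cl, length, integer(1))
  counts <- tabulate(sizes, nbins = max(sizes))
  names(counts) <- as.character(seq_along(counts))
  counts
}

#' Geodesic distance distribution
#'
#' Counts of ordered actor pairs at each directed shortest-path length.
#' By default distances 1 to 5 are kept separately and everything longer
#' (including unreachable pairs) is pooled into one `"5+/Inf"` bucket.
#'
#' @param net a `directed_network`.
#' @param max_distance largest distance kept as its own bucket.
#' @param pool_beyond if `TRUE` (default) distances beyond `max_distance` are
#'   pooled with unreachable pairs; otherwise they are kept in a `">max"`
#'   bucket separate from `"Inf"`.
#' @return named numeric vector of pair counts summing to n(n-1).
#' @export
geodesic_distribution <- function(net, max_distance = 5, pool_beyond = TRUE) {
  g <- igraph::graph_from_adjacency_matrix(adj(net), mode = "directed")
  d <- igraph::distances(g, mode = "out")
  d <- d[row(d) != col(d)]
  counts <- vapply(seq_len(max_distance), function(k) sum(d == k), numeric(1))
  names(counts) <- as.character(seq_len(max_distance))
  beyond <- sum(is.finite(d) & d > max_distance)
  inf <- sum(is.infinite(d))
  if (pool_beyond) {
    counts <- c(counts, `5+/Inf` = beyond + inf)
    names(counts)[length(counts)] <-
      sprintf("%d+/Inf", max_distance)
  } else {
    counts <- c(counts, beyond, inf)
    names(counts)[length(counts) - 1:0] <-
      c(sprintf(">%d", max_distance), "Inf")
  }
  counts
}

#' Arc counts by consanguineal relatedness class
#'
#' Bins the arcs of a network by the exact relatedness coefficient of the
#' dyad (pedigree-derived coefficients are dyadic rationals, so exact
#' matching with a small tolerance is appropriate).
#'
#' @param net a `directed_network`.
#' @param relatedness symmetric matrix of relatedness coefficients in [0, 1].
#' @param tol matching tolerance for grouping values into classes.
#' @return named numeric vector of arc counts per relatedness value
#'   (descending), summing to the arc count.
#' @export
consanguineous_tie_distribution <- function(net, relatedness, tol = 1e-9) {
  x <- adj(net)
  r <- relatedness
  if (any(r < -tol) || any(r > 1 + tol))
    stop("relatedness values must lie in [0, 1]")
  vals <- sort(unique(round(r[row(r) != col(r)] / tol) * tol),
               decreasing = TRUE)
  arcs_r <- r[x == 1 & row(r) != col(r)]
  counts <- vapply(vals, function(v) sum(abs(arcs_r - v) <= tol), numeric(1))
  names(counts) <- format(vals, trim = TRUE)
  counts
}

#' Product-moment graph correlation
#'
#' Pearson correlation between two networks over the n(n-1) off-diagonal
#' cells.
#'
#' @param a,b `directed_network` objects over the same actors.
#' @return correlation in [-1, 1], or `NaN` with a warning when either graph
#'   has zero variance.
#' @export
graph_correlation <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("networks must share the actor set")
  off <- row(a) != col(a)
  va <- adj(a)[off]; vb <- adj(b)[off]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    warning("graph correlation undefined: a graph has zero variance")
    return(NaN)
  }
  stats::cor(va, vb)
}

#' Kin composition of triad classes
#'
#' For each requested M-A-N triad class, the number of triads whose three
#' dyads are all "close kin" (max of consanguineal and affinal relatedness at
#' or above `threshold`) and the class total.
#'
#' @param net a `directed_network`.
#' @param consanguineal,affinal symmetric relatedness matrices.
#' @param threshold close-kin cutoff in (0, 1], default 0.125.
#' @param classes M-A-N codes to report (default all 16).
#' @return data frame with columns `class`, `all_close_kin`, `total`, `share`.
#' @export
kin_triad_composition <- function(net, consanguineal, affinal,
                                  threshold = 0.125,
                                  classes = NULL) {
  stopifnot(threshold > 0, threshold <= 1)
  x <- adj(net)
  n <- nrow(x)
  kin <- pmax(consanguineal, affinal) >= threshold
  codes <- c("003", "012", "102", "021D", "021U", "021C", "111D", "111U",
             "030T", "030C", "201", "120D", "120U", "120C", "210", "300")
  if (is.null(classes)) classes <- codes
  total <- stats::setNames(numeric(length(codes)), codes)
  kin_count <- total
  combs <- utils::combn(n, 3)
  for (c3 in seq_len(ncol(combs))) {
    trio <- combs[, c3]
    cls <- codes[classify_triad(x[trio, trio])]
    total[cls] <- total[cls] + 1
    if (kin[trio[1], trio[2]] && kin[trio[1], trio[3]] &&
        kin[trio[2], trio[3]])
      kin_count[cls] <- kin_count[cls] + 1
  }
  out <- data.frame(class = classes,
                    all_close_kin = as.numeric(kin_count[classes]),
                    total = as.numeric(total[classes]))
  out$share <- ifelse(out$total > 0, out$all_close_kin / out$total, NaN)
  out
}

# M-A-N class (1..16) of a 3x3 adjacency sub-matrix.
classify_triad <- function(s) {
  pairs <- rbind(c(1, 2), c(1, 3), c(2, 3))
  m <- a <- nn <- 0
  for (p in seq_len(3)) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    tie <- s[i, j] + s[j, i]
    if (tie == 2) m <- m + 1 else if (tie == 1) a <- a + 1 else nn <- nn + 1
  }
  key <- paste0(m, a, nn)
  switch(key,
    "003" = 1, "012" = 2, "102" = 3, "201" = 11, "210" = 15, "300" = 16,
    "021" = classify_021(s), "111" = classify_111(s),
    "030" = classify_030(s), "120" = classify_120(s),
    stop("unclassifiable triad"))
}

classify_021 <- function(s) {
  outd <- rowSums(s); ind <- colSums(s)
  if (max(outd) == 2) return(4)   # 021D: one sender to both others
  if (max(ind) == 2) return(5)    # 021U
  6                               # 021C: path
}

classify_111 <- function(s) {
  # find the asymmetric dyad and the mutual dyad
  mut <- which(s == 1 & t(s) == 1, arr.ind = TRUE)
  asym <- which(s == 1 & t(s) == 0, arr.ind = TRUE)
  # 111D: asymmetric arc points *into* the mutual dyad; 111U: out of it
  if (asym[1, "col"] %in% mut[1, ]) 7 else 8
}

classify_030 <- function(s) {
  # 030T has an actor with out-degree 2; 030C is the 3-cycle
  if (max(rowSums(s)) == 2) 9 else 10
}

classify_120 <- function(s) {
  mutm <- (s == 1 & t(s) == 1)
  third <- which(rowSums(mutm) == 0)  # actor not in the mutual dyad
  outd <- sum(s[third, ]); ind <- sum(s[, third])
  if (outd == 2) 12        # 120D: third sends to both members
  else if (ind == 2) 13    # 120U: third receives from both
  else 14                  # 120C
}
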