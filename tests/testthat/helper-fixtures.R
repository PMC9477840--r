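# Fixtures and independent brute-force oracles used across the suite.

rand_net <- function(n, p = 0.3) {
  x <- matrix(stats::rbinom(n * n, 1, p), n, n)
  diag(x) <- 0
  directed_network(x, paste0("a", seq_len(n)))
}

# Small village with every covariate the model specifications reference.
tiny_village <- function(n = 8, n_hh = 3) {
  actors <- data.frame(
    label = paste0("a", seq_len(n)),
    household = rep(seq_len(n_hh), length.out = n),
    gender = stats::rbinom(n, 1, 0.5),
    ethnicity = stats::rbinom(n, 1, 0.3),
    age = stats::runif(n, 18, 75),
    bmi = stats::rnorm(n, 24, 2),
    melanin = stats::rnorm(n, 50, 5),
    wealth = stats::rlnorm(n, 6, 1),
    household_size = sample(2:6, n, replace = TRUE),
    stringsAsFactors = FALSE)
  lab <- actors$label
  symm <- function(scale = 1) {
    m <- matrix(stats::runif(n * n), n, n) * scale
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 0
    dimnames(m) <- list(lab, lab)
    m
  }
  dyads <- list(consanguineal = symm(0.5), affinal = symm(0.4),
                distance = symm(900), godparent = round(symm()),
                infidelity = round(symm()))
  village(actors, dyads)
}

prep_tiny <- function(n = 8, n_hh = 3) {
  preprocess_covariates(tiny_village(n, n_hh))
}

# Literal-formula statistic oracle: plain loops, no shared code with the
# package's vectorized/compiled implementations.
naive_statistic <- function(type, x, i, W = NULL, hh = NULL) {
  n <- nrow(x)
  js <- setdiff(seq_len(n), i)
  s <- 0
  switch(type,
    outdegree = sum(x[i, ]),
    reciprocity = sum(sapply(js, function(j) x[i, j] * x[j, i])),
    dyadic = sum(sapply(js, function(j) x[i, j] * W[i, j])),
    dyadic_reciprocity =
      sum(sapply(js, function(j) x[i, j] * x[j, i] * W[i, j])),
    outdegree_activity = sum(x[i, ])^2,
    indegree_popularity =
      sum(sapply(js, function(j) x[i, j] * sum(x[, j]))),
    outdegree_popularity =
      sum(sapply(js, function(j) x[i, j] * sum(x[j, ]))),
    transitive_triplets = {
      for (j in js) for (h in js)
        if (h != j) s <- s + x[i, j] * x[i, h] * x[h, j]
      s
    },
    transitive_reciprocated_triplets = {
      for (j in js) for (h in js)
        if (h != j) s <- s + x[i, j] * x[j, i] * x[i, h] * x[h, j]
      s
    },
    three_cycles = {
      for (j in js) for (h in js)
        if (h != j) s <- s + x[i, j] * x[j, h] * x[h, i]
      s
    },
    dense_triads = {
      for (j in js) for (h in js)
        if (h > j) s <- s + as.numeric(x[i, j] && x[j, i] && x[i, h] &&
                                         x[h, i] && x[j, h] && x[h, j])
      s
    },
    transitive_triplets_jumping_hh = {
      for (j in js) for (h in js)
        if (h != j)
          s <- s + x[i, j] * x[i, h] * x[h, j] *
            (hh[i] == hh[h]) * (hh[j] != hh[i])
      s
    },
    shared_popularity = {
      for (h in js) {
        m <- 0
        for (t in setdiff(seq_len(n), c(i, h))) m <- m + x[i, t] * x[h, t]
        s <- s + choose(m, 2)
      }
      s
    },
    stop("unknown type"))
}

# exhaustive M-A-N classification of one triple
brute_triad_class <- function(s) {
  dy <- function(i, j) s[i, j] + 2 * s[j, i]
  # count mutual/asym/null over the three unordered dyads
  codes <- c(dy(1, 2) , dy(1, 3), dy(2, 3))
  m <- sum(codes == 3); a <- sum(codes %in% c(1, 2)); nn <- sum(codes == 0)
  key <- paste0(m, a, nn)
  if (key %in% c("003", "012", "102", "201", "210", "300")) return(key)
  if (key == "021") {
    if (max(rowSums(s)) == 2) return("021D")
    if (max(colSums(s)) == 2) return("021U")
    return("021C")
  }
  if (key == "030") {
    if (max(rowSums(s)) == 2) return("030T") else return("030C")
  }
  if (key == "111") {
    mut <- which(s == 1 & t(s) == 1, arr.ind = TRUE)[1, ]
    asym <- which(s == 1 & t(s) == 0, arr.ind = TRUE)[1, ]
    return(if (asym["col"] %in% mut) "111D" else "111U")
  }
  if (key == "120") {
    mutm <- s == 1 & t(s) == 1
    third <- which(rowSums(mutm) == 0)
    if (sum(s[third, ]) == 2) return("120D")
    if (sum(s[, third]) == 2) return("120U")
    return("120C")
  }
  stop("bad triad")
}

brute_triad_census <- function(net) {
  x <- unclass(net)
  n <- nrow(x)
  codes <- c("003", "012", "102", "021D", "021U", "021C", "111D", "111U",
             "030T", "030C", "201", "120D", "120U", "120C", "210", "300")
  out <- stats::setNames(numeric(16), codes)
  cmb <- utils::combn(n, 3)
  for (k in seq_len(ncol(cmb))) {
    cls <- brute_triad_class(x[cmb[, k], cmb[, k]])
    out[cls] <- out[cls] + 1
  }
  out
}

# maximal fully-mutual subsets by exhaustive subset enumeration
brute_clique_census <- function(net) {
  x <- unclass(net)
  n <- nrow(x)
  m <- x * t(x)
  is_clique <- function(v) {
    if (length(v) == 1) return(TRUE)
    all(m[v, v][upper.tri(diag(length(v)))] == 1)
  }
  subsets <- unlist(lapply(seq_len(n), function(k)
    utils::combn(n, k, simplify = FALSE)), recursive = FALSE)
  cliques <- Filter(is_clique, subsets)
  maximal <- Filter(function(v) {
    !any(vapply(cliques, function(w)
      length(w) > length(v) && all(v %in% w), logical(1)))
  }, cliques)
  sizes <- vapply(maximal, length, integer(1))
  counts <- tabulate(sizes, nbins = max(sizes))
  stats::setNames(counts, as.character(seq_along(counts)))
}

# all-pairs directed shortest paths by repeated boolean matrix products
brute_geodesics <- function(net) {
  x <- unclass(net)
  n <- nrow(x)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  reach <- diag(n) == 1
  step <- x > 0
  cur <- diag(n) == 1
  for (k in seq_len(n)) {
    cur <- (cur %*% x) > 0
    newly <- cur & !reach & d == Inf
    d[newly] <- k
    reach <- reach | cur
  }
  d
}
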