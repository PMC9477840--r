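#' Recipe for a synthetic village
#'
#' Defaults emulate the study conditions of a small horticulturalist village:
#' about 108 adults in about 32 households, pedigree-derived relatedness with
#' mean near 0.05, balanced gender, a minority ethnicity share near 0.15,
#' right-skewed ages on [18, 75], log-normal household wealth, and
#' inter-household distances from uniform placement in a square scaled so the
#' mean distance is roughly 500 m. The generating evaluation function
#' defaults to a conventional specification (out-degree, reciprocity,
#' distance, consanguineal and affinal relatedness) with weights of the
#' magnitude typical for support networks.
#'
#' @param n actor count.
#' @param households target household count; defaults to roughly one
#'   household per 3.4 adults (32 at n = 108).
#' @param relatedness_mean target mean pairwise consanguineal relatedness.
#' @param gender_balance probability of `gender = 1`.
#' @param ethnicity_prop probability of the minority ethnicity.
#' @param age_range adult age bounds.
#' @param wealth_meanlog,wealth_sdlog log-normal household wealth parameters
#'   (monetary units).
#' @param bmi_mean,bmi_sd,melanin_mean,melanin_sd normal covariate
#'   parameters.
#' @param mean_distance target mean inter-household distance in metres.
#' @param false_negative,false_positive per-report tie flip rates used by
#'   [generate_reports()].
#' @param beta named generating weights for the conventional effects.
#' @param burnin_rate tie-change opportunities per actor for the burn-in
#'   chain of [generate_network()].
#' @return a `village_recipe` list.
#' @export
village_recipe <- function(n = 108, households = max(2, round(n / 3.4)),
                           relatedness_mean = 0.05,
                           gender_balance = 0.5, ethnicity_prop = 0.15,
                           age_range = c(18, 75),
                           wealth_meanlog = log(323), wealth_sdlog = 1.1,
                           bmi_mean = 23.9, bmi_sd = 2.6,
                           melanin_mean = 51.6, melanin_sd = 4.7,
                           mean_distance = 500,
                           false_negative = 0.05, false_positive = 0.01,
                           beta = c(`Out-degree` = -1.558,
                                    Reciprocity = 1.652,
                                    `Geographic Distance` = -0.062,
                                    `Consanguineal Relatedness` = 2.847,
                                    `Affinal Relatedness` = 2.082),
                           burnin_rate = 200) {
  stopifnot(n >= households, relatedness_mean > 0)
  if (relatedness_mean > 0.5)
    stop("infeasible target: mean relatedness cannot exceed 0.5")
  stopifnot(false_negative >= 0, false_negative < 1,
            false_positive >= 0, false_positive < 1)
  structure(as.list(environment()), class = "village_recipe")
}

#' Simulate a three-generation pedigree
#'
#' Founders form unrelated couples; each couple raises children; children
#' marry across families (or unrelated in-migrants) and raise a second
#' generation. Relatedness is Wright's coefficient computed by the tabular
#' (path-counting) method, so parent-child and full siblings are 0.5,
#' grandparent-grandchild and avuncular pairs 0.25, first cousins 0.125.
#' Households hold one married couple and their unmarried children, keeping
#' within-household relatedness above between-household relatedness. The
#' founder-family count is derived from the target mean relatedness: fewer,
#' larger families raise the mean.
#'
#' @param recipe a [village_recipe()].
#' @return list with `relatedness` (n x n symmetric matrix, zero diagonal),
#'   `household` (integer vector), `spouse` (integer vector, `NA` for
#'   unmarried) and `generation`.
#' @export
generate_pedigree <- function(recipe) {
  n <- recipe$n
  # Within a three-generation family of size s, mean pairwise relatedness is
  # close to 0.5 once cross-family marriages tie grandchildren together;
  # mean over all pairs ~ 0.5 (s - 1) / (n - 1) for s = n / F.
  fam_size <- min(n, max(4, round(recipe$relatedness_mean * (n - 1) / 0.5
                                  + 1)))
  n_fam <- max(2, ceiling(n / fam_size))
  # children per founder couple chosen so the pedigree overshoots n;
  # escalated if a draw happens to come up short
  c1 <- max(2, ceiling(((1.4 * n) / n_fam - 2) / 2.8))
  grow <- function(c1) {
  id <- 0L
  sire <- dam <- integer(0)
  gen <- integer(0)
  new_person <- function(s = NA_integer_, d = NA_integer_, g) {
    id <<- id + 1L
    sire[id] <<- s; dam[id] <<- d; gen[id] <<- g
    as.integer(id)
  }
  founders <- replicate(n_fam, c(new_person(g = 0L), new_person(g = 0L)))
  children <- vector("list", n_fam)
  for (f in seq_len(n_fam)) {
    kids <- max(1, c1 + stats::rpois(1, 1) - 1)
    children[[f]] <- vapply(seq_len(kids), function(k)
      new_person(founders[1, f], founders[2, f], 1L), integer(1))
  }
  # marry generation-1 members across families; leftover marry in-migrants
  spouse <- rep(NA_integer_, 4 * n)
  fam_of <- integer(4 * n)
  for (f in seq_len(n_fam)) fam_of[children[[f]]] <- f
  for (f in seq_len(n_fam)) fam_of[founders[, f]] <- f
  g1 <- unlist(children)
  unmarried <- sample(g1)
  while (length(unmarried) >= 2) {
    a <- unmarried[1]
    mate <- unmarried[-1][fam_of[unmarried[-1]] != fam_of[a]]
    if (!length(mate)) break
    b <- mate[1]
    spouse[a] <- b; spouse[b] <- a
    unmarried <- setdiff(unmarried, c(a, b))
  }
  for (a in unmarried) {              # marry an unrelated in-migrant
    if (stats::runif(1) < 0.6) {
      b <- new_person(g = 1L)
      fam_of[b] <- 0L
      spouse[a] <- b; spouse[b] <- a
    }
  }
  for (f in seq_len(n_fam))
    spouse[founders[1, f]] <- founders[2, f]
  for (f in seq_len(n_fam))
    spouse[founders[2, f]] <- founders[1, f]
  # generation 2
  for (a in g1) {
    b <- spouse[a]
    if (is.na(b) || b < a) next      # one pass per couple
    kids <- 1 + stats::rpois(1, 2)
    for (k in seq_len(kids)) {
      cid <- new_person(a, b, 2L)
      fam_of[cid] <- fam_of[a]
    }
  }
  list(sire = sire[seq_len(id)], dam = dam[seq_len(id)],
       gen = gen[seq_len(id)], spouse = spouse[seq_len(id)], total = id)
  }
  repeat {
    ped <- grow(c1)
    if (ped$total >= n) break
    c1 <- c1 + 1
  }
  sire <- ped$sire; dam <- ped$dam; gen <- ped$gen; spouse <- ped$spouse
  total <- ped$total
  # additive-relationship matrix by the tabular method (IDs are ordered so
  # parents precede children)
  A <- matrix(0, total, total)
  for (p in seq_len(total)) {
    A[p, p] <- 1
    has_parents <- !is.na(sire[p]) && !is.na(dam[p])
    if (p > 1) {
      q <- seq_len(p - 1)
      A[p, q] <- A[q, p] <- if (has_parents)
        0.5 * (A[q, sire[p]] + A[q, dam[p]]) else 0
    }
  }
  # sample n adults, preferring older generations so households stay intact
  keep <- order(gen, sample(total))
  keep <- sort(keep[seq_len(n)])
  r <- A[keep, keep]
  diag(r) <- 0
  # households: one per couple (couple + their unmarried kept children);
  # unmarried adults without kept parents form single households
  hh <- rep(NA_integer_, length(keep))
  names(hh) <- keep
  next_hh <- 0
  pos <- function(ids) match(ids, keep)
  for (a in keep) {
    ia <- pos(a)
    if (!is.na(hh[ia])) next
    b <- spouse[a]
    if (!is.na(b) && b %in% keep) {
      next_hh <- next_hh + 1
      hh[ia] <- next_hh
      hh[pos(b)] <- next_hh
      kids <- which(keep %in% which((sire %in% c(a, b)) |
                                      (dam %in% c(a, b))))
      for (kk in kids) {
        kid_id <- keep[kk]
        kid_sp <- spouse[kid_id]
        if (is.na(kid_sp) || !(kid_sp %in% keep)) hh[kk] <- next_hh
      }
    }
  }
  for (ia in which(is.na(hh))) {
    # unmarried adult: join parents' household when kept, else own household
    a <- keep[ia]
    par <- c(sire[a], dam[a])
    par <- par[!is.na(par) & par %in% keep]
    if (length(par) && !is.na(hh[pos(par[1])])) {
      hh[ia] <- hh[pos(par[1])]
    } else {
      next_hh <- next_hh + 1
      hh[ia] <- next_hh
    }
  }
  sp <- spouse[keep]
  sp_idx <- ifelse(!is.na(sp) & sp %in% keep, match(sp, keep), NA_integer_)
  list(relatedness = unname(r), household = as.integer(unname(hh)),
       spouse = sp_idx, generation = gen[keep])
}

#' Affinal relatedness from a pedigree
#'
#' Affinal relatedness of i and j is the consanguineal relatedness between
#' i's spouse and j (or j's spouse and i; the strongest path is retained),
#' with spouses themselves set to 1, and zeroed wherever it is below twice
#' the consanguineal relatedness of the pair (blood ties take primacy unless
#' the marriage tie is clearly stronger).
#'
#' @param consanguineal symmetric relatedness matrix.
#' @param spouse integer vector: `spouse[i]` is i's spouse index or `NA`.
#' @return symmetric affinal relatedness matrix.
#' @export
generate_affinal <- function(consanguineal, spouse) {
  n <- nrow(consanguineal)
  aff <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- spouse[i]
    if (is.na(s)) next
    aff[i, ] <- pmax(aff[i, ], consanguineal[s, ])
    aff[i, s] <- 1
  }
  aff <- pmax(aff, t(aff))
  aff[aff < 2 * consanguineal] <- 0
  diag(aff) <- 0
  aff
}

#' Generate actor covariates and inter-household distances
#'
#' Gender is balanced Bernoulli; ethnicity Bernoulli with the minority
#' share; age comes from a right-skewed gamma truncated to the adult range;
#' household wealth is log-normal (shared within household); BMI and melanin
#' are normal. Households are placed uniformly in a square whose side is
#' scaled so the mean inter-household distance matches the recipe
#' (E[distance] is about 0.5214 times the side for uniform placement);
#' within-household distance is 0.
#'
#' @param recipe a [village_recipe()].
#' @param household integer household assignment per actor.
#' @return list with `actors` (data frame) and `distance` (matrix, metres).
#' @export
generate_covariates <- function(recipe, household) {
  n <- recipe$n
  lab <- sprintf("v%03d", seq_len(n))
  hh_ids <- sort(unique(household))
  n_hh <- length(hh_ids)
  age <- recipe$age_range[1] +
    stats::qgamma(stats::runif(n, 0, stats::pgamma(diff(recipe$age_range),
                                                   shape = 2, scale = 10)),
                  shape = 2, scale = 10)
  hw <- stats::rlnorm(n_hh, recipe$wealth_meanlog, recipe$wealth_sdlog)
  names(hw) <- hh_ids
  side <- recipe$mean_distance / 0.5214
  xy <- cbind(stats::runif(n_hh, 0, side), stats::runif(n_hh, 0, side))
  rownames(xy) <- hh_ids
  dist_hh <- as.matrix(stats::dist(xy))
  idx <- match(household, hh_ids)
  distance <- dist_hh[idx, idx]
  dimnames(distance) <- list(lab, lab)
  actors <- data.frame(
    label = lab,
    household = household,
    gender = stats::rbinom(n, 1, recipe$gender_balance),
    ethnicity = stats::rbinom(n, 1, recipe$ethnicity_prop),
    age = as.numeric(age),
    bmi = stats::rnorm(n, recipe$bmi_mean, recipe$bmi_sd),
    melanin = stats::rnorm(n, recipe$melanin_mean, recipe$melanin_sd),
    wealth = as.numeric(hw[idx]),
    household_size = as.numeric(table(household)[as.character(household)]),
    stringsAsFactors = FALSE)
  list(actors = actors, distance = distance)
}

#' Draw an approximately stationary network from an evaluation function
#'
#' Runs the ministep simulator from a sparse random start for a long burn-in
#' so that the returned network is an (approximate) draw from the stationary
#' distribution of the generating process.
#'
#' @inheritParams effect_statistics
#' @param start_density density of the random starting graph.
#' @param burnin_rate tie-change opportunities per actor for the burn-in.
#' @param degeneracy_bounds warn when the final density leaves this interval.
#' @return a `directed_network`.
#' @export
generate_network <- function(evalfn, village, start_density = 0.02,
                             burnin_rate = 200,
                             degeneracy_bounds = c(0.005, 0.995)) {
  n <- village$n
  x0 <- matrix(stats::rbinom(n * n, 1, start_density), n, n)
  start <- directed_network(x0, village$labels, "start")
  out <- simulate_chain(evalfn, start, village,
                        sim_settings(rate = burnin_rate, mode = "fixed"))
  dens <- graph_density(out)
  if (dens < degeneracy_bounds[1] || dens > degeneracy_bounds[2]) {
    extreme <- names(which.max(abs(evalfn$beta)))
    warning(sprintf(
      "degenerate burn-in density %.3f; check generating weight '%s'",
      dens, extreme))
  }
  out
}

#' Noisy double-sampled reports of a true network
#'
#' Giver and receiver reports flip true ties to absent at the false-negative
#' rate and true non-ties to present at the false-positive rate,
#' independently per report direction.
#'
#' @param net the true `directed_network`.
#' @param false_negative,false_positive flip rates in [0, 1).
#' @return list with `giver` and `receiver` networks.
#' @export
generate_reports <- function(net, false_negative = 0.05,
                             false_positive = 0.01) {
  stopifnot(false_negative >= 0, false_negative < 1,
            false_positive >= 0, false_positive < 1)
  noisy <- function() {
    x <- adj(net)
    flips_fn <- stats::rbinom(length(x), 1, false_negative)
    flips_fp <- stats::rbinom(length(x), 1, false_positive)
    y <- ifelse(x == 1, 1 - flips_fn, flips_fp)
    y <- matrix(y, nrow(x))
    diag(y) <- 0
    directed_network(y, actor_labels(net))
  }
  list(giver = noisy(), receiver = noisy())
}

#' Generate a complete synthetic village
#'
#' Full pipeline: pedigree and households, affinal kinship, covariates and
#' distances, godparent and infidelity indicators (sparse symmetric
#' Bernoulli dyads), a true aid network drawn from the generating evaluation
#' function, and noisy double-sampled reports whose mutual-assent
#' reconstruction is attached as the verified network.
#'
#' @param recipe a [village_recipe()].
#' @param seed optional integer seed for full reproducibility.
#' @return a preprocessable [village()] with attributes `true_network` and
#'   `generating_beta`.
#' @export
synthetic_village <- function(recipe = village_recipe(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ped <- generate_pedigree(recipe)
  cov <- generate_covariates(recipe, ped$household)
  lab <- cov$actors$label
  name_mat <- function(m) { dimnames(m) <- list(lab, lab); m }
  aff <- generate_affinal(ped$relatedness, ped$spouse)
  n <- recipe$n
  sym_bernoulli <- function(p) {
    m <- matrix(0, n, n)
    up <- upper.tri(m)
    m[up] <- stats::rbinom(sum(up), 1, p)
    m + t(m)
  }
  dyads <- list(consanguineal = name_mat(ped$relatedness),
                affinal = name_mat(aff),
                distance = cov$distance,
                godparent = name_mat(sym_bernoulli(0.017)),
                infidelity = name_mat(sym_bernoulli(0.005)))
  vil <- village(cov$actors, dyads)
  vil_p <- preprocess_covariates(vil)
  spec <- build_specification("conventional", vil_p)
  evalfn <- set_beta(spec$evalfn, recipe$beta[names(spec$evalfn$beta)])
  truth <- generate_network(evalfn, spec$village,
                            burnin_rate = recipe$burnin_rate)
  reports <- generate_reports(truth, recipe$false_negative,
                              recipe$false_positive)
  vil$giver <- reports$giver
  vil$receiver <- reports$receiver
  vil$verified <- build_verified_network(reports$giver, reports$receiver)
  attr(vil, "true_network") <- truth
  attr(vil, "generating_beta") <- evalfn$beta
  vil
}
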