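# Internal effect codes shared with src/ministep.cpp.
EFFECT_CODES <- c(outdegree = 1L, reciprocity = 2L, dyadic = 3L,
                  dyadic_reciprocity = 4L, outdegree_activity = 5L,
                  indegree_popularity = 6L, outdegree_popularity = 7L,
                  transitive_triplets = 8L,
                  transitive_reciprocated_triplets = 9L, three_cycles = 10L,
                  dense_triads = 11L, transitive_triplets_jumping_hh = 12L,
                  shared_popularity = 13L)

STRUCTURAL_TYPES <- c("outdegree", "reciprocity", "outdegree_activity",
                      "indegree_popularity", "outdegree_popularity",
                      "transitive_triplets",
                      "transitive_reciprocated_triplets", "three_cycles",
                      "dense_triads", "transitive_triplets_jumping_hh",
                      "shared_popularity")

#' Define one evaluation-function effect
#'
#' An effect pairs a per-actor network statistic \eqn{s_{k,i}(x)} with a
#' weight \eqn{\beta_k}. Structural effects reference no covariate; covariate
#' effects reference actor or dyad covariates by name. Dyadic covariate
#' effects (`"dyadic"`, and the covariate-weighted reciprocity
#' `"dyadic_reciprocity"`) use the covariate non-centred; `"similarity"`
#' centres pairwise similarities at their mean.
#'
#' @param type one of the structural types (`"outdegree"`, `"reciprocity"`,
#'   `"outdegree_activity"`, `"indegree_popularity"`,
#'   `"outdegree_popularity"`, `"transitive_triplets"`,
#'   `"transitive_reciprocated_triplets"`, `"three_cycles"`,
#'   `"dense_triads"`, `"transitive_triplets_jumping_hh"`,
#'   `"shared_popularity"`) or a covariate type (`"dyadic"`,
#'   `"dyadic_reciprocity"`, `"alter"`, `"ego"`, `"same"`, `"similarity"`).
#' @param covariate name of the referenced covariate (actor covariate for
#'   alter/ego/same/similarity; dyad covariate for dyadic effects); `NULL`
#'   for structural effects.
#' @param beta effect weight (default 0).
#' @param name display name; defaults to a `type(covariate)` label.
#' @return an `effect_spec` object.
#' @export
effect <- function(type, covariate = NULL, beta = 0, name = NULL) {
  valid <- c(STRUCTURAL_TYPES, "dyadic", "dyadic_reciprocity", "alter",
             "ego", "same", "similarity")
  if (!type %in% valid)
    stop("unknown effect type '", type, "'; valid types: ",
         paste(valid, collapse = ", "))
  structural <- type %in% STRUCTURAL_TYPES
  if (structural && !is.null(covariate))
    stop("structural effect '", type, "' must not reference a covariate")
  if (!structural && is.null(covariate))
    stop("effect '", type, "' needs a covariate")
  if (is.null(name))
    name <- if (structural) type else paste0(type, "(", covariate, ")")
  kind <- if (structural) "structural"
          else if (type %in% c("dyadic", "dyadic_reciprocity")) "dyad-covariate"
          else "actor-covariate"
  structure(list(name = name, type = type, kind = kind,
                 covariate = covariate, beta = beta),
            class = "effect_spec")
}

#' @export
print.effect_spec <- function(x, ...) {
  cat(sprintf("<effect> %-34s beta = %g\n", x$name, x$beta))
  invisible(x)
}

#' Build an evaluation function from effects
#'
#' @param ... `effect_spec` objects (or a single list of them).
#' @param beta optional numeric vector overriding the per-effect weights.
#' @return an `evaluation_function`: an ordered effect list plus aligned
#'   weight vector.
#' @export
evaluation_function <- function(..., beta = NULL) {
  effs <- list(...)
  if (length(effs) == 1 && !inherits(effs[[1]], "effect_spec"))
    effs <- effs[[1]]
  stopifnot(all(vapply(effs, inherits, logical(1), "effect_spec")))
  nms <- vapply(effs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("effect names must be unique")
  if (is.null(beta)) beta <- vapply(effs, `[[`, numeric(1), "beta")
  if (length(beta) != length(effs))
    stop("beta length must match the number of effects")
  beta <- as.numeric(beta)
  names(beta) <- nms
  structure(list(effects = effs, beta = beta), class = "evaluation_function")
}

#' @export
print.evaluation_function <- function(x, ...) {
  cat(sprintf("<evaluation_function> %d effects\n", length(x$effects)))
  for (e in x$effects) cat(sprintf("  %-34s beta = %g\n", e$name,
                                   x$beta[[e$name]]))
  invisible(x)
}

#' @rdname evaluation_function
#' @param evalfn an `evaluation_function`
#' @param beta replacement weight vector (recycled by name when named)
#' @export
set_beta <- function(evalfn, beta) {
  stopifnot(length(beta) == length(evalfn$effects))
  evalfn$beta[] <- as.numeric(beta)
  evalfn
}

# Resolve one effect to its compiled (code, weight-matrix) form.
compile_effect <- function(eff, village) {
  n <- village$n
  get_actor <- function(nm) {
    v <- village$actors[[nm]]
    if (is.null(v)) stop("effect '", eff$name,
                         "' references missing actor covariate '", nm, "'")
    as.numeric(v)
  }
  get_dyad <- function(nm) {
    m <- village$dyads[[nm]]
    if (is.null(m)) stop("effect '", eff$name,
                         "' references missing dyad covariate '", nm, "'")
    m
  }
  switch(eff$type,
    dyadic = list(code = EFFECT_CODES[["dyadic"]],
                  W = get_dyad(eff$covariate)),
    dyadic_reciprocity = list(code = EFFECT_CODES[["dyadic_reciprocity"]],
                              W = get_dyad(eff$covariate)),
    alter = {
      v <- get_actor(eff$covariate)
      list(code = EFFECT_CODES[["dyadic"]],
           W = matrix(v, n, n, byrow = TRUE))
    },
    ego = {
      v <- get_actor(eff$covariate)
      list(code = EFFECT_CODES[["dyadic"]], W = matrix(v, n, n))
    },
    same = {
      v <- get_actor(eff$covariate)
      list(code = EFFECT_CODES[["dyadic"]],
           W = (outer(v, v, `==`)) * 1)
    },
    similarity = {
      v <- get_actor(eff$covariate)
      rg <- diff(range(v))
      if (rg == 0) stop("similarity effect on constant covariate '",
                        eff$covariate, "'")
      sim <- 1 - abs(outer(v, v, `-`)) / rg
      simc <- sim - mean(sim[row(sim) != col(sim)])
      list(code = EFFECT_CODES[["dyadic"]], W = simc)
    },
    # structural
    list(code = EFFECT_CODES[[eff$type]], W = NULL)
  )
}

compile_evalfn <- function(evalfn, village) {
  comp <- lapply(evalfn$effects, compile_effect, village = village)
  hh <- match(village$actors$household, unique(village$actors$household))
  list(codes = vapply(comp, `[[`, integer(1), "code"),
       weights = lapply(comp, `[[`, "W"),
       hh = as.integer(hh), beta = unname(evalfn$beta))
}

#' Per-actor effect statistics
#'
#' Evaluates the statistic \eqn{s_{k,i}(x)} of every effect for every actor.
#'
#' @param evalfn an `evaluation_function`.
#' @param net a `directed_network`.
#' @param village the [village()] data (preprocessed).
#' @return numeric n x K matrix; columns named by effect.
#' @export
effect_statistics <- function(evalfn, net, village) {
  x <- adj(net)
  n <- nrow(x)
  comp <- compile_evalfn(evalfn, village)
  hh <- comp$hh
  rs <- rowSums(x); cs <- colSums(x)
  xx <- x %*% x
  out <- matrix(0, n, length(evalfn$effects),
                dimnames = list(rownames(net),
                                vapply(evalfn$effects, `[[`, character(1),
                                       "name")))
  for (k in seq_along(comp$codes)) {
    W <- comp$weights[[k]]
    out[, k] <- switch(as.character(comp$codes[k]),
      "1" = rs,
      "2" = rowSums(x * t(x)),
      "3" = rowSums(x * W),
      "4" = rowSums(x * t(x) * W),
      "5" = rs^2,
      "6" = as.numeric(x %*% cs),
      "7" = as.numeric(x %*% rs),
      "8" = rowSums(x * xx),
      "9" = rowSums(x * t(x) * xx),
      "10" = diag(x %*% xx),
      "11" = {
        m <- x * t(x)
        diag(m %*% m %*% m) / 2
      },
      "12" = {
        same <- outer(hh, hh, `==`) * 1
        A <- x * same          # i -> h within household
        B <- x * (1 - same)    # i -> j across households
        rowSums(B * (A %*% x))
      },
      "13" = {
        m <- x %*% t(x)
        diag(m) <- 0
        rowSums(choose(m, 2))
      },
      stop("unknown effect code"))
  }
  out
}

#' Toggle change statistics for one focal actor
#'
#' For actor `i` and every alter `j`, the change
#' \eqn{\Delta_{k,ij} = s_{k,i}(x^{\pm ij}) - s_{k,i}(x)} in each effect's
#' statistic caused by toggling the tie \eqn{x_{ij}}, computed by local
#' bookkeeping.
#'
#' @inheritParams effect_statistics
#' @param i focal actor (index or label).
#' @return K x n matrix of change statistics (column `i` is `NA`).
#' @export
change_statistics <- function(evalfn, net, village, i) {
  i <- resolve_actor(net, i)
  comp <- compile_evalfn(evalfn, village)
  d <- .change_stats_cpp(adj(net), i, comp$codes, comp$weights, comp$hh)
  dimnames(d) <- list(vapply(evalfn$effects, `[[`, character(1), "name"),
                      rownames(net))
  d
}

#' Evaluation gain of toggling one tie
#'
#' The weighted sum \eqn{\sum_k \beta_k \Delta_{k,ij}} governing the
#' attractiveness of the toggle; the no-change alternative has gain 0 by
#' definition.
#'
#' @inheritParams change_statistics
#' @param j alter (index or label), distinct from `i`.
#' @export
evaluation_gain <- function(evalfn, net, village, i, j) {
  i <- resolve_actor(net, i); j <- resolve_actor(net, j)
  if (i == j) stop("self-ties are not toggled: i must differ from j")
  d <- change_statistics(evalfn, net, village, i)
  sum(evalfn$beta * d[, j])
}

resolve_actor <- function(net, i) {
  if (is.character(i)) {
    k <- match(i, rownames(net))
    if (is.na(k)) stop("unknown actor '", i, "'")
    return(k)
  }
  i <- as.integer(i)
  if (i < 1 || i > nrow(net)) stop("actor index out of range")
  i
}

#' The four archetypal model specifications
#'
#' Builds the nested evaluation-function specifications used throughout:
#' `"conventional"` (out-degree, reciprocity, geographic distance,
#' consanguineal and affinal relatedness), `"extended"` (adds relative wealth
#' rank, the three consanguinity interactions, godparent and infidelity
#' indicators, and alter/ego/homophily effects for the seven actor
#' covariates), `"networked_limited"` (adds in-degree popularity, out-degree
#' popularity and transitive triplets) and `"networked_comprehensive"` (adds
#' out-degree activity, transitive reciprocated triplets, three-cycles, dense
#' triads, household-jumping transitive triplets and shared popularity).
#'
#' The consanguinity-by-wealth-rank and consanguinity-by-distance
#' interactions are elementwise matrix products attached to the village as
#' derived dyad covariates; consanguinity-by-reciprocity uses the
#' covariate-weighted reciprocity statistic.
#'
#' @param name specification name.
#' @param village preprocessed [village()] data (used to materialise the
#'   interaction matrices and to validate covariate references).
#' @return list with elements `evalfn` (the [evaluation_function()]) and
#'   `village` (with any derived interaction covariates attached).
#' @export
build_specification <- function(name = c("conventional", "extended",
                                         "networked_limited",
                                         "networked_comprehensive"),
                                village) {
  name <- match.arg(name)
  if (!isTRUE(village$preprocessed))
    stop("preprocess_covariates() must be applied first")
  effs <- list(
    effect("outdegree", name = "Out-degree"),
    effect("reciprocity", name = "Reciprocity"),
    effect("dyadic", "distance", name = "Geographic Distance"),
    effect("dyadic", "consanguineal", name = "Consanguineal Relatedness"),
    effect("dyadic", "affinal", name = "Affinal Relatedness"))
  if (name != "conventional") {
    need <- c("relative_wealth_rank", "godparent", "infidelity")
    miss <- setdiff(need, names(village$dyads))
    if (length(miss)) stop("missing dyad covariates: ",
                           paste(miss, collapse = ", "))
    cons <- village$dyads$consanguineal
    village$dyads$cons_x_rwr <- cons * village$dyads$relative_wealth_rank
    village$dyads$cons_x_distance <- cons * village$dyads$distance
    actor_covs <- c("wealth", "household_size", "age", "gender", "ethnicity",
                    "melanin", "bmi")
    labs <- c("Household Wealth", "Household Size", "Age", "Gender: Female",
              "Ethnicity: Miskito", "Melanin Index", "Body Mass Index")
    effs <- append(effs, list(
      effect("dyadic", "relative_wealth_rank", name = "Relative Wealth Rank"),
      effect("dyadic_reciprocity", "consanguineal",
             name = "Cons. Rel. x Reciprocity"),
      effect("dyadic", "cons_x_rwr", name = "Cons. Rel. x Relative Wealth Rank"),
      effect("dyadic", "cons_x_distance",
             name = "Cons. Rel. x Geographic Distance"),
      effect("dyadic", "godparent", name = "Godparental Relation"),
      effect("dyadic", "infidelity", name = "Infidelity Relation")))
    effs <- append(effs, mapply(function(cv, lb)
      effect("alter", cv, name = paste0(lb, " (Alter)")),
      actor_covs, labs, SIMPLIFY = FALSE))
    effs <- append(effs, mapply(function(cv, lb)
      effect("ego", cv, name = paste0(lb, " (Ego)")),
      actor_covs, labs, SIMPLIFY = FALSE))
    effs <- append(effs, list(
      effect("similarity", "age", name = "Age Similarity"),
      effect("same", "gender", name = "Same Gender"),
      effect("same", "ethnicity", name = "Same Ethnicity"),
      effect("similarity", "melanin", name = "Melanin Index Similarity"),
      effect("similarity", "bmi", name = "Body Mass Index Similarity")))
  }
  if (name %in% c("networked_limited", "networked_comprehensive"))
    effs <- append(effs, list(
      effect("indegree_popularity", name = "In-degree Popularity"),
      effect("outdegree_popularity", name = "Out-degree Popularity"),
      effect("transitive_triplets", name = "Transitive Triplets")))
  if (name == "networked_comprehensive")
    effs <- append(effs, list(
      effect("outdegree_activity", name = "Out-degree Activity"),
      effect("transitive_reciprocated_triplets",
             name = "Transitive Reciprocated Triplets"),
      effect("three_cycles", name = "Three Cycles"),
      effect("dense_triads", name = "Dense Triads"),
      effect("transitive_triplets_jumping_hh",
             name = "Transitive Triplets Jumping HHs"),
      effect("shared_popularity", name = "Shared Popularity")))
  ev <- evaluation_function(effs)
  # validate covariate references eagerly
  invisible(compile_evalfn(ev, village))
  list(evalfn = ev, village = village)
}

#' Read and write evaluation-function specifications
#'
#' Lossless round-trip of an [evaluation_function()] through a structured
#' text (YAML) file: one entry per effect with its name, type, covariate
#' reference and weight.
#'
#' @param evalfn an `evaluation_function`.
#' @param path file path.
#' @return `write_evalfn()` returns the path invisibly; `read_evalfn()`
#'   returns the reconstructed `evaluation_function`.
#' @export
write_evalfn <- function(evalfn, path) {
  entries <- lapply(seq_along(evalfn$effects), function(k) {
    e <- evalfn$effects[[k]]
    out <- list(name = e$name, type = e$type,
                beta = unname(evalfn$beta[k]))
    if (!is.null(e$covariate)) out$covariate <- e$covariate
    out
  })
  yaml::write_yaml(list(effects = entries), path,
                   precision = 17)
  invisible(path)
}

#' @rdname write_evalfn
#' @export
read_evalfn <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!length(cfg$effects)) stop("specification file lists no effects")
  effs <- lapply(cfg$effects, function(e)
    effect(e$type, covariate = e$covariate, beta = e$beta, name = e$name))
  evaluation_function(effs)
}
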