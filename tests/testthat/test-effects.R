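# every effect type, with a covariate where one is needed
all_effect_specs <- function() {
  list(effect("outdegree"), effect("reciprocity"),
       effect("dyadic", "consanguineal"),
       effect("dyadic_reciprocity", "consanguineal"),
       effect("alter", "age"), effect("ego", "wealth"),
       effect("same", "gender"), effect("similarity", "bmi"),
       effect("outdegree_activity"), effect("indegree_popularity"),
       effect("outdegree_popularity"), effect("transitive_triplets"),
       effect("transitive_reciprocated_triplets"), effect("three_cycles"),
       effect("dense_triads"), effect("transitive_triplets_jumping_hh"),
       effect("shared_popularity"))
}

test_that("per-actor statistics equal the literal-formula oracle", {
  set.seed(31)
  vil <- prep_tiny(8, 3)
  ev <- evaluation_function(all_effect_specs())
  hh <- vil$actors$household
  for (rep in 1:10) {
    net <- rand_net(8, stats::runif(1, 0.2, 0.6))
    x <- unclass(net)
    S <- effect_statistics(ev, net, vil)
    for (i in 1:8) {
      for (k in seq_along(ev$effects)) {
        eff <- ev$effects[[k]]
        W <- switch(eff$type,
          dyadic = , dyadic_reciprocity = vil$dyads[[eff$covariate]],
          alter = matrix(vil$actors[[eff$covariate]], 8, 8, byrow = TRUE),
          ego = matrix(vil$actors[[eff$covariate]], 8, 8),
          same = outer(vil$actors[[eff$covariate]],
                       vil$actors[[eff$covariate]], `==`) * 1,
          similarity = {
            v <- vil$actors[[eff$covariate]]
            sim <- 1 - abs(outer(v, v, `-`)) / diff(range(v))
            sim - mean(sim[row(sim) != col(sim)])
          },
          NULL)
        type <- if (eff$type %in% c("alter", "ego", "same", "similarity"))
          "dyadic" else eff$type
        expect_equal(S[i, k], naive_statistic(type, x, i, W, hh),
                     info = paste(eff$name, "actor", i))
      }
    }
  }
})

test_that("structural statistics on binary graphs are non-negative integers", {
  set.seed(32)
  vil <- prep_tiny(8, 3)
  structural <- Filter(function(e) e$kind == "structural",
                       all_effect_specs())
  ev <- evaluation_function(structural)
  for (rep in 1:5) {
    S <- effect_statistics(ev, rand_net(8, 0.4), vil)
    expect_true(all(S >= 0))
    expect_equal(S, round(S))
  }
})

test_that("change statistics equal the statistic difference for every effect", {
  set.seed(33)
  vil <- prep_tiny(8, 3)
  ev <- evaluation_function(all_effect_specs())
  net <- rand_net(8, 0.35)
  for (case in 1:200) {
    i <- sample(8, 1); j <- sample(setdiff(1:8, i), 1)
    d <- change_statistics(ev, net, vil, i)[, j]
    net2 <- net
    net2[i, j] <- 1L - net2[i, j]
    dd <- effect_statistics(ev, net2, vil)[i, ] -
      effect_statistics(ev, net, vil)[i, ]
    expect_equal(unname(d), unname(dd), info = paste("case", case))
    net <- net2   # walk through network space
  }
})

test_that("toggle changes are antisymmetric and error on self-ties", {
  set.seed(34)
  vil <- prep_tiny(8, 3)
  ev <- evaluation_function(all_effect_specs())
  for (case in 1:25) {
    net <- rand_net(8, 0.4)
    i <- sample(8, 1); j <- sample(setdiff(1:8, i), 1)
    d_there <- change_statistics(ev, net, vil, i)[, j]
    net2 <- net; net2[i, j] <- 1L - net2[i, j]
    d_back <- change_statistics(ev, net2, vil, i)[, j]
    expect_equal(unname(d_there), -unname(d_back))
  }
  expect_error(evaluation_gain(ev, rand_net(8), vil, 3, 3), "differ")
})

test_that("structural statistics are invariant to actor relabeling", {
  set.seed(35)
  # households permuted alongside actors
  vil <- prep_tiny(7, 3)
  structural <- Filter(function(e) e$kind == "structural",
                       all_effect_specs())
  ev <- evaluation_function(structural)
  net <- rand_net(7, 0.4)
  S <- effect_statistics(ev, net, vil)
  p <- sample(7)
  vp <- vil
  vp$actors <- vil$actors[p, ]
  vp$actors$label <- vil$actors$label      # keep label/validation stable
  vp$labels <- vil$labels
  netp <- directed_network(unclass(net)[p, p], vil$labels)
  Sp <- effect_statistics(ev, netp, vp)
  expect_equal(unname(Sp), unname(S[p, ]))
})

test_that("statistics depend only on the focal actor's local neighbourhood", {
  set.seed(36)
  vil <- prep_tiny(8, 3)
  local_specs <- list(effect("outdegree"), effect("reciprocity"),
                      effect("dyadic", "consanguineal"),
                      effect("alter", "age"), effect("ego", "wealth"))
  ev <- evaluation_function(local_specs)
  net <- rand_net(8, 0.4)
  i <- 1
  s_before <- effect_statistics(ev, net, vil)[i, ]
  # toggle an arc not incident to i
  net[4, 5] <- 1L - net[4, 5]
  s_after <- effect_statistics(ev, net, vil)[i, ]
  expect_equal(s_after, s_before)
})

test_that("the archetypal specifications have the documented effect lists", {
  set.seed(37)
  vil <- prep_tiny(12, 4)
  conv <- build_specification("conventional", vil)
  expect_length(conv$evalfn$effects, 5)
  expect_equal(vapply(conv$evalfn$effects, `[[`, character(1), "name"),
               c("Out-degree", "Reciprocity", "Geographic Distance",
                 "Consanguineal Relatedness", "Affinal Relatedness"))
  ext <- build_specification("extended", vil)
  expect_length(ext$evalfn$effects, 30)
  lim <- build_specification("networked_limited", vil)
  expect_length(lim$evalfn$effects, 33)
  comp <- build_specification("networked_comprehensive", vil)
  expect_length(comp$evalfn$effects, 39)
  # nesting
  nm <- function(s) vapply(s$evalfn$effects, `[[`, character(1), "name")
  expect_true(all(nm(conv) %in% nm(ext)))
  expect_true(all(nm(ext) %in% nm(lim)))
  expect_true(all(nm(lim) %in% nm(comp)))
  # interaction matrices are elementwise products of the preprocessed parts
  expect_equal(comp$village$dyads$cons_x_distance,
               vil$dyads$consanguineal * vil$dyads$distance)
  expect_equal(comp$village$dyads$cons_x_rwr,
               vil$dyads$consanguineal * comp$village$dyads$relative_wealth_rank)
  expect_error(build_specification("nope", vil))
  # spec invariants
  for (e in comp$evalfn$effects) {
    if (e$kind == "structural") expect_null(e$covariate)
    else expect_false(is.null(e$covariate))
  }
  expect_false(anyDuplicated(nm(comp)) > 0)
})

test_that("evaluation gains are weighted sums of change statistics", {
  set.seed(38)
  vil <- prep_tiny(8, 3)
  ev0 <- evaluation_function(all_effect_specs())    # all beta 0
  net <- rand_net(8, 0.4)
  expect_equal(evaluation_gain(ev0, net, vil, 1, 2), 0)
  # a single reciprocity effect: adding a reciprocating tie gains beta
  evr <- evaluation_function(list(effect("reciprocity", beta = 1.7)))
  x <- matrix(0, 8, 8); x[2, 1] <- 1
  net <- directed_network(x, vil$labels)
  g <- evaluation_gain(evr, net, vil, 1, 2)
  expect_equal(g, 1.7)
  expect_equal(exp(g), 5.5, tolerance = 0.01)
  # random weights: gain is the dot product with the change statistics
  ev <- evaluation_function(all_effect_specs(),
                            beta = stats::rnorm(17, 0, 0.5))
  net <- rand_net(8, 0.4)
  for (case in 1:20) {
    i <- sample(8, 1); j <- sample(setdiff(1:8, i), 1)
    d <- change_statistics(ev, net, vil, i)[, j]
    expect_equal(evaluation_gain(ev, net, vil, i, j), sum(ev$beta * d))
  }
})

test_that("effects referencing missing covariates fail loudly", {
  vil <- prep_tiny(6, 2)
  ev <- evaluation_function(list(effect("dyadic", "no_such")))
  expect_error(effect_statistics(ev, rand_net(6), vil), "no_such")
  expect_error(effect("outdegree", covariate = "age"), "must not reference")
  expect_error(effect("alter"), "needs a covariate")
  expect_error(effect("wiggle"), "unknown effect type")
})

test_that("evaluation functions round-trip through specification files", {
  set.seed(39)
  ev <- evaluation_function(list(
    effect("outdegree", beta = -1.25),
    effect("reciprocity", beta = 1 / 3),
    effect("dyadic", "consanguineal", beta = 2.847),
    effect("similarity", "age", beta = -0.0625,
           name = "Age Similarity")))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_evalfn(ev, path)
  back <- read_evalfn(path)
  expect_equal(back$beta, ev$beta)
  for (k in seq_along(ev$effects))
    expect_equal(back$effects[[k]][c("name", "type", "covariate")],
                 ev$effects[[k]][c("name", "type", "covariate")])
  expect_error(read_evalfn(withr::local_tempfile(lines = "effects: []",
                                                 fileext = ".yaml")))
})
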