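test_that("directed networks enforce their invariants", {
  m <- matrix(c(0, 1, 1, 0), 2, 2)
  net <- directed_network(m)
  expect_s3_class(net, "directed_network")
  expect_equal(n_actors(net), 2)
  m2 <- m; diag(m2) <- 1
  expect_equal(sum(diag(directed_network(m2))), 0)  # self-ties cleared
  expect_error(directed_network(matrix(2, 2, 2)), "0 or 1")
  expect_error(directed_network(matrix(0, 1, 1)), "at least 2")
  expect_error(directed_network(matrix(c(0, NA, 1, 0), 2, 2)), "missing")
  expect_error(directed_network(matrix(0, 2, 3)), "square")
})

test_that("mutual assent and the absent-actor rule build the verified network", {
  lab <- paste0("a", 1:4)
  g <- matrix(0L, 4, 4, dimnames = list(lab, lab))
  r <- g
  g["a1", "a2"] <- 1                      # giver only -> dropped
  g["a1", "a3"] <- 1; r["a1", "a3"] <- 1  # both -> kept
  g["a2", "a4"] <- 1                      # a4 absent: giver report decides
  r["a4", "a1"] <- 1                      # a4 absent: receiver report decides
  giver <- directed_network(g, lab); receiver <- directed_network(r, lab)
  v <- build_verified_network(giver, receiver)
  expect_equal(v["a1", "a2"], 0L)
  expect_equal(v["a1", "a3"], 1L)
  expect_equal(v["a2", "a4"], 0L)
  v2 <- build_verified_network(giver, receiver, absent = "a4")
  expect_equal(v2["a2", "a4"], 1L)        # unilateral report of present a2
  expect_equal(v2["a4", "a1"], 1L)        # unilateral report of present a1
  v3 <- build_verified_network(giver, receiver, absent = c("a3", "a4"))
  expect_equal(v3["a3", "a4"], 0L)        # both absent -> absent
  expect_error(build_verified_network(giver, receiver, absent = "zz"),
               "unknown")
})

test_that("mutual-assent core equals the report intersection", {
  set.seed(41)
  for (rep in 1:5) {
    a <- rand_net(9, 0.4); b <- rand_net(9, 0.4)
    v <- build_verified_network(a, b)
    expect_equal(sum(unclass(v)), sum(unclass(a) * unclass(b)))
  }
})

test_that("covariate preprocessing applies the standard transformations", {
  set.seed(7)
  vil <- tiny_village(10, 4)
  vp <- preprocess_covariates(vil)
  for (nm in c("wealth", "age", "bmi", "melanin", "household_size")) {
    expect_equal(mean(vp$actors[[nm]]), 0, tolerance = 1e-12)
    expect_equal(stats::sd(vp$actors[[nm]]), 1, tolerance = 1e-12)
  }
  # distance: ln(d + 1), so 0 maps to 0
  expect_equal(vp$dyads$distance, log(vil$dyads$distance + 1))
  expect_equal(log(0 + 1), 0)
  # relative wealth rank is a directed antisymmetric integer difference
  rwr <- vp$dyads$relative_wealth_rank
  expect_equal(rwr, -t(rwr))
  n_hh <- length(unique(vil$actors$household))
  expect_true(all(abs(rwr) <= n_hh - 1))
  # binary covariates untouched
  expect_equal(vp$actors$gender, vil$actors$gender)
  vil_bad <- vil; vil_bad$actors$age <- rep(5, 10)
  expect_error(preprocess_covariates(vil_bad), "age.*zero variance")
  vil_neg <- vil; vil_neg$dyads$distance[2, 1] <- -3
  expect_error(preprocess_covariates(vil_neg), "negative")
})

test_that("whole-graph descriptives match their definitions", {
  n <- 5
  full <- directed_network(matrix(1, n, n) - diag(n))
  expect_equal(graph_density(full), 1)
  expect_equal(reciprocity_proportion(full), 1)
  expect_equal(transitivity_weak(full), 1)
  one <- matrix(0, 3, 3); one[1, 2] <- 1
  single <- directed_network(one)
  expect_equal(reciprocity_proportion(single), 0)
  empty <- directed_network(matrix(0, 3, 3))
  expect_warning(expect_true(is.nan(reciprocity_proportion(empty))))
  expect_warning(expect_true(is.nan(transitivity_weak(empty))))
  # any symmetrized graph has reciprocity 1
  set.seed(3)
  x <- unclass(rand_net(8, 0.3)); x <- pmax(x, t(x))
  expect_equal(reciprocity_proportion(directed_network(x)), 1)
  ds <- degree_summaries(full)
  expect_equal(ds$mean_degree, n - 1)
  expect_equal(ds$sd_out, 0)
  expect_equal(ds$max_in, n - 1)
})

test_that("triad census matches brute-force classification", {
  empty5 <- directed_network(matrix(0, 5, 5))
  tc <- triad_census(empty5)
  expect_equal(unname(tc[["003"]]), 10)
  expect_equal(sum(tc), choose(5, 3))
  expect_equal(sum(tc[-1]), 0)
  set.seed(11)
  for (rep in 1:8) {
    net <- rand_net(7, stats::runif(1, 0.15, 0.6))
    tc <- triad_census(net)
    expect_equal(as.numeric(tc), as.numeric(brute_triad_census(net)),
                 info = paste("rep", rep))
    expect_equal(sum(tc), choose(7, 3))
  }
  expect_error(triad_census(directed_network(matrix(0, 2, 2))), "3 actors")
})

test_that("clique census counts maximal fully mutual subsets", {
  empty4 <- directed_network(matrix(0, 4, 4))
  expect_equal(clique_census(empty4), c(`1` = 4L))
  tri <- matrix(0, 4, 4); tri[1:3, 1:3] <- 1; diag(tri) <- 0
  net <- directed_network(tri)
  expect_equal(clique_census(net), c(`1` = 1L, `2` = 0L, `3` = 1L))
  set.seed(5)
  for (rep in 1:6) {
    net <- rand_net(8, stats::runif(1, 0.3, 0.7))
    got <- clique_census(net)
    want <- brute_clique_census(net)
    expect_equal(as.numeric(got), as.numeric(want), info = paste("rep", rep))
    # every actor covered at least once
    expect_gte(sum(got * as.integer(names(got))), n_actors(net))
  }
})

test_that("geodesic distribution matches all-pairs brute force", {
  n <- 4
  full <- directed_network(matrix(1, n, n) - diag(n))
  gd <- geodesic_distribution(full)
  expect_equal(unname(gd[["1"]]), n * (n - 1))
  chain <- matrix(0, 3, 3); chain[1, 2] <- chain[2, 3] <- 1
  gd <- geodesic_distribution(directed_network(chain))
  expect_equal(unname(gd[["2"]]), 1)
  set.seed(13)
  for (rep in 1:6) {
    net <- rand_net(10, stats::runif(1, 0.08, 0.3))
    gd <- geodesic_distribution(net)
    d <- brute_geodesics(net)
    d <- d[row(d) != col(d)]
    for (k in 1:5) expect_equal(unname(gd[[as.character(k)]]), sum(d == k))
    expect_equal(unname(gd[["5+/Inf"]]), sum(d > 5))
    expect_equal(sum(gd), 10 * 9)
  }
})

test_that("arcs are binned by exact relatedness class", {
  lab <- paste0("a", 1:4)
  r <- matrix(0, 4, 4, dimnames = list(lab, lab))
  r[1, 2] <- r[2, 1] <- 0.5
  r[1, 3] <- r[3, 1] <- 0.5
  r[2, 3] <- r[3, 2] <- 0.25
  x <- matrix(0, 4, 4); x[1, 2] <- x[2, 1] <- x[2, 3] <- 1
  net <- directed_network(x, lab)
  cd <- consanguineous_tie_distribution(net, r)
  expect_equal(unname(cd[["0.50"]]), 2)
  expect_equal(unname(cd[["0.25"]]), 1)
  expect_equal(sum(cd), 3)
  r0 <- matrix(0, 4, 4)
  expect_equal(sum(consanguineous_tie_distribution(net, r0)), 3)
  expect_error(consanguineous_tie_distribution(net, r * 4), "\\[0, 1\\]")
})

test_that("graph correlation behaves like a product-moment correlation", {
  set.seed(17)
  a <- rand_net(8, 0.4)
  expect_equal(graph_correlation(a, a), 1)
  comp <- directed_network(1 - unclass(a) - diag(8))
  expect_equal(graph_correlation(a, comp), -1)
  b <- rand_net(8, 0.4)
  expect_equal(graph_correlation(a, b), graph_correlation(b, a))
  # invariant to simultaneous relabeling
  p <- sample(8)
  ap <- directed_network(unclass(a)[p, p]); bp <- directed_network(unclass(b)[p, p])
  expect_equal(graph_correlation(ap, bp), graph_correlation(a, b))
  const <- directed_network(matrix(0, 8, 8))
  expect_warning(expect_true(is.nan(graph_correlation(a, const))))
})

test_that("kin composition of triad classes covers the extreme cases", {
  set.seed(19)
  net <- rand_net(6, 0.5)
  allkin <- matrix(0.5, 6, 6); diag(allkin) <- 0
  none <- matrix(0, 6, 6)
  res <- kin_triad_composition(net, allkin, none)
  nonempty <- res$total > 0
  expect_true(all(res$share[nonempty] == 1))
  res0 <- kin_triad_composition(net, none, none)
  expect_true(all(res0$share[res0$total > 0] == 0))
  expect_equal(sum(res$total), choose(6, 3))
})

test_that("village CSV files round-trip through write and read", {
  set.seed(23)
  vil <- synthetic_village(village_recipe(n = 20), seed = 23)
  dir <- withr::local_tempdir()
  write_village(vil, dir)
  dyads <- file.path(dir, paste0("dyad_", names(vil$dyads), ".csv"))
  names(dyads) <- names(vil$dyads)
  back <- read_village(file.path(dir, "actors.csv"), dyads,
                       c(giver = file.path(dir, "giver.csv"),
                         receiver = file.path(dir, "receiver.csv")))
  expect_equal(back$labels, vil$labels)
  expect_equal(unclass(back$giver), unclass(vil$giver),
               ignore_attr = "observation_label")
  expect_equal(unclass(back$verified), unclass(vil$verified),
               ignore_attr = "observation_label")
  for (nm in names(vil$dyads))
    expect_equal(back$dyads[[nm]], vil$dyads[[nm]], tolerance = 1e-12)
  # a 3-actor edge-list fixture
  d2 <- withr::local_tempdir()
  utils::write.csv(data.frame(label = c("x", "y", "z"),
                              household = c(1, 1, 2)),
                   file.path(d2, "actors.csv"), row.names = FALSE)
  utils::write.csv(data.frame(source = c("x", "y"), target = c("y", "z")),
                   file.path(d2, "giver.csv"), row.names = FALSE)
  v3 <- read_village(file.path(d2, "actors.csv"),
                     edge_list_paths = c(giver = file.path(d2, "giver.csv")))
  expect_equal(v3$n, 3)
  expect_equal(sum(unclass(v3$giver)), 2)
  utils::write.csv(data.frame(source = "x", target = "w"),
                   file.path(d2, "bad.csv"), row.names = FALSE)
  expect_error(read_village(file.path(d2, "actors.csv"),
                            edge_list_paths = c(giver = file.path(d2, "bad.csv"))),
               "unknown actors.*w")
})
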