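#' Read a run configuration
#'
#' YAML configuration driving the command pipeline. Recognised top-level
#' fields: `actor_table`, `dyad_matrices` (named map), `edge_lists` (named
#' map with `giver`/`receiver`), `absent`, `specifications` (character
#' vector), `rates` (numeric vector of rate-parameter values), `seed`,
#' `output_dir`, `estimation` (subphases, iterations_per_subphase,
#' phase3_iterations), `gof` (families, replicates), `recipe` (synthetic
#' village overrides).
#'
#' @param path YAML file path.
#' @return a named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(specifications = "conventional", rates = 36, seed = 1,
                   output_dir = ".", absent = character())
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (any(unlist(cfg$rates) <= 0)) stop("rates must be positive")
  bad <- setdiff(unlist(cfg$specifications),
                 c("conventional", "extended", "networked_limited",
                   "networked_comprehensive"))
  if (length(bad)) stop("invalid specification names: ",
                        paste(bad, collapse = ", "))
  structure(cfg, class = "run_config")
}

load_config_village <- function(config) {
  vil <- read_village(config$actor_table,
                      unlist(config$dyad_matrices),
                      unlist(config$edge_lists),
                      absent = unlist(config$absent))
  preprocess_covariates(vil)
}

config_out <- function(config, name) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  file.path(config$output_dir, name)
}

provenance <- function(config) {
  sprintf("# seed=%s sasnet=%s", config$seed,
          as.character(utils::packageVersion("sasnet")))
}

write_table <- function(df, path, config) {
  con <- file(path, "w")
  writeLines(provenance(config), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  path
}

#' Descriptive report
#'
#' Computes whole-graph descriptives, censuses, kin composition of triads
#' and the giver/receiver graph correlation for the configured village, and
#' writes them as tidy CSV under the configured output directory.
#'
#' @param config a `run_config` (or path to one).
#' @return invisibly, a list with the computed tables.
#' @export
cmd_descriptives <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  vil <- load_config_village(config)
  net <- vil$verified
  if (is.null(net)) stop("configuration provides no verified network")
  degenerate <- sum(adj(net)) == 0
  if (degenerate) message("note: network is empty (degenerate descriptives)")
  summary_df <- data.frame(
    statistic = c("n", "arcs", "density", "reciprocity", "transitivity",
                  "mean_degree", "sd_out", "sd_in", "max_out", "max_in"),
    value = {
      ds <- degree_summaries(net)
      c(n_actors(net), sum(adj(net)), graph_density(net),
        if (degenerate) NaN else reciprocity_proportion(net),
        if (degenerate) NaN else suppressWarnings(transitivity_weak(net)),
        ds$mean_degree, ds$sd_out, ds$sd_in, ds$max_out, ds$max_in)
    })
  tc <- triad_census(net)
  cc <- clique_census(net)
  gd <- geodesic_distribution(net)
  kin <- if (!is.null(vil$dyads$consanguineal) &&
             !is.null(vil$dyads$affinal))
    kin_triad_composition(net, vil$dyads$consanguineal, vil$dyads$affinal)
  gcor <- if (!is.null(vil$giver) && !is.null(vil$receiver))
    suppressWarnings(graph_correlation(vil$giver, vil$receiver)) else NA
  out <- list(summary = summary_df,
              triads = data.frame(class = names(tc), count = as.numeric(tc)),
              cliques = data.frame(size = names(cc), count = as.numeric(cc)),
              geodesics = data.frame(distance = names(gd),
                                     pairs = as.numeric(gd)),
              kin_triads = kin,
              graph_correlation = data.frame(statistic = "graph_correlation",
                                             value = gcor))
  for (nm in names(out))
    if (!is.null(out[[nm]]))
      write_table(out[[nm]], config_out(config, paste0(nm, ".csv")), config)
  invisible(out)
}

#' Fit the configured specifications
#'
#' One method-of-moments fit per (specification, rate) combination, written
#' as CSV reports mirroring the usual estimate/se/p table layout.
#'
#' @param config a `run_config` (or path).
#' @param allow_nonconverged do not raise an error on non-convergence.
#' @return invisibly, a named list of `saom_fit` objects
#'   (`<spec>_rate<rate>`).
#' @export
cmd_fit <- function(config, allow_nonconverged = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  vil <- load_config_village(config)
  est <- do.call(est_settings, as.list(config$estimation %||% list()))
  fits <- list()
  for (spec_name in unlist(config$specifications)) {
    spec <- build_specification(spec_name, vil)
    for (rate in unlist(config$rates)) {
      key <- sprintf("%s_rate%g", spec_name, rate)
      fit <- fit_saom(spec$evalfn, vil$verified, spec$village,
                      sim_settings(rate = rate), est, seed = config$seed)
      if (!fit$converged && !allow_nonconverged)
        stop("fit '", key, "' did not converge (overall ratio ",
             round(fit$overall_ratio, 3), ")")
      write_table(cbind(fit_report(fit),
                        converged = fit$converged,
                        overall_ratio = fit$overall_ratio,
                        rate = rate),
                  config_out(config, paste0("fit_", key, ".csv")), config)
      fits[[key]] <- fit
    }
  }
  invisible(fits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Relative-importance report
#'
#' @param config a `run_config` (or path).
#' @param fits named list from [cmd_fit()].
#' @return invisibly, the effect-level importance table (one column per
#'   fit, rows I_k(x)) plus per-fit R_H.
#' @export
cmd_importance <- function(config, fits) {
  if (is.character(config)) config <- read_run_config(config)
  if (!length(fits)) stop("no fits supplied")
  cols <- lapply(fits, function(fit) {
    imp <- relative_importance(fit$evalfn, fit$net, fit$village)
    c(imp$global, R_H = imp$r_h)
  })
  effects <- unique(unlist(lapply(cols, names)))
  tab <- data.frame(effect = effects)
  for (nm in names(cols)) tab[[nm]] <- cols[[nm]][effects]
  write_table(tab, config_out(config, "importance.csv"), config)
  invisible(tab)
}

#' Goodness-of-fit report
#'
#' @param config a `run_config` (or path).
#' @param fits named list from [cmd_fit()].
#' @return invisibly, a data frame of per-(fit, family) MHD and p.
#' @export
cmd_gof <- function(config, fits) {
  if (is.character(config)) config <- read_run_config(config)
  if (!length(fits)) stop("no fits supplied")
  gof_cfg <- config$gof %||% list()
  families <- unlist(gof_cfg$families) %||% GOF_FAMILIES
  R <- gof_cfg$replicates %||% 1000
  rows <- list()
  for (nm in names(fits)) {
    res <- run_gof(fits[[nm]], families = families, R = R)
    for (fam in names(res))
      rows[[paste(nm, fam)]] <- data.frame(fit = nm, family = fam,
                                           mhd = res[[fam]]$mhd,
                                           p = res[[fam]]$p, R = R)
  }
  tab <- do.call(rbind, c(rows, make.row.names = FALSE))
  write_table(tab, config_out(config, "gof.csv"), config)
  invisible(tab)
}

#' Simulate an ensemble from a fitted or configured model
#'
#' @param config a `run_config` (or path).
#' @param fit a `saom_fit`.
#' @param R replicate count.
#' @return invisibly, the replicate-by-effect statistic matrix (also written
#'   as tidy CSV).
#' @export
cmd_simulate <- function(config, fit, R = 100) {
  if (is.character(config)) config <- read_run_config(config)
  set.seed(config$seed)
  ens <- simulate_ensemble(fit$evalfn, fit$net, fit$village,
                           fit$settings_sim, R = R)
  tab <- data.frame(replicate = rep(seq_len(nrow(ens$stats)),
                                    ncol(ens$stats)),
                    effect = rep(colnames(ens$stats),
                                 each = nrow(ens$stats)),
                    statistic = as.numeric(ens$stats))
  write_table(tab, config_out(config, "simulated_statistics.csv"), config)
  invisible(ens$stats)
}

#' Generate and write a synthetic village
#'
#' @param config a `run_config` (or path); `config$recipe` entries override
#'   [village_recipe()] defaults.
#' @return invisibly, the village (written in the CSV formats
#'   [read_village()] reads).
#' @export
cmd_synth <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  recipe <- do.call(village_recipe, as.list(config$recipe %||% list()))
  vil <- synthetic_village(recipe, seed = config$seed)
  write_village(vil, config$output_dir)
  invisible(vil)
}
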