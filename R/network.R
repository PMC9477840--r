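#' Directed binary network
#'
#' Construct a directed network over `n` actors from a 0/1 adjacency matrix.
#' Self-ties are forbidden; the diagonal is forced to zero.
#'
#' @param ties square 0/1 matrix (or object coercible to one); rows are tie
#'   senders, columns receivers.
#' @param labels actor identifiers; defaults to the matrix dimnames or
#'   `a1..an`.
#' @param observation_label free-text label for the observation moment.
#' @return an object of class `directed_network`: an integer adjacency matrix
#'   with actor labels as dimnames.
#' @export
directed_network <- function(ties, labels = NULL,
                             observation_label = "t0") {
  ties <- as.matrix(ties)
  if (nrow(ties) != ncol(ties)) stop("adjacency matrix must be square")
  n <- nrow(ties)
  if (n < 2) stop("a directed network needs at least 2 actors")
  if (anyNA(ties)) stop("missing tie entries are forbidden")
  if (!all(ties %in% c(0, 1))) stop("tie values must be 0 or 1")
  if (is.null(labels)) labels <- rownames(ties)
  if (is.null(labels)) labels <- paste0("a", seq_len(n))
  if (length(labels) != n) stop("labels must match the actor count")
  storage.mode(ties) <- "integer"
  diag(ties) <- 0L
  dimnames(ties) <- list(labels, labels)
  structure(ties, class = c("directed_network", "matrix", "array"),
            observation_label = observation_label)
}

#' @export
print.directed_network <- function(x, ...) {
  cat(sprintf("<directed_network> %d actors, %d arcs (%s)\n",
              nrow(x), sum(unclass(x)), attr(x, "observation_label")))
  invisible(x)
}

#' @rdname directed_network
#' @param net a `directed_network`
#' @export
n_actors <- function(net) nrow(net)

#' @rdname directed_network
#' @export
actor_labels <- function(net) rownames(net)

# strip class for plain matrix arithmetic
adj <- function(net) {
  m <- unclass(net)
  attr(m, "observation_label") <- NULL
  m
}

#' Assemble a village dataset
#'
#' Bundle double-sampled aid reports, actor covariates, dyadic covariates and
#' household membership into one object. All components must share the same
#' actor set.
#'
#' @param actors data frame of actor covariates, one row per actor, with a
#'   `label` column and a `household` column.
#' @param dyads named list of square numeric matrices (labelled rows/columns).
#' @param giver,receiver `directed_network` objects holding the "support
#'   giving" and "support receiving" reports (may be `NULL`).
#' @param verified `directed_network` of verified ties (may be `NULL`; see
#'   [build_verified_network()]).
#' @param absent character vector of actors absent at interview time.
#' @return a list of class `village`.
#' @export
village <- function(actors, dyads = list(), giver = NULL, receiver = NULL,
                    verified = NULL, absent = character()) {
  if (!is.data.frame(actors) || is.null(actors$label))
    stop("actors must be a data frame with a 'label' column")
  labels <- as.character(actors$label)
  if (anyDuplicated(labels)) stop("duplicate actor labels")
  if (is.null(actors$household)) stop("actors must carry a 'household' column")
  check_labels <- function(obj, what) {
    if (is.null(obj)) return()
    if (!identical(rownames(obj), labels))
      stop(sprintf("%s actor set does not match the actor table: %s", what,
                   paste(setdiff(union(rownames(obj), labels),
                                 intersect(rownames(obj), labels)),
                         collapse = ", ")))
  }
  for (nm in names(dyads)) {
    m <- dyads[[nm]]
    if (!is.matrix(m) || nrow(m) != ncol(m))
      stop(sprintf("dyad covariate '%s' must be a square matrix", nm))
    check_labels(m, sprintf("dyad covariate '%s'", nm))
  }
  check_labels(giver, "giver report")
  check_labels(receiver, "receiver report")
  check_labels(verified, "verified network")
  bad <- setdiff(absent, labels)
  if (length(bad)) stop("unknown absent actors: ", paste(bad, collapse = ", "))
  structure(list(actors = actors, dyads = dyads, giver = giver,
                 receiver = receiver, verified = verified,
                 absent = as.character(absent), labels = labels,
                 n = length(labels), preprocessed = FALSE),
            class = "village")
}

#' @export
print.village <- function(x, ...) {
  cat(sprintf("<village> %d actors, %d households, %d dyad covariates%s\n",
              x$n, length(unique(x$actors$household)), length(x$dyads),
              if (isTRUE(x$preprocessed)) " (preprocessed)" else ""))
  invisible(x)
}

households_of <- function(village) {
  hh <- village$actors$household
  names(hh) <- village$labels
  hh
}

#' Build the verified tie network from double-sampled reports
#'
#' A tie i -> j is verified when i reports giving aid to j *and* j reports
#' receiving aid from i (mutual assent). For dyads involving exactly one
#' absent actor (someone who gave no reports), the unilateral report of the
#' present actor is taken at face value; ties between two absent actors are
#' coded absent.
#'
#' @param giver `directed_network` of "I give to ..." reports.
#' @param receiver `directed_network` of "I receive from ..." reports; entry
#'   (i, j) = 1 means j reported receiving from i.
#' @param absent character vector of absent actor labels.
#' @return a `directed_network` of verified ties.
#' @export
build_verified_network <- function(giver, receiver, absent = character()) {
  if (!identical(dim(giver), dim(receiver)) ||
      !identical(rownames(giver), rownames(receiver)))
    stop("giver and receiver reports must cover the same actors")
  labels <- rownames(giver)
  bad <- setdiff(absent, labels)
  if (length(bad)) stop("unknown absent actors: ", paste(bad, collapse = ", "))
  g <- adj(giver); r <- adj(receiver)
  out <- g * r
  ab <- labels %in% absent
  if (any(ab)) {
    # i absent, j present: trust j's receiver report for i -> j
    out[ab, !ab] <- r[ab, !ab, drop = FALSE]
    # j absent, i present: trust i's giver report for i -> j
    out[!ab, ab] <- g[!ab, ab, drop = FALSE]
    out[ab, ab] <- 0L
  }
  directed_network(out, labels,
                   observation_label = attr(giver, "observation_label"))
}

#' Preprocess village covariates for modelling
#'
#' Applies the standard transformations: household wealth is natural-log
#' transformed then z-scored; household size, age, melanin index and BMI are
#' z-scored; geographic distance becomes ln(d + 1); a directed dyadic
#' relative wealth rank matrix (household wealth rank of i minus that of j,
#' rank 1 = poorest household) is derived. Binary covariates are untouched.
#'
#' @param village a [village()] object with raw covariates.
#' @return the village with transformed covariates and `preprocessed = TRUE`.
#' @export
preprocess_covariates <- function(village) {
  stopifnot(inherits(village, "village"))
  if (isTRUE(village$preprocessed)) return(village)
  ac <- village$actors
  zscore <- function(v, nm) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0)
      stop(sprintf("covariate '%s' has zero variance", nm))
    (v - mean(v)) / s
  }
  if (!is.null(ac$wealth)) {
    if (any(ac$wealth <= 0)) stop("wealth must be positive for log transform")
    rank_hh <- compute_wealth_ranks(ac)
    rwr <- outer(rank_hh, rank_hh, `-`)
    dimnames(rwr) <- list(village$labels, village$labels)
    village$dyads$relative_wealth_rank <- rwr
    ac$wealth <- zscore(log(ac$wealth), "wealth")
  }
  for (nm in c("household_size", "age", "melanin", "bmi"))
    if (!is.null(ac[[nm]])) ac[[nm]] <- zscore(ac[[nm]], nm)
  village$actors <- ac
  if (!is.null(village$dyads$distance)) {
    d <- village$dyads$distance
    if (any(d < 0)) stop("negative geographic distance")
    village$dyads$distance <- log(d + 1)
  }
  village$preprocessed <- TRUE
  village
}

# intra-village household wealth rank per actor (1 = poorest household)
compute_wealth_ranks <- function(actors) {
  hw <- tapply(actors$wealth, actors$household, function(v) v[1])
  rk <- rank(hw, ties.method = "first")
  as.numeric(rk[as.character(actors$household)])
}

#' Read a village dataset from CSV files
#'
#' @param actor_table_path CSV with one row per actor (columns `label`,
#'   `household`, covariates).
#' @param dyad_matrix_paths named character vector of CSV square matrices with
#'   a header row of actor labels and labels in the first column.
#' @param edge_list_paths named character vector with entries `giver` and/or
#'   `receiver`, CSV edge lists with columns `source,target`.
#' @param absent character vector of absent actor labels.
#' @return a [village()] object (verified network built when both reports are
#'   present).
#' @export
read_village <- function(actor_table_path, dyad_matrix_paths = character(),
                         edge_list_paths = character(),
                         absent = character()) {
  actors <- utils::read.csv(actor_table_path, stringsAsFactors = FALSE)
  if (is.null(actors$label)) stop("actor table needs a 'label' column")
  actors$label <- as.character(actors$label)
  labels <- actors$label
  dyads <- lapply(dyad_matrix_paths, function(p) {
    m <- utils::read.csv(p, row.names = 1, check.names = FALSE)
    m <- as.matrix(m)
    if (!setequal(rownames(m), labels) || !setequal(colnames(m), labels))
      stop(sprintf("actor set in '%s' does not match the actor table: %s", p,
                   paste(setdiff(union(rownames(m), labels),
                                 intersect(rownames(m), labels)),
                         collapse = ", ")))
    m[labels, labels]
  })
  names(dyads) <- names(dyad_matrix_paths)
  read_net <- function(p) {
    el <- utils::read.csv(p, stringsAsFactors = FALSE)
    if (!all(c("source", "target") %in% names(el)))
      stop(sprintf("edge list '%s' needs columns source,target", p))
    bad <- setdiff(unique(c(el$source, el$target)), labels)
    if (length(bad))
      stop(sprintf("unknown actors in '%s': %s", p,
                   paste(bad, collapse = ", ")))
    m <- matrix(0L, length(labels), length(labels),
                dimnames = list(labels, labels))
    m[cbind(match(el$source, labels), match(el$target, labels))] <- 1L
    directed_network(m, labels)
  }
  giver <- if ("giver" %in% names(edge_list_paths))
    read_net(edge_list_paths[["giver"]]) else NULL
  receiver <- if ("receiver" %in% names(edge_list_paths))
    read_net(edge_list_paths[["receiver"]]) else NULL
  verified <- if (!is.null(giver) && !is.null(receiver))
    build_verified_network(giver, receiver, absent) else NULL
  village(actors, dyads, giver, receiver, verified, absent)
}

#' Write a village dataset as CSV files
#'
#' Writes the actor table, dyad covariate matrices and report edge lists in
#' the formats [read_village()] reads.
#'
#' @param village a [village()] object.
#' @param dir output directory (created if needed).
#' @return invisibly, the named list of written paths.
#' @export
write_village <- function(village, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(actors = file.path(dir, "actors.csv"))
  utils::write.csv(village$actors, paths$actors, row.names = FALSE)
  for (nm in names(village$dyads)) {
    p <- file.path(dir, paste0("dyad_", nm, ".csv"))
    utils::write.csv(as.data.frame(village$dyads[[nm]]), p, row.names = TRUE)
    paths[[paste0("dyad_", nm)]] <- p
  }
  write_net <- function(net, nm) {
    idx <- which(adj(net) == 1L, arr.ind = TRUE)
    el <- data.frame(source = rownames(net)[idx[, 1]],
                     target = rownames(net)[idx[, 2]])
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(el, p, row.names = FALSE)
    p
  }
  if (!is.null(village$giver)) paths$giver <- write_net(village$giver, "giver")
  if (!is.null(village$receiver))
    paths$receiver <- write_net(village$receiver, "receiver")
  invisible(paths)
}
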