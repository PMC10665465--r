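# Readers and writers for every format the pipeline touches. All CSVs are
# UTF-8 with header rows; latitudes are decimal degrees (south negative);
# times are Ma before present; newick branch lengths are Ma.

#' Read a dated ultrametric tree from newick
#'
#' Parses newick text or a file, checks bracket balance (reporting the
#' character position of the first imbalance), requires branch lengths,
#' and validates ultrametricity within a relative tolerance of 1e-6.
#'
#' @param source path to a newick file, or newick text when `text = TRUE`.
#' @param text interpret `source` as literal newick text.
#' @return an ultrametric `phylo`.
#' @export
read_dated_tree <- function(source, text = FALSE) {
  nwk <- if (text) source else paste(readLines(source), collapse = "")
  depth <- 0L
  for (i in seq_len(nchar(nwk))) {
    ch <- substr(nwk, i, i)
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0) stop("unbalanced ')' at position ", i)
    }
  }
  if (depth != 0) stop("unbalanced '(': ", depth, " unclosed at end of input")
  tree <- ape::read.tree(text = nwk)
  if (is.null(tree)) stop("newick parse failure")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("newick tree must carry branch lengths on every edge")
  }
  assert_ultrametric(tree, tol = 1e-6)
  tree
}

#' Write a dated tree as newick
#'
#' @param tree a `phylo`.
#' @param path output file.
#' @export
write_dated_tree <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 15)
  invisible(path)
}

#' Parse a shift-event table (BAMM event_data dialect)
#'
#' Columns: `generation`, `leftchild`, `rightchild`, `abstime`,
#' `lambdainit`, `lambdashift`, `muinit`, `mushift`. Each row is anchored
#' at the branch subtending MRCA(leftchild, rightchild); an empty
#' `rightchild` anchors the event on the leftchild tip's pendant branch.
#' The row with abstime 0 is the root regime (mandatory).
#'
#' @param path CSV file, or a data.frame already in the dialect.
#' @param tree the `phylo` the events refer to.
#' @param generation which generation to extract when several are present
#'   (default: the first).
#' @return event configuration data.frame with columns `node`, `abstime`,
#'   `lambda0`, `b`, `mu0`, `z` (see [tip_rates()]).
#' @export
parse_event_table <- function(path, tree, generation = NULL) {
  ev <- if (is.data.frame(path)) path else
    read.csv(path, stringsAsFactors = FALSE)
  need <- c("generation", "leftchild", "rightchild", "abstime",
            "lambdainit", "lambdashift", "muinit", "mushift")
  miss <- setdiff(need, names(ev))
  if (length(miss)) stop("event table missing column(s): ",
                         paste(miss, collapse = ", "))
  gens <- unique(ev$generation)
  if (is.null(generation)) generation <- gens[1]
  ev <- ev[ev$generation == generation, , drop = FALSE]
  if (nrow(ev) == 0) stop("no rows for generation ", generation)
  ev$rightchild[is.na(ev$rightchild)] <- ""
  anchor <- integer(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    l <- ev$leftchild[i]; r <- ev$rightchild[i]
    li <- match(l, tree$tip.label)
    if (is.na(li)) stop("unknown tip label: ", l)
    if (!nzchar(r)) {
      anchor[i] <- li
    } else {
      ri <- match(r, tree$tip.label)
      if (is.na(ri)) stop("unknown tip label: ", r)
      anchor[i] <- if (li == ri) li else ape::getMRCA(tree, c(l, r))
    }
  }
  out <- data.frame(node = anchor, abstime = ev$abstime,
                    lambda0 = ev$lambdainit, b = ev$lambdashift,
                    mu0 = ev$muinit, z = ev$mushift)
  validate_events(tree, out)
  out
}

#' Write an event configuration in the BAMM event_data dialect
#'
#' Internal anchor nodes are encoded by a pair of tip labels whose MRCA is
#' the node; tip anchors carry the tip label and an empty rightchild.
#'
#' @param events event configuration data.frame (`node`, `abstime`,
#'   `lambda0`, `b`, `mu0`, `z`).
#' @param tree the `phylo` the events refer to.
#' @param path output CSV.
#' @param generation generation number to write (default 1).
#' @export
write_event_table <- function(events, tree, path, generation = 1) {
  ntip <- ape::Ntip(tree)
  desc <- NULL
  lr <- t(vapply(events$node, function(v) {
    if (v <= ntip) return(c(tree$tip.label[v], ""))
    if (is.null(desc)) desc <<- phangorn::Descendants(tree, type = "tips")
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    c(tree$tip.label[min(desc[[kids[1]]])],
      tree$tip.label[min(desc[[kids[2]]])])
  }, character(2)))
  out <- data.frame(generation = generation, leftchild = lr[, 1],
                    rightchild = lr[, 2], abstime = events$abstime,
                    lambdainit = events$lambda0, lambdashift = events$b,
                    muinit = events$mu0, mushift = events$z)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read occurrence records, unit tables, genus profiles
#'
#' Thin CSV wrappers that validate the expected columns.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_occurrences <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("genus", "unit", "source_count", "introduced", "granularity",
            "overlap")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("occurrences missing column(s): ",
                         paste(miss, collapse = ", "))
  x$introduced <- as.logical(x$introduced)
  x
}

#' @rdname read_occurrences
#' @export
read_units <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "centroid_lat", "centroid_lon", "area_km2", "region_group")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("units missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(x$area_km2 <= 0)) stop("unit areas must be positive")
  x
}

#' @rdname read_occurrences
#' @export
read_profiles <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  if (!"genus" %in% names(x) && "tip" %in% names(x)) x$genus <- x$tip
  need <- c("genus", "stem_age", "lambda_tip", "netdiv_tip")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("profiles missing column(s): ",
                         paste(miss, collapse = ", "))
  x
}

#' @rdname read_occurrences
#' @export
read_sequence_records <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  x$published <- as.logical(x$published)
  check_records(x)
  x
}

#' Pipeline configuration defaults
#'
#' Collects the tunable settings of the analysis chain: per-region QC
#' source-count thresholds, the 13 latitudinal belt definitions, the
#' quartile metric, lowess span (0.5), null-model replicates (999), the
#' branch discretization fraction for rates through time (0.02), and the
#' seed.
#'
#' @param qc_thresholds named vector, see [default_qc_thresholds()].
#' @param quartile_metric one of "age", "lambda", "netdiv".
#' @param lowess_span lowess span in (0, 1].
#' @param null_reps null-model replicates, >= 1.
#' @param seg_frac rate discretization fraction of tree height.
#' @param seed integer seed.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(qc_thresholds = default_qc_thresholds(),
                            quartile_metric = "netdiv",
                            lowess_span = 0.5, null_reps = 999,
                            seg_frac = 0.02, seed = 1L) {
  stopifnot(all(qc_thresholds >= 1), lowess_span > 0, lowess_span <= 1,
            null_reps >= 1, seg_frac > 0)
  structure(list(qc_thresholds = qc_thresholds,
                 belts = belt_definitions(),
                 quartile_metric = quartile_metric,
                 lowess_span = lowess_span, null_reps = null_reps,
                 seg_frac = seg_frac, seed = seed),
            class = "pipeline_config")
}
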