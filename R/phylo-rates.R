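# Rate regimes and rate extraction. An event configuration is a data.frame
# with one row per regime-origin event:
#   node    - id of the node subtending the anchor branch (the regime applies
#             to that branch from `abstime` on, and to everything downstream
#             until overridden by a later event)
#   abstime - Ma since the root at which the regime starts
#   lambda0, b - speciation at regime start and exponential change (1/Ma):
#                lambda(t) = lambda0 * exp(b * (t - abstime))
#   mu0, z     - extinction, same parameterization (z = 0: constant)
# The root regime is the row with node == root and abstime == 0.

validate_events <- function(tree, events) {
  need <- c("node", "abstime", "lambda0", "b", "mu0", "z")
  if (!all(need %in% names(events))) {
    stop("event configuration must have columns ",
         paste(need, collapse = ", "))
  }
  root <- ape::Ntip(tree) + 1L
  if (!any(events$node == root & events$abstime <= 1e-9)) {
    stop("no root regime: an event with node = root and abstime = 0 is required")
  }
  h <- tree_height(tree)
  if (any(events$abstime < -1e-9 | events$abstime > h + 1e-9)) {
    stop("event abstime outside [0, tree height]")
  }
  stopifnot(all(events$lambda0 > 0), all(events$mu0 >= 0))
  invisible(events)
}

# For each node, the events anchored on its root-to-node path, as an index
# list; used by both tip_rates and rate_through_time.
path_events <- function(tree, events) {
  p <- parent_vec(tree)
  np <- ape::Ntip(tree) + tree$Nnode
  ev_by_node <- split(seq_len(nrow(events)), events$node)
  out <- vector("list", np)
  root <- ape::Ntip(tree) + 1L
  # breadth-first from the root so parents are filled before children
  ord <- c(root, tree$edge[order(node_depths(tree)[tree$edge[, 2]]), 2])
  for (v in ord) {
    own <- ev_by_node[[as.character(v)]]
    inherited <- if (v == root) integer(0) else out[[p[v]]]
    out[[v]] <- c(inherited, own)
  }
  out
}

# Regime in effect on the branch subtending `node` at absolute time `at`:
# the applicable event with the latest abstime <= at ("latest wins").
regime_at <- function(events, path_idx, at, tol = 1e-9) {
  idx <- path_idx[events$abstime[path_idx] <= at + tol]
  if (length(idx) == 0) stop("no regime in effect at abstime ", at)
  # latest abstime wins; at equal abstime the more downstream event (later
  # in root-to-node path order) takes precedence
  m <- max(events$abstime[idx])
  idx <- idx[events$abstime[idx] >= m - tol]
  idx[length(idx)]
}

#' Tip rates under an event configuration
#'
#' For each tip, the nearest upstream event on its root-to-tip path defines
#' its regime; rates are the regime's instantaneous values at the present:
#' `lambda_tip = lambda0 * exp(b * (H - abstime))` with `H` the tree height,
#' and likewise for extinction with `z`.
#'
#' @param tree ultrametric `phylo`, branch lengths in Ma.
#' @param events event configuration data.frame (see [parse_event_table()]).
#' @return data.frame with columns `tip`, `lambda_tip`, `mu_tip`,
#'   `netdiv_tip` (= lambda - mu) and `stem_age` (Ma).
#' @export
tip_rates <- function(tree, events) {
  validate_events(tree, events)
  h <- tree_height(tree)
  pe <- path_events(tree, events)
  ntip <- ape::Ntip(tree)
  lam <- mu <- numeric(ntip)
  for (i in seq_len(ntip)) {
    e <- regime_at(events, pe[[i]], h)
    d <- h - events$abstime[e]
    lam[i] <- events$lambda0[e] * exp(events$b[e] * d)
    mu[i] <- events$mu0[e] * exp(events$z[e] * d)
  }
  data.frame(tip = tree$tip.label, lambda_tip = lam, mu_tip = mu,
             netdiv_tip = lam - mu,
             stem_age = stem_age(tree, tree$tip.label),
             stringsAsFactors = FALSE)
}

#' Mean rates through time for a set of tips
#'
#' Restricts the tree to the subtree spanned by `tips` (the union of their
#' root-to-tip paths) and, at each grid time, averages
#' the regime rate over all branches alive at that time. Rates are
#' discretized piecewise-constant along each branch in segments of
#' `seg_frac` times the tree height, each segment carrying the regime rate
#' evaluated at its midpoint.
#'
#' @param tree ultrametric `phylo`.
#' @param events event configuration data.frame.
#' @param tips tip labels defining the assemblage; default all tips.
#' @param grid numeric vector of times in Ma before present, within
#'   `[0, height]`.
#' @param seg_frac branch discretization length as a fraction of tree
#'   height (default 0.02).
#' @return data.frame with columns `time` (Ma before present), `lambda`,
#'   `mu`, `netdiv` (mean over lineages) and `n_lineages`.
#' @export
rate_through_time <- function(tree, events, tips = tree$tip.label, grid,
                              seg_frac = 0.02) {
  if (length(tips) == 0) stop("empty tip subset")
  miss <- setdiff(tips, tree$tip.label)
  if (length(miss)) stop("unknown tip(s): ", paste(miss, collapse = ", "))
  validate_events(tree, events)
  h <- tree_height(tree)
  if (any(grid < -1e-9 | grid > h + 1e-9)) {
    stop("grid times must lie within [0, tree height]")
  }
  seg <- seg_frac * h
  dep <- node_depths(tree)
  p <- parent_vec(tree)
  pe <- path_events(tree, events)

  # branches on the root-to-tip paths of the subset
  tip_idx <- match(tips, tree$tip.label)
  root <- ape::Ntip(tree) + 1L
  keep <- integer(0)
  for (i in tip_idx) {
    v <- i
    while (v != root && !(v %in% keep)) {
      keep <- c(keep, v)
      v <- p[v]
    }
  }
  ntip <- ape::Ntip(tree)
  start <- dep[p[keep]]
  end <- dep[keep]
  is_tip <- keep <= ntip

  branch_rate <- function(k, at) {
    # midpoint of the seg-length segment of branch k that contains `at`
    j <- floor((at - start[k]) / seg)
    mid <- start[k] + (j + 0.5) * seg
    if (mid > end[k]) mid <- (start[k] + j * seg + end[k]) / 2
    e <- regime_at(events, pe[[keep[k]]], mid)
    d <- mid - events$abstime[e]
    c(events$lambda0[e] * exp(events$b[e] * d),
      events$mu0[e] * exp(events$z[e] * d))
  }

  out <- data.frame(time = grid, lambda = NA_real_, mu = NA_real_,
                    netdiv = NA_real_, n_lineages = NA_integer_)
  for (gi in seq_along(grid)) {
    at <- h - grid[gi]
    # half-open spans avoid double counting at internal nodes; tips extend
    # to the present inclusively
    alive <- which(start <= at + 1e-12 &
                     (at < end - 1e-12 | (is_tip & at <= end + 1e-12)))
    if (length(alive) == 0) {
      out$n_lineages[gi] <- 0L
      next
    }
    rates <- vapply(alive, branch_rate, numeric(2), at = at)
    out$lambda[gi] <- mean(rates[1, ])
    out$mu[gi] <- mean(rates[2, ])
    out$netdiv[gi] <- out$lambda[gi] - out$mu[gi]
    out$n_lineages[gi] <- length(alive)
  }
  out
}

#' Per-tip sampling fractions from species richness
#'
#' Species-level incompleteness of a genus-level tree: each genus tip
#' carries the fraction `1 / richness`, plus a single backbone completeness
#' fraction for the tree as a whole (0.725 for a molecular-only tree with
#' genera missing; 0.97 for a complete genus-level tree under a
#' conservative assumption).
#'
#' @param richness named numeric vector (names = genus) of species richness,
#'   all >= 1.
#' @param backbone backbone completeness fraction in (0, 1].
#' @return list with elements `backbone` (scalar) and `tips` (data.frame
#'   `genus`, `clade`, `fraction`).
#' @export
sampling_fractions <- function(richness, backbone = 0.97) {
  if (is.null(names(richness)) || any(!nzchar(names(richness)))) {
    stop("richness must be a named vector (names = genus)")
  }
  if (any(richness < 1)) {
    stop("species richness must be >= 1 for every genus")
  }
  stopifnot(backbone > 0, backbone <= 1)
  list(backbone = backbone,
       tips = data.frame(genus = names(richness), clade = names(richness),
                         fraction = 1 / unname(richness),
                         stringsAsFactors = FALSE))
}

#' Write a sampling-fraction file
#'
#' First line: backbone fraction; then one `tip<TAB>clade<TAB>fraction`
#' line per genus.
#'
#' @param sf result of [sampling_fractions()].
#' @param path output file.
#' @export
write_sampling_fractions <- function(sf, path) {
  lines <- c(format(sf$backbone, digits = 15),
             sprintf("%s\t%s\t%s", sf$tips$genus, sf$tips$clade,
                     format(sf$tips$fraction, digits = 15, trim = TRUE)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sampling_fractions
#' @export
read_sampling_fractions <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines[-1], "\t", fixed = TRUE)
  tips <- data.frame(genus = vapply(parts, `[`, "", 1),
                     clade = vapply(parts, `[`, "", 2),
                     fraction = as.numeric(vapply(parts, `[`, "", 3)),
                     stringsAsFactors = FALSE)
  list(backbone = as.numeric(lines[1]), tips = tips)
}
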