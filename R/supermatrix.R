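# Sequence screening and greedy composite-terminal selection. Sequence
# records are data.frames with columns species, genus, marker, length,
# published (logical), date (orderable: Date, ISO string, or numeric),
# accession.

check_records <- function(records) {
  need <- c("species", "genus", "marker", "length", "published", "date",
            "accession")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(records) && any(records$length < 1)) {
    stop("sequence lengths must be >= 1")
  }
  invisible(records)
}

#' Keep one sequence per (species, marker)
#'
#' Retains the longest sequence of each species for each marker; among
#' equal lengths the published one is preferred, and among those the most
#' recently published. Precedence: length, then published flag, then date.
#'
#' @param records sequence-record data.frame (see package docs).
#' @return data.frame with exactly one row per (species, marker) pair.
#' @export
dedupe_longest <- function(records) {
  check_records(records)
  if (nrow(records) == 0) return(records)
  o <- order(records$species, records$marker, -records$length,
             -as.integer(records$published), -xtfrm(records$date))
  records <- records[o, , drop = FALSE]
  keep <- !duplicated(records[c("species", "marker")])
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Relative sequence length
#'
#' A sequence's length divided by the maximum length of that marker within
#' the genus.
#'
#' @param length sequence length in bp.
#' @param genus_marker_max maximum length of the marker in the genus.
#' @return fraction in (0, 1].
#' @export
relative_length <- function(length, genus_marker_max) {
  if (any(genus_marker_max == 0)) {
    stop("genus_marker_max is 0: marker absent from genus")
  }
  if (any(length < 1) || any(length > genus_marker_max)) {
    stop("length must satisfy 1 <= length <= genus_marker_max")
  }
  length / genus_marker_max
}

#' Assess genus monophyly on a reference species-level tree
#'
#' A genus is monophyletic iff the MRCA of its sampled species subtends no
#' other genus's species. For non-monophyletic genera, the maximal
#' genus-pure clades are enumerated and the largest one is selected as the
#' core set representing the genus (ties broken by the number of sequence
#' records in the clade when `records` is supplied, then by the
#' alphabetically first tip).
#'
#' @param reference_tree `phylo` over species.
#' @param genus_map data.frame with columns `species`, `genus`; every
#'   species must be a tip of `reference_tree`.
#' @param records optional deduplicated sequence records used for
#'   tie-breaking between equally large clades.
#' @return named list (one element per genus) of lists with fields `genus`,
#'   `status` ("monophyletic" or "non-monophyletic"), `clades` (list of tip
#'   sets) and `core` (character vector of species).
#' @export
classify_monophyly <- function(reference_tree, genus_map, records = NULL) {
  miss <- setdiff(genus_map$species, reference_tree$tip.label)
  if (length(miss)) {
    stop("species absent from reference tree: ", paste(miss, collapse = ", "))
  }
  ntip <- ape::Ntip(reference_tree)
  genus_of <- setNames(genus_map$genus, genus_map$species)
  tipg <- genus_of[reference_tree$tip.label]  # NA for unmapped tips
  desc <- phangorn::Descendants(reference_tree, type = "tips")
  p <- parent_vec(reference_tree)

  reports <- list()
  for (g in unique(genus_map$genus)) {
    tips_g <- which(!is.na(tipg) & tipg == g)
    if (length(tips_g) == 1) {
      core <- reference_tree$tip.label[tips_g]
      reports[[g]] <- list(genus = g, status = "monophyletic",
                           clades = list(core), core = core)
      next
    }
    mrca <- ape::getMRCA(reference_tree, tips_g)
    if (all(tipg[desc[[mrca]]] %in% g)) {
      core <- reference_tree$tip.label[tips_g]
      reports[[g]] <- list(genus = g, status = "monophyletic",
                           clades = list(core), core = core)
      next
    }
    # maximal genus-pure clades: nodes whose tips are all g, whose parent's
    # tips are not
    pure <- vapply(desc, function(d) all(tipg[d] %in% g), logical(1))
    pure[setdiff(seq_len(ntip), tips_g)] <- FALSE
    maximal <- which(pure & !pure[pmax(p, 1)])
    clades <- lapply(maximal, function(n)
      sort(reference_tree$tip.label[desc[[n]]]))
    sizes <- lengths(clades)
    nrec <- if (is.null(records)) rep(0L, length(clades)) else
      vapply(clades, function(cl) sum(records$species %in% cl), integer(1))
    first_tip <- vapply(clades, `[`, "", 1)
    best <- order(-sizes, -nrec, first_tip)[1]
    reports[[g]] <- list(genus = g, status = "non-monophyletic",
                         clades = clades, core = clades[[best]])
  }
  reports
}

#' Flatten monophyly reports to a table
#'
#' @param reports result of [classify_monophyly()].
#' @return data.frame with columns `genus`, `status`, `n_clades`,
#'   `core_size`, `core` (semicolon-separated species).
#' @export
monophyly_table <- function(reports) {
  data.frame(
    genus = vapply(reports, `[[`, "", "genus"),
    status = vapply(reports, `[[`, "", "status"),
    n_clades = vapply(reports, function(r) length(r$clades), integer(1)),
    core_size = vapply(reports, function(r) length(r$core), integer(1)),
    core = vapply(reports, function(r) paste(r$core, collapse = ";"), ""),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Greedy marker-coverage selection for one genus
#'
#' Chooses a minimal species set maximizing marker coverage: markers are
#' processed in ascending order of the number of species carrying them
#' (ties alphabetical); for each not-yet-covered marker the candidate
#' species covering the most markers overall is added (ties: highest total
#' relative sequence length, then alphabetical species id); finally, for
#' each covered marker the longest sequence among the selected species is
#' chosen.
#'
#' @param genus_records deduplicated records of a single genus (already
#'   restricted to the monophyletic core where applicable).
#' @return list with fields `genus`, `species_used` (sorted character),
#'   `per_marker` (data.frame `marker`, `species`, `accession`, `length`)
#'   and `composite` (TRUE when more than one species contributes).
#' @export
greedy_select <- function(genus_records) {
  check_records(genus_records)
  if (nrow(genus_records) == 0) stop("at least one record required")
  if (length(unique(genus_records$genus)) > 1) {
    stop("greedy_select expects records of a single genus")
  }
  r <- genus_records
  marker_max <- tapply(r$length, r$marker, max)
  r$rel_len <- r$length / marker_max[r$marker]
  n_sp <- tapply(r$species, r$marker, function(s) length(unique(s)))
  marker_order <- names(n_sp)[order(n_sp, names(n_sp))]
  sp_markers <- split(r$marker, r$species)           # markers per species
  sp_relsum <- tapply(r$rel_len, r$species, sum)

  covered <- character(0)
  used <- character(0)
  for (m in marker_order) {
    if (m %in% covered) next
    cand <- unique(r$species[r$marker == m])
    n_cov <- lengths(sp_markers[cand])
    relsum <- sp_relsum[cand]
    best <- cand[order(-n_cov, -relsum, cand)][1]
    used <- c(used, best)
    covered <- union(covered, sp_markers[[best]])
  }

  rs <- r[r$species %in% used, , drop = FALSE]
  rs <- rs[order(rs$marker, -rs$length, -as.integer(rs$published),
                 -xtfrm(rs$date), rs$species), , drop = FALSE]
  rs <- rs[!duplicated(rs$marker), , drop = FALSE]
  list(genus = r$genus[1],
       species_used = sort(used),
       per_marker = data.frame(marker = rs$marker, species = rs$species,
                               accession = rs$accession, length = rs$length,
                               stringsAsFactors = FALSE, row.names = NULL),
       composite = length(used) > 1)
}

#' Full selection pipeline over all genera
#'
#' Deduplicates records, optionally screens monophyly on a reference tree
#' (restricting each non-monophyletic genus to its largest genus-pure
#' clade), and runs [greedy_select()] per genus.
#'
#' @param records raw sequence records for all genera.
#' @param reference_tree optional species-level `phylo` for monophyly
#'   screening.
#' @param genus_map data.frame `species`, `genus`; required with
#'   `reference_tree`.
#' @return list with elements `selections` (list of [greedy_select()]
#'   results by genus) and `monophyly` (reports, or NULL).
#' @export
select_supermatrix <- function(records, reference_tree = NULL,
                               genus_map = NULL) {
  deduped <- dedupe_longest(records)
  reports <- NULL
  if (!is.null(reference_tree)) {
    if (is.null(genus_map)) stop("genus_map required with reference_tree")
    reports <- classify_monophyly(reference_tree, genus_map, deduped)
    core_sp <- unlist(lapply(reports, `[[`, "core"), use.names = FALSE)
    # species not on the reference tree are left untouched
    on_tree <- deduped$species %in% reference_tree$tip.label
    deduped <- deduped[!on_tree | deduped$species %in% core_sp, , drop = FALSE]
  }
  selections <- lapply(split(deduped, deduped$genus), greedy_select)
  list(selections = selections, monophyly = reports)
}

#' Flatten selections to a per-marker table
#'
#' @param selections list of [greedy_select()] results.
#' @return data.frame with columns `genus`, `marker`, `accession`,
#'   `species`, `composite`.
#' @export
selection_table <- function(selections) {
  do.call(rbind, lapply(selections, function(s) {
    cbind(data.frame(genus = s$genus, stringsAsFactors = FALSE),
          s$per_marker[c("marker", "accession", "species")],
          data.frame(composite = s$composite))
  })) -> out
  rownames(out) <- NULL
  out
}
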