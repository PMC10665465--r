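# Incidence quality control and per-unit assemblage metrics. Geographic
# units ("GSUs") are rows of a data.frame with columns id, centroid_lat,
# centroid_lon, area_km2, region_group, and one belt_* fraction column per
# latitudinal belt (see belt_definitions()). Occurrence records carry
# genus, unit, source_count, introduced, granularity, overlap.

REGION_GROUPS <- c("Europe", "Australia", "China", "Madagascar",
                   "NorthAmerica", "Other")

#' Default per-region source-count thresholds
#'
#' Occurrences in European units require corroboration by at least 3 data
#' sources; Australia, China, Madagascar and North America require 2; all
#' remaining regions are retained in full (threshold 1) owing to relative
#' data deficiency.
#'
#' @return named integer vector over region groups.
#' @export
default_qc_thresholds <- function() {
  c(Europe = 3L, Australia = 2L, China = 2L, Madagascar = 2L,
    NorthAmerica = 2L, Other = 1L)
}

#' Spatial-conflict resolution for occurrence records
#'
#' Accepts or rejects a record based on how much of its footprint falls
#' inside the assigned unit: locality records need overlap >= 0.80,
#' grid-cell records need overlap strictly > 0.50, coordinate records must
#' fall inside the unit (overlap 1), and range-map records are always
#' accepted (their boundaries are taken from the source data).
#'
#' @param records occurrence data.frame with columns `granularity`
#'   (coordinate | locality | gridcell | rangemap) and `overlap` in [0, 1].
#' @return logical vector, TRUE for accepted records.
#' @export
resolve_overlap <- function(records) {
  gran <- records$granularity
  known <- c("coordinate", "locality", "gridcell", "rangemap")
  bad <- setdiff(unique(gran), known)
  if (length(bad)) stop("unknown granularity: ", paste(bad, collapse = ", "))
  ov <- records$overlap
  if (any(ov < 0 | ov > 1)) stop("overlap must lie in [0, 1]")
  (gran == "locality" & ov >= 0.80) |
    (gran == "gridcell" & ov > 0.50) |
    (gran == "coordinate" & ov >= 1 - 1e-9) |
    (gran == "rangemap")
}

#' Quality-controlled genus x unit incidence
#'
#' Builds the presence table from overlap-accepted occurrence records:
#' a (genus, unit) presence survives iff it is not introduced there and is
#' corroborated by at least the region-specific number of data sources.
#' Multiple records of the same pair are aggregated (maximum source count;
#' introduced only when every record is flagged introduced).
#'
#' @param records occurrence data.frame (columns `genus`, `unit`,
#'   `source_count`, `introduced`), already filtered by [resolve_overlap()].
#' @param units unit table with columns `id`, `region_group`.
#' @param thresholds named vector of per-region source-count thresholds;
#'   defaults to [default_qc_thresholds()].
#' @return data.frame with columns `genus`, `unit` (one row per surviving
#'   presence).
#' @export
qc_filter <- function(records, units, thresholds = default_qc_thresholds()) {
  miss <- setdiff(records$unit, units$id)
  if (length(miss)) stop("unit(s) not in unit table: ",
                         paste(miss, collapse = ", "))
  if (any(thresholds < 1)) stop("thresholds must be >= 1")
  if (nrow(records) == 0) {
    return(data.frame(genus = character(0), unit = character(0)))
  }
  key <- paste(records$genus, records$unit, sep = "\r")
  agg_src <- tapply(records$source_count, key, max)
  agg_intro <- tapply(records$introduced, key, all)
  keys <- names(agg_src)
  genus <- sub("\r.*$", "", keys)
  unit <- sub("^.*\r", "", keys)
  region <- units$region_group[match(unit, units$id)]
  thr <- thresholds[region]
  thr[is.na(thr)] <- thresholds["Other"]
  keep <- !agg_intro & agg_src >= thr
  out <- data.frame(genus = genus[keep], unit = unit[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$unit, out$genus), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-unit assemblage metrics
#'
#' Unweighted arithmetic means of stem age, speciation rate and net
#' diversification rate over the genera incident to each unit, plus genus
#' richness. Units listed in `units` but empty of genera are flagged
#' missing (`richness` 0, metrics NA) so they can be excluded downstream.
#'
#' @param incidence data.frame `genus`, `unit` (from [qc_filter()]).
#' @param profiles genus profile data.frame with columns `genus` (or `tip`),
#'   `stem_age`, `lambda_tip`, `netdiv_tip`.
#' @param units optional unit table; when given, centroid coordinates are
#'   joined and empty units are retained as missing rows.
#' @return data.frame per unit: `unit`, `richness`, `mean_age`,
#'   `mean_lambda`, `mean_netdiv` (+ `centroid_lat`, `centroid_lon` when
#'   `units` is supplied).
#' @export
assemblage_summary <- function(incidence, profiles, units = NULL) {
  if ("tip" %in% names(profiles) && !"genus" %in% names(profiles)) {
    profiles$genus <- profiles$tip
  }
  idx <- match(incidence$genus, profiles$genus)
  if (anyNA(idx)) {
    stop("no profile for genus: ",
         paste(unique(incidence$genus[is.na(idx)]), collapse = ", "))
  }
  f <- factor(incidence$unit)
  out <- data.frame(
    unit = levels(f),
    richness = as.integer(tabulate(f)),
    mean_age = as.numeric(tapply(profiles$stem_age[idx], f, mean)),
    mean_lambda = as.numeric(tapply(profiles$lambda_tip[idx], f, mean)),
    mean_netdiv = as.numeric(tapply(profiles$netdiv_tip[idx], f, mean)),
    stringsAsFactors = FALSE)
  if (!is.null(units)) {
    empty <- setdiff(units$id, out$unit)
    if (length(empty)) {
      out <- rbind(out, data.frame(unit = empty, richness = 0L,
                                   mean_age = NA_real_,
                                   mean_lambda = NA_real_,
                                   mean_netdiv = NA_real_))
    }
    out$centroid_lat <- units$centroid_lat[match(out$unit, units$id)]
    out$centroid_lon <- units$centroid_lon[match(out$unit, units$id)]
  }
  rownames(out) <- NULL
  out
}

#' Global quartile partition of a genus metric
#'
#' Bins all genera at the global 25/50/75 percentiles (linear
#' interpolation) of stem age, speciation rate or net diversification
#' rate. A value exactly at a boundary goes to the lower bin.
#'
#' @param profiles genus profile data.frame.
#' @param metric one of "age", "lambda", "netdiv".
#' @return list with `labels` (named factor Q1..Q4 over genera) and
#'   `breaks` (the three percentile cut points).
#' @export
quartile_partition <- function(profiles, metric = c("age", "lambda", "netdiv")) {
  metric <- match.arg(metric)
  col <- switch(metric, age = "stem_age", lambda = "lambda_tip",
                netdiv = "netdiv_tip")
  x <- profiles[[col]]
  names(x) <- profiles$genus
  x <- x[is.finite(x)]
  if (length(unique(x)) < 4) {
    stop("fewer than 4 distinct finite values: quartiles degenerate")
  }
  br <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  lab <- cut(x, c(-Inf, br, Inf), labels = c("Q1", "Q2", "Q3", "Q4"),
             right = TRUE)
  names(lab) <- names(x)
  list(labels = lab, breaks = br)
}

#' Per-unit quartile proportions
#'
#' @param incidence data.frame `genus`, `unit`.
#' @param partition result of [quartile_partition()].
#' @return data.frame per unit with columns `unit`, `q1`..`q4` (proportions
#'   summing to 1 for non-empty units).
#' @export
unit_quartile_proportions <- function(incidence, partition) {
  lab <- partition$labels[incidence$genus]
  if (anyNA(lab)) {
    stop("genus without quartile label: ",
         paste(unique(incidence$genus[is.na(lab)]), collapse = ", "))
  }
  tab <- table(incidence$unit, lab)
  prop <- tab / rowSums(tab)
  out <- data.frame(unit = rownames(tab), q1 = prop[, "Q1"],
                    q2 = prop[, "Q2"], q3 = prop[, "Q3"], q4 = prop[, "Q4"],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' The 13 ten-degree latitudinal belts
#'
#' @return data.frame with columns `belt`, `lat_min`, `lat_max`, spanning
#'   S55 to N75 with the equatorial belt S5-N5.
#' @export
belt_definitions <- function() {
  lo <- c(-5, -15, -25, -35, -45, -55, 5, 15, 25, 35, 45, 55, 65)
  hi <- lo + 10
  nm <- function(v) ifelse(v < 0, paste0("S", -v), paste0("N", v))
  # southern belts are named nearest-the-equator first (S5-S15, not S15-S5)
  belt <- ifelse(hi <= 0, paste0(nm(hi), "-", nm(lo)),
                 paste0(nm(lo), "-", nm(hi)))
  data.frame(belt = belt, lat_min = lo, lat_max = hi,
             stringsAsFactors = FALSE)
}

belt_column <- function(belt) paste0("belt_", gsub("-", "_", belt))

#' Assign units to latitudinal belts
#'
#' A unit belongs to the unique belt containing strictly more than half of
#' its area; units with no majority belt get NA.
#'
#' @param units unit table carrying one `belt_*` area-fraction column per
#'   belt of [belt_definitions()].
#' @return character vector (belt id or NA) aligned with `units` rows.
#' @export
assign_belts <- function(units) {
  belts <- belt_definitions()$belt
  cols <- belt_column(belts)
  miss <- setdiff(cols, names(units))
  if (length(miss)) stop("missing belt fraction column(s): ",
                         paste(miss, collapse = ", "))
  fr <- as.matrix(units[cols])
  if (any(fr < -1e-9 | fr > 1 + 1e-9) || any(rowSums(fr) > 1 + 1e-9)) {
    stop("belt fractions must lie in [0,1] and sum to at most 1")
  }
  j <- max.col(fr, ties.method = "first")
  best <- fr[cbind(seq_len(nrow(fr)), j)]
  ifelse(best > 0.5, belts[j], NA_character_)
}

#' Genus sets per latitudinal belt
#'
#' Aggregates the genera of all units assigned to each belt; genera found
#' in several belts appear in each.
#'
#' @param incidence data.frame `genus`, `unit`.
#' @param units unit table.
#' @param assignment optional precomputed [assign_belts()] vector.
#' @return named list (belt -> sorted character vector of genera).
#' @export
belt_genus_union <- function(incidence, units, assignment = assign_belts(units)) {
  belt_of_unit <- setNames(assignment, units$id)
  b <- belt_of_unit[incidence$unit]
  keep <- !is.na(b)
  lapply(split(incidence$genus[keep], b[keep]), function(g) sort(unique(g)))
}

#' Growth-form and photosynthetic-pathway labels
#'
#' A genus is woody when more than 60% of its species are woody,
#' herbaceous when fewer than 40% are, and unclassified in between; it is
#' labeled CAM or C4 when any of its species uses that pathway.
#'
#' @param profiles genus profile data.frame.
#' @param woody_fraction numeric in [0,1], aligned with `profiles` rows.
#' @param cam_any,c4_any logical, TRUE when any species of the genus is
#'   CAM / C4.
#' @return `profiles` with added columns `growth_form` ("woody",
#'   "herbaceous", "unclassified"), `cam`, `c4`.
#' @export
annotate_profiles <- function(profiles, woody_fraction, cam_any, c4_any) {
  if (any(woody_fraction < 0 | woody_fraction > 1, na.rm = TRUE)) {
    stop("woody_fraction must lie in [0, 1]")
  }
  profiles$growth_form <- ifelse(woody_fraction > 0.6, "woody",
                          ifelse(woody_fraction < 0.4, "herbaceous",
                                 "unclassified"))
  profiles$cam <- as.logical(cam_any)
  profiles$c4 <- as.logical(c4_any)
  profiles
}
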