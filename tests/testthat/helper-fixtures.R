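# Fixture builders shared across test files.

# sequence-record rows with defaults
seq_rec <- function(species, marker, length, genus = "G",
                    published = TRUE, date = "2010-01-01",
                    accession = NULL) {
  n <- max(lengths(list(species, marker, length)))
  if (is.null(accession)) accession <- sprintf("acc%03d", seq_len(n))
  data.frame(species = species, genus = genus, marker = marker,
             length = length, published = published, date = date,
             accession = accession, stringsAsFactors = FALSE)
}

# independent brute-force enumeration of maximal genus-pure clades: every
# node (tip or internal) whose tip set is all-genus and whose parent's is not
brute_pure_clades <- function(tree, tips_of_genus) {
  ntip <- ape::Ntip(tree)
  np <- ntip + tree$Nnode
  tipset <- function(v) {
    if (v <= ntip) return(tree$tip.label[v])
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    unlist(lapply(kids, tipset))
  }
  parent <- integer(np)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  pure <- vapply(seq_len(np), function(v)
    all(tipset(v) %in% tips_of_genus), logical(1))
  keep <- which(pure & (parent == 0 | !pure[pmax(parent, 1)]))
  lapply(keep, function(v) sort(tipset(v)))
}

# random sequence-record instance for one genus (for brute-force coverage
# comparison)
random_genus_records <- function(n_species, n_markers) {
  species <- sprintf("sp%02d", seq_len(n_species))
  markers <- sprintf("mk%02d", seq_len(n_markers))
  rows <- expand.grid(species = species, marker = markers,
                      stringsAsFactors = FALSE)
  rows <- rows[runif(nrow(rows)) < 0.6, , drop = FALSE]
  # every marker needs at least one carrier
  for (m in setdiff(markers, unique(rows$marker))) {
    rows <- rbind(rows, data.frame(species = sample(species, 1), marker = m))
  }
  seq_rec(rows$species, rows$marker,
          length = sample(200:1500, nrow(rows), replace = TRUE),
          accession = sprintf("a%04d", seq_len(nrow(rows))))
}

# maximum achievable marker coverage over all species subsets (brute force)
brute_max_coverage <- function(records) {
  species <- unique(records$species)
  best <- 0L
  for (k in seq_along(species)) {
    for (sub in utils::combn(species, k, simplify = FALSE)) {
      cov <- length(unique(records$marker[records$species %in% sub]))
      best <- max(best, cov)
    }
  }
  best
}

# small fixed dated tree used across tests: ((A:1,B:1):2,C:3);
abc_tree <- function() ape::read.tree(text = "((A:1,B:1):2,C:3);")

root_events <- function(tree, lambda0 = 0.1, b = 0, mu0 = 0.03, z = 0) {
  data.frame(node = ape::Ntip(tree) + 1L, abstime = 0,
             lambda0 = lambda0, b = b, mu0 = mu0, z = z)
}

# minimal unit table with belt fraction columns all zero except as given
make_units <- function(n, lat = seq(-50, 60, length.out = n),
                       region = "Other") {
  u <- data.frame(id = sprintf("u%02d", seq_len(n)),
                  centroid_lat = lat, centroid_lon = seq_len(n),
                  area_km2 = 3e5, region_group = region,
                  stringsAsFactors = FALSE)
  for (b in angiodiv::belt_definitions()$belt) {
    u[[paste0("belt_", gsub("-", "_", b))]] <- 0
  }
  u
}
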