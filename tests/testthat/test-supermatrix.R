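# Sequence screening and greedy composite-terminal selection.

test_that("dedupe keeps the longest, then published, then most recent", {
  r <- rbind(seq_rec("sp1", "ITS", 500), seq_rec("sp1", "ITS", 600))
  expect_equal(dedupe_longest(r)$length, 600)

  r <- rbind(seq_rec("sp1", "ITS", 600, date = "2010-06-01"),
             seq_rec("sp1", "ITS", 600, date = "2015-06-01"))
  expect_equal(dedupe_longest(r)$date, "2015-06-01")

  # published beats unpublished at equal length, even when older
  r <- rbind(seq_rec("sp1", "ITS", 600, published = FALSE,
                     date = "2018-01-01"),
             seq_rec("sp1", "ITS", 600, published = TRUE,
                     date = "2012-01-01"))
  expect_true(dedupe_longest(r)$published)

  one <- seq_rec("sp1", "ITS", 450)
  expect_equal(dedupe_longest(one), one)
  empty <- one[0, ]
  expect_equal(nrow(dedupe_longest(empty)), 0)
})

test_that("dedupe yields one record per (species, marker) and is idempotent", {
  set.seed(11)
  r <- seq_rec(sample(c("s1", "s2", "s3"), 40, TRUE),
               sample(c("ITS", "matK", "rbcL"), 40, TRUE),
               sample(300:900, 40, TRUE),
               published = sample(c(TRUE, FALSE), 40, TRUE),
               date = sample(c("2008-01-01", "2013-01-01", "2019-01-01"),
                             40, TRUE))
  d <- dedupe_longest(r)
  expect_false(any(duplicated(d[c("species", "marker")])))
  expect_equal(dedupe_longest(d), d)
  # the survivor is never shorter than any competitor
  for (i in seq_len(nrow(d))) {
    rivals <- r[r$species == d$species[i] & r$marker == d$marker[i], ]
    expect_gte(d$length[i], max(rivals$length))
  }
})

test_that("relative length is the ratio to the genus marker maximum", {
  expect_equal(relative_length(450, 600), 0.75)
  expect_equal(relative_length(600, 600), 1.0)
  expect_error(relative_length(10, 0), "absent")
  expect_error(relative_length(700, 600))
})

test_that("monophyly classification matches brute-force clade enumeration", {
  tr <- ape::read.tree(text = "((a1:1,a2:1):3,(b1:3,(a3:1,b2:1):2):1);")
  gm <- data.frame(species = c("a1", "a2", "a3", "b1", "b2"),
                   genus = c("A", "A", "A", "B", "B"))
  rep <- classify_monophyly(tr, gm)
  expect_equal(rep$A$status, "non-monophyletic")
  expect_setequal(vapply(rep$A$clades, paste, "", collapse = ","),
                  c("a1,a2", "a3"))
  expect_equal(rep$A$core, c("a1", "a2"))
  expect_equal(rep$B$status, "non-monophyletic")

  brute <- brute_pure_clades(tr, c("a1", "a2", "a3"))
  expect_setequal(vapply(rep$A$clades, paste, "", collapse = ","),
                  vapply(brute, paste, "", collapse = ","))
})

test_that("single-tip and single-genus trees are monophyletic", {
  tr <- ape::read.tree(text = "((a1:1,a2:1):1,a3:2);")
  gm <- data.frame(species = c("a1", "a2", "a3"), genus = "A")
  rep <- classify_monophyly(tr, gm)
  expect_equal(rep$A$status, "monophyletic")
  expect_setequal(rep$A$core, c("a1", "a2", "a3"))

  gm1 <- data.frame(species = "a2", genus = "Z")
  expect_equal(classify_monophyly(tr, gm1)$Z$status, "monophyletic")

  expect_error(classify_monophyly(tr, data.frame(species = "zz", genus = "Z")),
               "zz")
})

test_that("monophyly properties hold on random trees", {
  set.seed(21)
  for (i in 1:20) {
    ntip <- sample(6:14, 1)
    tr <- ape::rcoal(ntip)
    tr$tip.label <- sprintf("t%02d", seq_len(ntip))
    gm <- data.frame(species = tr$tip.label,
                     genus = sample(c("A", "B"), ntip, TRUE))
    if (length(unique(gm$genus)) < 2) gm$genus[1] <- setdiff(c("A", "B"), gm$genus[1])
    reps <- classify_monophyly(tr, gm)
    for (g in names(reps)) {
      tips_g <- sort(gm$species[gm$genus == g])
      # clades partition the genus tips
      expect_equal(sort(unlist(reps[[g]]$clades)), tips_g)
      # core is one of the clades and no pure clade strictly contains it
      expect_true(all(reps[[g]]$core %in% tips_g))
      sizes <- lengths(reps[[g]]$clades)
      expect_equal(length(reps[[g]]$core), max(sizes))
      # agreement with brute force
      brute <- brute_pure_clades(tr, tips_g)
      expect_setequal(vapply(reps[[g]]$clades, paste, "", collapse = ","),
                      vapply(brute, paste, "", collapse = ","))
    }
  }
})

test_that("greedy selection reproduces the worked examples", {
  # coverage-driven selection across three markers
  r <- rbind(seq_rec("sp1", "matK", 800, accession = "m1"),
             seq_rec("sp1", "ITS", 600, accession = "i1"),
             seq_rec("sp2", "ITS", 500, accession = "i2"),
             seq_rec("sp2", "rbcL", 1300, accession = "r2"),
             seq_rec("sp3", "rbcL", 1400, accession = "r3"))
  s <- greedy_select(r)
  expect_equal(s$species_used, c("sp1", "sp2"))
  pm <- setNames(s$per_marker$species, s$per_marker$marker)
  expect_equal(pm[["matK"]], "sp1")
  expect_equal(pm[["ITS"]], "sp1")
  expect_equal(pm[["rbcL"]], "sp2")
  expect_equal(s$per_marker$length[s$per_marker$marker == "rbcL"], 1300)
  expect_true(s$composite)

  # coverage, not length, drives species choice
  r2 <- rbind(seq_rec("sp1", "ITS", 400, accession = "x1"),
              seq_rec("sp1", "rbcL", 900, accession = "x2"),
              seq_rec("sp2", "ITS", 600, accession = "x3"))
  s2 <- greedy_select(r2)
  expect_equal(s2$species_used, "sp1")
  expect_equal(s2$per_marker$length[s2$per_marker$marker == "ITS"], 400)
  expect_false(s2$composite)

  # one species covering everything
  r3 <- rbind(seq_rec("sp9", "ITS", 500), seq_rec("sp9", "matK", 700))
  s3 <- greedy_select(r3)
  expect_equal(s3$species_used, "sp9")
  expect_false(s3$composite)
})

test_that("greedy selection achieves maximal coverage with minimal species", {
  set.seed(31)
  for (i in 1:60) {
    r <- dedupe_longest(random_genus_records(sample(2:6, 1), sample(2:5, 1)))
    s <- greedy_select(r)
    expect_equal(nrow(s$per_marker), brute_max_coverage(r))
    expect_lte(length(s$species_used), nrow(s$per_marker))
    # every chosen accession's species is in species_used
    expect_true(all(s$per_marker$species %in% s$species_used))
    # idempotence: selecting from the selection's own records changes nothing
    own <- r[r$accession %in% s$per_marker$accession, ]
    s2 <- greedy_select(own)
    expect_equal(s2$per_marker[order(s2$per_marker$marker), ],
                 s$per_marker[order(s$per_marker$marker), ],
                 ignore_attr = TRUE)
  }
})

test_that("full selection pipeline restricts to monophyletic cores", {
  tr <- ape::read.tree(text = "((a1:1,a2:1):3,(b1:3,(a3:1,b2:1):2):1);")
  gm <- data.frame(species = c("a1", "a2", "a3", "b1", "b2"),
                   genus = c("A", "A", "A", "B", "B"))
  r <- rbind(seq_rec(c("a1", "a2", "a3"), "ITS", c(500, 400, 900),
                     genus = "A"),
             seq_rec(c("b1", "b2"), "ITS", c(700, 800), genus = "B"))
  out <- select_supermatrix(r, tr, gm)
  # a3 is outside A's core clade {a1, a2}: its longer sequence is ignored
  expect_equal(out$selections$A$per_marker$species, "a1")
  tab <- selection_table(out$selections)
  expect_setequal(tab$genus, c("A", "B"))
  mono <- monophyly_table(out$monophyly)
  expect_equal(mono$status[mono$genus == "A"], "non-monophyletic")
})
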