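# Dated-tree operations and rate extraction.

test_that("stem age is the parent node's time", {
  tr <- abc_tree()
  expect_equal(stem_age(tr, "A"), 1)
  expect_equal(stem_age(tr, "B"), 1)
  expect_equal(stem_age(tr, "C"), 3)
  expect_error(stem_age(tr, "Z"), "Z")
})

test_that("unsampled genera attach at family or order crowns", {
  tr <- ape::read.tree(text = "((gA:10,gB:10):10,(gC:15,gD:15):5);")
  tax <- data.frame(genus = c("gA", "gB", "gC", "gD"),
                    family = c("F1", "F1", "F2", "F2"),
                    order = "O1", stringsAsFactors = FALSE)
  add <- data.frame(genus = "gX", family = "F1", order = "O1")
  tr2 <- attach_unsampled(tr, add, tax)
  expect_true("gX" %in% tr2$tip.label)
  expect_equal(stem_age(tr2, "gX"), 10)                  # F1 crown age
  expect_equal(unname(stem_age(tr2, c("gA", "gB"))), c(10, 10))
  # existing branch lengths unchanged
  expect_equal(sort(tr2$edge.length),
               sort(c(tr$edge.length, 10)))
  # ultrametric with pendant edge = crown age
  expect_silent(angiodiv:::assert_ultrametric(tr2))

  # single-member family falls through to the order crown (age 20)
  tax1 <- tax; tax1$family <- c("F1", "F3", "F2", "F2")
  add2 <- data.frame(genus = "gY", family = "F3", order = "O1")
  tr3 <- attach_unsampled(tr, add2, tax1)
  expect_equal(stem_age(tr3, "gY"), 20)

  # neither family nor order has a crown
  add3 <- data.frame(genus = "gZ", family = "F9", order = "O9")
  expect_error(attach_unsampled(tr, add3, tax), "crown")

  expect_equal(attach_unsampled(tr, add[0, ], tax), tr)
})

test_that("polytomy resolution is binary, ultrametric and seed-stable", {
  tr <- ape::read.tree(text = "((A:10,B:10,C:10,D:10,E:10):5,F:15);")
  r1 <- resolve_polytomies(tr, seed = 5)
  r2 <- resolve_polytomies(tr, seed = 5)
  r3 <- resolve_polytomies(tr, seed = 6)
  expect_true(ape::is.binary(r1))
  expect_identical(ape::write.tree(r1), ape::write.tree(r2))
  expect_false(identical(ape::write.tree(r1), ape::write.tree(r3)))
  expect_setequal(r1$tip.label, tr$tip.label)
  expect_silent(angiodiv:::assert_ultrametric(r1))
  # k-child polytomy gains k-2 internal nodes
  expect_equal(r1$Nnode, tr$Nnode + 3)
  # pre-existing node times survive: the (A..E) crown at 10, root at 15
  nt <- round(node_times(r1), 9)
  expect_true(all(c(10, 15) %in% nt))
  # tips stay at the present
  expect_equal(unname(nt[seq_len(ape::Ntip(r1))]), rep(0, 6))
  # binary input is returned unchanged
  b <- abc_tree()
  expect_identical(resolve_polytomies(b, 1), b)
})

test_that("tip rates follow the exponential-change regime formula", {
  tr <- abc_tree()
  # constant-rate root regime
  tp <- tip_rates(tr, root_events(tr, lambda0 = 0.1, b = 0, mu0 = 0.03))
  expect_equal(tp$lambda_tip, rep(0.1, 3))
  expect_equal(tp$netdiv_tip, rep(0.07, 3))

  # shift on C's pendant branch at abstime 1
  ev <- rbind(root_events(tr, 0.1, 0, 0.03),
              data.frame(node = match("C", tr$tip.label), abstime = 1,
                         lambda0 = 0.2, b = -0.1, mu0 = 0.05, z = 0))
  tp <- tip_rates(tr, ev)
  lamC <- 0.2 * exp(-0.1 * (3 - 1))
  expect_equal(tp$lambda_tip[tp$tip == "C"], lamC, tolerance = 1e-12)
  expect_equal(tp$netdiv_tip[tp$tip == "C"], lamC - 0.05, tolerance = 1e-12)
  expect_equal(round(lamC, 6), 0.163746)
  # A and B keep the root regime
  expect_equal(tp$lambda_tip[tp$tip == "A"], 0.1)
  # identity r = lambda - mu
  expect_equal(tp$netdiv_tip, tp$lambda_tip - tp$mu_tip)

  expect_error(tip_rates(tr, ev[-1, ]), "root regime")
})

test_that("latest upstream event wins on a shared path", {
  tr <- ape::read.tree(text = "((A:1,B:1):2,C:3);")
  ab_crown <- ape::getMRCA(tr, c("A", "B"))
  ev <- rbind(root_events(tr, 0.1, 0, 0.0),
              data.frame(node = ab_crown, abstime = 1.0,
                         lambda0 = 0.3, b = 0, mu0 = 0, z = 0),
              data.frame(node = match("A", tr$tip.label), abstime = 2.5,
                         lambda0 = 0.5, b = 0, mu0 = 0, z = 0))
  tp <- tip_rates(tr, ev)
  expect_equal(tp$lambda_tip[tp$tip == "A"], 0.5)
  expect_equal(tp$lambda_tip[tp$tip == "B"], 0.3)
  expect_equal(tp$lambda_tip[tp$tip == "C"], 0.1)
})

test_that("rates through time average regimes over surviving branches", {
  tr <- abc_tree()
  # constant regime: flat curve, lineage counts follow the tree
  rtt <- rate_through_time(tr, root_events(tr, 0.1, 0, 0.03),
                           grid = c(2.5, 1.5, 0))
  expect_equal(rtt$lambda, rep(0.1, 3))
  expect_equal(rtt$n_lineages, c(2L, 2L, 3L))

  # two lineages with different constant rates average arithmetically
  ev <- rbind(root_events(tr, 0.1, 0, 0),
              data.frame(node = match("C", tr$tip.label), abstime = 0,
                         lambda0 = 0.3, b = 0, mu0 = 0, z = 0))
  rtt2 <- rate_through_time(tr, ev, grid = 2.5)
  expect_equal(rtt2$lambda, 0.2)

  # exponential decay matches fine-grid evaluation within the
  # discretization tolerance (segment length = 0.02 * height)
  ev3 <- root_events(tr, 0.2, -0.1, 0)
  rtt3 <- rate_through_time(tr, ev3, tips = "C", grid = seq(0, 2.9, 0.1))
  exact <- 0.2 * exp(-0.1 * (3 - rtt3$time))
  expect_lt(max(abs(rtt3$lambda - exact)),
            0.2 * abs(-0.1) * 0.02 * 3)  # rate slope x segment length bound

  expect_error(rate_through_time(tr, ev3, tips = character(0), grid = 0),
               "empty")
})

test_that("present-day rate through time equals the mean tip rate", {
  cfg <- simulation_config(seed = 77, n_tips = 40)
  sim <- simulate_tree_with_shifts(cfg)
  rtt <- rate_through_time(sim$tree, sim$events, grid = 0)
  tp <- tip_rates(sim$tree, sim$events)
  h <- angiodiv:::tree_height(sim$tree)
  # segment-midpoint evaluation differs from the instantaneous present-day
  # rate by at most slope * seg/2 per tip
  tol <- max(abs(sim$events$b)) * 0.02 * h * max(tp$lambda_tip) + 1e-12
  expect_lt(abs(rtt$lambda - mean(tp$lambda_tip)), tol)
  expect_equal(rtt$n_lineages, 40L)
})

test_that("sampling fractions are reciprocals of species richness", {
  sf <- sampling_fractions(c(gA = 250, gB = 1), backbone = 0.97)
  expect_equal(sf$tips$fraction, c(1 / 250, 1))
  expect_equal(sf$backbone, 0.97)
  expect_error(sampling_fractions(c(gA = 0)), ">= 1")

  f <- tempfile()
  on.exit(unlink(f))
  write_sampling_fractions(sf, f)
  lines <- readLines(f)
  expect_equal(as.numeric(lines[1]), 0.97)
  back <- read_sampling_fractions(f)
  expect_equal(back$backbone, 0.97)
  expect_equal(back$tips$fraction, sf$tips$fraction)
})
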