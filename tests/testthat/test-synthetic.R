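test_that("network generation is deterministic and respects its contracts", {
  a <- generate_network(8, edge_density = 0.2, seed = 201)
  b <- generate_network(8, edge_density = 0.2, seed = 201)
  expect_identical(a$network$edges, b$network$edges)
  expect_identical(
    lapply(a$rules$rules, function(r) r$text),
    lapply(b$rules$rules, function(r) r$text)
  )
  c <- generate_network(8, edge_density = 0.2, seed = 202)
  expect_false(identical(a$network$edges, c$network$edges))
  expect_error(generate_network(5, edge_density = 0), "edge_density")
  expect_error(generate_network(5, edge_density = 1.5), "edge_density")
})

test_that("a dense 2-node all-activating net is the mutual-activation toggle", {
  gn <- generate_network(2, edge_density = 1, sign_ratio = 1, and_fraction = 0, seed = 203)
  rs <- gn$rules
  # both all-off and all-on are fixed points
  for (s in list(c(N01 = 0L, N02 = 0L), c(N01 = 1L, N02 = 1L))) {
    expect_identical(eval_rule(rs$rules[["N01"]], s), s[["N01"]])
    expect_identical(eval_rule(rs$rules[["N02"]], s), s[["N02"]])
  }
})

test_that("exact occupancy handles fixed points, clamps and symmetry", {
  # point mass on a fixed point stays there
  rs <- toggle_rules()
  occ <- exact_occupancy(rs, c(A = 1, B = 0))
  expect_equal(occ$occupancy, c(A = 1, B = 0), tolerance = 1e-9)
  # mutual inhibition from the uniform distribution: half occupancy each
  occ2 <- exact_occupancy(rs, c(A = 0.5, B = 0.5))
  expect_equal(occ2$occupancy, c(A = 0.5, B = 0.5), tolerance = 1e-8)
  # clamped nodes sit exactly at their clamp
  rsc <- rule_set(
    list(boolean_rule("A", "not B"), boolean_rule("B", "not A")),
    clamps = c(A = 1L)
  )
  occ3 <- exact_occupancy(rsc, c(A = 0.5, B = 0.5))
  expect_equal(occ3$occupancy[["A"]], 1, tolerance = 1e-9)
  expect_equal(occ3$occupancy[["B"]], 0, tolerance = 1e-8)
  # state-space guard
  big <- rule_set(lapply(sprintf("N%02d", 1:13), function(nd) boolean_rule(nd, nd)))
  expect_error(exact_occupancy(big, stats::setNames(rep(0.5, 13), big$nodes)), "<= 12")
})

test_that("a chain's occupancy is dictated by its frozen root", {
  nodes <- c("A", "B", "C")
  rs <- rule_set(
    list(
      boolean_rule("A", "A", nodes = nodes), # regulator-free root holds state
      boolean_rule("B", "A", nodes = nodes),
      boolean_rule("C", "B", nodes = nodes)
    ),
    nodes = nodes
  )
  on <- exact_occupancy(rs, c(A = 1, B = 0.5, C = 0.5))$occupancy
  expect_equal(on, c(A = 1, B = 1, C = 1), tolerance = 1e-8)
  off <- exact_occupancy(rs, c(A = 0, B = 0.5, C = 0.5))$occupancy
  expect_equal(off, c(A = 0, B = 0, C = 0), tolerance = 1e-8)
  mix <- exact_occupancy(rs, c(A = 0.3, B = 0.5, C = 0.5))$occupancy
  expect_equal(unname(mix), rep(0.3, 3), tolerance = 1e-8)
})

test_that("ground-truth synergy is zero for self-pairs and reproducible", {
  gn <- generate_network(6, edge_density = 0.3, seed = 204)
  rs <- gn$rules
  reporter <- rs$nodes[[6]]
  drugs <- list(
    D1 = drug("D1", rs$nodes[[1]], "antagonist"),
    D2 = drug("D2", rs$nodes[[2]], "antagonist")
  )
  p <- uniform_profile(rs)
  self_pair <- data.frame(drug1 = "D1", drug2 = "D1")
  out <- generate_ground_truth_synergy(rs, drugs, self_pair, reporter, p, noise_sd = 0)
  expect_equal(out$observed, 0, tolerance = 1e-9)

  pairs <- data.frame(drug1 = "D1", drug2 = "D2")
  o1 <- generate_ground_truth_synergy(rs, drugs, pairs, reporter, p, noise_sd = 0)
  o2 <- generate_ground_truth_synergy(rs, drugs, pairs, reporter, p, noise_sd = 0)
  expect_identical(o1$observed, o2$observed)
})

test_that("redundant activators of the reporter give a synergistic ground truth", {
  # reporter R fires if either parallel input is on; only the pair kills it
  nodes <- c("X", "Y", "R")
  rs <- rule_set(
    list(
      boolean_rule("X", "X", nodes = nodes),
      boolean_rule("Y", "Y", nodes = nodes),
      boolean_rule("R", "X or Y", nodes = nodes)
    ),
    nodes = nodes
  )
  drugs <- list(
    DX = drug("DX", "X", "antagonist"),
    DY = drug("DY", "Y", "antagonist")
  )
  out <- generate_ground_truth_synergy(
    rs, drugs, data.frame(drug1 = "DX", drug2 = "DY"), "R",
    c(X = 1, Y = 1, R = 1),
    noise_sd = 0
  )
  expect_gt(out$observed, 0.5)
})

test_that("scenarios regenerate bit-identically from their seed", {
  s1 <- generate_scenario(n_nodes = 7, n_cell_lines = 2, n_drugs = 4, n_pairs = 5, seed = 205)
  s2 <- generate_scenario(n_nodes = 7, n_cell_lines = 2, n_drugs = 4, n_pairs = 5, seed = 205)
  expect_identical(s1$network$edges, s2$network$edges)
  expect_identical(s1$expression, s2$expression)
  expect_identical(s1$mutations, s2$mutations)
  expect_identical(s1$pairs, s2$pairs)
  expect_identical(s1$reporter, s2$reporter)
})

test_that("the oracle agrees with long ensemble simulation on random models", {
  for (seed in c(211, 212)) {
    gn <- generate_network(7, edge_density = 0.25, seed = seed)
    p <- uniform_profile(gn$rules)
    ens <- simulate_ensemble(gn$rules,
      profile = p, steps = 1500, repeats = 400,
      seed = seed + 1000, repeat_means = TRUE
    )
    ex <- exact_occupancy(gn$rules, p)$occupancy
    se <- apply(ens$repeat_means, 1, sd) / sqrt(ncol(ens$repeat_means))
    expect_true(all(abs(rowMeans(ens$repeat_means) - ex) <= 3 * se + 1e-8))
  }
})
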