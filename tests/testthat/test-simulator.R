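test_that("async_step leaves fixed points unchanged and flips one updatable node", {
  rs <- toggle_rules()
  # (1,0) is a fixed point of mutual inhibition
  s <- c(A = 1L, B = 0L)
  expect_identical(async_step(s, rs), s)
  # from (0,0) both nodes want to turn on: exactly one flips
  set.seed(21)
  s2 <- async_step(c(A = 0L, B = 0L), rs)
  expect_identical(sum(s2), 1L)
})

test_that("each updatable node is chosen uniformly", {
  rs <- mutual_activation_rules()
  # at (1,0) both nodes can change (A wants 0, B wants 1)
  set.seed(22)
  picks <- replicate(10000, {
    s <- async_step(c(A = 1L, B = 0L), rs)
    s[["A"]] == 0L # TRUE if A was the updated node
  })
  expect_lt(abs(mean(picks) - 0.5), 0.02)
})

test_that("clamped nodes are never selected even when their rule disagrees", {
  rs <- rule_set(
    list(boolean_rule("A", "B"), boolean_rule("B", "A")),
    clamps = c(A = 0L)
  )
  set.seed(23)
  s <- c(A = 0L, B = 1L) # A's rule says 1, but A is clamped
  for (i in 1:20) s <- async_step(s, rs)
  expect_identical(s[["A"]], 0L)
  expect_identical(s[["B"]], 0L) # B follows clamped A down
})

test_that("entropy profile reproduces closed-form values", {
  # one absorbing state from t = 0: H(t) = 0 exactly
  m <- matrix(1L, nrow = 2, ncol = 10)
  expect_true(all(entropy_profile(m)$H == 0))
  # two states at frequency 1/2 each: H = 1 bit
  tr <- list(
    matrix(c(1L, 0L), nrow = 2, ncol = 4),
    matrix(c(0L, 1L), nrow = 2, ncol = 4)
  )
  expect_equal(entropy_profile(tr)$H, rep(1, 4))
  # frequencies (0.5, 0.25, 0.25): H = 1.5 bits
  m3 <- cbind(c(0L, 0L), c(0L, 0L), c(1L, 0L), c(0L, 1L))
  expect_equal(entropy_profile(m3)$H[4], 1.5)
})

test_that("steady-state detection finds the entropy-slope minimum (earliest tie)", {
  # strictly linear decrease: constant slope, earliest window start wins
  lin <- data.frame(t = seq(0, 1000, by = 10), H = as.numeric(101:1))
  t_lin <- detect_steady_state(lin, window = 100)
  expect_identical(t_lin, as.integer(lin$t[11])) # first centred-window position

  # flat, sharp drop, flat: minimum slope inside the drop (brute-force check)
  H <- c(rep(3, 40), seq(3, 0.2, length.out = 21), rep(0.2, 40))
  prof <- data.frame(t = seq_along(H) * 10 - 10, H = H)
  t_star <- detect_steady_state(prof, window = 100)
  w <- 10L
  cs <- (w + 1):(length(H) - w)
  slope <- (H[cs + w] - H[cs - w]) / (prof$t[cs + w] - prof$t[cs - w])
  expect_identical(t_star, as.integer(prof$t[cs[which.min(slope)]]))
  expect_gt(t_star, 300)
  expect_lt(t_star, 700)

  expect_error(
    detect_steady_state(data.frame(t = 1:3, H = c(1, NaN, 0)), window = 1),
    "non-finite"
  )
})

test_that("trajectories change at most one node per step and absorb at fixed points", {
  gn <- generate_network(6, edge_density = 0.3, seed = 31)
  ens <- simulate_ensemble(gn$rules,
    profile = uniform_profile(gn$rules),
    steps = 150, repeats = 5, seed = 32, return_traj = TRUE,
    entropy_window = 30, entropy_stride = 5
  )
  for (tr in ens$trajectories) {
    flips <- colSums(abs(tr[, -1, drop = FALSE] - tr[, -ncol(tr), drop = FALSE]))
    expect_true(all(flips <= 1))
  }
})

test_that("engine entropy matches the plain-R entropy computation", {
  rs <- toggle_rules()
  ens <- simulate_ensemble(rs,
    profile = uniform_profile(rs),
    steps = 100, repeats = 20, seed = 33, return_traj = TRUE,
    entropy_window = 20, entropy_stride = 5
  )
  ref <- entropy_profile(ens$trajectories, stride = 5)
  expect_equal(ens$entropy$t, ref$t)
  expect_equal(ens$entropy$H, ref$H, tolerance = 1e-12)
})

test_that("identical seeds give bit-identical ensembles, different seeds differ", {
  rs <- toggle_rules()
  a <- simulate_ensemble(rs,
    profile = uniform_profile(rs), steps = 200, repeats = 30,
    seed = 77, return_traj = TRUE, entropy_window = 40, entropy_stride = 5
  )
  b <- simulate_ensemble(rs,
    profile = uniform_profile(rs), steps = 200, repeats = 30,
    seed = 77, return_traj = TRUE, entropy_window = 40, entropy_stride = 5
  )
  expect_identical(a$trajectories, b$trajectories)
  expect_identical(a$steady_activity, b$steady_activity)
  c <- simulate_ensemble(rs,
    profile = uniform_profile(rs), steps = 200, repeats = 30,
    seed = 78, return_traj = TRUE, entropy_window = 40, entropy_stride = 5
  )
  expect_false(identical(a$trajectories, c$trajectories))
})

test_that("the two-node toggle settles near half occupancy from uniform starts", {
  rs <- toggle_rules()
  ens <- simulate_ensemble(rs,
    profile = uniform_profile(rs),
    steps = 500, repeats = 1000, seed = 55,
    entropy_window = 100, entropy_stride = 10
  )
  expect_lt(abs(ens$steady_activity[["A"]] - 0.5), 0.05)
  expect_lt(abs(ens$steady_activity[["B"]] - 0.5), 0.05)
})

test_that("activities stay in [0,1] and clamped nodes sit exactly at their clamp", {
  rs <- rule_set(
    list(boolean_rule("A", "B"), boolean_rule("B", "A"), boolean_rule("C", "A or B")),
    clamps = c(C = 0L)
  )
  ens <- simulate_ensemble(rs,
    profile = uniform_profile(rs), steps = 300, repeats = 50,
    seed = 91, entropy_window = 60, entropy_stride = 5
  )
  expect_true(all(ens$activity >= 0 & ens$activity <= 1))
  expect_true(all(ens$activity["C", ] == 0))
  expect_identical(ens$steady_activity[["C"]], 0)
})

test_that("small-network ensemble activity matches the exact chain occupancy", {
  for (seed in c(101, 102, 103)) {
    gn <- generate_network(6, edge_density = 0.25, seed = seed)
    p <- uniform_profile(gn$rules, 0.5)
    ens <- simulate_ensemble(gn$rules,
      profile = p, steps = 1000, repeats = 300,
      seed = seed + 500, repeat_means = TRUE
    )
    ex <- exact_occupancy(gn$rules, p)$occupancy
    se <- apply(ens$repeat_means, 1, sd) / sqrt(ncol(ens$repeat_means))
    expect_true(all(abs(rowMeans(ens$repeat_means) - ex) <= 3 * se + 1e-8))
  }
})
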