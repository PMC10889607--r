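test_that("dose 0 never clamps and dose 1 always clamps the target", {
  cl <- c(ESR1 = NA_integer_, X = NA_integer_)
  fulv <- drug("FULVESTRANT", "ESR1", "antagonist")
  set.seed(61)
  for (i in 1:50) {
    expect_true(is.na(apply_drug(cl, fulv, 0)[["ESR1"]]))
    expect_identical(apply_drug(cl, fulv, 1)[["ESR1"]], 0L)
  }
  agon <- drug("MEGESTROL", "X", "agonist")
  expect_identical(apply_drug(cl, agon, 1)[["X"]], 1L)
})

test_that("the clamp fraction matches the dose within the binomial 99% CI", {
  cl <- c(ESR1 = NA_integer_)
  fulv <- drug("FULVESTRANT", "ESR1", "antagonist")
  n <- 10000
  set.seed(62)
  for (dose in c(0, 0.25, 0.75, 1)) {
    hits <- sum(replicate(n, !is.na(apply_drug(cl, fulv, dose)[["ESR1"]])))
    ci <- qbinom(c(0.005, 0.995), n, dose)
    expect_gte(hits, ci[1])
    expect_lte(hits, ci[2])
  }
})

test_that("unknown drug targets raise an error naming drug and node", {
  cl <- c(A = NA_integer_)
  bad <- drug("MYSTERY", "GHOST", "antagonist")
  expect_error(apply_drug(cl, bad, 1), "MYSTERY.*GHOST")
})

test_that("mutation clamps beat drug clamps, with a warning", {
  cl <- c(AKT = 0L) # LOF clamp already present
  agon <- drug("TRISENOX", "AKT", "agonist")
  set.seed(63)
  expect_warning(out <- apply_drug(cl, agon, 1), "existing clamp")
  expect_identical(out[["AKT"]], 0L)
})

test_that("multi-target drugs draw per target independently by default", {
  cl <- c(MEK1 = NA_integer_, MEK2 = NA_integer_)
  tram <- drug("TRAMETINIB", c("MEK1", "MEK2"), "antagonist")
  set.seed(64)
  draws <- replicate(4000, {
    out <- apply_drug(cl, tram, 0.5)
    c(!is.na(out[["MEK1"]]), !is.na(out[["MEK2"]]))
  })
  # independence: P(both) ~ 0.25
  both <- mean(draws[1, ] & draws[2, ])
  expect_lt(abs(both - 0.25), 0.03)
  # shared draw: targets always clamped together
  shared <- replicate(500, {
    out <- apply_drug(cl, tram, 0.5, shared_draw = TRUE)
    is.na(out[["MEK1"]]) == is.na(out[["MEK2"]])
  })
  expect_true(all(shared))
})

test_that("the dose grid reproduces unperturbed and fully-inhibited limits", {
  net <- cascade_network()
  rs <- compile_default_rules(net)
  prof_p <- uniform_profile(rs, 1) # everything on: all-ones fixed point
  inhib_a <- drug("ROOT-INH", "A", "antagonist")
  other <- drug("NULL-DRUG", "D", "antagonist")
  grid <- simulate_combination_grid(
    rs, prof_p, inhib_a, other,
    doses = c(0, 0.25, 0.75, 1), steps = 300, repeats = 40,
    phase1_repeats = 40, seed = 71, entropy_window = 60, entropy_stride = 5
  )
  # (0,0) cell: unperturbed all-ones steady state, exactly
  expect_equal(unname(grid$activity[, 1, 1]), rep(1, 4))
  # antagonist at dose 1 clamps its target to 0 along the whole row
  expect_true(all(grid$activity["A", 4, ] == 0))
  # cascade decays once the persistent root is clamped off
  expect_lt(max(grid$activity[, 4, 1]), 0.05)
  # monotherapy activities are the grid edges (never re-simulated)
  expect_identical(monotherapy_activity(grid, 1), grid$activity[, , 1])
  expect_identical(monotherapy_activity(grid, 2), grid$activity[, 1, ])
})

test_that("intermediate doses clamp the expected fraction of repeats", {
  net <- cascade_network()
  rs <- compile_default_rules(net)
  prof_p <- uniform_profile(rs, 1)
  inhib_a <- drug("ROOT-INH", "A", "antagonist")
  null_d <- drug("NULL-DRUG", "D", "antagonist")
  grid <- simulate_combination_grid(
    rs, prof_p, inhib_a, null_d,
    doses = c(0, 0.25, 0.75, 1), steps = 250, repeats = 400,
    phase1_repeats = 20, seed = 72, entropy_window = 50, entropy_stride = 5
  )
  # clamped repeats end with A = 0, unclamped stay 1; activity ~ 1 - dose
  for (i in 2:3) {
    dose <- grid$doses[i]
    se <- sqrt(dose * (1 - dose) / 400)
    expect_lt(abs(grid$activity["A", i, 1] - (1 - dose)), 4 * se + 0.02)
  }
})

test_that("a dose-1 root inhibitor drives the cascade to the clamped-model occupancy", {
  net <- cascade_network()
  rs <- compile_default_rules(net)
  prof_p <- uniform_profile(rs, 1)
  inhib_a <- drug("ROOT-INH", "A", "antagonist")
  null_d <- drug("NULL-DRUG", "D", "antagonist")
  grid <- simulate_combination_grid(
    rs, prof_p, inhib_a, null_d,
    steps = 300, repeats = 40, phase1_repeats = 40, seed = 73,
    entropy_window = 60, entropy_stride = 5
  )
  clamped <- rule_set(rs$rules, clamps = c(A = 0L), nodes = rs$nodes)
  ex <- exact_occupancy(clamped, uniform_profile(rs, 1))$occupancy
  expect_true(all(abs(grid$activity[, 4, 1] - ex[rs$nodes]) < 0.05))
})

test_that("drug tables round-trip and flag agonists", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(
    data.frame(
      drug = c("LAPATINIB", "LAPATINIB", "MEGESTROL"),
      target = c("EGFR", "HER2", "PGR"),
      mode = c("antagonist", "antagonist", "agonist")
    ),
    path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  drugs <- read_drug_table(path)
  expect_named(drugs, c("LAPATINIB", "MEGESTROL"))
  expect_identical(nrow(drugs$LAPATINIB$targets), 2L)
  expect_identical(drugs$MEGESTROL$targets$mode, "agonist")
})
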