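test_that("default rule compilation follows the OR / inhibitor-wins conventions", {
  net <- signaling_network(
    data.frame(
      source = c("A", "B", "A", "B", "C", "E", "F"),
      target = c("C", "C", "D", "D", "D", "G", "G"),
      sign = c("+", "+", "+", "+", "-", "-", "-")
    ),
    nodes = c("A", "B", "C", "D", "E", "F", "G", "H")
  )
  rs <- compile_default_rules(net)

  # C with activators {A,B}: C(t+1) = A or B
  grid <- expand.grid(A = 0:1, B = 0:1, C = 0:1, D = 0:1, E = 0:1, F = 0:1, G = 0:1, H = 0:1)
  for (k in seq_len(nrow(grid))) {
    s <- unlist(grid[k, ])
    expect_identical(eval_rule(rs$rules[["C"]], s), as.integer(s[["A"]] | s[["B"]]))
    # D: (A or B) and not C
    expect_identical(
      eval_rule(rs$rules[["D"]], s),
      as.integer((s[["A"]] | s[["B"]]) && !s[["C"]])
    )
    # G has only inhibitors: not (E or F)
    expect_identical(eval_rule(rs$rules[["G"]], s), as.integer(!(s[["E"]] | s[["F"]])))
    # H regulator-free: identity, can never change
    expect_identical(eval_rule(rs$rules[["H"]], s), as.integer(s[["H"]]))
  }
})

test_that("self-loop ligands appear among their own activators", {
  net <- signaling_network(
    data.frame(source = "X", target = "Y", sign = "-"),
    nodes = c("X", "Y"), self_loops = "X"
  )
  rs <- compile_default_rules(net)
  expect_identical(eval_rule(rs$rules[["X"]], c(X = 1, Y = 1)), 1L)
  expect_identical(eval_rule(rs$rules[["X"]], c(X = 0, Y = 0)), 0L)
})

test_that("inhibitor-wins holds exhaustively for compiled rules", {
  # Any node with >= 1 inhibitor is forced off when any inhibitor is on.
  net <- signaling_network(
    data.frame(
      source = c("A", "B", "C", "E"),
      target = c("D", "D", "D", "D"),
      sign = c("+", "+", "-", "-")
    )
  )
  rs <- compile_default_rules(net)
  grid <- expand.grid(A = 0:1, B = 0:1, C = 0:1, E = 0:1, D = 0:1)
  for (k in seq_len(nrow(grid))) {
    s <- unlist(grid[k, ])
    out <- eval_rule(rs$rules[["D"]], s)
    expect_true(out %in% c(0L, 1L))
    if (s[["C"]] == 1 || s[["E"]] == 1) expect_identical(out, 0L)
  }
})

test_that("network validation rejects bad input", {
  edges <- data.frame(source = "A", target = "B", sign = "+")
  expect_error(
    signaling_network(rbind(edges, edges)),
    "duplicate edge"
  )
  expect_error(
    signaling_network(edges, nodes = c("A", "A", "B")),
    "duplicate node"
  )
  expect_error(
    signaling_network(data.frame(source = "A", target = "B", sign = "maybe")),
    "unrecognised edge sign"
  )
  expect_error(
    signaling_network(edges, nodes = "A"),
    "not declared"
  )
  expect_error(
    boolean_rule("X", "A or", nodes = c("X", "A")),
    "unexpected end"
  )
  expect_error(
    boolean_rule("X", "A or Q", nodes = c("X", "A")),
    "undeclared node.*Q"
  )
})

test_that("rule overrides replace listed expressions only", {
  nodes <- c("MTORC1", "RHEB", "NRG1", "IGF1", "PIM", "KMT2D", "PAX7", "AKT_i")
  rs <- rule_set(
    list(
      boolean_rule("MTORC1", "RHEB", nodes = nodes),
      boolean_rule("KMT2D", "PAX7 and not AKT_i", nodes = nodes)
    ),
    nodes = nodes
  )
  ov <- data.frame(
    cell_line = c("ERpos", "ERpos"),
    node = c("MTORC1", "KMT2D"),
    expression = c("RHEB or NRG1 or IGF1 or PIM", "PAX7 or not AKT_i")
  )
  rs2 <- apply_overrides(rs, ov, "ERpos")

  s <- c(
    MTORC1 = 0, RHEB = 0, NRG1 = 1, IGF1 = 0, PIM = 0,
    KMT2D = 0, PAX7 = 0, AKT_i = 0
  )
  # NRG1 alone now sustains MTORC1
  expect_identical(eval_rule(rs$rules[["MTORC1"]], s), 0L)
  expect_identical(eval_rule(rs2$rules[["MTORC1"]], s), 1L)
  # AND -> OR: PAX7=0, AKT_i=0 flips KMT2D from 0 to 1
  expect_identical(eval_rule(rs$rules[["KMT2D"]], s), 0L)
  expect_identical(eval_rule(rs2$rules[["KMT2D"]], s), 1L)
  # untouched rules identical; other cell lines untouched
  expect_identical(apply_overrides(rs, ov, "TNBC"), rs)
  expect_identical(
    apply_overrides(rs, ov[0, ], "ERpos"),
    rs
  )
})

test_that("mutation clamps encode GOF as 1 and LOF as 0 and reject conflicts", {
  net <- signaling_network(
    data.frame(source = c("PIK3CA", "TP53"), target = c("X", "X"), sign = c("+", "-"))
  )
  rs <- compile_default_rules(net)
  mut <- data.frame(
    cell_line = c("MCF7", "MCF7", "OTHER"),
    node = c("PIK3CA", "TP53", "PIK3CA"),
    effect = c("GOF", "LOF", "LOF")
  )
  rs2 <- apply_mutations(rs, mut, "MCF7")
  expect_identical(rs2$clamps[["PIK3CA"]], 1L)
  expect_identical(rs2$clamps[["TP53"]], 0L)
  expect_identical(apply_mutations(rs, mut[0, ], "MCF7"), rs)

  bad <- data.frame(
    cell_line = "MCF7", node = c("TP53", "TP53"), effect = c("GOF", "LOF")
  )
  expect_error(apply_mutations(rs, bad, "MCF7"), "conflicting")
  expect_error(
    apply_mutations(rs, data.frame(cell_line = "MCF7", node = "NOPE", effect = "GOF"), "MCF7"),
    "absent from the model"
  )
})

test_that("overrides and mutations are idempotent and commute on disjoint nodes", {
  nodes <- c("A", "B", "C", "D")
  rs <- rule_set(
    list(
      boolean_rule("A", "B", nodes = nodes),
      boolean_rule("B", "A", nodes = nodes),
      boolean_rule("C", "A and B", nodes = nodes),
      boolean_rule("D", "C", nodes = nodes)
    ),
    nodes = nodes
  )
  mut <- data.frame(cell_line = "X", node = "A", effect = "GOF")
  ov <- data.frame(cell_line = "X", node = "C", expression = "A or B")

  m1 <- apply_mutations(rs, mut, "X")
  expect_identical(apply_mutations(m1, mut, "X"), m1)
  o1 <- apply_overrides(rs, ov, "X")
  expect_identical(apply_overrides(o1, ov, "X"), o1)
  expect_identical(
    apply_overrides(apply_mutations(rs, mut, "X"), ov, "X"),
    apply_mutations(apply_overrides(rs, ov, "X"), mut, "X")
  )
})

test_that("overriding a clamped node warns and the clamp wins", {
  nodes <- c("A", "B")
  rs <- rule_set(
    list(boolean_rule("A", "B", nodes = nodes), boolean_rule("B", "A", nodes = nodes)),
    nodes = nodes
  )
  rs <- apply_mutations(rs, data.frame(cell_line = "X", node = "A", effect = "LOF"), "X")
  expect_warning(
    rs2 <- apply_overrides(
      rs, data.frame(cell_line = "X", node = "A", expression = "B or A"), "X"
    ),
    "clamp wins"
  )
  expect_identical(rs2$clamps[["A"]], 0L)
})

test_that("edge lists round-trip through both the TSV and SIF dialects", {
  net <- cascade_network()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write.table(net$edges, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_edge_list(tsv)
  expect_setequal(
    paste(back$edges$source, back$edges$target, back$edges$sign),
    paste(net$edges$source, net$edges$target, net$edges$sign)
  )

  sif <- withr::local_tempfile(fileext = ".sif")
  writeLines(
    c("A\tactivates\tB", "B\tactivates\tC", "C\tinhibits\tD"),
    sif
  )
  net2 <- read_edge_list(sif)
  expect_identical(
    net2$edges$sign,
    c("activating", "activating", "inhibitory")
  )
})

test_that("rule tables round-trip through delimited text", {
  rs <- toggle_rules()
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(
    data.frame(node = c("A", "B"), expression = c("not B", "not A")),
    path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  back <- read_rule_table(path)
  expect_identical(back$rules[["A"]]$text, rs$rules[["A"]]$text)
  expect_identical(back$rules[["B"]]$text, rs$rules[["B"]]$text)
})
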