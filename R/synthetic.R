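# Synthetic scenarios with known ground truth, and the exact asynchronous
# Markov-chain oracle for small networks.

#' Generate a random signed signalling network with compiled rules
#'
#' Draws a weakly connected signed digraph (a random chain guarantees
#' connectivity, extra random edges bring it to the requested density),
#' compiles the default Boolean rules, and rewrites a configurable fraction
#' of multi-activator nodes to AND logic to emulate curated rule
#' refinements.
#'
#' @param n_nodes Number of nodes (>= 2).
#' @param edge_density Fraction of the `n*(n-1)` ordered pairs carrying an
#'   edge, in (0, 1].
#' @param sign_ratio Probability that an edge is activating (default 0.7).
#' @param and_fraction Fraction of multi-activator nodes whose activators
#'   are joined with AND instead of OR (default 0.3).
#' @param seed Integer seed; identical (arguments, seed) regenerate the
#'   identical network.
#' @return List with elements `network` ([signaling_network()]) and
#'   `rules` ([rule_set()]).
#' @export
generate_network <- function(n_nodes, edge_density = 0.15, sign_ratio = 0.7,
                             and_fraction = 0.3, seed = NULL) {
  stopifnot(n_nodes >= 2L)
  if (edge_density <= 0 || edge_density > 1) stop("edge_density must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  perm <- sample(nodes)
  chain <- data.frame(
    source = perm[-n_nodes], target = perm[-1L],
    stringsAsFactors = FALSE
  )
  m_target <- max(n_nodes - 1L, round(edge_density * n_nodes * (n_nodes - 1L)))
  all_pairs <- expand.grid(source = nodes, target = nodes, stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$source != all_pairs$target, ]
  key <- paste(all_pairs$source, all_pairs$target)
  used <- paste(chain$source, chain$target)
  remaining <- all_pairs[!key %in% used, , drop = FALSE]
  n_extra <- min(m_target - nrow(chain), nrow(remaining))
  extra <- if (n_extra > 0) {
    remaining[sample.int(nrow(remaining), n_extra), , drop = FALSE]
  } else {
    remaining[0, , drop = FALSE]
  }
  edges <- rbind(chain, extra)
  edges$sign <- ifelse(runif(nrow(edges)) < sign_ratio, "activating", "inhibitory")
  network <- signaling_network(edges, nodes = nodes)

  rules <- compile_default_rules(network)
  e <- network$edges
  multi <- Filter(
    function(nd) sum(e$target == nd & e$sign == "activating") >= 2L,
    nodes
  )
  rewrite <- multi[runif(length(multi)) < and_fraction]
  if (length(rewrite)) {
    new_rules <- rules$rules
    for (nd in rewrite) {
      act <- e$source[e$target == nd & e$sign == "activating"]
      inh <- e$source[e$target == nd & e$sign == "inhibitory"]
      expr <- if (length(inh)) {
        sprintf(
          "(%s) and not (%s)",
          paste(act, collapse = " and "), paste(inh, collapse = " or ")
        )
      } else {
        paste(act, collapse = " and ")
      }
      new_rules[[nd]] <- boolean_rule(nd, expr, nodes = nodes)
    }
    rules <- rule_set(new_rules, nodes = nodes)
  }
  list(network = network, rules = rules)
}

#' Exact long-run node occupancy of the asynchronous chain
#'
#' Builds the full uniform-asynchronous transition matrix over the 2^n
#' state space (each updatable node flips with equal probability; fixed
#' points self-loop), then power-iterates the initial distribution through
#' the half-damped operator `(I + P)/2` to its long-run limit.  Damping
#' removes periodicity while preserving stationary and absorbing structure,
#' so the limit equals the time-averaged occupancy the ensemble simulator
#' estimates.  Clamped nodes are held at their clamp.
#'
#' @param rules A [rule_set()] with at most 12 nodes.
#' @param init_prob Named per-node on-probabilities defining a product
#'   initial distribution (clamps override), or a full distribution vector
#'   of length 2^n over states (bit i of the state index = node i).
#' @param tol Convergence tolerance on the max absolute change (default
#'   1e-10).
#' @param max_iter Iteration cap.
#' @return List: `occupancy` (named per-node), `distribution` (length 2^n),
#'   `iterations`.
#' @export
exact_occupancy <- function(rules, init_prob, tol = 1e-10, max_iter = 200000L) {
  stopifnot(inherits(rules, "rule_set"))
  nodes <- rules$nodes
  n <- length(nodes)
  if (n > 12L) {
    stop("exact occupancy limited to <= 12 nodes; use simulate_ensemble() instead")
  }
  N <- 2L^n
  clamp <- rep(NA_integer_, n)
  clamp[match(names(rules$clamps), nodes)] <- rules$clamps
  bits <- matrix(0L, nrow = N, ncol = n)
  for (i in seq_len(n)) {
    bits[, i] <- bitwAnd(seq_len(N) - 1L, 2L^(i - 1L)) > 0L
  }

  # Rule outputs for every state.
  from <- integer(0)
  to <- integer(0)
  pr <- numeric(0)
  for (st in seq_len(N)) {
    s <- stats::setNames(bits[st, ], nodes)
    diffs <- integer(0)
    for (i in seq_len(n)) {
      if (!is.na(clamp[i])) next
      if (eval_rule(rules$rules[[nodes[i]]], s) != s[[i]]) diffs <- c(diffs, i)
    }
    if (length(diffs) == 0L) {
      from <- c(from, st)
      to <- c(to, st)
      pr <- c(pr, 1)
    } else {
      nxt <- bitwXor(st - 1L, 2L^(diffs - 1L)) + 1L
      from <- c(from, rep(st, length(diffs)))
      to <- c(to, nxt)
      pr <- c(pr, rep(1 / length(diffs), length(diffs)))
    }
  }
  P <- Matrix::sparseMatrix(i = from, j = to, x = pr, dims = c(N, N))

  if (length(init_prob) == N && is.null(names(init_prob))) {
    mu <- as.numeric(init_prob)
    if (abs(sum(mu) - 1) > 1e-8 || any(mu < 0)) {
      stop("initial distribution must be a probability vector over 2^n states")
    }
  } else {
    p <- init_prob[nodes]
    if (anyNA(p)) stop("init_prob must cover every node")
    p[!is.na(clamp)] <- clamp[!is.na(clamp)]
    mu <- rep(1, N)
    for (i in seq_len(n)) {
      mu <- mu * ifelse(bits[, i] == 1L, p[[i]], 1 - p[[i]])
    }
  }

  it <- 0L
  repeat {
    mu_new <- 0.5 * (mu + as.numeric(mu %*% P))
    delta <- max(abs(mu_new - mu))
    mu <- mu_new
    it <- it + 1L
    if (delta < tol || it >= max_iter) break
  }
  if (it >= max_iter) warning("power iteration hit max_iter before tolerance")
  occupancy <- stats::setNames(as.numeric(mu %*% bits), nodes)
  list(occupancy = occupancy, distribution = mu, iterations = it)
}

.drug_clamps_full <- function(rules, drugs) {
  # Deterministic (dose 1) clamps of one or more drugs; earlier clamps and
  # mutation clamps win on conflict.
  clamps <- rules$clamps
  for (d in drugs) {
    for (i in seq_len(nrow(d$targets))) {
      nd <- d$targets$node[i]
      val <- if (d$targets$mode[i] == "agonist") 1L else 0L
      if (!nd %in% names(clamps)) clamps[[nd]] <- val
    }
  }
  rule_set(rules$rules, clamps = clamps, nodes = rules$nodes)
}

#' Ground-truth observed synergy scores from a hidden model
#'
#' Emulates an experimental synergy screen: each drug's full-dose effect is
#' computed on the hidden model with the exact oracle, the effect `y` of a
#' treatment is `1 -` the reporter node's occupancy (suppression of the
#' proliferation readout), and the observed score of a pair is the HSA
#' statistic `y_C - max(y_A, y_B)` plus optional Gaussian noise.
#'
#' @param rules Hidden "true" [rule_set()] (<= 12 nodes).
#' @param drugs Named list of [drug()] objects.
#' @param pairs Data frame with columns `drug1`, `drug2`.
#' @param reporter Reporter node whose suppression defines the drug effect.
#' @param init_prob Named per-node initial on-probabilities.
#' @param noise_sd Standard deviation of additive observation noise
#'   (default 0: bit-reproducible scores).
#' @param seed Integer seed (used only for the noise).
#' @return The `pairs` data frame with an `observed` column appended.
#' @export
generate_ground_truth_synergy <- function(rules, drugs, pairs, reporter,
                                          init_prob, noise_sd = 0,
                                          seed = NULL) {
  stopifnot(reporter %in% rules$nodes)
  if (!is.null(seed)) set.seed(seed)
  effect <- function(drug_list) {
    clamped <- .drug_clamps_full(rules, drug_list)
    occ <- exact_occupancy(clamped, init_prob)$occupancy
    1 - occ[[reporter]]
  }
  eff_single <- vapply(drugs, function(d) effect(list(d)), numeric(1))
  obs <- vapply(seq_len(nrow(pairs)), function(k) {
    d1 <- pairs$drug1[k]
    d2 <- pairs$drug2[k]
    y_c <- effect(list(drugs[[d1]], drugs[[d2]]))
    observed_hsa(eff_single[[d1]], eff_single[[d2]], y_c)
  }, numeric(1))
  if (noise_sd > 0) obs <- obs + rnorm(length(obs), sd = noise_sd)
  pairs$observed <- obs
  pairs
}

#' Generate a complete synthetic study scenario
#'
#' Produces every input the pipeline consumes, with ground truth computed
#' from a hidden "true" model rather than hand-assigned: a signed network
#' and its (partly AND-rewritten) rules; a non-negative expression matrix
#' whose min-max-scaled values give initial-state probabilities; a sparse
#' GOF/LOF mutation table; a drug set hitting 1-2 targets each; and a
#' drug-pair list whose observed HSA scores come from the hidden model's
#' reporter readout per cell line.
#'
#' @param n_nodes Hidden model size (<= 12 so the exact oracle applies).
#' @param n_cell_lines,n_drugs,n_pairs Scenario dimensions.
#' @param edge_density,sign_ratio,and_fraction Passed to
#'   [generate_network()].
#' @param mutation_rate Per (cell line, node) probability of a clamping
#'   mutation (default 0.08).
#' @param noise_sd Observation noise on the ground-truth scores.
#' @param seed Integer seed; the scenario regenerates bit-identically.
#' @return Object of class `bn_scenario`: network, rules, expression,
#'   mutations, drugs, pairs (with per-cell-line observed scores),
#'   reporter, roles, and the generating config.
#' @export
generate_scenario <- function(n_nodes = 10L, n_cell_lines = 3L, n_drugs = 8L,
                              n_pairs = 15L, edge_density = 0.18,
                              sign_ratio = 0.7, and_fraction = 0.25,
                              mutation_rate = 0.08, noise_sd = 0.05,
                              seed = 1L) {
  stopifnot(n_nodes >= 4L, n_nodes <= 12L, n_drugs >= 2L)
  net <- generate_network(n_nodes, edge_density, sign_ratio, and_fraction,
    seed = derive_seed(seed, "network")
  )
  nodes <- net$rules$nodes
  cell_lines <- sprintf("CL%02d", seq_len(n_cell_lines))

  set.seed(derive_seed(seed, "expression"))
  expression <- matrix(
    NA_real_,
    nrow = length(nodes), ncol = n_cell_lines,
    dimnames = list(nodes, cell_lines)
  )
  for (g in seq_along(nodes)) {
    expression[g, ] <- runif(n_cell_lines, 0, runif(1, 1, 100))
  }

  # Reporter: the regulated node with the deepest upstream pathway (most
  # ancestors), so drug perturbations can actually propagate to it; never
  # mutated, never targeted.
  e <- net$network$edges
  ancestors_of <- function(nd) {
    seen <- character(0)
    frontier <- nd
    while (length(frontier)) {
      up <- unique(e$source[e$target %in% frontier])
      frontier <- setdiff(up, c(seen, nd))
      seen <- union(seen, frontier)
    }
    seen
  }
  regulated <- nodes[nodes %in% e$target]
  anc <- lapply(stats::setNames(regulated, regulated), ancestors_of)
  reporter <- regulated[[which.max(vapply(anc, length, integer(1)))]]

  set.seed(derive_seed(seed, "mutations"))
  mut <- expand.grid(
    cell_line = cell_lines, node = setdiff(nodes, reporter),
    stringsAsFactors = FALSE
  )
  keep <- runif(nrow(mut)) < mutation_rate
  mutations <- data.frame(
    cell_line = mut$cell_line[keep], node = mut$node[keep],
    effect = ifelse(runif(sum(keep)) < 0.5, "GOF", "LOF"),
    stringsAsFactors = FALSE
  )

  # Drugs hit the reporter's upstream pathway, as a targeted-therapy panel
  # would; fall back to the whole network if the pathway is tiny.
  set.seed(derive_seed(seed, "drugs"))
  targetable <- setdiff(anc[[reporter]], reporter)
  if (length(targetable) < 3L) targetable <- setdiff(nodes, reporter)
  drugs <- lapply(seq_len(n_drugs), function(i) {
    k <- sample(1:2, 1L)
    drug(
      sprintf("DRUG%02d", i),
      sample(targetable, k),
      ifelse(runif(k) < 0.8, "antagonist", "agonist")
    )
  })
  names(drugs) <- vapply(drugs, function(d) d$name, "")

  all_pairs <- t(combn(names(drugs), 2L))
  take <- sample.int(nrow(all_pairs), min(n_pairs, nrow(all_pairs)))
  pair_df <- data.frame(
    drug1 = all_pairs[take, 1L], drug2 = all_pairs[take, 2L],
    stringsAsFactors = FALSE
  )

  # Roles: sign of the reporter on proliferation; remaining nodes split.
  set.seed(derive_seed(seed, "roles"))
  roles <- stats::setNames(
    ifelse(runif(length(nodes)) < 0.7, "oncoprotein", "tumor-suppressor"),
    nodes
  )
  roles[[reporter]] <- "oncoprotein"

  scaled <- suppressWarnings(min_max_scale(expression))
  pairs_by_line <- do.call(rbind, lapply(cell_lines, function(cl) {
    cl_rules <- apply_mutations(net$rules, mutations, cl)
    profile <- cell_line_profile(cl_rules, scaled, cl)
    out <- generate_ground_truth_synergy(
      cl_rules, drugs, pair_df, reporter, profile$init_prob,
      noise_sd = noise_sd, seed = derive_seed(seed, paste0("noise-", cl))
    )
    out$cell_line <- cl
    out
  }))

  structure(
    list(
      network = net$network, rules = net$rules, expression = expression,
      mutations = mutations, drugs = drugs,
      pairs = pairs_by_line[, c("drug1", "drug2", "cell_line", "observed")],
      reporter = reporter, roles = roles, cell_lines = cell_lines,
      config = list(
        n_nodes = n_nodes, n_cell_lines = n_cell_lines, n_drugs = n_drugs,
        n_pairs = n_pairs, edge_density = edge_density,
        sign_ratio = sign_ratio, and_fraction = and_fraction,
        mutation_rate = mutation_rate, noise_sd = noise_sd, seed = seed
      )
    ),
    class = "bn_scenario"
  )
}

#' @export
print.bn_scenario <- function(x, ...) {
  cat(
    "Synthetic scenario: ", length(x$rules$nodes), " nodes, ",
    length(x$cell_lines), " cell lines, ", length(x$drugs), " drugs, ",
    nrow(x$pairs), " (pair, cell line) observations; reporter ", x$reporter,
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Planted-signal consensus-PSS scenario for selection benchmarks
#'
#' Builds a candidate x drug-pair consensus PSS matrix in which the
#' observed synergy scores are, up to Gaussian noise, the sum of the
#' mandatory rows and a small set of informative candidate rows.  The
#' informative set is recorded so selection methods can be scored on
#' recovering it.
#'
#' @param n_candidates Optional candidate proteins (default 10).
#' @param n_informative Planted informative candidates (default 2).
#' @param n_pairs Drug pairs (default 40).
#' @param noise_sd Observation noise SD (default 0.1).
#' @param mandatory Always-included proteins (default E2F1, CASP3).
#' @param seed Integer seed.
#' @return List: `pss_matrix`, `observed`, `informative`, `candidates`,
#'   `mandatory`.
#' @export
planted_pss_scenario <- function(n_candidates = 10L, n_informative = 2L,
                                 n_pairs = 40L, noise_sd = 0.1,
                                 mandatory = c("E2F1", "CASP3"), seed = 1L) {
  stopifnot(n_informative <= n_candidates)
  set.seed(seed)
  candidates <- sprintf("P%02d", seq_len(n_candidates))
  rows <- c(mandatory, candidates)
  m <- matrix(
    runif(length(rows) * n_pairs, -0.5, 0.5),
    nrow = length(rows),
    dimnames = list(rows, sprintf("pair%03d", seq_len(n_pairs)))
  )
  informative <- candidates[seq_len(n_informative)]
  observed <- colSums(m[c(mandatory, informative), , drop = FALSE]) +
    rnorm(n_pairs, sd = noise_sd)
  list(
    pss_matrix = m, observed = observed, informative = informative,
    candidates = candidates, mandatory = mandatory
  )
}
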