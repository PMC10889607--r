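# Signed signalling network and its compilation into default Boolean rules.

.normalize_sign <- function(sign) {
  s <- tolower(trimws(as.character(sign)))
  out <- rep(NA_character_, length(s))
  out[s %in% c("+", "1", "activates", "activating", "activation", "a")] <- "activating"
  out[s %in% c("-", "−", "-1", "inhibits", "inhibitory", "inhibition", "i")] <- "inhibitory"
  if (anyNA(out)) {
    stop("unrecognised edge sign(s): ", paste(unique(s[is.na(out)]), collapse = ", "))
  }
  out
}

#' Construct a signed signalling network
#'
#' Nodes are merged protein entities (complexes conventionally end in `_c`,
#' isoform groups in `_i`); edges carry an activating or inhibitory sign.
#' Self-loops mark ligands assumed to be produced in an autocrine manner, so
#' their activity persists once on.
#'
#' @param edges Data frame with columns `source`, `target`, `sign`
#'   (`"activating"`/`"inhibitory"`, also `+`/`-` accepted).
#' @param nodes Optional character vector of declared nodes; defaults to all
#'   edge endpoints plus `self_loops`.
#' @param self_loops Character vector of auto-activating (ligand) nodes.
#' @return Object of class `signaling_network`.
#' @examples
#' net <- signaling_network(
#'   data.frame(
#'     source = c("A", "B", "C"), target = c("C", "C", "D"),
#'     sign = c("+", "+", "-")
#'   )
#' )
#' compile_default_rules(net)
#' @export
signaling_network <- function(edges, nodes = NULL, self_loops = character()) {
  stopifnot(is.data.frame(edges))
  need <- c("source", "target", "sign")
  if (!all(need %in% names(edges))) {
    stop("edges must have columns: ", paste(need, collapse = ", "))
  }
  edges <- data.frame(
    source = as.character(edges$source),
    target = as.character(edges$target),
    sign = .normalize_sign(edges$sign),
    stringsAsFactors = FALSE
  )
  if (is.null(nodes)) {
    nodes <- unique(c(edges$source, edges$target, self_loops))
  } else {
    nodes <- as.character(nodes)
    if (anyDuplicated(nodes)) {
      stop("duplicate node identifier(s): ", paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
    }
    unknown <- setdiff(unique(c(edges$source, edges$target, self_loops)), nodes)
    if (length(unknown)) {
      stop("edge endpoint(s) not declared as nodes: ", paste(unknown, collapse = ", "))
    }
  }
  key <- paste(edges$source, edges$target, edges$sign, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- edges[duplicated(key), , drop = FALSE]
    stop(
      "duplicate edge(s): ",
      paste(paste0(dup$source, "->", dup$target, " (", dup$sign, ")"), collapse = ", ")
    )
  }
  # Explicit self-edges in the edge list are treated as auto-activation.
  auto <- edges$source == edges$target & edges$sign == "activating"
  self_loops <- unique(c(as.character(self_loops), edges$source[auto]))
  edges <- edges[!auto, , drop = FALSE]
  structure(
    list(nodes = nodes, edges = edges, self_loops = self_loops),
    class = "signaling_network"
  )
}

#' @export
print.signaling_network <- function(x, ...) {
  cat(
    "Signalling network:", length(x$nodes), "nodes,", nrow(x$edges), "edges,",
    length(x$self_loops), "autocrine self-loop(s)\n"
  )
  invisible(x)
}

#' Read a signed edge list from delimited text
#'
#' Accepts either a headered TSV with columns `source`, `target`, `sign`
#' (`+`/`-`), or the SIF dialect `source<TAB>relation<TAB>target` with
#' relation in `activates`/`inhibits` (no header).
#'
#' @param path File path.
#' @return A `signaling_network`.
#' @export
read_edge_list <- function(path) {
  first <- readLines(path, n = 1L)
  fields <- tolower(strsplit(first, "\t", fixed = TRUE)[[1]])
  if (all(c("source", "target", "sign") %in% fields)) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    return(signaling_network(df))
  }
  df <- read.delim(path,
    header = FALSE, stringsAsFactors = FALSE,
    col.names = c("source", "relation", "target")
  )
  signaling_network(data.frame(
    source = df$source, target = df$target, sign = df$relation,
    stringsAsFactors = FALSE
  ))
}

#' A set of Boolean update rules plus mutation clamps
#'
#' Every declared node carries exactly one update rule; nodes listed in
#' `clamps` are additionally fixed to 0/1 and never update (the clamp takes
#' precedence over the rule).
#'
#' @param rules Named list of [boolean_rule()] objects (one per node).
#' @param clamps Named integer vector of 0/1 clamp values.
#' @param nodes Optional declared node set; defaults to rule targets plus
#'   all referenced inputs and clamped nodes.
#' @return Object of class `rule_set`.
#' @export
rule_set <- function(rules, clamps = integer(), nodes = NULL) {
  stopifnot(is.list(rules))
  targets <- vapply(rules, function(r) r$target, "")
  names(rules) <- targets
  if (anyDuplicated(targets)) {
    stop("multiple rules for node(s): ", paste(unique(targets[duplicated(targets)]), collapse = ", "))
  }
  clamps <- .validate_clamps(clamps)
  inputs <- unique(unlist(lapply(rules, function(r) r$inputs)))
  if (is.null(nodes)) {
    nodes <- unique(c(targets, inputs, names(clamps)))
  } else {
    unknown <- setdiff(unique(c(targets, inputs, names(clamps))), nodes)
    if (length(unknown)) stop("undeclared node(s): ", paste(unknown, collapse = ", "))
  }
  # Referenced inputs without a rule of their own hold their state.
  missing <- setdiff(nodes, c(targets, names(clamps)))
  for (m in missing) rules[[m]] <- boolean_rule(m, m)
  structure(
    list(nodes = nodes, rules = rules[nodes[nodes %in% names(rules)]], clamps = clamps),
    class = "rule_set"
  )
}

.validate_clamps <- function(clamps) {
  if (length(clamps) == 0L) return(stats::setNames(integer(0), character(0)))
  if (is.null(names(clamps)) || any(!nzchar(names(clamps)))) stop("clamps must be named")
  clamps <- vapply(clamps, as.integer, integer(1))
  if (!all(clamps %in% c(0L, 1L))) stop("clamp values must be 0 or 1")
  clamps
}

#' @export
print.rule_set <- function(x, n = 10L, ...) {
  cat("Boolean rule set:", length(x$nodes), "nodes,", length(x$clamps), "clamp(s)\n")
  shown <- utils::head(x$nodes, n)
  for (nd in shown) {
    if (nd %in% names(x$clamps)) {
      cat("  ", nd, " = ", x$clamps[[nd]], " (clamped)\n", sep = "")
    } else {
      cat("  ", nd, "(t+1) = ", x$rules[[nd]]$text, "\n", sep = "")
    }
  }
  if (length(x$nodes) > n) cat("  ... and", length(x$nodes) - n, "more\n")
  invisible(x)
}

#' Compile default Boolean rules from network topology
#'
#' Applies the default logic conventions: a node with several activators
#' turns on when any is on (OR); an inhibitory regulator wins over all
#' activators, giving `(OR of activators) and not (OR of inhibitors)`;
#' inhibitor-only nodes get `not (OR of inhibitors)`; autocrine self-loop
#' nodes include themselves among their activators; regulator-free nodes
#' hold their current value.
#'
#' @param network A [signaling_network()].
#' @return A [rule_set()] with one rule per node and no clamps.
#' @export
compile_default_rules <- function(network) {
  stopifnot(inherits(network, "signaling_network"))
  e <- network$edges
  rules <- lapply(network$nodes, function(nd) {
    act <- e$source[e$target == nd & e$sign == "activating"]
    inh <- e$source[e$target == nd & e$sign == "inhibitory"]
    if (nd %in% network$self_loops) act <- unique(c(act, nd))
    expr <- if (length(act) && length(inh)) {
      sprintf(
        "(%s) and not (%s)",
        paste(act, collapse = " or "), paste(inh, collapse = " or ")
      )
    } else if (length(act)) {
      paste(act, collapse = " or ")
    } else if (length(inh)) {
      sprintf("not (%s)", paste(inh, collapse = " or "))
    } else {
      nd # identity: regulator-free nodes hold their state
    }
    boolean_rule(nd, expr, nodes = network$nodes)
  })
  rule_set(rules, nodes = network$nodes)
}

#' Clamp mutated nodes to fixed Boolean values
#'
#' Gain-of-function mutations clamp the node to 1, loss-of-function to 0;
#' clamped nodes never change during simulation.
#'
#' @param rules A [rule_set()].
#' @param mutations Data frame with columns `cell_line`, `node`, `effect`
#'   (`"GOF"`/`"LOF"`, long forms accepted).
#' @param cell_line Cell line whose rows are applied.
#' @return A new `rule_set` with the clamps added.
#' @export
apply_mutations <- function(rules, mutations, cell_line) {
  stopifnot(inherits(rules, "rule_set"), is.data.frame(mutations))
  need <- c("cell_line", "node", "effect")
  if (!all(need %in% names(mutations))) {
    stop("mutation table must have columns: ", paste(need, collapse = ", "))
  }
  rows <- mutations[mutations$cell_line == cell_line, , drop = FALSE]
  if (nrow(rows) == 0L) return(rules)
  eff <- toupper(trimws(as.character(rows$effect)))
  eff[eff %in% c("GAIN-OF-FUNCTION", "GAIN_OF_FUNCTION", "GAIN")] <- "GOF"
  eff[eff %in% c("LOSS-OF-FUNCTION", "LOSS_OF_FUNCTION", "LOSS")] <- "LOF"
  if (!all(eff %in% c("GOF", "LOF"))) {
    stop("unrecognised mutation effect(s): ", paste(unique(eff[!eff %in% c("GOF", "LOF")]), collapse = ", "))
  }
  unknown <- setdiff(unique(rows$node), rules$nodes)
  if (length(unknown)) {
    stop("mutation on node(s) absent from the model: ", paste(unknown, collapse = ", "))
  }
  conflict <- tapply(eff, rows$node, function(x) length(unique(x)) > 1L)
  if (any(conflict)) {
    stop(
      "conflicting GOF and LOF annotations for '", cell_line, "' node(s): ",
      paste(names(conflict)[conflict], collapse = ", ")
    )
  }
  clamps <- rules$clamps
  val <- ifelse(eff == "GOF", 1L, 0L)
  for (i in seq_len(nrow(rows))) clamps[[rows$node[i]]] <- val[i]
  rule_set(rules$rules, clamps = clamps, nodes = rules$nodes)
}

#' Replace Boolean rules with cell-line-specific overrides
#'
#' Replaces the update expression of the listed nodes only; rules for nodes
#' under a mutation clamp are left alone (the clamp wins, with a warning).
#'
#' @param rules A [rule_set()].
#' @param overrides Data frame with columns `cell_line`, `node`,
#'   `expression` (infix rule text).
#' @param cell_line Cell line whose rows are applied.
#' @return A new `rule_set`.
#' @export
apply_overrides <- function(rules, overrides, cell_line) {
  stopifnot(inherits(rules, "rule_set"), is.data.frame(overrides))
  need <- c("cell_line", "node", "expression")
  if (!all(need %in% names(overrides))) {
    stop("override table must have columns: ", paste(need, collapse = ", "))
  }
  rows <- overrides[overrides$cell_line == cell_line, , drop = FALSE]
  if (nrow(rows) == 0L) return(rules)
  new_rules <- rules$rules
  for (i in seq_len(nrow(rows))) {
    nd <- rows$node[i]
    if (!nd %in% rules$nodes) stop("override for node absent from the model: ", nd)
    if (nd %in% names(rules$clamps)) {
      warning("node '", nd, "' is clamped by a mutation; override ignored (clamp wins)")
      next
    }
    new_rules[[nd]] <- boolean_rule(nd, rows$expression[i], nodes = rules$nodes)
  }
  rule_set(new_rules, clamps = rules$clamps, nodes = rules$nodes)
}

#' Build a rule set from an explicit node/expression table
#'
#' @param table Data frame with columns `node`, `expression`.
#' @param nodes Optional declared node set.
#' @return A [rule_set()].
#' @export
rule_set_from_table <- function(table, nodes = NULL) {
  stopifnot(is.data.frame(table))
  if (!all(c("node", "expression") %in% names(table))) {
    stop("rule table must have columns: node, expression")
  }
  rules <- lapply(seq_len(nrow(table)), function(i) {
    boolean_rule(as.character(table$node[i]), as.character(table$expression[i]), nodes = nodes)
  })
  rule_set(rules, nodes = nodes)
}

#' Read a rule table (node, expression) from delimited text
#' @param path File path.
#' @param nodes Optional declared node set.
#' @return A [rule_set()].
#' @export
read_rule_table <- function(path, nodes = NULL) {
  rule_set_from_table(read.delim(path, stringsAsFactors = FALSE), nodes = nodes)
}

#' Read a mutation table (cell_line, node, effect) from delimited text
#' @param path File path.
#' @return Data frame.
#' @export
read_mutation_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell_line", "node", "effect")
  if (!all(need %in% names(df))) {
    stop("mutation table must have columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Read a rule-override table (cell_line, node, expression) from delimited text
#' @param path File path.
#' @return Data frame.
#' @export
read_override_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell_line", "node", "expression")
  if (!all(need %in% names(df))) {
    stop("override table must have columns: ", paste(need, collapse = ", "))
  }
  df
}

# Internal: postfix codes for every node, clamp vector (-1 free / 0 / 1).
compile_ruleset_codes <- function(rules) {
  idx <- stats::setNames(seq_along(rules$nodes), rules$nodes)
  codes <- lapply(rules$nodes, function(nd) {
    if (nd %in% names(rules$clamps)) {
      as.integer(idx[[nd]]) # irrelevant under clamp; identity keeps it inert
    } else {
      compile_rule_code(rules$rules[[nd]]$ast, idx)
    }
  })
  clamp <- rep(-1L, length(rules$nodes))
  clamp[match(names(rules$clamps), rules$nodes)] <- rules$clamps
  list(codes = codes, clamp = clamp, index = idx)
}
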