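# Protein synergy scores (PSS) and HSA synergy scores.

#' Protein synergy score from monotherapy and combination activities
#'
#' For an oncoprotein with steady-state activities `X1`, `X2` under each
#' monotherapy and `X12` under the combination,
#' `PSS = min(X1, X2) - X12`: the score is positive when the combination
#' suppresses the oncoprotein below the better single agent.  For a tumor
#' suppressor, `PSS = Y12 - max(Y1, Y2)`: positive when the combination
#' raises it above the better single agent.  Activities in \[0,1\] bound the
#' score to \[-1, +1\]; 0 is the additive (HSA-expected) effect.
#'
#' @param role `"oncoprotein"` or `"tumor-suppressor"`.
#' @param act1,act2 Monotherapy steady-state activities in \[0,1\].
#' @param act_combo Combination steady-state activity in \[0,1\].
#' @return Numeric PSS value(s) in \[-1, 1\].
#' @examples
#' pss("oncoprotein", 0.6, 0.4, 0.1) # 0.3, synergistic suppression
#' pss("tumor-suppressor", 0.2, 0.3, 0.9) # 0.6
#' @export
pss <- function(role, act1, act2, act_combo) {
  role <- match_role(role)
  acts <- c(act1, act2, act_combo)
  if (any(!is.finite(acts)) || any(acts < 0 | acts > 1)) {
    stop("activities must be finite values in [0,1]")
  }
  out <- if (role == "oncoprotein") {
    pmin(act1, act2) - act_combo
  } else {
    act_combo - pmax(act1, act2)
  }
  stopifnot(all(abs(out) <= 1 + 1e-12))
  out
}

match_role <- function(role) {
  r <- tolower(gsub("[ _]", "-", trimws(role)))
  if (r %in% c("onco", "oncoprotein", "onco-protein")) return("oncoprotein")
  if (r %in% c("ts", "tumor-suppressor", "tumour-suppressor", "tumor-suppressor-protein")) {
    return("tumor-suppressor")
  }
  stop("protein role must be 'oncoprotein' or 'tumor-suppressor', got '", role, "'")
}

#' Consensus PSS over a dose grid
#'
#' The consensus is the 75th percentile (linear interpolation between order
#' statistics) of a protein's PSS values over all dose-grid cells,
#' zero-dose cells included.
#'
#' @param values Numeric PSS values (one per dose cell).
#' @param prob Percentile (default 0.75).
#' @return Single numeric consensus value.
#' @export
consensus_pss <- function(values, prob = 0.75) {
  if (length(values) == 0L) stop("no PSS values to take a consensus over")
  unname(quantile(values, probs = prob, type = 7, names = FALSE))
}

#' Observed HSA synergy score
#'
#' `S_HSA = y_c - max(y_A, y_B)`: the combination effect minus the larger
#' monotherapy effect.  Positive values indicate synergy, negative values
#' antagonism.
#'
#' @param y_a,y_b Monotherapy effects.
#' @param y_c Combination effect.
#' @return Numeric score(s).
#' @export
observed_hsa <- function(y_a, y_b, y_c) {
  y_c - pmax(y_a, y_b)
}

#' Per-protein synergy profile of a simulated dose grid
#'
#' Computes the PSS of every role-annotated protein at each dose cell,
#' reading monotherapy activities from the grid edges (cell `(a, 0)` for
#' drug A, `(0, b)` for drug B), and reduces each protein to its consensus
#' PSS (75th percentile over all cells).
#'
#' @param grid A `bn_dose_grid` from [simulate_combination_grid()].
#' @param roles Named character vector mapping node ->
#'   `"oncoprotein"`/`"tumor-suppressor"` (nodes absent from `roles` are
#'   not scored); defaults to [default_protein_roles()].
#' @param prob Consensus percentile (default 0.75).
#' @return Object of class `pss_profile`: data frame columns `node`,
#'   `role`, `consensus_pss`, with the per-dose PSS array in attribute
#'   `per_dose`.
#' @export
pss_profile <- function(grid, roles = default_protein_roles(), prob = 0.75) {
  stopifnot(inherits(grid, "bn_dose_grid"))
  nodes <- intersect(dimnames(grid$activity)[[1]], names(roles))
  if (length(nodes) == 0L) stop("no role-annotated nodes present in the dose grid")
  nd <- length(grid$doses)
  per_dose <- array(NA_real_,
    dim = c(length(nodes), nd, nd),
    dimnames = list(nodes, paste0("A", grid$doses), paste0("B", grid$doses))
  )
  for (nd_i in seq_along(nodes)) {
    node <- nodes[nd_i]
    role <- match_role(roles[[node]])
    for (i in seq_len(nd)) {
      for (j in seq_len(nd)) {
        per_dose[nd_i, i, j] <- pss(
          role,
          grid$activity[node, i, 1L], # drug A alone at dose i
          grid$activity[node, 1L, j], # drug B alone at dose j
          grid$activity[node, i, j]
        )
      }
    }
  }
  consensus <- apply(per_dose, 1L, consensus_pss, prob = prob)
  df <- data.frame(
    node = nodes,
    role = vapply(roles[nodes], match_role, ""),
    consensus_pss = consensus,
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(df, per_dose = per_dose, pair = grid$drugs, class = c("pss_profile", "data.frame"))
}

#' Predicted HSA synergy score from selected proteins
#'
#' Sums the consensus PSS of the selected proteins; the default selection
#' is the 13-protein signature spanning the apoptosis, cell-cycle, hormone
#' and PI3K/AKT readouts.
#'
#' @param profile A [pss_profile()], or a named vector of consensus PSS.
#' @param selected Character vector of protein names.
#' @return Single numeric predicted score.
#' @export
predicted_hsa <- function(profile, selected = default_selected_proteins()) {
  cons <- if (inherits(profile, "pss_profile")) {
    stats::setNames(profile$consensus_pss, profile$node)
  } else {
    profile
  }
  missing <- setdiff(selected, names(cons))
  if (length(missing)) {
    stop("selected protein(s) missing from the PSS profile: ", paste(missing, collapse = ", "))
  }
  sum(cons[selected])
}

#' Default onco/tumor-suppressor role table
#'
#' Bundled roles for the commonly scored nodes: apoptosis executors and
#' cell-cycle brakes (CASP3, P21, BID, FADD, GATA3) as tumor suppressors;
#' proliferative and hormone-signalling nodes (BCL2, CYCLIN_D, MTORC1,
#' ESR1, PGR, PAK1, STAT3, WNT1, E2F1) as oncoproteins.  Intended as an
#' auditable starting point; pass your own table to [pss_profile()] to
#' override.
#'
#' @return Named character vector node -> role.
#' @export
default_protein_roles <- function() {
  c(
    CASP3 = "tumor-suppressor", P21 = "tumor-suppressor",
    BID = "tumor-suppressor", FADD = "tumor-suppressor",
    GATA3 = "tumor-suppressor",
    BCL2 = "oncoprotein", CYCLIN_D = "oncoprotein", MTORC1 = "oncoprotein",
    ESR1 = "oncoprotein", PGR = "oncoprotein", PAK1 = "oncoprotein",
    STAT3 = "oncoprotein", WNT1 = "oncoprotein", E2F1 = "oncoprotein"
  )
}

#' Default selected-protein signature for the predicted HSA score
#' @return Character vector of 13 protein names.
#' @export
default_selected_proteins <- function() {
  c(
    "BCL2", "CYCLIN_D", "MTORC1", "ESR1", "PGR", "PAK1", "STAT3",
    "WNT1", "BID", "GATA3", "FADD", "P21", "CASP3"
  )
}

#' Read a protein role table (node, role) from delimited text
#' @param path File path.
#' @return Named character vector node -> role.
#' @export
read_role_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("node", "role") %in% names(df))) {
    stop("role table must have columns: node, role")
  }
  stats::setNames(vapply(df$role, match_role, ""), df$node)
}
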