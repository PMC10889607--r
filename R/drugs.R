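# Drugs as probabilistic clamps and the two-phase dose-grid protocol.

#' Construct a drug acting on one or more target nodes
#'
#' @param name Drug name.
#' @param targets Character vector of target node names.
#' @param modes `"antagonist"` (clamps the target off) or `"agonist"`
#'   (clamps it on); recycled across targets.
#' @return Object of class `bn_drug`.
#' @export
drug <- function(name, targets, modes = "antagonist") {
  stopifnot(is.character(name), length(name) == 1L, length(targets) >= 1L)
  modes <- tolower(rep_len(modes, length(targets)))
  if (!all(modes %in% c("agonist", "antagonist"))) {
    stop("drug mode must be 'agonist' or 'antagonist'")
  }
  structure(
    list(
      name = name,
      targets = data.frame(
        node = as.character(targets), mode = modes,
        stringsAsFactors = FALSE
      )
    ),
    class = "bn_drug"
  )
}

#' @export
print.bn_drug <- function(x, ...) {
  lab <- paste0(
    x$targets$node,
    ifelse(x$targets$mode == "agonist", "*", "")
  )
  cat(x$name, ": ", paste(lab, collapse = ", "),
    "  (* = agonist)\n",
    sep = ""
  )
  invisible(x)
}

#' Read a drug table (drug, target, mode) from delimited text
#'
#' One row per (drug, target); `mode` is `agonist`/`antagonist`.
#'
#' @param path File path.
#' @return Named list of [drug()] objects.
#' @export
read_drug_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("drug", "target", "mode")
  if (!all(need %in% names(df))) {
    stop("drug table must have columns: ", paste(need, collapse = ", "))
  }
  drugs <- lapply(split(df, df$drug), function(d) drug(d$drug[1], d$target, d$mode))
  drugs[unique(df$drug)]
}

#' Apply a drug to a clamp set at a given dose
#'
#' The dose is the probability that each target node becomes clamped
#' (antagonist to 0, agonist to 1), decided by one Bernoulli draw per target
#' at application time; the draw holds for the remainder of the simulation
#' repeat.  A node already clamped to a different value (a mutation clamp)
#' keeps its clamp, with a warning.  Uses the current R random-number
#' stream.
#'
#' @param clamps Named integer vector over all nodes (NA = free, 0/1 =
#'   clamped).
#' @param drug A [drug()].
#' @param dose Probability in \[0,1\].
#' @param shared_draw If `TRUE`, one Bernoulli draw covers all targets of
#'   the drug; default is an independent draw per target.
#' @return Updated clamp vector.
#' @export
apply_drug <- function(clamps, drug, dose, shared_draw = FALSE) {
  stopifnot(inherits(drug, "bn_drug"), !is.null(names(clamps)))
  if (!is.numeric(dose) || length(dose) != 1L || dose < 0 || dose > 1) {
    stop("dose must be a single probability in [0,1]")
  }
  unknown <- setdiff(drug$targets$node, names(clamps))
  if (length(unknown)) {
    stop(
      "drug '", drug$name, "' targets node(s) absent from the model: ",
      paste(unknown, collapse = ", ")
    )
  }
  k <- nrow(drug$targets)
  hit <- if (shared_draw) rep(runif(1L) < dose, k) else runif(k) < dose
  for (i in seq_len(k)) {
    if (!hit[i]) next
    nd <- drug$targets$node[i]
    val <- if (drug$targets$mode[i] == "agonist") 1L else 0L
    if (!is.na(clamps[[nd]]) && clamps[[nd]] != val) {
      warning(
        "drug '", drug$name, "' cannot clamp '", nd, "' to ", val,
        ": existing clamp ", clamps[[nd]], " wins"
      )
      next
    }
    clamps[[nd]] <- val
  }
  clamps
}

.free_clamps <- function(rules) {
  cl <- stats::setNames(rep(NA_integer_, length(rules$nodes)), rules$nodes)
  cl[names(rules$clamps)] <- rules$clamps
  cl
}

#' Simulate a drug pair over a dose-probability grid
#'
#' Two-phase protocol: the unperturbed model is first simulated to its
#' entropy-detected steady state; then, per grid cell `(doseA, doseB)` and
#' per repeat, drug clamps are drawn (Bernoulli with the dose as success
#' probability), the simulation continues from the pre-treatment state, and
#' post-drug steady-state activities are recorded.  The default grid is the
#' 4 x 4 dose set \{0, 0.25, 0.75, 1\} per drug.  Monotherapy activities are
#' the grid edges (doseB = 0 row, doseA = 0 column); they are not
#' re-simulated separately.
#'
#' @param rules A [rule_set()] (cell-line specific: clamps applied).
#' @param profile A [cell_line_profile()] for initial states.
#' @param drug_a,drug_b [drug()] objects.
#' @param doses Numeric dose vector (default `c(0, 0.25, 0.75, 1)`).
#' @param steps Steps per phase (default 5000).
#' @param repeats Repeats per dose cell (default 30).
#' @param phase1_repeats Repeats for the unperturbed phase (default 100).
#' @param seed Integer seed.
#' @param entropy_window,entropy_stride Steady-state detection settings.
#' @param shared_draw Passed to [apply_drug()].
#' @return Object of class `bn_dose_grid` with `activity` (nodes x doses x
#'   doses array), `doses`, `drugs`, and the phase-1 steady state.
#' @export
simulate_combination_grid <- function(rules, profile, drug_a, drug_b,
                                      doses = c(0, 0.25, 0.75, 1),
                                      steps = 5000L, repeats = 30L,
                                      phase1_repeats = 100L, seed = NULL,
                                      entropy_window = 100L,
                                      entropy_stride = 10L,
                                      shared_draw = FALSE) {
  stopifnot(inherits(rules, "rule_set"))
  if (is.null(seed)) seed <- sample.int(2147483646L, 1L)
  for (d in list(drug_a, drug_b)) {
    unknown <- setdiff(d$targets$node, rules$nodes)
    if (length(unknown)) {
      stop(
        "drug '", d$name, "' targets node(s) absent from the model: ",
        paste(unknown, collapse = ", ")
      )
    }
  }

  phase1 <- simulate_ensemble(rules, profile,
    steps = steps, repeats = phase1_repeats,
    seed = derive_seed(seed, "phase1"),
    entropy_window = entropy_window, entropy_stride = entropy_stride
  )
  if (phase1$steady_start > 0.9 * steps) {
    warning("entropy still falling near the end of phase 1; last-window average used")
  }
  starts <- phase1$final_states[, ((seq_len(repeats) - 1L) %% phase1_repeats) + 1L,
    drop = FALSE
  ]

  n <- length(rules$nodes)
  nd <- length(doses)
  act <- array(NA_real_,
    dim = c(n, nd, nd),
    dimnames = list(rules$nodes, paste0("A", doses), paste0("B", doses))
  )
  base <- .free_clamps(rules)
  conflicts <- character(0)
  for (i in seq_len(nd)) {
    for (j in seq_len(nd)) {
      set.seed(derive_seed(seed, sprintf("draw-%d-%d", i, j)))
      cm <- matrix(NA_integer_,
        nrow = n, ncol = repeats,
        dimnames = list(rules$nodes, NULL)
      )
      for (r in seq_len(repeats)) {
        cl <- withCallingHandlers(
          apply_drug(
            apply_drug(base, drug_a, doses[i], shared_draw),
            drug_b, doses[j], shared_draw
          ),
          warning = function(w) {
            conflicts <<- unique(c(conflicts, conditionMessage(w)))
            invokeRestart("muffleWarning")
          }
        )
        cm[, r] <- cl
      }
      cell <- simulate_ensemble(rules,
        init = starts, clamp_matrix = cm,
        steps = steps, seed = derive_seed(seed, sprintf("sim-%d-%d", i, j)),
        entropy_window = entropy_window, entropy_stride = entropy_stride
      )
      act[, i, j] <- cell$steady_activity
    }
  }
  if (length(conflicts)) {
    warning(
      "clamp conflict(s) during drug application (mutation clamp wins): ",
      paste(conflicts, collapse = "; ")
    )
  }
  structure(
    list(
      activity = act, doses = doses,
      drugs = c(drug_a$name, drug_b$name),
      phase1_steady = phase1$steady_activity,
      phase1_steady_start = phase1$steady_start,
      repeats = as.integer(repeats), seed = seed
    ),
    class = "bn_dose_grid"
  )
}

#' @export
print.bn_dose_grid <- function(x, ...) {
  cat(
    "Dose grid ", x$drugs[1], " + ", x$drugs[2], ": ",
    length(x$doses), "x", length(x$doses), " doses {",
    paste(x$doses, collapse = ", "), "}, ", dim(x$activity)[1], " nodes\n",
    sep = ""
  )
  invisible(x)
}

#' Monotherapy activities read from the dose-grid edges
#'
#' @param grid A `bn_dose_grid`.
#' @param which 1 for drug A (doseB = 0 row), 2 for drug B (doseA = 0
#'   column).
#' @return Nodes x doses matrix.
#' @export
monotherapy_activity <- function(grid, which = 1L) {
  stopifnot(inherits(grid, "bn_dose_grid"), which %in% c(1L, 2L))
  if (which == 1L) grid$activity[, , 1L] else grid$activity[, 1L, ]
}

#' Export a dose grid as a long-format table
#'
#' @param grid A `bn_dose_grid`.
#' @param cell_line Optional cell-line label column.
#' @return Data frame (pair, cell_line, node, dose_a, dose_b, activity).
#' @export
dose_grid_table <- function(grid, cell_line = NA_character_) {
  nd <- length(grid$doses)
  nodes <- dimnames(grid$activity)[[1]]
  expand <- expand.grid(
    node = nodes, i = seq_len(nd), j = seq_len(nd),
    stringsAsFactors = FALSE
  )
  data.frame(
    pair = paste(grid$drugs, collapse = " + "),
    cell_line = cell_line,
    node = expand$node,
    dose_a = grid$doses[expand$i],
    dose_b = grid$doses[expand$j],
    activity = grid$activity[cbind(match(expand$node, nodes), expand$i, expand$j)],
    stringsAsFactors = FALSE
  )
}
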