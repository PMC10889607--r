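# File round-trips, run configuration, pipeline orchestration and the
# command-line entry point.

#' Read an expression matrix (genes x cell lines) from delimited text
#'
#' First column = gene names, header row = cell-line names.
#'
#' @param path File path.
#' @return Numeric matrix with gene row names.
#' @export
read_expression_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Read a drug-pair list (drug1, drug2, cell_line, observed) from
#' delimited text
#' @param path File path.
#' @return Data frame.
#' @export
read_pair_list <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("drug1", "drug2", "cell_line", "observed")
  if (!all(need %in% names(df))) {
    stop("pair list must have columns: ", paste(need, collapse = ", "))
  }
  df
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a synthetic scenario as a directory of delimited input files
#'
#' Produces the standard file set the pipeline readers consume (edge list,
#' rule table, expression matrix, mutation table, drug table, role table,
#' drug-pair list) plus a JSON manifest with the generating configuration,
#' seed and ground truth.
#'
#' @param scenario A `bn_scenario` from [generate_scenario()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "bn_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_tsv(scenario$network$edges, file.path(dir, "edges.tsv"))
  rules_df <- data.frame(
    node = scenario$rules$nodes,
    expression = vapply(
      scenario$rules$nodes,
      function(nd) scenario$rules$rules[[nd]]$text, ""
    ),
    stringsAsFactors = FALSE
  )
  .write_tsv(rules_df, file.path(dir, "rules.tsv"))
  expr_df <- data.frame(
    gene = rownames(scenario$expression), scenario$expression,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  .write_tsv(expr_df, file.path(dir, "expression.tsv"))
  .write_tsv(scenario$mutations, file.path(dir, "mutations.tsv"))
  drug_df <- do.call(rbind, lapply(scenario$drugs, function(d) {
    data.frame(
      drug = d$name, target = d$targets$node, mode = d$targets$mode,
      stringsAsFactors = FALSE
    )
  }))
  .write_tsv(drug_df, file.path(dir, "drugs.tsv"))
  .write_tsv(
    data.frame(
      node = names(scenario$roles), role = unname(scenario$roles),
      stringsAsFactors = FALSE
    ),
    file.path(dir, "roles.tsv")
  )
  .write_tsv(scenario$pairs, file.path(dir, "pairs.tsv"))
  jsonlite::write_json(
    list(
      config = scenario$config, reporter = scenario$reporter,
      cell_lines = scenario$cell_lines
    ),
    file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' Read a scenario directory back into pipeline inputs
#'
#' @param dir Directory written by [write_scenario()] (or assembled by
#'   hand in the same layout).
#' @return List: `rules`, `expression`, `mutations`, `drugs`, `roles`,
#'   `pairs`, `manifest`.
#' @export
read_scenario <- function(dir) {
  rules <- read_rule_table(file.path(dir, "rules.tsv"))
  list(
    rules = rules,
    expression = read_expression_matrix(file.path(dir, "expression.tsv")),
    mutations = read_mutation_table(file.path(dir, "mutations.tsv")),
    drugs = read_drug_table(file.path(dir, "drugs.tsv")),
    roles = read_role_table(file.path(dir, "roles.tsv")),
    pairs = read_pair_list(file.path(dir, "pairs.tsv")),
    manifest = if (file.exists(file.path(dir, "manifest.json"))) {
      jsonlite::read_json(file.path(dir, "manifest.json"))
    }
  )
}

#' Run the full synergy-prediction pipeline
#'
#' Chains all stages: per cell line, builds the mutation-clamped rule set
#' and expression-derived profile; per drug pair, simulates the dose grid
#' and computes consensus PSS profiles; selects proteins (a fixed list or
#' the genetic algorithm); evaluates predicted vs observed HSA scores
#' pooled and per cell line; clusters the true-positive and true-negative
#' PSS profiles into mechanism groups; and writes delimited outputs plus a
#' JSON manifest.
#'
#' @param inputs List with `rules` (a [rule_set()]), `expression` (genes x
#'   cell lines matrix), `mutations`, `drugs` (named list of [drug()]),
#'   `roles` (named node -> role vector), `pairs` (data frame `drug1`,
#'   `drug2`, `cell_line`, `observed`), optional `overrides`.  As produced
#'   by [read_scenario()] or assembled from the readers.
#' @param out_dir Output directory; `NULL` skips file output.
#' @param selection `"ga"` to run the genetic algorithm, or a character
#'   vector of protein names.
#' @param steps,repeats,phase1_repeats,entropy_window,entropy_stride,doses
#'   Simulation settings (see [simulate_combination_grid()]).
#' @param ga Optional [ga_config()] used when `selection = "ga"`.
#' @param k_synergy,k_antagonism Mechanism-group counts for the
#'   true-positive and true-negative clusterings (defaults 5 and 3).
#' @param seed Integer root seed for the whole run.
#' @return List of class `bn_pipeline`: `pss_matrix`, `scores` (per pair:
#'   predicted, observed), `selection`, `evaluation` (pooled `bn_eval`),
#'   `per_cell_line`, `clusters`.
#' @export
run_pipeline <- function(inputs, out_dir = NULL, selection = "ga",
                         steps = 5000L, repeats = 30L, phase1_repeats = 100L,
                         entropy_window = 100L, entropy_stride = 10L,
                         doses = c(0, 0.25, 0.75, 1), ga = NULL,
                         k_synergy = 5L, k_antagonism = 3L, seed = 1L) {
  stopifnot(inherits(inputs$rules, "rule_set"), is.data.frame(inputs$pairs))
  scaled <- suppressWarnings(min_max_scale(inputs$expression))
  pairs <- inputs$pairs
  cell_lines <- unique(pairs$cell_line)

  profiles <- list()
  line_rules <- list()
  for (cl in cell_lines) {
    r <- apply_mutations(inputs$rules, inputs$mutations, cl)
    if (!is.null(inputs$overrides)) r <- apply_overrides(r, inputs$overrides, cl)
    line_rules[[cl]] <- r
    profiles[[cl]] <- cell_line_profile(r, scaled, cl)
  }

  # Consensus PSS per (pair, cell line) instance.
  scored_nodes <- intersect(inputs$rules$nodes, names(inputs$roles))
  inst_id <- paste(pairs$drug1, pairs$drug2, pairs$cell_line, sep = "|")
  pss_matrix <- matrix(
    NA_real_,
    nrow = length(scored_nodes), ncol = nrow(pairs),
    dimnames = list(scored_nodes, inst_id)
  )
  for (k in seq_len(nrow(pairs))) {
    cl <- pairs$cell_line[k]
    grid <- simulate_combination_grid(
      line_rules[[cl]], profiles[[cl]],
      inputs$drugs[[pairs$drug1[k]]], inputs$drugs[[pairs$drug2[k]]],
      doses = doses, steps = steps, repeats = repeats,
      phase1_repeats = phase1_repeats,
      seed = derive_seed(seed, paste0("grid-", inst_id[k])),
      entropy_window = entropy_window, entropy_stride = entropy_stride
    )
    prof <- pss_profile(grid, roles = inputs$roles)
    pss_matrix[prof$node, k] <- prof$consensus_pss
  }

  if (identical(selection, "ga")) {
    if (is.null(ga)) {
      ga <- ga_config(
        mandatory = intersect(c("E2F1", "CASP3"), scored_nodes),
        seed = derive_seed(seed, "ga")
      )
    }
    ga_res <- ga_evolve(pss_matrix, pairs$observed, config = ga)
    selected <- ga_res$best_subset
  } else {
    ga_res <- NULL
    selected <- selection
  }

  predicted <- vapply(
    seq_len(ncol(pss_matrix)),
    function(k) predicted_hsa(pss_matrix[, k], selected), numeric(1)
  )
  scores <- data.frame(
    pairs[, c("drug1", "drug2", "cell_line")],
    predicted = predicted, observed = pairs$observed,
    stringsAsFactors = FALSE
  )
  evaluation <- classify_and_score(scores$predicted, scores$observed)
  per_cell_line <- lapply(split(scores, scores$cell_line), function(s) {
    tryCatch(classify_and_score(s$predicted, s$observed), error = function(e) NULL)
  })

  cluster_of <- function(rows, k) {
    if (length(rows) < 2L) return(NULL)
    m <- t(pss_matrix[selected, rows, drop = FALSE])
    suppressWarnings(cluster_pss(m, k = min(k, nrow(m))))
  }
  tp <- which(scores$predicted > 0 & scores$observed > 0)
  tn <- which(scores$predicted <= 0 & scores$observed <= 0)
  clusters <- list(
    synergistic = cluster_of(tp, k_synergy),
    antagonistic = cluster_of(tn, k_antagonism)
  )

  out <- structure(
    list(
      pss_matrix = pss_matrix, scores = scores, selection = selected,
      ga = ga_res, evaluation = evaluation, per_cell_line = per_cell_line,
      clusters = clusters, seed = seed
    ),
    class = "bn_pipeline"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    pss_long <- data.frame(
      instance = rep(colnames(pss_matrix), each = nrow(pss_matrix)),
      node = rep(rownames(pss_matrix), times = ncol(pss_matrix)),
      consensus_pss = as.vector(pss_matrix),
      stringsAsFactors = FALSE
    )
    .write_tsv(pss_long, file.path(out_dir, "pss.tsv"))
    .write_tsv(scores, file.path(out_dir, "scores.tsv"))
    jsonlite::write_json(
      list(
        selection = selected,
        evaluation = list(
          pearson = evaluation$pearson, auc = evaluation$auc,
          sensitivity = evaluation$sensitivity,
          specificity = evaluation$specificity,
          counts = as.list(evaluation$counts)
        )
      ),
      file.path(out_dir, "evaluation.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    jsonlite::write_json(
      list(
        seed = seed, steps = steps, repeats = repeats,
        phase1_repeats = phase1_repeats, doses = doses,
        entropy_window = entropy_window, entropy_stride = entropy_stride,
        n_pairs = nrow(pairs), cell_lines = cell_lines
      ),
      file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  out
}

#' @export
print.bn_pipeline <- function(x, ...) {
  cat(
    "Synergy pipeline run: ", nrow(x$scores), " (pair, cell line) scores, ",
    length(x$selection), " selected proteins\n",
    sep = ""
  )
  print(x$evaluation)
  invisible(x)
}

#' Command-line entry point
#'
#' Thin shell over the package functions.  Subcommands:
#' \describe{
#'   \item{synth}{`bnsynergy synth <out_dir> [--seed N] [--nodes N]` —
#'     write a synthetic scenario directory.}
#'   \item{pipeline}{`bnsynergy pipeline <config.yaml>` — run the pipeline
#'     from a YAML config (keys: `scenario_dir`, `out_dir`, `selection`,
#'     `steps`, `repeats`, `phase1_repeats`, `seed`, ...).}
#'   \item{evaluate}{`bnsynergy evaluate <scores.tsv>` — evaluate a
#'     predicted/observed score table.}
#' }
#'
#' @param args Character vector of command-line arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status (0 on success), invisibly.
#' @export
bnsynergy_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: bnsynergy <synth|pipeline|evaluate> ..."
  if (length(args) < 1L) {
    message(usage)
    return(invisible(1L))
  }
  opt <- function(flag, default) {
    i <- which(args == flag)
    if (length(i)) as.integer(args[i[1L] + 1L]) else default
  }
  status <- tryCatch(
    {
      switch(args[[1L]],
        synth = {
          dir <- args[[2L]]
          sc <- generate_scenario(
            n_nodes = opt("--nodes", 10L),
            seed = opt("--seed", 1L)
          )
          write_scenario(sc, dir)
          message("scenario written to ", dir)
          0L
        },
        pipeline = {
          cfg <- yaml::read_yaml(args[[2L]])
          inputs <- read_scenario(cfg$scenario_dir)
          res <- run_pipeline(
            inputs,
            out_dir = cfg$out_dir,
            selection = if (is.null(cfg$selection)) "ga" else unlist(cfg$selection),
            steps = if (is.null(cfg$steps)) 5000L else cfg$steps,
            repeats = if (is.null(cfg$repeats)) 30L else cfg$repeats,
            phase1_repeats = if (is.null(cfg$phase1_repeats)) 100L else cfg$phase1_repeats,
            seed = if (is.null(cfg$seed)) 1L else cfg$seed
          )
          print(res)
          0L
        },
        evaluate = {
          df <- read.delim(args[[2L]], stringsAsFactors = FALSE)
          print(classify_and_score(df$predicted, df$observed))
          0L
        },
        {
          message(usage)
          1L
        }
      )
    },
    error = function(e) {
      message("error: ", conditionMessage(e))
      1L
    }
  )
  invisible(status)
}
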