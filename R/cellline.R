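# Expression-derived initial-state probabilities and initial-state sampling.

#' Min-max scale an expression matrix across cell lines
#'
#' Per gene `j` and cell line `k`, the scaled value is
#' `(x_jk - min(x_j)) / (max(x_j) - min(x_j))`, so each gene's minimum maps
#' to 0 and its maximum to 1 across the cell-line columns.  Genes with a
#' degenerate range (`max == min`) are uninformative and are set to 0.5
#' everywhere, with a warning.
#'
#' @param mat Non-negative numeric matrix, genes in rows, cell lines in
#'   columns (TPM-like scale).
#' @return Matrix of scaled values in \[0, 1\].
#' @examples
#' min_max_scale(rbind(g1 = c(2, 4, 6, 8, 10)))
#' @export
min_max_scale <- function(mat) {
  mat <- as.matrix(mat)
  if (!is.numeric(mat)) stop("expression matrix must be numeric")
  if (any(mat < 0, na.rm = TRUE)) stop("expression values must be non-negative")
  if (ncol(mat) < 1L) stop("expression matrix needs at least one cell-line column")
  lo <- apply(mat, 1L, min)
  hi <- apply(mat, 1L, max)
  span <- hi - lo
  degen <- span == 0
  span[degen] <- 1
  out <- (mat - lo) / span
  if (any(degen)) {
    out[degen, ] <- 0.5
    genes <- rownames(mat)[degen]
    if (is.null(genes)) genes <- which(degen)
    warning(
      "constant expression across cell lines for ", sum(degen),
      " gene(s) (set to 0.5): ", paste(utils::head(genes, 5L), collapse = ", ")
    )
  }
  out
}

#' Build a cell-line profile of initial-state probabilities
#'
#' Maps each model node to the probability that it starts in the on state,
#' taken from the min-max-scaled expression of its gene(s) in the given
#' cell line.  Complex/isoform nodes mapped to several genes receive the
#' mean of the member genes' scaled values; nodes with no measured gene
#' default to `default_prob` (maximum-entropy 0.5).  Mutation clamps are
#' inherited from the rule set.
#'
#' @param rules A [rule_set()] (defines the node set and clamps).
#' @param scaled Matrix from [min_max_scale()], genes x cell lines.
#' @param cell_line Column of `scaled` to use.
#' @param node_map Optional named list mapping node -> character vector of
#'   member genes.
#' @param default_prob Probability for unmeasured nodes (default 0.5).
#' @return Object of class `cell_line_profile` with fields `cell_line`,
#'   `init_prob` (named, in \[0,1\]) and `clamps`.
#' @export
cell_line_profile <- function(rules, scaled, cell_line, node_map = NULL,
                              default_prob = 0.5) {
  stopifnot(inherits(rules, "rule_set"))
  scaled <- as.matrix(scaled)
  if (!cell_line %in% colnames(scaled)) {
    stop("cell line '", cell_line, "' not found in the expression matrix")
  }
  if (default_prob < 0 || default_prob > 1) stop("default_prob must be in [0,1]")
  col <- scaled[, cell_line]
  p <- vapply(rules$nodes, function(nd) {
    genes <- if (!is.null(node_map) && nd %in% names(node_map)) node_map[[nd]] else nd
    present <- intersect(genes, rownames(scaled))
    if (length(present)) mean(col[present]) else default_prob
  }, numeric(1))
  if (any(p < 0 | p > 1)) stop("initial probabilities must lie in [0,1]")
  clamps <- rules$clamps
  p[names(clamps)] <- as.numeric(clamps)
  structure(
    list(cell_line = cell_line, init_prob = p, clamps = clamps),
    class = "cell_line_profile"
  )
}

#' @export
print.cell_line_profile <- function(x, ...) {
  cat(
    "Cell-line profile '", x$cell_line, "': ", length(x$init_prob),
    " nodes, ", length(x$clamps), " clamp(s)\n",
    sep = ""
  )
  invisible(x)
}

#' Sample full initial network states from a cell-line profile
#'
#' Each non-clamped node is drawn independently as Bernoulli with its
#' initial probability; clamped nodes take their clamp value.  Uses the
#' current R random-number stream (seed with [set.seed()] for
#' reproducibility).
#'
#' @param profile A [cell_line_profile()], or a named probability vector.
#' @param n Number of states to draw.
#' @return Integer 0/1 matrix, nodes x `n`, with node row names.
#' @export
sample_initial_states <- function(profile, n = 1L) {
  if (inherits(profile, "cell_line_profile")) {
    p <- profile$init_prob
    clamps <- profile$clamps
  } else {
    p <- profile
    clamps <- stats::setNames(integer(0), character(0))
  }
  stopifnot(!is.null(names(p)), all(p >= 0 & p <= 1))
  m <- matrix(
    as.integer(runif(length(p) * n) < rep(p, times = n)),
    nrow = length(p), ncol = n, dimnames = list(names(p), NULL)
  )
  if (length(clamps)) m[names(clamps), ] <- rep(clamps, times = n)
  m
}
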