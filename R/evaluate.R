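# Prediction evaluation (Pearson, AUC, sensitivity, specificity) and
# correlation-distance clustering of PSS profiles into mechanism groups.

#' Min-max rescale scores to \[-1, +1\]
#'
#' Affine map sending the minimum to -1 and the maximum to +1; used to put
#' predicted and observed synergy scores on a common scale before
#' plotting/comparison.  Pearson correlation is unchanged by this map.
#'
#' @param scores Numeric vector with at least two distinct values.
#' @return Rescaled vector.
#' @export
rescale_scores <- function(scores) {
  if (length(scores) < 2L) stop("need at least two scores to rescale")
  lo <- min(scores)
  hi <- max(scores)
  if (hi == lo) stop("cannot rescale constant scores")
  (scores - lo) / (hi - lo) * 2 - 1
}

#' Classify and score synergy predictions against observations
#'
#' Labels each drug pair synergistic when its observed score exceeds 0 and
#' calls a prediction positive when it exceeds `threshold` (default 0).
#' Reports Pearson correlation on the continuous scores, the confusion
#' counts, sensitivity, specificity, and the ranking AUC of the predictions
#' against the labels (undefined and reported as `NA` when only one class
#' is present).
#'
#' @param predicted Numeric predicted synergy scores.
#' @param observed Numeric observed synergy scores (same length/order).
#' @param threshold Decision threshold on the predicted score (default 0).
#' @return Object of class `bn_eval`: `pearson`, `auc`, `sensitivity`,
#'   `specificity`, `counts` (TP/FP/TN/FN), `n`.
#' @export
classify_and_score <- function(predicted, observed, threshold = 0) {
  stopifnot(length(predicted) == length(observed), length(predicted) >= 2L)
  if (any(!is.finite(predicted)) || any(!is.finite(observed))) {
    stop("scores must be finite")
  }
  if (sd(predicted) == 0) stop("constant predictions: cannot evaluate")
  if (sd(observed) == 0) stop("constant observations: cannot evaluate")
  labels <- observed > 0
  pred_pos <- predicted > threshold
  tp <- sum(pred_pos & labels)
  fp <- sum(pred_pos & !labels)
  tn <- sum(!pred_pos & !labels)
  fn <- sum(!pred_pos & labels)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  auc <- if (length(unique(labels)) == 2L) {
    as.numeric(pROC::auc(pROC::roc(
      response = labels, predictor = predicted,
      levels = c(FALSE, TRUE), direction = "<", quiet = TRUE
    )))
  } else {
    NA_real_
  }
  structure(
    list(
      pearson = cor(predicted, observed), auc = auc,
      sensitivity = sens, specificity = spec,
      counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
      n = length(predicted), threshold = threshold
    ),
    class = "bn_eval"
  )
}

#' @export
print.bn_eval <- function(x, ...) {
  cat(
    "Synergy prediction evaluation (n = ", x$n, "):\n",
    "  Pearson r   = ", format(x$pearson, digits = 3), "\n",
    "  AUC         = ", format(x$auc, digits = 3), "\n",
    "  sensitivity = ", format(x$sensitivity, digits = 3), "\n",
    "  specificity = ", format(x$specificity, digits = 3), "\n",
    "  counts: ", paste(names(x$counts), x$counts, sep = "=", collapse = " "),
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Correlation distance between PSS profiles
#'
#' `d = 1 - r` between profile rows, giving distances in \[0, 2\].
#' Zero-variance profiles are uncorrelated with everything; their distance
#' is set to the maximum (2) with a warning.
#'
#' @param mat Profiles in rows (drug pairs x proteins).
#' @return A `dist` object.
#' @export
correlation_distance <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("need at least two profiles")
  degen <- apply(mat, 1L, sd) == 0
  cm <- suppressWarnings(cor(t(mat)))
  if (any(degen)) {
    warning(
      sum(degen), " zero-variance profile(s); correlation distance set to 2"
    )
    cm[degen, ] <- -1
    cm[, degen] <- -1
  }
  diag(cm) <- 1
  as.dist(1 - cm)
}

#' Cluster drug-pair PSS profiles into mechanism groups
#'
#' Hierarchical agglomerative clustering (average linkage) on the
#' correlation distance between selected-protein PSS vectors, cut into `k`
#' groups.  Each group's signature is the set of proteins whose mean PSS
#' within the group exceeds `signature_threshold` (the dominant
#' positive-PSS proteins driving the common mechanism).
#'
#' @param profiles Drug pairs x proteins matrix of consensus PSS values
#'   (row names label the pairs).
#' @param k Number of groups to cut (the synergistic and antagonistic sets
#'   are conventionally cut at 5 and 3 groups respectively).
#' @param signature_threshold Minimum group-mean PSS for a protein to enter
#'   the signature (default 0.1).
#' @return Object of class `bn_clustering`: `groups` (named integer
#'   vector), `hclust`, `dist`, `signatures` (list per group).
#' @export
cluster_pss <- function(profiles, k, signature_threshold = 0.1) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2L) stop("need at least two profiles to cluster")
  if (k < 1L || k > nrow(profiles)) stop("k must be between 1 and the number of profiles")
  d <- correlation_distance(profiles)
  hc <- hclust(d, method = "average")
  groups <- cutree(hc, k = k)
  signatures <- lapply(split(seq_len(nrow(profiles)), groups), function(rows) {
    m <- colMeans(profiles[rows, , drop = FALSE])
    names(m)[m > signature_threshold]
  })
  structure(
    list(groups = groups, hclust = hc, dist = d, signatures = signatures, k = k),
    class = "bn_clustering"
  )
}

#' @export
print.bn_clustering <- function(x, ...) {
  cat("PSS mechanism clustering:", length(x$groups), "profiles in", x$k, "groups\n")
  for (g in seq_len(x$k)) {
    sig <- x$signatures[[as.character(g)]]
    cat(
      "  group ", g, " (n = ", sum(x$groups == g), "): ",
      if (length(sig)) paste(sig, collapse = ", ") else "(no dominant proteins)",
      "\n",
      sep = ""
    )
  }
  invisible(x)
}

#' Export a clustering dendrogram in Newick format
#'
#' @param clustering A `bn_clustering`.
#' @param path Output file.
#' @export
write_newick <- function(clustering, path) {
  stopifnot(inherits(clustering, "bn_clustering"))
  ape::write.tree(ape::as.phylo(clustering$hclust), file = path)
}
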