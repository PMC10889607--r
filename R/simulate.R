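# Asynchronous ensemble simulation, entropy profile and steady-state
# detection.

#' Derive a reproducible child seed from a root seed
#'
#' Hashes a root seed together with a character tag so that each stage of a
#' run gets its own deterministic stream.  The result is a non-negative
#' integer below 2^31.
#'
#' @param seed Integer root seed.
#' @param tag Character tag naming the consumer.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- as.integer(seed) %% 2147483647
  for (ch in utf8ToInt(paste0(tag))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

#' One uniform-asynchronous update step (reference implementation)
#'
#' Among the non-clamped nodes whose rule output differs from their current
#' value, one is chosen uniformly at random and flipped.  If no node can
#' change, the state is a fixed point and is returned unchanged.  Uses the
#' current R random-number stream.  This is the plain-R reference for the
#' compiled ensemble engine and is convenient for inspecting single
#' trajectories.
#'
#' @param state Named 0/1 vector over all nodes.
#' @param rules A [rule_set()].
#' @return Named 0/1 vector after one step.
#' @export
async_step <- function(state, rules) {
  stopifnot(inherits(rules, "rule_set"))
  if (!all(rules$nodes %in% names(state))) stop("state must cover all nodes")
  free <- setdiff(rules$nodes, names(rules$clamps))
  nxt <- vapply(free, function(nd) eval_rule(rules$rules[[nd]], state), integer(1))
  can <- free[nxt != state[free]]
  if (length(can) == 0L) return(state)
  pick <- can[[sample.int(length(can), 1L)]]
  state[[pick]] <- 1L - state[[pick]]
  state
}

#' Cumulative pooled entropy profile of a trajectory ensemble
#'
#' `H(t) = -sum_S P_t(S) log2 P_t(S)` where `P_t(S)` is the empirical
#' frequency of the full network state `S` among all observations pooled
#' over repeats and over steps 0..t.  Entropy is reported at checkpoint
#' times spaced `stride` steps apart.
#'
#' @param trajectories A single nodes x (T+1) 0/1 matrix, or a list of them
#'   (one per repeat, equal lengths).
#' @param stride Checkpoint spacing in steps (default 1).
#' @return Data frame with columns `t` and `H` (bits).
#' @export
entropy_profile <- function(trajectories, stride = 1L) {
  if (is.matrix(trajectories)) trajectories <- list(trajectories)
  stopifnot(length(trajectories) >= 1L, stride >= 1L)
  tlen <- ncol(trajectories[[1L]])
  keys <- lapply(trajectories, function(m) {
    stopifnot(ncol(m) == tlen)
    apply(m, 2L, paste, collapse = "")
  })
  steps <- tlen - 1L
  cks <- unique(c(seq(stride - 1L, steps, by = stride), steps))
  H <- vapply(cks, function(tt) {
    obs <- unlist(lapply(keys, function(k) k[seq_len(tt + 1L)]), use.names = FALSE)
    p <- table(obs) / length(obs)
    -sum(p * log2(p))
  }, numeric(1))
  data.frame(t = cks, H = H)
}

#' Detect the steady-state step from an entropy profile
#'
#' The steady state is declared where the windowed finite-difference slope
#' of `H(t)` is at its minimum (most negative); ties break to the earliest
#' time.  The slope at checkpoint `c` is the centred difference over
#' `window` simulation steps.
#'
#' @param profile Data frame with columns `t`, `H` (as from
#'   [entropy_profile()]).
#' @param window Slope window in simulation steps (default 100).
#' @return The detected step `t*` (integer).
#' @export
detect_steady_state <- function(profile, window = 100L) {
  stopifnot(is.data.frame(profile), all(c("t", "H") %in% names(profile)))
  if (any(!is.finite(profile$H))) stop("entropy profile contains non-finite values")
  tt <- profile$t
  H <- profile$H
  stride <- if (length(tt) > 1L) max(1, stats::median(diff(tt))) else 1L
  w <- max(1L, as.integer(round(window / stride)))
  nb <- length(H)
  if (nb < 2L * w + 1L) {
    stop("entropy profile shorter than the smoothing window")
  }
  cs <- (w + 1L):(nb - w)
  slope <- (H[cs + w] - H[cs - w]) / (tt[cs + w] - tt[cs - w])
  as.integer(tt[cs[which.min(slope)]])
}

#' Steady-state protein activities from a step-resolved activity matrix
#'
#' Per node, the mean of the ensemble activity over all steps from `t_star`
#' to the final step.
#'
#' @param activity Nodes x (T+1) matrix of ensemble-mean activities (column
#'   `k` is step `k-1`), or a `bn_ensemble`.
#' @param t_star Detected steady-state step.
#' @return Named numeric vector of activities in \[0,1\].
#' @export
steady_state_activities <- function(activity, t_star) {
  if (inherits(activity, "bn_ensemble")) activity <- activity$activity
  steps <- ncol(activity) - 1L
  stopifnot(t_star >= 0L, t_star <= steps)
  rowMeans(activity[, (t_star + 1L):(steps + 1L), drop = FALSE])
}

#' Simulate an ensemble of asynchronous trajectories to steady state
#'
#' Runs `repeats` uniform-asynchronous trajectories of `steps` updates,
#' pools their states into the entropy profile, detects the steady-state
#' step at the entropy-slope minimum, and averages activities from there to
#' the end.  Initial states are sampled from the cell-line profile (or
#' given explicitly); clamped nodes stay at their clamp throughout.
#'
#' @param rules A [rule_set()].
#' @param profile A [cell_line_profile()] (or named probability vector)
#'   used to sample initial states; ignored when `init` is given.
#' @param init Optional nodes x repeats 0/1 matrix of initial states.
#' @param steps Trajectory length (default 5000).
#' @param repeats Ensemble size (default 100).
#' @param seed Integer seed; all randomness (initial states and update
#'   choices) derives from it.
#' @param entropy_window Slope window in steps for steady-state detection
#'   (default 100).
#' @param entropy_stride Entropy checkpoint spacing in steps (default 10).
#' @param clamp_matrix Optional nodes x repeats matrix of per-repeat clamps
#'   (NA = free, 0/1 = clamped), e.g. drawn drug clamps.  Mutation clamps in
#'   `rules` take precedence.
#' @param repeat_means If `TRUE`, also return each repeat's per-node mean
#'   activity over the steady window (for Monte-Carlo standard errors).
#' @param return_traj If `TRUE`, return the full trajectories (small runs
#'   only).
#' @return Object of class `bn_ensemble` with fields `activity` (nodes x
#'   steps+1), `entropy` (data frame `t`, `H`), `steady_start`,
#'   `steady_activity`, `final_states`, and optionally `repeat_means`,
#'   `trajectories`.
#' @export
simulate_ensemble <- function(rules, profile = NULL, init = NULL,
                              steps = 5000L, repeats = 100L, seed = NULL,
                              entropy_window = 100L, entropy_stride = 10L,
                              clamp_matrix = NULL, repeat_means = FALSE,
                              return_traj = FALSE) {
  stopifnot(inherits(rules, "rule_set"))
  if (is.null(seed)) seed <- sample.int(2147483646L, 1L)
  comp <- compile_ruleset_codes(rules)
  n <- length(rules$nodes)

  if (is.null(init)) {
    if (is.null(profile)) stop("either a cell-line profile or an init matrix is required")
    set.seed(derive_seed(seed, "init"))
    init <- sample_initial_states(profile, repeats)
  } else {
    init <- as.matrix(init)
    if (nrow(init) != n) stop("init matrix must have one row per node")
    if (is.null(rownames(init))) rownames(init) <- rules$nodes
    init <- init[rules$nodes, , drop = FALSE]
    repeats <- ncol(init)
  }

  clamp <- matrix(rep(comp$clamp, repeats), nrow = n)
  if (!is.null(clamp_matrix)) {
    cm <- as.matrix(clamp_matrix)
    if (!identical(dim(cm), dim(clamp))) stop("clamp_matrix must be nodes x repeats")
    if (!is.null(rownames(cm))) cm <- cm[rules$nodes, , drop = FALSE]
    take <- !is.na(cm) & clamp < 0 # mutation clamps keep precedence
    clamp[take] <- cm[take]
  }

  res <- .simulate_ensemble_cpp(
    comp$codes, init, clamp,
    as.integer(steps), derive_seed(seed, "engine"),
    as.integer(entropy_stride), return_traj, -1L
  )
  rownames(res$activity) <- rules$nodes
  rownames(res$final) <- rules$nodes
  entropy <- data.frame(t = res$entropy_t, H = res$entropy)
  t_star <- detect_steady_state(entropy, window = entropy_window)
  steady <- steady_state_activities(res$activity, t_star)

  out <- list(
    activity = res$activity,
    entropy = entropy,
    steady_start = t_star,
    steady_activity = steady,
    final_states = res$final,
    steps = as.integer(steps), repeats = as.integer(repeats), seed = seed
  )
  if (repeat_means) {
    res2 <- .simulate_ensemble_cpp(
      comp$codes, init, clamp,
      as.integer(steps), derive_seed(seed, "engine"),
      as.integer(entropy_stride), FALSE, as.integer(t_star)
    )
    rm <- res2$repeat_means
    rownames(rm) <- rules$nodes
    out$repeat_means <- rm
  }
  if (return_traj) {
    out$trajectories <- lapply(res$traj, function(m) {
      rownames(m) <- rules$nodes
      m
    })
  }
  structure(out, class = "bn_ensemble")
}

#' @export
print.bn_ensemble <- function(x, ...) {
  cat(
    "Asynchronous ensemble: ", nrow(x$activity), " nodes, ", x$repeats,
    " repeats, ", x$steps, " steps; steady state from t* = ", x$steady_start,
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Write steady-state activities as a delimited table
#'
#' @param activities Named vector, or a matrix with nodes in rows and
#'   conditions in columns.
#' @param path Output file.
#' @export
write_activity_table <- function(activities, path) {
  if (is.null(dim(activities))) {
    activities <- matrix(activities,
      ncol = 1,
      dimnames = list(names(activities), "activity")
    )
  }
  df <- data.frame(node = rownames(activities), activities, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
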