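# Shared toy models and fixture builders (all generated in code).

# Mutual inhibition: two fixed points (1,0) and (0,1).
toggle_rules <- function() {
  rule_set(list(
    boolean_rule("A", "not B"),
    boolean_rule("B", "not A")
  ))
}

# Mutual activation: fixed points (0,0) and (1,1).
mutual_activation_rules <- function() {
  rule_set(list(
    boolean_rule("A", "B"),
    boolean_rule("B", "A")
  ))
}

# Linear cascade with a persistent (self-loop) root: A -> B -> C -> D.
cascade_network <- function() {
  signaling_network(
    data.frame(
      source = c("A", "B", "C"),
      target = c("B", "C", "D"),
      sign = "activating"
    ),
    nodes = c("A", "B", "C", "D"),
    self_loops = "A"
  )
}

uniform_profile <- function(rules, p = 0.5) {
  stats::setNames(rep(p, length(rules$nodes)), rules$nodes)
}

# Three blocks of PSS profiles with distinct dominant-positive proteins.
planted_block_profiles <- function(n_per_block = 5, noise_sd = 0.03, seed = 401) {
  set.seed(seed)
  proteins <- sprintf("PR%02d", 1:9)
  sig <- rbind(
    c(0.8, 0.8, 0.8, -0.2, -0.2, -0.2, 0, 0, 0),
    c(-0.2, -0.2, -0.2, 0.8, 0.8, 0.8, 0, 0, 0),
    c(0, 0, 0, -0.2, -0.2, -0.2, 0.8, 0.8, 0.8)
  )
  profiles <- do.call(rbind, lapply(1:3, function(b) {
    m <- matrix(rep(sig[b, ], n_per_block), nrow = n_per_block, byrow = TRUE)
    m + matrix(rnorm(length(m), sd = noise_sd), nrow = n_per_block)
  }))
  colnames(profiles) <- proteins
  rownames(profiles) <- sprintf("pair%02d", seq_len(nrow(profiles)))
  list(profiles = profiles, truth = rep(1:3, each = n_per_block))
}

# Ten-pair prediction/observation fixture with hand-computed metrics.
metric_fixture <- function() {
  list(
    observed = c(0.5, -0.2, 0.3, -0.4, 0.1, -0.1, 0.6, -0.3, 0.2, -0.5),
    predicted = c(0.4, 0.1, -0.2, -0.3, 0.3, -0.4, 0.5, 0.2, 0.1, -0.1),
    pearson = 0.5883523231795883,
    auc = 0.82,
    sensitivity = 0.8,
    specificity = 0.6,
    counts = c(TP = 4L, FP = 2L, TN = 3L, FN = 1L)
  )
}
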