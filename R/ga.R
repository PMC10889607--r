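# Genetic algorithm selecting the protein subset whose summed consensus
# PSS best correlates with observed HSA synergy scores.

#' Genetic-algorithm configuration
#'
#' Defaults follow the selection scheme used throughout the package: a
#' population of 60 variable-length chromosomes, the top 30 surviving each
#' generation to parent 30 offspring (mutation and crossover each applied
#' with probability 0.9), joined by 30 fresh random chromosomes.  Two
#' proteins (by default E2F1 and CASP3, the proliferation and apoptosis
#' readouts) are mandatory members of every chromosome.
#'
#' @param population Population size (default 60).
#' @param survivors Chromosomes kept per generation (default 30).
#' @param offspring Offspring produced per generation (default 30).
#' @param fresh Fresh random chromosomes per generation (default 30).
#' @param p_mutation,p_crossover Operator probabilities (default 0.9).
#' @param generations Number of generations (default 500; the full-scale
#'   setting is 10000).
#' @param len_min,len_max Chromosome length bounds at initialisation
#'   (default 3..20, mandatory members included).
#' @param mandatory Proteins present in every chromosome.
#' @param seed Integer seed.
#' @return List of class `ga_config`.
#' @export
ga_config <- function(population = 60L, survivors = 30L, offspring = 30L,
                      fresh = 30L, p_mutation = 0.9, p_crossover = 0.9,
                      generations = 500L, len_min = 3L, len_max = 20L,
                      mandatory = c("E2F1", "CASP3"), seed = NULL) {
  stopifnot(
    p_mutation >= 0, p_mutation <= 1, p_crossover >= 0, p_crossover <= 1,
    survivors <= population, offspring + fresh == population,
    len_min >= length(mandatory), len_max >= len_min, generations >= 0
  )
  structure(
    list(
      population = as.integer(population), survivors = as.integer(survivors),
      offspring = as.integer(offspring), fresh = as.integer(fresh),
      p_mutation = p_mutation, p_crossover = p_crossover,
      generations = as.integer(generations),
      len_min = as.integer(len_min), len_max = as.integer(len_max),
      mandatory = mandatory, seed = seed
    ),
    class = "ga_config"
  )
}

#' Fitness of a protein subset: Pearson correlation of predicted vs
#' observed synergy
#'
#' The prediction for each drug pair is the sum of the subset's consensus
#' PSS values; fitness is the Pearson correlation with the observed HSA
#' scores across pairs.  Degenerate (zero-variance) predictions score -1,
#' the worst possible fitness.
#'
#' @param subset Character vector of protein names (rows of `pss_matrix`).
#' @param pss_matrix Proteins x drug-pairs matrix of consensus PSS values.
#' @param observed Observed HSA score per drug pair (columns).
#' @return Pearson r in \[-1, 1\].
#' @export
ga_fitness <- function(subset, pss_matrix, observed) {
  stopifnot(length(observed) == ncol(pss_matrix))
  if (length(observed) < 3L) stop("need at least 3 drug pairs for a fitness value")
  if (sd(observed) == 0) stop("observed scores have zero variance")
  missing <- setdiff(subset, rownames(pss_matrix))
  if (length(missing)) {
    stop("subset protein(s) missing from the PSS matrix: ", paste(missing, collapse = ", "))
  }
  pred <- colSums(pss_matrix[subset, , drop = FALSE])
  if (sd(pred) == 0) {
    return(-1)
  }
  cor(pred, observed)
}

.random_chromosome <- function(candidates, config) {
  n_opt_max <- min(config$len_max - length(config$mandatory), length(candidates))
  n_opt_min <- min(max(0L, config$len_min - length(config$mandatory)), n_opt_max)
  k <- if (n_opt_max > n_opt_min) {
    sample(n_opt_min:n_opt_max, 1L)
  } else {
    n_opt_max
  }
  sort(c(config$mandatory, sample(candidates, k)))
}

.mutate_chromosome <- function(chrom, candidates, config) {
  opt <- setdiff(chrom, config$mandatory)
  absent <- setdiff(candidates, opt)
  n_opt_max <- min(config$len_max - length(config$mandatory), length(candidates))
  n_opt_min <- max(0L, config$len_min - length(config$mandatory))
  ops <- c(
    if (length(absent) && length(opt) < n_opt_max) "add",
    if (length(opt) > n_opt_min) "remove",
    if (length(absent) && length(opt)) "swap"
  )
  if (is.null(ops)) return(chrom)
  op <- if (length(ops) == 1L) ops else sample(ops, 1L)
  opt <- switch(op,
    add = c(opt, sample(absent, 1L)),
    remove = opt[-sample.int(length(opt), 1L)],
    swap = c(opt[-sample.int(length(opt), 1L)], sample(absent, 1L))
  )
  sort(c(config$mandatory, opt))
}

.crossover_chromosomes <- function(p1, p2, candidates, config) {
  # Uniform set-crossover: each candidate locus inherited from a random parent.
  from1 <- runif(length(candidates)) < 0.5
  opt <- candidates[
    (from1 & candidates %in% p1) | (!from1 & candidates %in% p2)
  ]
  sort(c(config$mandatory, opt))
}

#' Evolve a protein selection with the genetic algorithm
#'
#' Per generation the population is ranked by [ga_fitness()], the top
#' `survivors` parent `offspring` children (crossover then mutation, each
#' applied with its configured probability), and `fresh` new random
#' chromosomes complete the next population.  Survivors themselves do not
#' re-enter the population, so the best chromosome ever seen is tracked in
#' a hall of fame of size one and returned.  Fitness values are cached by
#' protein set.
#'
#' @param pss_matrix Proteins x drug-pairs consensus PSS matrix.
#' @param observed Observed HSA score per pair.
#' @param candidates Candidate protein pool (default: all rows of
#'   `pss_matrix` except the mandatory members).
#' @param config A [ga_config()].
#' @return List of class `ga_result`: `best_subset`, `best_fitness`,
#'   `trace` (data frame generation / best_fitness / best_subset), and the
#'   config.
#' @export
ga_evolve <- function(pss_matrix, observed, candidates = NULL,
                      config = ga_config()) {
  stopifnot(inherits(config, "ga_config"))
  if (is.null(candidates)) {
    candidates <- setdiff(rownames(pss_matrix), config$mandatory)
  }
  missing <- setdiff(config$mandatory, rownames(pss_matrix))
  if (length(missing)) {
    stop("mandatory protein(s) missing from the PSS matrix: ", paste(missing, collapse = ", "))
  }
  if (length(candidates) + length(config$mandatory) < config$len_min) {
    stop("candidate pool smaller than the minimum chromosome length")
  }
  if (!is.null(config$seed)) set.seed(config$seed)

  cache <- new.env(parent = emptyenv())
  fit <- function(chrom) {
    key <- paste(chrom, collapse = "|")
    v <- cache[[key]]
    if (is.null(v)) {
      v <- ga_fitness(chrom, pss_matrix, observed)
      cache[[key]] <- v
    }
    v
  }

  pop <- replicate(config$population, .random_chromosome(candidates, config),
    simplify = FALSE
  )
  best_subset <- NULL
  best_fitness <- -Inf
  trace <- vector("list", config$generations + 1L)

  for (gen in 0:config$generations) {
    fitness <- vapply(pop, fit, numeric(1))
    ord <- order(fitness, decreasing = TRUE)
    if (fitness[ord[1L]] > best_fitness) {
      best_fitness <- fitness[ord[1L]]
      best_subset <- pop[[ord[1L]]]
    }
    trace[[gen + 1L]] <- data.frame(
      generation = gen, best_fitness = best_fitness,
      best_subset = paste(best_subset, collapse = ","),
      stringsAsFactors = FALSE
    )
    if (gen == config$generations) break

    parents <- pop[ord[seq_len(config$survivors)]]
    children <- vector("list", config$offspring)
    for (i in seq_len(config$offspring)) {
      pair <- sample.int(length(parents), 2L, replace = TRUE)
      child <- if (runif(1) < config$p_crossover) {
        .crossover_chromosomes(
          parents[[pair[1L]]], parents[[pair[2L]]],
          candidates, config
        )
      } else {
        parents[[pair[1L]]]
      }
      if (runif(1) < config$p_mutation) {
        child <- .mutate_chromosome(child, candidates, config)
      }
      children[[i]] <- child
    }
    freshers <- replicate(config$fresh, .random_chromosome(candidates, config),
      simplify = FALSE
    )
    pop <- c(children, freshers)
  }

  structure(
    list(
      best_subset = best_subset, best_fitness = best_fitness,
      trace = do.call(rbind, trace), config = config
    ),
    class = "ga_result"
  )
}

#' @export
print.ga_result <- function(x, ...) {
  cat(
    "GA selection: best fitness ", format(x$best_fitness, digits = 4),
    " with ", length(x$best_subset), " proteins\n  ",
    paste(x$best_subset, collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Exhaustive best subset (brute-force reference)
#'
#' Enumerates every subset of the candidate pool (mandatory members always
#' included) and returns the fitness-optimal one.  Only feasible for small
#' pools (<= 15 candidates); used as the independent reference for the GA.
#'
#' @inheritParams ga_evolve
#' @param mandatory Proteins included in every subset.
#' @return List with `best_subset`, `best_fitness`.
#' @export
brute_force_selection <- function(pss_matrix, observed, candidates = NULL,
                                  mandatory = c("E2F1", "CASP3")) {
  if (is.null(candidates)) candidates <- setdiff(rownames(pss_matrix), mandatory)
  if (length(candidates) > 15L) stop("brute force limited to <= 15 candidates")
  best_subset <- sort(mandatory)
  best_fitness <- ga_fitness(best_subset, pss_matrix, observed)
  for (mask in seq_len(2^length(candidates) - 1L)) {
    opt <- candidates[bitwAnd(mask, 2^(seq_along(candidates) - 1L)) > 0]
    chrom <- sort(c(mandatory, opt))
    f <- ga_fitness(chrom, pss_matrix, observed)
    if (f > best_fitness) {
      best_fitness <- f
      best_subset <- chrom
    }
  }
  list(best_subset = best_subset, best_fitness = best_fitness)
}
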