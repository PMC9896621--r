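# Genetic-algorithm descriptor selection. A chromosome is a 0/1 gene vector
# over candidate descriptor columns; fitness is the Cohen's kappa of the
# chosen learner under leave-20%-out CV on the training partition. The GA
# uses tournament selection (size 3), uniform crossover, per-gene mutation
# 1/length and elitism 1; all operator choices are configurable.

#' GA configuration
#'
#' @param population_size,generations GA schedule.
#' @param crossover_rate probability a child is produced by uniform
#'   crossover rather than copied from its first parent.
#' @param mutation_rate per-gene flip probability; `NULL` means 1/length.
#' @param elitism_count chromosomes copied unchanged to the next generation.
#' @param tournament_size selection-tournament size.
#' @param init_density expected fraction of set genes in the initial
#'   population; `NULL` picks `min(0.5, 25/n_genes)` so early models stay
#'   near the target descriptor counts.
#' @param seed integer seed.
#' @return list of class `gfa_config`.
#' @export
gfa_config <- function(population_size = 50L, generations = 100L,
                       crossover_rate = 0.9, mutation_rate = NULL,
                       elitism_count = 1L, tournament_size = 3L,
                       init_density = NULL, seed = 1L) {
  if (population_size < 2L) stop("gfa_config: population must be >= 2")
  if (crossover_rate < 0 || crossover_rate > 1 ||
      (!is.null(mutation_rate) && (mutation_rate < 0 || mutation_rate > 1)))
    stop("gfa_config: rates must lie in [0, 1]")
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 elitism_count = as.integer(elitism_count),
                 tournament_size = as.integer(tournament_size),
                 init_density = init_density, seed = as.integer(seed)),
            class = "gfa_config")
}

#' Fitness of one chromosome: CV kappa of the learner on selected columns
#'
#' The all-zero chromosome gets the sentinel fitness -1 (worst possible)
#' instead of raising an error, so the GA can discard it silently.
#'
#' @param genes 0/1 vector over the columns of `fm$X`.
#' @param fm a [feature_matrix()] already restricted to the training
#'   partition (binary labels).
#' @param fold 0-based CV fold assignment per row (fixed for a whole GA run
#'   so fitnesses are comparable).
#' @param learner `"xgb"` (compiled fast path) or `"rf"`.
#' @param xgb_params,rf_params learner hyperparameters for fitness models
#'   (smaller than the defaults: the GA evaluates thousands of models).
#' @return Cohen's kappa (or -1 for the empty chromosome).
#' @export
evaluate_fitness <- function(genes, fm, fold, learner = "xgb",
                             xgb_params = list(nrounds = 6L, max_depth = 1L,
                                               eta = 0.65, lambda = 1,
                                               nbins = 16L, min_hess = 1e-3),
                             rf_params = list(ntree = 30L, max_depth = 10L,
                                              min_node = 5L)) {
  cols <- which(genes > 0)
  if (!length(cols)) return(-1)
  X <- fm$X[, cols, drop = FALSE]
  y <- as.numeric(fm$labels == "active")
  if (learner == "xgb") {
    p <- xgb_params
    return(cpp_gbt_cv_kappa(X, y, as.integer(fold), p$nrounds, p$max_depth,
                            p$eta, p$lambda, p$nbins, p$min_hess))
  }
  # rf fitness path (slower; kept for parity with the scan winner choice)
  pred <- integer(length(y))
  for (f in sort(unique(fold))) {
    tr <- fold != f
    m <- cpp_rf_fit(X[tr, , drop = FALSE], as.integer(y[tr]), 2L,
                    rf_params$ntree, max(1L, floor(sqrt(ncol(X)))),
                    rf_params$max_depth, rf_params$min_node, 1L + f)
    pr <- cpp_rf_predict(m, X[!tr, , drop = FALSE])
    pred[!tr] <- as.integer(pr[, 2] > 0.5)
  }
  cohens_kappa(confusion_counts(y, pred, c(0, 1)))
}

#' Run one GA phase over an arbitrary fitness function
#'
#' With `elitism_count >= 1` the best-ever fitness is non-decreasing across
#' generations; identical config and seed give identical results. Fitness
#' values are memoized, so converged populations are cheap.
#'
#' @param n_genes chromosome length.
#' @param fitness_fn function(genes) -> numeric fitness.
#' @param config a [gfa_config()].
#' @param cardinality optional `c(min, max)`; outside it a soft penalty
#'   `lambda * excess` is subtracted from the fitness.
#' @param lambda penalty weight per descriptor outside the range.
#' @param init_population optional 0/1 matrix seeding the initial population
#'   (rows recycled to `population_size`).
#' @return list: `best_genes`, `best_fitness` (raw, unpenalized),
#'   `history` (per-generation best/mean penalized fitness),
#'   `final_population`, `final_fitness`.
#' @export
run_gfa <- function(n_genes, fitness_fn, config, cardinality = NULL,
                    lambda = 0.05, init_population = NULL) {
  if (n_genes < 2L) stop("run_gfa: need at least 2 candidate descriptors")
  pm <- config$mutation_rate %||% (1 / n_genes)
  dens <- config$init_density %||% min(0.5, 25 / n_genes)
  cache <- new.env(parent = emptyenv())
  eval_raw <- function(genes) {
    key <- paste0("k", paste(which(genes > 0), collapse = ","))
    hit <- get0(key, envir = cache)
    if (!is.null(hit)) return(hit)
    val <- fitness_fn(genes)
    assign(key, val, envir = cache)
    val
  }
  penalize <- function(genes, raw) {
    if (is.null(cardinality)) return(raw)
    k <- sum(genes)
    raw - lambda * max(0, k - cardinality[2]) -
      lambda * max(0, cardinality[1] - k)
  }
  with_seed(config$seed, {
    pop <- if (is.null(init_population))
      matrix(rbinom(config$population_size * n_genes, 1L, dens),
             config$population_size, n_genes)
    else
      init_population[rep_len(seq_len(nrow(init_population)),
                              config$population_size), , drop = FALSE]
    best_genes <- NULL; best_fit <- -Inf; best_raw <- -Inf
    hist_best <- hist_mean <- numeric(config$generations)
    fit <- numeric(config$population_size)
    for (gen in seq_len(config$generations)) {
      raw <- apply(pop, 1, eval_raw)
      for (i in seq_len(config$population_size))
        fit[i] <- penalize(pop[i, ], raw[i])
      gb <- which.max(fit)
      if (fit[gb] > best_fit) {
        best_fit <- fit[gb]; best_raw <- raw[gb]; best_genes <- pop[gb, ]
      }
      hist_best[gen] <- best_fit
      hist_mean[gen] <- mean(fit)
      if (gen == config$generations) break
      newpop <- matrix(0L, config$population_size, n_genes)
      n_elite <- min(config$elitism_count, config$population_size)
      if (n_elite > 0) {
        elite <- order(-fit)[seq_len(n_elite)]
        newpop[seq_len(n_elite), ] <- pop[elite, , drop = FALSE]
        # best-ever re-injected with slot 1 to guarantee monotonicity
        newpop[1L, ] <- best_genes
      }
      tournament <- function() {
        cand <- sample.int(config$population_size, config$tournament_size,
                           replace = TRUE)
        cand[which.max(fit[cand])]
      }
      for (i in seq.int(n_elite + 1L, config$population_size)) {
        p1 <- pop[tournament(), ]
        if (runif(1) < config$crossover_rate) {
          p2 <- pop[tournament(), ]
          mask <- runif(n_genes) < 0.5
          child <- ifelse(mask, p1, p2)
        } else child <- p1
        flip <- runif(n_genes) < pm
        child[flip] <- 1L - child[flip]
        newpop[i, ] <- child
      }
      pop <- newpop
    }
    list(best_genes = best_genes, best_fitness = best_raw,
         history = data.frame(generation = seq_len(config$generations),
                              best = hist_best, mean = hist_mean),
         final_population = pop, final_fitness = fit)
  })
}

# Selection frequency of each gene in a population, used to truncate the
# phase-1 candidate pool; ties are broken by frequency within the best
# decile of the population, then by column order.
.gene_frequency <- function(pop, fit) {
  freq <- colMeans(pop)
  decile <- order(-fit)[seq_len(max(1L, ceiling(nrow(pop) / 10)))]
  freq_top <- colMeans(pop[decile, , drop = FALSE])
  list(freq = freq, freq_top = freq_top)
}

#' Two-phase genetic descriptor selection
#'
#' Phase 1 (population 50, 100 generations) explores the full candidate pool
#' and truncates it to the 50 descriptors most frequently selected in the
#' final population. Phase 2 refines those 50 into a 10-20 descriptor model
#' under a soft cardinality penalty; the full-scale schedule is population
#' 500 x 5000 generations (`preset = "full"`), the desk-scale preset runs
#' 50 x 200. If the final best chromosome still falls outside 10-20 genes it
#' is repaired using final-population gene frequencies.
#'
#' @param fm training-partition [feature_matrix()] (binary labels).
#' @param learner fitness learner, `"xgb"` or `"rf"`.
#' @param seed integer seed (folds and both GA phases).
#' @param preset `"desk"` or `"full"` phase-2 schedule.
#' @param cardinality target descriptor-count range for phase 2.
#' @param phase1_keep candidate-pool size after phase 1.
#' @param nfolds CV folds for the fitness kappa.
#' @param repair enforce the cardinality range on the returned model.
#' @return list: `descriptors` (selected column names), `fitness` (CV kappa
#'   of the final model), `phase1_descriptors`, `history1`, `history2`.
#' @export
two_phase_select <- function(fm, learner = "xgb", seed = 1L,
                             preset = c("desk", "full"),
                             cardinality = c(10L, 20L), phase1_keep = 50L,
                             nfolds = 5L, repair = TRUE) {
  preset <- match.arg(preset)
  cols <- colnames(fm$X)
  fold <- with_seed(child_seed(seed, 3L),
                    sample(rep_len(seq_len(nfolds), nrow(fm$X)))) - 1L
  # fitness models only ever compare bin boundaries, so the candidate matrix
  # is prebinned once and every GA evaluation works on bin indices
  fmb <- structure(list(X = cpp_prebin(fm$X, 16L), labels = fm$labels,
                        compound_of = fm$compound_of),
                   class = "feature_matrix")
  fit_fn <- function(genes) evaluate_fitness(genes, fmb, fold, learner)

  history1 <- NULL
  phase1_descriptors <- cols
  if (length(cols) >= phase1_keep) {
    cfg1 <- gfa_config(population_size = 50L, generations = 100L,
                       seed = child_seed(seed, 101L))
    # mild parsimony pressure: phase 1's goal is a <= phase1_keep pool, so
    # chromosomes beyond that size are penalized lightly
    g1 <- run_gfa(length(cols), fit_fn, cfg1,
                  cardinality = c(5L, phase1_keep), lambda = 0.02)
    fr <- .gene_frequency(g1$final_population, g1$final_fitness)
    ord <- order(-fr$freq, -fr$freq_top, seq_along(cols))
    keep <- sort(ord[seq_len(phase1_keep)])
    phase1_descriptors <- cols[keep]
    history1 <- g1$history
  } else {
    message(sprintf("two_phase_select: %d candidate columns < %d, phase 1 skipped",
                    length(cols), phase1_keep))
    keep <- seq_along(cols)
  }

  fm2 <- structure(list(X = fmb$X[, keep, drop = FALSE], labels = fm$labels,
                        compound_of = fm$compound_of),
                   class = "feature_matrix")
  fit_fn2 <- function(genes) evaluate_fitness(genes, fm2, fold, learner)
  cfg2 <- if (preset == "full")
    gfa_config(population_size = 500L, generations = 5000L,
               seed = child_seed(seed, 202L))
  else
    gfa_config(population_size = 50L, generations = 200L,
               seed = child_seed(seed, 202L))
  g2 <- run_gfa(length(keep), fit_fn2, cfg2, cardinality = cardinality)

  genes <- g2$best_genes
  if (repair) {
    fr <- .gene_frequency(g2$final_population, g2$final_fitness)
    k <- sum(genes)
    if (k > cardinality[2]) {
      set_idx <- which(genes > 0)
      drop_n <- k - cardinality[2]
      genes[set_idx[order(fr$freq[set_idx])][seq_len(drop_n)]] <- 0L
    } else if (k < cardinality[1]) {
      unset <- which(genes == 0)
      add_n <- cardinality[1] - k
      genes[unset[order(-fr$freq[unset])][seq_len(add_n)]] <- 1L
    }
  }
  list(descriptors = phase1_descriptors[genes > 0],
       fitness = fit_fn2(genes),
       phase1_descriptors = phase1_descriptors,
       history1 = history1, history2 = g2$history)
}
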