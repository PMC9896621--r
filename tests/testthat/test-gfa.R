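# Cheap deterministic fitness functions exercise the GA mechanics without
# model training; model-based fitness is covered at the end and in the
# acceptance suite.

test_that("no variation operators means the population never changes", {
  init <- matrix(rep(c(1L, 0L, 1L, 0L, 0L, 1L), 4), 4, 6, byrow = TRUE)
  cfg <- gfa_config(population_size = 4, generations = 10,
                    crossover_rate = 0, mutation_rate = 0, seed = 3)
  g <- run_gfa(6, function(genes) sum(genes), cfg, init_population = init)
  expect_equal(g$best_genes, init[1, ])
  expect_true(all(apply(g$final_population, 1, identical, init[1, ])))
})

test_that("history bookkeeping and elitism monotonicity", {
  weights <- c(5, -2, 3, 0.5, -1, 2, 1, -3, 0.2, 4)
  fit_fn <- function(genes) sum(genes * weights) - 0.1 * sum(genes)
  cfg <- gfa_config(population_size = 20, generations = 40, seed = 11)
  g <- run_gfa(10, fit_fn, cfg)
  expect_equal(nrow(g$history), 40)
  expect_true(all(diff(g$history$best) >= 0))
  # optimum: all positive-weight genes on
  expect_equal(which(g$best_genes == 1), which(weights > 0.1))
  # seed determinism
  g2 <- run_gfa(10, fit_fn, cfg)
  expect_identical(g$best_genes, g2$best_genes)
  expect_identical(g$history, g2$history)
})

test_that("selection pressure raises mean fitness early on", {
  weights <- seq(-1, 1, length.out = 30)
  fit_fn <- function(genes) sum(genes * weights)
  g <- run_gfa(30, fit_fn, gfa_config(30, 30, seed = 2))
  expect_gt(mean(g$history$mean[6:10]), mean(g$history$mean[1:5]))
})

test_that("cardinality penalty pushes the best model into range", {
  fit_fn <- function(genes) 0.5  # flat landscape: only the penalty matters
  g <- run_gfa(40, fit_fn, gfa_config(30, 50, seed = 5),
               cardinality = c(10, 20), lambda = 0.05)
  expect_true(sum(g$best_genes) >= 10 && sum(g$best_genes) <= 20)
})

test_that("fitness sentinel, constant columns, and planted-column ordering", {
  fm <- toy_signal_matrix(n_cmp = 30, poses_per = 4, p_noise = 7, seed = 12)
  fm$X <- cbind(fm$X, CONST = 1)
  fold <- rep_len(0:4, nrow(fm$X))
  expect_equal(evaluate_fitness(rep(0L, ncol(fm$X)), fm, fold), -1)
  k_const <- evaluate_fitness(as.integer(colnames(fm$X) == "CONST"), fm, fold)
  expect_lt(abs(k_const), 0.1)
  # all three planted columns beat every single-column model (sweep oracle)
  k_all <- evaluate_fitness(as.integer(grepl("^SIG", colnames(fm$X))), fm,
                            fold)
  singles <- vapply(seq_len(ncol(fm$X)), function(j) {
    g <- integer(ncol(fm$X)); g[j] <- 1L
    evaluate_fitness(g, fm, fold)
  }, numeric(1))
  expect_gt(k_all, max(singles))
  # rf fitness path agrees on the planted signal
  k_rf <- evaluate_fitness(as.integer(grepl("^SIG", colnames(fm$X))), fm,
                           fold, learner = "rf")
  expect_gt(k_rf, max(0.5, k_const))
})

test_that("two-phase selection: 471 -> 50 -> 10..20 and recovery", {
  posevote:::with_seed(31, {
    n <- 220
    p <- 471
    lab <- rep(c("active", "inactive"), length.out = n)
    X <- matrix(rbinom(n * p, 1, 0.25), n, p)
    X[, 7] <- rbinom(n, 1, ifelse(lab == "active", 0.92, 0.08))
    colnames(X) <- sprintf("D%03d", seq_len(p))
    rownames(X) <- sprintf("p%03d", seq_len(n))
    co <- setNames(sub("#.*", "", rownames(X)), rownames(X))
    fm <- structure(list(X = X, labels = setNames(lab, rownames(X)),
                         compound_of = co), class = "feature_matrix")
    sel <- two_phase_select(fm, seed = 6)
    expect_length(sel$phase1_descriptors, 50)
    expect_true(length(sel$descriptors) >= 10 && length(sel$descriptors) <= 20)
    # the single informative column always survives both phases
    expect_true("D007" %in% sel$phase1_descriptors)
    expect_true("D007" %in% sel$descriptors)
    expect_equal(nrow(sel$history1), 100)
    expect_equal(nrow(sel$history2), 200)
    # phase 1 is skipped (with a message) below the truncation size
    fm_small <- structure(list(X = X[, 1:30], labels = fm$labels,
                               compound_of = co), class = "feature_matrix")
    expect_message(s2 <- two_phase_select(fm_small, seed = 6), "skipped")
    expect_null(s2$history1)
  })
})

test_that("two-phase selection is seed-deterministic", {
  fm <- toy_signal_matrix(n_cmp = 24, poses_per = 3, p_noise = 12, seed = 8)
  s1 <- two_phase_select(fm, seed = 4)
  s2 <- two_phase_select(fm, seed = 4)
  expect_identical(s1$descriptors, s2$descriptors)
  expect_identical(s1$history2, s2$history2)
})

test_that("invalid configs are rejected", {
  expect_error(gfa_config(population_size = 1), "population")
  expect_error(gfa_config(crossover_rate = 1.5), "rates")
  expect_error(run_gfa(1, identity, gfa_config()), "at least 2")
})
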