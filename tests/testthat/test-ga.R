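test_that("fitness is the reciprocal MSE with an epsilon floor", {
  expect_equal(ga_fitness(0.5), 2)
  expect_equal(ga_fitness(1), 1)
  expect_equal(ga_fitness(0), 1e12)
  expect_error(ga_fitness(-1), "non-negative")
})

test_that("single-point crossover swaps the gene tail and conserves genes", {
  a <- c(hidden_size = 8, learning_rate = 0.1, mu = 0.5, mu_dec = 0.2)
  b <- c(hidden_size = 32, learning_rate = 0.9, mu = 2, mu_dec = 0.8)
  kids <- single_point_crossover(a, b, point = 2)
  expect_equal(unname(kids$child_a), c(8, 0.1, 2, 0.8))
  expect_equal(unname(kids$child_b), c(32, 0.9, 0.5, 0.2))
  # multiset of genes conserved across children at every cut point
  for (pt in 1:3) {
    kids <- single_point_crossover(a, b, point = pt)
    for (g in 1:4) {
      expect_setequal(unname(c(kids$child_a[g], kids$child_b[g])),
                      unname(c(a[g], b[g])))
    }
  }
  # identical parents yield identical children; apply = FALSE copies
  same <- single_point_crossover(a, a, point = 3)
  expect_equal(same$child_a, a)
  off <- single_point_crossover(a, b, point = 1, apply = FALSE)
  expect_equal(off$child_a, a)
  expect_equal(off$child_b, b)
})

test_that("mutation respects probabilities and bounds", {
  g <- c(hidden_size = 8, learning_rate = 0.1, mu = 0.5, mu_dec = 0.2)
  set.seed(41)
  expect_equal(mutate_chromosome(g, mp = 0), g)
  b <- gene_bounds()
  for (rep in 1:50) {
    m <- mutate_chromosome(g, mp = 1)
    expect_true(all(m >= b["lower", ] & m <= b["upper", ]))
    expect_equal(m[["hidden_size"]], round(m[["hidden_size"]]))
  }
  set.seed(7); m1 <- mutate_chromosome(g, 0.5)
  set.seed(7); m2 <- mutate_chromosome(g, 0.5)
  expect_identical(m1, m2)
})

test_that("random chromosomes always satisfy the gene bounds", {
  set.seed(42)
  b <- gene_bounds()
  for (rep in 1:100) {
    g <- random_chromosome()
    expect_true(all(g >= b["lower", ] & g <= b["upper", ]))
    expect_equal(g[["hidden_size"]], round(g[["hidden_size"]]))
  }
})

test_that("a one-generation, two-individual run returns the fitter individual", {
  toy <- two_gaussian_toy(n_per = 10, seed = 43)
  res <- ga_evolve(toy$x, toy$labels, ga_config(ps = 2, ngen = 1,
                                                max_epochs_evolve = 5),
                   n_out = 2, final_max_epochs = 5, seed = 43)
  expect_equal(res$best$fitness, res$log$best_fitness[1])
  expect_equal(nrow(res$log), 1)
})

test_that("evolution on a separable toy problem improves and is monotone", {
  toy <- two_gaussian_toy(n_per = 15, seed = 44)
  res <- ga_evolve(toy$x, toy$labels,
                   ga_config(ps = 8, ngen = 5, max_epochs_evolve = 10),
                   n_out = 2, final_max_epochs = 20, seed = 44)
  expect_true(all(diff(res$log$best_fitness) >= 0))      # elitism guarantee
  expect_gte(res$log$best_fitness[5], res$log$best_fitness[1])
  expect_lte(res$best$mse, 1 / res$log$best_fitness[1] + 1e-12)
  b <- gene_bounds()
  genes <- as.matrix(res$log[, c("hidden_size", "learning_rate", "mu", "mu_dec")])
  expect_true(all(t(genes) >= b["lower", ] & t(genes) <= b["upper", ]))
})

test_that("a fixed seed replays the evolution log bit-identically", {
  toy <- two_gaussian_toy(n_per = 10, seed = 45)
  cfg <- ga_config(ps = 4, ngen = 3, max_epochs_evolve = 5)
  r1 <- ga_evolve(toy$x, toy$labels, cfg, n_out = 2, final_max_epochs = 5,
                  seed = 45)
  r2 <- ga_evolve(toy$x, toy$labels, cfg, n_out = 2, final_max_epochs = 5,
                  seed = 45)
  expect_identical(r1$log, r2$log)
  expect_identical(r1$best$chromosome, r2$best$chromosome)
})

test_that("the next generation preserves population size and bounds", {
  set.seed(46)
  cfg <- ga_config(ps = 10, ngen = 1)
  pop <- replicate(10, random_chromosome(), simplify = FALSE)
  fitnesses <- sort(runif(10), decreasing = TRUE)
  for (sel in c("rank", "roulette")) {
    cfg$selection <- sel
    nxt <- faceage:::next_generation(pop, fitnesses, cfg)
    expect_length(nxt, 10)
    b <- gene_bounds()
    for (g in nxt) expect_true(all(g >= b["lower", ] & g <= b["upper", ]))
    expect_identical(nxt[[1]], pop[[1]])  # elite carried unchanged
  }
})

test_that("a diverging candidate receives fitness zero without aborting", {
  toy <- two_gaussian_toy(n_per = 6, seed = 47)
  res <- with_mocked_bindings(
    ga_evolve(toy$x, toy$labels, ga_config(ps = 2, ngen = 1,
                                           max_epochs_evolve = 3),
              n_out = 2, final_max_epochs = 3, seed = 47),
    mlp_train = function(net, x, targets, config) {
      faceage:::diverged("forced divergence")
    }
  )
  expect_equal(res$best$fitness, 0)
})
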