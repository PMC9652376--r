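## Genetic-algorithm evolution of network configurations.
##
## A chromosome encodes (hidden_size, learning_rate, mu, mu_dec). Each
## candidate network is trained and scored by fitness = 1/MSE; the
## population is ranked, the top half recombined by single-point crossover,
## mutated, and the single fittest individual carried over unchanged
## (elitism), so the best fitness is monotone non-decreasing.

GENE_NAMES <- c("hidden_size", "learning_rate", "mu", "mu_dec")

#' Gene bounds for network-configuration chromosomes
#'
#' @return 2 x 4 matrix (rows lower/upper) over
#'   hidden_size in [1, 64], learning_rate in [1e-4, 1], mu in [1e-4, 10],
#'   mu_dec in [0.01, 0.99].
#' @export
gene_bounds <- function() {
  b <- matrix(c(1, 64, 1e-4, 1, 1e-4, 10, 0.01, 0.99), nrow = 2)
  dimnames(b) <- list(c("lower", "upper"), GENE_NAMES)
  b
}

#' Fitness of a trained candidate network
#'
#' The reciprocal of the training mean squared error, floored at
#' epsilon = 1e-12 so a perfect fit yields fitness 1e12.
#'
#' @param mse Non-negative training MSE.
#' @return Fitness value; larger is fitter.
#' @export
ga_fitness <- function(mse) {
  if (any(mse < 0)) stop("mse must be non-negative", call. = FALSE)
  1 / pmax(mse, 1e-12)
}

#' Genetic-algorithm configuration
#'
#' Defaults follow the study configuration: population size 100,
#' 25 generations, mutation probability 0.1, crossover probability 0.5,
#' one elite individual.
#'
#' @param ps Population size (even, >= 2).
#' @param ngen Number of generations (>= 1).
#' @param mp Per-gene mutation probability.
#' @param cp Crossover probability.
#' @param elitism Number of elites carried unchanged (default 1).
#' @param max_epochs_evolve Per-candidate training epoch budget during
#'   evolution (default 50; the final best is retrained with the full
#'   budget of its [network_config()]).
#' @param selection `"rank"` (top half are parents, paired at random) or
#'   `"roulette"` (fitness-proportional).
#' @param trainer Trainer passed to each candidate's [network_config()].
#' @return List of class `"ga_config"`.
#' @export
ga_config <- function(ps = 100L, ngen = 25L, mp = 0.1, cp = 0.5,
                      elitism = 1L, max_epochs_evolve = 50L,
                      selection = c("rank", "roulette"),
                      trainer = c("lm", "gdm")) {
  selection <- match.arg(selection)
  trainer <- match.arg(trainer)
  stopifnot(ps >= 2, ps %% 2 == 0, ngen >= 1, mp >= 0, mp <= 1,
            cp >= 0, cp <= 1, elitism >= 0)
  structure(list(ps = as.integer(ps), ngen = as.integer(ngen), mp = mp,
                 cp = cp, elitism = as.integer(elitism),
                 max_epochs_evolve = as.integer(max_epochs_evolve),
                 selection = selection, trainer = trainer),
            class = "ga_config")
}

#' Sample a random chromosome within the gene bounds
#' @return Named numeric vector of the 4 genes (hidden_size integral).
#' @export
random_chromosome <- function() {
  b <- gene_bounds()
  g <- stats::runif(4, b["lower", ], b["upper", ])
  g[1] <- round(g[1])
  names(g) <- GENE_NAMES
  g
}

validate_chromosome <- function(g) {
  b <- gene_bounds()
  stopifnot(length(g) == 4, all(g >= b["lower", ] - 1e-12),
            all(g <= b["upper", ] + 1e-12), g[1] == round(g[1]))
  invisible(g)
}

#' Single-point crossover of two chromosomes
#'
#' When `apply` is TRUE the genes at indices >= `point` are exchanged
#' between the parents; otherwise the children are copies of the parents.
#'
#' @param parent_a,parent_b Chromosomes (length-4 gene vectors).
#' @param point Cut index in 1..3 (cut lies before gene `point + 1`).
#' @param apply Whether the crossover is applied (drawn with probability
#'   Cp by the caller).
#' @return List with `child_a`, `child_b`.
#' @export
single_point_crossover <- function(parent_a, parent_b, point, apply = TRUE) {
  stopifnot(point %in% 1:3)
  ca <- parent_a; cb <- parent_b
  if (apply) {
    idx <- (point + 1L):4L
    ca[idx] <- parent_b[idx]
    cb[idx] <- parent_a[idx]
  }
  list(child_a = ca, child_b = cb)
}

#' Mutate a chromosome
#'
#' Each gene is independently resampled uniformly within its bounds with
#' probability `mp`.
#'
#' @param chromosome Length-4 gene vector.
#' @param mp Per-gene mutation probability.
#' @return Mutated chromosome (within bounds; hidden_size integral).
#' @export
mutate_chromosome <- function(chromosome, mp) {
  b <- gene_bounds()
  hit <- stats::runif(4) < mp
  if (any(hit)) {
    fresh <- stats::runif(4, b["lower", ], b["upper", ])
    chromosome[hit] <- fresh[hit]
    chromosome[1] <- round(chromosome[1])
  }
  chromosome
}

chromosome_to_config <- function(g, goal = 1e-3, max_epochs = 200L,
                                 trainer = "lm") {
  network_config(hidden_size = as.integer(g[1]), learning_rate = g[2],
                 mu = g[3], mu_dec = g[4], goal = goal,
                 max_epochs = max_epochs, trainer = trainer)
}

train_candidate <- function(g, x, targets, n_out, max_epochs, trainer) {
  cfg <- chromosome_to_config(g, max_epochs = max_epochs, trainer = trainer)
  net <- mlp_init(ncol(x), cfg$hidden_size, n_out)
  fit <- tryCatch(mlp_train(net, x, targets, cfg),
                  faceage_divergence = function(e) NULL)
  if (is.null(fit)) {
    list(fit = NULL, mse = Inf, fitness = 0)
  } else {
    list(fit = fit, mse = fit$mse, fitness = ga_fitness(fit$mse))
  }
}

#' Evolve a population of network configurations
#'
#' Initializes `ps` random chromosomes; each generation trains every
#' candidate network on the training set, scores fitness = 1/MSE, sorts by
#' descending fitness, carries the elite unchanged, and fills the next
#' generation by single-point crossover over the selected parents followed
#' by mutation. A candidate whose training diverges receives fitness 0.
#' After the last generation the best individual is retrained with the
#' full `final_max_epochs` budget.
#'
#' @param x Training inputs (N x K eigen-weight matrix).
#' @param labels 0-based class labels (length N).
#' @param config A [ga_config()].
#' @param n_out Number of output classes (default 8).
#' @param final_max_epochs Epoch budget for the final retraining (default
#'   200).
#' @param seed Optional integer seed governing the whole evolution.
#' @return List of class `"ga_result"`: `best` (list chromosome/fit/mse/
#'   fitness), `log` (data.frame generation/best_fitness/mean_fitness/
#'   best genes), `config`.
#' @export
ga_evolve <- function(x, labels, config = ga_config(), n_out = 8L,
                      final_max_epochs = 200L, seed = NULL) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("empty training data", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  targets <- one_hot(labels, n_out)
  pop <- replicate(config$ps, random_chromosome(), simplify = FALSE)
  log_rows <- list()
  best <- NULL
  for (gen in seq_len(config$ngen)) {
    evals <- lapply(pop, function(g) {
      res <- train_candidate(g, x, targets, n_out,
                             config$max_epochs_evolve, config$trainer)
      c(list(chromosome = g), res)
    })
    fitnesses <- vapply(evals, function(e) e$fitness, numeric(1))
    ord <- order(fitnesses, decreasing = TRUE)
    evals <- evals[ord]
    fitnesses <- fitnesses[ord]
    if (is.null(best) || fitnesses[1] > best$fitness) best <- evals[[1]]
    log_rows[[gen]] <- data.frame(
      generation = gen, best_fitness = best$fitness,
      mean_fitness = mean(fitnesses),
      t(best$chromosome))
    if (gen == config$ngen) break
    pop <- next_generation(lapply(evals, `[[`, "chromosome"),
                           fitnesses, config)
  }
  final_cfg <- chromosome_to_config(best$chromosome,
                                    max_epochs = final_max_epochs,
                                    trainer = config$trainer)
  final_net <- mlp_init(ncol(x), final_cfg$hidden_size, n_out)
  final_fit <- tryCatch(mlp_train(final_net, x, targets, final_cfg),
                        faceage_divergence = function(e) NULL)
  if (!is.null(final_fit) && final_fit$mse <= best$mse) {
    best$fit <- final_fit
    best$mse <- final_fit$mse
    best$fitness <- ga_fitness(final_fit$mse)
  }
  structure(list(best = best, log = do.call(rbind, log_rows),
                 config = config),
            class = "ga_result")
}

next_generation <- function(chromosomes, fitnesses, config) {
  ps <- config$ps
  elite <- utils::head(chromosomes, config$elitism)
  if (config$selection == "rank") {
    parents <- chromosomes[seq_len(max(2L, ps %/% 2L))]
  } else {
    w <- fitnesses / sum(fitnesses)
    if (!all(is.finite(w))) w <- rep(1 / ps, ps)
    parents <- chromosomes[sample.int(ps, max(2L, ps %/% 2L),
                                      replace = TRUE, prob = w)]
  }
  children <- list()
  while (length(children) < ps - length(elite)) {
    pair <- sample.int(length(parents), 2L)
    kids <- single_point_crossover(parents[[pair[1]]], parents[[pair[2]]],
                                   point = sample.int(3L, 1L),
                                   apply = stats::runif(1) < config$cp)
    children[[length(children) + 1L]] <- mutate_chromosome(kids$child_a, config$mp)
    if (length(children) < ps - length(elite)) {
      children[[length(children) + 1L]] <- mutate_chromosome(kids$child_b, config$mp)
    }
  }
  c(elite, children)
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("GA evolution: %d generations, population %d\n",
              x$config$ngen, x$config$ps))
  cat(sprintf("  best fitness %.4g (training MSE %.4g)\n",
              x$best$fitness, x$best$mse))
  cat("  best genes:\n")
  print(round(x$best$chromosome, 5))
  invisible(x)
}
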