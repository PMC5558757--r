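# Genetic algorithm over tree structure (pruning), per-node classifier
# family and hyperparameters; fitness is the validation error rate of the
# tree fitted on the training split.

#' Genetic algorithm configuration
#'
#' Defaults are sized for minutes-scale runs on per-variant datasets:
#' population 40, 25 generations, tournament selection of 3, uniform
#' crossover with probability 0.9, per-gene mutation 0.03, elitism 1.
#'
#' @param population_size,generations,tournament_size GA dimensions.
#' @param crossover_prob Probability a mating pair undergoes uniform
#'   crossover.
#' @param mutation_prob Per-gene probability of redrawing a gene uniformly.
#' @param elitism_count Best genomes copied unchanged each generation.
#' @param seed Integer master seed.
#' @param n_workers Parallel workers for fitness evaluation (results are
#'   bit-identical to serial evaluation).
#' @return List of class `ga_config`.
#' @export
ga_config <- function(population_size = 40L, generations = 25L,
                      tournament_size = 3L, crossover_prob = 0.9,
                      mutation_prob = 0.03, elitism_count = 1L,
                      seed = 1L, n_workers = 1L) {
  stopifnot(population_size >= 1L, population_size >= elitism_count,
            elitism_count >= 0L, generations >= 0L, tournament_size >= 1L,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 tournament_size = as.integer(tournament_size),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 elitism_count = as.integer(elitism_count),
                 seed = as.integer(seed),
                 n_workers = as.integer(n_workers)),
            class = "ga_config")
}

# stable integer key of a genome; drives the per-genome RNG stream so that
# parallel and serial evaluation agree exactly
.genome_key <- function(genome) {
  k <- 0
  for (g in genome) k <- (k * 131 + as.numeric(g) + 7) %% 2147483647
  as.integer(k)
}

#' Evolve an omnivariate tree configuration
#'
#' Initializes the population uniformly at random from the seed, then runs
#' tournament selection, uniform crossover, per-gene mutation and elitism.
#' `fitness(genome)` is the error rate on the validation split of the tree
#' fitted on the training split; every fitness evaluation derives its RNG
#' stream from `(seed, genome)` so results are independent of evaluation
#' order and worker count. Ties are broken toward more pruned genomes, then
#' earlier appearance. With `elitism_count >= 1` the best-so-far fitness is
#' non-increasing across generations.
#'
#' @param train List with `X` (feature matrix) and `y` (binary labels).
#' @param validation Like `train`; must be disjoint from it.
#' @param config A [ga_config()].
#' @param tree_config An [omni_tree_config()].
#' @return List of class `ga_result`: `best_genome`, `best_fitness`,
#'   `best_tree` (fitted on `train`), `history` (data.frame of per-generation
#'   best/mean/worst fitness), `n_evaluated`.
#' @export
evolve <- function(train, validation, config = ga_config(),
                   tree_config = omni_tree_config()) {
  stopifnot(is.matrix(train$X), is.matrix(validation$X))
  if (!nrow(validation$X)) stop("evolve: empty validation set")
  levels <- genome_levels(tree_config)

  cache <- new.env(parent = emptyenv())
  eval_one <- function(genome) {
    s <- .mix_seed(config$seed, .genome_key(genome))
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(s)
    tree <- fit_tree(train$X, train$y, genome, tree_config, seed = s)
    pred <- predict_tree(tree, validation$X)
    err <- mean(pred != validation$y)
    if (!is.finite(err)) stop("evolve: non-finite fitness")
    list(fitness = err, tree = tree)
  }
  eval_population <- function(pop) {
    keys <- vapply(pop, function(g) paste(g, collapse = ","), character(1))
    todo <- !vapply(keys, exists, logical(1), envir = cache)
    uniq <- which(todo & !duplicated(keys))
    if (length(uniq)) {
      res <- if (config$n_workers > 1L) {
        parallel::mclapply(pop[uniq], eval_one,
                           mc.cores = config$n_workers)
      } else {
        lapply(pop[uniq], eval_one)
      }
      for (i in seq_along(uniq)) assign(keys[uniq[i]], res[[i]],
                                        envir = cache)
    }
    unname(vapply(keys, function(k) get(k, envir = cache)$fitness,
                  numeric(1)))
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  pop <- replicate(config$population_size, random_genome(tree_config),
                   simplify = FALSE)

  best <- NULL  # list(genome, fitness, active, order)
  consider <- function(genome, fitness, order) {
    cand <- list(genome = genome, fitness = fitness,
                 active = .n_active(genome, tree_config), order = order)
    if (is.null(best) || cand$fitness < best$fitness - 1e-12 ||
        (abs(cand$fitness - best$fitness) <= 1e-12 &&
           (cand$active < best$active ||
              (cand$active == best$active && FALSE)))) {
      best <<- cand
    }
  }
  history <- data.frame(generation = integer(), best = numeric(),
                        mean = numeric(), worst = numeric())
  order_counter <- 0L
  score_gen <- function(pop, gen) {
    fit <- eval_population(pop)
    for (i in seq_along(pop)) {
      order_counter <<- order_counter + 1L
      consider(pop[[i]], fit[i], order_counter)
    }
    history[nrow(history) + 1L, ] <<- list(gen, min(fit), mean(fit),
                                           max(fit))
    fit
  }

  fit <- score_gen(pop, 0L)
  gen <- 0L
  while (gen < config$generations) {
    gen <- gen + 1L
    elite_idx <- order(fit, vapply(pop, .n_active, integer(1),
                                   config = tree_config))
    elite <- pop[head(elite_idx, config$elitism_count)]
    tournament <- function() {
      idx <- sample.int(length(pop), config$tournament_size,
                        replace = TRUE)
      idx[which.min(fit[idx])]
    }
    children <- list()
    while (length(children) < config$population_size -
           config$elitism_count) {
      p1 <- pop[[tournament()]]
      p2 <- pop[[tournament()]]
      if (runif(1) < config$crossover_prob) {
        mask <- runif(length(p1)) < 0.5
        c1 <- ifelse(mask, p1, p2)
        c2 <- ifelse(mask, p2, p1)
      } else {
        c1 <- p1; c2 <- p2
      }
      mutate <- function(g) {
        hit <- runif(length(g)) < config$mutation_prob
        if (any(hit)) {
          g[hit] <- vapply(levels[hit], function(l) sample.int(l, 1L) - 1L,
                           integer(1))
        }
        as.integer(g)
      }
      children <- c(children, list(mutate(c1)), list(mutate(c2)))
    }
    pop <- c(elite, head(children, config$population_size -
                           config$elitism_count))
    fit <- score_gen(pop, gen)
  }

  best_entry <- get(paste(best$genome, collapse = ","), envir = cache)
  structure(list(best_genome = best$genome, best_fitness = best$fitness,
                 best_tree = best_entry$tree, history = history,
                 n_evaluated = length(ls(cache))),
            class = "ga_result")
}

#' Write a GA run log as TSV
#'
#' @param result A [evolve()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ga_log <- function(result, path) {
  stopifnot(inherits(result, "ga_result"))
  write.table(result$history, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
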