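# Feature-space reduction.
#
# Two routes: a genetic algorithm over binary feature-inclusion masks whose
# fitness is a class-separability rating (mean cross-class Euclidean
# distance over mean within-class distance), and an unsupervised PCA
# baseline. Distances are scale-sensitive, so callers standardize features
# (training-fold statistics) before either route.

#' Euclidean distance between two feature vectors
#' @param x,y numeric vectors of equal length.
#' @return `sqrt(sum((x - y)^2))`.
#' @export
euclidean <- function(x, y) {
  if (length(x) != length(y)) {
    abort("feature vectors differ in length", "eegstress_shape_error")
  }
  sqrt(sum((x - y)^2))
}

split_by_class <- function(x, labels) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(labels))
  lev <- sort(unique(as.character(labels)))
  if (length(lev) < 2L) {
    abort("need at least two classes", "eegstress_validation_error")
  }
  lapply(lev, function(l) x[labels == l, , drop = FALSE])
}

#' Mean cross-class distance
#'
#' Averages the Euclidean distance over every cross-class pair of feature
#' vectors, then over all unordered class pairs. With classes of unequal
#' sizes each class pair is normalized by `M_i * M_j`.
#'
#' @param classes list of numeric matrices, one per class (rows = vectors).
#' @return mean cross-class distance.
#' @export
inter_class_separability <- function(classes) {
  if (any(vapply(classes, nrow, integer(1)) == 0L)) {
    abort("every class must be non-empty", "eegstress_validation_error")
  }
  n <- length(classes)
  stopifnot(n >= 2L)
  tot <- 0
  npairs <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      tot <- tot + mean(cross_dist(classes[[i]], classes[[j]]))
      npairs <- npairs + 1L
    }
  }
  tot / npairs
}

#' Mean within-class distance
#'
#' Averages the Euclidean distance over all ordered pairs inside each class
#' (self-distances included, so the `M_i^2` pair count is the normalizer),
#' then averages over classes.
#'
#' @param classes list of numeric matrices, one per class.
#' @return mean within-class distance (0 when every class has collapsed to a
#'   point or is a singleton).
#' @export
intra_class_closeness <- function(classes) {
  if (any(vapply(classes, nrow, integer(1)) == 0L)) {
    abort("every class must be non-empty", "eegstress_validation_error")
  }
  mean(vapply(classes, function(m) mean(cross_dist(m, m)), numeric(1)))
}

# all-pairs Euclidean distances between the rows of a and of b, computed
# from explicit differences (the Gram-expansion shortcut loses precision
# near zero, where sqrt amplifies cancellation error)
cross_dist <- function(a, b) {
  tb <- t(b)
  m <- vapply(seq_len(nrow(a)), function(i) sqrt(colSums((tb - a[i, ])^2)),
              numeric(nrow(b)))
  t(matrix(m, nrow = nrow(b), ncol = nrow(a)))
}

#' Class-separability rating of a feature subset
#'
#' The ratio of [inter_class_separability()] to [intra_class_closeness()]
#' restricted to the masked feature columns: high when classes sit far apart
#' and are internally tight. Perfectly collapsed classes (zero within-class
#' distance) return the sentinel `1e12` so such masks rank highest instead
#' of failing.
#'
#' @param x numeric matrix, rows = feature vectors (standardized).
#' @param labels class label per row; both classes must be present.
#' @param mask logical (or 0/1) vector over columns; at least one bit set.
#' @return scalar rating.
#' @export
separability_rating <- function(x, labels, mask = NULL) {
  x <- as.matrix(x)
  if (is.null(mask)) mask <- rep(TRUE, ncol(x))
  mask <- as.logical(mask)
  if (!any(mask)) abort("empty feature mask", "eegstress_validation_error")
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) < 2L) {
    abort("need at least two classes", "eegstress_validation_error")
  }
  # one C-level pairwise distance computation serves both terms
  D <- as.matrix(stats::dist(x[, mask, drop = FALSE]))
  idx <- lapply(lev, function(l) which(labels == l))
  inter <- 0; npairs <- 0L
  for (i in seq_len(length(lev) - 1L)) {
    for (j in (i + 1L):length(lev)) {
      inter <- inter + mean(D[idx[[i]], idx[[j]]])
      npairs <- npairs + 1L
    }
  }
  inter <- inter / npairs
  intra <- mean(vapply(idx, function(k) mean(D[k, k]), numeric(1)))
  if (intra == 0) return(1e12)
  inter / intra
}

#' Genetic-algorithm configuration
#'
#' Defaults: population 50 evolved for 100 generations, tournament selection
#' of size 3, uniform crossover at rate 0.9, per-bit mutation 1/n_features,
#' elitism 1, generational replacement.
#'
#' @param population_size number of chromosomes (>= 2).
#' @param n_generations generations to evolve.
#' @param crossover_rate probability a selected pair undergoes uniform
#'   crossover.
#' @param mutation_rate_per_bit per-bit flip probability; `NULL` means
#'   1/n_features, resolved at run time.
#' @param tournament_size contestants per tournament.
#' @param elitism_count chromosomes copied unchanged each generation.
#' @param random_seed integer seed; every stochastic step derives from it.
#' @return list of class `ga_config`.
#' @export
ga_config <- function(population_size = 50L, n_generations = 100L,
                      crossover_rate = 0.9, mutation_rate_per_bit = NULL,
                      tournament_size = 3L, elitism_count = 1L,
                      random_seed = 1L) {
  stopifnot(population_size >= 2L, n_generations >= 1L,
            crossover_rate >= 0, crossover_rate <= 1,
            is.null(mutation_rate_per_bit) ||
              (mutation_rate_per_bit >= 0 && mutation_rate_per_bit <= 1),
            tournament_size >= 1L, elitism_count < population_size)
  structure(list(population_size = as.integer(population_size),
                 n_generations = as.integer(n_generations),
                 crossover_rate = crossover_rate,
                 mutation_rate_per_bit = mutation_rate_per_bit,
                 tournament_size = as.integer(tournament_size),
                 elitism_count = as.integer(elitism_count),
                 random_seed = as.integer(random_seed)),
            class = "ga_config")
}

#' Select features with a genetic algorithm
#'
#' Evolves binary inclusion masks over the feature columns, scoring each
#' chromosome with [separability_rating()] on the rows given (callers pass
#' training folds only so test data never touches the fitness). Offspring
#' that lose every bit are repaired by setting one uniformly random bit.
#' With elitism >= 1 the best-so-far fitness is non-decreasing; identical
#' seed and inputs reproduce the mask bit for bit.
#'
#' @param x standardized numeric matrix, rows = feature vectors.
#' @param labels class label per row.
#' @param cfg a [ga_config()].
#' @param init optional logical matrix (population_size x n_features) of
#'   starting chromosomes; default random with inclusion probability 0.5.
#' @return list with `mask` (logical), `fitness` (its rating), and `history`
#'   (best fitness per generation).
#' @export
ga_select <- function(x, labels, cfg = ga_config(), init = NULL) {
  x <- as.matrix(x)
  nf <- ncol(x)
  if (nf < 1L) abort("no feature columns", "eegstress_validation_error")
  pmut <- if (is.null(cfg$mutation_rate_per_bit)) 1 / nf else cfg$mutation_rate_per_bit
  np <- cfg$population_size
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$random_seed)

  pop <- if (is.null(init)) {
    matrix(stats::runif(np * nf) < 0.5, nrow = np)
  } else {
    stopifnot(nrow(init) == np, ncol(init) == nf)
    init
  }
  pop <- t(apply(pop, 1, repair_mask))

  fit <- apply(pop, 1, function(m) separability_rating(x, labels, m))
  best_i <- which.max(fit)
  best <- list(mask = pop[best_i, ], fitness = fit[best_i])
  history <- numeric(cfg$n_generations + 1L)
  history[1] <- best$fitness

  for (g in seq_len(cfg$n_generations)) {
    nxt <- matrix(FALSE, nrow = np, ncol = nf)
    n_elite <- cfg$elitism_count
    if (n_elite > 0L) {
      elite <- order(fit, decreasing = TRUE)[seq_len(n_elite)]
      nxt[seq_len(n_elite), ] <- pop[elite, , drop = FALSE]
    }
    i <- n_elite
    while (i < np) {
      p1 <- pop[tournament(fit, cfg$tournament_size), ]
      p2 <- pop[tournament(fit, cfg$tournament_size), ]
      if (stats::runif(1) < cfg$crossover_rate) {
        swap <- stats::runif(nf) < 0.5
        tmp <- p1[swap]; p1[swap] <- p2[swap]; p2[swap] <- tmp
      }
      for (child in list(p1, p2)) {
        if (i >= np) break
        flip <- stats::runif(nf) < pmut
        child <- xor(child, flip)
        i <- i + 1L
        nxt[i, ] <- repair_mask(child)
      }
    }
    pop <- nxt
    fit <- apply(pop, 1, function(m) separability_rating(x, labels, m))
    gen_best <- which.max(fit)
    if (fit[gen_best] > best$fitness) {
      best <- list(mask = pop[gen_best, ], fitness = fit[gen_best])
    }
    history[g + 1L] <- best$fitness
  }
  list(mask = best$mask, fitness = best$fitness, history = history)
}

repair_mask <- function(m) {
  if (!any(m)) m[sample.int(length(m), 1L)] <- TRUE
  m
}

tournament <- function(fit, size) {
  contenders <- sample.int(length(fit), size, replace = TRUE)
  contenders[which.max(fit[contenders])]
}

#' PCA baseline reduction
#'
#' Centers on the training rows, projects both matrices onto the leading
#' principal directions, and reports explained-variance ratios. By default
#' the smallest number of components reaching 95% cumulative explained
#' variance is retained.
#'
#' @param train numeric matrix the rotation is fitted on (>= 2 rows).
#' @param apply_to matrix projected with the training rotation (defaults to
#'   `train`).
#' @param n_components fixed component count, or `NULL` to use
#'   `variance_threshold`.
#' @param variance_threshold cumulative explained-variance target in (0, 1].
#' @return list with `train`, `projected`, `rotation`, `center`,
#'   `explained_variance_ratio` (non-increasing), `n_components`.
#' @export
pca_reduce <- function(train, apply_to = train, n_components = NULL,
                       variance_threshold = 0.95) {
  train <- as.matrix(train)
  stopifnot(nrow(train) >= 2L)
  pc <- stats::prcomp(train, center = TRUE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  if (is.null(n_components)) {
    n_components <- which(cumsum(evr) >= variance_threshold)[1]
    if (is.na(n_components)) n_components <- rank
  }
  if (n_components > rank) {
    abort(sprintf("n_components (%d) exceeds the data rank (%d)",
                  n_components, rank),
          "eegstress_validation_error")
  }
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  project <- function(m) {
    sweep(as.matrix(m), 2, pc$center, "-") %*% rot
  }
  list(train = project(train),
       projected = project(apply_to),
       rotation = rot,
       center = pc$center,
       explained_variance_ratio = evr,
       n_components = as.integer(n_components))
}
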