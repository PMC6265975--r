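test_that("euclidean distance satisfies its basic identities", {
  expect_equal(euclidean(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean(1:10, 1:10), 0)
  set.seed(12)
  for (i in 1:20) {
    x <- rnorm(10); y <- rnorm(10)
    expect_equal(euclidean(x, y), oracle_euclid(x, y), tolerance = 1e-12)
    expect_equal(euclidean(x, y), euclidean(y, x))
  }
  expect_error(euclidean(1:3, 1:4), class = "eegstress_shape_error")
})

test_that("inter/intra separability reproduce the worked two-cluster example", {
  A <- rbind(c(0, 0), c(0, 2)); B <- rbind(c(10, 0), c(10, 2))
  inter <- inter_class_separability(list(A, B))
  intra <- intra_class_closeness(list(A, B))
  expect_equal(inter, (10 + sqrt(104) + sqrt(104) + 10) / 4, tolerance = 1e-12)
  expect_equal(inter, 10.0990, tolerance = 1e-4)
  expect_equal(intra, 1.0, tolerance = 1e-12)
  x <- rbind(A, B)
  expect_equal(separability_rating(x, c("a", "a", "b", "b")),
               inter / intra, tolerance = 1e-12)
})

test_that("separability edge cases: singletons, duplicates, collapse", {
  pt <- matrix(c(1, 1), 1)
  expect_equal(inter_class_separability(list(pt, pt)), 0)
  expect_equal(intra_class_closeness(list(pt, pt)), 0)

  A <- rbind(c(0, 0), c(0, 2)); B <- rbind(c(10, 0), c(10, 2))
  # duplicating every vector of a class leaves the means unchanged
  expect_equal(inter_class_separability(list(rbind(A, A), B)),
               inter_class_separability(list(A, B)), tolerance = 1e-12)
  # collapsed classes -> sentinel rating preferring perfect separation
  x <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5))
  expect_equal(separability_rating(x, c("a", "a", "b", "b")), 1e12)

  expect_error(inter_class_separability(list(A, A[0, , drop = FALSE])),
               class = "eegstress_validation_error")
  expect_error(separability_rating(A, c("a", "a")),
               class = "eegstress_validation_error")
  expect_error(separability_rating(rbind(A, B), c("a", "a", "b", "b"),
                                   rep(FALSE, 2)),
               class = "eegstress_validation_error")
})

test_that("separability matches brute-force triple-loop oracles on random instances", {
  set.seed(13)
  for (i in 1:40) {
    n_per <- sample(1:3, 2, replace = TRUE)
    nf <- sample(1:4, 1)
    x <- matrix(rnorm(sum(n_per) * nf), ncol = nf)
    labels <- rep(c("a", "b"), n_per)
    mask <- runif(nf) < 0.7
    if (!any(mask)) mask[1] <- TRUE
    classes <- lapply(c("a", "b"), function(l) {
      m <- x[labels == l, mask, drop = FALSE]
      m
    })
    expect_equal(inter_class_separability(classes), oracle_inter(classes),
                 tolerance = 1e-9)
    expect_equal(intra_class_closeness(classes), oracle_intra(classes),
                 tolerance = 1e-9)
    expect_equal(separability_rating(x, labels, mask),
                 oracle_rating(x, labels, mask), tolerance = 1e-9)
  }
})

test_that("separability rating is invariant to positive scaling and translation", {
  set.seed(14)
  x <- matrix(rnorm(24), 8)
  labels <- rep(c("a", "b"), each = 4)
  r <- separability_rating(x, labels)
  expect_equal(separability_rating(3.7 * x, labels), r, tolerance = 1e-9)
  shift <- matrix(rep(c(5, -2, 11), each = 8), 8)
  expect_equal(separability_rating(x + shift, labels), r, tolerance = 1e-9)
})

test_that("GA is seed-deterministic, monotone under elitism, and fixes identical populations", {
  set.seed(15)
  x <- matrix(rnorm(20 * 6), 20)
  x[11:20, 2] <- x[11:20, 2] + 3
  labels <- rep(c("calm", "stress"), each = 10)
  cfg <- ga_config(population_size = 12L, n_generations = 15L, random_seed = 42L)
  a <- ga_select(x, labels, cfg)
  b <- ga_select(x, labels, cfg)
  expect_identical(a$mask, b$mask)
  expect_identical(a$history, b$history)
  expect_true(all(diff(a$history) >= 0))

  # mutation 0 + crossover 0 + identical seed population is a fixed point
  init <- matrix(TRUE, 12L, 6L); init[, 5:6] <- FALSE
  frozen <- ga_config(population_size = 12L, n_generations = 5L,
                      crossover_rate = 0, mutation_rate_per_bit = 0,
                      random_seed = 1L)
  out <- ga_select(x, labels, frozen, init = init)
  expect_identical(out$mask, init[1, ])
})

test_that("GA recovers a planted informative feature among noise", {
  hits <- 0L
  for (s in 1:10) {
    set.seed(600 + s)
    n <- 30; nf <- 12
    labels <- rep(c("calm", "stress"), each = n / 2)
    x <- matrix(rnorm(n * nf), n)
    x[, 4] <- ifelse(labels == "stress", 1, 0) + rnorm(n, sd = 0.05)
    x <- zscore_apply(zscore_fit(x), x)
    sel <- ga_select(x, labels,
                     ga_config(population_size = 20L, n_generations = 25L,
                               random_seed = s))
    hits <- hits + sel$mask[4]
  }
  expect_gte(hits, 9L)
})

test_that("PCA baseline reconstructs at full rank and orders variance", {
  set.seed(16)
  x <- matrix(rnorm(30 * 5), 30)
  red <- pca_reduce(x, n_components = 5L)
  centered <- sweep(x, 2, colMeans(x))
  expect_equal(red$train %*% t(red$rotation), centered, tolerance = 1e-9)
  evr <- red$explained_variance_ratio
  expect_true(all(diff(evr) <= 1e-12))
  expect_lte(sum(evr), 1 + 1e-12)
  expect_error(pca_reduce(x, n_components = 6L),
               class = "eegstress_validation_error")
})

test_that("PCA concentrates a planted anisotropic direction", {
  set.seed(17)
  t <- rnorm(200)
  x <- cbind(t, t) + matrix(rnorm(400, sd = 0.1), 200)
  red <- pca_reduce(x)
  expect_gte(red$explained_variance_ratio[1], 0.95)
  expect_identical(red$n_components, 1L)
  # oracle: leading eigenvalue share of the 2x2 covariance
  ev <- eigen(cov(x))$values
  expect_equal(red$explained_variance_ratio[1], ev[1] / sum(ev),
               tolerance = 1e-9)
})

test_that("PCA projection of held-out data uses training center and rotation", {
  set.seed(18)
  tr <- matrix(rnorm(40), 10)
  te <- matrix(rnorm(8), 2)
  red <- pca_reduce(tr, te, n_components = 2L)
  manual <- sweep(te, 2, colMeans(tr)) %*% red$rotation
  expect_equal(red$projected, manual, tolerance = 1e-12)
})
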