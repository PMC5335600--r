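test_that("descriptor filtering applies the three rejection rules", {
  set.seed(42)
  n <- 100
  y <- rep(c(0L, 1L), 50)
  sparse <- c(rep(0, 85), rnorm(15))            # 15% non-zero -> rejected
  constant <- rep(5, n)                          # CV = 0 -> rejected
  good <- rnorm(n, 10, 4)
  x <- cbind(sparse = sparse, constant = constant, good = good)
  keep <- filter_descriptors(x, y)
  expect_identical(keep, 3L)

  ## correlated pair: the higher F-score member survives
  strong <- c(rnorm(50, 0), rnorm(50, 4))[order(rep(1:2, 50))]
  strong <- ifelse(y == 1, rnorm(n, 4), rnorm(n, 0))
  weak <- strong + rnorm(n, 0, 0.1)              # r > 0.9, lower separation
  weak <- weak[sample(n)]                        # decorrelate labels a bit
  weak <- strong * 0.99 + rnorm(n, 0, 0.05)      # keep correlation high
  x2 <- cbind(a = weak, b = strong)
  fs <- f_score(x2, y)
  keep2 <- filter_descriptors(x2, y)
  expect_identical(keep2, unname(which.max(fs)))

  expect_error(filter_descriptors(cbind(z = rep(0, 10)), rep(0:1, 5)),
               class = "adm_all_rejected")
})

test_that("descriptor filtering is idempotent and column-order consistent", {
  set.seed(7)
  for (k in 1:25) {
    x <- matrix(rnorm(60 * 8), 60, 8)
    x[, 1] <- 0                                   # all-zero column
    x[, 2] <- x[, 3] * 0.97 + rnorm(60, 0, 0.05)  # correlated pair
    x[sample(60, 50), 4] <- 0                     # sparse column
    y <- rep(c(0L, 1L), 30)
    keep <- filter_descriptors(x, y)
    ## brute-force re-application of the quoted rules
    expect_identical(keep, filter_bruteforce(x, y), info = paste("case", k))
    ## applying the filter to the surviving block changes nothing
    keep2 <- filter_descriptors(x[, keep, drop = FALSE], y)
    expect_identical(keep[keep2], keep)
    expect_length(keep2, length(keep))
    ## permuting columns permutes the selection accordingly
    perm <- sample(ncol(x))
    keep_p <- filter_descriptors(x[, perm, drop = FALSE], y)
    expect_setequal(perm[keep_p], keep)
  }
})

test_that("class-separation F-score matches its definition on a toy case", {
  x <- cbind(f = c(1, 2, 3, 10, 11, 12))
  y <- c(0, 0, 0, 1, 1, 1)
  mu <- mean(x); mp <- mean(x[4:6]); mn <- mean(x[1:3])
  expected <- ((mp - mu)^2 + (mn - mu)^2) / (var(x[4:6]) + var(x[1:3]))
  expect_equal(unname(f_score(x, y)), expected)
})

test_that("cluster balancing keeps brute-force cluster centres", {
  ## 5-point toy set with a printed dissimilarity matrix
  d <- matrix(c(
    0.0, 0.1, 0.2, 0.9, 0.8,
    0.1, 0.0, 0.15, 0.85, 0.9,
    0.2, 0.15, 0.0, 0.95, 0.85,
    0.9, 0.85, 0.95, 0.0, 0.1,
    0.8, 0.9, 0.85, 0.1, 0.0), 5, 5, byrow = TRUE)
  ds <- structure(list(
    x = matrix(rnorm(7 * 3), 7, 3), y = c(rep(1L, 5), 0L, 0L),
    feature_names = c("a", "b", "c"), fingerprints = NULL,
    role = "training"), class = "adm_dataset")
  dd <- matrix(0, 7, 7)
  dd[1:5, 1:5] <- d
  red <- cluster_balance(ds, 2L, dissimilarity = dd)
  expect_equal(sum(red$y == 1L), 2L)
  expect_equal(sum(red$y == 0L), 2L)
  ## centres equal the brute-force argmin of summed dissimilarities within
  ## the two obvious clusters {1,2,3} and {4,5}
  c1 <- centre_bruteforce(d, 1:3)
  c2 <- centre_bruteforce(d, 4:5)
  expect_true(all(ds$x[c(c1, c2), 1] %in% red$x[red$y == 1L, 1]))

  ## identical members: tie broken by lowest input index
  d_tie <- matrix(0.5, 4, 4); diag(d_tie) <- 0
  d_tie[1, 2] <- d_tie[2, 1] <- 0; d_tie[1, 3] <- d_tie[3, 1] <- 0
  d_tie[2, 3] <- d_tie[3, 2] <- 0   # members 1,2,3 identical
  ds2 <- structure(list(
    x = matrix(seq_len(6), 6, 1), y = c(rep(1L, 4), 0L, 0L),
    feature_names = "a", fingerprints = NULL, role = "training"),
    class = "adm_dataset")
  dd2 <- matrix(0.7, 6, 6); diag(dd2) <- 0
  dd2[1:4, 1:4] <- d_tie
  red2 <- cluster_balance(ds2, 2L, dissimilarity = dd2)
  expect_true(1 %in% red2$x[red2$y == 1L, 1])   # lowest index of the triple

  ## target equal to class size: unchanged
  red3 <- cluster_balance(ds2, 4L, dissimilarity = dd2)
  expect_identical(red3$x, ds2$x)
  expect_error(cluster_balance(ds2, 10L, dissimilarity = dd2),
               class = "adm_target_too_large")
})

test_that("AUC equals the pairwise-concordance oracle", {
  expect_equal(auc_score(c(0.9, 0.8, 0.7, 0.3, 0.2), c(1, 1, 0, 1, 0)),
               auc_bruteforce(c(0.9, 0.8, 0.7, 0.3, 0.2), c(1, 1, 0, 1, 0)))
  ## 10-row toy set with ties
  s <- c(0.1, 0.4, 0.4, 0.35, 0.8, 0.8, 0.2, 0.6, 0.55, 0.4)
  y <- c(0, 1, 0, 0, 1, 1, 0, 1, 1, 0)
  expect_equal(auc_score(s, y), auc_bruteforce(s, y))
  set.seed(3)
  for (k in 1:20) {
    s <- round(runif(14), 1)
    y <- sample(c(0, 1), 14, replace = TRUE, prob = c(0.5, 0.5))
    if (length(unique(y)) < 2) next
    expect_equal(auc_score(s, y), auc_bruteforce(s, y))
  }
  expect_error(auc_score(1:3, c(1, 1, 1)), class = "adm_degenerate_labels")
  ## independent library cross-check
  skip_if_not_installed("pROC")
  s <- c(0.2, 0.7, 0.4, 0.9, 0.1, 0.6, 0.6, 0.3)
  y <- c(0, 1, 0, 1, 0, 1, 0, 0)
  expect_equal(auc_score(s, y),
               as.numeric(suppressMessages(pROC::auc(y, s))))
})

test_that("classification statistics cover the degenerate contracts", {
  cs <- admetk:::classification_stats
  perfect <- cs(c(1L, 1L, 0L, 0L), c(2, 1.5, -1, -2), c(1, 1, 0, 0))
  expect_equal(unlist(perfect),
               c(ACC = 1, AUC = 1, sensitivity = 1, specificity = 1))
  allpos <- cs(rep(1L, 4), c(1, 1, 1, 1), c(1, 1, 0, 0))
  expect_equal(allpos$sensitivity, 1)
  expect_equal(allpos$specificity, 0)
  expect_equal(allpos$ACC, 0.5)
})

test_that("normalization uses training parameters only (no leakage)", {
  train <- synthesize_dataset(60, 60, effect_size = 2, seed = 5)
  fit <- adme_svm_fit(train, folds = 5L, seed = 5,
                      grid = list(log2C = c(0, 4), log2gamma = c(-7, -3),
                                  refine_step = 1))
  xn <- sweep(sweep(train$x[, fit$selected, drop = FALSE], 2, fit$centre),
              2, fit$scale, "/")
  expect_true(all(abs(colMeans(xn)) < 1e-10))
  expect_true(all(abs(apply(xn, 2, sd) - 1) < 1e-10))
  ## a shifted test set normalized with training parameters keeps means
  ## away from zero - the transform was not refit
  test <- synthesize_dataset(40, 40, effect_size = 2, seed = 6)
  test$x <- test$x + 1
  xt <- sweep(sweep(test$x[, fit$selected, drop = FALSE], 2, fit$centre),
              2, fit$scale, "/")
  expect_gt(mean(abs(colMeans(xt))), 0.5)
})

test_that("grid search learns separable data and memorizes duplicates", {
  ds <- synthesize_dataset(80, 80, effect_size = 3, seed = 11)
  fit <- adme_svm_fit(ds, seed = 11)
  expect_gte(fit$stats$ACC_CV, 0.95)
  expect_gte(fit$stats$AUC_CV, 0.95)

  ## duplicated feature rows with consistent labels are memorizable
  base <- matrix(rnorm(10 * 4), 10, 4)
  x <- base[rep(1:10, each = 6), ]
  y <- rep(rep(c(0L, 1L), 5), each = 6)
  dup <- structure(list(x = x, y = y,
                        feature_names = paste0("D", 1:4),
                        fingerprints = NULL, role = "training"),
                   class = "adm_dataset")
  fit2 <- adme_svm_fit(dup, folds = 5L, seed = 2, filter = FALSE)
  expect_equal(fit2$stats$ACC_CV, 1.0)

  expect_error(
    adme_svm_fit(structure(list(x = matrix(rnorm(20), 10), y = rep(1L, 10),
                                feature_names = c("a", "b"),
                                fingerprints = NULL, role = "training"),
                           class = "adm_dataset")),
    class = "adm_degenerate_labels")
})

test_that("external evaluation uses the stored schema and flags mismatches", {
  train <- synthesize_dataset(60, 60, effect_size = 3, seed = 21)
  fit <- adme_svm_fit(train, folds = 5L, seed = 21)
  test <- synthesize_dataset(40, 40, effect_size = 3, seed = 22)
  test$role <- "test"
  st <- evaluate_external(fit, test)
  expect_gte(st$ACC, 0.9)
  expect_gte(st$AUC, 0.95)
  bad <- test
  bad$feature_names <- paste0("X", seq_along(bad$feature_names))
  expect_error(evaluate_external(fit, bad), class = "adm_schema_mismatch")
})

test_that("the dataset generator is seed-reproducible and calibrated", {
  a <- synthesize_dataset(30, 25, effect_size = 1.5, seed = 99)
  b <- synthesize_dataset(30, 25, effect_size = 1.5, seed = 99)
  expect_identical(a$x, b$x)
  expect_identical(a$fingerprints, b$fingerprints)
  expect_equal(sum(a$y == 1L), 30L)
  expect_equal(sum(a$y == 0L), 25L)
  c2 <- synthesize_dataset(30, 25, effect_size = 1.5, seed = 100)
  expect_false(identical(a$x, c2$x))
  ## informative features carry the stated shift
  shift <- colMeans(a$x[a$y == 1L, 1:10]) - colMeans(a$x[a$y == 0L, 1:10])
  expect_equal(mean(shift), 1.5, tolerance = 0.35)
})
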