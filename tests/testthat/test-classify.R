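test_that("species filter applies the minimum-recording boundary", {
  labs <- c(rep(list("common"), 20), rep(list("rare"), 19),
            rep(list(c("common", "rare")), 0))
  es <- embedding_set(matrix(0, 39, 4), labs)
  out <- filter_species(es, min_recordings = 20)
  expect_equal(out$species, "common")
  # records stripped of dropped labels are kept as all-negatives
  expect_equal(sum(lengths(out$records$labels) == 0), 19)

  ident <- filter_species(es, min_recordings = 1)
  expect_setequal(ident$species, c("common", "rare"))

  # counting oracle on a random label set
  set.seed(15)
  labs2 <- replicate(60, sample(paste0("sp", 1:7), sample(0:3, 1)),
                     simplify = FALSE)
  es2 <- embedding_set(matrix(0, 60, 4), labs2)
  for (mr in c(5, 12, 25)) {
    got <- filter_species(es2, mr)$species
    want <- sort(Filter(function(s) {
      sum(vapply(labs2, function(l) s %in% l, logical(1))) >= mr
    }, paste0("sp", 1:7)))
    expect_equal(got, want)
  }
})

test_that("train/test split is disjoint, exhaustive and reproducible", {
  es <- embedding_set(matrix(rnorm(50 * 3), 50, 3),
                      rep(list("a"), 50),
                      unit_id = sprintf("r%02d", 1:50))
  sp <- split_train_test(es, 0.7, seed = 2)
  expect_equal(nrow(sp$train$features), round(0.7 * 50))
  expect_equal(nrow(sp$test$features), 50 - 35)
  expect_length(intersect(sp$train$unit_id, sp$test$unit_id), 0)
  expect_setequal(c(sp$train$unit_id, sp$test$unit_id), es$unit_id)
  sp2 <- split_train_test(es, 0.7, seed = 2)
  expect_identical(sp$train$unit_id, sp2$train$unit_id)
  sp3 <- split_train_test(es, 0.7, seed = 3)
  expect_false(identical(sp$train$unit_id, sp3$train$unit_id))
})

test_that("the head learns linearly separable clusters", {
  recs <- make_separable_records(n_species = 2, per_species = 40, dim = 16,
                                 noise_sd = 0.05, seed = 7)
  m <- train_head(recs, epochs = 300, seed = 8)
  th <- select_threshold(m, recs)
  on_train <- evaluate(m, th, recs)
  expect_gte(on_train$subset_accuracy, 0.99)
  # descent sanity: final loss below initial loss
  expect_lt(m$loss[length(m$loss)], m$loss[1])
})

test_that("constant-label species converge toward their base rate", {
  set.seed(19)
  X <- matrix(rnorm(80 * 6), 80, 6)
  labs <- c(rep(list(c("always", "half")), 40), rep(list("always"), 40))
  es <- embedding_set(X, labs)
  expect_warning(
    m <- train_head(es, species = c("always", "half"), epochs = 400,
                    seed = 20),
    "single class"
  )
  p <- predict(m, es)
  # 'always' present in every record: probabilities pushed toward 1
  expect_gt(mean(p[, "always"]), 0.9)
})

test_that("threshold line search uses the smallest maximising grid point", {
  prob <- matrix(c(0.9, 0.1), nrow = 1,
                 dimnames = list("r1", c("p", "a")))
  Y <- matrix(c(1, 0), nrow = 1, dimnames = list("r1", c("p", "a")))
  expect_equal(select_threshold(prob, labels = Y), 0.11)

  # all labels absent, all probabilities < 1: perfect accuracy is reachable
  prob2 <- matrix(runif(20, 0, 0.8), 5, 4,
                  dimnames = list(NULL, paste0("s", 1:4)))
  Y2 <- matrix(0, 5, 4, dimnames = list(NULL, paste0("s", 1:4)))
  th <- select_threshold(prob2, labels = Y2)
  expect_equal(mean(rowSums((prob2 >= th) != (Y2 > 0)) == 0), 1)
})

test_that("threshold search matches the exhaustive grid oracle", {
  set.seed(23)
  for (i in 1:12) {
    n <- sample(4:12, 1); k <- sample(2:5, 1)
    prob <- matrix(runif(n * k), n, k,
                   dimnames = list(NULL, paste0("s", 1:k)))
    Y <- matrix(rbinom(n * k, 1, 0.4), n, k,
                dimnames = list(NULL, paste0("s", 1:k)))
    expect_equal(select_threshold(prob, labels = Y),
                 oracle_threshold(prob, Y))
  }
})

test_that("metrics behave at the extremes", {
  recs <- make_separable_records(n_species = 3, per_species = 10, dim = 8,
                                 noise_sd = 0.01, seed = 30)
  m <- train_head(recs, epochs = 400, seed = 31)
  th <- select_threshold(m, recs)
  rep0 <- evaluate(m, th, recs)
  expect_true(all(rep0$per_species_f1 == 1))
  expect_equal(rep0$subset_accuracy, 1)
  expect_equal(rep0$macro_auroc, 1)

  # complement of truth: F1 collapses to zero
  flipped <- embedding_set(recs$features,
                           lapply(recs$labels, function(s)
                             setdiff(m$species, s)),
                           recs$unit_id)
  rep1 <- evaluate(m, th, flipped)
  expect_true(all(rep1$per_species_f1 == 0))
  expect_equal(rep1$subset_accuracy, 0)
})

test_that("AUROC equals the pairwise Mann-Whitney oracle and is threshold-free", {
  set.seed(35)
  recs <- make_separable_records(n_species = 3, per_species = 12, dim = 8,
                                 noise_sd = 0.5, seed = 36)
  m <- train_head(recs, epochs = 100, seed = 37)
  prob <- predict(m, recs)
  Y <- matrix(0, nrow(prob), 3, dimnames = list(NULL, m$species))
  for (i in seq_along(recs$labels)) Y[i, recs$labels[[i]]] <- 1
  for (j in 1:3) {
    expect_equal(birdsurv:::auroc(prob[, j], Y[, j]),
                 oracle_auroc(prob[, j], Y[, j]))
  }
  # tied scores handled with mid-ranks
  s <- c(0.2, 0.5, 0.5, 0.9); y <- c(0, 0, 1, 1)
  expect_equal(birdsurv:::auroc(s, y), oracle_auroc(s, y))
  expect_equal(birdsurv:::auroc(s, y), 0.875)

  # AUROC is threshold-free
  r1 <- evaluate(m, 0.2, recs)
  r2 <- evaluate(m, 0.8, recs)
  expect_equal(r1$macro_auroc, r2$macro_auroc)
})

test_that("repeated runs aggregate deterministically", {
  recs <- make_separable_records(n_species = 3, per_species = 15, dim = 8,
                                 noise_sd = 0.1, seed = 40)
  a <- suppressWarnings(repeated_runs(recs, n_runs = 3, base_seed = 5,
                                      epochs = 80))
  b <- suppressWarnings(repeated_runs(recs, n_runs = 3, base_seed = 5,
                                      epochs = 80))
  expect_identical(a$runs, b$runs)
  expect_gte(a$subset_accuracy[["mean"]], min(a$runs$subset_accuracy))
  expect_lte(a$subset_accuracy[["mean"]], max(a$runs$subset_accuracy))

  # n_runs = 1 equals a single manual split/train/evaluate
  one <- suppressWarnings(repeated_runs(recs, n_runs = 1, base_seed = 5,
                                        epochs = 80))
  sp <- split_train_test(recs, 0.7, seed = 6)
  m <- suppressWarnings(train_head(sp$train,
                                   species = sort(unique(unlist(recs$labels))),
                                   epochs = 80, seed = 6))
  th <- select_threshold(m, sp$train)
  ev <- evaluate(m, th, sp$test)
  expect_equal(one$runs$subset_accuracy[1], ev$subset_accuracy)
  expect_equal(one$runs$macro_auroc[1], ev$macro_auroc)
})

test_that("label noise does not improve exact-match accuracy (median)", {
  recs <- make_separable_records(n_species = 4, per_species = 15, dim = 8,
                                 noise_sd = 0.05, seed = 50)
  res <- vapply(1:5, function(s) {
    vapply(c(0, 0.3), function(noise) {
      set.seed(200 + s)
      labs <- lapply(recs$labels, function(l) {
        if (noise > 0 && runif(1) < noise) {
          sample(sort(unique(unlist(recs$labels))), 1)
        } else l
      })
      noisy <- embedding_set(recs$features, labs, recs$unit_id)
      sp <- split_train_test(noisy, 0.7, seed = 300 + s)
      m <- suppressWarnings(train_head(
        sp$train, species = sort(unique(unlist(recs$labels))),
        epochs = 80, seed = 300 + s))
      evaluate(m, select_threshold(m, sp$train), sp$test)$subset_accuracy
    }, numeric(1))
  }, numeric(2))
  expect_lte(median(res[2, ]), median(res[1, ]))
})
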