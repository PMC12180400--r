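#' Filter label universe to adequately sampled species
#'
#' Keeps species present in at least `min_recordings` recordings; labels
#' outside the kept set are dropped from every recording. Recordings left
#' with no labels are retained as all-negative examples.
#'
#' @param records an `embedding_set`.
#' @param min_recordings minimum positive recordings per kept species
#'   (default 20).
#' @return list with `species` (kept, sorted) and `records` (reduced
#'   `embedding_set`).
#' @export
filter_species <- function(records, min_recordings = 20) {
  stopifnot(inherits(records, "embedding_set"))
  counts <- table(unlist(lapply(records$labels, unique)))
  keep <- sort(names(counts)[counts >= min_recordings])
  labs <- lapply(records$labels, function(s) intersect(s, keep))
  list(species = keep,
       records = embedding_set(records$features, labs, records$unit_id))
}

#' Random train/test split of an embedding set
#'
#' Uniform unstratified split: a random `train_fraction` of recordings
#' (rounded to nearest) goes to training, the rest to test. Disjoint,
#' exhaustive and reproducible under the seed.
#'
#' @param records an `embedding_set`.
#' @param train_fraction fraction of recordings in the training set
#'   (default 0.7).
#' @param seed integer seed.
#' @return list with `train` and `test` embedding sets.
#' @export
split_train_test <- function(records, train_fraction = 0.7, seed = 1) {
  stopifnot(inherits(records, "embedding_set"),
            train_fraction > 0, train_fraction < 1)
  n <- nrow(records$features)
  set.seed(as.integer(seed))
  n_train <- round(train_fraction * n)
  idx <- sample.int(n, n_train)
  take <- function(i) embedding_set(records$features[i, , drop = FALSE],
                                    records$labels[i], records$unit_id[i])
  list(train = take(idx), test = take(setdiff(seq_len(n), idx)))
}

# label matrix (recordings x species) from an embedding set
#' @keywords internal
label_matrix <- function(records, species) {
  Y <- matrix(0, nrow = length(records$labels), ncol = length(species),
              dimnames = list(records$unit_id, species))
  for (i in seq_along(records$labels)) {
    j <- match(intersect(records$labels[[i]], species), species)
    Y[i, j] <- 1
  }
  Y
}

#' Train a multi-label neural classifier head on embeddings
#'
#' A one-hidden-layer multi-layer perceptron over per-recording embedding
#' features: rectified-linear hidden layer, one sigmoid output per species
#' giving the probability the species is present, mean binary cross-entropy
#' loss, optimised full-batch with Adam. This is the classifier head one
#' trains on top of a frozen pretrained embedding extractor.
#'
#' @param train an `embedding_set` used for training.
#' @param species character vector of output species (e.g. from
#'   [filter_species()]); defaults to all species labelled in `train`.
#' @param hidden_units hidden-layer width (default 128).
#' @param epochs full-batch Adam steps (default 200).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed integer seed controlling weight initialisation.
#' @return object of class `mlp_head` with weights, the species list, and
#'   the per-epoch training `loss` trace.
#' @export
train_head <- function(train, species = NULL, hidden_units = 128,
                       epochs = 200, learning_rate = 1e-3, seed = 1) {
  stopifnot(inherits(train, "embedding_set"), hidden_units >= 1,
            epochs >= 1)
  X <- train$features
  n <- nrow(X)
  if (n < 2) stop("need at least 2 training records", call. = FALSE)
  species <- species %||% sort(unique(unlist(train$labels)))
  if (!length(species)) stop("no species to classify", call. = FALSE)
  Y <- label_matrix(train, species)
  single_class <- colSums(Y) %in% c(0, n)
  if (any(single_class)) {
    warning("species with a single class in training: ",
            paste(species[single_class], collapse = ", "),
            "; trained anyway (BCE remains well-defined)")
  }
  d <- ncol(X)
  k <- length(species)
  set.seed(as.integer(seed))
  # He/Glorot-style scaled initialisation
  W1 <- matrix(stats::rnorm(d * hidden_units, sd = sqrt(2 / d)), d)
  b1 <- rep(0, hidden_units)
  W2 <- matrix(stats::rnorm(hidden_units * k, sd = sqrt(1 / hidden_units)),
               hidden_units)
  b2 <- rep(0, k)
  params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  mom <- lapply(params, function(p) p * 0)
  vel <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  loss_trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    H <- X %*% params$W1
    H <- sweep(H, 2, params$b1, `+`)
    A <- pmax(H, 0)
    Z <- A %*% params$W2
    Z <- sweep(Z, 2, params$b2, `+`)
    P <- 1 / (1 + exp(-Z))
    Pc <- pmin(pmax(P, 1e-12), 1 - 1e-12)
    loss_trace[ep] <- -mean(Y * log(Pc) + (1 - Y) * log(1 - Pc))
    # gradients of mean BCE wrt logits: (P - Y)/(n*k)
    dZ <- (P - Y) / (n * k)
    grads <- list(
      W1 = NULL, b1 = NULL,
      W2 = crossprod(A, dZ), b2 = colSums(dZ)
    )
    dA <- dZ %*% t(params$W2)
    dH <- dA * (H > 0)
    grads$W1 <- crossprod(X, dH)
    grads$b1 <- colSums(dH)
    for (nm in names(params)) {
      mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * grads[[nm]]
      vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * grads[[nm]]^2
      mhat <- mom[[nm]] / (1 - beta1^ep)
      vhat <- vel[[nm]] / (1 - beta2^ep)
      params[[nm]] <- params[[nm]] -
        learning_rate * mhat / (sqrt(vhat) + eps)
    }
  }
  structure(
    list(W1 = params$W1, b1 = params$b1, W2 = params$W2, b2 = params$b2,
         species = species, dim = d, hidden_units = hidden_units,
         epochs = epochs, learning_rate = learning_rate, seed = seed,
         loss = loss_trace),
    class = "mlp_head"
  )
}

#' @export
print.mlp_head <- function(x, ...) {
  cat(sprintf(
    "Multi-label MLP head: %d -> %d -> %d species (%d epochs, lr %.2g)\n",
    x$dim, x$hidden_units, length(x$species), x$epochs, x$learning_rate))
  cat(sprintf("  final training BCE: %.4f\n", x$loss[length(x$loss)]))
  invisible(x)
}

#' @export
#' @rdname train_head
#' @param object an `mlp_head`.
#' @param newdata an `embedding_set` or feature matrix.
#' @param ... ignored.
predict.mlp_head <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "embedding_set")) newdata$features else newdata
  stopifnot(ncol(X) == object$dim)
  H <- pmax(sweep(X %*% object$W1, 2, object$b1, `+`), 0)
  Z <- sweep(H %*% object$W2, 2, object$b2, `+`)
  P <- 1 / (1 + exp(-Z))
  dimnames(P) <- list(rownames(X), object$species)
  P
}

# subset (exact-match) accuracy of thresholded probabilities
#' @keywords internal
subset_accuracy_at <- function(prob, Y, threshold) {
  pred <- prob >= threshold
  mean(rowSums(pred != (Y > 0)) == 0)
}

#' Select the presence threshold by line search on the training set
#'
#' Evaluates subset (exact-match) accuracy on the grid
#' `{0, grid_step, ..., 1}`; a species is predicted present when its output
#' probability is at least the threshold. Returns the smallest threshold
#' attaining the maximum accuracy.
#'
#' @param model an `mlp_head`, or a probability matrix.
#' @param train an `embedding_set` (ignored if `model` is already a
#'   probability matrix and `labels` is given).
#' @param grid_step grid spacing on `[0, 1]` (default 0.01).
#' @param labels optional label matrix/list overriding `train`'s labels.
#' @return the selected threshold (a grid point).
#' @export
select_threshold <- function(model, train = NULL, grid_step = 0.01,
                             labels = NULL) {
  if (inherits(model, "mlp_head")) {
    prob <- predict(model, train)
    Y <- label_matrix(train, model$species)
  } else {
    prob <- model
    Y <- if (is.matrix(labels)) labels else
      label_matrix(train %||% stop("labels required"), colnames(prob))
  }
  grid <- seq(0, 1, by = grid_step)
  acc <- vapply(grid, function(th) subset_accuracy_at(prob, Y, th),
                numeric(1))
  grid[which.max(acc)]  # which.max takes the first (smallest) maximiser
}

# rank-statistic AUROC with mid-rank tie handling (Mann-Whitney form)
#' @keywords internal
auroc <- function(scores, truth) {
  pos <- sum(truth > 0)
  neg <- sum(truth <= 0)
  if (pos == 0 || neg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[truth > 0]) - pos * (pos + 1) / 2) / (pos * neg)
}

#' Evaluate a classifier head on a test set
#'
#' Per-species F1 at the given threshold (harmonic mean of precision and
#' recall; 0 when both are undefined), subset accuracy (fraction of test
#' recordings whose entire predicted label set matches the truth exactly),
#' mean per-label accuracy, and macro-AUROC (unweighted mean over species
#' with both classes present in the test set of the rank-statistic AUROC
#' with mid-rank ties).
#'
#' @param model an `mlp_head`.
#' @param threshold presence threshold in `[0, 1]`.
#' @param test an `embedding_set`.
#' @return object of class `classifier_report`: list with `per_species_f1`,
#'   `subset_accuracy`, `label_accuracy`, `macro_auroc`, `macro_f1`,
#'   `threshold`, `n_test`, `species`, `excluded_species` (single-class in
#'   test, excluded from the macro averages).
#' @export
evaluate <- function(model, threshold, test) {
  stopifnot(inherits(model, "mlp_head"), threshold >= 0, threshold <= 1)
  prob <- predict(model, test)
  Y <- label_matrix(test, model$species)
  pred <- prob >= threshold
  f1 <- vapply(seq_along(model$species), function(j) {
    tp <- sum(pred[, j] & Y[, j] > 0)
    fp <- sum(pred[, j] & Y[, j] <= 0)
    fn <- sum(!pred[, j] & Y[, j] > 0)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  names(f1) <- model$species
  aucs <- vapply(seq_along(model$species), function(j) {
    auroc(prob[, j], Y[, j])
  }, numeric(1))
  names(aucs) <- model$species
  excluded <- model$species[is.na(aucs)]
  structure(
    list(per_species_f1 = f1,
         subset_accuracy = mean(rowSums(pred != (Y > 0)) == 0),
         label_accuracy = mean(pred == (Y > 0)),
         macro_auroc = mean(aucs, na.rm = TRUE),
         macro_f1 = mean(f1),
         per_species_auroc = aucs,
         threshold = threshold, n_test = nrow(Y),
         species = model$species, excluded_species = excluded),
    class = "classifier_report"
  )
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(
    "Classifier report: %d species, %d test recordings, threshold %.2f\n",
    length(x$species), x$n_test, x$threshold))
  cat(sprintf("  subset accuracy %.3f | per-label accuracy %.3f\n",
              x$subset_accuracy, x$label_accuracy))
  cat(sprintf("  macro-F1 %.3f | macro-AUROC %.3f\n",
              x$macro_f1, x$macro_auroc))
  if (length(x$excluded_species)) {
    cat("  excluded from macro-AUROC (single class in test):",
        paste(x$excluded_species, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Repeated train/test evaluation
#'
#' Runs `n_runs` independent train/test splits (seeded `base_seed + run`),
#' trains a head on each, selects its threshold on the training set and
#' evaluates on the test set; aggregates subset accuracy and macro-AUROC as
#' mean and SD across runs.
#'
#' @param records an `embedding_set` (already filtered).
#' @param species species list (e.g. from [filter_species()]).
#' @param n_runs number of runs (default 100).
#' @param base_seed integer; run `i` uses seed `base_seed + i`.
#' @param train_fraction,hidden_units,epochs,learning_rate,grid_step passed
#'   through to the stages.
#' @return list with `subset_accuracy` and `macro_auroc` (each
#'   `c(mean, sd)`), `macro_f1`, `runs` (per-run data frame), `n_runs`.
#' @export
repeated_runs <- function(records, species = NULL, n_runs = 100,
                          base_seed = 1, train_fraction = 0.7,
                          hidden_units = 128, epochs = 200,
                          learning_rate = 1e-3, grid_step = 0.01) {
  stopifnot(inherits(records, "embedding_set"), n_runs >= 1)
  species <- species %||% sort(unique(unlist(records$labels)))
  runs <- data.frame(run = seq_len(n_runs), subset_accuracy = NA_real_,
                     macro_auroc = NA_real_, macro_f1 = NA_real_,
                     threshold = NA_real_)
  for (i in seq_len(n_runs)) {
    sd_i <- as.integer(base_seed) + i
    sp <- split_train_test(records, train_fraction, seed = sd_i)
    m <- train_head(sp$train, species = species,
                    hidden_units = hidden_units, epochs = epochs,
                    learning_rate = learning_rate, seed = sd_i)
    th <- select_threshold(m, sp$train, grid_step = grid_step)
    rep_i <- evaluate(m, th, sp$test)
    runs$subset_accuracy[i] <- rep_i$subset_accuracy
    runs$macro_auroc[i] <- rep_i$macro_auroc
    runs$macro_f1[i] <- rep_i$macro_f1
    runs$threshold[i] <- th
  }
  agg <- function(v) c(mean = mean(v), sd = stats::sd(v))
  list(subset_accuracy = agg(runs$subset_accuracy),
       macro_auroc = agg(runs$macro_auroc),
       macro_f1 = agg(runs$macro_f1),
       runs = runs, n_runs = n_runs)
}
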