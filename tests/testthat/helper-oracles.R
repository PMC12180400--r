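# Independent brute-force oracles used across tests. These deliberately use
# the most naive construction available so they stay independent of the
# package's own code paths.

# set-membership incidence construction: loop over every (species, unit) pair
oracle_incidence <- function(events, unit_ids) {
  sp <- sort(unique(events$species))
  m <- matrix(0L, length(sp), length(unit_ids),
              dimnames = list(sp, unit_ids))
  for (s in sp) {
    for (u in unit_ids) {
      hit <- any(events$species == s & events$unit_id == u)
      m[s, u] <- as.integer(hit)
    }
  }
  m
}

# double-loop frequency of occurrence
oracle_fo <- function(sets) {
  sp <- sort(unique(unlist(sets)))
  sapply(sp, function(s) {
    n <- 0
    for (u in sets) if (s %in% u) n <- n + 1
    n / length(sets)
  })
}

# 2-D grid-search least squares for S(t) = (a/b)(1 - exp(-b t)),
# iteratively refined until the grid spacing falls below `resolution`
oracle_accum_grid <- function(t, y, a_range = c(0.01, 50),
                              b_range = c(1e-4, 2), resolution = 1e-4) {
  rss <- function(a, b) sum((y - (a / b) * (1 - exp(-b * t)))^2)
  repeat {
    a_grid <- seq(a_range[1], a_range[2], length.out = 41)
    b_grid <- seq(b_range[1], b_range[2], length.out = 41)
    v <- outer(a_grid, b_grid, Vectorize(rss))
    ij <- which(v == min(v), arr.ind = TRUE)[1, ]
    da <- diff(a_grid[1:2]); db <- diff(b_grid[1:2])
    a_best <- a_grid[ij[1]]; b_best <- b_grid[ij[2]]
    if (da < resolution && db < resolution) {
      return(list(a = a_best, b = b_best, rss = min(v)))
    }
    a_range <- c(max(1e-8, a_best - 2 * da), a_best + 2 * da)
    b_range <- c(max(1e-8, b_best - 2 * db), b_best + 2 * db)
  }
}

# sup deviation of the ECDF from the standard normal CDF: dense grid plus
# both sides of every jump point
oracle_ks_stat <- function(x) {
  Fn <- stats::ecdf(x)
  grid <- seq(min(x) - 1, max(x) + 1, by = 1e-3)
  pts <- sort(unique(c(grid, x)))
  d_at <- abs(Fn(pts) - stats::pnorm(pts))
  d_left <- abs(Fn(pts - 1e-12) - stats::pnorm(pts))
  max(d_at, d_left)
}

# exact signed-rank two-sided p by explicit enumeration of all sign vectors
oracle_wilcoxon_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  total <- sum(r)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p <- (sum(w_all <= w_obs + 1e-9) + sum(w_all >= total - w_obs - 1e-9)) /
    2^n
  list(statistic = w_obs, p_value = min(1, p))
}

# exhaustive threshold grid search for subset accuracy
oracle_threshold <- function(prob, Y, grid_step = 0.01) {
  grid <- seq(0, 1, by = grid_step)
  best <- -1; arg <- NA
  for (th in grid) {
    pred <- prob >= th
    acc <- mean(apply(pred == (Y > 0), 1, all))
    if (acc > best + 1e-12) {
      best <- acc
      arg <- th
    }
  }
  arg
}

# pairwise-comparison AUROC: fraction of (positive, negative) pairs ordered
# correctly, ties counted 1/2
oracle_auroc <- function(scores, truth) {
  pos <- scores[truth > 0]
  neg <- scores[truth <= 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# small synthetic PC event table with cues, for cue-analysis tests
make_cue_events <- function(tab) {
  detection_events(method = "PC", site = "S", unit_id = tab$unit,
                   species = tab$species, cue = tab$cue)
}

# separable embedding data: well-spaced prototypes, tiny noise
make_separable_records <- function(n_species = 10, per_species = 30,
                                   dim = 32, noise_sd = 0.05, seed = 42) {
  em <- embedding_model(n_species, dim = dim, noise_sd = noise_sd,
                        seed = seed)
  set.seed(seed + 1)
  labels <- lapply(seq_len(n_species * per_species), function(i) {
    em$species[1 + (i - 1) %% n_species]
  })
  simulate_embeddings(em, labels, seed = seed + 2)
}
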