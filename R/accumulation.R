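#' Species accumulation series
#'
#' Cumulative number of distinct species against survey effort. With
#' `ordering = "chronological"` units are taken in their `order_index`
#' order (the single observed series a field study yields); with
#' `ordering = "permuted"` the cumulative richness is averaged over random
#' unit orderings, a smoother and ordering-free alternative.
#'
#' @param x an `incidence` object from [build_incidence()].
#' @param ordering `"chronological"` (default) or `"permuted"`.
#' @param n_permutations number of random orderings when permuted.
#' @param seed integer seed for the permutations.
#' @return data frame with columns `t` (effort, in units) and `S_obs`
#'   (cumulative species count; the permuted mean is generally fractional).
#' @examples
#' ev <- detection_events(method = "PC", site = "A",
#'                        unit_id = c("u1", "u2", "u3"),
#'                        species = c("a", "a", "b"))
#' un <- sampling_units(paste0("u", 1:3), "PC", "A", 0:2, 10)
#' accumulation_series(build_incidence(ev, un))
#' @export
accumulation_series <- function(x, ordering = c("chronological", "permuted"),
                                n_permutations = 100, seed = 1) {
  stopifnot(inherits(x, "incidence"))
  ordering <- match.arg(ordering)
  n <- ncol(x)
  if (n < 1) stop("incidence matrix has no sampling units", call. = FALSE)
  cum_rich <- function(cols) {
    seen <- rep(FALSE, nrow(x))
    out <- numeric(n)
    for (t in seq_len(n)) {
      seen <- seen | (x[, cols[t]] > 0)
      out[t] <- sum(seen)
    }
    out
  }
  if (ordering == "chronological") {
    S <- cum_rich(seq_len(n))
  } else {
    set.seed(as.integer(seed))
    acc <- numeric(n)
    for (p in seq_len(n_permutations)) {
      acc <- acc + cum_rich(sample.int(n))
    }
    S <- acc / n_permutations
  }
  data.frame(t = seq_len(n), S_obs = S)
}

#' Fit the exponential species accumulation model
#'
#' Fits \deqn{S(t) = \frac{a}{b}\left(1 - e^{-bt}\right)} to a cumulative
#' species series by least squares, where `t` is survey effort (point-count
#' number), `a` is the initial rate of species increase (species per unit
#' effort) and `a/b` is the asymptotic species richness. The effort needed
#' for 90% survey completeness is \eqn{t_{0.9} = -\ln(0.1)/b}.
#'
#' For fixed `b` the asymptote `c = a/b` enters the model linearly and has a
#' closed-form least-squares optimum, so the fit profiles the residual sum
#' of squares over `b` alone and solves it by deterministic 1-D
#' minimisation (golden-section bracket scan followed by [stats::optimize()]
#' refinement). No starting values or random restarts are needed.
#'
#' @param series data frame with columns `t` and `S_obs` (from
#'   [accumulation_series()]), or an `incidence` object (the chronological
#'   series is used).
#' @return object of class `accum_fit` with components `a`, `b`,
#'   `asymptote` (`a/b`), `t90` (`-log(0.1)/b`), `residual_ss`, `n_units`,
#'   `fitted`, `series`.
#' @examples
#' t <- 1:50
#' s <- (10 / 0.2) * (1 - exp(-0.2 * t))
#' fit <- fit_accumulation(data.frame(t = t, S_obs = s))
#' coef(fit)
#' @export
fit_accumulation <- function(series) {
  if (inherits(series, "incidence")) series <- accumulation_series(series)
  stopifnot(all(c("t", "S_obs") %in% names(series)))
  t <- as.numeric(series$t)
  y <- as.numeric(series$S_obs)
  if (length(unique(t)) < 3) {
    stop("need at least 3 distinct effort values to fit", call. = FALSE)
  }
  if (any(diff(y[order(t)]) < -1e-9)) {
    stop("cumulative species counts must be non-decreasing", call. = FALSE)
  }
  if (all(y == 0)) stop("all-zero series cannot be fitted", call. = FALSE)

  # profiled residual sum of squares: c(b) = sum(y f)/sum(f^2),
  # f = 1 - exp(-b t)
  rss <- function(b) {
    f <- 1 - exp(-b * t)
    cc <- sum(y * f) / sum(f * f)
    sum((y - cc * f)^2)
  }
  # bracket scan over log-spaced b, then refine
  bgrid <- exp(seq(log(1e-6), log(10 / stats::median(t)) + log(100),
                   length.out = 400))
  v <- vapply(bgrid, rss, numeric(1))
  i <- which.min(v)
  lo <- bgrid[max(1, i - 1)]
  hi <- bgrid[min(length(bgrid), i + 1)]
  opt <- stats::optimize(rss, lower = lo, upper = hi, tol = 1e-12)
  b <- opt$minimum
  f <- 1 - exp(-b * t)
  cc <- sum(y * f) / sum(f * f)
  if (!is.finite(b) || b <= 0 || !is.finite(cc) || cc <= 0) {
    stop(sprintf("accumulation fit failed to converge (best RSS %.4g)",
                 opt$objective), call. = FALSE)
  }
  a <- cc * b
  structure(
    list(a = a, b = b, asymptote = cc, t90 = -log(0.1) / b,
         residual_ss = opt$objective, n_units = length(t),
         fitted = cc * f, series = data.frame(t = t, S_obs = y)),
    class = "accum_fit"
  )
}

#' @export
print.accum_fit <- function(x, digits = 4, ...) {
  cat("Species accumulation model: S(t) = (a/b) (1 - exp(-b t))\n")
  cat(sprintf("  a = %.*g (initial rate), b = %.*g\n",
              digits, x$a, digits, x$b))
  cat(sprintf("  asymptote a/b = %.*g species; t0.9 = %.*g units\n",
              digits, x$asymptote, digits, x$t90))
  cat(sprintf("  residual SS = %.*g over %d units\n",
              digits, x$residual_ss, x$n_units))
  invisible(x)
}

#' @export
summary.accum_fit <- function(object, ...) {
  res <- object$series$S_obs - object$fitted
  out <- list(
    coefficients = c(a = object$a, b = object$b),
    asymptote = object$asymptote, t90 = object$t90,
    residual_ss = object$residual_ss, n_units = object$n_units,
    sigma = sqrt(object$residual_ss / max(1, object$n_units - 2)),
    residual_range = range(res),
    completeness = object$series$S_obs[object$n_units] / object$asymptote
  )
  class(out) <- "summary.accum_fit"
  out
}

#' @export
print.summary.accum_fit <- function(x, digits = 4, ...) {
  cat("Species accumulation fit\n")
  print(signif(x$coefficients, digits))
  cat(sprintf("asymptote: %.*g   t0.9: %.*g   observed completeness: %.1f%%\n",
              digits, x$asymptote, digits, x$t90, 100 * x$completeness))
  cat(sprintf("residual SD: %.*g on %d units\n", digits, x$sigma,
              x$n_units))
  invisible(x)
}

#' @export
coef.accum_fit <- function(object, ...) {
  c(a = object$a, b = object$b)
}

#' @export
predict.accum_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$series$t else {
    if (is.data.frame(newdata)) newdata$t else as.numeric(newdata)
  }
  object$asymptote * (1 - exp(-object$b * t))
}

#' @export
residuals.accum_fit <- function(object, ...) {
  object$series$S_obs - object$fitted
}

#' @export
plot.accum_fit <- function(x, ...) {
  plot(x$series$t, x$series$S_obs, pch = 16,
       xlab = "effort (sampling units)", ylab = "cumulative species",
       ...)
  tt <- seq(min(x$series$t), max(x$series$t), length.out = 200)
  graphics::lines(tt, predict(x, tt))
  graphics::abline(h = x$asymptote, lty = 3)
  invisible(x)
}

#' Effort required for 90% survey completeness
#'
#' For the exponential accumulation model the effort at which the expected
#' cumulative richness reaches a fraction `q` of the asymptote is
#' \eqn{t_q = -\ln(1-q)/b}; the conventional completeness target is
#' `q = 0.9`, so \eqn{t_{0.9} = -\ln(0.1)/b}.
#'
#' @param fit an `accum_fit` object, or a positive decay parameter `b`.
#' @param q completeness fraction, default 0.9.
#' @return effort in sampling units.
#' @examples
#' t90(log(10))        # exactly 1
#' t90(log(10) / 34)   # exactly 34
#' @export
t90 <- function(fit, q = 0.9) {
  b <- if (inherits(fit, "accum_fit")) fit$b else as.numeric(fit)
  if (!is.finite(b) || b <= 0) {
    stop("decay parameter b must be positive", call. = FALSE)
  }
  -log(1 - q) / b
}

#' Richness, overlap and forest-dependency summary across methods
#'
#' Set algebra over per-method species sets: per-method counts, combined
#' (union) richness, species unique to each method, the all-methods
#' intersection, every Venn region, and per-method forest-dependency class
#' counts (classes `FF`, `F`, `f`; species with class `none` are excluded
#' from the forest tallies and never aggregated across classes).
#'
#' @param sets named list of character vectors (species per method), or a
#'   named list of `incidence` objects.
#' @param dependency optional lookup data frame with columns `species`,
#'   `class`.
#' @return object of class `richness_summary`: list with `species_sets`,
#'   `counts`, `combined`, `unique_counts`, `intersection`, `venn`
#'   (region sizes keyed by membership pattern) and `forest_counts`
#'   (methods x classes matrix) when a lookup is given.
#' @export
richness_summary <- function(sets, dependency = NULL) {
  stopifnot(is.list(sets), length(sets) >= 1, !is.null(names(sets)))
  sets <- lapply(sets, function(s) {
    if (inherits(s, "incidence")) rownames(s)[rowSums(s) > 0] else
      unique(as.character(s))
  })
  methods <- names(sets)
  all_sp <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) all_sp %in% s,
                   logical(length(all_sp)))
  if (length(all_sp) == 1) member <- matrix(member, nrow = 1,
                                            dimnames = list(all_sp, methods))
  counts <- vapply(sets, length, integer(1))
  pattern <- apply(member, 1, function(r) paste(methods[r], collapse = "+"))
  venn <- table(pattern)
  uniq <- vapply(methods, function(m) {
    others <- unlist(sets[setdiff(methods, m)])
    sum(!(sets[[m]] %in% others))
  }, integer(1))
  inter <- if (length(sets) == 1) length(sets[[1]]) else
    length(Reduce(intersect, sets))
  forest <- NULL
  if (!is.null(dependency)) {
    cls <- c("FF", "F", "f")
    forest <- t(vapply(sets, function(s) {
      d <- dependency$class[match(s, dependency$species)]
      vapply(cls, function(k) sum(d == k, na.rm = TRUE), integer(1))
    }, integer(3)))
    colnames(forest) <- cls
  }
  structure(
    list(species_sets = sets, counts = counts,
         combined = length(all_sp), unique_counts = uniq,
         intersection = inter,
         venn = stats::setNames(as.integer(venn), names(venn)),
         forest_counts = forest),
    class = "richness_summary"
  )
}

#' @export
print.richness_summary <- function(x, ...) {
  cat("Species richness by method:\n")
  print(x$counts)
  cat(sprintf("combined: %d   all-method intersection: %d\n",
              x$combined, x$intersection))
  cat("unique to one method:\n")
  print(x$unique_counts)
  if (!is.null(x$forest_counts)) {
    cat("forest-dependency classes (FF specialist / F generalist / f visitor):\n")
    print(x$forest_counts)
  }
  invisible(x)
}
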