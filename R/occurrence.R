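#' Effort-matched simulated point counts from ARU recordings
#'
#' A 10-minute point count is matched in effort by pooling `k` one-minute
#' recordings: each simulated point count draws `k` distinct recordings
#' uniformly without replacement from the site-wide pool and takes the union
#' of their species annotations. Draws are independent across simulated
#' counts, so the pool is reused between counts (with 300 annotated
#' recordings and 40 counts of 10, global without-replacement is
#' impossible); set `replace_within = TRUE` to allow a recording to repeat
#' within one simulated count.
#'
#' @param recordings an `incidence` object over ARU recordings (columns are
#'   recordings).
#' @param k recordings pooled per simulated count (default 10, matching the
#'   10-minute count duration).
#' @param n_sim number of simulated point counts.
#' @param seed integer seed.
#' @param replace_within draw recordings with replacement within one
#'   simulated count (default `FALSE`: a real count cannot survey the same
#'   minute twice).
#' @return object of class `simulated_pcs`: list with `species_sets`
#'   (list of `n_sim` species character vectors), `members` (list of member
#'   recording ids), `k`, `n_sim`.
#' @export
simulate_effort_matched_pcs <- function(recordings, k = 10, n_sim, seed = 1,
                                        replace_within = FALSE) {
  stopifnot(inherits(recordings, "incidence"), k >= 1, n_sim >= 1)
  pool <- colnames(recordings)
  if (!replace_within && length(pool) < k) {
    stop(sprintf("recording pool (%d) smaller than k = %d",
                 length(pool), k), call. = FALSE)
  }
  set.seed(as.integer(seed))
  members <- vector("list", n_sim)
  species_sets <- vector("list", n_sim)
  sp <- rownames(recordings)
  for (i in seq_len(n_sim)) {
    pick <- sample(length(pool), k, replace = replace_within)
    members[[i]] <- pool[pick]
    present <- rowSums(recordings[, pick, drop = FALSE]) > 0
    species_sets[[i]] <- sp[present]
  }
  structure(list(species_sets = species_sets, members = members,
                 k = as.integer(k), n_sim = as.integer(n_sim)),
            class = "simulated_pcs")
}

#' @export
print.simulated_pcs <- function(x, ...) {
  cat(sprintf("%d simulated point counts of %d recordings each\n",
              x$n_sim, x$k))
  cat(sprintf("  mean species per simulated count: %.1f\n",
              mean(lengths(x$species_sets))))
  invisible(x)
}

#' Frequency of occurrence
#'
#' The fraction of sampling units (point counts, simulated point counts or
#' checklists) in which each species was recorded — the study's
#' relative-abundance proxy. Species recorded nowhere are omitted from the
#' table; [fo_lookup()] returns 0 for them.
#'
#' @param units the sampling units: an `incidence` object, a
#'   `simulated_pcs` object, or a list of species character vectors.
#' @param method,site labels stored on the table.
#' @return object of class `frequency_table`: data frame with columns
#'   `species` and `fo`, sorted by `fo` descending then species name, with
#'   attributes `n_units`, `method`, `site`.
#' @examples
#' frequency_of_occurrence(list(c("a", "b"), "a", "a"))
#' @export
frequency_of_occurrence <- function(units, method = NA_character_,
                                    site = NA_character_) {
  sets <- if (inherits(units, "incidence")) {
    apply(units, 2, function(col) rownames(units)[col > 0],
          simplify = FALSE)
  } else if (inherits(units, "simulated_pcs")) {
    units$species_sets
  } else {
    units
  }
  n <- length(sets)
  if (n < 1) stop("frequency of occurrence needs at least one unit",
                  call. = FALSE)
  counts <- table(unlist(lapply(sets, unique)))
  fo <- as.numeric(counts) / n
  out <- data.frame(species = names(counts), fo = fo,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$fo, out$species), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_units") <- n
  attr(out, "method") <- method
  attr(out, "site") <- site
  class(out) <- c("frequency_table", "data.frame")
  out
}

#' @rdname frequency_of_occurrence
#' @param table a `frequency_table`.
#' @param species species to look up; absentees return 0.
#' @export
fo_lookup <- function(table, species) {
  i <- match(species, table$species)
  out <- table$fo[i]
  out[is.na(i)] <- 0
  out
}
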