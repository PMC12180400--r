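#' Heard-versus-seen composition of point counts
#'
#' For each species, over the point-count units in which it was recorded:
#' the number of units (`n_observations`), the fraction of those units in
#' which it was (only) heard, and a flag for species more often heard than
#' seen (`fraction_heard > 0.5`). When a species was both heard and seen
#' within one unit the unit counts as seen by default — sight is the
#' stronger cue (`cue_resolution = "seen_wins"`); `"heard_any"` counts the
#' unit as heard if any record in it was heard.
#'
#' @param pc_events `detection_events` with `method == "PC"` and cues
#'   recorded (`heard`/`seen`; `unknown` cues are an error — the analysis
#'   requires cue capture in the field).
#' @param cue_resolution per-unit cue rule, `"seen_wins"` (default) or
#'   `"heard_any"`.
#' @return object of class `cue_summary`: data frame with columns
#'   `species`, `n_observations`, `fraction_heard`, `more_heard_than_seen`,
#'   sorted by `n_observations` descending.
#' @export
cue_summary <- function(pc_events, cue_resolution = c("seen_wins",
                                                      "heard_any")) {
  cue_resolution <- match.arg(cue_resolution)
  stopifnot(inherits(pc_events, "detection_events"))
  if (any(pc_events$method != "PC")) {
    stop("cue analysis is defined for point counts only", call. = FALSE)
  }
  if (any(pc_events$cue == "unknown")) {
    stop("events with cue = 'unknown' present: record heard/seen cues ",
         "during point counts to run the cue analysis", call. = FALSE)
  }
  key <- interaction(pc_events$species, pc_events$unit_id, drop = TRUE)
  seen_any <- tapply(pc_events$cue == "seen", key, any)
  heard_any <- tapply(pc_events$cue == "heard", key, any)
  unit_heard <- if (cue_resolution == "seen_wins") !seen_any else heard_any
  sp_of <- tapply(pc_events$species, key, function(s) s[1])
  agg <- data.frame(species = as.character(sp_of),
                    heard = as.logical(unit_heard))
  n_obs <- tapply(rep(1L, nrow(agg)), agg$species, sum)
  n_heard <- tapply(agg$heard, agg$species, sum)
  out <- data.frame(
    species = names(n_obs),
    n_observations = as.integer(n_obs),
    fraction_heard = as.numeric(n_heard) / as.numeric(n_obs),
    stringsAsFactors = FALSE
  )
  out$more_heard_than_seen <- out$fraction_heard > 0.5
  out <- out[order(-out$n_observations, out$species), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cue_summary", "data.frame")
  out
}

#' Overlap between heard-dominant species and ARU detections
#'
#' Of the species more often heard than seen during point counts, the
#' fraction also recorded by the autonomous recording units. Reported as a
#' whole percent (standard round-half-to-even).
#'
#' @param flagged a `cue_summary` (only rows with `more_heard_than_seen`
#'   are used) or a character vector of heard-dominant species.
#' @param aru_species character vector of species detected by the ARU.
#' @return list with `n_flagged`, `n_overlap`, `fraction` and
#'   `percent` (rounded to a whole percent).
#' @export
heard_aru_overlap <- function(flagged, aru_species) {
  sp <- if (inherits(flagged, "cue_summary")) {
    flagged$species[flagged$more_heard_than_seen]
  } else {
    unique(as.character(flagged))
  }
  if (!length(sp)) {
    stop("no heard-dominant species to intersect", call. = FALSE)
  }
  n_overlap <- sum(sp %in% aru_species)
  frac <- n_overlap / length(sp)
  list(n_flagged = length(sp), n_overlap = n_overlap,
       fraction = frac, percent = round(100 * frac))
}
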