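#' Parameterised synthetic bird community
#'
#' Defines a community of `n_species` species, each permanently present at
#' the site, with heterogeneous per-channel detection probabilities. The
#' model is occupancy-free: every species is available on every survey and
#' only detection is stochastic, because all downstream analyses operate
#' purely on detections. Relative abundance weights (log-normal on the
#' simplex) drive detectability through a saturating exposure curve
#' `p = 1 - exp(-rate * n_species * w)` per channel, so common species are
#' detected often and rare ones seldom, with channel-specific rates. The
#' defaults (`sigma_abundance = 2`, sight 0.05, vocal-per-minute 0.02,
#' checklist 0.6) were chosen so a 40-count campaign shows realistic survey
#' structure: a species accumulation curve that is still rising after tens
#' of counts, point counts missing the rarest species, checklists
#' accumulating the longest lists, and most (not all) species more often
#' heard than seen — a surveyed minute offers nine vocal opportunities per
#' count against one sighting opportunity.
#'
#' @param n_species number of species in the community.
#' @param seed integer seed controlling the community draw.
#' @param abundance optional simplex weights (length `n_species`); drawn
#'   log-normal with `sdlog = sigma_abundance` and normalised when omitted.
#' @param p_sight,p_vocal_minute,checklist_detect optional explicit
#'   per-species probabilities overriding the abundance-driven defaults:
#'   probability of sighting the species during one point count, of
#'   detecting it acoustically in one surveyed minute, and of it appearing
#'   on one checklist.
#' @param sigma_abundance log-scale SD of the abundance weights.
#' @param sight_rate,vocal_rate,list_rate channel exposure rates (see above).
#' @return an object of class `community_model`.
#' @examples
#' cm <- community_model(20, seed = 1)
#' range(cm$p_vocal_minute)
#' @export
community_model <- function(n_species, seed = 1, abundance = NULL,
                            p_sight = NULL, p_vocal_minute = NULL,
                            checklist_detect = NULL,
                            sigma_abundance = 2,
                            sight_rate = 0.05, vocal_rate = 0.02,
                            list_rate = 0.6) {
  stopifnot(n_species >= 1)
  set.seed(as.integer(seed))
  if (is.null(abundance)) {
    w <- stats::rlnorm(n_species, sdlog = sigma_abundance)
    abundance <- w / sum(w)
  } else {
    stopifnot(length(abundance) == n_species)
    if (abs(sum(abundance) - 1) > 1e-8) {
      stop("abundance must sum to 1", call. = FALSE)
    }
  }
  expose <- function(rate) 1 - exp(-rate * n_species * abundance)
  p_sight <- p_sight %||% expose(sight_rate)
  p_vocal_minute <- p_vocal_minute %||% expose(vocal_rate)
  checklist_detect <- checklist_detect %||% expose(list_rate)
  for (v in list(p_sight, p_vocal_minute, checklist_detect)) {
    stopifnot(length(v) == n_species)
  }
  assert_prob(p_sight, "p_sight")
  assert_prob(p_vocal_minute, "p_vocal_minute")
  assert_prob(checklist_detect, "checklist_detect")
  structure(
    list(
      n_species = as.integer(n_species),
      species = sprintf("Species synthetica%03d", seq_len(n_species)),
      abundance = abundance, p_sight = p_sight,
      p_vocal_minute = p_vocal_minute,
      checklist_detect = checklist_detect, seed = as.integer(seed)
    ),
    class = "community_model"
  )
}

#' @export
print.community_model <- function(x, ...) {
  cat(sprintf("Synthetic community: %d species (seed %d)\n",
              x$n_species, x$seed))
  cat(sprintf("  median p_sight %.3f, p_vocal/minute %.3f, checklist %.3f\n",
              stats::median(x$p_sight), stats::median(x$p_vocal_minute),
              stats::median(x$checklist_detect)))
  invisible(x)
}

#' Simulate point-count surveys from a synthetic community
#'
#' One sampling unit per (point, visit). Each point count comprises a
#' 1-minute settling interval followed by 9 surveyed minutes: species `s`
#' is sighted with probability `p_sight[s]` (one opportunity per count) and
#' heard with probability `1 - (1 - p_vocal_minute[s])^9` (one opportunity
#' per surveyed minute), independently. The detection probability is
#' therefore `1 - (1 - p_sight)(1 - p_vocal_minute)^9`. The cue is `seen`
#' whenever the sight channel fired and `heard` when only the sound channel
#' did (sight is taken as the stronger cue).
#'
#' @param model a [community_model()].
#' @param n_points number of point-count stations.
#' @param n_visits visits per station.
#' @param site site label.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param minutes surveyed minutes per count after settling (default 9).
#' @return list with elements `events` (`detection_events`) and `units`
#'   (`sampling_units`, effort 10 minutes each).
#' @export
simulate_point_counts <- function(model, n_points, n_visits, site = "SYN",
                                  seed = 1, minutes = 9) {
  stopifnot(inherits(model, "community_model"), n_points >= 1, n_visits >= 1)
  set.seed(as.integer(seed))
  n_units <- n_points * n_visits
  grid <- expand.grid(point = seq_len(n_points), visit = seq_len(n_visits))
  ids <- sprintf("%s_pc_p%02d_v%02d", site, grid$point, grid$visit)
  K <- model$n_species
  sight <- matrix(stats::runif(K * n_units) < model$p_sight,
                  nrow = K)
  p_hear <- 1 - (1 - model$p_vocal_minute)^minutes
  heard <- matrix(stats::runif(K * n_units) < p_hear, nrow = K)
  det <- sight | heard
  idx <- which(det, arr.ind = TRUE)
  ev <- detection_events(
    method = "PC", site = site, unit_id = ids[idx[, 2]],
    species = model$species[idx[, 1]],
    cue = ifelse(sight[idx], "seen", "heard")
  )
  ev$visit <- grid$visit[idx[, 2]]
  un <- sampling_units(ids, "PC", site, order_index = seq_len(n_units) - 1L,
                       effort = 10)
  list(events = ev, units = un)
}

#' Simulate one-minute ARU recordings
#'
#' Each recording is one surveyed minute: species `s` is annotated with
#' probability `p_vocal_minute[s]`. Each annotation is assigned to the
#' foreground or background layer with equal probability; the layer is
#' display-only (presence analyses union the layers).
#'
#' @inheritParams simulate_point_counts
#' @param n_recordings number of one-minute recordings.
#' @return list with `events` and `units` (effort 1 minute each);
#'   `n_recordings = 0` yields empty collections.
#' @export
simulate_recordings <- function(model, n_recordings, site = "SYN", seed = 1) {
  stopifnot(inherits(model, "community_model"), n_recordings >= 0)
  set.seed(as.integer(seed))
  ids <- if (n_recordings > 0) {
    sprintf("%s_rec_%05d", site, seq_len(n_recordings))
  } else character(0)
  K <- model$n_species
  if (n_recordings == 0) {
    ev <- detection_events(method = character(0), site = character(0),
                           unit_id = character(0), species = character(0))
    un <- sampling_units(character(0), character(0), character(0),
                         integer(0), numeric(0))
    return(list(events = ev, units = un))
  }
  det <- matrix(stats::runif(K * n_recordings) < model$p_vocal_minute,
                nrow = K)
  idx <- which(det, arr.ind = TRUE)
  layer <- ifelse(stats::runif(nrow(idx)) < 0.5, "foreground", "background")
  ev <- detection_events(
    method = "ARU", site = site, unit_id = ids[idx[, 2]],
    species = model$species[idx[, 1]], layer = layer
  )
  ev$timestamp <- sprintf("2017-01-01T%02d:%02d:00",
                          6L + (idx[, 2] - 1L) %/% 60L, (idx[, 2] - 1L) %% 60L)
  un <- sampling_units(ids, "ARU", site,
                       order_index = seq_len(n_recordings) - 1L, effort = 1)
  list(events = ev, units = un)
}

#' Simulate citizen-science checklists
#'
#' Species `s` appears on each list with probability `checklist_detect[s]`.
#' List coordinates are jittered uniformly over a disc of radius
#' `jitter_km` around the site centre (small-angle lat/lon conversion, so
#' radii are accurate to ~0.1%), emulating lists scattered across nearby
#' atlas pentads.
#'
#' @inheritParams simulate_point_counts
#' @param n_lists number of full-protocol checklists.
#' @param site_lat,site_lon site centre, decimal degrees.
#' @param jitter_km radius of the coordinate jitter disc (km).
#' @return list with `events` and `units` (effort 120 minutes each,
#'   coordinates attached).
#' @export
simulate_checklists <- function(model, n_lists, site = "SYN", seed = 1,
                                site_lat = -0.39, site_lon = 36.96,
                                jitter_km = 15) {
  stopifnot(inherits(model, "community_model"), n_lists >= 0)
  set.seed(as.integer(seed))
  if (n_lists == 0) {
    ev <- detection_events(method = character(0), site = character(0),
                           unit_id = character(0), species = character(0))
    un <- sampling_units(character(0), character(0), character(0),
                         integer(0), numeric(0))
    return(list(events = ev, units = un))
  }
  ids <- sprintf("%s_list_%04d", site, seq_len(n_lists))
  theta <- stats::runif(n_lists, 0, 2 * pi)
  r <- jitter_km * sqrt(stats::runif(n_lists))
  lat <- site_lat + (r * sin(theta)) / 111.19
  lon <- site_lon + (r * cos(theta)) / (111.19 * cos(site_lat * pi / 180))
  K <- model$n_species
  det <- matrix(stats::runif(K * n_lists) < model$checklist_detect, nrow = K)
  idx <- which(det, arr.ind = TRUE)
  ev <- detection_events(
    method = "KBM", site = site, unit_id = ids[idx[, 2]],
    species = model$species[idx[, 1]]
  )
  ev$lat <- lat[idx[, 2]]
  ev$lon <- lon[idx[, 2]]
  un <- sampling_units(ids, "KBM", site, order_index = seq_len(n_lists) - 1L,
                       effort = 120, lat = lat, lon = lon)
  list(events = ev, units = un)
}

#' Gaussian-prototype embedding model
#'
#' Emulates a pretrained bioacoustic embedding network: each species has a
#' fixed prototype vector, and a one-minute recording is represented by the
#' mean over its 5-second segments of (mean of present-species prototypes +
#' isotropic Gaussian noise).
#'
#' @param n_species number of species (prototypes).
#' @param dim embedding dimensionality (default 1280, the width typical of
#'   large pretrained bird-vocalisation encoders).
#' @param noise_sd isotropic segment noise SD.
#' @param segments_per_recording 5-second segments per 1-minute recording
#'   (default 12).
#' @param seed integer seed controlling the prototype draw.
#' @param species optional species names for the prototypes.
#' @return object of class `embedding_model`.
#' @export
embedding_model <- function(n_species, dim = 1280, noise_sd = 0.1,
                            segments_per_recording = 12, seed = 1,
                            species = NULL) {
  stopifnot(n_species >= 1, dim >= 1, noise_sd >= 0,
            segments_per_recording >= 1)
  set.seed(as.integer(seed))
  proto <- matrix(stats::rnorm(n_species * dim), nrow = n_species)
  species <- species %||% sprintf("Species synthetica%03d", seq_len(n_species))
  rownames(proto) <- species
  structure(
    list(dim = as.integer(dim), prototypes = proto,
         noise_sd = noise_sd,
         segments_per_recording = as.integer(segments_per_recording),
         species = species, seed = as.integer(seed)),
    class = "embedding_model"
  )
}

#' Simulate per-recording embeddings for labelled recordings
#'
#' Every segment vector is the mean of the prototypes of the species present
#' in the recording plus isotropic noise; the recording feature is the mean
#' over segments. Recordings with no species get pure noise around the
#' origin.
#'
#' @param emodel an [embedding_model()].
#' @param labels list of character vectors: species present per recording
#'   (may be empty).
#' @param unit_id optional recording ids.
#' @param seed integer seed.
#' @param keep_segments also attach the per-recording segment matrices as
#'   attribute `segments` (a list of segments x dim matrices).
#' @return an `embedding_set`: list with `features` (recordings x dim
#'   matrix), `labels` (list of species sets) and `unit_id`.
#' @export
simulate_embeddings <- function(emodel, labels, unit_id = NULL, seed = 1,
                                keep_segments = FALSE) {
  stopifnot(inherits(emodel, "embedding_model"), is.list(labels))
  set.seed(as.integer(seed))
  n <- length(labels)
  unit_id <- unit_id %||% sprintf("rec_%05d", seq_len(n))
  d <- emodel$dim
  m <- emodel$segments_per_recording
  feats <- matrix(0, nrow = n, ncol = d)
  seg_list <- if (keep_segments) vector("list", n) else NULL
  for (i in seq_len(n)) {
    sp <- labels[[i]]
    base <- if (length(sp)) {
      colMeans(emodel$prototypes[sp, , drop = FALSE])
    } else {
      rep(0, d)
    }
    segs <- matrix(rep(base, each = m), nrow = m) +
      matrix(stats::rnorm(m * d, sd = emodel$noise_sd), nrow = m)
    feats[i, ] <- colMeans(segs)
    if (keep_segments) seg_list[[i]] <- segs
  }
  rownames(feats) <- unit_id
  out <- embedding_set(feats, labels, unit_id)
  if (keep_segments) attr(out, "segments") <- seg_list
  out
}

#' @rdname simulate_embeddings
#' @param features numeric matrix, one row per recording.
#' @export
embedding_set <- function(features, labels, unit_id = NULL) {
  stopifnot(is.matrix(features), length(labels) == nrow(features))
  unit_id <- unit_id %||% rownames(features) %||%
    sprintf("rec_%05d", seq_len(nrow(features)))
  structure(list(features = features, labels = labels,
                 unit_id = as.character(unit_id)),
            class = "embedding_set")
}

#' @export
print.embedding_set <- function(x, ...) {
  cat(sprintf("Embedding set: %d recordings x %d dims, %d labelled\n",
              nrow(x$features), ncol(x$features),
              sum(lengths(x$labels) > 0)))
  invisible(x)
}
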