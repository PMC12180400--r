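#' Detection events and sampling units
#'
#' The package represents field data in two long-format data frames:
#'
#' * **Detection events** (`detection_events`): one row per species record
#'   inside one sampling unit. Columns: `method` (`"PC"`, `"ARU"` or `"KBM"`),
#'   `site`, `unit_id` (point-count id, recording id or checklist id),
#'   `species` (scientific binomial; the identity key), `cue` (`"heard"`,
#'   `"seen"` or `"unknown"`; only point counts carry a cue),
#'   `layer` (`"foreground"`, `"background"` or `"n/a"`; only ARU annotations
#'   carry a layer) and `date`.
#' * **Sampling units** (`sampling_units`): one row per survey unit. Columns:
#'   `unit_id`, `method`, `site`, `order_index` (chronological rank, unique
#'   within site and method), `effort` (minutes: a point count is 10, a
#'   recording 1, a checklist at least 120) and optional `lat`/`lon`
#'   (decimal degrees).
#'
#' @param method,site,unit_id,species,cue,layer,date vectors recycled to a
#'   common length; see Details above for admissible values.
#' @return `detection_events()` returns a validated data frame of class
#'   `detection_events`.
#' @examples
#' detection_events(method = "PC", site = "A", unit_id = "p1v1",
#'                  species = "Pycnonotus barbatus", cue = "heard")
#' @export
detection_events <- function(method, site, unit_id, species,
                             cue = "unknown", layer = "n/a",
                             date = as.Date(NA)) {
  if (length(unit_id) == 0) {
    df <- data.frame(method = character(0), site = character(0),
                     unit_id = character(0), species = character(0),
                     cue = character(0), layer = character(0),
                     date = as.Date(character(0)))
    class(df) <- unique(c("detection_events", class(df)))
    return(df)
  }
  df <- data.frame(
    method = as.character(method), site = as.character(site),
    unit_id = as.character(unit_id), species = as.character(species),
    cue = as.character(cue), layer = as.character(layer),
    date = date, stringsAsFactors = FALSE
  )
  validate_detection_events(df)
}

#' @rdname detection_events
#' @param x a data frame of detection events to validate.
#' @export
validate_detection_events <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("method", "site", "unit_id", "species", "cue", "layer")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("detection events missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(x$method %in% .methods)) {
    stop("method must be one of ", paste(.methods, collapse = ", "),
         call. = FALSE)
  }
  if (!all(x$cue %in% .cues)) {
    stop("cue must be one of ", paste(.cues, collapse = ", "), call. = FALSE)
  }
  if (!all(x$layer %in% .layers)) {
    stop("layer must be 'foreground', 'background' or 'n/a'", call. = FALSE)
  }
  bad_cue <- x$cue != "unknown" & x$method != "PC"
  if (any(bad_cue)) {
    stop("cue may only be recorded for point counts (method = 'PC')",
         call. = FALSE)
  }
  bad_layer <- x$layer != "n/a" & x$method != "ARU"
  if (any(bad_layer)) {
    stop("layer may only be recorded for ARU annotations (method = 'ARU')",
         call. = FALSE)
  }
  class(x) <- unique(c("detection_events", class(x)))
  x
}

#' @rdname detection_events
#' @param order_index chronological rank of each unit, unique within
#'   `(site, method)`.
#' @param effort survey effort in minutes; must be positive.
#' @param lat,lon optional coordinates in decimal degrees.
#' @return `sampling_units()` returns a validated data frame of class
#'   `sampling_units`.
#' @export
sampling_units <- function(unit_id, method, site, order_index, effort,
                           lat = NA_real_, lon = NA_real_) {
  if (length(unit_id) == 0) {
    df <- data.frame(unit_id = character(0), method = character(0),
                     site = character(0), order_index = integer(0),
                     effort = numeric(0), lat = numeric(0),
                     lon = numeric(0))
    class(df) <- unique(c("sampling_units", class(df)))
    return(df)
  }
  df <- data.frame(
    unit_id = as.character(unit_id), method = as.character(method),
    site = as.character(site), order_index = as.integer(order_index),
    effort = as.numeric(effort), lat = as.numeric(lat),
    lon = as.numeric(lon), stringsAsFactors = FALSE
  )
  if (any(df$effort <= 0)) stop("effort must be positive", call. = FALSE)
  if (any(df$order_index < 0)) {
    stop("order_index must be non-negative", call. = FALSE)
  }
  dup <- duplicated(df[, c("site", "method", "order_index")])
  if (any(dup)) {
    stop("order_index must be unique within (site, method)", call. = FALSE)
  }
  if (anyDuplicated(df$unit_id)) {
    stop("unit_id must be unique", call. = FALSE)
  }
  class(df) <- unique(c("sampling_units", class(df)))
  df
}

# Per-method CSV schemas. One detection per row, comma-separated UTF-8.
.schemas <- list(
  PC  = c(site = "site", unit_id = "unit_id", visit = "visit", date = "date",
          species = "species", cue = "cue"),
  ARU = c(site = "site", unit_id = "unit_id", timestamp = "timestamp",
          species = "species", layer = "layer"),
  KBM = c(list_id = "list_id", lat = "lat", lon = "lon", date = "date",
          species = "species")
)

#' Read and write detection tables
#'
#' Delimited-text (CSV, UTF-8, header) readers and writers for the three
#' survey methods. Expected columns are, by method:
#' point counts `site,unit_id,visit,date,species,cue`; ARU annotations
#' `site,unit_id,timestamp,species,layer`; citizen-science checklists
#' `list_id,lat,lon,date,species`. A cue column is rejected for ARU/KBM
#' files and a layer column for PC/KBM files, mirroring the field protocols
#' (only an observer can note heard-versus-seen; only an annotated recording
#' has foreground/background layers).
#'
#' @param path path to a CSV file.
#' @param method one of `"PC"`, `"ARU"`, `"KBM"`.
#' @param col_map optional named character vector mapping the schema's
#'   canonical column names to the names actually used in the file, e.g.
#'   `c(species = "sci_name")` for dialect variation.
#' @param site site label assigned to checklist events (the KBM schema
#'   carries coordinates, not a site; lists are attached to a site by the
#'   distance filter). Ignored for PC/ARU files, which name their site.
#' @return `read_detections()` returns a `detection_events` data frame; for
#'   KBM files the coordinates are carried in `lat`/`lon` columns.
#' @export
read_detections <- function(path, method = c("PC", "ARU", "KBM"),
                            col_map = NULL, site = "KBM") {
  method <- match.arg(method)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  schema <- .schemas[[method]]
  have <- names(raw)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      have[have == col_map[[canon]]] <- canon
    }
    names(raw) <- have
  }
  miss <- setdiff(names(schema), have)
  if (length(miss)) {
    stop(sprintf("%s file is missing required column(s): %s",
                 method, paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (method != "PC" && "cue" %in% have) {
    stop(sprintf("a 'cue' column is not allowed in %s files", method),
         call. = FALSE)
  }
  if (method != "ARU" && "layer" %in% have) {
    stop(sprintf("a 'layer' column is not allowed in %s files", method),
         call. = FALSE)
  }
  # drop fully blank rows
  blank <- apply(raw, 1, function(r) all(is.na(r) | trimws(r) == ""))
  raw <- raw[!blank, , drop = FALSE]

  parse_date <- function(v, fmt_col) {
    out <- as.Date(as.character(v), format = "%Y-%m-%d")
    bad <- which(!is.na(v) & trimws(as.character(v)) != "" & is.na(out))
    if (length(bad)) {
      stop(sprintf("unparseable date in %s at data row %d: '%s'",
                   fmt_col, bad[1], v[bad[1]]), call. = FALSE)
    }
    out
  }

  ev <- switch(method,
    PC = detection_events(
      method = "PC", site = raw$site, unit_id = raw$unit_id,
      species = raw$species,
      cue = if ("cue" %in% have) raw$cue else "unknown",
      date = parse_date(raw$date, "date")
    ),
    ARU = {
      ts <- as.character(raw$timestamp)
      detection_events(
        method = "ARU", site = raw$site, unit_id = raw$unit_id,
        species = raw$species, layer = raw$layer,
        date = parse_date(substr(ts, 1, 10), "timestamp")
      )
    },
    KBM = {
      df <- detection_events(
        method = "KBM", site = site, unit_id = raw$list_id,
        species = raw$species, date = parse_date(raw$date, "date")
      )
      df$lat <- as.numeric(raw$lat)
      df$lon <- as.numeric(raw$lon)
      df
    }
  )
  if (method == "PC" && "visit" %in% have) ev$visit <- raw$visit
  if (method == "ARU") ev$timestamp <- as.character(raw$timestamp)
  ev
}

#' @rdname read_detections
#' @param events a `detection_events` data frame (single method).
#' @export
write_detections <- function(events, path) {
  stopifnot(inherits(events, "detection_events"))
  method <- unique(events$method)
  if (length(method) != 1) {
    stop("write one method per file", call. = FALSE)
  }
  out <- switch(method,
    PC = data.frame(site = events$site, unit_id = events$unit_id,
                    visit = events$visit %||% NA,
                    date = as.character(events$date),
                    species = events$species, cue = events$cue),
    ARU = data.frame(site = events$site, unit_id = events$unit_id,
                     timestamp = events$timestamp %||%
                       as.character(events$date),
                     species = events$species, layer = events$layer),
    KBM = data.frame(list_id = events$unit_id, lat = events$lat,
                     lon = events$lon, date = as.character(events$date),
                     species = events$species)
  )
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = TRUE)
  invisible(path)
}

#' Species registry with forest dependency and conservation status
#'
#' Builds a registry keyed on scientific name from detection events, joined
#' against optional lookup tables. Forest dependency follows the three-class
#' East African convention: `FF` forest specialist, `F` forest generalist,
#' `f` forest visitor; species absent from the lookup default to `none`.
#' Conservation status uses IUCN codes (`LC`, `NT`, `VU`, `EN`, `CR`);
#' unknown when absent.
#'
#' @param events one or more `detection_events` data frames (or a list).
#' @param dependency optional data frame with columns `species`, `class`
#'   (values in `FF`, `F`, `f`).
#' @param status optional data frame with columns `species`, `status`.
#' @return data frame with columns `species`, `forest_dependency`, `status`.
#' @export
species_registry <- function(events, dependency = NULL, status = NULL) {
  if (is.data.frame(events)) events <- list(events)
  sp <- sort(unique(unlist(lapply(events, function(e) e$species))))
  reg <- data.frame(species = sp, forest_dependency = "none",
                    status = "unknown", stringsAsFactors = FALSE)
  if (!is.null(dependency)) {
    stopifnot(all(c("species", "class") %in% names(dependency)))
    bad <- setdiff(unique(dependency$class), c("FF", "F", "f"))
    if (length(bad)) {
      stop("unknown forest-dependency class: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    i <- match(reg$species, dependency$species)
    reg$forest_dependency[!is.na(i)] <- dependency$class[i[!is.na(i)]]
  }
  if (!is.null(status)) {
    stopifnot(all(c("species", "status") %in% names(status)))
    i <- match(reg$species, status$species)
    reg$status[!is.na(i)] <- status$status[i[!is.na(i)]]
  }
  reg
}

#' Species-by-unit incidence matrix
#'
#' Collapses detection events to a binary species-by-sampling-unit presence
#' matrix, the substrate for richness, accumulation and frequency-of-
#' occurrence computations. Units with no events appear as all-zero columns:
#' they still represent survey effort. Columns are ordered by the units'
#' chronological `order_index`.
#'
#' @param events a `detection_events` data frame.
#' @param units a `sampling_units` data frame covering every `unit_id`
#'   appearing in `events`.
#' @return an object of class `incidence`: a binary matrix (species rows,
#'   unit columns) with the unit table attached as attribute `units`.
#' @examples
#' ev <- detection_events(method = "PC", site = "A",
#'                        unit_id = c("u1", "u1", "u2"),
#'                        species = c("sp1", "sp2", "sp1"))
#' un <- sampling_units(c("u1", "u2"), "PC", "A", 0:1, effort = 10)
#' build_incidence(ev, un)
#' @export
build_incidence <- function(events, units) {
  stopifnot(inherits(units, "sampling_units"))
  unknown <- setdiff(unique(events$unit_id), units$unit_id)
  if (length(unknown)) {
    stop("events reference unknown unit(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  units <- units[order(units$site, units$method, units$order_index), ,
                 drop = FALSE]
  sp <- sort(unique(events$species))
  m <- matrix(0L, nrow = length(sp), ncol = nrow(units),
              dimnames = list(sp, units$unit_id))
  if (nrow(events)) {
    i <- match(events$species, sp)
    j <- match(events$unit_id, units$unit_id)
    m[cbind(i, j)] <- 1L
  }
  structure(m, units = units, class = c("incidence", "matrix"))
}

#' @rdname build_incidence
#' @param x an `incidence` object.
#' @param ... ignored.
#' @export
print.incidence <- function(x, ...) {
  cat(sprintf("Incidence matrix: %d species x %d sampling units\n",
              nrow(x), ncol(x)))
  u <- attr(x, "units")
  cat(sprintf("  methods: %s; sites: %s\n",
              paste(unique(u$method), collapse = ", "),
              paste(unique(u$site), collapse = ", ")))
  invisible(x)
}

#' Filter checklists by great-circle distance to a site
#'
#' Citizen-science atlas checklists cover 5-arcminute pentads; lists are
#' matched to a study site by retaining those whose coordinates fall within
#' a radius of the site (the operative selection is the radius, not pentad
#' polygon intersection). Distance is great-circle (haversine) on a
#' spherical Earth of radius 6371 km.
#'
#' @param lists a `sampling_units` data frame with non-missing `lat`/`lon`.
#' @param site_lat,site_lon site coordinates, decimal degrees.
#' @param max_km radius in kilometres (default 20; `Inf` keeps all).
#' @return the subset of `lists` within `max_km`, with a `dist_km` column.
#' @export
filter_checklists_by_distance <- function(lists, site_lat, site_lon,
                                          max_km = 20) {
  bad <- is.na(lists$lat) | is.na(lists$lon)
  if (any(bad)) {
    stop("checklist(s) missing coordinates: ",
         paste(utils::head(lists$unit_id[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  d_km <- geosphere::distHaversine(
    cbind(lists$lon, lists$lat), c(site_lon, site_lat), r = 6371000
  ) / 1000
  out <- lists[d_km <= max_km, , drop = FALSE]
  out$dist_km <- d_km[d_km <= max_km]
  out
}
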