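test_that("point-count CSV ingest preserves rows and cues", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "site,unit_id,visit,date,species,cue",
    "A,u1,1,2017-01-05,Pycnonotus barbatus,heard",
    "A,u1,1,2017-01-05,Cinnyris venustus,seen",
    "A,u2,2,2017-01-06,Pycnonotus barbatus,heard"
  ), f)
  ev <- read_detections(f, "PC")
  expect_s3_class(ev, "detection_events")
  expect_equal(nrow(ev), 3)
  expect_true(all(ev$method == "PC"))
  expect_equal(ev$cue, c("heard", "seen", "heard"))
  expect_equal(ev$date[1], as.Date("2017-01-05"))
})

test_that("schema violations are rejected with a named column", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,unit_id,species", "A,u1,x"), f)
  expect_error(read_detections(f, "PC"), "visit")

  # a cue column has no meaning for ARU annotations
  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "site,unit_id,timestamp,species,layer,cue",
    "A,r1,2017-01-05T06:00:00,x,foreground,heard"
  ), g)
  expect_error(read_detections(g, "ARU"), "cue")

  # bad dates surface the offending row
  h <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "site,unit_id,visit,date,species,cue",
    "A,u1,1,not-a-date,x,heard"
  ), h)
  expect_error(read_detections(h, "PC"), "date")
})

test_that("event invariants are enforced at construction", {
  expect_error(
    detection_events(method = "ARU", site = "A", unit_id = "r1",
                     species = "x", cue = "heard"),
    "point counts"
  )
  expect_error(
    detection_events(method = "PC", site = "A", unit_id = "u1",
                     species = "x", layer = "foreground"),
    "ARU"
  )
})

test_that("write/read round-trip is lossless for all three methods", {
  cm <- community_model(12, seed = 5)
  sims <- list(
    PC = simulate_point_counts(cm, 3, 2, seed = 1),
    ARU = simulate_recordings(cm, 15, seed = 2),
    KBM = simulate_checklists(cm, 6, seed = 3)
  )
  for (m in names(sims)) {
    ev <- sims[[m]]$events
    f <- withr::local_tempfile(fileext = ".csv")
    write_detections(ev, f)
    back <- read_detections(f, m, site = "SYN")
    key <- c("method", "site", "unit_id", "species", "cue", "layer")
    ord <- function(d) d[order(d$unit_id, d$species), key]
    expect_equal(ord(back), ord(as.data.frame(ev)),
                 ignore_attr = TRUE, label = m)
  }
})

test_that("column mapping handles dialect variation", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "site,unit_id,visit,date,sci_name,cue",
    "A,u1,1,2017-01-05,Pycnonotus barbatus,heard"
  ), f)
  ev <- read_detections(f, "PC", col_map = c(species = "sci_name"))
  expect_equal(ev$species, "Pycnonotus barbatus")
})

test_that("incidence matrix matches brute-force set membership", {
  un <- sampling_units(paste0("u", 1:2), "PC", "A", 0:1, 10)
  ev <- detection_events(method = "PC", site = "A",
                         unit_id = c("u1", "u2", "u1", "u1"),
                         species = c("spA", "spA", "spB", "spB"))
  inc <- build_incidence(ev, un)
  expect_equal(unname(inc["spA", ]), c(1L, 1L))
  # duplicate detections collapse to a single presence
  expect_equal(unname(inc["spB", ]), c(1L, 0L))

  set.seed(7)
  un2 <- sampling_units(paste0("u", 1:8), "PC", "A", 0:7, 10)
  ev2 <- detection_events(
    method = "PC", site = "A",
    unit_id = sample(un2$unit_id, 60, replace = TRUE),
    species = sample(paste0("sp", 1:12), 60, replace = TRUE)
  )
  inc2 <- build_incidence(ev2, un2)
  expect_equal(unclass(inc2)[, ], oracle_incidence(ev2, un2$unit_id),
               ignore_attr = TRUE)

  # invariant to event ordering
  shuf <- ev2[sample(nrow(ev2)), ]
  inc3 <- build_incidence(validate_detection_events(shuf), un2)
  expect_equal(unclass(inc2)[, ], unclass(inc3)[, ])
})

test_that("incidence construction flags unknown units and keeps empty ones", {
  un <- sampling_units(c("u1", "u2", "u3"), "PC", "A", 0:2, 10)
  ev <- detection_events(method = "PC", site = "A", unit_id = "u1",
                         species = "spA")
  inc <- build_incidence(ev, un)
  expect_equal(ncol(inc), 3)   # u2, u3 appear as all-zero effort columns
  expect_equal(sum(inc[, "u3"]), 0)
  bad <- detection_events(method = "PC", site = "A", unit_id = "u9",
                          species = "spA")
  expect_error(build_incidence(bad, un), "unknown unit")
})

test_that("checklist distance filter uses a 6371 km spherical Earth", {
  un <- sampling_units(c("l0", "l1"), "KBM", "K", 0:1, 120,
                       lat = c(0, 1), lon = c(36, 36))
  kept <- filter_checklists_by_distance(un, 0, 36, max_km = 20)
  expect_equal(kept$unit_id, "l0")
  expect_equal(kept$dist_km, 0)
  # one degree of latitude on a 6371 km sphere is ~111.19 km
  all_kept <- filter_checklists_by_distance(un, 0, 36, max_km = Inf)
  expect_equal(all_kept$dist_km[2], 6371 * pi / 180, tolerance = 1e-6)
  expect_equal(nrow(all_kept), 2)

  miss <- sampling_units("l2", "KBM", "K", 0L, 120)
  expect_error(filter_checklists_by_distance(miss, 0, 36, 20), "l2")
})

test_that("distance filter is monotone in the radius", {
  set.seed(11)
  un <- sampling_units(sprintf("l%02d", 1:30), "KBM", "K", 0:29, 120,
                       lat = runif(30, -1, 1), lon = runif(30, 35, 38))
  prev <- character(0)
  for (r in c(5, 20, 60, 200, Inf)) {
    ids <- filter_checklists_by_distance(un, 0, 36.5, r)$unit_id
    expect_true(all(prev %in% ids))
    prev <- ids
  }
  expect_setequal(prev, un$unit_id)
})

test_that("species registry joins dependency and status lookups", {
  ev <- detection_events(method = "PC", site = "A", unit_id = "u1",
                         species = c("spA", "spB", "spC"))
  dep <- data.frame(species = c("spA", "spB"), class = c("FF", "f"))
  st <- data.frame(species = "spC", status = "NT")
  reg <- species_registry(ev, dep, st)
  expect_equal(reg$forest_dependency, c("FF", "f", "none"))
  expect_equal(reg$status, c("unknown", "unknown", "NT"))
  expect_error(
    species_registry(ev, data.frame(species = "spA", class = "XX")),
    "class"
  )
})
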