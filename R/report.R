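#' Run configuration for the end-to-end survey comparison
#'
#' Builds and validates the configuration driving [run_report()]. Every
#' stage draws its randomness from a named child stream derived from the
#' single `seed`, so stages are independently reproducible. Defaults mirror
#' a two-site field campaign: 10 point-count stations per site visited 4 or
#' 6 times (40 and 60 counts), pools of annotated one-minute recordings
#' resampled into the same number of effort-matched simulated counts
#' (k = 10 one-minute recordings = one 10-minute count), and full-protocol
#' checklists.
#'
#' @param sites list of per-site settings; each site is a list with
#'   `name`, `n_points`, `n_visits`, `n_recordings`, `n_lists`, `n_sim`.
#' @param n_species community size of the synthetic community.
#' @param k recordings per simulated point count (validated so that
#'   `k` x 1-minute recordings equal the 10-minute count duration).
#' @param alpha significance level of the normality gate.
#' @param min_recordings classifier label filter threshold.
#' @param embedding_dim,noise_sd,segments embedding model settings.
#' @param hidden_units,epochs,learning_rate,train_fraction,n_runs classifier
#'   settings.
#' @param pc_minutes surveyed minutes per point count (after settling).
#' @param seed master seed.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(sites = NULL, n_species = 60, k = 10, alpha = 0.05,
                       min_recordings = 20, embedding_dim = 1280,
                       noise_sd = 0.1, segments = 12, hidden_units = 128,
                       epochs = 200, learning_rate = 1e-3,
                       train_fraction = 0.7, n_runs = 5, pc_minutes = 9,
                       seed = 1) {
  sites <- sites %||% list(
    list(name = "siteA", n_points = 10, n_visits = 4,
         n_recordings = 300, n_lists = 46, n_sim = 40),
    list(name = "siteB", n_points = 10, n_visits = 6,
         n_recordings = 900, n_lists = 12, n_sim = 60)
  )
  cfg <- list(sites = sites, n_species = n_species, k = k, alpha = alpha,
              min_recordings = min_recordings,
              embedding_dim = embedding_dim, noise_sd = noise_sd,
              segments = segments, hidden_units = hidden_units,
              epochs = epochs, learning_rate = learning_rate,
              train_fraction = train_fraction, n_runs = n_runs,
              pc_minutes = pc_minutes, seed = as.integer(seed))
  validate_run_config(cfg)
}

#' @rdname run_config
#' @param cfg a configuration list.
#' @export
validate_run_config <- function(cfg) {
  need <- c("sites", "n_species", "k", "alpha", "seed")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) {
    stop("run config missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  pc_minutes <- cfg$pc_minutes %||% 9
  if (cfg$k * 1 != pc_minutes + 1) {
    stop(sprintf(
      "effort mismatch: k = %d one-minute recordings must equal the ",
      cfg$k), sprintf(
      "%d-minute point count (settling + %d surveyed minutes)",
      pc_minutes + 1, pc_minutes), call. = FALSE)
  }
  for (s in cfg$sites) {
    sneed <- c("name", "n_points", "n_visits", "n_recordings", "n_lists",
               "n_sim")
    smiss <- setdiff(sneed, names(s))
    if (length(smiss)) {
      stop("site config missing field(s): ",
           paste(smiss, collapse = ", "), call. = FALSE)
    }
    if (s$n_sim < 1) stop("n_sim must be >= 1", call. = FALSE)
  }
  if (!is.null(cfg$paths)) {
    missing_paths <- !vapply(unlist(cfg$paths), file.exists, logical(1))
    if (any(missing_paths)) {
      stop("input path(s) do not exist: ",
           paste(unlist(cfg$paths)[missing_paths], collapse = ", "),
           call. = FALSE)
    }
  }
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path a YAML configuration file.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- unclass(run_config())
  for (nm in setdiff(names(defaults), names(cfg))) {
    cfg[[nm]] <- defaults[[nm]]
  }
  validate_run_config(cfg)
}

#' @keywords internal
log_stage <- function(quiet, stage, ...) {
  if (!quiet) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
  }
}

#' End-to-end synthetic survey comparison report
#'
#' Chains every stage of the analysis on the synthetic community: simulate
#' point counts, ARU recordings and checklists per site; tally richness and
#' forest composition; fit the species accumulation model; resample
#' recordings into effort-matched simulated point counts; compute
#' frequency-of-occurrence tables; run the normality-gated paired
#' comparisons for every method pair; summarise heard-versus-seen cues; and
#' train/evaluate the embedding classifier. Writes one CSV per stage plus a
#' human-readable summary to `out_dir`. With a fixed config seed the output
#' files are byte-identical across runs.
#'
#' @param config a `run_config` (or a YAML path accepted by
#'   [read_run_config()]).
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with all in-memory stage results.
#' @export
run_report <- function(config = run_config(), out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(unclass(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  cm <- community_model(config$n_species, seed = seed)
  emodel <- embedding_model(config$n_species, dim = config$embedding_dim,
                            noise_sd = config$noise_sd,
                            segments_per_recording = config$segments,
                            seed = seed, species = cm$species)
  dep_cls <- c("FF", "F", "f")
  set.seed(stage_seed(seed, "report"))
  dependency <- data.frame(
    species = cm$species,
    class = sample(dep_cls, config$n_species, replace = TRUE),
    stringsAsFactors = FALSE
  )
  results <- list(config = config, community = cm, dependency = dependency)
  summary_lines <- c(
    "Survey method comparison report (synthetic community)",
    sprintf("master seed: %d; %d species; k = %d recordings per simulated count",
            seed, config$n_species, config$k),
    sprintf("normality gate alpha = %.3g; classifier min_recordings = %d",
            config$alpha, config$min_recordings)
  )

  for (si in seq_along(config$sites)) {
    s <- config$sites[[si]]
    log_stage(quiet, "simulate", "site %s", s$name)
    pc <- simulate_point_counts(cm, s$n_points, s$n_visits, site = s$name,
                                seed = stage_seed(seed, "simulate_pc") + si,
                                minutes = config$pc_minutes)
    aru <- simulate_recordings(cm, s$n_recordings, site = s$name,
                               seed = stage_seed(seed, "simulate_aru") + si)
    kbm <- simulate_checklists(cm, s$n_lists, site = s$name,
                               seed = stage_seed(seed, "simulate_kbm") + si)
    inc_pc <- build_incidence(pc$events, pc$units)
    inc_aru <- build_incidence(aru$events, aru$units)
    inc_kbm <- build_incidence(kbm$events, kbm$units)

    rich <- richness_summary(
      list(PC = inc_pc, ARU = inc_aru, KBM = inc_kbm), dependency
    )
    fit <- fit_accumulation(accumulation_series(inc_pc))
    log_stage(quiet, "accumulate",
              "site %s: asymptote %.1f species, t0.9 = %.1f counts",
              s$name, fit$asymptote, fit$t90)

    sim <- simulate_effort_matched_pcs(
      inc_aru, k = config$k, n_sim = s$n_sim,
      seed = stage_seed(seed, "occurrence") + si
    )
    fo_pc <- frequency_of_occurrence(inc_pc, method = "PC", site = s$name)
    fo_aru <- frequency_of_occurrence(sim, method = "ARU", site = s$name)
    fo_kbm <- frequency_of_occurrence(inc_kbm, method = "KBM",
                                      site = s$name)
    cmp <- list(
      PC_ARU = compare_methods(fo_pc, fo_aru, alpha = config$alpha),
      PC_KBM = compare_methods(fo_pc, fo_kbm, alpha = config$alpha),
      ARU_KBM = compare_methods(fo_aru, fo_kbm, alpha = config$alpha)
    )
    for (nm in names(cmp)) {
      log_stage(quiet, "compare", "site %s %s: gate -> %s, p = %.3g",
                s$name, nm, cmp[[nm]]$test_used, cmp[[nm]]$p_value)
    }
    cues <- cue_summary(pc$events)
    overlap <- heard_aru_overlap(cues, rownames(inc_aru)[rowSums(inc_aru) > 0])

    # stage CSVs
    pfx <- file.path(out_dir, s$name)
    utils::write.csv(data.frame(method = names(rich$counts),
                                richness = as.integer(rich$counts)),
                     paste0(pfx, "_richness.csv"), row.names = FALSE)
    curve <- data.frame(t = fit$series$t, observed = fit$series$S_obs,
                        fitted = fit$fitted)
    utils::write.csv(curve, paste0(pfx, "_accumulation.csv"),
                     row.names = FALSE)
    fo_all <- pair_frequencies(fo_pc, fo_aru)
    fo_all$fo_kbm <- fo_lookup(fo_kbm, fo_all$species)
    names(fo_all) <- c("species", "fo_pc", "fo_aru_sim", "diff_pc_aru",
                       "fo_kbm")
    fo_all <- fo_all[order(-fo_all$fo_pc, fo_all$species), ]
    utils::write.csv(fo_all, paste0(pfx, "_occurrence.csv"),
                     row.names = FALSE)
    cmp_df <- do.call(rbind, lapply(names(cmp), function(nm) {
      x <- cmp[[nm]]
      data.frame(site = s$name, pair = nm, ks_stat = x$ks_stat,
                 ks_p = x$ks_p, test = x$test_used,
                 statistic = x$statistic, p_value = x$p_value,
                 n_pairs = x$n_pairs)
    }))
    utils::write.csv(cmp_df, paste0(pfx, "_comparison.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(cues), paste0(pfx, "_heardseen.csv"),
                     row.names = FALSE)

    summary_lines <- c(
      summary_lines, "",
      sprintf("== site %s ==", s$name),
      sprintf("richness PC/ARU/KBM/combined: %d/%d/%d/%d",
              rich$counts[["PC"]], rich$counts[["ARU"]],
              rich$counts[["KBM"]], rich$combined),
      sprintf("accumulation: a = %.3f, b = %.4f, asymptote %.1f, t0.9 = %.1f",
              fit$a, fit$b, fit$asymptote, fit$t90),
      sprintf("heard-dominant species: %d; also on ARU: %d (%d%%)",
              overlap$n_flagged, overlap$n_overlap, overlap$percent),
      vapply(names(cmp), function(nm) {
        x <- cmp[[nm]]
        sprintf("%s: KS D = %.3f p = %.3g -> %s, stat = %.2f, p = %.3g, n = %d",
                nm, x$ks_stat, x$ks_p, x$test_used, x$statistic,
                x$p_value, x$n_pairs)
      }, character(1))
    )
    results$sites[[s$name]] <- list(
      pc = pc, aru = aru, kbm = kbm, richness = rich, fit = fit,
      fo = list(PC = fo_pc, ARU = fo_aru, KBM = fo_kbm),
      comparisons = cmp, cues = cues, overlap = overlap
    )
  }

  # classifier stage on the first site's recordings
  s1 <- config$sites[[1]]
  aru1 <- results$sites[[s1$name]]$aru
  rec_labels <- split(aru1$events$species, aru1$events$unit_id)
  labels <- rep(list(character(0)), nrow(aru1$units))
  names(labels) <- aru1$units$unit_id
  labels[names(rec_labels)] <- lapply(rec_labels, unique)
  log_stage(quiet, "classify", "embedding %d recordings at %d dims",
            length(labels), config$embedding_dim)
  emb <- simulate_embeddings(emodel, unname(labels),
                             unit_id = names(labels),
                             seed = stage_seed(seed, "simulate_emb"))
  filt <- filter_species(emb, min_recordings = config$min_recordings)
  labelled <- lengths(filt$records$labels) > 0
  use <- embedding_set(filt$records$features[labelled, , drop = FALSE],
                       filt$records$labels[labelled],
                       filt$records$unit_id[labelled])
  cls <- NULL
  if (length(filt$species) >= 1 && nrow(use$features) >= 10) {
    cls <- suppressWarnings(repeated_runs(
      use, species = filt$species, n_runs = config$n_runs,
      base_seed = stage_seed(seed, "classify"),
      train_fraction = config$train_fraction,
      hidden_units = config$hidden_units, epochs = config$epochs,
      learning_rate = config$learning_rate
    ))
    utils::write.csv(cls$runs, file.path(out_dir, "classifier_runs.csv"),
                     row.names = FALSE)
    summary_lines <- c(
      summary_lines, "",
      sprintf("classifier (%d species kept, %d labelled recordings, %d runs):",
              length(filt$species), nrow(use$features), config$n_runs),
      sprintf("  subset accuracy %.3f +/- %.3f; macro-AUROC %.3f +/- %.3f",
              cls$subset_accuracy[["mean"]], cls$subset_accuracy[["sd"]],
              cls$macro_auroc[["mean"]], cls$macro_auroc[["sd"]])
    )
  } else {
    summary_lines <- c(summary_lines, "",
                       "classifier: skipped (too few labelled recordings)")
  }
  results$classifier <- cls

  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  log_stage(quiet, "report", "written to %s", out_dir)
  invisible(results)
}
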