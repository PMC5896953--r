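# maps a named list of overrides onto a config constructor, rejecting
# unknown keys before any computation runs
build_config <- function(overrides, constructor, what) {
  overrides <- overrides %||% list()
  known <- names(formals(constructor))
  bad <- setdiff(names(overrides), known)
  if (length(bad))
    stop("unknown ", what, " config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(constructor, overrides)
}

#' Run the full simulate-detect-analyze pipeline
#'
#' Reads a JSON run configuration, builds every stage configuration up
#' front (invalid or unknown keys are rejected before any computation),
#' then runs: TBS simulation and event detection (`events.tsv`,
#' `ltp.json`), propagation-pair simulation and fitting (`fit.json`), patch
#' simulation and grouped channel statistics (`patch_measurements.tsv`,
#' `patch_stats.json`), and cohort association (`association.json`).  A
#' `manifest.json` records the config hash, seed and package version;
#' identical config + seed yields identical artifacts.
#'
#' Recognized top-level keys: `seed`, `out_dir`, `detection`, `tbs`,
#' `propagation`, `patch`, `cohort`, `verbose`.
#'
#' @param config_path Path to the JSON run configuration.
#' @param out_dir Output directory override (defaults to the config's
#'   `out_dir`, or `"gcdspike-run"`).
#' @return Invisibly, a named list of the artifact paths.
#' @export
run_pipeline <- function(config_path, out_dir = NULL) {
  if (!file.exists(config_path))
    stop("config file not found: ", config_path, call. = FALSE)
  rc <- jsonlite::read_json(config_path, simplifyVector = TRUE)
  known <- c("seed", "out_dir", "detection", "tbs", "propagation", "patch",
             "cohort", "verbose")
  bad <- setdiff(names(rc), known)
  if (length(bad))
    stop("unknown run-config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  seed <- as.integer(rc$seed %||% 1L)
  out_dir <- out_dir %||% rc$out_dir %||% "gcdspike-run"
  verbose <- isTRUE(rc$verbose)
  say <- function(...) if (verbose) message("[gcdspike] ", ...)

  # all stage configs are validated before any computation
  det_cfg <- build_config(as.list(rc$detection), detection_config,
                          "detection")
  tbs_over <- as.list(rc$tbs); tbs_over$seed <- tbs_over$seed %||% seed
  tbs_cfg <- build_config(tbs_over, tbs_gen_config, "tbs")
  prop <- as.list(rc$propagation)
  distances <- prop$distances_um %||% seq(10, 250, by = 20)
  prop$distances_um <- NULL
  prop$seed <- prop$seed %||% seed
  prop_cfg <- build_config(prop, propagation_gen_config, "propagation")
  patch_over <- as.list(rc$patch); patch_over$seed <- patch_over$seed %||% seed
  patch_cfg <- build_config(patch_over, patch_gen_config, "patch")
  coh_over <- as.list(rc$cohort); coh_over$seed <- coh_over$seed %||% seed
  coh_cfg <- build_config(coh_over, ltp_cohort_config, "cohort")

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  wjson <- function(x, f) {
    p <- file.path(out_dir, f)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    p
  }

  say("simulating TBS session (seed ", tbs_cfg$seed, ")")
  ses <- make_tbs_session(tbs_cfg)
  say("detecting events")
  ev <- detect_session_events(ses, epoch = "induction", cfg = det_cfg)
  paths$events <- file.path(out_dir, "events.tsv")
  utils::write.table(ev, paths$events, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  exp1 <- session_ltp_experiment(ses, det_cfg)
  paths$ltp <- wjson(list(ltp_pct = ltp_magnitude(exp1),
                          spike_count = count_induction_spikes(exp1),
                          condition = exp1$condition), "ltp.json")

  say("simulating propagation pairs")
  pairs <- make_dual_ap_session(prop_cfg, distances)
  pts <- propagation_points(pairs)
  att <- fit_attenuation(pts)
  vel <- fit_velocity(pts)
  paths$fit <- wjson(list(attenuation = unclass(att), velocity = vel),
                     "fit.json")

  say("simulating outside-out patches")
  meas <- do.call(rbind, lapply(
    list(recording_site("soma"), recording_site("dendrite", 50),
         recording_site("dendrite", 150)),
    function(st) {
      pc <- patch_cfg; pc$seed <- patch_cfg$seed + round(st$distance_um)
      set <- make_patch_sweep_set(pc, st,
                                  c(na = TRUE, ka = TRUE, kdr = TRUE))
      rbind(measure_component(set, "ka"), measure_component(set, "kdr"))
    }))
  paths$patch_meas <- file.path(out_dir, "patch_measurements.tsv")
  utils::write.table(meas, paths$patch_meas, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  ka <- meas[meas$component == "ka", ]
  paths$patch_stats <- wjson(
    list(ka = unclass(group_and_test(ka))), "patch_stats.json")

  say("simulating LTP cohort")
  cohort <- make_ltp_cohort(coh_cfg)
  assoc <- spike_ltp_association(cohort)
  paths$association <- wjson(assoc[c("r", "p", "n", "degenerate")],
                             "association.json")

  paths$manifest <- wjson(
    list(config_md5 = unname(tools::md5sum(config_path)), seed = seed,
         package_version = as.character(utils::packageVersion("gcdspike"))),
    "manifest.json")
  say("done: ", out_dir)
  invisible(paths)
}
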