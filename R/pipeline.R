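## End-to-end orchestration: simulate the rearrangement, generate the site
## table, profile and segment the heterozygous frequencies, delineate and
## annotate breakpoints, type the fusion-repeat junction, optionally run a
## Y-STR cluster TMRCA, and score everything against the simulator's truth
## records.

#' Assemble and validate a pipeline run configuration
#'
#' Nested component configurations take their usual defaults; supply named
#' lists to override individual fields. Unknown keys are rejected (typo
#' guard). The root seed is fanned out per component and echoed into every
#' output header.
#'
#' @param seed root seed.
#' @param karyotype simulated individual (see [truth_copy_profile()]).
#' @param genome,pileup named lists of overrides for [genome_config()] /
#'   [pileup_config()].
#' @param profiler named list of overrides for [profiler_config()].
#' @param nahr named list of overrides for [nahr_event()].
#' @param tmrca list: `enabled`, `t_sim` (true cluster age, generations),
#'   `n_lineages`, `t_max`, `dt`, `span` (years/generation), `ref_year`.
#' @param window `c(lo, hi)` profiling window on toyX, or `NULL` for the
#'   default window bracketing both repeats.
#' @param out_dir optional output directory for report files.
#' @param verbosity 0 = quiet, 1 = stage messages to stderr.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       karyotype = "male_carrier",
                       genome = list(), pileup = list(),
                       profiler = list(), nahr = list(),
                       tmrca = list(), window = NULL,
                       out_dir = NULL, verbosity = 0L) {
  check_keys <- function(given, allowed, where) {
    bad <- setdiff(names(given), allowed)
    if (length(bad)) {
      stop(sprintf("unknown %s key(s): %s", where,
                   paste(bad, collapse = ", ")))
    }
  }
  check_keys(genome, setdiff(names(formals(genome_config)), "seed"),
             "genome config")
  check_keys(pileup, setdiff(names(formals(pileup_config)), "seed"),
             "pileup config")
  check_keys(profiler, names(formals(profiler_config)), "profiler config")
  check_keys(nahr, names(formals(nahr_event)), "nahr event")
  tmrca_defaults <- list(enabled = TRUE, t_sim = 20, n_lineages = 20,
                         t_max = 500, dt = 1, span = 25, ref_year = 2010)
  check_keys(tmrca, names(tmrca_defaults), "tmrca config")
  tmrca <- utils::modifyList(tmrca_defaults, tmrca)

  gcfg <- do.call(genome_config,
                  c(list(seed = component_seed(seed, "genome-root")), genome))
  pcfg <- do.call(pileup_config,
                  c(list(seed = component_seed(seed, "pileup-root")), pileup))
  prof_cfg <- do.call(profiler_config, profiler)
  event <- do.call(nahr_event, nahr)
  if (is.null(window)) {
    window <- c(gcfg$repeatA_start - 14000, gcfg$repeatB_start + 21000)
  }
  if (window[1] >= window[2]) stop("window lower bound must precede upper")
  cfg <- list(seed = as.integer(seed), karyotype = karyotype,
              genome = gcfg, pileup = pcfg, profiler = prof_cfg,
              nahr = event, tmrca = tmrca, window = window,
              out_dir = out_dir, verbosity = verbosity)
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from JSON
#'
#' The file holds any subset of the arguments of [run_config()]; defaults
#' fill the rest and the assembled configuration is validated (unknown
#' keys rejected with the offending names).
#'
#' @param path JSON file.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("cannot parse config JSON: ",
                                           conditionMessage(e)))
  allowed <- names(formals(run_config))
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (nm in c("genome", "pileup", "profiler", "nahr", "tmrca")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- as.list(raw[[nm]])
  }
  do.call(run_config, raw)
}

#' Run the full simulation-to-report chain
#'
#' Stages: reference build, NAHR, truth copy profile, site-table
#' simulation, frequency profiling, heterozygous-band segmentation,
#' breakpoint delineation and repeat annotation, per-segment copy-model
#' inference, fusion-junction typing, and (optionally) a Y-STR cluster
#' simulation with TMRCA posterior and calendar conversion. Every
#' recovered item is matched against the simulator's truth records and
#' flagged pass/fail. Deterministic for a fixed configuration.
#'
#' @param config a [run_config()].
#' @return A list of class `run_report`.
#' @export
run_end_to_end <- function(config = run_config()) {
  stopifnot(is(config, "run_config"))
  say <- function(...) {
    if (config$verbosity > 0L) message(sprintf(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  say("stage simulate: building reference pair and applying NAHR")
  pair <- stage("simulate", build_reference(config$genome))
  derived <- stage("simulate", apply_nahr(pair, config$nahr))
  profile <- stage("simulate", truth_copy_profile(derived, config$karyotype))

  say("stage pileup: simulating site table")
  sites <- stage("pileup",
                 simulate_site_table(profile, config$pileup,
                                     window = config$window))

  say("stage profile: frequencies, heterozygote calls, segmentation")
  freq <- stage("profile", filter_and_frequency(sites, config$profiler))
  het <- stage("profile", call_het_sites(freq, config$profiler))
  segments <- stage("profile", segment_het_profile(het, config$profiler))
  breakpoints <- stage("profile", delineate_breakpoints(segments, het))
  breakpoints <- stage("profile", annotate_with_repeats(
    breakpoints, profile$repeats, sites))
  copy_models <- stage("profile", lapply(seq_len(nrow(segments)), function(i) {
    infer_copy_counts(segments[i, ], het, config$profiler)
  }))

  say("stage junction: typing the fusion amplicon")
  junction_product <- if (config$karyotype == "deletion_female") "delX"
                      else "derY"
  junction <- if (config$karyotype %in% c("male_carrier", "deletion_female")) {
    amp <- stage("junction", fusion_amplicon(derived, junction_product))
    prof <- stage("junction", extract_states(amp$seq, pair,
                                             context = amp$context))
    stage("junction", classify_junction(prof))
  } else NULL

  tmrca <- NULL
  if (isTRUE(config$tmrca$enabled)) {
    say("stage tmrca: Y-STR cluster simulation and posterior")
    tm <- config$tmrca
    rates <- stage("tmrca", default_ystr_rates())
    set.seed(component_seed(config$seed, "founder"))
    founder <- setNames(sample(10:30, length(rates), replace = TRUE),
                        names(rates))
    panel <- stage("tmrca", simulate_str_cluster(
      founder, tm$t_sim, rates, tm$n_lineages,
      seed = component_seed(config$seed, "tmrca-root")))
    post <- stage("tmrca", cluster_tmrca(panel, rates,
                                         t_max = tm$t_max, dt = tm$dt))
    ci <- credible_interval(post)
    tmrca <- list(
      t_sim = tm$t_sim, ci = ci,
      posterior_median = posterior_median(post),
      calendar = unclass(calendar_convert(ci, tm$span, tm$ref_year)),
      covered = tm$t_sim >= ci[1] && tm$t_sim <= ci[2])
  }

  ## score recovered calls against truth
  truth <- profile$truth
  expected_bands <- switch(config$karyotype,
                           male_carrier = c(1/2, 1/3, 1/2),
                           deletion_female = 1/2,
                           male_control = 1/2,
                           female_control = 1/2)
  checks <- list(
    band_structure = isTRUE(all.equal(segments$band, expected_bands,
                                      tolerance = 1e-9)))
  if (config$karyotype == "male_carrier") {
    bp1 <- breakpoints[breakpoints$left_band == 1/2 &
                         breakpoints$right_band == 1/3, , drop = FALSE]
    bp2 <- breakpoints[breakpoints$left_band == 1/3 &
                         breakpoints$right_band == 1/2, , drop = FALSE]
    rep_a <- profile$repeats[profile$repeats$id == "A_PAR", ]
    checks$breakpoint1_contains_crossover <-
      nrow(bp1) == 1L && bp1$left_pos < truth$a_cut &&
      bp1$right_pos > truth$a_cut
    checks$breakpoint1_overlaps_repeatA <-
      nrow(bp1) == 1L && bp1$left_pos < rep_a$end &&
      bp1$right_pos > rep_a$start
    checks$breakpoint2_contains_pab <-
      nrow(bp2) == 1L && bp2$left_pos < profile$pab &&
      bp2$right_pos > profile$pab
    checks$triplication_called <-
      any(vapply(copy_models, function(cm) {
        cm$c == 3L && !cm$ambiguous
      }, logical(1)))
    checks$junction_class <- !is.null(junction) &&
      junction$class == (if (!is.null(config$nahr$conversion_tract))
        "JUNC2" else "JUNC1")
  }
  if (config$karyotype == "male_control") {
    checks$no_het_in_x_specific <- !any(het$pos >= profile$pab)
  }
  if (config$karyotype == "deletion_female") {
    checks$junction_class <- !is.null(junction) &&
      junction$class %in% c("MERGED_COMPLEX", "JUNC2")
  }

  report <- structure(list(
    seed = config$seed, karyotype = config$karyotype,
    config_hash = config_hash(serializable_config(config)),
    truth = truth,
    n_sites = nrow(sites), n_het = nrow(het),
    segments = segments, breakpoints = breakpoints,
    copy_models = lapply(copy_models, function(cm) {
      cm[c("m", "c", "loglik", "margin", "ambiguous")]
    }),
    junction = if (!is.null(junction)) {
      list(class = junction$class, switch_count = junction$switch_count,
           extra_variants = junction$extra_variants)
    },
    tmrca = tmrca,
    checks = checks, all_passed = all(unlist(checks))),
    class = "run_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

serializable_config <- function(config) {
  cfg <- unclass(config)
  cfg$genome <- unclass(cfg$genome)
  cfg$pileup <- unclass(cfg$pileup)
  cfg$profiler <- unclass(cfg$profiler)
  cfg$nahr <- unclass(cfg$nahr)
  cfg$out_dir <- NULL
  cfg$verbosity <- NULL
  cfg
}

#' Write a run report to disk
#'
#' `report.json` (machine-readable, config hash included) and
#' `report.txt` (human-readable summary).
#'
#' @param report a `run_report`.
#' @param dir output directory, created if needed.
#' @return Invisibly, the JSON path.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(json_path)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("parshift end-to-end report (seed %d, karyotype %s)\n",
              x$seed, x$karyotype))
  cat(sprintf("  sites simulated: %d; heterozygous calls: %d\n",
              x$n_sites, x$n_het))
  cat(sprintf("  segments: %s\n",
              paste(sprintf("%.3g [%s..%s] n=%d", x$segments$band,
                            format(x$segments$start, big.mark = ","),
                            format(x$segments$end, big.mark = ","),
                            x$segments$n_sites), collapse = " | ")))
  if (nrow(x$breakpoints)) {
    for (i in seq_len(nrow(x$breakpoints))) {
      b <- x$breakpoints[i, ]
      cat(sprintf(
        "  breakpoint %d: (%s, %s) %s%s\n", i,
        format(b$left_pos, big.mark = ","),
        format(b$right_pos, big.mark = ","),
        if (nzchar(b$repeats)) paste0("in ", b$repeats) else "outside repeats",
        if (b$mq0_flag) " [MQ0]" else ""))
    }
  }
  if (!is.null(x$junction)) {
    cat(sprintf("  junction class: %s\n", x$junction$class))
  }
  if (!is.null(x$tmrca)) {
    cat(sprintf(
      "  TMRCA: true t=%g, 95%% CI [%d, %d] generations, i.e. %d..%d\n",
      x$tmrca$t_sim, x$tmrca$ci[1], x$tmrca$ci[2],
      x$tmrca$calendar$year_old, x$tmrca$calendar$year_recent))
  }
  for (nm in names(x$checks)) {
    cat(sprintf("  [%s] %s\n", if (isTRUE(x$checks[[nm]])) "ok" else "FAIL",
                nm))
  }
  invisible(x)
}
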