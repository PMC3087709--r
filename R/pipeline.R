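# Run configuration (YAML round-trip) and the end-to-end pipeline driver.

#' Default run configuration
#'
#' One nested list holding every tunable parameter of the pipeline with its
#' default: the peak rule (2.5 SD threshold, 2 consecutive probes, 2
#' supporting replicates), the dual response filter (2-fold) and the
#' strongly-dependent report threshold (5-fold), the bipartite consensus
#' (GTNAC-n6-GTNAC, 250 bp promoter windows), and the simulation scenario.
#'
#' @param seed integer seed applied to every stochastic stage.
#' @return a `run_config` list.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    peaks = list(k_sd = 2.5, min_run = 2L, min_replicates = 2L,
                 max_probe_gap_bp = NULL, use_log_ratio = FALSE),
    expression = list(theta = 2, theta_top = 5, wt = "WT", mutant = "glnR",
                      timepoints = c("T0", "T30", "T45")),
    motif = list(a = "GTNAC", b = "GTNAC", spacer_min = 6L, spacer_max = 6L,
                 window = 250L),
    scenario = list()), class = "run_config")
}

check_keys <- function(x, template, path = "config") {
  extra <- setdiff(names(x), names(template))
  if (length(extra))
    stop("unknown ", path, " key(s): ", paste(extra, collapse = ", "))
  for (nm in names(x)) {
    if (is.list(template[[nm]]) && !is.null(names(template[[nm]])) &&
        nm != "scenario") {
      if (!is.list(x[[nm]]))
        stop(path, "$", nm, " must be a mapping")
      check_keys(x[[nm]], template[[nm]], paste0(path, "$", nm))
    }
  }
  invisible(TRUE)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) && nm != "scenario")
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a run configuration from YAML
#'
#' Values present in the file override the defaults; unknown keys are
#' rejected. `scenario` keys are validated against [sim_scenario()].
#'
#' @param path YAML file path.
#' @return a `run_config` list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  template <- default_config()
  check_keys(raw, template)
  if (!is.null(raw$scenario)) {
    extra <- setdiff(names(raw$scenario), names(formals(sim_scenario)))
    if (length(extra))
      stop("unknown scenario key(s): ", paste(extra, collapse = ", "))
  }
  cfg <- merge_config(unclass(template), raw)
  structure(cfg, class = "run_config")
}

#' Write a run configuration as YAML
#' @param config a `run_config` list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_peak_params <- function(config)
  peak_params(k_sd = config$peaks$k_sd, min_run = config$peaks$min_run,
              min_replicates = config$peaks$min_replicates,
              max_probe_gap_bp = config$peaks$max_probe_gap_bp,
              use_log_ratio = config$peaks$use_log_ratio)

config_consensus <- function(config)
  bipartite_consensus(config$motif$a, config$motif$b,
                      config$motif$spacer_min, config$motif$spacer_max)

#' Call binding regions across timepoints
#'
#' Runs the peak rule on every IP replicate of every timepoint, merges
#' replicates with control subtraction per timepoint, and also returns the
#' cross-timepoint union of reported regions (the style of a published
#' target table: one row per region, bound at any timepoint).
#'
#' @param tracks nested list as produced by [simulate_chip_tracks()]:
#'   `tracks[[timepoint]]$ip` (named list of probe tracks) and
#'   `tracks[[timepoint]]$control`.
#' @param params a [peak_params()] object.
#' @return list with `by_timepoint` (per-timepoint [merge_replicates()]
#'   results) and `union` (reported regions merged across timepoints).
#' @export
call_binding_regions <- function(tracks, params = peak_params()) {
  by_tp <- lapply(tracks, function(tpdata) {
    peaksets <- lapply(tpdata$ip, call_peaks_single, params = params)
    control_peaks <- call_peaks_single(tpdata$control, params)
    merge_replicates(peaksets, control_peaks, params)
  })
  all_regions <- do.call(c, unname(lapply(by_tp, `[[`, "regions")))
  union <- if (is.null(all_regions) || length(all_regions) == 0L)
    GRanges()
  else {
    u <- reduce(all_regions, min.gapwidth = 0L, ignore.strand = TRUE)
    hits <- findOverlaps(u, all_regions, ignore.strand = TRUE)
    tps <- lapply(split(subjectHits(hits), queryHits(hits)), function(i)
      unique(unlist(as.list(mcols(all_regions)$timepoints[i]))))
    mx <- vapply(split(subjectHits(hits), queryHits(hits)), function(i)
      max(mcols(all_regions)$max_ratio[i]), numeric(1))
    mcols(u) <- DataFrame(timepoints = CharacterList(tps), max_ratio = mx)
    u
  }
  list(by_timepoint = by_tp, union = union)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline on a simulated or supplied study
#'
#' Executes peak calling (per replicate and timepoint, with control
#' subtraction), target assignment, the expression dependence analysis,
#' promoter-window motif annotation, and regulon classification; optionally
#' writes all reports plus a provenance JSON (configuration, seed, package
#' version, checksums of written files) to `outdir`.
#'
#' @param config a `run_config` list (see [default_config()]).
#' @param study optional study list (`genome`, `tracks`, `expression`) as
#'   from [simulate_study()]; when `NULL`, one is simulated from
#'   `config$scenario` under `config$seed`.
#' @param outdir optional output directory.
#' @return list with `regions` (cross-timepoint union, targets assigned),
#'   `by_timepoint`, `dependence`, `motifs`, `regulon`, `report`, `truth`
#'   (when simulated) and `files` (written paths, if any).
#' @export
run_pipeline <- function(config = default_config(), study = NULL,
                         outdir = NULL) {
  if (is.null(study)) {
    scen <- do.call(sim_scenario, c(list(seed = config$seed),
                                    config$scenario))
    study <- run_stage("simulate", simulate_study(scen))
  }
  params <- config_peak_params(config)
  peaks <- run_stage("peaks", call_binding_regions(study$tracks, params))
  regions <- run_stage("targets",
                       assign_targets(peaks$union, study$genome$genes))
  dep <- run_stage("expression",
                   dependence_calls(study$expression$se,
                                    wt = config$expression$wt,
                                    mutant = config$expression$mutant,
                                    theta_wt = config$expression$theta,
                                    theta_mutant = config$expression$theta,
                                    timepoints = config$expression$timepoints))
  consensus <- config_consensus(config)
  windows <- run_stage("motif",
                       promoter_windows(regions, study$genome$seq,
                                        width = config$motif$window))
  motifs <- run_stage("motif", annotate_regions_with_sites(windows,
                                                           consensus))
  records <- run_stage("classify", classify_regulon(dep, regions))
  report <- run_stage("report",
                      regulon_report(records, motif_table = motifs$table,
                                     regions = regions))
  files <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    files <- c(regulon = file.path(outdir, "regulon.tsv"),
               regions = file.path(outdir, "regions.tsv"),
               motifs = file.path(outdir, "motif_hits.tsv"),
               dependence = file.path(outdir, "dependence.tsv"),
               provenance = file.path(outdir, "provenance.json"))
    utils::write.table(report$table, files[["regulon"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(report$regions, files[["regions"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(motifs$table, files[["motifs"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(dep, files[["dependence"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    written <- files[names(files) != "provenance"]
    jsonlite::write_json(
      list(package = "glnregulon",
           version = as.character(utils::packageVersion("glnregulon")),
           seed = config$seed,
           config = unclass(config),
           checksums = as.list(tools::md5sum(unname(written)))),
      files[["provenance"]], auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(regions = regions, by_timepoint = peaks$by_timepoint,
       dependence = dep, motifs = motifs, regulon = records,
       report = report, truth = study$truth, files = files)
}
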