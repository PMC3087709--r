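# Threshold-based peak calling on tiling probe ratio tracks, with
# cross-replicate reproducibility and empty-vector control subtraction.

#' Peak-calling parameters
#'
#' @param k_sd threshold multiplier: a probe is "high" when its ratio exceeds
#'   the track mean by more than `k_sd` standard deviations. Default 2.5.
#' @param min_run minimum number of consecutive high probes required to call
#'   a peak. Default 2.
#' @param min_replicates minimum number of distinct replicates that must
#'   support a merged binding region. Default 2.
#' @param max_probe_gap_bp maximum genomic gap (bp) between successive probes
#'   for them to count as consecutive; `NULL` (default) means twice the
#'   track's median probe spacing, so array coverage gaps cannot bridge
#'   unrelated probes.
#' @param use_log_ratio if `TRUE`, mean/sd and the threshold are computed on
#'   log2 ratios rather than linear ratios.
#' @return a `peak_params` list.
#' @export
peak_params <- function(k_sd = 2.5, min_run = 2L, min_replicates = 2L,
                        max_probe_gap_bp = NULL, use_log_ratio = FALSE) {
  stopifnot(k_sd > 0, min_run >= 1, min_replicates >= 1)
  structure(list(k_sd = k_sd, min_run = as.integer(min_run),
                 min_replicates = as.integer(min_replicates),
                 max_probe_gap_bp = max_probe_gap_bp,
                 use_log_ratio = isTRUE(use_log_ratio)),
            class = "peak_params")
}

track_values <- function(track, params) {
  v <- mcols(track)$ratio
  if (params$use_log_ratio) log2(v) else v
}

#' Per-track peak threshold
#'
#' The significance cutoff for one hybridisation: the mean of all probe
#' ratios on the track plus `k_sd` sample standard deviations. Computed per
#' track (per replicate, per timepoint), not pooled across experiments.
#'
#' @param track a probe track.
#' @param params a [peak_params()] object.
#' @return the threshold, on the linear or log2 scale per
#'   `params$use_log_ratio`.
#' @export
track_threshold <- function(track, params = peak_params()) {
  if (length(track) < 2L)
    stop("track threshold needs at least 2 probes")
  v <- track_values(track, params)
  mean(v) + params$k_sd * stats::sd(v)
}

default_max_gap <- function(track, params) {
  if (!is.null(params$max_probe_gap_bp)) return(params$max_probe_gap_bp)
  if (length(track) < 2L) return(Inf)
  sp <- stats::median(diff(start(track)))
  2 * sp
}

#' Call peaks on a single track
#'
#' Finds maximal runs of consecutive probes whose ratio exceeds the track
#' threshold. Probes are consecutive when adjacent in track order and their
#' genomic gap is at most `max_probe_gap_bp`. Runs shorter than `min_run`
#' are discarded; each surviving run is one peak spanning the first base of
#' its first probe to the last base of its last probe.
#'
#' @inheritParams track_threshold
#' @param threshold optional externally supplied threshold (same scale as
#'   `params$use_log_ratio` implies); defaults to [track_threshold()].
#' @return `GRanges` of peaks with `max_ratio`, `n_probes`, `replicate_id`
#'   and `timepoint` metadata columns.
#' @export
call_peaks_single <- function(track, params = peak_params(),
                              threshold = NULL) {
  info <- track_info(track)
  empty <- GRanges(seqinfo = seqinfo(track))
  mcols(empty) <- DataFrame(max_ratio = numeric(0), n_probes = integer(0),
                            replicate_id = character(0),
                            timepoint = character(0))
  if (length(track) < 2L) return(empty)
  if (is.null(threshold)) threshold <- track_threshold(track, params)
  v <- track_values(track, params)
  high <- v > threshold
  if (!any(high)) return(empty)
  maxgap <- default_max_gap(track, params)
  # run breaks: not high, different replicon, or genomic gap too large
  n <- length(track)
  same_run <- rep(FALSE, n)
  if (n > 1L) {
    gap_bp <- start(track)[-1L] - end(track)[-n] - 1L
    same_run[-1L] <- high[-1L] & high[-n] &
      as.character(seqnames(track))[-1L] == as.character(seqnames(track))[-n] &
      gap_bp <= maxgap
  }
  run_id <- cumsum(!same_run)
  keep <- which(high)
  runs <- split(keep, run_id[keep])
  runs <- runs[lengths(runs) >= params$min_run]
  if (!length(runs)) return(empty)
  first <- vapply(runs, `[`, integer(1), 1L)
  last <- vapply(runs, function(x) x[length(x)], integer(1))
  gr <- GRanges(seqnames(track)[first],
                IRanges(start(track)[first], end(track)[last]),
                seqinfo = seqinfo(track))
  mcols(gr) <- DataFrame(
    max_ratio = unname(vapply(runs, function(x) max(mcols(track)$ratio[x]),
                              numeric(1))),
    n_probes = unname(lengths(runs)),
    replicate_id = as.character(info$replicate_id %||% NA_character_),
    timepoint = as.character(info$timepoint %||% NA_character_))
  gr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Merge per-replicate peaks into binding regions
#'
#' Peaks from all replicates are clustered by single-linkage genomic overlap
#' (at least 1 bp). Clusters supported by at least `min_replicates` distinct
#' replicates are kept; of those, any cluster overlapping a control peak by
#' at least 1 bp is flagged `present_in_control` and moved to the
#' diagnostics list rather than reported. The region interval is the union
#' of its member peaks.
#'
#' @param peaksets named list of peak `GRanges` (one per replicate; names are
#'   replicate identifiers, used when a peak set lacks `replicate_id`).
#' @param control_peaks `GRanges` of peaks called on control tracks (may be
#'   empty or `NULL`).
#' @param params a [peak_params()] object.
#' @return list with `regions` (reported binding regions) and `diagnostics`
#'   (reproducible clusters excluded because they were present in the
#'   control); both `GRanges` with `supporting_replicates`, `n_replicates`,
#'   `timepoints`, `max_ratio` and `present_in_control` columns.
#' @export
merge_replicates <- function(peaksets, control_peaks = NULL,
                             params = peak_params()) {
  stopifnot(length(peaksets) >= 1L)
  if (is.null(names(peaksets)))
    names(peaksets) <- paste0("rep", seq_along(peaksets))
  pool <- do.call(c, lapply(names(peaksets), function(nm) {
    p <- peaksets[[nm]]
    if (is.null(mcols(p)$replicate_id) || anyNA(mcols(p)$replicate_id))
      mcols(p)$replicate_id <- nm
    p
  }))
  empty <- GRanges()
  mcols(empty) <- DataFrame(supporting_replicates = CharacterList(),
                            n_replicates = integer(0),
                            timepoints = CharacterList(),
                            max_ratio = numeric(0),
                            present_in_control = logical(0))
  if (length(pool) == 0L)
    return(list(regions = empty, diagnostics = empty))
  clusters <- reduce(pool, min.gapwidth = 0L, ignore.strand = TRUE)
  hits <- findOverlaps(clusters, pool, minoverlap = 1L, ignore.strand = TRUE)
  member <- split(subjectHits(hits), queryHits(hits))
  reps <- lapply(member, function(i) unique(mcols(pool)$replicate_id[i]))
  tps <- lapply(member, function(i) {
    tp <- mcols(pool)$timepoint
    if (is.null(tp)) character(0) else unique(stats::na.omit(tp[i]))
  })
  mx <- vapply(member, function(i) max(mcols(pool)$max_ratio[i]), numeric(1))
  mcols(clusters) <- DataFrame(
    supporting_replicates = unname(CharacterList(reps)),
    n_replicates = unname(lengths(reps)),
    timepoints = unname(CharacterList(tps)),
    max_ratio = unname(mx))
  clusters <- clusters[clusters$n_replicates >= params$min_replicates]
  in_control <- if (is.null(control_peaks) || length(control_peaks) == 0L)
    rep(FALSE, length(clusters))
  else overlapsAny(clusters, control_peaks, minoverlap = 1L,
                   ignore.strand = TRUE)
  mcols(clusters)$present_in_control <- in_control
  list(regions = clusters[!in_control], diagnostics = clusters[in_control])
}

#' Assign binding regions to downstream target genes
#'
#' A region is `intergenic` when it overlaps no gene body. Target genes are
#' the genes immediately downstream of the region, one candidate per side:
#' on the right, the nearest gene whose start lies at or beyond the region
#' start, kept only if it is on `+` (pointing away, so the region is
#' promoter-proximal upstream of it); on the left, the nearest gene whose
#' end lies at or before the region end, kept only if it is on `-`. A region
#' in the gap of a divergent gene pair therefore reports both flanking
#' genes; a tandem-context region reports one; a convergent-context region
#' reports none (logged).
#'
#' @param regions binding-region `GRanges`.
#' @param genes gene `GRanges` from [gene_annotation()].
#' @return `regions` with `intergenic` (logical) and `target_gene_ids`
#'   (`CharacterList`) metadata columns added.
#' @export
assign_targets <- function(regions, genes) {
  if (length(regions) == 0L) {
    mcols(regions)$intergenic <- logical(0)
    mcols(regions)$target_gene_ids <- CharacterList()
    return(regions)
  }
  inter <- !overlapsAny(regions, genes, ignore.strand = TRUE)
  gsn <- as.character(seqnames(genes))
  gstr <- as.character(strand(genes))
  targets <- vector("list", length(regions))
  for (i in seq_along(regions)) {
    sn <- as.character(seqnames(regions))[i]
    rs <- start(regions)[i]; re <- end(regions)[i]
    tg <- character(0)
    # right side: nearest gene starting at/after the region; a target only
    # if on '+' (pointing away from the region)
    cand <- which(gsn == sn & start(genes) >= rs)
    if (length(cand)) {
      j <- cand[which.min(start(genes)[cand])]
      if (gstr[j] == "+") tg <- c(tg, genes$gene_id[j])
    }
    # left side: nearest gene ending at/before the region; a target only
    # if on '-'
    cand <- which(gsn == sn & end(genes) <= re)
    if (length(cand)) {
      j <- cand[which.max(end(genes)[cand])]
      if (gstr[j] == "-") tg <- c(tg, genes$gene_id[j])
    }
    targets[[i]] <- unique(tg)
  }
  n_none <- sum(lengths(targets) == 0L)
  if (n_none > 0L)
    message(n_none, " region(s) with no downstream target gene")
  mcols(regions)$intergenic <- inter
  mcols(regions)$target_gene_ids <- CharacterList(targets)
  regions
}

#' Count binding regions, overall and per timepoint
#'
#' @param regions binding-region `GRanges` (with an optional `timepoints`
#'   column as produced by [merge_replicates()]).
#' @return list with `total` and `by_timepoint` (named integer vector; a
#'   region supported at several timepoints counts once per timepoint).
#' @export
count_binding_regions <- function(regions) {
  total <- length(regions)
  by_tp <- integer(0)
  tp <- mcols(regions)$timepoints
  if (!is.null(tp) && total > 0L) {
    flat <- unlist(as.list(tp))
    if (length(flat)) by_tp <- c(table(flat))
  }
  list(total = total, by_timepoint = by_tp)
}

#' Unique genes targeted by reported binding regions
#'
#' @param regions output of [assign_targets()].
#' @return character vector of gene ids.
#' @export
bound_gene_set <- function(regions) {
  tg <- mcols(regions)$target_gene_ids
  if (is.null(tg)) return(character(0))
  sort(unique(unlist(as.list(tg))))
}
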