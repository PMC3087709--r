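# Seeded simulator: genome with planted GlnR boxes, tiling ChIP tracks with
# enrichment peaks shaped by the sonication-fragment footprint, and
# replicated expression matrices with planted regulator-dependent genes.

#' Simulation scenario
#'
#' Bundles every knob of the synthetic study in one seeded object. The
#' defaults emulate the study design the analysis assumes: a ~1 Mb GC-rich
#' replicon tiled by 60-mer probes at 180 bp spacing, two ChIP replicates
#' plus one empty-vector control per timepoint, enrichment footprints with a
#' 500 bp half-width (the centre of the 300-1000 bp sonication fragment
#' range), multiplicative log-normal array noise, planted binding sites that
#' are enriched only after nitrogen starvation (with a designated persistent,
#' glnA-like exception bound at all timepoints), and a three-replicate
#' expression design over strains WT/glnR and timepoints T0/T30/T45 with
#' planted regulator-dependent genes.
#'
#' @param seed integer seed; all randomness flows from it.
#' @param replicon_name,replicon_length replicon identity and size (bp).
#' @param n_genes number of genes to place.
#' @param gene_length_mean,gene_length_sd gene length distribution (bp).
#' @param gc background GC fraction.
#' @param probe_spacing,probe_length tiling design (bp).
#' @param n_sites planted reproducible binding sites.
#' @param site_fold enrichment fold at the peak of a planted site.
#' @param n_persistent leading planted sites also enriched at T0.
#' @param n_artefacts planted artefact sites enriched in IP *and* control.
#' @param artefact_fold enrichment fold of artefact sites.
#' @param fragment_halfwidth half-width (bp) of the triangular enrichment
#'   kernel approximating the sonication-fragment footprint.
#' @param chip_noise_sd sd of log2 ratio noise on ChIP tracks.
#' @param n_chip_reps ChIP replicates per timepoint.
#' @param timepoints timepoint labels.
#' @param strains expression strains (wild type first, mutant second).
#' @param n_dependent,n_independent,n_null planted expression gene classes:
#'   regulator-dependent responders, regulator-independent responders, and
#'   flat genes.
#' @param n_bound_dependent how many dependent genes are also bound
#'   (category i); the rest are unbound (category ii).
#' @param n_bound_null how many null genes are bound but non-responsive
#'   (category iv).
#' @param induction_range,repression_range fold ranges for planted
#'   responders (both arms of the dual filter).
#' @param expr_noise_sd sd of log2 expression noise.
#' @param n_expr_reps biological expression replicates per cell.
#' @return a `sim_scenario` list.
#' @export
sim_scenario <- function(seed = 1L,
                         replicon_name = "chrSim", replicon_length = 1e6,
                         n_genes = 300L,
                         gene_length_mean = 900, gene_length_sd = 100,
                         gc = 0.7,
                         probe_spacing = 180L, probe_length = 60L,
                         n_sites = 20L, site_fold = 8,
                         n_persistent = 1L,
                         n_artefacts = 2L, artefact_fold = 6,
                         fragment_halfwidth = 500L,
                         chip_noise_sd = 0.25, n_chip_reps = 2L,
                         timepoints = c("T0", "T30", "T45"),
                         strains = c("WT", "glnR"),
                         n_dependent = 30L, n_independent = 30L,
                         n_null = 200L,
                         n_bound_dependent = 15L, n_bound_null = 5L,
                         induction_range = c(4, 76.4),
                         repression_range = c(4, 15),
                         expr_noise_sd = 0.25, n_expr_reps = 3L) {
  stopifnot(site_fold >= 1, artefact_fold >= 1,
            n_bound_dependent <= n_dependent, n_bound_null <= n_null,
            n_persistent <= n_sites, seed < 2^31)
  as.list(environment())
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# one concrete instance of the strict bipartite box
random_box_instance <- function() {
  mid <- function() sample(c("A", "C", "G", "T"), 1L)
  paste0("GT", mid(), "AC",
         paste(sample(c("A", "C", "G", "T"), 6L, replace = TRUE),
               collapse = ""),
         "GT", mid(), "AC")
}

#' Simulate a genome with planted binding sites
#'
#' Places non-overlapping genes of mixed orientation along the replicon,
#' draws a GC-rich background sequence, selects intergenic positions for the
#' planted binding sites (and control artefact sites) and embeds a concrete
#' bipartite box instance at each planted site. The expected target gene(s)
#' of each planted site (the flanking genes the site is promoter-proximal
#' to) are recorded in the ground truth.
#'
#' @param scenario a [sim_scenario()].
#' @return list with `genes` (a [gene_annotation()] `GRanges`), `seq`
#'   (`DNAStringSet`) and `truth` (planted site table and artefact
#'   positions).
#' @export
simulate_genome <- function(scenario) {
  set.seed(scenario$seed)
  L <- as.integer(scenario$replicon_length)
  n <- scenario$n_genes
  pitch <- floor(L / n)
  mean_len <- scenario$gene_length_mean
  if (mean_len + 400 > pitch)
    stop("infeasible gene packing: ", n, " genes of ~", mean_len,
         " bp do not fit in ", L, " bp")
  len <- pmin(pmax(round(stats::rnorm(n, mean_len, scenario$gene_length_sd)),
                   300L), pitch - 400L)
  jitter <- sample.int(200L, n, replace = TRUE)
  gstart <- (seq_len(n) - 1L) * pitch + jitter
  gend <- gstart + len - 1L
  gstrand <- sample(c("+", "-"), n, replace = TRUE)
  ids <- sprintf("gene_%04d", seq_len(n))
  seqlen <- stats::setNames(L, scenario$replicon_name)
  genes <- gene_annotation(rep(scenario$replicon_name, n), gstart, gend,
                           gstrand, ids, seqlen,
                           product = "simulated gene")
  seq_chars <- strsplit(random_dna(L, scenario$gc), "")[[1]]

  # candidate gaps between successive genes: wide enough for a 250 bp
  # window, and with at least one flanking gene pointing away so the planted
  # site has a promoter target
  gap_start <- gend[-n] + 1L
  gap_end <- gstart[-1L] - 1L
  wide <- which(gap_end - gap_start + 1L >= 600L &
                  (gstrand[-1L] == "+" | gstrand[-n] == "-"))
  need <- scenario$n_sites + scenario$n_artefacts
  if (length(wide) < need)
    stop("not enough wide intergenic gaps for planted sites")
  chosen <- wide[round(seq(1L, length(wide), length.out = need))]
  site_gaps <- chosen[seq_len(scenario$n_sites)]
  artefact_gaps <- chosen[scenario$n_sites + seq_len(scenario$n_artefacts)]

  site_pos <- floor((gap_start[site_gaps] + gap_end[site_gaps]) / 2)
  site_box <- vapply(seq_along(site_gaps), function(i) random_box_instance(),
                     character(1))
  # embed each box centred on its site position
  for (i in seq_along(site_pos)) {
    box <- strsplit(site_box[i], "")[[1]]
    from <- site_pos[i] - floor(length(box) / 2)
    seq_chars[from:(from + length(box) - 1L)] <- box
  }
  # expected promoter targets: the flanking gene(s) the site points into
  site_targets <- lapply(site_gaps, function(g) {
    tg <- character(0)
    if (gstrand[g + 1L] == "+") tg <- c(tg, ids[g + 1L])
    if (gstrand[g] == "-") tg <- c(tg, ids[g])
    tg
  })
  persistent <- seq_len(scenario$n_sites) <= scenario$n_persistent
  truth <- list(
    sites = data.frame(
      site_id = sprintf("site_%02d", seq_len(scenario$n_sites)),
      pos = site_pos,
      fold = rep(scenario$site_fold, scenario$n_sites),
      persistent = persistent,
      box = site_box,
      targets = vapply(site_targets, paste, character(1), collapse = "/"),
      row.names = NULL),
    target_genes = site_targets,
    artefact_pos = floor((gap_start[artefact_gaps] +
                          gap_end[artefact_gaps]) / 2))
  seqs <- DNAStringSet(paste(seq_chars, collapse = ""))
  names(seqs) <- scenario$replicon_name
  list(genes = genes, seq = seqs, truth = truth)
}

triangular_kernel <- function(d, halfwidth) pmax(0, 1 - abs(d) / halfwidth)

#' Simulate tiling ChIP ratio tracks
#'
#' Builds the probe grid and, for each timepoint, `n_chip_reps` IP tracks
#' plus one empty-vector control. The expected ratio of a probe is
#' `1 + (fold - 1) * w(d)` with `w` a triangular kernel of configurable
#' half-width around each planted site (distance `d` from probe centre to
#' site centre), multiplied by log-normal noise (`2^N(0, sd)`). Planted
#' sites carry no enrichment at T0 unless flagged persistent; artefact sites
#' are enriched in every track including the control.
#'
#' @param scenario a [sim_scenario()].
#' @param genome output of [simulate_genome()].
#' @return nested list: `tracks[[timepoint]]$ip` (list of probe tracks) and
#'   `tracks[[timepoint]]$control`.
#' @export
simulate_chip_tracks <- function(scenario, genome) {
  set.seed(scenario$seed + 1000L)
  L <- as.integer(scenario$replicon_length)
  starts <- seq(1L, L - scenario$probe_length + 1L,
                by = scenario$probe_spacing)
  probes <- GRanges(scenario$replicon_name,
                    IRanges(starts, width = scenario$probe_length),
                    seqinfo = seqinfo(genome$genes))
  centre <- starts + floor(scenario$probe_length / 2)
  hw <- scenario$fragment_halfwidth
  sites <- genome$truth$sites
  base_enrich <- function(pos, fold) {
    e <- numeric(length(centre))
    for (i in seq_along(pos)) {
      d <- centre - pos[i]
      e <- e + (fold[i] - 1) * triangular_kernel(d, hw)
    }
    e
  }
  artefact <- base_enrich(genome$truth$artefact_pos,
                          rep(scenario$artefact_fold,
                              length(genome$truth$artefact_pos)))
  noisy <- function(expected)
    expected * 2^stats::rnorm(length(expected), 0, scenario$chip_noise_sd)
  tracks <- list()
  for (tp in scenario$timepoints) {
    fold_tp <- ifelse(tp == "T0" & !sites$persistent, 1, sites$fold)
    signal <- 1 + base_enrich(sites$pos, fold_tp) + artefact
    ip <- lapply(seq_len(scenario$n_chip_reps), function(r)
      probe_track(probes, noisy(signal), sprintf("rep%d", r), tp,
                  is_control = FALSE))
    names(ip) <- sprintf("rep%d", seq_len(scenario$n_chip_reps))
    control <- probe_track(probes, noisy(1 + artefact), "control", tp,
                           is_control = TRUE)
    tracks[[tp]] <- list(ip = ip, control = control)
  }
  tracks
}

#' Simulate a replicated expression time course
#'
#' Plants three gene classes: regulator-dependent responders (induced at T30
#' and repressed at T45 in the wild type only), regulator-independent
#' responders (same response in both strains), and flat null genes. Gene
#' identities can be supplied (e.g. from a simulated genome) so that a
#' designated subset of the dependent and null genes coincides with bound
#' genes; otherwise synthetic ids are generated along with a synthetic
#' bound set.
#'
#' @param scenario a [sim_scenario()].
#' @param gene_ids optional character vector supplying ids for all
#'   `n_dependent + n_independent + n_null` genes, in that role order.
#' @param bound_genes optional character vector marking which of those genes
#'   are bound; defaults to the first `n_bound_dependent` dependent ids plus
#'   the first `n_bound_null` null ids.
#' @return list with `se` (a [expression_matrix()]) and `truth` (data.frame:
#'   `gene_id`, `role`, `bound`, `fold_induction`, `fold_repression`,
#'   `category`).
#' @export
simulate_expression <- function(scenario, gene_ids = NULL,
                                bound_genes = NULL) {
  set.seed(scenario$seed + 2000L)
  nd <- scenario$n_dependent; ni <- scenario$n_independent
  nn <- scenario$n_null
  total <- nd + ni + nn
  if (is.null(gene_ids))
    gene_ids <- sprintf("g%04d", seq_len(total))
  stopifnot(length(gene_ids) == total, !anyDuplicated(gene_ids))
  role <- rep(c("dependent", "independent", "null"), c(nd, ni, nn))
  if (is.null(bound_genes))
    bound_genes <- c(gene_ids[seq_len(scenario$n_bound_dependent)],
                     gene_ids[nd + ni + seq_len(scenario$n_bound_null)])
  bound <- gene_ids %in% bound_genes
  fi <- fr <- rep(1, total)
  resp <- role != "null"
  fi[resp] <- stats::runif(sum(resp), scenario$induction_range[1],
                           scenario$induction_range[2])
  fr[resp] <- stats::runif(sum(resp), scenario$repression_range[1],
                           scenario$repression_range[2])
  base <- stats::runif(total, 4, 8)
  tps <- c("T0", "T30", "T45")
  design <- expand.grid(replicate = seq_len(scenario$n_expr_reps),
                        timepoint = tps, strain = scenario$strains,
                        stringsAsFactors = FALSE)
  mu_cell <- function(strain, tp) {
    responds <- ifelse(role == "independent", TRUE,
                ifelse(role == "dependent", strain == scenario$strains[1],
                       FALSE))
    m <- base
    if (tp == "T30") m <- m + ifelse(responds, log2(fi), 0)
    if (tp == "T45") m <- m + ifelse(responds, log2(fi) - log2(fr), 0)
    m
  }
  vals <- sapply(seq_len(nrow(design)), function(j)
    mu_cell(design$strain[j], design$timepoint[j]) +
      stats::rnorm(total, 0, scenario$expr_noise_sd))
  rownames(vals) <- gene_ids
  se <- expression_matrix(vals, design$strain, design$timepoint,
                          design$replicate)
  category <- ifelse(role == "dependent" & bound, "i",
              ifelse(role == "dependent", "ii",
              ifelse(role == "independent", "iii",
              ifelse(bound, "iv", "none"))))
  truth <- data.frame(gene_id = gene_ids, role = role, bound = bound,
                      fold_induction = fi, fold_repression = fr,
                      category = category, row.names = NULL)
  list(se = se, truth = truth)
}

#' Simulate a complete study
#'
#' Runs [simulate_genome()], [simulate_chip_tracks()] and
#' [simulate_expression()] under one seed, wiring the planted binding-site
#' targets into the expression roles: the first `n_bound_dependent` bound
#' genes become regulator-dependent responders (category i) and all
#' remaining bound genes become bound non-responders (category iv), so that
#' planted and inferred categories are directly comparable.
#'
#' @param scenario a [sim_scenario()].
#' @return list with `genome`, `tracks`, `expression`, `truth`.
#' @export
simulate_study <- function(scenario = sim_scenario()) {
  genome <- simulate_genome(scenario)
  tracks <- simulate_chip_tracks(scenario, genome)
  bound <- unique(unlist(genome$truth$target_genes))
  if (length(bound) < scenario$n_bound_dependent)
    stop("scenario plants fewer bound target genes (", length(bound),
         ") than n_bound_dependent (", scenario$n_bound_dependent, ")")
  # every bound gene must carry a planted role, or planted and inferred
  # categories could disagree: the first n_bound_dependent become
  # category-i responders, all remaining bound genes category-iv
  bound_dep <- bound[seq_len(scenario$n_bound_dependent)]
  bound_null <- setdiff(bound, bound_dep)
  nd <- scenario$n_dependent; ni <- scenario$n_independent
  nn <- scenario$n_null
  if (length(bound_null) > nn)
    stop("more bound non-responders than null genes in the design")
  other <- setdiff(genome$genes$gene_id, bound)
  n_other_needed <- (nd - length(bound_dep)) + ni + (nn - length(bound_null))
  if (length(other) < n_other_needed)
    stop("not enough unbound genes for the expression design")
  gene_ids <- c(bound_dep, other[seq_len(nd - length(bound_dep))],
                other[(nd - length(bound_dep)) + seq_len(ni)],
                bound_null,
                other[(nd - length(bound_dep)) + ni +
                        seq_len(nn - length(bound_null))])
  expr <- simulate_expression(scenario, gene_ids = gene_ids,
                              bound_genes = c(bound_dep, bound_null))
  list(genome = genome, tracks = tracks, expression = expr,
       truth = list(sites = genome$truth$sites,
                    artefact_pos = genome$truth$artefact_pos,
                    bound_genes = c(bound_dep, bound_null),
                    expression = expr$truth))
}

#' Write a simulated study to disk
#'
#' Emits FASTA, GFF3, bedGraph tracks, the expression TSV and a
#' ground-truth JSON, all derived from the in-memory simulation.
#'
#' @param study output of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_simulation <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "genome.fa"),
             gff = file.path(dir, "genes.gff3"),
             expression = file.path(dir, "expression.tsv"),
             truth = file.path(dir, "truth.json"))
  Biostrings::writeXStringSet(study$genome$seq, paths[["fasta"]])
  write_gff3(study$genome$genes, paths[["gff"]])
  write_expression_tsv(study$expression$se, paths[["expression"]])
  for (tp in names(study$tracks)) {
    for (nm in names(study$tracks[[tp]]$ip)) {
      p <- file.path(dir, sprintf("chip_%s_%s.bedGraph", tp, nm))
      write_bedgraph_track(study$tracks[[tp]]$ip[[nm]], p)
      paths[[paste("track", tp, nm, sep = "_")]] <- p
    }
    p <- file.path(dir, sprintf("chip_%s_control.bedGraph", tp))
    write_bedgraph_track(study$tracks[[tp]]$control, p)
    paths[[paste("track", tp, "control", sep = "_")]] <- p
  }
  jsonlite::write_json(list(sites = study$truth$sites,
                            artefact_pos = study$truth$artefact_pos,
                            bound_genes = study$truth$bound_genes,
                            expression = study$truth$expression),
                       paths[["truth"]], digits = NA)
  invisible(paths)
}
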