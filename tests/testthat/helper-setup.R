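suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
  library(Biostrings)
  library(SummarizedExperiment)
})

# ---- small constructors ------------------------------------------------------

make_track <- function(ratio, start = seq(1L, by = 100L,
                                          length.out = length(ratio)),
                       width = 60L, replicon = "chr", seqlen = NULL,
                       replicate_id = "rep1", timepoint = "T30",
                       is_control = FALSE) {
  if (is.null(seqlen)) seqlen <- max(start) + width + 1000L
  probes <- GRanges(replicon, IRanges(start, width = width),
                    seqinfo = Seqinfo(replicon, seqlen))
  probe_track(probes, ratio, replicate_id, timepoint, is_control)
}

toy_genes <- function(starts, ends, strands, replicon = "chr",
                      seqlen = max(ends) + 500L) {
  gene_annotation(rep(replicon, length(starts)), starts, ends, strands,
                  sprintf("g%02d", seq_along(starts)),
                  stats::setNames(seqlen, replicon))
}

random_annotation <- function(n_genes, seqlen, seed) {
  set.seed(seed)
  # non-overlapping genes on a grid with random gaps and strands
  pitch <- floor(seqlen / n_genes)
  starts <- (seq_len(n_genes) - 1L) * pitch + sample.int(pitch %/% 4,
                                                         n_genes, TRUE)
  lens <- sample.int(pitch %/% 2, n_genes, TRUE) + 10L
  toy_genes(starts, pmin(starts + lens, seqlen - 1L),
            sample(c("+", "-"), n_genes, TRUE), seqlen = seqlen)
}

# ---- independent oracles -----------------------------------------------------

# brute-force run finder: every window of >= min_run consecutive probes all
# above threshold with permissible gaps, overlap-merged into maximal runs
oracle_peaks <- function(values, starts, ends, threshold, min_run, maxgap) {
  n <- length(values)
  wins <- list()
  for (i in seq_len(n)) {
    if (values[i] <= threshold) next
    j <- i
    while (j < n && values[j + 1L] > threshold &&
           (starts[j + 1L] - ends[j] - 1L) <= maxgap) j <- j + 1L
    if (j - i + 1L >= min_run) wins[[length(wins) + 1L]] <- c(i, j)
  }
  if (!length(wins))
    return(data.frame(start = integer(0), end = integer(0)))
  m <- do.call(rbind, wins)
  ir <- reduce(IRanges(m[, 1], m[, 2]), min.gapwidth = 0L)
  data.frame(start = starts[start(ir)], end = ends[end(ir)])
}

rc_chr <- function(x) {
  chartr("ACGTacgt", "TGCAtgca",
         paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

iupac_regex <- function(pattern) {
  paste0(vapply(strsplit(pattern, "")[[1]], function(ch) {
    letters <- strsplit(Biostrings::IUPAC_CODE_MAP[[ch]], "")[[1]]
    if (length(letters) == 1L) letters
    else paste0("[", paste(letters, collapse = ""), "]")
  }, character(1)), collapse = "")
}

# exhaustive offset/spacer/strand search via zero-width regex lookahead
oracle_bipartite <- function(seq, a, b, smin, smax) {
  L <- nchar(seq)
  out <- list()
  for (s in smin:smax) {
    w <- nchar(a) + s + nchar(b)
    pat <- paste0("(?=", iupac_regex(a), "[ACGT]{", s, "}",
                  iupac_regex(b), ")")
    for (strand in c("+", "-")) {
      subj <- if (strand == "+") seq else rc_chr(seq)
      m <- gregexpr(pat, subj, perl = TRUE)[[1]]
      pos <- as.integer(m)
      pos <- pos[pos > 0L]
      if (!length(pos)) next
      st <- if (strand == "+") pos else L - (pos + w - 1L) + 1L
      out[[length(out) + 1L]] <- data.frame(start = st, end = st + w - 1L,
                                            strand = strand, spacer = s)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), spacer = integer(0)))
  res <- do.call(rbind, out)
  res[order(res$start, res$strand, res$spacer), , drop = FALSE]
}

random_dna_chr <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# expression matrix with exact cell means (replicates all equal unless sd>0)
exact_expression <- function(means, strains, timepoints, n_reps = 2L,
                             sd = 0) {
  # means: named list strain -> matrix genes x timepoints (log2)
  design <- expand.grid(replicate = seq_len(n_reps), timepoint = timepoints,
                        strain = strains, stringsAsFactors = FALSE)
  genes <- rownames(means[[1]])
  vals <- sapply(seq_len(nrow(design)), function(j)
    means[[design$strain[j]]][, design$timepoint[j]] +
      stats::rnorm(length(genes), 0, sd))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = length(genes))
  rownames(vals) <- genes
  expression_matrix(vals, design$strain, design$timepoint, design$replicate)
}
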