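# Bipartite GlnR-box consensus scanning, promoter window extraction, and
# position weight matrix construction/scoring.

#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#'   matchPattern subseq consensusMatrix IUPAC_CODE_MAP
NULL

iupac_ok <- function(x) {
  all(strsplit(toupper(x), "")[[1]] %in% names(IUPAC_CODE_MAP))
}

#' Bipartite operator consensus
#'
#' The GlnR box is modelled as two 5-bp half-sites separated by a short
#' spacer: `GTNAC-n6-GTNAC` in the strict default. A relaxed preset
#' (`a = "KTNAC"`, `b = "GWNAC"`) covers the half-site variants seen among
#' *in vivo* bound promoters, and a widely spaced mode (e.g.
#' `spacer_max = 18`) matches the nasA-style arrangement of two a-sites.
#'
#' @param a,b IUPAC half-site patterns (case-insensitive).
#' @param spacer_min,spacer_max inclusive spacer length range (bp).
#' @return a `bipartite_consensus` list.
#' @export
bipartite_consensus <- function(a = "GTNAC", b = "GTNAC",
                                spacer_min = 6L, spacer_max = 6L) {
  a <- toupper(a); b <- toupper(b)
  if (!iupac_ok(a) || !iupac_ok(b))
    stop("half-site patterns must use IUPAC nucleotide codes")
  stopifnot(spacer_min >= 0, spacer_min <= spacer_max)
  structure(list(a = a, b = b, spacer_min = as.integer(spacer_min),
                 spacer_max = as.integer(spacer_max)),
            class = "bipartite_consensus")
}

#' Relaxed GlnR-box preset
#' @inheritParams bipartite_consensus
#' @return a [bipartite_consensus()] with `a = "KTNAC"`, `b = "GWNAC"`.
#' @export
relaxed_consensus <- function(spacer_min = 6L, spacer_max = 6L)
  bipartite_consensus("KTNAC", "GWNAC", spacer_min, spacer_max)

# starts of IUPAC pattern matches on one strand; subject ambiguity codes
# never match (hits touching a non-ACGT subject base are rejected upstream)
half_site_starts <- function(pattern, subject) {
  start(matchPattern(DNAString(pattern), subject, fixed = "subject"))
}

scan_bipartite_one <- function(subject, consensus, seq_id) {
  subject <- DNAString(toupper(as.character(subject)))
  L <- length(subject)
  la <- nchar(consensus$a); lb <- nchar(consensus$b)
  chars <- strsplit(as.character(subject), "")[[1]]
  bad <- which(!(chars %in% c("A", "C", "G", "T")))
  hits_strand <- function(subj, strand_label) {
    sa <- half_site_starts(consensus$a, subj)
    sb <- half_site_starts(consensus$b, subj)
    res <- list()
    for (s in consensus$spacer_min:consensus$spacer_max) {
      i <- sa[(sa + la + s) %in% sb]
      if (!length(i)) next
      res[[length(res) + 1L]] <- data.frame(
        start = i, end = i + la + s + lb - 1L, spacer = s,
        match = vapply(i, function(p)
          as.character(subseq(subj, p, p + la + s + lb - 1L)), character(1)),
        pattern = sprintf("%s-n%d-%s", consensus$a, s, consensus$b))
    }
    if (!length(res)) return(NULL)
    out <- do.call(rbind, res)
    out$strand <- strand_label
    out
  }
  fwd <- hits_strand(subject, "+")
  rev <- hits_strand(reverseComplement(subject), "-")
  if (!is.null(rev)) {
    # map reverse-strand coordinates back to the forward strand
    s0 <- rev$start
    rev$start <- L - rev$end + 1L
    rev$end <- L - s0 + 1L
  }
  out <- rbind(fwd, rev)
  if (!is.null(out) && nrow(out) > 0L && length(bad)) {
    touches <- vapply(seq_len(nrow(out)), function(r)
      any(bad >= out$start[r] & bad <= out$end[r]), logical(1))
    out <- out[!touches, , drop = FALSE]
  }
  if (is.null(out) || nrow(out) == 0L)
    return(data.frame(sequence_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      spacer = integer(0), match = character(0),
                      pattern = character(0)))
  out$sequence_id <- seq_id
  out <- out[, c("sequence_id", "start", "end", "strand", "spacer",
                 "match", "pattern")]
  out[order(out$start, out$strand, out$spacer), , drop = FALSE]
}

#' Scan sequences for a bipartite consensus
#'
#' Reports every match of `a + spacer + b` on both strands for every spacer
#' length in the configured range; overlapping hits are all reported.
#' Reverse-strand hits are given in forward-strand coordinates with strand
#' `"-"`; the `match` column shows the motif as read on the matching strand.
#' Ambiguity codes in the subject are never matched.
#'
#' @param seqs a character vector, `DNAString` or `DNAStringSet`.
#' @param consensus a [bipartite_consensus()].
#' @return data.frame of hits: `sequence_id`, `start`, `end` (1-based
#'   inclusive), `strand`, `spacer`, `match`, `pattern`.
#' @export
scan_bipartite <- function(seqs, consensus = bipartite_consensus()) {
  stopifnot(inherits(consensus, "bipartite_consensus"))
  if (is(seqs, "DNAString")) seqs <- DNAStringSet(seqs)
  if (is.character(seqs)) seqs <- DNAStringSet(toupper(seqs))
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  out <- do.call(rbind, lapply(seq_along(seqs), function(i)
    scan_bipartite_one(seqs[[i]], consensus, ids[i])))
  rownames(out) <- NULL
  out
}

#' Extract promoter windows around binding regions
#'
#' Returns a fixed-width sequence window centred on each region midpoint,
#' clipped at replicon ends (clipped windows are shorter; a message reports
#' them).
#'
#' @param regions binding-region `GRanges`.
#' @param genome named `DNAStringSet` of replicon sequences.
#' @param width window width in bp (default 250).
#' @return `DNAStringSet` of windows; names identify region and targets, and
#'   `mcols` carry the window coordinates.
#' @export
promoter_windows <- function(regions, genome, width = 250L) {
  if (length(regions) == 0L) return(DNAStringSet())
  sn <- as.character(seqnames(regions))
  missing_seq <- setdiff(unique(sn), names(genome))
  if (length(missing_seq))
    stop("no sequence for replicon(s): ", paste(missing_seq, collapse = ", "))
  mid <- floor((start(regions) + end(regions)) / 2)
  ws <- mid - floor(width / 2)
  we <- ws + width - 1L
  sl <- vapply(genome, length, integer(1))[sn]
  ws_c <- pmax(ws, 1L)
  we_c <- pmin(we, sl)
  n_clip <- sum(ws_c != ws | we_c != we)
  if (n_clip > 0L)
    message(n_clip, " window(s) clipped at replicon ends")
  tg <- mcols(regions)$target_gene_ids
  labels <- if (!is.null(tg))
    vapply(as.list(tg), function(x)
      if (length(x)) paste(x, collapse = "/") else "none", character(1))
  else rep("none", length(regions))
  out <- DNAStringSet(vapply(seq_along(regions), function(i)
    as.character(subseq(genome[[sn[i]]], ws_c[i], we_c[i])), character(1)))
  names(out) <- sprintf("%s:%d-%d|%s", sn, start(regions), end(regions),
                        labels)
  mcols(out) <- DataFrame(replicon = sn, window_start = ws_c,
                          window_end = we_c, targets = labels)
  out
}

#' Build a position weight matrix from aligned sites
#'
#' Column-wise base frequencies with a pseudocount, plus per-column
#' information content in bits (2 minus the column entropy, so always in
#' \[0, 2\]). Log-odds scores used by [pwm_scan()] are taken against the
#' supplied background; for a GC-rich genome pass its mononucleotide
#' composition (see [base_composition()]) rather than the uniform default.
#'
#' @param sites character vector or `DNAStringSet` of equal-length aligned
#'   sites (at least 2).
#' @param pseudocount added per base per column (default 0.5).
#' @param background named numeric vector over A,C,G,T summing to 1;
#'   `NULL` means uniform.
#' @return a `pwm` object: list with `prob` (4 x width), `background`, `ic`.
#' @export
build_pwm <- function(sites, pseudocount = 0.5, background = NULL) {
  if (is.character(sites)) sites <- DNAStringSet(toupper(sites))
  if (length(sites) < 2L) stop("need at least 2 sites to build a PWM")
  if (length(unique(Biostrings::width(sites))) != 1L)
    stop("sites must all have the same length")
  if (is.null(background))
    background <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  background <- background[c("A", "C", "G", "T")]
  stopifnot(abs(sum(background) - 1) < 1e-6)
  counts <- consensusMatrix(sites)[c("A", "C", "G", "T"), , drop = FALSE]
  counts <- counts + pseudocount
  prob <- sweep(counts, 2L, colSums(counts), "/")
  ent <- -colSums(prob * log2(prob))
  structure(list(prob = prob, background = background,
                 ic = pmax(0, 2 - ent)),
            class = "pwm")
}

#' Mononucleotide composition of a genome
#' @param genome `DNAStringSet` (or character) of sequences.
#' @return named frequency vector over A,C,G,T.
#' @export
base_composition <- function(genome) {
  if (is.character(genome)) genome <- DNAStringSet(toupper(genome))
  counts <- colSums(Biostrings::alphabetFrequency(genome)[, c("A", "C", "G",
                                                              "T"),
                                                          drop = FALSE])
  counts / sum(counts)
}

pwm_logodds <- function(pwm) log2(sweep(pwm$prob, 1L, pwm$background, "/"))

score_offsets <- function(lo, subject) {
  chars <- strsplit(toupper(as.character(subject)), "")[[1]]
  idx <- match(chars, c("A", "C", "G", "T"))
  w <- ncol(lo); n <- length(idx)
  if (n < w) return(numeric(0))
  offs <- seq_len(n - w + 1L)
  sc <- numeric(length(offs))
  for (j in seq_len(w)) {
    v <- lo[cbind(idx[offs + j - 1L], j)]
    sc <- sc + ifelse(is.na(v), -Inf, v)   # non-ACGT base voids the window
  }
  sc
}

#' Scan a sequence with a PWM
#'
#' Computes the log-odds score at every offset on both strands and returns
#' hits at or above `threshold`, sorted by decreasing score.
#'
#' @param seq character or `DNAString`.
#' @param pwm a [build_pwm()] object.
#' @param threshold minimum log-odds score (bits); `-Inf` returns all
#'   offsets.
#' @return data.frame with `start`, `end`, `strand`, `score`.
#' @export
pwm_scan <- function(seq, pwm, threshold = 0) {
  stopifnot(inherits(pwm, "pwm"))
  subject <- DNAString(toupper(as.character(seq)))
  lo <- pwm_logodds(pwm)
  w <- ncol(lo); L <- length(subject)
  fwd <- score_offsets(lo, subject)
  rev <- score_offsets(lo, reverseComplement(subject))
  out <- rbind(
    if (length(fwd)) data.frame(start = seq_along(fwd),
                                end = seq_along(fwd) + w - 1L,
                                strand = "+", score = fwd),
    if (length(rev)) data.frame(start = L - (seq_along(rev) + w - 1L) + 1L,
                                end = L - seq_along(rev) + 1L,
                                strand = "-", score = rev))
  if (is.null(out))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0)))
  out <- out[out$score >= threshold, , drop = FALSE]
  out <- out[order(-out$score, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate promoter windows with consensus sites
#'
#' Scans each promoter window with the bipartite consensus and reports all
#' hits per region, or the literal flag `"n/a"` when a window carries none.
#'
#' @param windows `DNAStringSet` from [promoter_windows()] (names identify
#'   regions).
#' @param consensus a [bipartite_consensus()].
#' @return list with `table` (data.frame: `region`, `n_sites`, `sites`),
#'   `hits` (full hit table), `n_with_sites`, `n_without_sites`.
#' @export
annotate_regions_with_sites <- function(windows,
                                        consensus = bipartite_consensus()) {
  if (length(windows) == 0L)
    return(list(table = data.frame(region = character(0),
                                   n_sites = integer(0),
                                   sites = character(0)),
                hits = NULL, n_with_sites = 0L, n_without_sites = 0L))
  hits <- scan_bipartite(windows, consensus)
  by_region <- split(hits$match, factor(hits$sequence_id,
                                        levels = names(windows)))
  tab <- data.frame(
    region = names(windows),
    n_sites = unname(lengths(by_region)),
    sites = vapply(by_region, function(x)
      if (length(x)) paste(x, collapse = ";") else "n/a", character(1)),
    row.names = NULL)
  list(table = tab, hits = hits,
       n_with_sites = sum(tab$n_sites > 0L),
       n_without_sites = sum(tab$n_sites == 0L))
}

#' Spacer length implied by full-length sites
#'
#' Given equal-length full sites and the half-site width, returns the
#' implied spacer (site length minus twice the half-site width).
#'
#' @param sites character vector of full sites.
#' @param half_width half-site width in bp (default 5).
#' @return integer spacer length; errors if site lengths disagree.
#' @export
consensus_spacer <- function(sites, half_width = 5L) {
  len <- unique(nchar(sites))
  if (length(len) != 1L)
    stop("sites have differing lengths: ", paste(len, collapse = ", "))
  sp <- len - 2L * half_width
  if (sp < 0L) stop("sites shorter than two half-sites")
  as.integer(sp)
}
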