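#' @import methods
#' @importFrom GenomicRanges GRanges mcols mcols<- reduce findOverlaps gaps
#'   strand strand<- seqnames start end width resize countOverlaps
#' @importFrom IRanges IRanges overlapsAny subsetByOverlaps CharacterList
#' @importFrom S4Vectors metadata metadata<- queryHits subjectHits DataFrame
#'   Rle runValue
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqlevels<-
#'   seqinfo seqinfo<- Seqinfo seqnames<-
#' @importFrom BiocGenerics sort
NULL

# -- genome annotation ---------------------------------------------------------

#' Assemble a gene annotation
#'
#' Builds the annotation container used throughout the package: a `GRanges`
#' of gene bodies carrying `gene_id`, `product` and `homologue_id` metadata
#' columns, with replicon lengths recorded as `seqlengths`.
#'
#' @param replicon character vector of replicon names, one per gene.
#' @param start,end 1-based inclusive gene coordinates.
#' @param strand `"+"` or `"-"` per gene.
#' @param gene_id unique gene identifiers.
#' @param seqlen named integer vector of replicon lengths.
#' @param product,homologue_id optional free-text annotation columns.
#' @return a `GRanges` of genes, sorted by position within replicon.
#' @export
gene_annotation <- function(replicon, start, end, strand, gene_id, seqlen,
                            product = NA_character_,
                            homologue_id = NA_character_) {
  if (anyDuplicated(gene_id))
    stop("gene_id values must be unique within an annotation")
  if (any(end < start))
    stop("gene end must be >= start")
  if (!all(strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  gr <- GRanges(replicon, IRanges(start, end), strand = strand,
                gene_id = gene_id, product = product,
                homologue_id = homologue_id)
  sl <- seqlen[as.character(seqnames(gr))]
  if (anyNA(sl))
    stop("gene(s) on replicon(s) absent from the length table: ",
         paste(unique(as.character(seqnames(gr))[is.na(sl)]), collapse = ", "))
  bad <- end(gr) > sl | start(gr) < 1
  if (any(bad))
    stop("gene(s) extend beyond replicon bounds: ",
         paste(gr$gene_id[bad], collapse = ", "))
  seqlevels(gr) <- names(seqlen)
  seqinfo(gr) <- Seqinfo(names(seqlen), unname(seqlen))
  sort(gr, ignore.strand = TRUE)
}

#' Read gene features from a GFF3 file
#'
#' Imports `gene` features (1-based inclusive coordinates, per the GFF3
#' dialect) and replicon lengths from `##sequence-region` pragmas.
#'
#' @param path path to a GFF3 file.
#' @return a gene `GRanges` as produced by [gene_annotation()].
#' @export
read_gff3 <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("failed to parse GFF3 '", path,
                                          "': ", conditionMessage(e)))
  # replicon lengths from pragmas; rtracklayer records them when present
  lines <- readLines(path, warn = FALSE)
  prag <- grep("^##sequence-region", lines, value = TRUE)
  seqlen <- integer(0)
  if (length(prag)) {
    parts <- strsplit(trimws(prag), "\\s+")
    seqlen <- vapply(parts, function(p) as.integer(p[4]), integer(1))
    names(seqlen) <- vapply(parts, `[`, character(1), 2)
  }
  gr <- gr[gr$type == "gene"]
  if (length(gr) == 0L) {
    warning("annotation contains no gene features")
    return(GRanges(seqinfo = Seqinfo(names(seqlen), unname(seqlen))))
  }
  if (length(seqlen)) {
    unknown <- !(as.character(seqnames(gr)) %in% names(seqlen))
    if (any(unknown))
      stop("feature on replicon absent from ##sequence-region pragmas: ",
           paste(unique(as.character(seqnames(gr))[unknown]), collapse = ", "))
  } else {
    seqlen <- vapply(split(end(gr), as.character(seqnames(gr))), max,
                     numeric(1))
  }
  ids <- if (!is.null(gr$ID)) gr$ID else gr$Name
  if (is.null(ids) || anyNA(ids))
    stop("gene features must carry an ID attribute")
  gene_annotation(as.character(seqnames(gr)), start(gr), end(gr),
                  as.character(strand(gr)), ids, seqlen,
                  product = if (is.null(gr$product)) NA_character_ else
                    as.character(gr$product),
                  homologue_id = if (is.null(gr$homologue)) NA_character_ else
                    as.character(gr$homologue))
}

#' Write a gene annotation as GFF3
#'
#' @param genes gene `GRanges` from [gene_annotation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  out <- genes
  mcols(out) <- DataFrame(source = "glnregulon", type = "gene",
                          ID = genes$gene_id,
                          product = genes$product,
                          homologue = genes$homologue_id)
  con <- file(path, open = "wt")
  writeLines("##gff-version 3", con)
  sl <- seqlengths(out)
  for (sn in names(sl))
    writeLines(sprintf("##sequence-region %s 1 %d", sn, sl[[sn]]), con)
  close(con)
  rtracklayer::export(out, path, format = "gff3", append = TRUE)
  invisible(path)
}

# -- intergenic complement -----------------------------------------------------

#' Intergenic regions of an annotation
#'
#' Computes the per-replicon complement of the union of gene bodies, so
#' nested or overlapping genes never create spurious regions. Each region is
#' labelled with its flanking genes and an orientation class: `divergent`
#' when the flanking genes point away from each other (left gene on `-`,
#' right gene on `+`), `convergent` when they point toward each other,
#' `tandem` when co-oriented, and `chromosome_end` when a flank is missing.
#'
#' @param genes gene `GRanges` with `seqlengths` set.
#' @return `GRanges` of intergenic regions with `left_gene`, `right_gene`
#'   and `orientation_class` metadata columns.
#' @export
intergenic_regions <- function(genes) {
  sl <- seqlengths(genes)
  if (anyNA(sl)) stop("annotation must carry replicon lengths")
  whole <- GRanges(names(sl), IRanges(1L, unname(sl)))
  merged <- reduce(genes, ignore.strand = TRUE)
  inter <- GenomicRanges::setdiff(whole, merged, ignore.strand = TRUE)
  if (length(inter) == 0L) {
    mcols(inter) <- DataFrame(left_gene = character(0),
                              right_gene = character(0),
                              orientation_class = character(0))
    return(inter)
  }
  gsort <- sort(genes, ignore.strand = TRUE)
  left_gene <- right_gene <- rep(NA_character_, length(inter))
  left_strand <- right_strand <- rep(NA_character_, length(inter))
  for (i in seq_along(inter)) {
    sn <- as.character(seqnames(inter))[i]
    on <- gsort[as.character(seqnames(gsort)) == sn]
    lf <- on[end(on) < start(inter)[i]]
    rt <- on[start(on) > end(inter)[i]]
    if (length(lf)) {
      j <- which.max(end(lf))
      left_gene[i] <- lf$gene_id[j]
      left_strand[i] <- as.character(strand(lf))[j]
    }
    if (length(rt)) {
      j <- which.min(start(rt))
      right_gene[i] <- rt$gene_id[j]
      right_strand[i] <- as.character(strand(rt))[j]
    }
  }
  oc <- ifelse(is.na(left_strand) | is.na(right_strand), "chromosome_end",
        ifelse(left_strand == "-" & right_strand == "+", "divergent",
        ifelse(left_strand == "+" & right_strand == "-", "convergent",
               "tandem")))
  mcols(inter) <- DataFrame(left_gene = left_gene, right_gene = right_gene,
                            orientation_class = oc)
  inter
}

# -- probe tracks --------------------------------------------------------------

#' Construct a probe ratio track
#'
#' A track is a `GRanges` of tiling probes in genomic order with a positive
#' `ratio` metadata column (IP over total-DNA signal) and the hybridisation's
#' identity (`replicate_id`, `timepoint`, `is_control`) in its `metadata()`.
#' Non-finite or non-positive ratios are dropped with a message.
#'
#' @param probes `GRanges` of probe positions.
#' @param ratio numeric vector of linear ratios, one per probe.
#' @param replicate_id replicate label, e.g. `"rep1"`.
#' @param timepoint timepoint label, e.g. `"T30"`.
#' @param is_control logical; `TRUE` for empty-vector control hybridisations.
#' @return a sorted probe-track `GRanges`.
#' @export
probe_track <- function(probes, ratio, replicate_id, timepoint,
                        is_control = FALSE) {
  stopifnot(length(probes) == length(ratio))
  keep <- is.finite(ratio) & ratio > 0
  if (any(!keep))
    message(sum(!keep), " probe(s) with non-finite or non-positive ratio dropped")
  tr <- probes[keep]
  mcols(tr) <- DataFrame(ratio = ratio[keep])
  tr <- sort(tr, ignore.strand = TRUE)
  metadata(tr) <- list(replicate_id = replicate_id, timepoint = timepoint,
                       is_control = isTRUE(is_control))
  tr
}

#' Track identity accessor
#' @param track a probe track.
#' @return list with `replicate_id`, `timepoint`, `is_control`.
#' @export
track_info <- function(track) metadata(track)

#' Read a probe ratio track from bedGraph
#'
#' bedGraph intervals (0-based half-open on disk, handled by rtracklayer)
#' are interpreted as probes carrying one linear ratio each.
#'
#' @param path bedGraph file path.
#' @param annotation optional gene `GRanges`; when supplied, probe intervals
#'   outside its replicon bounds raise an error.
#' @inheritParams probe_track
#' @return a probe-track `GRanges`.
#' @export
read_bedgraph_track <- function(path, annotation = NULL, replicate_id,
                                timepoint, is_control = FALSE) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (!is.null(annotation)) {
    sl <- seqlengths(annotation)
    sn <- as.character(seqnames(gr))
    if (!all(sn %in% names(sl)))
      stop("probe interval on unknown replicon: ",
           paste(setdiff(unique(sn), names(sl)), collapse = ", "))
    if (any(end(gr) > sl[sn]) || any(start(gr) < 1L))
      stop("probe interval outside replicon bounds in '", path, "'")
  }
  probe_track(GRanges(seqnames(gr), IRanges(start(gr), end(gr))),
              gr$score, replicate_id, timepoint, is_control)
}

#' Write a probe track as bedGraph
#'
#' The track line name encodes replicate, timepoint and control status.
#'
#' @param track a probe track.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph_track <- function(track, path) {
  info <- track_info(track)
  out <- track
  names(mcols(out))[names(mcols(out)) == "ratio"] <- "score"
  line <- methods::new("BasicTrackLine",
                       name = paste(info$replicate_id, info$timepoint,
                                    if (isTRUE(info$is_control)) "control"
                                    else "ip", sep = "_"))
  rtracklayer::export(out, path, format = "bedGraph", trackLine = line)
  invisible(path)
}
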