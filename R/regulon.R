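# Integration of binding, response and dependence evidence into regulon
# categories.

#' Classify genes into regulon categories
#'
#' Joins regulator-dependence calls with the set of genes targeted by
#' reported binding regions and assigns each gene one category:
#' \describe{
#'   \item{i}{responsive, dependent, and bound (direct regulon member);}
#'   \item{ii}{responsive and dependent but not bound (likely regulated via
#'     an intermediate);}
#'   \item{iii}{responsive but regulator-independent;}
#'   \item{iv}{bound but not responsive under the conditions studied;}
#'   \item{none}{no supporting evidence.}
#' }
#' Bound genes missing from the expression calls are treated as
#' non-responsive and flagged `no_expression_data`, never silently dropped.
#'
#' @param dependence output of [dependence_calls()].
#' @param bound_genes character vector of bound gene ids (see
#'   [bound_gene_set()]), or an [assign_targets()] `GRanges`.
#' @return data.frame with `gene_id`, `bound`, `responsive`, `dependent`,
#'   `category` and `flag`, sorted by gene id.
#' @export
classify_regulon <- function(dependence, bound_genes) {
  if (is(bound_genes, "GRanges")) bound_genes <- bound_gene_set(bound_genes)
  if (anyDuplicated(dependence$gene_id)) {
    dup <- unique(dependence$gene_id[duplicated(dependence$gene_id)])
    conflicting <- vapply(dup, function(g) {
      rows <- dependence[dependence$gene_id == g, , drop = FALSE]
      nrow(unique(rows)) > 1L
    }, logical(1))
    if (any(conflicting))
      stop("conflicting duplicate dependence records for gene(s): ",
           paste(dup[conflicting], collapse = ", "))
    dependence <- dependence[!duplicated(dependence$gene_id), , drop = FALSE]
  }
  genes <- sort(union(dependence$gene_id, bound_genes))
  idx <- match(genes, dependence$gene_id)
  responsive <- ifelse(is.na(idx), FALSE, dependence$wt_passes[idx])
  dependent <- ifelse(is.na(idx), FALSE, dependence$dependent[idx])
  bound <- genes %in% bound_genes
  category <- ifelse(responsive & dependent & bound, "i",
              ifelse(responsive & dependent, "ii",
              ifelse(responsive, "iii",
              ifelse(bound, "iv", "none"))))
  flag <- ifelse(is.na(idx), "no_expression_data", "")
  data.frame(gene_id = genes, bound = bound, responsive = responsive,
             dependent = dependent, category = category, flag = flag,
             row.names = NULL)
}

#' Regulon report
#'
#' One row per classified gene with all evidence columns, a per-category
#' summary, and (optionally) a binding-region listing in the style of a
#' published target table.
#'
#' @param records output of [classify_regulon()].
#' @param annotation optional data.frame with `gene_id`, `homologue_id`,
#'   `product` columns to join.
#' @param motif_table optional data.frame from
#'   [annotate_regions_with_sites()]`$table`.
#' @param regions optional [assign_targets()] `GRanges` for the region
#'   listing.
#' @param path optional output TSV path.
#' @return list with `table`, `summary` (named category counts) and
#'   `regions` (data.frame listing or `NULL`).
#' @export
regulon_report <- function(records, annotation = NULL, motif_table = NULL,
                           regions = NULL, path = NULL) {
  tab <- records
  if (!is.null(annotation)) {
    keep <- intersect(c("gene_id", "homologue_id", "product"),
                      colnames(annotation))
    tab <- merge(tab, annotation[, keep, drop = FALSE], by = "gene_id",
                 all.x = TRUE, sort = TRUE)
  }
  summary <- table(factor(records$category,
                          levels = c("i", "ii", "iii", "iv", "none")))
  region_tab <- NULL
  if (!is.null(regions) && length(regions) > 0L) {
    tg <- mcols(regions)$target_gene_ids
    region_tab <- data.frame(
      replicon = as.character(seqnames(regions)),
      start = start(regions), end = end(regions),
      intergenic = mcols(regions)$intergenic %||% NA,
      targets = vapply(as.list(tg %||% CharacterList(rep(list(character(0)),
                                                         length(regions)))),
                       paste, character(1), collapse = "/"),
      row.names = NULL)
    if (!is.null(motif_table) && nrow(motif_table) == nrow(region_tab))
      region_tab$sites <- motif_table$sites
  }
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(table = tab, summary = c(summary), regions = region_tab)
}
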