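# Nitrogen-response filtering and regulator-dependence calls on replicated
# log2 expression time courses (strains x timepoints x replicates).

#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

#' Build an expression matrix container
#'
#' Wraps a gene x sample matrix of log2 intensities in a
#' `SummarizedExperiment` with `strain`, `timepoint` and `replicate` sample
#' annotations.
#'
#' @param values numeric matrix, genes in rows (rownames are gene ids).
#' @param strain,timepoint,replicate per-column sample annotations.
#' @return a `SummarizedExperiment` with one assay, `log2`.
#' @export
expression_matrix <- function(values, strain, timepoint, replicate) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            ncol(values) == length(strain),
            length(strain) == length(timepoint),
            length(timepoint) == length(replicate))
  if (!all(is.finite(values)))
    stop("expression values must be finite")
  colnames(values) <- paste(strain, timepoint, replicate, sep = ":")
  SummarizedExperiment(
    assays = list(log2 = values),
    colData = DataFrame(strain = as.character(strain),
                        timepoint = as.character(timepoint),
                        replicate = as.integer(replicate)))
}

#' Read an expression matrix from TSV
#'
#' Expects a first column `gene_id` and sample columns headed
#' `strain:timepoint:rep`.
#'
#' @param path TSV path.
#' @return a `SummarizedExperiment` as from [expression_matrix()].
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (colnames(df)[1] != "gene_id")
    stop("first column of an expression TSV must be 'gene_id'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  parts <- strsplit(colnames(m), ":", fixed = TRUE)
  if (any(lengths(parts) != 3L))
    stop("sample columns must be named 'strain:timepoint:rep'")
  expression_matrix(m,
                    strain = vapply(parts, `[`, character(1), 1L),
                    timepoint = vapply(parts, `[`, character(1), 2L),
                    replicate = vapply(parts, `[`, character(1), 3L))
}

#' Write an expression matrix as TSV
#' @param se expression `SummarizedExperiment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(se, path) {
  m <- assay(se, "log2")
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-gene median centring
#'
#' Subtracts each gene's median log2 value from its row, so every output row
#' has median zero. Fold changes are invariant under this normalisation.
#'
#' @param se expression `SummarizedExperiment`.
#' @return the centred `SummarizedExperiment`.
#' @export
median_center <- function(se) {
  m <- assay(se, "log2")
  med <- apply(m, 1L, stats::median)
  SummarizedExperiment::assay(se, "log2") <- m - med
  se
}

strain_tp_means <- function(se, strain, timepoints) {
  m <- assay(se, "log2")
  cd <- colData(se)
  sapply(timepoints, function(tp) {
    cols <- which(cd$strain == strain & cd$timepoint == tp)
    if (length(cols) == 0L)
      stop("no samples for strain '", strain, "' at timepoint '", tp, "'")
    rowMeans(m[, cols, drop = FALSE])
  })
}

#' Nitrogen-response fold changes and the dual filter
#'
#' For each gene, fold induction is the linear ratio of the (replicate-mean)
#' expression at T30 over T0, and fold repression the ratio of T30 over T45,
#' both computed in the log2 domain and exponentiated. A gene passes the
#' response filter when both exceed `theta` (default 2): induced more than
#' `theta`-fold by nitrogen starvation and repressed more than `theta`-fold
#' by ammonium re-addition.
#'
#' @param se expression `SummarizedExperiment`.
#' @param strain strain whose response is evaluated (default `"WT"`).
#' @param theta dual-filter fold-change threshold.
#' @param timepoints the three timepoint labels, in order (before
#'   starvation, starved, after ammonium re-addition).
#' @return data.frame with `gene_id`, `fold_induction`, `fold_repression`,
#'   `passes_response_filter` and `theta`.
#' @export
fold_changes <- function(se, strain = "WT", theta = 2,
                         timepoints = c("T0", "T30", "T45")) {
  stopifnot(length(timepoints) == 3L)
  mu <- strain_tp_means(se, strain, timepoints)
  fi <- 2^(mu[, 2L] - mu[, 1L])
  fr <- 2^(mu[, 2L] - mu[, 3L])
  data.frame(gene_id = rownames(mu),
             fold_induction = unname(fi),
             fold_repression = unname(fr),
             passes_response_filter = unname(fi > theta & fr > theta),
             theta = theta,
             row.names = NULL)
}

#' Regulator-dependence calls
#'
#' A gene is regulator-dependent when it passes the dual response filter in
#' the wild type (at `theta_wt`) but fails it in the regulator deletion
#' mutant (at `theta_mutant`). Both per-strain calls are returned so
#' alternative operationalisations can be audited.
#'
#' @inheritParams fold_changes
#' @param wt,mutant strain labels.
#' @param theta_wt wild-type dual-filter threshold (default 2).
#' @param theta_mutant threshold below which the mutant counts as
#'   non-responsive (default 2).
#' @return data.frame with per-strain folds/calls and `dependent`.
#' @export
dependence_calls <- function(se, wt = "WT", mutant = "glnR",
                             theta_wt = 2, theta_mutant = 2,
                             timepoints = c("T0", "T30", "T45")) {
  w <- fold_changes(se, wt, theta_wt, timepoints)
  m <- fold_changes(se, mutant, theta_mutant, timepoints)
  stopifnot(identical(w$gene_id, m$gene_id))
  data.frame(gene_id = w$gene_id,
             wt_fold_induction = w$fold_induction,
             wt_fold_repression = w$fold_repression,
             wt_passes = w$passes_response_filter,
             mutant_fold_induction = m$fold_induction,
             mutant_fold_repression = m$fold_repression,
             mutant_passes = m$passes_response_filter,
             dependent = w$passes_response_filter & !m$passes_response_filter,
             row.names = NULL)
}

#' Per-gene two-way ANOVA with Benjamini-Hochberg correction
#'
#' Fits the classical fixed-effects two-way model
#' `log2 ~ strain * timepoint` gene by gene, extracts F and p for the two
#' main effects and the interaction, and applies the Benjamini-Hochberg
#' step-up correction per effect across genes. Genes with zero variance get
#' p = 1 by convention so they can never be called significant.
#'
#' @param se expression `SummarizedExperiment`.
#' @param strains optional subset of strains to include.
#' @param alpha significance level for the `sig_*` flags.
#' @return data.frame with per-gene F, p and BH-adjusted q values for
#'   `strain`, `timepoint` and their interaction, plus significance flags.
#' @export
two_way_anova_bh <- function(se, strains = NULL, alpha = 0.05) {
  cd <- colData(se)
  keep <- if (is.null(strains)) seq_len(ncol(se)) else
    which(cd$strain %in% strains)
  m <- assay(se, "log2")[, keep, drop = FALSE]
  strain <- factor(cd$strain[keep])
  timepoint <- factor(cd$timepoint[keep])
  if (nlevels(strain) < 2L || nlevels(timepoint) < 2L)
    stop("two-way ANOVA needs at least 2 levels per factor")
  fit_one <- function(y) {
    if (stats::var(y) == 0)
      return(c(NA, 1, NA, 1, NA, 1))
    a <- stats::anova(stats::lm(y ~ strain * timepoint))
    c(a["strain", "F value"], a["strain", "Pr(>F)"],
      a["timepoint", "F value"], a["timepoint", "Pr(>F)"],
      a["strain:timepoint", "F value"], a["strain:timepoint", "Pr(>F)"])
  }
  res <- t(apply(m, 1L, fit_one))
  out <- data.frame(gene_id = rownames(m),
                    F_strain = res[, 1], p_strain = res[, 2],
                    F_timepoint = res[, 3], p_timepoint = res[, 4],
                    F_interaction = res[, 5], p_interaction = res[, 6],
                    row.names = NULL)
  out$q_strain <- stats::p.adjust(out$p_strain, method = "BH")
  out$q_timepoint <- stats::p.adjust(out$p_timepoint, method = "BH")
  out$q_interaction <- stats::p.adjust(out$p_interaction, method = "BH")
  out$sig_strain <- out$q_strain < alpha
  out$sig_timepoint <- out$q_timepoint < alpha
  out$sig_interaction <- out$q_interaction < alpha
  out
}

#' Top responsive genes by fold induction
#'
#' Genes passing the dual response filter, sorted by decreasing fold
#' induction (ties broken by gene id), truncated to `n` rows. Homologue and
#' product columns are joined when an annotation table is supplied.
#'
#' @param calls output of [fold_changes()].
#' @param n number of rows to keep.
#' @param annotation optional data.frame with `gene_id`, `homologue_id`,
#'   `product`.
#' @return the ranked data.frame.
#' @export
top_table <- function(calls, n = 20L, annotation = NULL) {
  passing <- calls[calls$passes_response_filter, , drop = FALSE]
  ord <- order(-passing$fold_induction, passing$gene_id)
  out <- utils::head(passing[ord, , drop = FALSE], n)
  if (!is.null(annotation)) {
    keep <- intersect(c("gene_id", "homologue_id", "product"),
                      colnames(annotation))
    out <- merge(out, annotation[, keep, drop = FALSE], by = "gene_id",
                 all.x = TRUE, sort = FALSE)
    out <- out[order(-out$fold_induction, out$gene_id), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
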