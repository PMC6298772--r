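# Screen scoring: filter low-count guides, normalize to reads-per-million,
# log2 fold-change with a pseudocount against the plasmid reference, and
# gene ranking by the second-most enriched / second-most depleted sgRNA.

#' Filter guides with low raw read counts
#'
#' A guide is retained iff its raw count is at least `threshold` in the
#' compared sample and (with the default scope `"both"`) also in the
#' reference sample, protecting both the numerator and the denominator of
#' the fold-change from shot noise. `scope = "sample"` applies the filter to
#' the compared sample only.
#'
#' @param counts A [screen_counts()] object.
#' @param sample Sample id compared against the reference.
#' @param threshold Minimum raw read count (default 30; guides with fewer
#'   reads are excluded).
#' @param scope `"both"` (default) or `"sample"`.
#' @return Character vector of retained guide ids.
#' @export
filter_low_counts <- function(counts, sample, threshold = 30,
                              scope = c("both", "sample")) {
  stopifnot(inherits(counts, "screen_counts"))
  scope <- match.arg(scope)
  m <- counts$counts
  if (nrow(m) == 0) stop("empty count matrix")
  if (!sample %in% colnames(m)) stop("unknown sample: ", sample)
  keep <- m[, sample] >= threshold
  if (scope == "both") keep <- keep & m[, counts$reference_sample] >= threshold
  retained <- rownames(m)[keep]
  message(sum(!keep), " of ", nrow(m), " guides excluded (raw count < ",
          threshold, ", scope = ", scope, ")")
  retained
}

#' Normalize raw screen counts to reads-per-million
#'
#' Each cell is `raw * 1e6 / column total`; totals are computed over all
#' guides, before any filtering, so every column sums to 1e6.
#'
#' @param counts A [screen_counts()] object.
#' @return Numeric matrix of reads-per-million values.
#' @export
normalize_to_depth <- function(counts) {
  stopifnot(inherits(counts, "screen_counts"))
  m <- counts$counts
  totals <- colSums(m)
  zero <- colnames(m)[totals == 0]
  if (length(zero)) {
    stop("sample(s) with zero total reads: ", paste(zero, collapse = ", "))
  }
  sweep(m, 2, totals, "/") * 1e6
}

#' Guide-level log2 fold-change with a pseudocount
#'
#' `lfc = log2((norm_sample + pseudocount) / (norm_reference + pseudocount))`.
#' The pseudocount is applied on the reads-per-million scale (numerator and
#' denominator alike), which keeps the statistic invariant to sequencing
#' depth.
#'
#' @param norm_sample,norm_reference Non-negative reads-per-million values.
#' @param pseudocount Pseudocount added to both (default 1).
#' @return Numeric vector of log2 fold-changes.
#' @export
guide_lfc <- function(norm_sample, norm_reference, pseudocount = 1) {
  if (any(norm_sample < 0) || any(norm_reference < 0)) {
    stop("normalized abundances must be non-negative")
  }
  log2((norm_sample + pseudocount) / (norm_reference + pseudocount))
}

#' Rank genes by the second-most extreme guide fold-change
#'
#' For every gene, over its guides that passed the count filter:
#' `second_best_enriched` is the second-largest log2 fold-change and
#' `second_best_depleted` the second-smallest. Genes are then ranked by
#' these statistics (enrichment descending, depletion ascending), with ties
#' broken by gene label. Genes with fewer than two passed guides and the
#' pooled control pseudo-gene are reported but excluded from ranking.
#'
#' @param lfc_table A guide-level data frame as produced by [run_screen()]
#'   (columns `guide_id`, `gene`, `lfc`, `passed_filter`).
#' @param library A [guide_library()] used to flag control guides.
#' @return A `gene_rank_table` data frame.
#' @export
rank_genes <- function(lfc_table, library) {
  stopifnot(all(c("guide_id", "gene", "lfc", "passed_filter") %in%
                  names(lfc_table)))
  ctrl_genes <- unique(library$gene[library$is_control])
  genes <- sort(unique(lfc_table$gene))
  passed <- lfc_table[lfc_table$passed_filter, , drop = FALSE]
  by_gene <- split(passed$lfc, factor(passed$gene, levels = genes))

  second_largest <- function(v) if (length(v) < 2) NA_real_ else
    sort(v, decreasing = TRUE)[2]
  second_smallest <- function(v) if (length(v) < 2) NA_real_ else
    sort(v)[2]

  out <- data.frame(
    gene = genes,
    n_guides_passed = vapply(by_gene, length, integer(1)),
    second_best_enriched = vapply(by_gene, second_largest, numeric(1)),
    second_best_depleted = vapply(by_gene, second_smallest, numeric(1)),
    stringsAsFactors = FALSE
  )
  out$excluded <- out$gene %in% ctrl_genes | out$n_guides_passed < 2
  out$exclusion_reason <- ifelse(out$gene %in% ctrl_genes, "control",
                                 ifelse(out$n_guides_passed < 2,
                                        "lt2_guides", ""))
  rankable <- which(!out$excluded)
  out$enrichment_rank <- NA_integer_
  out$depletion_rank <- NA_integer_
  ord_e <- rankable[order(-out$second_best_enriched[rankable],
                          out$gene[rankable])]
  out$enrichment_rank[ord_e] <- seq_along(ord_e)
  ord_d <- rankable[order(out$second_best_depleted[rankable],
                          out$gene[rankable])]
  out$depletion_rank[ord_d] <- seq_along(ord_d)
  rownames(out) <- NULL
  class(out) <- c("gene_rank_table", "data.frame")
  out
}

#' Run the full screen-scoring pipeline
#'
#' Normalize to reads-per-million, filter low-count guides on raw counts,
#' compute pseudocount log2 fold-changes of the compared sample against the
#' reference, and rank genes by the second-most extreme guide.
#'
#' @param counts A [screen_counts()] object.
#' @param library A [guide_library()] matching the count rows.
#' @param sample Sample id to compare against the reference (default: the
#'   first non-reference sample).
#' @param reference Reference sample id (default: the matrix's declared
#'   plasmid reference); pass another sample id for e.g. a
#'   treated-vs-untreated comparison.
#' @param threshold Raw-count filter threshold (default 30).
#' @param pseudocount Pseudocount for the fold-change (default 1).
#' @param filter_scope `"both"` or `"sample"`; see [filter_low_counts()].
#' @return List with `guides` (per-guide table) and `genes` (a
#'   [rank_genes()] table), plus the parameters used.
#' @export
run_screen <- function(counts, library, sample = NULL, reference = NULL,
                       threshold = 30, pseudocount = 1,
                       filter_scope = c("both", "sample")) {
  stopifnot(inherits(counts, "screen_counts"))
  filter_scope <- match.arg(filter_scope)
  if (is.null(reference)) reference <- counts$reference_sample
  if (is.null(sample)) {
    sample <- setdiff(colnames(counts$counts), reference)[1]
  }
  m <- counts$counts
  if (!setequal(rownames(m), library$guide_id)) {
    stop("count matrix rows do not match the guide library")
  }
  lib <- library[match(rownames(m), library$guide_id), , drop = FALSE]

  rpm <- normalize_to_depth(counts)
  cmp <- screen_counts(m, reference) # re-anchor filter on the compared pair
  retained <- filter_low_counts(cmp, sample, threshold, filter_scope)
  passed <- rownames(m) %in% retained

  lfc <- rep(NA_real_, nrow(m))
  lfc[passed] <- guide_lfc(rpm[passed, sample], rpm[passed, reference],
                           pseudocount)
  guides <- data.frame(
    guide_id = rownames(m), gene = lib$gene,
    raw_count_sample = m[, sample], raw_count_reference = m[, reference],
    norm_sample = rpm[, sample], norm_reference = rpm[, reference],
    lfc = lfc, passed_filter = passed,
    row.names = NULL, stringsAsFactors = FALSE
  )
  genes <- rank_genes(guides, library)
  list(guides = guides, genes = genes,
       params = list(sample = sample, reference = reference,
                     threshold = threshold, pseudocount = pseudocount,
                     filter_scope = filter_scope))
}
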