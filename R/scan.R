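# Negative-feedback-regulator differential-expression scan and the RPPA
# association analyses: Welch t-tests with Bonferroni correction and
# -log2(p) scores, row median/MAD normalization for heatmaps, Mann-Whitney
# group comparisons, quartile splits and Pearson correlation.

#' Welch two-sample t-test
#'
#' Two-tailed by default, with the Welch-Satterthwaite degrees of freedom.
#' `equal_var = TRUE` gives the pooled-variance (classic unpaired) variant.
#' If both groups are constant with equal means the test is undefined and
#' `p = 1` is returned with a warning.
#'
#' @param x,y Numeric samples, each with at least 2 observations.
#' @param equal_var Pool the variances? Default `FALSE` (Welch).
#' @return List with `t`, `df` and `p`.
#' @export
welch_t_test <- function(x, y, equal_var = FALSE) {
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 observations")
  }
  if (var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y)) {
      warning("both groups constant with equal means; p = 1")
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    }
    stop("both groups constant with different means: t is undefined")
  }
  ht <- t.test(x, y, var.equal = equal_var)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = min(1, ht$p.value))
}

#' Scan a regulator panel for mutation-linked differential expression
#'
#' Each panel gene's expression is compared between mutant and wild-type
#' samples with a two-tailed Welch t-test (on the log2 scale by default,
#' matching how such RSEM-style values are conventionally analyzed), the
#' p-values are Bonferroni-corrected over the panel, and `-log2(p)` is
#' reported as the significance score against `alpha`.
#'
#' @param expr Genes x samples expression matrix (non-negative).
#' @param annot Sample annotation data frame (`sample_id` plus logical
#'   mutation flag columns).
#' @param panel Panel gene symbols (default [default_regulator_panel()]).
#' @param group_by Mutation predicate over flag columns, e.g.
#'   `"EGFR|KRAS"`: a sample is "mutant" if any named flag is TRUE.
#' @param alpha Significance level on the corrected p (default 0.01).
#' @param log2_transform Test on `log2(x + 1)`? Default `TRUE`.
#' @param score_on Compute `-log2(p)` from the `"adjusted"` (default) or
#'   `"raw"` p-value.
#' @param equal_var Passed to [welch_t_test()].
#' @return A `regulator_scan` data frame, one row per panel gene, with
#'   `mean_mutant`, `mean_wildtype`, `t_stat`, `df`, `p_raw`, `p_adj`,
#'   `neg_log2_p`, `direction` and `significant`.
#' @export
scan_regulators <- function(expr, annot, panel = default_regulator_panel(),
                            group_by = "EGFR|KRAS", alpha = 0.01,
                            log2_transform = TRUE,
                            score_on = c("adjusted", "raw"),
                            equal_var = FALSE) {
  score_on <- match.arg(score_on)
  miss <- setdiff(panel, rownames(expr))
  if (length(miss)) {
    stop("panel gene(s) absent from expression matrix: ",
         paste(miss, collapse = ", "))
  }
  flags <- strsplit(group_by, "|", fixed = TRUE)[[1]]
  bad <- setdiff(flags, names(annot))
  if (length(bad)) stop("unknown mutation flag(s): ", paste(bad, collapse = ", "))
  annot <- annot[match(colnames(expr), annot$sample_id), , drop = FALSE]
  if (any(is.na(annot$sample_id))) {
    stop("annotation does not cover all expression samples")
  }
  mutant <- Reduce(`|`, lapply(flags, function(f) annot[[f]]))
  if (!any(mutant) || all(mutant)) {
    stop("grouping must yield two non-empty sample sets")
  }

  vals <- if (log2_transform) log2(expr + 1) else expr
  rows <- lapply(panel, function(g) {
    x <- vals[g, mutant]
    y <- vals[g, !mutant]
    ht <- welch_t_test(x, y, equal_var = equal_var)
    data.frame(gene = g, mean_mutant = mean(x), mean_wildtype = mean(y),
               t_stat = ht$t, df = ht$df, p_raw = ht$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p_raw * length(panel)) # Bonferroni over the panel
  out$neg_log2_p <- -log2(if (score_on == "adjusted") out$p_adj else out$p_raw)
  out$direction <- ifelse(out$mean_mutant >= out$mean_wildtype, "up", "down")
  # corrected p-values are capped at 1, so alpha >= 1 disables the filter
  out$significant <- if (alpha >= 1) rep(TRUE, nrow(out)) else
    out$p_adj < alpha
  attr(out, "alpha") <- alpha
  attr(out, "n_mutant") <- sum(mutant)
  attr(out, "n_wildtype") <- sum(!mutant)
  class(out) <- c("regulator_scan", "data.frame")
  out
}

#' Row median/MAD normalization for heatmap display
#'
#' Each cell becomes `(value - row median) / row MAD`, where MAD is the raw
#' median absolute deviation `median(|x - median(x)|)` (no consistency
#' scaling). Rows with MAD 0 yield missing values with a warning.
#'
#' @param expr Numeric matrix (genes x samples).
#' @return Matrix of the same shape.
#' @export
normalize_rows_for_heatmap <- function(expr) {
  out <- t(apply(expr, 1, function(v) {
    med <- median(v)
    m <- median(abs(v - med))
    if (m == 0) rep(NA_real_, length(v)) else (v - med) / m
  }))
  dimnames(out) <- dimnames(expr)
  if (anyNA(out)) {
    warning("row(s) with zero median absolute deviation set to NA: ",
            paste(rownames(expr)[apply(is.na(out), 1, all)], collapse = ", "))
  }
  out
}

#' Mann-Whitney U test
#'
#' U is computed from rank sums with midrank ties. The null distribution is
#' enumerated exactly for small tie-free samples (`nx + ny <= 16`);
#' otherwise the normal approximation with tie and continuity corrections
#' is used. The one-tailed alternative is "x stochastically greater".
#'
#' @param x,y Numeric samples (each non-empty).
#' @param tail `"two"` (default) or `"one"`.
#' @return List with `label_a`, `label_b`, `n_a`, `n_b`, `U_stat`, `p`,
#'   `tail`.
#' @export
mann_whitney <- function(x, y, tail = c("two", "one")) {
  tail <- match.arg(tail)
  stopifnot(length(x) >= 1, length(y) >= 1)
  if (length(unique(c(x, y))) == 1) { # fully tied: no evidence either way
    return(list(label_a = "x", label_b = "y", n_a = length(x),
                n_b = length(y), U_stat = length(x) * length(y) / 2,
                p = 1, tail = tail))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 16) && !ties
  ht <- suppressWarnings(wilcox.test(
    x, y, alternative = if (tail == "two") "two.sided" else "greater",
    exact = exact, correct = TRUE
  ))
  list(label_a = deparse(substitute(x)), label_b = deparse(substitute(y)),
       n_a = length(x), n_b = length(y),
       U_stat = unname(ht$statistic), p = min(1, ht$p.value), tail = tail)
}

#' Split samples into highest and lowest quartile groups
#'
#' Nearest-rank quartiles: with `n` samples sorted ascending, the low group
#' is every sample with value at or below the `ceiling(n/4)`-th sorted
#' value, and the high group every sample with value at or above the
#' `(floor(3n/4) + 1)`-th. For distinct values this yields the usual
#' floor(n/4)-sized tails (e.g. 46 and 46 from a cohort of 182 or 184);
#' ties are included on both sides, and a fully constant vector puts every
#' sample in both groups with a warning.
#'
#' @param values Named numeric vector (names = sample ids), `n >= 4`.
#' @return List with `high` and `low` (character vectors of sample ids) and
#'   the two cut values.
#' @export
quartile_groups <- function(values) {
  n <- length(values)
  stopifnot(n >= 4)
  if (is.null(names(values))) names(values) <- as.character(seq_len(n))
  s <- sort(values)
  low_cut <- s[ceiling(n / 4)]
  high_cut <- s[floor(3 * n / 4) + 1]
  low <- names(values)[values <= low_cut]
  high <- names(values)[values >= high_cut]
  if (length(unique(values)) == 1) {
    warning("all values equal: both quartile groups contain every sample")
  }
  list(high = high, low = low, high_cut = unname(high_cut),
       low_cut = unname(low_cut))
}

#' Pearson correlation with one- or two-tailed p-value
#'
#' r by the product-moment formula; p from
#' `t = r * sqrt((n - 2) / (1 - r^2))` against a t distribution with
#' `n - 2` degrees of freedom. The one-tailed alternative tests a positive
#' association.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, neither constant.
#' @param tail `"two"` (default) or `"one"`.
#' @return List with `n`, `r`, `p`, `tail`.
#' @export
pearson_correlation <- function(x, y, tail = c("two", "one")) {
  tail <- match.arg(tail)
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) stop("constant vector: correlation undefined")
  ht <- cor.test(x, y, method = "pearson",
                 alternative = if (tail == "two") "two.sided" else "greater")
  list(n = length(x), r = unname(ht$estimate), p = min(1, ht$p.value),
       tail = tail)
}

#' Run the RPPA association analyses for one regulator gene
#'
#' Reproduces the three phosphoprotein comparisons around one regulator:
#' each marker compared between mutant and wild-type samples (one-tailed
#' Mann-Whitney for the coupled marker where the directional prediction
#' holds, two-tailed otherwise), between highest- and lowest-quartile
#' expressors of the gene, and the Pearson correlation (one-tailed,
#' positive) of the coupled marker with log2 expression of the gene.
#'
#' @param expr Genes x samples expression matrix.
#' @param rppa Markers x samples RPPA matrix (samples may be a subset of the
#'   expression samples).
#' @param annot Sample annotation data frame.
#' @param gene Regulator gene (default `"DUSP6"`).
#' @param coupled_marker Marker with the directional prediction (default
#'   `"MAPKPT202Y204"`, phospho-ERK).
#' @param group_by Mutation predicate, as in [scan_regulators()].
#' @return List with `mutation_comparisons`, `quartile_comparisons` (data
#'   frames, one row per marker) and `correlation`.
#' @export
rppa_associations <- function(expr, rppa, annot, gene = "DUSP6",
                              coupled_marker = "MAPKPT202Y204",
                              group_by = "EGFR|KRAS") {
  shared <- intersect(colnames(expr), colnames(rppa))
  if (length(shared) < 4) stop("too few shared samples between tables")
  rppa <- rppa[, shared, drop = FALSE]
  annot <- annot[match(shared, annot$sample_id), , drop = FALSE]
  flags <- strsplit(group_by, "|", fixed = TRUE)[[1]]
  mutant <- Reduce(`|`, lapply(flags, function(f) annot[[f]]))

  one_row <- function(marker, a, b, tail) {
    mw <- mann_whitney(rppa[marker, a], rppa[marker, b], tail = tail)
    data.frame(marker = marker, n_a = mw$n_a, n_b = mw$n_b,
               U_stat = mw$U_stat, p = mw$p, tail = tail,
               stringsAsFactors = FALSE)
  }
  tails <- ifelse(rownames(rppa) == coupled_marker, "one", "two")
  mut_cmp <- do.call(rbind, Map(one_row, rownames(rppa),
                                MoreArgs = list(a = which(mutant),
                                                b = which(!mutant)),
                                tail = tails))
  qg <- quartile_groups(setNames(expr[gene, shared], shared))
  quart_cmp <- do.call(rbind, Map(one_row, rownames(rppa),
                                  MoreArgs = list(a = qg$high, b = qg$low),
                                  tail = tails))
  corr <- pearson_correlation(log2(expr[gene, shared]),
                              rppa[coupled_marker, ], tail = "one")
  list(mutation_comparisons = mut_cmp, quartile_comparisons = quart_cmp,
       correlation = corr, quartiles = qg)
}
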