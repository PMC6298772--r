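# Independent oracles used by the test suite. These transcribe the target
# formulas directly and share no code with the package implementation.

# direct transcription of the screen-scoring formulas:
# rpm -> raw-count filter -> pseudocount log2 ratio -> second-most extreme
# guide per gene -> ranks with lexicographic tie-break
oracle_screen <- function(raw, reference, sample, gene_of, threshold = 30,
                          pseudocount = 1, scope = "both",
                          control_genes = "CONTROL") {
  rpm <- raw
  for (j in seq_len(ncol(raw))) rpm[, j] <- raw[, j] / sum(raw[, j]) * 1e6
  keep <- raw[, sample] >= threshold
  if (scope == "both") keep <- keep & raw[, reference] >= threshold
  lfc <- log2((rpm[, sample] + pseudocount) / (rpm[, reference] + pseudocount))
  genes <- sort(unique(gene_of))
  sb_enr <- sb_dep <- stats::setNames(rep(NA_real_, length(genes)), genes)
  for (g in genes) {
    v <- lfc[gene_of == g & keep]
    if (length(v) >= 2) {
      s <- sort(v)
      sb_enr[g] <- s[length(s) - 1]
      sb_dep[g] <- s[2]
    }
  }
  rankable <- !is.na(sb_enr) & !(genes %in% control_genes)
  enr_rank <- dep_rank <- stats::setNames(rep(NA_integer_, length(genes)),
                                          genes)
  oe <- which(rankable)[order(-sb_enr[rankable], genes[rankable])]
  enr_rank[oe] <- seq_along(oe)
  od <- which(rankable)[order(sb_dep[rankable], genes[rankable])]
  dep_rank[od] <- seq_along(od)
  list(lfc = ifelse(keep, lfc, NA_real_), keep = keep,
       second_best_enriched = sb_enr, second_best_depleted = sb_dep,
       enrichment_rank = enr_rank, depletion_rank = dep_rank)
}

# a random small screen instance (guides x 3 samples) for oracle comparisons
random_screen_instance <- function(seed) {
  set.seed(seed)
  n_genes <- sample(3:12, 1)
  gpg <- sample(2:5, 1)
  n <- min(n_genes * gpg, 50)
  gene_of <- rep(sprintf("G%02d", seq_len(n_genes)), each = gpg)[seq_len(n)]
  guide_ids <- sprintf("sg%03d", seq_len(n))
  raw <- matrix(rpois(n * 3, lambda = sample(c(15, 60, 200), 1)), n, 3,
                dimnames = list(guide_ids,
                                c("plasmid", "untreated_final",
                                  "treated_final")))
  list(raw = raw, gene_of = gene_of, guide_ids = guide_ids)
}

# exact permutation p-value of the Welch t statistic over all group
# relabelings (two-tailed)
welch_permutation_p <- function(x, y) {
  welch_t <- function(a, b) {
    (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
  }
  pooled <- c(x, y)
  nx <- length(x)
  t_obs <- abs(welch_t(x, y))
  splits <- utils::combn(length(pooled), nx)
  t_perm <- apply(splits, 2, function(idx) {
    abs(welch_t(pooled[idx], pooled[-idx]))
  })
  mean(t_perm >= t_obs - 1e-12)
}

# exact two- or one-tailed Mann-Whitney p from the exact null distribution
# of U (tie-free data), independent of the normal approximation under test
mw_exact_p <- function(x, y, tail = "two") {
  u <- sum(vapply(x, function(xi) sum(xi > y), numeric(1)))
  nx <- length(x); ny <- length(y)
  p_ge <- 1 - stats::pwilcox(u - 1, nx, ny)
  p_le <- stats::pwilcox(u, nx, ny)
  if (tail == "one") p_ge else min(1, 2 * min(p_ge, p_le))
}
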