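make_counts <- function(m) {
  rownames(m) <- sprintf("sg%03d", seq_len(nrow(m)))
  screen_counts(m, colnames(m)[1])
}

test_that("low-count filter applies the threshold to the compared pair", {
  m <- cbind(plasmid = c(100, 29, 30, 100), final = c(29, 100, 30, 100))
  sc <- make_counts(m)
  expect_equal(suppressMessages(filter_low_counts(sc, "final")),
               c("sg003", "sg004"))
  # sample-only scope ignores the reference column
  expect_equal(suppressMessages(
    filter_low_counts(sc, "final", scope = "sample")),
    c("sg002", "sg003", "sg004"))
  # threshold 0 retains everything
  expect_equal(length(suppressMessages(filter_low_counts(sc, "final", 0))), 4)
  empty <- make_counts(m)
  empty$counts <- empty$counts[0, , drop = FALSE]
  expect_error(filter_low_counts(empty, "final"), "empty")
})

test_that("depth normalization gives reads-per-million columns", {
  m <- cbind(plasmid = c(10, 30, 60), final = c(5, 0, 0))
  rpm <- normalize_to_depth(make_counts(m))
  expect_equal(rpm[, "plasmid"], c(sg001 = 1e5, sg002 = 3e5, sg003 = 6e5))
  expect_equal(unname(rpm[, "final"]), c(1e6, 0, 0))
  expect_error(normalize_to_depth(make_counts(cbind(a = c(1, 1),
                                                    b = c(0, 0)))), "b")
})

test_that("guide LFC follows the pseudocount formula and is antisymmetric", {
  expect_equal(guide_lfc(5, 5), 0)
  expect_equal(guide_lfc(7, 0, pseudocount = 1), 3)
  x <- runif(20, 0, 100); y <- runif(20, 0, 100)
  expect_equal(guide_lfc(x, y), -guide_lfc(y, x))
  expect_error(guide_lfc(-1, 5), "non-negative")
})

test_that("gene ranking takes the second-most extreme guide, with oracle agreement", {
  lfc_tab <- data.frame(
    guide_id = sprintf("g%d", 1:8),
    gene = rep(c("A", "B"), each = 4),
    lfc = c(5, 3, 1, 0, 2, 2, -4, -1),
    passed_filter = TRUE
  )
  lib <- guide_library(lfc_tab$guide_id, lfc_tab$gene)
  rk <- rank_genes(lfc_tab, lib)
  expect_equal(rk$second_best_enriched[rk$gene == "A"], 3)
  expect_equal(rk$second_best_depleted[rk$gene == "A"], 1)
  expect_equal(rk$second_best_enriched[rk$gene == "B"], 2) # tie kept as-is
  expect_equal(rk$enrichment_rank, c(1, 2))
  expect_equal(rk$depletion_rank, c(2, 1))

  # genes with < 2 passed guides are excluded, not scored
  lfc_tab$passed_filter <- c(TRUE, FALSE, FALSE, FALSE, rep(TRUE, 4))
  rk2 <- rank_genes(lfc_tab, lib)
  expect_true(rk2$excluded[rk2$gene == "A"])
  expect_equal(rk2$exclusion_reason[rk2$gene == "A"], "lt2_guides")
  expect_equal(rk2$enrichment_rank[rk2$gene == "B"], 1)

  # 200 random genes x 4 guides against the brute-force sort oracle
  set.seed(42)
  genes <- sprintf("G%03d", 1:200)
  tab <- data.frame(guide_id = sprintf("g%d", 1:800),
                    gene = rep(genes, each = 4),
                    lfc = rnorm(800), passed_filter = TRUE)
  rk3 <- rank_genes(tab, guide_library(tab$guide_id, tab$gene))
  sb <- t(vapply(split(tab$lfc, tab$gene),
                 function(v) sort(v)[c(3, 2)], numeric(2)))
  expect_equal(rk3$second_best_enriched, unname(sb[rk3$gene, 1]))
  expect_equal(rk3$second_best_depleted, unname(sb[rk3$gene, 2]))
  expect_equal(rk3$gene[order(rk3$enrichment_rank)],
               names(sort(-sb[, 1])))
})

test_that("control pseudo-genes are reported but never ranked", {
  sim <- simulate_screen(screen_sim_spec(n_genes = 20, n_control_guides = 8,
                                         seed = 2))
  res <- suppressMessages(run_screen(sim$counts, sim$library,
                                     sample = "treated_final", threshold = 0))
  ctrl <- res$genes[res$genes$gene == "CONTROL", ]
  expect_true(ctrl$excluded)
  expect_equal(ctrl$exclusion_reason, "control")
  expect_true(is.na(ctrl$enrichment_rank))
  ranked <- res$genes[!res$genes$excluded, ]
  expect_setequal(ranked$enrichment_rank, seq_len(nrow(ranked)))
  expect_setequal(ranked$depletion_rank, seq_len(nrow(ranked)))
})

test_that("comparing the reference to itself gives all-zero LFCs", {
  sim <- simulate_screen(screen_sim_spec(n_genes = 15, seed = 4))
  res <- suppressMessages(run_screen(sim$counts, sim$library,
                                     sample = "plasmid", threshold = 0))
  expect_true(all(res$guides$lfc == 0))
  expect_true(all(res$genes$second_best_enriched[!res$genes$excluded] == 0))
})

test_that("a strongly planted gene is recovered at enrichment rank 1", {
  spec <- screen_sim_spec(n_genes = 1000, guides_per_gene = 4,
                          mean_depth = 500, nb_dispersion = 0.2,
                          planted_effects = c(GENE00042 = 2), seed = 7)
  sim <- simulate_screen(spec)
  res <- suppressMessages(run_screen(sim$counts, sim$library,
                                     sample = "treated_final"))
  expect_equal(res$genes$gene[which(res$genes$enrichment_rank == 1)],
               "GENE00042")
})

test_that("null second-best statistics are calibrated against a label-permutation null", {
  sim <- simulate_screen(screen_sim_spec(n_genes = 500, n_control_guides = 0,
                                         seed = 31))
  res <- suppressMessages(run_screen(sim$counts, sim$library,
                                     sample = "treated_final"))
  obs <- res$genes$second_best_enriched[!res$genes$excluded]
  guides <- res$guides[res$guides$passed_filter, ]
  set.seed(99)
  null_sb <- replicate(50, {
    g <- sample(guides$gene)
    vapply(split(guides$lfc, g),
           function(v) if (length(v) < 2) NA_real_ else
             sort(v, decreasing = TRUE)[2], numeric(1))
  })
  q999 <- quantile(abs(null_sb), 0.999, na.rm = TRUE)
  # under the null the observed genes are themselves draws from this
  # distribution: allow the expected handful of exceedances, no more
  expect_lte(sum(abs(obs) > q999), 5)
})
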