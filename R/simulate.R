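# Synthetic-data generators. Each generator is a pure function of its spec:
# identical spec (including seed) gives identical output. Each table draws
# from its own named RNG stream derived from the master seed (see subseed()),
# so adding a table never perturbs the others.

#' Specification for a synthetic CRISPR knockout screen
#'
#' Defaults emulate a pooled genome-scale knockout screen scored against its
#' plasmid library: four guides per gene, an average 500-fold read coverage
#' per guide, and overdispersed counts (variance `m + dispersion * m^2`).
#'
#' @param n_genes Number of targeted genes (>= 1).
#' @param guides_per_gene Guides per gene (>= 2; gene ranking uses the
#'   second-most extreme guide).
#' @param n_control_guides Non-targeting control guides, pooled under the
#'   reserved gene label `"CONTROL"`.
#' @param mean_depth Mean reads per guide.
#' @param nb_dispersion Negative-binomial dispersion `phi` (> 0 gives
#'   variance `m + phi m^2`; 0 degenerates to Poisson).
#' @param planted_effects Named numeric vector: gene -> log2 effect on the
#'   treated final population (positive = enriched, negative = depleted).
#' @param seed Integer master seed.
#' @return A `screen_sim_spec` list.
#' @export
screen_sim_spec <- function(n_genes = 1000, guides_per_gene = 4,
                            n_control_guides = 100, mean_depth = 500,
                            nb_dispersion = 0.2, planted_effects = numeric(0),
                            seed = 1) {
  stopifnot(n_genes >= 1, mean_depth > 0, nb_dispersion >= 0,
            n_control_guides >= 0)
  if (guides_per_gene < 2) {
    stop("guides_per_gene must be >= 2: ranking needs a second guide")
  }
  if (length(planted_effects) && is.null(names(planted_effects))) {
    stop("planted_effects must be a named vector (gene -> log2 effect)")
  }
  structure(list(n_genes = n_genes, guides_per_gene = guides_per_gene,
                 n_control_guides = n_control_guides, mean_depth = mean_depth,
                 nb_dispersion = nb_dispersion,
                 planted_effects = planted_effects, seed = seed),
            class = "screen_sim_spec")
}

#' Simulate a pooled CRISPR knockout screen
#'
#' Generates a guide library and a count matrix with three samples:
#' `"plasmid"` (the reference pool), `"untreated_final"` and
#' `"treated_final"`. Library skew is lognormal(0, 1) renormalized to
#' proportions. Overdispersion is modelled hierarchically: each guide gets a
#' Gamma(1/phi, scale = phi) representation factor shared by all samples of
#' the screen (the common pool every sample derives from), and each sample's
#' counts are Poisson around depth x relative abundance x factor. Marginal
#' counts are therefore exactly negative binomial with mean `m` and variance
#' `m + phi m^2`, while the shared factor cancels from sample-vs-reference
#' fold-changes. Planted effects multiply treated-final abundances by
#' `2^effect` for every guide of the gene, with a per-guide Normal(0, 0.25)
#' log2 jitter so the second-best statistic is exercised on non-identical
#' guides.
#'
#' @param spec A [screen_sim_spec()].
#' @return List with `library` (a [guide_library()]), `counts` (a
#'   [screen_counts()] with reference `"plasmid"`) and `truth` (the planted
#'   effects, verbatim).
#' @export
simulate_screen <- function(spec) {
  stopifnot(inherits(spec, "screen_sim_spec"))
  genes <- sprintf("GENE%05d", seq_len(spec$n_genes))
  unknown <- setdiff(names(spec$planted_effects), genes)
  if (length(unknown)) {
    stop("planted_effects name genes outside the library: ",
         paste(unknown, collapse = ", "))
  }
  gene_of <- c(rep(genes, each = spec$guides_per_gene),
               rep(CONTROL_GENE, spec$n_control_guides))
  n_guides <- length(gene_of)
  guide_ids <- sprintf("sg_%s_%d", gene_of,
                       unlist(lapply(table(factor(gene_of,
                                                  levels = unique(gene_of))),
                                     seq_len), use.names = FALSE))
  lib <- guide_library(guide_ids, gene_of)

  prop <- with_stream(spec$seed, "screen/library_profile", {
    l <- rlnorm(n_guides, 0, 1)
    l / sum(l)
  })
  # guide representation factor common to all samples drawn from the pool
  rep_factor <- with_stream(spec$seed, "screen/representation", {
    if (spec$nb_dispersion > 0) {
      rgamma(n_guides, shape = 1 / spec$nb_dispersion,
             scale = spec$nb_dispersion)
    } else {
      rep(1, n_guides)
    }
  })
  total_depth <- spec$mean_depth * n_guides
  base_mu <- total_depth * prop * rep_factor

  effect <- rep(0, n_guides)
  if (length(spec$planted_effects)) {
    jitter <- with_stream(spec$seed, "screen/effect_jitter",
                          rnorm(n_guides, 0, 0.25))
    for (g in names(spec$planted_effects)) {
      idx <- which(gene_of == g)
      effect[idx] <- spec$planted_effects[[g]] + jitter[idx]
    }
  }

  draw <- function(name, mu) with_stream(spec$seed, name, rpois(n_guides, mu))
  counts <- cbind(
    plasmid = draw("screen/sample/plasmid", base_mu),
    untreated_final = draw("screen/sample/untreated_final", base_mu),
    treated_final = draw("screen/sample/treated_final", base_mu * 2^effect)
  )
  rownames(counts) <- guide_ids
  list(library = lib,
       counts = screen_counts(counts, "plasmid"),
       truth = spec$planted_effects)
}

#' Specification for a synthetic tumor expression cohort
#'
#' Defaults emulate a lung adenocarcinoma cohort split by RTK-RAS pathway
#' mutation status (107 mutant vs 123 wild-type tumors), with the 13-gene
#' negative-feedback regulator panel, a two-fold up-regulation of DUSP6 in
#' mutant samples, lognormal expression noise of 0.5 log2 units, and a
#' phospho-ERK RPPA marker linearly coupled to log2 DUSP6 expression.
#'
#' @param panel_genes Panel gene symbols.
#' @param n_mutant,n_wildtype Cohort sizes (each >= 2).
#' @param effect_gene Panel gene carrying the mutation-linked effect.
#' @param log2_effect Planted log2 up-regulation in mutant samples.
#' @param lognormal_sigma Per-gene expression SD in log2 units.
#' @param rppa_slope,rppa_noise_sd Linear coupling of the phospho-ERK marker
#'   to log2 `effect_gene` expression, and its Gaussian noise SD.
#' @param seed Integer master seed.
#' @return An `expression_sim_spec` list.
#' @export
expression_sim_spec <- function(panel_genes = default_regulator_panel(),
                                n_mutant = 107, n_wildtype = 123,
                                effect_gene = "DUSP6", log2_effect = 1,
                                lognormal_sigma = 0.5, rppa_slope = 1,
                                rppa_noise_sd = 0.5, seed = 1) {
  stopifnot(n_mutant >= 2, n_wildtype >= 2, lognormal_sigma > 0,
            rppa_noise_sd >= 0)
  if (!effect_gene %in% panel_genes) {
    stop("effect_gene must be a member of panel_genes")
  }
  structure(list(panel_genes = panel_genes, n_mutant = n_mutant,
                 n_wildtype = n_wildtype, effect_gene = effect_gene,
                 log2_effect = log2_effect, lognormal_sigma = lognormal_sigma,
                 rppa_slope = rppa_slope, rppa_noise_sd = rppa_noise_sd,
                 seed = seed),
            class = "expression_sim_spec")
}

#' Simulate an expression cohort with mutation annotations and RPPA values
#'
#' Baseline expression is lognormal per gene (gene-level log2 means drawn
#' once from Uniform(6, 12), RSEM-like); `effect_gene` is multiplied by
#' `2^log2_effect` in mutant samples only. The phospho-ERK marker
#' (`MAPKPT202Y204`) equals `slope * log2(expression of effect_gene)` plus
#' Gaussian noise; two uncoupled stress-kinase markers (`P38PT180Y18`,
#' `JNKPT183Y185`) are standard-normal noise.
#'
#' @param spec An [expression_sim_spec()].
#' @return List with `expression` (genes x samples matrix), `annotation`
#'   (data frame with `sample_id`, `EGFR`, `KRAS`, `tissue`), `rppa`
#'   (markers x samples matrix) and `truth`.
#' @export
simulate_expression_cohort <- function(spec) {
  stopifnot(inherits(spec, "expression_sim_spec"))
  n <- spec$n_mutant + spec$n_wildtype
  samples <- sprintf("S%04d", seq_len(n))
  mutant <- c(rep(TRUE, spec$n_mutant), rep(FALSE, spec$n_wildtype))
  p <- length(spec$panel_genes)

  base_mu <- with_stream(spec$seed, "cohort/gene_baselines",
                         stats::runif(p, 6, 12))
  expr <- with_stream(spec$seed, "cohort/expression", {
    log2e <- matrix(rnorm(p * n, 0, spec$lognormal_sigma), p, n) + base_mu
    2^log2e
  })
  dimnames(expr) <- list(spec$panel_genes, samples)
  expr[spec$effect_gene, mutant] <-
    expr[spec$effect_gene, mutant] * 2^spec$log2_effect

  # split mutant samples between the two driver oncogenes (alternating)
  which_egfr <- rep(c(TRUE, FALSE), length.out = spec$n_mutant)
  annot <- data.frame(
    sample_id = samples,
    EGFR = mutant & c(which_egfr, rep(FALSE, spec$n_wildtype)),
    KRAS = mutant & c(!which_egfr, rep(FALSE, spec$n_wildtype)),
    tissue = "tumor",
    stringsAsFactors = FALSE
  )

  rppa <- with_stream(spec$seed, "cohort/rppa", {
    perk <- spec$rppa_slope * log2(expr[spec$effect_gene, ]) +
      rnorm(n, 0, spec$rppa_noise_sd)
    rbind(MAPKPT202Y204 = perk,
          P38PT180Y18 = rnorm(n),
          JNKPT183Y185 = rnorm(n))
  })
  colnames(rppa) <- samples

  list(expression = expr, annotation = annot, rppa = rppa,
       truth = list(effect_gene = spec$effect_gene,
                    log2_effect = spec$log2_effect,
                    rppa_slope = spec$rppa_slope,
                    mutant_samples = samples[mutant]))
}

#' Specification for a synthetic dose-response experiment
#'
#' Defaults emulate a 72-hour small-molecule viability series: a 17-point
#' dose range from 0 to 8 uM in 0.5 uM steps, quadruplicate wells, 5%
#' coefficient-of-variation measurement noise, and three cell lines planted
#' at IC50s of 2 uM (steep, near-complete kill), 4.5 uM and 6 uM.
#'
#' @param cell_lines Data frame with columns `name`, `true_ic50` (uM),
#'   `hill` and `floor` (residual viability fraction).
#' @param doses Dose series in uM, ascending, starting at 0 (vehicle).
#' @param replicates Wells per dose (>= 1).
#' @param noise_cv Multiplicative Gaussian noise CV (>= 0).
#' @param baseline Vehicle-well fluorescence, arbitrary units.
#' @param seed Integer master seed.
#' @return A `dose_sim_spec` list.
#' @export
dose_sim_spec <- function(cell_lines = data.frame(
                            name = c("sensitive_line", "intermediate_line",
                                     "insensitive_line"),
                            true_ic50 = c(2, 4.5, 6),
                            hill = c(6, 4, 2.5),
                            floor = c(0.02, 0.05, 0.30)),
                          doses = seq(0, 8, by = 0.5), replicates = 4,
                          noise_cv = 0.05, baseline = 1e4, seed = 1) {
  stopifnot(replicates >= 1, noise_cv >= 0, baseline > 0,
            all(c("name", "true_ic50", "hill", "floor") %in%
                  names(cell_lines)))
  if (is.unsorted(doses, strictly = TRUE) || doses[1] != 0) {
    stop("doses must be strictly ascending and start at 0 (vehicle)")
  }
  stopifnot(all(cell_lines$true_ic50 > 0), all(cell_lines$hill > 0),
            all(cell_lines$floor >= 0 & cell_lines$floor <= 1))
  structure(list(cell_lines = cell_lines, doses = doses,
                 replicates = replicates, noise_cv = noise_cv,
                 baseline = baseline, seed = seed),
            class = "dose_sim_spec")
}

# noiseless Hill-curve viability fraction; v(0) = 1 exactly
hill_viability <- function(d, ic50, hill, floor) {
  ifelse(d == 0, 1, floor + (1 - floor) / (1 + (d / ic50)^hill))
}

#' Simulate plate-reader viability readings for a dose series
#'
#' Viability follows `v(d) = floor + (1 - floor) / (1 + (d/ic50)^hill)` with
#' `v(0) = 1` exactly; the recorded signal is
#' `v(d) * baseline * (1 + Normal(0, noise_cv))`.
#'
#' @param spec A [dose_sim_spec()].
#' @return A plate-readings data frame (columns `cell_line`, `condition`,
#'   `dose`, `replicate`, `signal`, `timepoint`).
#' @export
simulate_dose_response <- function(spec) {
  stopifnot(inherits(spec, "dose_sim_spec"))
  out <- list()
  for (i in seq_len(nrow(spec$cell_lines))) {
    cl <- spec$cell_lines[i, ]
    grid <- expand.grid(replicate = seq_len(spec$replicates),
                        dose = spec$doses)
    v <- hill_viability(grid$dose, cl$true_ic50, cl$hill, cl$floor)
    noise <- with_stream(spec$seed, paste0("dose/", cl$name),
                         rnorm(nrow(grid), 0, spec$noise_cv))
    out[[i]] <- data.frame(
      cell_line = cl$name, condition = "drug", dose = grid$dose,
      replicate = grid$replicate,
      signal = v * spec$baseline * (1 + noise),
      timepoint = 3, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}
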