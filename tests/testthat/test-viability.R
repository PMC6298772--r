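test_that("relative viability normalizes to the control-condition mean", {
  readings <- data.frame(
    cell_line = "A",
    condition = rep(c("ctrl", "drug"), c(2, 3)),
    dose = c(0, 0, 1, 1, 1),
    replicate = c(1, 2, 1, 2, 3),
    signal = c(190, 210, 90, 100, 110),
    timepoint = NA_real_
  )
  rv <- relative_viability(readings, control = "ctrl")
  drug <- rv[rv$condition == "drug", ]
  expect_equal(drug$mean_rel, 0.5)
  expect_equal(drug$sem, 10 / sqrt(3) / 200, tolerance = 1e-9)
  ctrl <- rv[rv$condition == "ctrl", ]
  expect_equal(ctrl$mean_rel, 1)
  expect_error(relative_viability(readings, control = "none"), "absent")
})

test_that("day-1 anchored scaling divides every timepoint by one control mean", {
  readings <- expand.grid(replicate = 1:2, timepoint = c(1, 3, 5),
                          condition = c("NonT", "siDUSP6"))
  readings$cell_line <- "PC9"
  readings$dose <- 0
  readings$signal <- ifelse(readings$condition == "NonT",
                            100 * readings$timepoint, 60 * readings$timepoint)
  rv <- relative_viability(readings, control = "NonT", control_timepoint = 1)
  expect_equal(rv$mean_rel[rv$condition == "NonT" & rv$timepoint == 1], 1)
  expect_equal(rv$mean_rel[rv$condition == "NonT" & rv$timepoint == 5], 5)
  expect_equal(rv$mean_rel[rv$condition == "siDUSP6" & rv$timepoint == 3], 1.8)
})

test_that("4PL fit recovers exact model data and flags flat curves", {
  d <- seq(0, 8, 0.5)
  v <- 0.1 + 0.9 / (1 + (d / 2)^4)
  v[d == 0] <- 1
  fit <- fit_4pl(d, v)
  expect_false(fit$flagged)
  expect_lt(abs(fit$ic50 - 2) / 2, 0.01)
  expect_lt(abs(fit$hill - 4), 0.2)
  expect_equal(fit$viability_at_ref_dose,
               0.1 + 0.9 / (1 + (3.2 / fit$ic50)^fit$hill), tolerance = 1e-6)
  # duplicate dose rows and replicate order do not change the fit
  idx <- sample(rep(seq_along(d), 2))
  fit2 <- fit_4pl(d[idx], v[idx])
  expect_equal(fit2$ic50, fit$ic50, tolerance = 1e-6)

  flat <- fit_4pl(d, rep(1, length(d)))
  expect_true(flat$flagged)
  expect_true(is.na(flat$ic50))
  expect_error(fit_4pl(c(1, 2, 3), c(1, 0.5, 0.2)), "5 distinct")
})

test_that("sensitivity classes implement the three-tier taxonomy", {
  mk <- function(ic50, v32, flagged = FALSE, vmax = 0.1) {
    structure(list(ic50 = ic50, viability_at_ref_dose = v32,
                   flagged = flagged, v_max_dose = vmax),
              class = "dose_response_fit")
  }
  expect_equal(classify_sensitivity(mk(2, 0.05)), "sensitive")
  expect_equal(classify_sensitivity(mk(2, 0.2)), "intermediate")
  expect_equal(classify_sensitivity(mk(4.5, 0.3)), "intermediate")
  expect_equal(classify_sensitivity(mk(6, 0.6)), "insensitive")
  expect_equal(classify_sensitivity(mk(NA, NA, flagged = TRUE, vmax = 0.9)),
               "insensitive")
  expect_equal(classify_sensitivity(mk(NA, NA, flagged = TRUE, vmax = 0.3)),
               "intermediate")
  # boundary: IC50 exactly 3 with deep kill is still sensitive; 5 is insensitive
  expect_equal(classify_sensitivity(mk(3, 0.05)), "sensitive")
  expect_equal(classify_sensitivity(mk(5, 0.4)), "insensitive")
})

test_that("rescue normalization divides by the zero-primary-dose row", {
  grid <- expand.grid(primary_dose = c(0, 1, 2), rescue_dose = c(0, 0.5, 1))
  grid$signal <- 100
  out <- rescue_normalize(grid)
  expect_true(all(out == 1))
  grid$signal <- ifelse(grid$primary_dose > 0, 50, 100)
  out2 <- rescue_normalize(grid)
  expect_true(all(out2["0", ] == 1))
  expect_true(all(out2[c("1", "2"), ] == 0.5))
  # random grid equals element-wise division by its own first row
  set.seed(5)
  grid$signal <- runif(nrow(grid), 50, 150)
  out3 <- rescue_normalize(grid)
  m <- matrix(grid$signal, 3, 3)
  expect_equal(unname(out3), sweep(m, 2, m[1, ], "/"))
  expect_error(rescue_normalize(grid[grid$primary_dose > 0 |
                                       grid$rescue_dose != 0.5, ]), "0.5")
})

test_that("delta-delta-Ct fold changes follow the closed form", {
  ct <- data.frame(
    gene = rep(c("DUSP6", "GAPDH"), each = 4),
    condition = rep(rep(c("dox", "vehicle"), each = 2), 2),
    replicate = rep(1:2, 4),
    ct = c(21, 21, 22, 22, 18, 18, 18, 18)
  )
  res <- delta_delta_ct(ct, "DUSP6", "GAPDH", "dox", "vehicle")
  expect_equal(res$fold_change, 2) # target 1 cycle earlier in dox
  # calibrator against itself is exactly 1
  self <- delta_delta_ct(ct, "DUSP6", "GAPDH", "vehicle", "vehicle")
  expect_equal(self$fold_change, 1)
  # ddCt of -3.32 is about a 10-fold induction
  ct2 <- ct
  ct2$ct[ct2$gene == "DUSP6" & ct2$condition == "dox"] <- 22 - 3.32
  res2 <- delta_delta_ct(ct2, "DUSP6", "GAPDH", "dox", "vehicle")
  expect_equal(res2$fold_change, 2^3.32, tolerance = 1e-12)
  expect_equal(res2$fold_change, 10, tolerance = 0.01)
  # multiplicative under composition of two shifts
  ct3 <- ct
  ct3$condition[ct3$condition == "dox"] <- "mid"
  ct3 <- rbind(ct3, within(ct, {
    condition[condition == "dox"] <- "high"
    ct[gene == "DUSP6" & condition == "high"] <- 19
  }))
  f_mid <- delta_delta_ct(ct3, "DUSP6", "GAPDH", "mid", "vehicle")$fold_change
  f_high <- delta_delta_ct(ct3, "DUSP6", "GAPDH", "high", "mid")$fold_change
  f_tot <- delta_delta_ct(ct3, "DUSP6", "GAPDH", "high", "vehicle")$fold_change
  expect_equal(f_mid * f_high, f_tot)
  expect_error(delta_delta_ct(ct, "DUSP6", "GAPDH", "missing", "vehicle"),
               "missing")
})

test_that("densitometry ratios cancel loading and scale", {
  expect_equal(densitometry_ratio(3, 2, loading = 5, control_ratio = 1.5), 1)
  expect_equal(densitometry_ratio(3, 2, control_ratio = 1), 1.5)
  expect_equal(densitometry_ratio(30, 20, loading = 50, control_ratio = 1),
               densitometry_ratio(3, 2, loading = 5, control_ratio = 1))
  expect_error(densitometry_ratio(0, 2), "positive")
})
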