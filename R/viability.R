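# Viability analysis: relative viability against a control condition,
# four-parameter logistic dose-response fits with IC50-based sensitivity
# classes, drug-rescue normalization, delta-delta-Ct and densitometry ratios.

#' Relative viability against a control condition
#'
#' Per (cell_line, condition, dose, timepoint): the replicate mean signal
#' divided by the control-condition mean of the same cell line (matched by
#' timepoint, or anchored at `control_timepoint` for day-1-style scaling).
#' SEM is the replicate standard error of the numerator divided by the
#' control mean.
#'
#' @param readings Plate-readings data frame (see [read_plate_readings()]).
#' @param control Condition label of the control wells.
#' @param control_timepoint Optional timepoint anchoring the control mean
#'   (e.g. `1` to scale every timepoint to the day-1 control); default
#'   matches controls per timepoint.
#' @return Data frame with `cell_line`, `condition`, `dose`, `timepoint`,
#'   `mean_rel`, `sem`, `n`.
#' @export
relative_viability <- function(readings, control,
                               control_timepoint = NULL) {
  if (!"timepoint" %in% names(readings)) readings$timepoint <- NA_real_
  if (!any(readings$condition == control)) {
    stop("control condition '", control, "' absent from readings")
  }
  tp_key <- function(tp) ifelse(is.na(tp), "none", as.character(tp))
  ctrl <- readings[readings$condition == control, , drop = FALSE]
  ctrl_key <- if (is.null(control_timepoint)) {
    paste(ctrl$cell_line, tp_key(ctrl$timepoint))
  } else {
    ctrl <- ctrl[ctrl$timepoint == control_timepoint, , drop = FALSE]
    ctrl$cell_line
  }
  ctrl_mean <- tapply(ctrl$signal, ctrl_key, mean)
  if (any(ctrl_mean <= 0)) stop("control mean signal must be positive")

  grp <- interaction(readings$cell_line, readings$condition, readings$dose,
                     tp_key(readings$timepoint), drop = TRUE, sep = "\r")
  agg <- do.call(rbind, lapply(split(readings, grp), function(d) {
    key <- if (is.null(control_timepoint)) {
      paste(d$cell_line[1], tp_key(d$timepoint[1]))
    } else d$cell_line[1]
    cm <- ctrl_mean[[key]]
    if (is.null(cm) || is.na(cm)) {
      stop("no control wells for cell line '", d$cell_line[1],
           "' at timepoint ", d$timepoint[1])
    }
    n <- nrow(d)
    data.frame(cell_line = d$cell_line[1], condition = d$condition[1],
               dose = d$dose[1], timepoint = d$timepoint[1],
               mean_rel = mean(d$signal) / cm,
               sem = if (n > 1) sd(d$signal) / sqrt(n) / cm else 0,
               n = n, stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg[order(agg$cell_line, agg$condition, agg$timepoint, agg$dose), ]
}

# 4PL sigmoid on linear dose; d = 0 evaluates to `top`
four_pl <- function(d, bottom, top, ic50, hill) {
  bottom + (top - bottom) / (1 + (d / ic50)^hill)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Unweighted least squares on per-dose replicate means of
#' `v(d) = bottom + (top - bottom) / (1 + (d/ic50)^hill)`, with multiple
#' starts over a grid of midpoints (quantiles of the positive dose range)
#' and Hill slopes
#' (0.5, 1, 2, 4); the lowest-RSS convergent fit wins. The IC50 reported is
#' the curve midpoint parameter; `viability_at_ref_dose` is the fitted curve
#' at `ref_dose`. Data whose viability range is below 0.05 carry no
#' dose-response information and yield a flagged fit with `ic50 = NA`, as
#' does non-convergence from every start.
#'
#' @param doses Dose vector in uM (>= 5 distinct values including 0).
#' @param rel_viability Relative viability fractions, same length.
#' @param ref_dose Reference dose for the fitted-viability readout
#'   (default 3.2 uM).
#' @param cell_line Optional label carried into the result.
#' @return A `dose_response_fit` list: `cell_line`, `bottom`, `top`, `ic50`,
#'   `hill`, `rss`, `viability_at_ref_dose`, `v_max_dose`, `max_dose`,
#'   `flagged`, `extrapolated`.
#' @export
fit_4pl <- function(doses, rel_viability, ref_dose = 3.2,
                    cell_line = NA_character_) {
  stopifnot(length(doses) == length(rel_viability))
  keep <- is.finite(doses) & is.finite(rel_viability)
  doses <- doses[keep]; rel_viability <- rel_viability[keep]
  if (length(unique(doses)) < 5 || !any(doses == 0)) {
    stop("need at least 5 distinct doses including 0")
  }
  # replicate/duplicate-dose aggregation: unweighted per-dose means
  v <- tapply(rel_viability, doses, mean)
  d <- as.numeric(names(v))
  ord <- order(d); d <- d[ord]; v <- as.numeric(v)[ord]
  max_dose <- max(d)
  v_max <- v[which.max(d)]
  res <- list(cell_line = cell_line, bottom = NA_real_, top = NA_real_,
              ic50 = NA_real_, hill = NA_real_, rss = NA_real_,
              viability_at_ref_dose = NA_real_, v_max_dose = v_max,
              max_dose = max_dose, flagged = TRUE, extrapolated = NA)
  class(res) <- "dose_response_fit"
  if (diff(range(v)) < 0.05) return(res) # flat: no dose response to fit

  ic50_grid <- unique(quantile(d[d > 0], c(0.15, 0.4, 0.65, 0.9),
                               names = FALSE))
  starts <- expand.grid(ic50 = ic50_grid, hill = c(0.5, 1, 2, 4))
  best <- NULL
  dat <- data.frame(d = d, v = v)
  for (i in seq_len(nrow(starts))) {
    fit <- try(suppressWarnings(minpack.lm::nlsLM(
      v ~ bottom + (top - bottom) / (1 + (d / ic50)^hill), data = dat,
      start = list(bottom = min(v), top = max(v),
                   ic50 = starts$ic50[i], hill = starts$hill[i]),
      lower = c(bottom = -0.5, top = 0, ic50 = 1e-4, hill = 0.05),
      upper = c(bottom = 1.5, top = 2, ic50 = 1e3, hill = 50),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) return(res)
  p <- as.list(coef(best$fit))
  if (p$bottom > p$top) { # orientation guard; the model is symmetric in them
    tmp <- p$bottom; p$bottom <- p$top; p$top <- tmp
  }
  res$bottom <- p$bottom; res$top <- p$top
  res$ic50 <- p$ic50; res$hill <- p$hill
  res$rss <- best$rss
  res$viability_at_ref_dose <- four_pl(ref_dose, p$bottom, p$top, p$ic50,
                                       p$hill)
  res$flagged <- FALSE
  res$extrapolated <- p$ic50 > max_dose || p$ic50 < min(d[d > 0])
  res
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (x$flagged) {
    cat("dose_response_fit (flagged: no usable fit)\n")
  } else {
    cat(sprintf(
      "dose_response_fit: ic50 = %.3g uM, hill = %.3g, bottom = %.3g, top = %.3g, rss = %.3g\n",
      x$ic50, x$hill, x$bottom, x$top, x$rss))
  }
  invisible(x)
}

#' Classify drug sensitivity from a dose-response fit
#'
#' Three-tier taxonomy: `sensitive` if the IC50 lies in `[1, 3]` uM and the
#' fitted viability at the reference dose (3.2 uM) is below 10%;
#' `insensitive` if the IC50 is at or above 5 uM, or the fit is flagged with
#' more than 50% viability remaining at the top tested dose; `intermediate`
#' otherwise. Cutoffs are overridable.
#'
#' @param fit A [fit_4pl()] result.
#' @param sensitive_ic50 IC50 window (uM) for the sensitive class.
#' @param sensitive_vmax Viability-at-reference-dose cutoff for sensitive.
#' @param insensitive_ic50 IC50 lower bound (uM) for the insensitive class.
#' @return One of `"sensitive"`, `"intermediate"`, `"insensitive"`.
#' @export
classify_sensitivity <- function(fit, sensitive_ic50 = c(1, 3),
                                 sensitive_vmax = 0.10,
                                 insensitive_ic50 = 5) {
  stopifnot(inherits(fit, "dose_response_fit"))
  if (fit$flagged) {
    return(if (isTRUE(fit$v_max_dose > 0.5)) "insensitive" else "intermediate")
  }
  if (fit$ic50 >= sensitive_ic50[1] && fit$ic50 <= sensitive_ic50[2] &&
      fit$viability_at_ref_dose < sensitive_vmax) {
    return("sensitive")
  }
  if (fit$ic50 >= insensitive_ic50) return("insensitive")
  "intermediate"
}

#' Dose-response analysis of a plate-readings table
#'
#' Per cell line: signals are normalized to the vehicle (dose 0) mean of the
#' same condition, a four-parameter logistic curve is fitted, and the
#' sensitivity class assigned.
#'
#' @param readings Plate-readings data frame.
#' @param ref_dose Reference dose for the viability readout (default 3.2).
#' @param ... Passed to [classify_sensitivity()].
#' @return Data frame with one row per cell line: 4PL parameters, `rss`,
#'   `ic50`, `viability_at_ref_dose`, `flagged` and `class`.
#' @export
analyze_dose_response <- function(readings, ref_dose = 3.2, ...) {
  out <- lapply(split(readings, readings$cell_line), function(d) {
    v0 <- mean(d$signal[d$dose == 0])
    if (!is.finite(v0) || v0 <= 0) {
      stop("cell line '", d$cell_line[1], "' lacks positive vehicle wells")
    }
    fit <- fit_4pl(d$dose, d$signal / v0, ref_dose = ref_dose,
                   cell_line = d$cell_line[1])
    data.frame(cell_line = d$cell_line[1], bottom = fit$bottom,
               top = fit$top, ic50 = fit$ic50, hill = fit$hill,
               rss = fit$rss,
               viability_at_ref_dose = fit$viability_at_ref_dose,
               flagged = fit$flagged,
               class = classify_sensitivity(fit, ...),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Normalize a drug-rescue grid to its zero-dose row
#'
#' For a (primary drug dose x rescue drug dose) grid, every well is divided
#' by the mean signal of the well with primary dose 0 at the same rescue
#' dose, so the zero-primary-dose row is identically 1.
#'
#' @param grid Data frame with columns `primary_dose`, `rescue_dose`,
#'   `signal` (replicates are averaged).
#' @return Numeric matrix, rows = primary doses (ascending), columns =
#'   rescue doses (ascending), of signal fractions.
#' @export
rescue_normalize <- function(grid) {
  stopifnot(all(c("primary_dose", "rescue_dose", "signal") %in% names(grid)))
  mean_sig <- tapply(grid$signal,
                     list(factor(grid$primary_dose),
                          factor(grid$rescue_dose)), mean)
  b <- as.numeric(rownames(mean_sig))
  v <- as.numeric(colnames(mean_sig))
  if (!0 %in% b) stop("no primary-dose-0 wells in the grid")
  base <- mean_sig[which(b == 0), ]
  missing_v <- v[is.na(base)]
  if (length(missing_v)) {
    stop("missing primary-dose-0 well for rescue dose ",
         paste(missing_v, collapse = ", "))
  }
  out <- sweep(mean_sig, 2, base, "/")
  out[order(b), order(v), drop = FALSE]
}

#' Relative expression by the delta-delta-Ct method
#'
#' Fold change `2^(-ddCt)` where
#' `ddCt = (Ct_target - Ct_reference)_condition -
#' (Ct_target - Ct_reference)_calibrator`, Ct values averaged over
#' replicates.
#'
#' @param ct Data frame with columns `gene`, `condition`, `replicate`, `ct`.
#' @param target Target gene.
#' @param reference Reference (housekeeping) gene, e.g. `"GAPDH"`.
#' @param condition Condition of interest.
#' @param calibrator Calibrator condition.
#' @return Data frame row with the mean Cts, `ddct` and `fold_change`.
#' @export
delta_delta_ct <- function(ct, target, reference, condition, calibrator) {
  mean_ct <- function(g, cond) {
    v <- ct$ct[ct$gene == g & ct$condition == cond]
    if (!length(v)) {
      stop("no Ct values for gene '", g, "' in condition '", cond, "'")
    }
    mean(v)
  }
  dct_cond <- mean_ct(target, condition) - mean_ct(reference, condition)
  dct_cal <- mean_ct(target, calibrator) - mean_ct(reference, calibrator)
  ddct <- dct_cond - dct_cal
  data.frame(target = target, reference = reference, condition = condition,
             calibrator = calibrator, ddct = ddct,
             fold_change = 2^(-ddct), stringsAsFactors = FALSE)
}

#' Relative phosphoprotein level from densitometry band intensities
#'
#' `(phospho / total) / control_ratio`. The loading-control intensity
#' cancels from the ratio and is accepted only for per-lane QC bookkeeping.
#'
#' @param phospho,total Band intensities (> 0) of the phosphorylated and
#'   total protein.
#' @param loading Loading-control intensity (> 0); does not affect the
#'   result.
#' @param control_ratio Phospho/total ratio of the control lane (> 0).
#' @return Relative phosphoprotein level (1 = control).
#' @export
densitometry_ratio <- function(phospho, total, loading = 1,
                               control_ratio = 1) {
  if (any(c(phospho, total, loading, control_ratio) <= 0)) {
    stop("band intensities and the control ratio must be positive")
  }
  (phospho / total) / control_ratio
}
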