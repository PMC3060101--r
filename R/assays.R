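#' Livak relative expression (2^-ddCt) with multiple reference genes
#'
#' Per sample, replicate Ct values are averaged at the cycle level, the
#' target's mean Ct is normalized against the arithmetic mean of the
#' reference genes' mean Cts (equivalently the geometric mean of reference
#' expression), and the resulting delta-Ct is calibrated against the
#' calibrator sample: relative expression = `2^-(dCt_sample -
#' dCt_calibrator)`.  Replicate dispersion is propagated: the standard
#' deviation of a sample's delta-Ct is
#' `sqrt(sd_target^2/n_target + sum(sd_ref^2/n_ref)/k^2)` for k reference
#' genes, and the log-normal error band on expression is reported as
#' `2^-(ddCt -/+ sd)`.
#'
#' @param table data.frame with columns `sample`, `gene`, `ct` (and
#'   optionally `replicate`; replicates are simply all rows sharing a
#'   (sample, gene) pair).
#' @param reference_genes character vector of reference (housekeeping)
#'   gene labels, e.g. `c("GAPDH", "PUM1")`.
#' @param calibrator sample label whose expression defines 1.0.
#' @param target target gene label; default: the unique non-reference gene.
#' @return data.frame per sample: sample, target, dct, ddct,
#'   rel_expr (2^-ddct; exactly 1 for the calibrator), sd_dct, rel_lo,
#'   rel_hi.
#' @export
ddct_relative_expression <- function(table, reference_genes, calibrator,
                                     target = NULL) {
  table <- as.data.frame(table)
  need <- c("sample", "gene", "ct")
  if (!all(need %in% names(table)))
    stop("qPCR table needs columns: ", paste(need, collapse = ", "))
  table$sample <- as.character(table$sample)
  table$gene <- as.character(table$gene)
  table$ct <- as.numeric(table$ct)
  if (any(!is.finite(table$ct)) || any(table$ct <= 0))
    stop("Ct values must be positive and finite")
  if (is.null(target)) {
    target <- setdiff(unique(table$gene), reference_genes)
    if (length(target) != 1L)
      stop("specify `target`: table has ", length(target),
           " non-reference genes")
  }
  samples <- unique(table$sample)
  if (!calibrator %in% samples)
    stop("calibrator sample '", calibrator, "' absent from table")
  per <- lapply(samples, function(s) {
    sub <- table[table$sample == s, ]
    grab <- function(g) {
      ct <- sub$ct[sub$gene == g]
      if (!length(ct))
        stop("sample '", s, "' has no Ct for gene '", g, "'")
      c(mean = mean(ct), var = if (length(ct) > 1)
        stats::var(ct) / length(ct) else 0)
    }
    tgt <- grab(target)
    refs <- vapply(reference_genes, grab, numeric(2))
    dct <- tgt["mean"] - mean(refs["mean", ])
    v <- tgt["var"] + sum(refs["var", ]) / length(reference_genes)^2
    c(dct = unname(dct), sd = sqrt(unname(v)))
  })
  dct <- vapply(per, `[`, 0, "dct")
  sdv <- vapply(per, `[`, 0, "sd")
  ddct <- dct - dct[samples == calibrator]
  out <- data.frame(sample = samples, target = target, dct = dct,
                    ddct = ddct, rel_expr = 2^(-ddct), sd_dct = sdv,
                    rel_lo = 2^(-(ddct + sdv)), rel_hi = 2^(-(ddct - sdv)),
                    stringsAsFactors = FALSE)
  out$rel_expr[out$sample == calibrator] <- 1  # exact by definition
  rownames(out) <- NULL
  out
}

#' Glucose uptake normalized to cell number
#'
#' Uptake over the assay window is the drop in medium glucose divided by
#' the final cell count in millions:
#' `U = (glucose_start - glucose_end) / (cell_count / 1e6)`,
#' in mg/ml per 10^6 cells.  A negative uptake (end > start) is returned
#' as-is with a warning: it flags assay failure and must not be hidden.
#'
#' @param glucose_start,glucose_end medium glucose (mg/ml) at assay start
#'   and end.
#' @param cell_count cells at assay end (> 0).
#' @param duration_hours assay duration, informational (default 48).
#' @return uptake in mg/ml per 10^6 cells.
#' @export
glucose_uptake <- function(glucose_start, glucose_end, cell_count,
                           duration_hours = 48) {
  if (any(glucose_start < 0) || any(glucose_end < 0))
    stop("glucose concentrations must be >= 0")
  if (any(cell_count <= 0)) stop("cell count must be positive")
  u <- (glucose_start - glucose_end) / (cell_count / 1e6)
  if (any(u < 0))
    warning("negative uptake (end > start): check the assay")
  u
}

#' Fold change between two conditions with propagated standard error
#'
#' `fold = mean(b) / mean(a)`; the standard error follows first-order
#' (delta-method) propagation of the per-condition standard errors of the
#' mean: `SE = fold * sqrt(se_a^2/mean_a^2 + se_b^2/mean_b^2)`.
#'
#' @param values_a replicate measurements of the baseline condition
#'   (denominator).
#' @param values_b replicate measurements of the comparison condition.
#' @return named numeric vector: fold, se.
#' @export
condition_fold_change <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b))
    stop("need at least one replicate per condition")
  ma <- mean(values_a); mb <- mean(values_b)
  if (ma == 0) stop("baseline condition has zero mean")
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  fold <- mb / ma
  se <- abs(fold) * sqrt((sem(values_a) / ma)^2 + (sem(values_b) / mb)^2)
  if (mb == 0) se <- sem(values_b) / abs(ma)  # delta method at fold = 0
  c(fold = fold, se = se)
}

#' Percent increase in cell number
#'
#' @param count_t0 count at the reference time (> 0).
#' @param count_t count at the later time.
#' @return `100 * (count_t - count_t0) / count_t0`.
#' @export
percent_increase <- function(count_t0, count_t) {
  if (any(count_t0 <= 0)) stop("reference count must be positive")
  100 * (count_t - count_t0) / count_t0
}

#' Population doubling time from a growth series
#'
#' Fits single-phase exponential growth by least squares of ln(count) on
#' time and returns `ln(2) / slope` in hours.  A non-positive slope (no net
#' growth) is an error rather than an infinite or negative time.
#'
#' @param time hours, strictly increasing, length >= 2.
#' @param count cell or nuclei counts (> 0), same length.
#' @return doubling time in hours.
#' @export
doubling_time <- function(time, count) {
  if (length(time) < 2 || length(time) != length(count))
    stop("need matched time/count vectors of length >= 2")
  if (is.unsorted(time, strictly = TRUE))
    stop("times must be strictly increasing")
  if (any(count <= 0)) stop("counts must be positive")
  slope <- stats::coef(stats::lm(log(count) ~ time))[["time"]]
  if (slope <= 0) stop("no net growth: slope of ln(count) is <= 0")
  log(2) / slope
}
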