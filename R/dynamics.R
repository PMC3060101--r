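#' Pipeline thresholds
#'
#' Configuration of the dynamic prefilter and the differential call.  Both
#' thresholds are fold changes compared on the natural-log scale with
#' inclusive boundaries (relative tolerance 1e-9 at the boundary, so a fold
#' of exactly 1.7 or exactly 2 qualifies despite floating point).
#'
#' @param prefilter_fold minimum fold change (relative to t = 0, direction
#'   symmetric) in the oncogene-line series for a gene to enter the
#'   analysis; default 1.7.
#' @param prefilter_cap maximum number of genes carried forward, ranked by
#'   max fold descending (ties by gene id); default 2500.  Use `Inf` for
#'   pure thresholding.
#' @param call_fold minimum normalized between-line expression ratio (in
#'   either direction) for a differential call; default 2.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(prefilter_fold = 1.7, prefilter_cap = 2500,
                            call_fold = 2) {
  stopifnot(prefilter_fold >= 1, call_fold >= 1, prefilter_cap >= 1)
  structure(list(prefilter_fold = prefilter_fold,
                 prefilter_cap = prefilter_cap,
                 call_fold = call_fold),
            class = "pipeline_config")
}

# inclusive >= with relative tolerance at the boundary
geq_tol <- function(x, threshold, tol = 1e-9) x >= threshold * (1 - tol)

#' Direction-symmetric fold change relative to t = 0
#'
#' `fold(t) = max(x_t/x_0, x_0/x_t)`, so both induction and repression
#' relative to the pre-inhibition steady state register as fold > 1, and
#' `fold(0) = 1` by construction.
#'
#' @param series positive numeric vector (or matrix, features x time) whose
#'   first element/column is the t = 0 measurement.
#' @return fold changes of the same shape as `series`.
#' @export
timepoint_fold_change <- function(series) {
  if (any(series <= 0)) stop("fold change requires positive values")
  if (is.matrix(series)) {
    ratio <- series / series[, 1]
    pmax(ratio, 1 / ratio)
  } else {
    ratio <- series / series[1]
    pmax(ratio, 1 / ratio)
  }
}

#' Dynamic prefilter on the oncogene-line series
#'
#' Selects genes whose oncogene-line expression reaches the prefilter fold
#' (relative to t = 0, either direction) at any time point after inhibitor
#' addition, ranks them by maximum fold descending, and keeps at most
#' `prefilter_cap` of them.  Tie-break: gene id ascending.  The parental
#' series plays no role here.
#'
#' @param experiment a gene-level [ts_experiment()].
#' @param config a [pipeline_config()].
#' @return character vector of retained gene ids, ranked; attribute
#'   `max_fold` carries each retained gene's maximum fold.
#' @export
prefilter_dynamic <- function(experiment, config = pipeline_config()) {
  folds <- timepoint_fold_change(experiment$oncogene)
  maxfold <- apply(folds[, -1, drop = FALSE], 1L, max)
  qual <- maxfold[geq_tol(maxfold, config$prefilter_fold)]
  ord <- order(-qual, names(qual), method = "radix")
  qual <- qual[ord]
  if (length(qual) > config$prefilter_cap)
    qual <- qual[seq_len(config$prefilter_cap)]
  structure(names(qual), max_fold = unname(qual))
}

#' Differential log-ratio trajectory
#'
#' The core statistic: the oncogene-to-parental expression ratio at each
#' time point, normalized to the ratio at the zero time point, on the
#' natural-log scale:
#' `r(t) = ln[(H(t)/A(t)) / (H(0)/A(0))]`.
#' Regulation shared by both lines cancels; `r(0) = 0` exactly.
#'
#' @param oncogene_series,parental_series positive numeric vectors on the
#'   same time grid, first element at t = 0.
#' @return numeric vector r(t); `r[1] == 0`.
#' @export
differential_trajectory <- function(oncogene_series, parental_series) {
  if (length(oncogene_series) != length(parental_series))
    stop("series lengths differ: grids do not match")
  if (any(oncogene_series <= 0) || any(parental_series <= 0))
    stop("non-positive intensity: floor intensities first")
  r <- (log(oncogene_series) - log(parental_series)) -
    (log(oncogene_series[1]) - log(parental_series[1]))
  r[1] <- 0  # exact by construction
  r
}

#' All differential trajectories of an experiment
#'
#' @param experiment a gene-level [ts_experiment()].
#' @param genes optional subset of gene ids (default: all).
#' @return genes x time matrix of r(t) values; column for t = 0 is 0.
#' @export
differential_trajectories <- function(experiment, genes = NULL) {
  h <- experiment$oncogene
  a <- experiment$parental
  if (!is.null(genes)) {
    h <- h[genes, , drop = FALSE]
    a <- a[genes, , drop = FALSE]
  }
  if (any(h <= 0) || any(a <= 0))
    stop("non-positive intensity: floor intensities first")
  r <- (log(h) - log(a)) - (log(h[, 1]) - log(a[, 1]))
  r[, 1] <- 0
  colnames(r) <- paste0("t", experiment$time)
  r
}

#' Call a gene from its trajectory
#'
#' A gene is differential iff `max_t |r(t)| >= ln(call_fold)` (inclusive
#' boundary).  Direction semantics: the inhibitor removes oncogene
#' signaling, so a trajectory falling to `-ln(call_fold)` or below means the
#' oncogene was maintaining expression (class `oncogene_up`); a rising
#' trajectory means the oncogene was repressing it (`oncogene_down`).  The
#' extreme is the value of largest magnitude; at an exact magnitude tie the
#' earliest time point wins.
#'
#' @param r numeric trajectory with r[1] = 0 at t = 0.
#' @param time matching time grid (hours).
#' @param config a [pipeline_config()].
#' @return one-row data.frame: class, max_abs_r, t_extreme, direction.
#' @export
call_differential <- function(r, time, config = pipeline_config()) {
  stopifnot(length(r) == length(time))
  i <- which.max(abs(r))
  m <- abs(r[i])
  diff <- geq_tol(m, log(config$call_fold))
  cls <- if (!diff) "not_differential"
         else if (r[i] < 0) "oncogene_up" else "oncogene_down"
  data.frame(class = cls, max_abs_r = m, t_extreme = time[i],
             direction = sign(r[i]))
}

#' Run the full differential dynamic expression pipeline
#'
#' Stages: floor intensities, quantile-normalize across all arrays of both
#' lines jointly, collapse probes to genes, prefilter on oncogene-line
#' dynamics, compute differential trajectories, call oncogene-specific
#' genes, and emit the log2 mean-centered display series for called genes.
#'
#' @param experiment a probe- or gene-level [ts_experiment()] of raw
#'   intensities.
#' @param config a [pipeline_config()].
#' @param floor_epsilon positive intensity floor (default 1).
#' @param quantile logical: apply cross-array quantile normalization
#'   (default TRUE).  Disable to study the raw statistic, e.g. on noiseless
#'   simulations where forcing a common distribution is meaningless.
#' @param joint logical: normalize the two lines' arrays together (default
#'   TRUE, the analysis target being the between-line ratio) rather than per
#'   line.
#' @return list with elements `calls` (a `gene_calls` data.frame over all
#'   genes), `trajectories` (prefiltered genes x time), `display` (log2
#'   mean-centered oncogene/parental series for called genes), `experiment`
#'   (the normalized gene-level experiment) and `report` (stage counts and
#'   thresholds).
#' @export
run_pipeline <- function(experiment, config = pipeline_config(),
                         floor_epsilon = 1, quantile = TRUE, joint = TRUE) {
  a <- experiment$parental
  h <- experiment$oncogene
  nt <- length(experiment$time)
  comb <- cbind(a, h)
  colnames(comb) <- paste0(rep(c("A", "H"), each = nt), "_", colnames(a))
  comb <- floor_intensities(comb, floor_epsilon)
  n_floored <- attr(comb, "n_floored")
  if (quantile) {
    comb <- if (joint) quantile_normalize(comb)
            else cbind(quantile_normalize(comb[, seq_len(nt), drop = FALSE]),
                       quantile_normalize(comb[, nt + seq_len(nt),
                                               drop = FALSE]))
  }
  n_probes <- nrow(comb)
  if (!is.null(experiment$annotation)) {
    comb <- collapse_probes(comb, experiment$annotation)
  }
  gene_exp <- ts_experiment(
    parental = comb[, seq_len(nt), drop = FALSE],
    oncogene = comb[, nt + seq_len(nt), drop = FALSE],
    time = experiment$time)
  keep <- prefilter_dynamic(gene_exp, config)
  traj <- differential_trajectories(gene_exp, genes = keep)
  calls_kept <- do.call(rbind, lapply(keep, function(g)
    call_differential(traj[g, ], gene_exp$time, config)))
  genes <- rownames(gene_exp$oncogene)
  calls <- data.frame(gene = genes, class = "not_differential",
                      max_abs_r = 0, t_extreme = 0, direction = 0,
                      passed_prefilter = genes %in% keep,
                      stringsAsFactors = FALSE)
  if (length(keep)) {
    i <- match(keep, calls$gene)
    calls$class[i] <- calls_kept$class
    calls$max_abs_r[i] <- calls_kept$max_abs_r
    calls$t_extreme[i] <- calls_kept$t_extreme
    calls$direction[i] <- calls_kept$direction
  }
  calls <- calls[order(-calls$max_abs_r, calls$gene), ]
  rownames(calls) <- NULL
  class(calls) <- c("gene_calls", "data.frame")
  called <- calls$gene[calls$class != "not_differential"]
  display <- lapply(stats::setNames(called, called), function(g) {
    rbind(oncogene = log2_mean_center(gene_exp$oncogene[g, ]),
          parental = log2_mean_center(gene_exp$parental[g, ]))
  })
  report <- list(
    thresholds = unclass(config), floor_epsilon = floor_epsilon,
    quantile = quantile, joint = joint,
    n_floored = n_floored, n_probes = n_probes,
    n_genes = length(genes), n_prefiltered = length(keep),
    n_called = length(called),
    n_oncogene_up = sum(calls$class == "oncogene_up"),
    n_oncogene_down = sum(calls$class == "oncogene_down"))
  list(calls = calls, trajectories = traj, display = display,
       experiment = gene_exp, report = report)
}

#' Series fold change, both candidate definitions
#'
#' Reports how much a single-line expression series changed over the chase,
#' under the two natural readings: `extreme_vs_t0` (largest direction-
#' symmetric fold relative to the t = 0 steady state) and `max_vs_min`
#' (ratio of the series maximum to its minimum, wherever they occur).
#'
#' @param series positive numeric vector, first element at t = 0.
#' @return named numeric vector with elements `extreme_vs_t0` and
#'   `max_vs_min`.
#' @export
series_fold_change <- function(series) {
  if (any(series <= 0)) stop("fold change requires positive values")
  c(extreme_vs_t0 = max(timepoint_fold_change(series)),
    max_vs_min = max(series) / min(series))
}
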