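#' Configuration of the inhibitor-chase simulator
#'
#' The simulator emulates a two-line chase design: at t = 0 a kinase
#' inhibitor silences oncogene signaling and each oncogene-driven
#' transcript relaxes from its driven steady state toward its basal level.
#' Log-expression decays exponentially, i.e. the noiseless mean for gene g
#' in line L is `mu_gL(t) = B_g * F_gL ^ exp(-t / tau_g)`: at t = 0 the
#' driven level `B_g * F_gL`, at t -> Inf the basal level `B_g`.
#'
#' @param n_genes number of genes simulated (default 2000; a desk-scale
#'   stand-in for the ~20k probes of a genome-wide array).
#' @param n_timepoints number of samples per line (default 16).
#' @param dt_hours grid spacing in hours (default 3; 16 points x 3 h = the
#'   0..45 h chase).
#' @param frac_oncogene_specific fraction of genes with an activating
#'   oncogene-specific effect (F_H > 1, F_A = 1; truth class
#'   `oncogene_up`).  Default 0.05.
#' @param frac_oncogene_down fraction with a repressive oncogene-specific
#'   effect (F_H < 1, F_A = 1; truth class `oncogene_down`).  Default 0.
#' @param frac_shared_regulated fraction regulated identically in both
#'   lines (F_H = F_A != 1; proto-oncogene regulation, cancelled by the
#'   trajectory statistic).  Default 0.10.
#' @param fold_effect_range length-2 vector, multiplicative fold effect
#'   bounds (> 1); folds are drawn uniformly, repressive effects use the
#'   reciprocal.  Default c(3, 5).
#' @param tau_range_hours length-2 vector of relaxation time constants in
#'   hours, drawn uniformly.  Default c(5, 15).
#' @param noise_sigma standard deviation of the multiplicative log-normal
#'   measurement noise on natural-log intensities.  Default 0.1.
#' @param baseline_log_mean,baseline_log_sd natural-log mean / sd of the
#'   per-gene basal intensity B_g (defaults 6 and 1: median ~400, a raw
#'   Illumina-like scale).
#' @param probes_per_gene probes simulated per gene (default 1; > 1
#'   exercises probe collapse, probes share the gene's kinetics but have
#'   probe-specific affinities).
#' @param seed integer RNG seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 2000, n_timepoints = 16,
                             dt_hours = 3,
                             frac_oncogene_specific = 0.05,
                             frac_oncogene_down = 0,
                             frac_shared_regulated = 0.10,
                             fold_effect_range = c(3, 5),
                             tau_range_hours = c(5, 15),
                             noise_sigma = 0.1,
                             baseline_log_mean = 6,
                             baseline_log_sd = 1,
                             probes_per_gene = 1,
                             seed = 1) {
  cfg <- list(n_genes = n_genes, n_timepoints = n_timepoints,
              dt_hours = dt_hours,
              frac_oncogene_specific = frac_oncogene_specific,
              frac_oncogene_down = frac_oncogene_down,
              frac_shared_regulated = frac_shared_regulated,
              fold_effect_range = fold_effect_range,
              tau_range_hours = tau_range_hours,
              noise_sigma = noise_sigma,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              probes_per_gene = probes_per_gene,
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  with(cfg, {
    if (n_genes < 1) stop("n_genes must be >= 1")
    if (n_timepoints < 2) stop("need at least 2 time points")
    if (dt_hours <= 0) stop("dt_hours must be positive")
    fr <- c(frac_oncogene_specific, frac_oncogene_down,
            frac_shared_regulated)
    if (any(fr < 0) || any(fr > 1) || sum(fr) > 1)
      stop("class fractions must lie in [0,1] and sum to at most 1")
    if (length(fold_effect_range) != 2 || any(fold_effect_range <= 1) ||
        diff(fold_effect_range) < 0)
      stop("fold_effect_range must be an increasing pair of folds > 1")
    if (length(tau_range_hours) != 2 || any(tau_range_hours <= 0) ||
        diff(tau_range_hours) < 0)
      stop("tau_range_hours must be an increasing pair of positive hours")
    if (noise_sigma < 0) stop("noise_sigma must be >= 0")
    if (baseline_log_sd < 0) stop("baseline_log_sd must be >= 0")
    if (probes_per_gene < 1) stop("probes_per_gene must be >= 1")
  })
  invisible(cfg)
}

#' Simulate an inhibitor-chase experiment with known truth
#'
#' Draws per-gene generative parameters, computes the noiseless relaxation
#' means for both lines on the shared time grid, and multiplies in
#' independent log-normal measurement noise.  Fully reproducible from
#' `config$seed`; the caller's RNG state is restored on exit.
#'
#' @param config a [synthetic_config()].
#' @return list with `experiment` (a [ts_experiment()], probe-level if
#'   `probes_per_gene > 1`, with annotation) and `truth` (data.frame: gene,
#'   class, baseline, fold_oncogene, fold_parental, tau, sigma).
#' @export
simulate_experiment <- function(config) {
  validate_synthetic_config(config)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  n <- config$n_genes
  time <- (seq_len(config$n_timepoints) - 1) * config$dt_hours
  genes <- sprintf("G%05d", seq_len(n))

  n_up <- round(config$frac_oncogene_specific * n)
  n_dn <- round(config$frac_oncogene_down * n)
  n_sh <- round(config$frac_shared_regulated * n)
  cls <- sample(rep(c("oncogene_up", "oncogene_down", "shared",
                      "unregulated"),
                    c(n_up, n_dn, n_sh, n - n_up - n_dn - n_sh)))

  B <- exp(stats::rnorm(n, config$baseline_log_mean,
                        config$baseline_log_sd))
  tau <- stats::runif(n, config$tau_range_hours[1],
                      config$tau_range_hours[2])
  fold <- stats::runif(n, config$fold_effect_range[1],
                       config$fold_effect_range[2])
  FH <- rep(1, n); FA <- rep(1, n)
  FH[cls == "oncogene_up"] <- fold[cls == "oncogene_up"]
  FH[cls == "oncogene_down"] <- 1 / fold[cls == "oncogene_down"]
  sh <- cls == "shared"
  # shared regulation is induced or repressed with equal probability
  shared_sign <- ifelse(stats::runif(n) < 0.5, 1, -1)
  FH[sh] <- FA[sh] <- fold[sh] ^ shared_sign[sh]

  truth <- data.frame(gene = genes, class = cls, baseline = B,
                      fold_oncogene = FH, fold_parental = FA, tau = tau,
                      sigma = config$noise_sigma, stringsAsFactors = FALSE)

  decay <- exp(-outer(1 / tau, time))        # n x T, exp(-t/tau)
  k <- config$probes_per_gene
  make_line <- function(f) {
    mu <- B * f ^ decay                      # recycles B, f over columns
    if (k > 1) {
      mu <- mu[rep(seq_len(n), each = k), , drop = FALSE] * probe_affinity
    }
    eps <- matrix(stats::rnorm(length(mu), 0, config$noise_sigma),
                  nrow(mu))
    m <- mu * exp(eps)
    rownames(m) <- feat
    m
  }
  if (k > 1) {
    # probe-specific multiplicative affinity, constant over time and lines
    probe_affinity <- exp(stats::rnorm(n * k, 0, 0.3))
    feat <- paste0(rep(genes, each = k), "_p", seq_len(k))
    annotation <- data.frame(probe = feat, gene = rep(genes, each = k),
                             stringsAsFactors = FALSE)
  } else {
    feat <- genes
    annotation <- data.frame(probe = genes, gene = genes,
                             stringsAsFactors = FALSE)
  }
  a <- make_line(FA)
  h <- make_line(FH)
  experiment <- ts_experiment(parental = a, oncogene = h, time = time,
                              annotation = annotation)
  list(experiment = experiment, truth = truth)
}

#' Noiseless differential trajectory implied by the generative model
#'
#' Closed form of the statistic on noiseless simulated data:
#' `r(t) = (exp(-t/tau) - 1) * ln(F_H / F_A)`.
#'
#' @param fold_oncogene,fold_parental per-line fold effects.
#' @param tau relaxation time constant (hours).
#' @param time time grid (hours).
#' @return numeric vector r(t).
#' @export
expected_trajectory <- function(fold_oncogene, fold_parental, tau, time) {
  (exp(-time / tau) - 1) * log(fold_oncogene / fold_parental)
}

#' Score a call set against simulation truth
#'
#' Confusion-matrix rates per oncogene-specific class and for the pooled
#' \dQuote{differential at all} decision.  Sensitivity = called c among
#' truly c; specificity = not called c among truly not c; FDP = fraction of
#' c calls that are wrong (0 when nothing is called).
#'
#' @param calls a `gene_calls` data.frame (column `class` with levels
#'   oncogene_up / oncogene_down / not_differential).
#' @param truth the truth data.frame from [simulate_experiment()].
#' @return data.frame with rows oncogene_up, oncogene_down, differential
#'   and columns class, n_true, n_called, tp, sensitivity, specificity,
#'   fdp.
#' @export
evaluate_recovery <- function(calls, truth) {
  calls <- as.data.frame(calls)
  if (!setequal(calls$gene, truth$gene))
    stop("call set and truth cover different gene universes")
  tr <- truth$class[match(calls$gene, truth$gene)]
  cl <- calls$class
  one <- function(label, truth_pos, call_pos) {
    tp <- sum(truth_pos & call_pos)
    data.frame(class = label, n_true = sum(truth_pos),
               n_called = sum(call_pos), tp = tp,
               sensitivity = if (sum(truth_pos)) tp / sum(truth_pos)
                             else NA_real_,
               specificity = if (sum(!truth_pos))
                 sum(!truth_pos & !call_pos) / sum(!truth_pos)
                 else NA_real_,
               fdp = if (sum(call_pos)) (sum(call_pos) - tp) / sum(call_pos)
                     else 0,
               stringsAsFactors = FALSE)
  }
  rbind(one("oncogene_up", tr == "oncogene_up", cl == "oncogene_up"),
        one("oncogene_down", tr == "oncogene_down", cl == "oncogene_down"),
        one("differential", tr %in% c("oncogene_up", "oncogene_down"),
            cl != "not_differential"))
}

#' Write / read simulator outputs
#'
#' The truth table is tab-separated with the documented columns of
#' [simulate_experiment()]; the configuration is stored as a DCF key-value
#' file readable by [read_synthetic_config()].
#'
#' @param truth,path,config truth table / file path / configuration.
#' @return the path, invisibly (writers), or the parsed object (readers).
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname write_truth
#' @export
write_synthetic_config <- function(config, path) {
  flat <- lapply(unclass(config), paste, collapse = " ")
  write.dcf(as.data.frame(flat, check.names = FALSE), path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_synthetic_config <- function(path) {
  raw <- as.list(as.data.frame(read.dcf(path), stringsAsFactors = FALSE))
  num <- function(x) as.numeric(strsplit(as.character(x), " +")[[1]])
  do.call(synthetic_config, lapply(raw, num))
}
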