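#' Read a probe x sample expression matrix
#'
#' Reads a tab-separated intensity table with probe identifiers in the first
#' column and sample identifiers in the header row.  Two dialects are
#' supported: plain TSV, and the GEO series-matrix dialect in which lines
#' beginning with `!` are metadata and the numeric table sits between the
#' `!series_matrix_table_begin` / `!series_matrix_table_end` markers.
#'
#' @param path file path.
#' @param dialect one of \dQuote{auto}, \dQuote{tsv}, \dQuote{geo}.
#' @return numeric matrix with probe rownames and sample colnames.
#' @export
read_expression_matrix <- function(path, dialect = c("auto", "tsv", "geo")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (dialect == "auto")
    dialect <- if (any(startsWith(lines, "!"))) "geo" else "tsv"
  if (dialect == "geo") {
    beg <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(beg) == 1L && length(end) == 1L && end > beg) {
      lines <- lines[(beg + 1L):(end - 1L)]
    } else {
      lines <- lines[!startsWith(lines, "!")]
    }
    lines <- lines[nzchar(lines)]
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1L)
    stop("ragged table: row ", which(widths != widths[1])[1],
         " has ", widths[widths != widths[1]][1], " fields, expected ",
         widths[1])
  header <- fields[[1]]
  samples <- gsub('^"|"$', "", header[-1])
  body <- fields[-1]
  probes <- gsub('^"|"$', "", vapply(body, `[`, "", 1L))
  dup <- unique(probes[duplicated(probes)])
  if (length(dup))
    stop("duplicated probe id(s): ", paste(dup, collapse = ", "))
  if (anyDuplicated(samples))
    stop("duplicated sample id(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  vals <- vapply(body, function(f) {
    v <- suppressWarnings(as.numeric(f[-1]))
    v
  }, numeric(length(samples)))
  mat <- t(if (is.null(dim(vals))) matrix(vals, nrow = 1) else vals)
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop("non-numeric cell at probe '", probes[bad[1]], "', sample '",
         samples[bad[2]], "'")
  }
  dimnames(mat) <- list(probes, samples)
  mat
}

#' Read a sample sheet
#'
#' Tab-separated table with columns `sample`, `line` and `time` (hours since
#' inhibitor addition).  Line labels may be \dQuote{parental}/\dQuote{A} or
#' \dQuote{oncogene}/\dQuote{H}.
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_sample_sheet <- function(path) {
  validate_sample_sheet(
    utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Read a probe-to-gene annotation table
#'
#' @param path tab-separated file with columns `probe` and `gene`.
#' @return validated data.frame.
#' @export
read_annotation <- function(path) {
  validate_annotation(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write / read a gene call table
#'
#' The call table is tab-separated with columns `gene`, `class`,
#' `max_abs_r`, `t_extreme`, `direction`, `passed_prefilter`, ordered by
#' descending `max_abs_r` with ties broken by gene id.  `direction` is the
#' sign of the extreme trajectory value (-1, 0 or 1).
#'
#' @param calls a `gene_calls` data.frame as produced by [run_pipeline()].
#' @param path output path.
#' @return `write_gene_calls()` returns `path` invisibly; `read_gene_calls()`
#'   returns the call table.
#' @export
write_gene_calls <- function(calls, path) {
  calls <- as.data.frame(calls)
  cols <- c("gene", "class", "max_abs_r", "t_extreme", "direction",
            "passed_prefilter")
  stopifnot(all(cols %in% names(calls)))
  calls <- calls[order(-calls$max_abs_r, calls$gene), cols]
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_calls
#' @export
read_gene_calls <- function(path) {
  calls <- utils::read.delim(path, stringsAsFactors = FALSE)
  calls$gene <- as.character(calls$gene)
  class(calls) <- c("gene_calls", "data.frame")
  calls
}

#' Write / read a trajectory table
#'
#' Genes x time matrix of the differential log-ratio trajectory, written as
#' TSV with a `gene` first column and `t<hours>` headers.
#'
#' @param traj numeric matrix, genes x time points.
#' @param path file path.
#' @return the path (write) or the matrix (read).
#' @export
write_trajectories <- function(traj, path) {
  df <- data.frame(gene = rownames(traj), traj, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- as.character(df[[1]])
  mat
}

#' Write a two-line experiment to disk
#'
#' Emits the same tab-separated matrix + sample-sheet pair that
#' [read_expression_matrix()] and [read_sample_sheet()] consume.  Samples
#' are named `<line>_t<time>`.
#'
#' @param experiment a [ts_experiment()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named character vector of the written paths, invisibly.
#' @export
write_experiment <- function(experiment, dir, prefix = "experiment") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  a <- experiment$parental
  h <- experiment$oncogene
  sa <- paste0("A_t", experiment$time)
  sh <- paste0("H_t", experiment$time)
  mat <- cbind(a, h)
  colnames(mat) <- c(sa, sh)
  mpath <- file.path(dir, paste0(prefix, "_matrix.tsv"))
  utils::write.table(
    data.frame(probe = rownames(mat), mat, check.names = FALSE),
    mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  sheet <- data.frame(
    sample = c(sa, sh),
    line = rep(c("parental", "oncogene"), each = length(experiment$time)),
    time = rep(experiment$time, 2))
  spath <- file.path(dir, paste0(prefix, "_samples.tsv"))
  utils::write.table(sheet, spath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix = mpath, samples = spath))
}

#' Read a two-line experiment from a matrix + sample-sheet pair
#'
#' @param matrix_path expression matrix TSV.
#' @param sheet_path sample sheet TSV.
#' @param annotation_path optional probe-to-gene TSV.
#' @return a [ts_experiment()].
#' @export
read_experiment <- function(matrix_path, sheet_path,
                            annotation_path = NULL) {
  ann <- if (!is.null(annotation_path)) read_annotation(annotation_path)
  assemble_experiment(read_expression_matrix(matrix_path),
                      read_sample_sheet(sheet_path),
                      annotation = ann)
}
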