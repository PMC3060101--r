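#' Inhibitor-chase time-series experiment
#'
#' Container for a matched two-line inhibitor-chase design: one expression
#' matrix per cell line (rows = probes or genes, columns = time points) on a
#' shared, strictly increasing time grid that includes the pre-inhibition
#' steady state t = 0.  The parental line carries the proto-oncogene; the
#' oncogene line carries the activated/overexpressed oncogene whose kinase
#' is inhibited at t = 0.
#'
#' @param parental numeric matrix, features x time points, for the parental
#'   (proto-oncogene) line.
#' @param oncogene numeric matrix of identical dimensions and rownames for
#'   the oncogene-transformed line.
#' @param time numeric vector of sampling times in hours, one per column.
#' @param annotation optional data.frame with columns `probe` and `gene`
#'   mapping row identifiers to gene symbols.
#' @return An object of class `ts_experiment`.
#' @export
ts_experiment <- function(parental, oncogene, time, annotation = NULL) {
  parental <- as.matrix(parental)
  oncogene <- as.matrix(oncogene)
  time <- as.numeric(time)
  if (is.null(rownames(parental)) || is.null(rownames(oncogene)))
    stop("both matrices need feature identifiers as rownames")
  if (!identical(dim(parental), dim(oncogene)))
    stop("parental and oncogene matrices must have identical dimensions")
  if (!identical(rownames(parental), rownames(oncogene)))
    stop("parental and oncogene matrices must share one feature universe")
  if (anyDuplicated(rownames(parental)))
    stop("duplicated feature identifiers: ",
         paste(unique(rownames(parental)[duplicated(rownames(parental))]),
               collapse = ", "))
  if (length(time) != ncol(parental))
    stop("time grid length (", length(time), ") != number of columns (",
         ncol(parental), ")")
  if (any(!is.finite(time)) || is.unsorted(time, strictly = TRUE))
    stop("time grid must be finite and strictly increasing")
  if (time[1] != 0)
    stop("time grid must include t = 0: ",
         "normalization to the zero time point is undefined without it")
  if (anyNA(parental) || anyNA(oncogene))
    stop("missing intensities are not supported; fix the input")
  if (!is.null(annotation)) annotation <- validate_annotation(annotation)
  colnames(parental) <- colnames(oncogene) <- paste0("t", time)
  structure(
    list(parental = parental, oncogene = oncogene, time = time,
         annotation = annotation),
    class = "ts_experiment")
}

validate_annotation <- function(annotation) {
  annotation <- as.data.frame(annotation)
  if (!all(c("probe", "gene") %in% names(annotation)))
    stop("annotation needs columns 'probe' and 'gene'")
  annotation$probe <- as.character(annotation$probe)
  annotation$gene <- as.character(annotation$gene)
  if (anyDuplicated(annotation$probe))
    stop("annotation maps some probe more than once")
  annotation[, c("probe", "gene")]
}

#' @export
print.ts_experiment <- function(x, ...) {
  cat("ts_experiment:", nrow(x$parental), "features x",
      length(x$time), "time points\n")
  cat("  time grid (h):", paste(x$time, collapse = ", "), "\n")
  cat("  lines: parental, oncogene\n")
  if (!is.null(x$annotation))
    cat("  annotation:", nrow(x$annotation), "probe -> gene entries\n")
  invisible(x)
}

#' @export
dim.ts_experiment <- function(x) dim(x$parental)

#' Assemble a two-line time-series experiment
#'
#' Partitions the samples of an expression matrix by cell line using the
#' sample sheet, orders each line by time, and enforces the design
#' invariants: both lines on an identical strictly increasing grid
#' containing t = 0, every sample annotated exactly once.
#'
#' @param matrix expression matrix (probes x samples) as returned by
#'   [read_expression_matrix()].
#' @param sheet sample sheet data.frame with columns `sample`, `line`
#'   (\dQuote{parental}/\dQuote{A} or \dQuote{oncogene}/\dQuote{H}) and
#'   `time` (hours).
#' @param annotation optional probe-to-gene annotation data.frame.
#' @return A [ts_experiment()].
#' @export
assemble_experiment <- function(matrix, sheet, annotation = NULL) {
  sheet <- validate_sample_sheet(sheet)
  missing <- setdiff(colnames(matrix), sheet$sample)
  if (length(missing))
    stop("samples absent from the sample sheet: ",
         paste(missing, collapse = ", "))
  extra <- setdiff(sheet$sample, colnames(matrix))
  if (length(extra))
    stop("sample sheet rows without a matrix column: ",
         paste(extra, collapse = ", "))
  split <- split(sheet, sheet$line)
  if (!all(c("parental", "oncogene") %in% names(split)))
    stop("both cell lines must be present in the sample sheet")
  grids <- lapply(split, function(s) sort(s$time))
  if (!isTRUE(all.equal(grids$parental, grids$oncogene, tolerance = 0)))
    stop("time grids differ between lines: parental {",
         paste(grids$parental, collapse = ","), "} vs oncogene {",
         paste(grids$oncogene, collapse = ","), "}")
  if (grids$parental[1] != 0)
    stop("no t = 0 sample: ",
         "normalization to the zero time point is undefined")
  pick <- function(s) {
    s <- s[order(s$time), , drop = FALSE]
    matrix[, s$sample, drop = FALSE]
  }
  ts_experiment(parental = pick(split$parental),
                oncogene = pick(split$oncogene),
                time = grids$parental,
                annotation = annotation)
}

validate_sample_sheet <- function(sheet) {
  sheet <- as.data.frame(sheet)
  need <- c("sample", "line", "time")
  if (!all(need %in% names(sheet)))
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  sheet$sample <- as.character(sheet$sample)
  sheet$time <- as.numeric(sheet$time)
  line <- tolower(as.character(sheet$line))
  map <- c(parental = "parental", a = "parental",
           oncogene = "oncogene", h = "oncogene")
  if (any(!line %in% names(map)))
    stop("unrecognized cell line label(s): ",
         paste(unique(sheet$line[!line %in% names(map)]), collapse = ", "))
  sheet$line <- unname(map[line])
  if (anyDuplicated(sheet$sample))
    stop("duplicated sample id in sheet: ",
         paste(unique(sheet$sample[duplicated(sheet$sample)]), collapse = ", "))
  key <- paste(sheet$line, sheet$time)
  if (anyDuplicated(key))
    stop("replicate arrays per (line, time) are not supported: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  if (any(!is.finite(sheet$time)))
    stop("non-numeric time in sample sheet")
  sheet
}
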