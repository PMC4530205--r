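## TSV loaders and writers for the pipeline's interchange formats.
## Schema checks raise errors that name the offending column or row.

#' Load a log2 expression matrix from TSV
#'
#' Expects a `probe_id` first column followed by one column per sample.
#'
#' @param path TSV file path.
#' @return numeric matrix, probes x samples, with dimnames.
#' @export
load_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "probe_id")
    stop("expression TSV must start with a 'probe_id' column")
  dup <- df$probe_id[duplicated(df$probe_id)]
  if (length(dup))
    stop("duplicated probe id(s): ", paste(unique(dup), collapse = ", "))
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$probe_id
  if (!is.numeric(mat)) stop("non-numeric expression values")
  bad <- which(!is.finite(mat), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-finite value at probe ", rownames(mat)[bad[1, 1]],
         ", sample ", colnames(mat)[bad[1, 2]])
  mat
}

#' Write an expression matrix as TSV
#' @param mat probes x samples matrix with dimnames.
#' @param path output path.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(probe_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a flow event table from TSV
#'
#' Expects columns `dna`, `lc`, `width` (linear channels).
#' @param path TSV file path.
#' @param tube optional tube label ("kappa"/"lambda") stored as attribute.
#' @export
load_events <- function(path, tube = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("dna", "lc", "width")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("event TSV missing column(s): ",
                         paste(miss, collapse = ", "))
  for (nm in need)
    if (!is.numeric(df[[nm]])) stop("column '", nm, "' is not numeric")
  if (!is.null(tube)) attr(df, "tube") <- match.arg(tube, c("kappa", "lambda"))
  df[need]
}

#' Write a flow event table as TSV
#' @param events data frame with columns `dna`, `lc`, `width`.
#' @param path output path.
#' @export
write_events <- function(events, path) {
  utils::write.table(events[c("dna", "lc", "width")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a clinical covariate table from TSV
#'
#' Expects a `sample_id` column; remaining columns are covariates.
#' @param path TSV file path.
#' @export
load_clinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    stop("clinical TSV must contain a 'sample_id' column")
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup))
    stop("duplicated sample id(s): ", paste(unique(dup), collapse = ", "))
  df
}

#' Load a survival table from TSV
#'
#' Expects `sample_id` plus `<endpoint>_time` / `<endpoint>_event` column
#' pairs (endpoints `os` and/or `pfs`); times must be non-negative and
#' events 0/1.
#' @param path TSV file path.
#' @export
load_survival <- function(path) {
  df <- load_clinical(path)
  eps <- intersect(c("os", "pfs"),
                   sub("_time$", "", grep("_time$", names(df), value = TRUE)))
  if (!length(eps)) stop("survival TSV needs at least one *_time column")
  for (e in eps) {
    tc <- paste0(e, "_time"); ec <- paste0(e, "_event")
    if (!ec %in% names(df)) stop("missing column: ", ec)
    if (any(df[[tc]] < 0)) stop("negative time in ", tc)
    if (!all(df[[ec]] %in% c(0, 1))) stop("events in ", ec, " must be 0/1")
  }
  df
}
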