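# TSV readers/writers for all pipeline artifacts. Dialect: tab-separated,
# UTF-8, '.' decimal, "NA" for missing; expression files have gene ids in the
# first column ("gene_id") and sample ids in the header.

#' Write an expression matrix to TSV
#'
#' @param x a \linkS4class{StudyExpression}, \linkS4class{MergedCohort} or
#'   genes x samples matrix.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeExpressionTsv <- function(x, path) {
  m <- if (is(x, "StudyExpression") || is(x, "MergedCohort")) exprsMat(x)
       else as.matrix(x)
  # 17 significant digits so doubles round-trip exactly
  fm <- matrix(sprintf("%.17g", m), nrow(m), ncol(m), dimnames = dimnames(m))
  fm[is.na(m)] <- "NA"
  df <- data.frame(gene_id = rownames(m), fm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' Expects the dialect written by \code{\link{writeExpressionTsv}}: a header
#' of sample ids, gene ids in the first column. Ragged rows or duplicate
#' sample ids raise a named parse error; duplicate gene ids keep the first
#' occurrence with a warning.
#'
#' @param path input file.
#' @return numeric genes x samples matrix.
#' @export
readExpressionTsv <- function(path) {
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(unique(nf)) != 1)
    stop("readExpressionTsv: ragged rows in '", path, "'", call. = FALSE)
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "", comment.char = "")
  sampleIds <- colnames(df)[-1]
  if (anyDuplicated(sampleIds))
    stop("readExpressionTsv: duplicate sample id(s): ",
         paste(unique(sampleIds[duplicated(sampleIds)]), collapse = ", "),
         call. = FALSE)
  genes <- df[[1]]
  if (anyDuplicated(genes)) {
    warning("readExpressionTsv: duplicate gene id(s); keeping first occurrence")
    keep <- !duplicated(genes)
    df <- df[keep, , drop = FALSE]
    genes <- genes[keep]
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

#' Read a GEO-series-matrix-like TSV
#'
#' Same layout as \code{\link{readExpressionTsv}} but lines starting with
#' \code{!} (series-matrix annotation) are skipped first.
#'
#' @param path input file.
#' @return numeric genes x samples matrix.
#' @export
readSeriesMatrix <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  readExpressionTsv(tmp)
}

#' Write sample metadata to TSV
#'
#' @param metadata data.frame with columns \code{sample_id}, \code{study_id},
#'   \code{who_grade}, \code{recurrence}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeMetadataTsv <- function(metadata, path) {
  need <- c("sample_id", "study_id", "who_grade", "recurrence")
  stopifnot(all(need %in% names(metadata)))
  write.table(metadata[, need], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' @param path input file.
#' @return data.frame with columns \code{sample_id}, \code{study_id},
#'   \code{who_grade} (integer), \code{recurrence}.
#' @export
readMetadataTsv <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   quote = "", comment.char = "")
  need <- c("sample_id", "study_id", "who_grade", "recurrence")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("readMetadataTsv: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("readMetadataTsv: duplicate sample id(s)", call. = FALSE)
  df$who_grade <- as.integer(df$who_grade)
  df
}
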