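# Recurrence contingency analysis and module-level concordance between the
# reclassified grade 2 subgroups and the histological grades.

#' Build a 2x2 recurrence contingency table for two groups
#'
#' Samples with unknown recurrence are excluded, mirroring the restriction of
#' recurrence analysis to annotated cases.
#'
#' @param groups named per-sample group labels.
#' @param recurrence named per-sample \code{yes}/\code{no}/\code{unknown},
#'   aligned by name with \code{groups}.
#' @param groupA,groupB the two group labels to tabulate (rows A then B).
#' @return 2x2 integer matrix with columns \code{recurred},
#'   \code{not_recurred}.
#' @export
recurrenceTable <- function(groups, recurrence, groupA, groupB) {
  stopifnot(length(groups) == length(recurrence))
  if (!is.null(names(groups)) && !is.null(names(recurrence)))
    recurrence <- recurrence[names(groups)]
  known <- recurrence != "unknown"
  tab <- matrix(0L, 2, 2,
                dimnames = list(c(groupA, groupB), c("recurred", "not_recurred")))
  for (i in 1:2) {
    gl <- c(groupA, groupB)[i]
    sel <- known & groups == gl
    if (!any(sel))
      stop("recurrenceTable: group '", gl,
           "' is empty after dropping unknown recurrence", call. = FALSE)
    tab[i, 1] <- sum(recurrence[sel] == "yes")
    tab[i, 2] <- sum(recurrence[sel] == "no")
  }
  tab
}

#' Chi-square test on a 2x2 contingency table
#'
#' Pearson chi-square with one degree of freedom (optional Yates continuity
#' correction), via \code{stats::chisq.test}; Fisher's exact p-value is
#' carried along as a diagnostic for small expected counts but never replaces
#' the chi-square result. A zero row or column marginal yields statistic 0 and
#' p = 1 with a warning.
#'
#' @param table 2x2 count matrix.
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return list: \code{statistic}, \code{p_value}, \code{df},
#'   \code{fisher_p}, \code{correct}.
#' @export
chiSquareTest <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), sum(table) >= 1)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("chiSquareTest: zero marginal; returning statistic 0, p = 1")
    return(list(statistic = 0, p_value = 1, df = 1L, fisher_p = 1,
                correct = correct))
  }
  ct <- suppressWarnings(chisq.test(table, correct = correct))
  ft <- fisher.test(table)
  list(statistic = unname(ct$statistic), p_value = ct$p.value, df = 1L,
       fisher_p = ft$p.value, correct = correct)
}

#' Recurrence rate of a table row
#'
#' @param row length-2 vector \code{c(recurred, not_recurred)} (e.g. one row
#'   of \code{\link{recurrenceTable}}).
#' @return list: \code{percent} (exact), \code{percent_rounded} (nearest
#'   integer, the reporting convention), \code{recurred}, \code{total}.
#' @examples
#' recurrenceRate(c(9, 3))$percent_rounded  # 75
#' @export
recurrenceRate <- function(row) {
  stopifnot(length(row) == 2, all(row >= 0))
  total <- sum(row)
  if (total == 0) stop("recurrenceRate: zero total", call. = FALSE)
  pct <- 100 * row[[1]] / total
  list(percent = pct, percent_rounded = round(pct),
       recurred = row[[1]], total = total)
}

groupMedians <- function(scores, samples) {
  apply(scores[, samples, drop = FALSE], 1L, median)
}

#' Module-level concordance between two sample groups
#'
#' Per-module median meta-gene expression is computed in each group; the
#' Pearson correlation of the two median vectors across modules quantifies
#' biological concordance (e.g. grade 1 versus grade-1-like). Per-module
#' Mann-Whitney flags mark modules whose score distributions differ between
#' the groups.
#'
#' @param metagenes a \linkS4class{MetaGeneMatrix}.
#' @param samplesA,samplesB sample ids (or logical/integer indices) of the two
#'   groups.
#' @param pCut per-module significance cutoff (default 0.05).
#' @return list: \code{medians} (data.frame module, median_a, median_b,
#'   p_value, significant), \code{rho}, \code{rho_p}.
#' @export
moduleConcordance <- function(metagenes, samplesA, samplesB, pCut = 0.05) {
  stopifnot(is(metagenes, "MetaGeneMatrix"))
  s <- metageneScores(metagenes)
  if (nrow(s) < 3)
    stop("moduleConcordance: need >= 3 modules for a stable correlation",
         call. = FALSE)
  a <- s[, samplesA, drop = FALSE]
  b <- s[, samplesB, drop = FALSE]
  if (!ncol(a) || !ncol(b))
    stop("moduleConcordance: both groups must be non-empty", call. = FALSE)
  medA <- apply(a, 1L, median)
  medB <- apply(b, 1L, median)
  p <- vapply(seq_len(nrow(s)), function(i)
    suppressWarnings(wilcox.test(a[i, ], b[i, ])$p.value), numeric(1))
  ct <- cor.test(medA, medB)
  list(medians = data.frame(module = rownames(s), median_a = medA,
                            median_b = medB, p_value = p,
                            significant = p <= pCut, row.names = NULL,
                            stringsAsFactors = FALSE),
       rho = unname(ct$estimate), rho_p = ct$p.value)
}

#' Differential concordance across four groups
#'
#' Compares the grade 3 minus grade 1 separation with the grade-3-like minus
#' grade-1-like separation in module space: per module the two median
#' differences are paired, their Pearson correlation is reported, and each
#' module is classified by whether it is Mann-Whitney-significant in both,
#' one, or neither comparison.
#'
#' @param metagenes a \linkS4class{MetaGeneMatrix}.
#' @param groups named list with sample ids for \code{g1}, \code{g3},
#'   \code{g1like}, \code{g3like}.
#' @param pCut per-module significance cutoff (default 0.05).
#' @return list: \code{differences} (data.frame module, delta_grade,
#'   delta_subgroup, sig_grade, sig_subgroup, class), \code{rho},
#'   \code{rho_p}.
#' @export
differentialConcordance <- function(metagenes, groups, pCut = 0.05) {
  stopifnot(is(metagenes, "MetaGeneMatrix"),
            all(c("g1", "g3", "g1like", "g3like") %in% names(groups)))
  s <- metageneScores(metagenes)
  if (nrow(s) < 3)
    stop("differentialConcordance: need >= 3 modules", call. = FALSE)
  for (g in c("g1", "g3", "g1like", "g3like"))
    if (!length(groups[[g]]))
      stop("differentialConcordance: group '", g, "' is empty", call. = FALSE)
  dGrade <- groupMedians(s, groups$g3) - groupMedians(s, groups$g1)
  dSub <- groupMedians(s, groups$g3like) - groupMedians(s, groups$g1like)
  pG <- vapply(seq_len(nrow(s)), function(i) suppressWarnings(
    wilcox.test(s[i, groups$g3], s[i, groups$g1])$p.value), numeric(1))
  pS <- vapply(seq_len(nrow(s)), function(i) suppressWarnings(
    wilcox.test(s[i, groups$g3like], s[i, groups$g1like])$p.value), numeric(1))
  sigG <- pG <= pCut; sigS <- pS <= pCut
  cls <- ifelse(sigG & sigS, "both",
                ifelse(sigG | sigS, "one", "neither"))
  ct <- cor.test(dGrade, dSub)
  list(differences = data.frame(module = rownames(s), delta_grade = dGrade,
                                delta_subgroup = dSub, sig_grade = sigG,
                                sig_subgroup = sigS, class = cls,
                                row.names = NULL, stringsAsFactors = FALSE),
       rho = unname(ct$estimate), rho_p = ct$p.value)
}
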