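#' Reads per kilobase of transcript per million mapped reads
#'
#' `RPKM = 1e9 * c / (L * N)` for count `c`, gene length `L` (bp) and
#' library size `N` (mapped reads).
#'
#' @param counts Integer matrix, genes x samples.
#' @param gene_lengths Positive bp lengths, one per gene.
#' @param library_sizes Positive mapped-read totals, one per sample;
#'   defaults to the column sums of `counts`.
#' @return Numeric matrix of RPKM values with the dimnames of `counts`.
#' @export
computeRPKM <- function(counts, gene_lengths,
                        library_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (length(gene_lengths) != nrow(counts))
    stop("one gene length per row required")
  if (length(library_sizes) != ncol(counts))
    stop("one library size per column required")
  if (any(gene_lengths <= 0)) stop("gene lengths must be positive")
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  1e9 * sweep(counts / gene_lengths, 2, library_sizes, "/")
}

#' Replicate-averaged RPKM over the 15 experimental conditions
#'
#' @param se A `SummarizedExperiment` with a `counts` assay, `gene_length`
#'   row annotation and `condition` column annotation.
#' @return Numeric matrix, genes x conditions (canonical condition order).
#' @export
conditionRPKM <- function(se) {
  rpkm <- computeRPKM(SummarizedExperiment::assay(se, "counts"),
                      SummarizedExperiment::rowData(se)$gene_length)
  cond <- SummarizedExperiment::colData(se)$condition
  lev <- nshortConditions()
  out <- vapply(lev, function(cc)
    rowMeans(rpkm[, cond == cc, drop = FALSE]), numeric(nrow(rpkm)))
  rownames(out) <- rownames(se)
  out
}

# Method-of-moments common dispersion across genes, pooled over replicate
# groups: for each gene/condition with >=2 replicates, phi-hat =
# (var - mean)/mean^2; the common value is the count-weighted mean of the
# positive part.
estimateCommonDispersion <- function(counts, groups) {
  counts <- as.matrix(counts)
  ests <- c(); wts <- c()
  for (g in unique(groups)) {
    sub <- counts[, groups == g, drop = FALSE]
    if (ncol(sub) < 2) next
    m <- rowMeans(sub)
    v <- apply(sub, 1, stats::var)
    keep <- m > 1
    if (!any(keep)) next
    ests <- c(ests, pmax((v[keep] - m[keep]) / m[keep]^2, 0))
    wts <- c(wts, m[keep])
  }
  if (!length(ests)) return(0.1)
  max(sum(ests * wts) / sum(wts), 1e-6)
}

#' Negative-binomial exact test between two replicate groups
#'
#' Two-sided conditional exact test on library-size-adjusted counts: counts
#' are scaled to the geometric-mean library size, group totals are modeled
#' as negative binomial with the supplied dispersion, and the p-value sums
#' the probability of every split of the conditional total at most as
#' likely as the observed one. `dispersion = 0` gives the conditional
#' binomial (Poisson) exact test. The log2 fold change compares normalized
#' group means with a 0.5 pseudo-count.
#'
#' @param counts_a,counts_b Matrices (genes x replicates) or vectors for a
#'   single gene; group A is the reference (control).
#' @param dispersion Common NB dispersion (scalar) or per-gene vector.
#' @param lib_a,lib_b Library sizes per replicate; default column sums.
#' @return data.frame with `log2FC`, `p_value` and an `untestable` flag for
#'   genes with all-zero counts in both groups (reported as p = 1, lfc = 0).
#' @export
nbExactTest <- function(counts_a, counts_b, dispersion,
                        lib_a = NULL, lib_b = NULL) {
  if (is.null(dim(counts_a))) counts_a <- matrix(counts_a, nrow = 1)
  if (is.null(dim(counts_b))) counts_b <- matrix(counts_b, nrow = 1)
  stopifnot(nrow(counts_a) == nrow(counts_b))
  if (is.null(lib_a)) lib_a <- colSums(counts_a)
  if (is.null(lib_b)) lib_b <- colSums(counts_b)
  na <- ncol(counts_a); nb <- ncol(counts_b)
  if (na < 1 || nb < 1) stop("at least one replicate per group")
  ref <- exp(mean(log(c(lib_a, lib_b))))
  adj_a <- sweep(counts_a, 2, ref / lib_a, "*")
  adj_b <- sweep(counts_b, 2, ref / lib_b, "*")
  sa <- rowSums(adj_a); sb <- rowSums(adj_b)
  p <- .nbExactPvals(round(sa), round(sb), na, nb, as.numeric(dispersion))
  lfc <- log2((sb / nb + 0.5) / (sa / na + 0.5))
  untestable <- (sa + sb) == 0
  lfc[untestable] <- 0
  p[untestable] <- 1
  data.frame(log2FC = lfc, p_value = p, untestable = untestable)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment.
#'
#' @param p_values Numeric vector in `[0, 1]`; `NA`/`NaN` are rejected.
#' @return Adjusted values in `[0, 1]`.
#' @export
bhAdjust <- function(p_values) {
  if (any(!is.finite(p_values))) stop("non-finite p-values")
  if (any(p_values < 0 | p_values > 1)) stop("p-values outside [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Differential expression of every treatment condition against the
#' ammonium pretreatment control
#'
#' Runs the NB exact test for each of the 12 treatment-by-time comparisons
#' versus the `preNH4` samples, with a common method-of-moments dispersion
#' (optionally shrunk per-gene) and BH adjustment within each comparison.
#'
#' @param se `SummarizedExperiment` of counts with the nitrogen-shift
#'   sample annotation.
#' @param dispersion Optional dispersion; estimated from the data when
#'   `NULL`.
#' @param shrink Weight in `[0, 1]` pulling per-gene moment estimates
#'   toward the common dispersion (1 = common only, the default).
#' @return data.frame with `gene_id`, `comparison`, `log2FC`, `p_value`,
#'   `fdr`.
#' @export
deTable <- function(se, dispersion = NULL, shrink = 1) {
  counts <- SummarizedExperiment::assay(se, "counts")
  cd <- SummarizedExperiment::colData(se)
  if (is.null(dispersion))
    dispersion <- estimateCommonDispersion(counts, cd$condition)
  if (shrink < 1) {
    m <- rowMeans(counts); v <- apply(counts, 1, stats::var)
    tag <- pmax((v - m) / pmax(m, 1)^2, 0)
    dispersion <- shrink * dispersion + (1 - shrink) * tag
  }
  ctrl <- counts[, cd$condition == "preNH4", drop = FALSE]
  lib <- colSums(counts)
  out <- lapply(nshortComparisons(), function(cmp) {
    trt <- counts[, cd$condition == cmp, drop = FALSE]
    res <- nbExactTest(ctrl, trt, dispersion,
                       lib_a = lib[cd$condition == "preNH4"],
                       lib_b = lib[cd$condition == cmp])
    data.frame(gene_id = rownames(counts), comparison = cmp,
               log2FC = res$log2FC, p_value = res$p_value,
               fdr = bhAdjust(res$p_value), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read an externally computed differential-expression table
#'
#' Plug-in point for DE results computed outside the package (for example
#' an edgeR exact-test table): a TSV with columns `gene_id`, `comparison`,
#' `log2FC`, `p_value` (or `p`), `fdr`.
#'
#' @param path TSV path.
#' @return data.frame in the layout of [deTable()].
#' @export
readDETable <- function(path) {
  de <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("p" %in% names(de) && !"p_value" %in% names(de))
    names(de)[names(de) == "p"] <- "p_value"
  need <- c("gene_id", "comparison", "log2FC", "p_value", "fdr")
  if (!all(need %in% names(de)))
    stop("DE table needs columns: ", paste(need, collapse = ", "))
  de[need]
}

#' Coded expression patterns
#'
#' Collapses per-comparison DE calls into the three-state code used for
#' response-type binning: +1 = significantly up (fdr < alpha, log2FC > 0),
#' -1 = significantly down, 0 = not significant, over the 12 fixed
#' treatment-by-time comparisons.
#'
#' @param de DE table from [deTable()] or [readDETable()].
#' @param alpha FDR threshold (default 0.05).
#' @return Integer matrix genes x 12 comparisons with entries in
#'   `{-1, 0, 1}`.
#' @export
codePatterns <- function(de, alpha = 0.05) {
  cmps <- nshortComparisons()
  genes <- unique(de$gene_id)
  tab <- table(de$gene_id)
  if (any(tab != length(cmps))) {
    bad <- names(tab)[tab != length(cmps)]
    stop("genes missing comparisons: ",
         paste(head(bad, 5), collapse = ", "))
  }
  code <- integer(nrow(de))
  sig <- de$fdr < alpha
  code[sig & de$log2FC > 0] <- 1L
  code[sig & de$log2FC < 0] <- -1L
  out <- matrix(0L, length(genes), length(cmps),
                dimnames = list(genes, cmps))
  out[cbind(match(de$gene_id, genes), match(de$comparison, cmps))] <- code
  out
}

#' Size of the coded-pattern space
#'
#' Number of distinct coded patterns over `n_comparisons` comparisons with
#' `n_states` states each (3^12 = 531,441 for this design).
#'
#' @param n_comparisons Nonnegative comparison count.
#' @param n_states States per comparison (default 3).
#' @return `n_states ^ n_comparisons`.
#' @export
countPossiblePatterns <- function(n_comparisons, n_states = 3) {
  stopifnot(n_comparisons >= 0, n_states >= 1)
  n_states^n_comparisons
}
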