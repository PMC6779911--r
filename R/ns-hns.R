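#' Candidate gene filter for the nitrate-specificity metric
#'
#' A gene is a candidate when its mean replicate-averaged RPKM over all
#' conditions exceeds 5 and its RPKM after the nitrate-spiked pretreatment
#' strictly exceeds the RPKM after nitrogen starvation (i.e. the gene is
#' generally upregulated on an N source).
#'
#' @param cond_rpkm Genes x conditions RPKM matrix ([conditionRPKM()]).
#' @param min_rpkm Mean-RPKM threshold (default 5).
#' @return Character vector of candidate gene ids.
#' @export
candidateFilter <- function(cond_rpkm, min_rpkm = 5) {
  if (!all(c("preNO3", "preN0") %in% colnames(cond_rpkm)))
    stop("pretreatment conditions missing from the expression matrix")
  keep <- rowMeans(cond_rpkm) > min_rpkm &
    cond_rpkm[, "preNO3"] > cond_rpkm[, "preN0"]
  rownames(cond_rpkm)[keep]
}

#' Three-dimensional nitrate-specificity scores
#'
#' On replicate-averaged `log2(RPKM + 1)` (subtraction on raw RPKM would be
#' dominated by high expressors; the scale is configurable), computes for
#' each candidate gene three contrasts: ammonium repression at 15 min
#' relative to the nitrate pretreatment (`d1`), nitrate induction at 15 min
#' relative to ammonium at 15 min (`d2`), and nitrate induction at 15 min
#' relative to nitrite at 15 min (`d3`); each is standardized over the
#' candidate population (`z1..z3`). The composite score is the mean of the
#' three z-values.
#'
#' @param cond_rpkm Genes x conditions RPKM matrix.
#' @param candidates Candidate gene ids from [candidateFilter()].
#' @param scale One of `"log2p1"` (default), `"raw"`,
#'   `"standardized_rpkm"` (per-gene z-scored RPKM before subtraction).
#' @return data.frame with one row per candidate: `gene_id`, `d1..d3`,
#'   `z1..z3`, `composite`.
#' @export
nsDimensions <- function(cond_rpkm, candidates,
                         scale = c("log2p1", "raw", "standardized_rpkm")) {
  scale <- match.arg(scale)
  if (!length(candidates)) stop("no candidate genes")
  x <- cond_rpkm[candidates, , drop = FALSE]
  x <- switch(scale,
    log2p1 = log2(x + 1),
    raw = x,
    standardized_rpkm = {
      s <- apply(x, 1, sd)
      (x - rowMeans(x)) / ifelse(s > 0, s, 1)
    })
  d1 <- x[, "preNO3"] - x[, "NH4_15min"]
  d2 <- x[, "NO3_15min"] - x[, "NH4_15min"]
  d3 <- x[, "NO3_15min"] - x[, "NO2_15min"]
  zs <- lapply(list(d1, d2, d3), function(d) {
    s <- sd(d)
    if (s == 0) stop("degenerate input: a specificity dimension has zero sd")
    (d - mean(d)) / s
  })
  data.frame(gene_id = candidates, d1 = d1, d2 = d2, d3 = d3,
             z1 = zs[[1]], z2 = zs[[2]], z3 = zs[[3]],
             composite = (zs[[1]] + zs[[2]] + zs[[3]]) / 3,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call nitrate-specific (NS) genes by percentile gating
#'
#' A candidate passes a dimension when its standardized contrast strictly
#' exceeds the empirical percentile (linear-interpolation definition) of
#' that dimension over candidates; NS genes pass all three.
#'
#' @param scores data.frame from [nsDimensions()].
#' @param percentile Gate in (0, 100), default 85.
#' @return `scores` with added logical columns `pass1..pass3`, `ns`.
#' @export
nsCall <- function(scores, percentile = 85) {
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must be inside (0, 100)")
  for (k in 1:3) {
    z <- scores[[paste0("z", k)]]
    thr <- quantile(z, percentile / 100, type = 7, names = FALSE)
    scores[[paste0("pass", k)]] <- z > thr
  }
  scores$ns <- scores$pass1 & scores$pass2 & scores$pass3
  scores
}

#' Intersect NS genes with nitrate-specific response types
#'
#' Highly nitrate-sensitive (HNS) genes are NS genes that also belong to a
#' nitrate-specific RT from the coded-pattern clustering.
#'
#' @param ns_set NS gene ids.
#' @param ns_rt_members Gene ids belonging to nitrate-flagged RTs.
#' @return Character vector of HNS gene ids.
#' @export
hnsIntersect <- function(ns_set, ns_rt_members) {
  intersect(ns_set, ns_rt_members)
}

#' Full NS/HNS calling from expression, RT assignment and RT flags
#'
#' Convenience wrapper chaining [candidateFilter()], [nsDimensions()],
#' [nsCall()] and [hnsIntersect()].
#'
#' @param cond_rpkm Genes x conditions RPKM matrix.
#' @param assignment RT assignment from [rtBin()].
#' @param ns_rt_flags Logical vector over RT ids from [labelNitrateRTs()].
#' @param percentile,min_rpkm,scale Passed through.
#' @return List with `scores` (gated score table), `ns` and `hns` gene id
#'   vectors, and `candidates`.
#' @export
callHNS <- function(cond_rpkm, assignment, ns_rt_flags,
                    percentile = 85, min_rpkm = 5, scale = "log2p1") {
  candidates <- candidateFilter(cond_rpkm, min_rpkm)
  scores <- nsCall(nsDimensions(cond_rpkm, candidates, scale), percentile)
  ns <- scores$gene_id[scores$ns]
  ns_rts <- names(ns_rt_flags)[ns_rt_flags]
  members <- names(assignment)[as.character(assignment) %in% ns_rts]
  list(scores = scores, candidates = candidates, ns = ns,
       hns = hnsIntersect(ns, members))
}
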