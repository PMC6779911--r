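#' One-minus-Pearson distance between coded patterns
#'
#' `d(u, v) = 1 - cor(u, v)` in `[0, 2]`. Pearson correlation is undefined
#' for zero-variance vectors (e.g. the all-zero never-DE pattern); by
#' convention identical constant vectors are at distance 0 and a constant
#' vector is at distance 1 from any non-identical vector, which groups
#' never-DE genes together without asserting similarity to responders.
#'
#' @param patterns Numeric matrix, items x positions (rows are compared).
#' @return A symmetric distance matrix.
#' @export
patternDistance <- function(patterns) {
  patterns <- as.matrix(patterns)
  if (nrow(patterns) < 2) stop("need at least two patterns")
  n <- nrow(patterns)
  sds <- apply(patterns, 1, sd)
  const <- sds == 0
  d <- matrix(1, n, n, dimnames = list(rownames(patterns),
                                       rownames(patterns)))
  if (any(!const)) {
    nc <- which(!const)
    cc <- cor(t(patterns[nc, , drop = FALSE]))
    d[nc, nc] <- 1 - cc
  }
  # constant rows: 0 to identical rows (constant or not), else 1
  for (i in which(const)) {
    same <- vapply(seq_len(n), function(j)
      all(patterns[i, ] == patterns[j, ]), logical(1))
    d[i, same] <- 0
    d[same, i] <- 0
  }
  diag(d) <- 0
  d
}

#' UPGMA (average-linkage) clustering of a distance matrix
#'
#' Agglomerative clustering where the inter-cluster distance is the
#' unweighted mean over all cross pairs. `members` carries multiplicities
#' so that clustering deduplicated items is exactly equivalent to
#' clustering the expanded data.
#'
#' @param dist_matrix Symmetric distance matrix (no `NA`s).
#' @param members Optional item multiplicities.
#' @return An `hclust` object.
#' @export
averageLinkage <- function(dist_matrix, members = NULL) {
  dist_matrix <- as.matrix(dist_matrix)
  if (any(!is.finite(dist_matrix))) stop("non-finite distances")
  d <- as.dist(dist_matrix)
  if (is.null(members)) hclust(d, method = "average")
  else hclust(d, method = "average", members = members)
}

#' Cut a dendrogram into exactly k clusters
#'
#' Undoes the last `k - 1` merges; cluster ids are assigned by order of
#' first member appearance.
#'
#' @param dendro `hclust` object.
#' @param k Target cluster count, `1 <= k <= n`.
#' @return Integer vector of cluster ids named by item.
#' @export
cutToK <- function(dendro, k) {
  n <- length(dendro$order)
  if (k < 1 || k > n) stop("k must be between 1 and the number of items")
  cutree(dendro, k = k)
}

#' Bin coded expression patterns into response types
#'
#' Clusters the coded patterns hierarchically (one-minus-Pearson distance,
#' average linkage) and cuts the dendrogram into `k` response types (RTs).
#' Identical patterns are deduplicated and clustered with multiplicity
#' weights, which leaves the UPGMA tree unchanged while keeping the
#' distance matrix at the size of the distinct-pattern set. When `k`
#' exceeds the number of distinct patterns every distinct pattern becomes
#' its own RT.
#'
#' @param patterns Coded pattern matrix from [codePatterns()].
#' @param k Number of response types (default 201).
#' @return A list with `assignment` (named integer vector gene -> RT id,
#'   RT ids numbered by first member), `k` (RT count actually produced) and
#'   `dendrogram` (the `hclust` tree over distinct patterns).
#' @export
rtBin <- function(patterns, k = 201) {
  patterns <- as.matrix(patterns)
  key <- apply(patterns, 1, paste, collapse = ",")
  uniq <- !duplicated(key)
  up <- patterns[uniq, , drop = FALSE]
  ukey <- key[uniq]
  mult <- as.vector(table(key)[ukey])
  if (nrow(up) == 1) {
    assign <- setNames(rep(1L, nrow(patterns)), rownames(patterns))
    return(list(assignment = assign, k = 1L, dendrogram = NULL))
  }
  dendro <- averageLinkage(patternDistance(up), members = mult)
  keff <- min(k, nrow(up))
  ucl <- cutToK(dendro, keff)
  assign <- ucl[match(key, ukey)]
  # canonical numbering by first gene carrying each RT
  first <- !duplicated(assign)
  relabel <- setNames(seq_len(keff), assign[first])
  assign <- relabel[as.character(assign)]
  names(assign) <- rownames(patterns)
  list(assignment = assign, k = keff, dendrogram = dendro)
}

#' Average standardized expression profile of each response type
#'
#' Per gene, the replicate-averaged RPKM across the 15 conditions is
#' z-scored (zero-variance genes contribute an all-zero profile); the RT
#' profile is the member mean.
#'
#' @param cond_rpkm Genes x conditions RPKM matrix ([conditionRPKM()]).
#' @param assignment Named RT assignment from [rtBin()].
#' @return A list with `profiles` (RT x condition matrix) and `sizes`.
#' @export
summarizeRTs <- function(cond_rpkm, assignment) {
  genes <- names(assignment)
  if (!all(genes %in% rownames(cond_rpkm)))
    stop("assignment covers genes absent from the expression matrix")
  x <- cond_rpkm[genes, , drop = FALSE]
  mu <- rowMeans(x); s <- apply(x, 1, sd)
  z <- (x - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  rts <- sort(unique(assignment))
  prof <- t(vapply(rts, function(r)
    colMeans(z[assignment == r, , drop = FALSE]), numeric(ncol(z))))
  rownames(prof) <- rts
  sizes <- as.vector(table(factor(assignment, levels = rts)))
  names(sizes) <- rts
  list(profiles = prof, sizes = sizes)
}

#' Flag nitrate-specific response types
#'
#' An RT is nitrate-specific when its mean standardized expression over the
#' early nitrate conditions (NO3 at 15 and 45 min) exceeds each of the
#' corresponding ammonium, nitrite and no-N means by more than `margin`.
#'
#' @param profiles RT profile matrix from [summarizeRTs()].
#' @param margin Required excess (default 0).
#' @return Named logical vector over RT ids.
#' @export
labelNitrateRTs <- function(profiles, margin = 0) {
  need <- c("NO3_15min", "NO3_45min", "NH4_15min", "NH4_45min",
            "NO2_15min", "NO2_45min", "noN_15min", "noN_45min")
  if (!all(need %in% colnames(profiles)))
    stop("profiles missing early-timepoint conditions")
  no3 <- rowMeans(profiles[, c("NO3_15min", "NO3_45min"), drop = FALSE])
  nh4 <- rowMeans(profiles[, c("NH4_15min", "NH4_45min"), drop = FALSE])
  no2 <- rowMeans(profiles[, c("NO2_15min", "NO2_45min"), drop = FALSE])
  non <- rowMeans(profiles[, c("noN_15min", "noN_45min"), drop = FALSE])
  out <- (no3 > nh4 + margin) & (no3 > no2 + margin) & (no3 > non + margin)
  setNames(out, rownames(profiles))
}
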