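#' Roll peptide abundances up to protein abundances
#'
#' Reference-scaled median rollup of log2 peptide abundances: within each
#' protein the reference peptide is the one observed in the most channels
#' (ties broken by highest mean abundance); every other peptide is shifted
#' by the median difference to the reference over their shared observed
#' channels (a peptide sharing no channel with the reference is dropped
#' with a warning); the protein value per channel is the median over
#' shifted peptides. Peptides mapping to more than one protein are rolled
#' into protein-group rows (ids joined with `;`) and flagged.
#'
#' @param peptides data.frame with `peptide_id`, `protein_id` (use
#'   `;`-separated ids for shared peptides) and one numeric log2 abundance
#'   column per sample channel (`NA` = missing).
#' @return A list with `matrix` (protein x channel log2 abundances),
#'   `provenance` (data.frame: protein id, peptide count, reference
#'   peptide, group flag).
#' @export
rollupPeptides <- function(peptides) {
  meta_cols <- c("peptide_id", "protein_id")
  chan <- setdiff(names(peptides), meta_cols)
  vals <- as.matrix(peptides[, chan, drop = FALSE])
  if (any(rowSums(!is.na(vals)) < 1))
    stop("every peptide needs at least one observed channel")
  is_group <- grepl(";", peptides$protein_id, fixed = TRUE)
  prots <- unique(peptides$protein_id)
  mat <- matrix(NA_real_, length(prots), length(chan),
                dimnames = list(prots, chan))
  prov <- data.frame(protein_id = prots,
                     n_peptides = 0L, reference = NA_character_,
                     is_group = prots %in% peptides$protein_id[is_group],
                     stringsAsFactors = FALSE)
  for (pi in seq_along(prots)) {
    rows <- which(peptides$protein_id == prots[pi])
    sub <- vals[rows, , drop = FALSE]
    nobs <- rowSums(!is.na(sub))
    mabund <- rowMeans(sub, na.rm = TRUE)
    ref <- order(-nobs, -mabund)[1]
    shifted <- matrix(NA_real_, 0, length(chan))
    kept <- 0L
    for (p in seq_along(rows)) {
      shared <- !is.na(sub[ref, ]) & !is.na(sub[p, ])
      if (!any(shared)) {
        warning("peptide ", peptides$peptide_id[rows[p]],
                " shares no channel with the reference; dropped")
        next
      }
      shift <- median(sub[ref, shared] - sub[p, shared])
      shifted <- rbind(shifted, sub[p, ] + shift)
      kept <- kept + 1L
    }
    mat[pi, ] <- apply(shifted, 2, function(col)
      if (all(is.na(col))) NA_real_ else median(col, na.rm = TRUE))
    prov$n_peptides[pi] <- kept
    prov$reference[pi] <- peptides$peptide_id[rows[ref]]
  }
  list(matrix = mat, provenance = prov)
}

#' Central-tendency normalization
#'
#' Subtracts each sample channel's median so every channel has median 0.
#' Idempotent.
#'
#' @param mat Protein x channel log2 matrix (`NA` allowed).
#' @return Normalized matrix.
#' @export
centralTendencyNormalize <- function(mat) {
  meds <- apply(mat, 2, median, na.rm = TRUE)
  if (any(!is.finite(meds))) stop("a channel has no finite values")
  sweep(mat, 2, meds, "-")
}

#' Two-stage standardization of protein profiles
#'
#' Per protein: z-score within each treatment block, then z-score the
#' concatenated vector so each row has mean 0 and sd 1. Zero-variance rows
#' become all zeros; a block of size one cannot be scaled and is passed
#' through centered only (flagged in the result's `single_blocks`
#' attribute).
#'
#' @param mat Protein x channel matrix.
#' @param treatment_blocks Factor/character assigning each channel to a
#'   treatment block.
#' @return Standardized matrix of the same shape.
#' @export
standardizeTwoStage <- function(mat, treatment_blocks) {
  if (length(treatment_blocks) != ncol(mat))
    stop("one block per channel required")
  zrow <- function(x) {
    if (all(is.na(x))) return(x)
    s <- sd(x, na.rm = TRUE); m <- mean(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) return(ifelse(is.na(x), NA, 0))
    (x - m) / s
  }
  single <- names(which(table(treatment_blocks) == 1))
  out <- mat
  for (b in unique(treatment_blocks)) {
    cols <- which(treatment_blocks == b)
    if (length(cols) == 1) {
      out[, cols] <- mat[, cols] - rowMeans(mat[, cols, drop = FALSE],
                                            na.rm = TRUE)
    } else {
      out[, cols] <- t(apply(mat[, cols, drop = FALSE], 1, zrow))
    }
  }
  out <- t(apply(out, 1, zrow))
  dimnames(out) <- dimnames(mat)
  attr(out, "single_blocks") <- single
  out
}

#' K-means clustering of standardized protein profiles into proteome
#' clusters (PCs)
#'
#' K-means on row-standardized profiles; on z-scored rows the Euclidean
#' metric is a monotone transform of one-minus-Pearson correlation
#' distance. Rows with missing values are mean-imputed (0 on the
#' standardized scale) for clustering only. Empty clusters are repaired by
#' splitting the largest cluster. Seed-deterministic.
#'
#' @param mat Standardized protein x channel matrix.
#' @param k Cluster count (default 100).
#' @param seed Integer seed.
#' @param exclude_groups Drop protein-group rows (ids containing `;`).
#' @return Named integer vector protein -> PC id.
#' @export
clusterProteome <- function(mat, k = 100, seed = 7L, exclude_groups = TRUE) {
  if (exclude_groups)
    mat <- mat[!grepl(";", rownames(mat), fixed = TRUE), , drop = FALSE]
  if (k > nrow(mat)) stop("k exceeds the number of proteins")
  m <- mat
  m[is.na(m)] <- 0
  set.seed(seed)
  fit <- suppressWarnings(
    kmeans(m, centers = k, iter.max = 100, nstart = 5,
           algorithm = "Lloyd"))
  cl <- fit$cluster
  # repair empties (possible under Lloyd): split the largest cluster
  present <- sort(unique(cl))
  missing <- setdiff(seq_len(k), present)
  for (mc in missing) {
    big <- as.integer(names(which.max(table(cl))))
    idx <- which(cl == big)
    take <- idx[seq_len(ceiling(length(idx) / 2))]
    cl[take] <- mc
  }
  setNames(as.integer(cl), rownames(m))
}

#' Hypergeometric enrichment of response types within proteome clusters
#'
#' For every RT x PC pair over the genes carrying both assignments:
#' upper-tail hypergeometric probability of the observed overlap,
#' BH-adjusted across all pairs, with fold enrichment relative to the
#' expected overlap.
#'
#' @param rt_assignment Named RT assignment (gene -> RT).
#' @param pc_assignment Named PC assignment (gene -> PC).
#' @return data.frame with `rt`, `pc`, `overlap`, `rt_size`, `pc_size`,
#'   `population`, `p_value`, `q_value`, `fold`.
#' @export
rtPcEnrichment <- function(rt_assignment, pc_assignment) {
  genes <- intersect(names(rt_assignment), names(pc_assignment))
  if (!length(genes)) stop("empty population: no genes share assignments")
  rt <- rt_assignment[genes]; pc <- pc_assignment[genes]
  N <- length(genes)
  tab <- table(rt, pc)
  rt_sz <- table(rt); pc_sz <- table(pc)
  out <- expand.grid(rt = rownames(tab), pc = colnames(tab),
                     stringsAsFactors = FALSE)
  out$overlap <- as.vector(tab)
  out$rt_size <- as.vector(rt_sz[out$rt])
  out$pc_size <- as.vector(pc_sz[out$pc])
  out$population <- N
  # P(X >= overlap), X ~ Hypergeom(draws = pc_size, successes = rt_size)
  out$p_value <- phyper(out$overlap - 1, out$rt_size,
                        N - out$rt_size, out$pc_size, lower.tail = FALSE)
  out$q_value <- bhAdjust(out$p_value)
  out$fold <- out$overlap / (out$rt_size * out$pc_size / N)
  out[order(out$p_value), ]
}
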