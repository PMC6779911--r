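#' Read motifs in MEME minimal text format
#'
#' Parses the minimal motif format (version line, optional alphabet,
#' strands and background lines, one or more `MOTIF` blocks each followed
#' by a `letter-probability matrix:` section).
#'
#' @param path Path to a MEME minimal format file.
#' @return A list of motifs; each is a list with `name`, `matrix` (4 x w
#'   probability matrix, rows A,C,G,T), `nsites`, `background` (named
#'   frequency vector from the file, uniform when absent).
#' @export
readMemeMotifs <- function(path) {
  lines <- readLines(path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bgl <- grep("^Background letter frequencies", lines)
  if (length(bgl)) {
    toks <- strsplit(trimws(lines[bgl[1] + 1]), "\\s+")[[1]]
    vals <- as.numeric(toks[seq(2, length(toks), 2)])
    names(vals) <- toks[seq(1, length(toks), 2)]
    bg <- vals[c("A", "C", "G", "T")]
  }
  starts <- grep("^MOTIF\\s", lines)
  if (!length(starts)) stop("no MOTIF entries in ", path)
  motifs <- lapply(starts, function(s) {
    name <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    h <- grep("letter-probability matrix:", lines[s:length(lines)])[1] + s - 1
    hdr <- lines[h]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hdr))
    nsites <- if (grepl("nsites=", hdr))
      as.numeric(sub(".*nsites=\\s*([0-9.]+).*", "\\1", hdr)) else NA_real_
    rows <- lines[(h + 1):(h + w)]
    m <- t(vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]][1:4]), numeric(4)))
    if (any(abs(rowSums(m) - 1) > 1e-6))
      stop("probability rows of motif ", name, " do not sum to 1")
    mat <- t(m)
    rownames(mat) <- c("A", "C", "G", "T")
    list(name = name, matrix = mat, nsites = nsites, background = bg)
  })
  names(motifs) <- vapply(motifs, `[[`, character(1), "name")
  motifs
}

#' The packaged synthetic ETS-like motif
#'
#' A synthetic 9 bp position probability matrix with the core `CCGGAAG`
#' consensus of an ETS-class binding site, shipped for simulation and
#' examples (it is constructed, not discovered from data).
#'
#' @return A single motif (see [readMemeMotifs()]).
#' @export
nitrosenseMotif <- function() {
  readMemeMotifs(system.file("extdata", "hns_a_synthetic.meme",
                             package = "nitrosense"))[[1]]
}

#' Extract promoter sequences upstream of start codons
#'
#' For a `+` strand gene the promoter is the `length` bases ending
#' immediately before the start codon; for a `-` strand gene, the reverse
#' complement of the bases immediately following the annotated end.
#' Coordinates are 0-based half-open. Promoters running off a contig edge
#' are truncated and flagged; an upstream neighbouring gene is deliberately
#' not truncated against.
#'
#' @param genome Named [Biostrings::DNAStringSet] of contigs.
#' @param genes data.frame with `gene_id`, `contig`, `start`, `end`
#'   (0-based half-open), `strand` (`+`/`-`).
#' @param length Promoter length in bp (default 500).
#' @return [Biostrings::DNAStringSet] named by gene id with a logical
#'   `truncated` attribute.
#' @export
extractPromoters <- function(genome, genes, length = 500L) {
  if (!all(genes$contig %in% names(genome)))
    stop("gene on unknown contig")
  widths <- setNames(Biostrings::width(genome), names(genome))
  seqs <- character(nrow(genes))
  trunc <- logical(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    W <- widths[[genes$contig[i]]]
    if (genes$start[i] < 0 || genes$end[i] > W || genes$start[i] >= genes$end[i])
      stop("gene ", genes$gene_id[i], " lies off its contig")
    if (genes$strand[i] == "+") {
      from0 <- max(genes$start[i] - length, 0)
      to0 <- genes$start[i]
      s <- Biostrings::subseq(genome[[genes$contig[i]]], from0 + 1, to0)
    } else {
      from0 <- genes$end[i]
      to0 <- min(genes$end[i] + length, W)
      s <- Biostrings::reverseComplement(
        Biostrings::subseq(genome[[genes$contig[i]]], from0 + 1, to0))
    }
    trunc[i] <- (to0 - from0) < length
    seqs[i] <- as.character(s)
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- genes$gene_id
  attr(out, "truncated") <- setNames(trunc, genes$gene_id)
  out
}

# log2-odds score matrix (bits) after background-weighted pseudocount
# regularization: p' = (p + pc * bg) / (1 + pc).
.scoreMatrix <- function(pwm, background, pseudocount = 0.1) {
  p <- sweep(pwm$matrix + pseudocount * background, 2,
             1 + pseudocount, "/")
  log2(p / background)
}

# Exact null score distribution by dynamic programming over the discretized
# per-position scores: integer bins at `granularity` bits; returns the
# upper-tail probability P(score >= s) for every achievable integer score.
.scoreTailDistribution <- function(smat, background, granularity = 1e-3) {
  ints <- round(smat / granularity)
  w <- ncol(ints)
  lo <- sum(apply(ints, 2, min)); hi <- sum(apply(ints, 2, max))
  probs <- numeric(hi - lo + 1)   # index = score - lo + 1
  # position 1
  off1 <- sum(apply(ints[, -1, drop = FALSE], 2, min))
  cur_lo <- min(ints[, 1]); cur_hi <- max(ints[, 1])
  cur <- numeric(cur_hi - cur_lo + 1)
  for (a in 1:4) {
    idx <- ints[a, 1] - cur_lo + 1
    cur[idx] <- cur[idx] + background[a]
  }
  for (j in seq_len(w)[-1]) {
    new_lo <- cur_lo + min(ints[, j]); new_hi <- cur_hi + max(ints[, j])
    nxt <- numeric(new_hi - new_lo + 1)
    for (a in 1:4) {
      sh <- ints[a, j]
      rng <- (cur_lo + sh - new_lo + 1):(cur_hi + sh - new_lo + 1)
      nxt[rng] <- nxt[rng] + cur * background[a]
    }
    cur <- nxt; cur_lo <- new_lo; cur_hi <- new_hi
  }
  tail <- rev(cumsum(rev(cur)))
  list(lo = cur_lo, hi = cur_hi, tail = tail,
       granularity = granularity, ints = ints)
}

# score every window of an integer-coded sequence (A=1..T=4, NA for
# ambiguous) against an integer score matrix; windows touching NA -> NA
.windowScores <- function(codes, ints) {
  w <- ncol(ints); L <- length(codes)
  if (L < w) return(integer(0))
  n <- L - w + 1
  tot <- rep(0L, n)
  bad <- rep(FALSE, n)
  for (j in seq_len(w)) {
    cj <- codes[j:(j + n - 1)]
    bad <- bad | is.na(cj)
    v <- ints[cbind(ifelse(is.na(cj), 1L, cj), j)]
    tot <- tot + v
  }
  tot[bad] <- NA_integer_
  tot
}

.revcompMotif <- function(pwm) {
  m <- pwm$matrix[4:1, ncol(pwm$matrix):1, drop = FALSE]
  rownames(m) <- c("A", "C", "G", "T")
  pwm$matrix <- m
  pwm
}

#' Scan promoters with a PWM using exact dynamic-programming p-values
#'
#' Scores every window on both strands with the log2-odds matrix (bits) and
#' assigns each window the probability that a background-generated window
#' scores at least as high, computed exactly by dynamic programming over
#' the discretized per-position score distribution. Windows containing
#' ambiguous bases are skipped; hits are windows with `p <= p_threshold`.
#'
#' @param promoters [Biostrings::DNAStringSet].
#' @param pwm A motif from [readMemeMotifs()].
#' @param p_threshold Hit threshold (default 1e-4).
#' @param background Optional named A/C/G/T frequencies; by default the
#'   0-order composition of the scanned promoter set.
#' @param pseudocount Background-weighted pseudocount (default 0.1).
#' @param granularity Score discretization in bits (default 1e-3).
#' @return data.frame with `gene_id`, `start` (0-based), `strand`, `score`
#'   (bits), `p_value`.
#' @export
scanPromoters <- function(promoters, pwm, p_threshold = 1e-4,
                          background = NULL, pseudocount = 0.1,
                          granularity = 1e-3) {
  if (is.null(background)) {
    freq <- colSums(Biostrings::alphabetFrequency(promoters)[,
      c("A", "C", "G", "T"), drop = FALSE])
    background <- freq / sum(freq)
  }
  background <- background[c("A", "C", "G", "T")]
  if (any(background <= 0)) stop("background frequencies must be positive")
  fwd <- pwm; rev <- .revcompMotif(pwm)
  sm_f <- .scoreMatrix(fwd, background, pseudocount)
  sm_r <- .scoreMatrix(rev, background, pseudocount)
  dp_f <- .scoreTailDistribution(sm_f, background, granularity)
  dp_r <- .scoreTailDistribution(sm_r, background, granularity)
  lut <- list(`+` = dp_f, `-` = dp_r)
  hits <- list()
  for (g in seq_along(promoters)) {
    codes <- match(strsplit(as.character(promoters[[g]]), "")[[1]],
                   c("A", "C", "G", "T"))
    for (strand in c("+", "-")) {
      dp <- lut[[strand]]
      sc <- .windowScores(codes, dp$ints)
      ok <- which(!is.na(sc))
      if (!length(ok)) next
      pv <- dp$tail[pmin(pmax(sc[ok], dp$lo), dp$hi) - dp$lo + 1]
      pv[sc[ok] > dp$hi] <- 0
      pv[sc[ok] < dp$lo] <- 1
      keep <- pv <= p_threshold
      if (!any(keep)) next
      hits[[length(hits) + 1L]] <- data.frame(
        gene_id = names(promoters)[g], start = ok[keep] - 1L,
        strand = strand, score = sc[ok][keep] * dp$granularity,
        p_value = pv[keep], stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(gene_id = character(), start = integer(),
                      strand = character(), score = numeric(),
                      p_value = numeric()))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Motif abundance and density statistics over gene sets
#'
#' Per labeled gene set: percent of promoters with at least one hit and
#' mean hits per promoter (promoters are fixed-length so per-promoter and
#' per-kb density differ only by a constant). Comparison sets larger than
#' `n_subsample` are summarized on a seeded random subsample of that size,
#' mirroring comparisons between a small focal set and large background
#' sets. When per-gene specificity scores are supplied, the Spearman
#' correlation between hit count and composite score is reported.
#'
#' @param hits Hit table from [scanPromoters()].
#' @param gene_sets Named list of character gene-id vectors.
#' @param universe All scanned gene ids (defines zero-hit promoters).
#' @param scores Optional data.frame with `gene_id` and `composite`.
#' @param n_subsample Subsample size for large sets (default: size of the
#'   smallest set).
#' @param seed Seed for the subsampling.
#' @return A list with `per_set` (data.frame: set, n, n_used,
#'   pct_with_hit, mean_hits), `per_gene` (hit counts over the universe),
#'   and `correlation` (`estimate`, `p_value`) when scores are given.
#' @export
motifDensityStats <- function(hits, gene_sets, universe,
                              scores = NULL, n_subsample = NULL,
                              seed = 1L) {
  if (any(!lengths(gene_sets))) stop("empty gene set")
  if (!all(unlist(gene_sets) %in% universe))
    stop("gene sets contain genes outside the scanned universe")
  counts <- table(factor(hits$gene_id, levels = universe))
  per_gene <- setNames(as.integer(counts), universe)
  if (is.null(n_subsample)) n_subsample <- min(lengths(gene_sets))
  set.seed(seed)
  per_set <- do.call(rbind, lapply(names(gene_sets), function(nm) {
    g <- gene_sets[[nm]]
    used <- if (length(g) > n_subsample) sample(g, n_subsample) else g
    h <- per_gene[used]
    data.frame(set = nm, n = length(g), n_used = length(used),
               pct_with_hit = 100 * mean(h >= 1), mean_hits = mean(h),
               stringsAsFactors = FALSE)
  }))
  correlation <- NULL
  if (!is.null(scores)) {
    common <- intersect(scores$gene_id, universe)
    ct <- suppressWarnings(
      cor.test(per_gene[common],
               scores$composite[match(common, scores$gene_id)],
               method = "spearman"))
    correlation <- list(estimate = unname(ct$estimate),
                        p_value = ct$p.value)
  }
  list(per_set = per_set, per_gene = per_gene, correlation = correlation)
}
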