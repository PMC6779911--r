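test_that("MEME minimal parsing of the packaged motif", {
  pwm <- nitrosenseMotif()
  expect_equal(ncol(pwm$matrix), 9)
  expect_equal(rownames(pwm$matrix), c("A", "C", "G", "T"))
  expect_equal(colSums(pwm$matrix), rep(1, 9), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(unname(pwm$background),
               c(0.3, 0.2, 0.2, 0.3))
  expect_equal(pwm$nsites, 40)
})

test_that("promoter extraction arithmetic on both strands", {
  genome <- Biostrings::DNAStringSet(c(
    chr1 = paste(rep("ACGT", 300), collapse = "")))  # 1200 bp
  genes <- data.frame(
    gene_id = c("plus", "short", "minus"),
    contig = "chr1",
    start = c(600L, 100L, 100L),
    end = c(900L, 200L, 400L),
    strand = c("+", "+", "-"), stringsAsFactors = FALSE)
  prom <- extractPromoters(genome, genes, length = 500L)
  # + strand: bases [100, 600) 0-based
  expect_equal(as.character(prom[["plus"]]),
               as.character(Biostrings::subseq(genome[[1]], 101, 600)))
  expect_equal(Biostrings::width(prom)[2], 100)   # truncated at the edge
  expect_true(attr(prom, "truncated")[["short"]])
  expect_false(attr(prom, "truncated")[["plus"]])
  # - strand: reverse complement of [400, 900) 0-based
  expect_equal(as.character(prom[["minus"]]),
               as.character(Biostrings::reverseComplement(
                 Biostrings::subseq(genome[[1]], 401, 900))))
  bad <- data.frame(gene_id = "off", contig = "chr1", start = 100L,
                    end = 1300L, strand = "+", stringsAsFactors = FALSE)
  expect_error(extractPromoters(genome, bad), "off its contig")
})

test_that("a planted consensus is found exactly once on the + strand", {
  pwm <- nitrosenseMotif()
  consensus <- "ACCGGAAGT"
  set.seed(2)
  bgseq <- paste(sample(c("A", "T"), 200, replace = TRUE), collapse = "")
  seq <- paste0(substr(bgseq, 1, 100), consensus,
                substr(bgseq, 101, 200))
  prom <- Biostrings::DNAStringSet(c(g1 = seq))
  hits <- scanPromoters(prom, pwm, p_threshold = 1e-3,
                        background = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3))
  plus <- hits[hits$strand == "+", ]
  expect_equal(nrow(plus), 1)
  expect_equal(plus$start, 100)  # 0-based planted position
})

test_that("DP tail probabilities equal exhaustive enumeration for short motifs", {
  set.seed(3)
  for (w in c(4, 5, 6)) {
    m <- matrix(rgamma(4 * w, 1), 4)
    m <- sweep(m, 2, colSums(m), "/")
    rownames(m) <- c("A", "C", "G", "T")
    pwm <- list(name = "rand", matrix = m, nsites = 20,
                background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
    bg <- c(A = 0.28, C = 0.22, G = 0.22, T = 0.28)
    dp <- nitrosense:::.scoreTailDistribution(
      nitrosense:::.scoreMatrix(pwm, bg), bg)
    oracle <- pwmTailReference(pwm, bg)
    probe <- unique(round(seq(dp$lo, dp$hi, length.out = 25)))
    for (s in probe) {
      got <- dp$tail[s - dp$lo + 1]
      expect_lt(abs(got - oracle(s)), 1e-6)
    }
    # monotone nonincreasing in score
    expect_true(all(diff(dp$tail) <= 1e-15))
  }
})

test_that("scanning a reverse complement mirrors the hit set", {
  pwm <- nitrosenseMotif()
  set.seed(4)
  seq <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE,
                      prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
  seq <- paste0(substr(seq, 1, 50), "ACCGGAAGT", substr(seq, 60, 400))
  fwd <- Biostrings::DNAStringSet(c(g = seq))
  rev <- Biostrings::DNAStringSet(c(g = as.character(
    Biostrings::reverseComplement(fwd[[1]]))))
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  h1 <- scanPromoters(fwd, pwm, 1e-3, background = bg)
  h2 <- scanPromoters(rev, pwm, 1e-3, background = bg)
  expect_equal(nrow(h1), nrow(h2))
  L <- nchar(seq); w <- 9
  mirrored <- sort(L - w - h2$start)
  expect_equal(sort(h1$start), mirrored)
  expect_equal(sort(h1$score), sort(h2$score), tolerance = 1e-9)
})

test_that("windows containing ambiguous bases are skipped", {
  pwm <- nitrosenseMotif()
  seq <- paste0("ACCGGNAGT", paste(rep("A", 60), collapse = ""),
                "ACCGGAAGT")
  hits <- scanPromoters(Biostrings::DNAStringSet(c(g = seq)), pwm, 1e-3,
                        background = c(A = 0.4, C = 0.1, G = 0.1, T = 0.4))
  expect_equal(hits$start[hits$strand == "+"], 69)
})

test_that("density statistics summarize gene sets and subsampling", {
  hits <- data.frame(gene_id = c("a", "a", "b"), start = c(1L, 5L, 2L),
                     strand = "+", score = 10, p_value = 1e-5,
                     stringsAsFactors = FALSE)
  universe <- c("a", "b", "c", "d")
  ds <- motifDensityStats(hits, list(with = c("a", "b"), none = c("c", "d")),
                          universe)
  expect_equal(ds$per_set$pct_with_hit, c(100, 0))
  expect_equal(ds$per_set$mean_hits, c(1.5, 0))
  # subsample of a set from itself at full size is the identity
  ds2 <- motifDensityStats(hits, list(s = c("a", "b")), universe,
                           n_subsample = 2)
  expect_equal(ds2$per_set$n_used, 2)
  expect_equal(ds2$per_set$pct_with_hit, 100)
  expect_error(motifDensityStats(hits, list(empty = character()), universe),
               "empty gene set")
  expect_error(motifDensityStats(hits, list(bad = "zz"), universe),
               "outside")
})

test_that("hit counts correlate with true specificity on planted promoters", {
  cfg <- simulationConfig(n_genes = 2000L, seed = 61L,
                          motif_rate_base = 0.1, motif_rate_slope = 0.5,
                          archetype_proportions = c(
                            n_replete = 0.2, n_deplete = 0.2,
                            nitrate_specific = 0.05,
                            ammonium_specific = 0.005, flat = 0.545))
  dat <- simulateNitrogenExperiment(cfg)
  pwm <- nitrosenseMotif()
  hits <- scanPromoters(dat$promoters, pwm, p_threshold = 1e-4)
  counts <- table(factor(hits$gene_id, levels = dat$truth$gene_id))
  spec <- ifelse(dat$truth$archetype == "nitrate_specific",
                 dat$truth$effect_size, 0)
  ct <- suppressWarnings(cor.test(as.integer(counts), spec,
                                  method = "spearman"))
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
  # density report orders the planted set above background
  sets <- list(planted = dat$truth$gene_id[spec > 0],
               flat = dat$truth$gene_id[dat$truth$archetype == "flat"])
  ds <- motifDensityStats(hits, sets, dat$truth$gene_id, seed = 1)
  expect_gte(ds$per_set$pct_with_hit[1], ds$per_set$pct_with_hit[2])
})
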