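.pepTable <- function(vals, protein = "p1") {
  data.frame(peptide_id = sprintf("%s_pep%d", protein, seq_len(nrow(vals))),
             protein_id = protein, vals, stringsAsFactors = FALSE,
             check.names = FALSE)
}

test_that("rollup base cases", {
  v <- matrix(c(1, 2, 3, 4), 1, dimnames = list(NULL, paste0("c", 1:4)))
  ru <- rollupPeptides(.pepTable(v))
  expect_equal(unname(ru$matrix[1, ]), c(1, 2, 3, 4))
  # two complete peptides differing by a constant collapse onto the
  # reference exactly
  v2 <- rbind(c(5, 6, 7, 8), c(1, 2, 3, 4))
  colnames(v2) <- paste0("c", 1:4)
  ru2 <- rollupPeptides(.pepTable(v2))
  expect_equal(unname(ru2$matrix[1, ]), c(5, 6, 7, 8))
  expect_equal(ru2$provenance$reference, "p1_pep1")
  # peptide sharing no channel with the reference is dropped with warning
  v3 <- rbind(c(1, 2, NA, NA), c(5, 3, NA, NA), c(NA, NA, 7, NA))
  colnames(v3) <- paste0("c", 1:4)
  expect_warning(ru3 <- rollupPeptides(.pepTable(v3)), "dropped")
  expect_equal(ru3$provenance$n_peptides, 2L)
})

test_that("shared peptides form flagged protein-group rows", {
  tab <- rbind(.pepTable(matrix(1:4, 1, dimnames = list(NULL, paste0("c", 1:4)))),
               .pepTable(matrix(5:8, 1, dimnames = list(NULL, paste0("c", 1:4))),
                         protein = "p1;p2"))
  ru <- rollupPeptides(tab)
  expect_true(ru$provenance$is_group[ru$provenance$protein_id == "p1;p2"])
  expect_false(ru$provenance$is_group[ru$provenance$protein_id == "p1"])
})

test_that("rollup equals the brute-force oracle on random tables", {
  set.seed(11)
  for (i in 1:200) {
    v <- randomPeptideTable(sample(1:5, 1), sample(3:8, 1))
    colnames(v) <- paste0("c", seq_len(ncol(v)))
    got <- suppressWarnings(rollupPeptides(.pepTable(v)))$matrix[1, ]
    want <- suppressWarnings(rollupReference(v))
    expect_equal(unname(got), unname(want))
  }
})

test_that("central tendency normalization zeroes sample medians", {
  m <- matrix(c(1, 2, 3, 10, 20, 30), 3,
              dimnames = list(paste0("p", 1:3), c("a", "b")))
  n1 <- centralTendencyNormalize(m)
  expect_equal(unname(n1[, "a"]), c(-1, 0, 1))
  expect_equal(apply(n1, 2, median), c(a = 0, b = 0))
  # idempotent
  expect_equal(centralTendencyNormalize(n1), n1)
  m[, 1] <- NA
  expect_error(centralTendencyNormalize(m), "no finite")
})

test_that("two-stage standardization yields unit rows", {
  set.seed(12)
  m <- matrix(rnorm(5 * 9, 10, 3), 5,
              dimnames = list(paste0("p", 1:5), paste0("s", 1:9)))
  blocks <- rep(c("t1", "t2", "t3"), each = 3)
  z <- standardizeTwoStage(m, blocks)
  expect_equal(unname(rowMeans(z)), rep(0, 5), tolerance = 1e-9)
  expect_equal(unname(apply(z, 1, sd)), rep(1, 5), tolerance = 1e-9)
  # constant row becomes zero
  m[1, ] <- 4
  z2 <- standardizeTwoStage(m, blocks)
  expect_equal(unname(z2[1, ]), rep(0, 9))
  # a single block reduces to one z-score
  z3 <- standardizeTwoStage(m[2:3, ], rep("one", 9))
  expect_equal(z3[1, ], (m[2, ] - mean(m[2, ])) / sd(m[2, ]),
               tolerance = 1e-9)
  # singleton block is centered and flagged
  z4 <- standardizeTwoStage(m[2:3, 1:4], c("a", "a", "a", "b"))
  expect_equal(attr(z4, "single_blocks"), "b")
  expect_error(standardizeTwoStage(m, blocks[1:3]), "one block per")
})

test_that("k-means separates planted groups and is deterministic", {
  set.seed(13)
  a <- matrix(rnorm(20 * 10, 0, 0.1), 20) + rep(sin(1:10), each = 20)
  b <- matrix(rnorm(20 * 10, 0, 0.1), 20) - rep(sin(1:10), each = 20)
  m <- rbind(a, b)
  rownames(m) <- sprintf("p%02d", 1:40)
  s <- apply(m, 1, sd)
  m <- (m - rowMeans(m)) / s
  cl <- clusterProteome(m, k = 2, seed = 5)
  expect_equal(length(unique(cl[1:20])), 1)
  expect_equal(length(unique(cl[21:40])), 1)
  expect_false(cl[[1]] == cl[[21]])
  expect_identical(cl, clusterProteome(m, k = 2, seed = 5))
  # identical rows co-cluster
  m2 <- m; m2[2, ] <- m2[1, ]
  cl2 <- clusterProteome(m2, k = 5, seed = 1)
  expect_equal(unname(cl2[1]), unname(cl2[2]))
  expect_error(clusterProteome(m, k = 100), "exceeds")
})

test_that("protein-group rows are excluded from clustering by default", {
  m <- matrix(rnorm(40), 4,
              dimnames = list(c("p1", "p2", "p3", "p1;p2"), NULL))
  cl <- clusterProteome(m, k = 2, seed = 1)
  expect_false("p1;p2" %in% names(cl))
})

test_that("hypergeometric enrichment matches closed forms", {
  # population 1000; one RT of 20 identical to one PC of 20
  pop <- sprintf("g%04d", 1:1000)
  rt <- setNames(c(rep(1L, 20), rep(2L, 980)), pop)
  pc <- setNames(c(rep(1L, 20), rep(2L, 980)), pop)
  et <- rtPcEnrichment(rt, pc)
  hit <- et[et$rt == "1" & et$pc == "1", ]
  closed <- sum(dhyper(20:20, 20, 980, 20))
  expect_equal(hit$p_value, closed, tolerance = 1e-12)
  expect_equal(hit$overlap, 20)
  # overlap at its expected value is unremarkable; zero overlap has p = 1
  set.seed(14)
  rt2 <- setNames(rep(1:2, each = 500), pop)
  pc2 <- setNames(rep(1:2, times = 500), pop)
  et2 <- rtPcEnrichment(rt2, pc2)
  exp_ov <- et2[et2$rt == "1" & et2$pc == "1", ]
  expect_equal(exp_ov$overlap, 250)
  # brute-force upper tail
  want <- sum(dhyper(250:500, 500, 500, 500))
  expect_equal(exp_ov$p_value, want, tolerance = 1e-12)
  expect_gte(exp_ov$p_value, 0.3)
  zt <- rtPcEnrichment(setNames(c(1L, 1L, 2L, 2L), letters[1:4]),
                       setNames(c(3L, 3L, 4L, 4L), letters[1:4]))
  expect_equal(zt$p_value[zt$rt == "1" & zt$pc == "4"], 1)
  expect_error(rtPcEnrichment(c(a = 1), c(b = 2)), "empty population")
})

test_that("planted transcript-protein concordance is detected, shuffles are not", {
  cfg <- simulationConfig(n_genes = 1200L, seed = 55L,
                          proteome_detect_fraction = 0.6)
  dat <- simulateNitrogenExperiment(cfg)
  ru <- rollupPeptides(dat$peptides)
  norm <- centralTendencyNormalize(ru$matrix)
  std <- standardizeTwoStage(norm, sub("_.*", "", colnames(norm)))
  pcs <- clusterProteome(std, k = 30, seed = 9)
  pat <- codePatterns(deTable(dat$se))
  rts <- rtBin(pat, k = 50)
  et <- rtPcEnrichment(rts$assignment, pcs)
  expect_true(any(et$q_value < 0.05))
  # the strongest pair should link a replete/deplete RT to a matching PC
  top <- et[1, ]
  expect_gt(top$fold, 1.5)
  # shuffled labels: no pair survives
  set.seed(1)
  shuf <- setNames(sample(pcs), names(pcs))
  et0 <- rtPcEnrichment(rts$assignment, shuf)
  expect_false(any(et0$q_value < 0.05))
})
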