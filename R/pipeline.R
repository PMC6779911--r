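#' Run the full analysis pipeline on a synthetic dataset
#'
#' Orchestrates the stages in dependency order on one seeded synthetic
#' dataset: simulation, differential expression and pattern coding,
#' response-type binning and nitrate-RT flagging, NS/HNS calling,
#' peptide rollup / normalization / proteome clustering / RT-PC
#' enrichment, promoter scanning and motif density statistics, the two
#' flux scenarios with loopless reduction and shuttle reporting, and the
#' labeling-rate summary. Reruns with the same configuration reproduce
#' identical outputs.
#'
#' @param config A [simulationConfig()].
#' @param k_rt Response-type count (default 201).
#' @param k_pc Proteome-cluster count (default 100).
#' @param percentile NS percentile gate (default 85).
#' @param min_rpkm Candidate mean-RPKM threshold (default 5).
#' @param alpha Coding FDR threshold (default 0.05).
#' @param p_threshold Motif-hit p-value threshold (default 1e-4).
#' @param stages Character subset of
#'   `c("expression", "proteome", "scan", "flux", "label")` to run
#'   (expression implies simulation; later stages need it).
#' @return A list with per-stage outputs and a `manifest` recording
#'   parameters, seeds and stage names.
#' @export
runPipeline <- function(config = simulationConfig(), k_rt = 201,
                        k_pc = 100, percentile = 85, min_rpkm = 5,
                        alpha = 0.05, p_threshold = 1e-4,
                        stages = c("expression", "proteome", "scan",
                                   "flux", "label")) {
  stages <- match.arg(stages, several.ok = TRUE)
  out <- list()
  dat <- simulateNitrogenExperiment(config)
  out$data <- dat
  manifest <- list(parameters = list(
    seed = config$seed, n_genes = config$n_genes, k_rt = k_rt,
    k_pc = k_pc, percentile = percentile, min_rpkm = min_rpkm,
    alpha = alpha, p_threshold = p_threshold), stages = character(0))

  if ("expression" %in% stages) {
    de <- deTable(dat$se)
    patterns <- codePatterns(de, alpha)
    rts <- rtBin(patterns, k_rt)
    crpkm <- conditionRPKM(dat$se)
    prof <- summarizeRTs(crpkm, rts$assignment)
    flags <- labelNitrateRTs(prof$profiles)
    hns <- callHNS(crpkm, rts$assignment, flags, percentile, min_rpkm)
    out$expression <- list(de = de, patterns = patterns, rts = rts,
                           cond_rpkm = crpkm, profiles = prof,
                           ns_rt_flags = flags, hns = hns)
    manifest$stages <- c(manifest$stages, "expression")
  }
  if ("proteome" %in% stages && nrow(dat$peptides) > 0) {
    ru <- rollupPeptides(dat$peptides)
    norm <- centralTendencyNormalize(ru$matrix)
    blocks <- sub("_.*", "", colnames(norm))  # treatment from condition
    std <- standardizeTwoStage(norm, blocks)
    kk <- min(k_pc, nrow(std))
    pcs <- clusterProteome(std, k = kk, seed = config$seed + 7L)
    enr <- if ("expression" %in% stages)
      rtPcEnrichment(out$expression$rts$assignment, pcs) else NULL
    out$proteome <- list(protein_matrix = norm, standardized = std,
                         pcs = pcs, enrichment = enr)
    manifest$stages <- c(manifest$stages, "proteome")
  }
  if ("scan" %in% stages && "expression" %in% stages) {
    pwm <- nitrosenseMotif()
    hits <- scanPromoters(dat$promoters, pwm, p_threshold)
    hns_set <- out$expression$hns$hns
    truth_ns <- dat$truth$gene_id[dat$truth$archetype == "nitrate_specific"]
    sets <- list(hns = if (length(hns_set)) hns_set else truth_ns,
                 background = dat$truth$gene_id[dat$truth$archetype ==
                                                  "flat"])
    dens <- motifDensityStats(hits, sets, names(dat$promoters),
                              scores = out$expression$hns$scores,
                              seed = config$seed + 11L)
    out$scan <- list(hits = hits, density = dens)
    manifest$stages <- c(manifest$stages, "scan")
  }
  if ("flux" %in% stages) {
    model <- ptoyNitrogenModel()
    out$flux <- lapply(c(nitrate = "nitrate", urea = "urea"),
                       function(sc) {
      metcon <- dat$metabolite_concentrations
      rates <- concentrationsToRates(metcon[metcon$scenario == sc, ])
      con <- applyConstraints(model, rates, sc)
      rel <- relaxToFeasible(con)
      sol <- looplessSolution(rel$model, fbaOptimize(rel$model))
      list(solution = sol, shuttle = shuttleReport(sol),
           relaxation = rel$report)
    })
    manifest$stages <- c(manifest$stages, "flux")
  }
  if ("label" %in% stages) {
    lab <- dat$labeling
    rates <- vapply(split(lab, lab$metabolite), labelingRate, numeric(1))
    comp <- compositionPercent(
      setNames(.LABELING_PANEL$pool, .LABELING_PANEL$metabolite))
    out$label <- list(rates_pct_per_h = rates, composition_pct = comp)
    manifest$stages <- c(manifest$stages, "label")
  }
  out$manifest <- manifest
  out
}

#' Score recovery of planted truth by the pipeline
#'
#' Precision and recall of the HNS call against the planted
#' nitrate-specific genes, plus response-type and proteome-cluster purity
#' (weighted mean fraction of each cluster belonging to its majority
#' archetype).
#'
#' @param result Output of [runPipeline()] (needs the expression stage).
#' @param truth Truth table of the simulated dataset.
#' @return List with `hns_precision`, `hns_recall`, `rt_purity`,
#'   `pc_purity` (NA without the proteome stage), and the `confusion`
#'   table of archetype by HNS call.
#' @export
recoveryReport <- function(result, truth = result$data$truth) {
  if (is.null(truth)) stop("no planted truth available")
  if (is.null(result$expression)) stop("expression stage was not run")
  hns <- result$expression$hns$hns
  pos <- truth$gene_id[truth$archetype == "nitrate_specific"]
  tp <- length(intersect(hns, pos))
  precision <- if (length(hns)) tp / length(hns) else NA_real_
  recall <- if (length(pos)) tp / length(pos) else NA_real_
  purity <- function(assign) {
    arch <- truth$archetype[match(names(assign), truth$gene_id)]
    ok <- !is.na(arch)
    tab <- table(assign[ok], arch[ok])
    sum(apply(tab, 1, max)) / sum(tab)
  }
  rt_purity <- purity(result$expression$rts$assignment)
  pc_purity <- if (!is.null(result$proteome)) purity(result$proteome$pcs)
               else NA_real_
  confusion <- table(archetype = truth$archetype,
                     hns = truth$gene_id %in% hns)
  list(hns_precision = precision, hns_recall = recall,
       rt_purity = rt_purity, pc_purity = pc_purity,
       confusion = confusion)
}
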