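#' Write and read the pipeline's tabular interchange files
#'
#' All tabular inputs and outputs travel as plain TSV; promoters as FASTA.
#' `writeSyntheticDataset()` materializes a simulated dataset to a
#' directory (counts, sample metadata, gene lengths, peptide table,
#' promoters, labeling series, metabolite concentrations, truth table) and
#' `readCountDataset()` reads the expression part back into a
#' `SummarizedExperiment`, so generated data round-trip through the same
#' readers real data would use.
#'
#' @param dataset Output of [simulateNitrogenExperiment()].
#' @param dir Output directory (created if needed).
#' @return `writeSyntheticDataset()` returns the file paths invisibly;
#'   `readCountDataset()` returns a `SummarizedExperiment`.
#' @export
writeSyntheticDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  wt <- function(x, f) utils::write.table(x, p(f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  counts <- SummarizedExperiment::assay(dataset$se, "counts")
  wt(data.frame(gene_id = rownames(counts), counts, check.names = FALSE),
     "counts.tsv")
  wt(as.data.frame(SummarizedExperiment::colData(dataset$se)),
     "samples.tsv")
  rd <- as.data.frame(SummarizedExperiment::rowData(dataset$se))
  wt(rd[, c("gene_id", "gene_length")], "gene_lengths.tsv")
  wt(dataset$peptides, "peptides.tsv")
  Biostrings::writeXStringSet(dataset$promoters, p("promoters.fasta"))
  wt(dataset$labeling, "labeling.tsv")
  wt(dataset$metabolite_concentrations, "metabolite_concentrations.tsv")
  wt(dataset$truth, "truth.tsv")
  invisible(p(c("counts.tsv", "samples.tsv", "gene_lengths.tsv",
                "peptides.tsv", "promoters.fasta", "labeling.tsv",
                "metabolite_concentrations.tsv", "truth.tsv")))
}

#' @rdname writeSyntheticDataset
#' @param dir Directory holding `counts.tsv`, `samples.tsv`,
#'   `gene_lengths.tsv`.
#' @export
readCountDataset <- function(dir) {
  rt <- function(f) utils::read.delim(file.path(dir, f),
                                      stringsAsFactors = FALSE,
                                      check.names = FALSE)
  counts <- rt("counts.tsv")
  gene_id <- counts$gene_id
  counts <- as.matrix(counts[, -1, drop = FALSE])
  rownames(counts) <- gene_id
  samples <- rt("samples.tsv")
  lens <- rt("gene_lengths.tsv")
  stopifnot(identical(samples$sample_id, colnames(counts)),
            identical(lens$gene_id, gene_id))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(samples, row.names = samples$sample_id),
    rowData = S4Vectors::DataFrame(gene_id = gene_id,
                                   gene_length = lens$gene_length))
}
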