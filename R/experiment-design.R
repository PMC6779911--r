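#' @import methods
#' @importFrom stats rnbinom rlnorm rnorm runif rpois rbinom quantile cor
#'   sd median hclust cutree as.dist kmeans phyper p.adjust cor.test
#'   pnbinom setNames complete.cases
#' @importFrom utils head tail
#' @useDynLib nitrosense, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Treatment x timepoint layout of the short-time nitrogen-shift design:
# three pretreatment samples (mid-exponential on ammonium; 2 h N-starved;
# 90 min after a nitrate spike) followed by four N treatments (no nitrogen,
# ammonium, nitrite, nitrate at 300 uM) sampled at 15 min, 45 min and 18 h.
.TREATMENTS <- c("noN", "NH4", "NO2", "NO3")
.TIMEPOINTS <- c("15min", "45min", "18h")
.PRE_CONDITIONS <- c("preNH4", "preN0", "preNO3")

#' Condition names of the nitrogen time-course design
#'
#' Returns the 15 treatment-by-timepoint condition labels in canonical order:
#' the three pretreatment samples followed by the 12 treatment conditions.
#'
#' @return Character vector of length 15.
#' @export
nshortConditions <- function() {
  c(.PRE_CONDITIONS,
    as.vector(t(outer(.TREATMENTS, .TIMEPOINTS, paste, sep = "_"))))
}

#' The 12 treatment-by-time comparisons coded against the ammonium control
#'
#' Every non-pretreatment condition is compared with the ammonium
#' pretreatment sample; this fixed order defines the columns of the coded
#' pattern matrix.
#'
#' @return Character vector of length 12.
#' @export
nshortComparisons <- function() {
  as.vector(t(outer(.TREATMENTS, .TIMEPOINTS, paste, sep = "_")))
}

#' Sample metadata for the nitrogen time-course design
#'
#' Builds the sample sheet of the short-time N-shift experiment: 15
#' conditions per replicate with treatment, timepoint, replicate and a flag
#' for whether inorganic nitrogen is still available in the medium at
#' sampling (it is exhausted by 18 h, absent in the no-N arm, and absent
#' after the 2 h starvation pretreatment; the nitrate-spiked pretreatment
#' counts as N-available).
#'
#' @param n_replicates Number of biological replicates (default 2).
#' @return A `data.frame` with columns `sample_id`, `condition`,
#'   `treatment`, `timepoint`, `replicate`, `n_available`.
#' @export
nshortDesign <- function(n_replicates = 2L) {
  stopifnot(n_replicates >= 1)
  conds <- nshortConditions()
  treatment <- c("preNH4", "preN0", "preNO3",
                 rep(.TREATMENTS, each = length(.TIMEPOINTS)))
  timepoint <- c("pre", "pre", "pre", rep(.TIMEPOINTS, times = 4))
  n_avail <- c(TRUE, FALSE, TRUE,
               as.vector(vapply(.TREATMENTS, function(tr) {
                 if (tr == "noN") c(FALSE, FALSE, FALSE)
                 else c(TRUE, TRUE, FALSE)  # external N exhausted by 18 h
               }, logical(3))))
  out <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
    data.frame(sample_id = paste0(conds, ".R", r),
               condition = conds, treatment = treatment,
               timepoint = timepoint, replicate = paste0("R", r),
               n_available = n_avail, stringsAsFactors = FALSE)
  }))
  rownames(out) <- out$sample_id
  out
}
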