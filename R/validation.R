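## validation: primer-extension (SNaPshot) peak-ratio betas and concordance
## with the array-based calls.

#' Beta value from primer-extension peak heights
#'
#' beta = hA/(hA + hB), the A-allele fraction of the two allele-specific
#' extension peak heights — the same functional form as the array beta
#' X/(X+Y).
#'
#' @param heightA,heightB nonnegative peak heights (vectorized); a pair of
#'   zeros is an error
#' @return numeric beta in [0,1]
#' @examples
#' snapshotBeta(300, 100)  # 0.75
#' @export
snapshotBeta <- function(heightA, heightB) {
  if (any(heightA < 0 | heightB < 0, na.rm = TRUE))
    stop("peak heights must be nonnegative")
  tot <- heightA + heightB
  if (any(tot == 0, na.rm = TRUE))
    stop("both peak heights are zero for some assay")
  heightA / tot
}

#' Concordance of SNaPshot betas with array-based allelic calls
#'
#' The array beta for a gene x clone is reconstructed as 0.5 plus the
#' signed gene score (positive for ALLELE_A, negative for ALLELE_B, zero
#' when no direction was assigned) — i.e. centered on the heterozygous gDNA
#' expectation. A pair is concordant when |beta_snapshot - beta_array| is
#' at most \code{tolerance}. Class-level agreement compares the array class
#' with the class implied by the snapshot beta under the same score
#' thresholds.
#'
#' @param peaks \code{data.frame} with \code{gene_id}, \code{clone_id} (or
#'   \code{sample_id}), \code{height_a}, \code{height_b}
#' @param panel a [GeneCallPanel-class] (or its call \code{data.frame})
#' @param tolerance absolute beta tolerance (default 0.1, the BA/SK
#'   boundary)
#' @return list with \code{pairs} (per-pair table) and \code{summary}
#'   (counts and percent concordant, half-up)
#' @export
assessConcordance <- function(peaks, panel, tolerance = 0.1) {
  calls <- if (is(panel, "GeneCallPanel")) geneCalls(panel) else
    as.data.frame(panel)
  thr <- if (is(panel, "GeneCallPanel")) callThresholds(panel) else
    list(t_sk = 0.1, t_ma = 0.2)
  peaks <- as.data.frame(peaks)
  if (is.null(peaks$clone_id) && !is.null(peaks$sample_id))
    peaks$clone_id <- peaks$sample_id
  m <- merge(peaks, calls, by = c("gene_id", "clone_id"))
  m <- m[m$class != "ND", , drop = FALSE]
  if (!nrow(m)) stop("no matched (gene, clone) pairs between peaks and calls")
  sgn <- ifelse(is.na(m$direction), 0,
         ifelse(m$direction == "ALLELE_A", 1,
         ifelse(m$direction == "ALLELE_B", -1, 0)))
  m$beta_array <- 0.5 + sgn * m$score
  m$beta_snapshot <- snapshotBeta(m$height_a, m$height_b)
  m$abs_difference <- abs(m$beta_snapshot - m$beta_array)
  m$concordant <- m$abs_difference <= tolerance
  snapScore <- abs(m$beta_snapshot - 0.5)
  m$snapshot_class <- ifelse(snapScore < thr$t_sk, "BA",
                      ifelse(snapScore < thr$t_ma, "SK", "MA"))
  m$class_agree <- m$snapshot_class == m$class
  keep <- c("gene_id", "clone_id", "beta_snapshot", "beta_array",
            "abs_difference", "concordant", "snapshot_class", "class",
            "class_agree")
  pairs <- m[, keep]
  summary <- data.frame(
    n_pairs = nrow(pairs),
    n_concordant = sum(pairs$concordant),
    pct_concordant = aeiPercent(sum(pairs$concordant), nrow(pairs), 0,
                                "half-up"),
    n_class_agree = sum(pairs$class_agree),
    tolerance = tolerance, stringsAsFactors = FALSE)
  list(pairs = pairs, summary = summary)
}
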