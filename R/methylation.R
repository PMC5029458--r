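## methylation: region-level comparisons of CpG beta values, DMP counting,
## non-CpG summaries, sample clustering, promoter-signal tests.

#' Assemble a methylation beta-value SummarizedExperiment
#'
#' @param beta CpG probe x sample matrix of methylation beta values in
#'   [0,1] (missing allowed)
#' @param annotation \code{data.frame} with one row per probe:
#'   \code{cpg_id}, \code{chromosome}, \code{position}, \code{gene_region}
#'   and \code{gene_id} (semicolon-separated, positionally paired, the
#'   450K-annotation idiom), \code{island_relation} (Island / N_Shore /
#'   S_Shore / N_Shelf / S_Shelf / OpenSea) and \code{site_class}
#'   (\code{"CpG"} or \code{"non-CpG"})
#' @return a \code{SummarizedExperiment} with assay \code{beta}
#' @export
makeMethylationSet <- function(beta, annotation) {
  annotation <- as.data.frame(annotation)
  stopifnot(all(c("cpg_id", "site_class") %in% names(annotation)))
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("methylation beta values must lie in [0,1]")
  annotation <- annotation[match(rownames(beta), annotation$cpg_id), ,
                           drop = FALSE]
  if (anyNA(annotation$cpg_id))
    stop("annotation missing for some probes in the beta matrix")
  SummarizedExperiment(assays = list(beta = beta),
                       rowData = DataFrame(annotation,
                                           row.names = rownames(beta)))
}

#' Remove blocklisted (e.g. cross-hybridizing) probes
#'
#' @param se methylation \code{SummarizedExperiment}
#' @param blocklist CpG ids to drop; unknown ids are ignored (counted in
#'   the message)
#' @return the filtered object
#' @export
filterMethProbes <- function(se, blocklist) {
  blocklist <- unique(blocklist)
  hit <- rownames(se) %in% blocklist
  unknown <- sum(!blocklist %in% rownames(se))
  message(sprintf("removed %d/%d probes (%d blocklist ids not on array)",
                  sum(hit), nrow(se), unknown))
  out <- se[!hit, ]
  if (nrow(out) == 0) warning("all probes removed by blocklist")
  out
}

# probes annotated to any of `genes` in gene-region `region`
# (positional pairing of semicolon lists, as on the 450K manifest)
regionProbeIds <- function(se, genes, region) {
  rd <- as.data.frame(rowData(se))
  hit <- vapply(seq_len(nrow(rd)), function(i) {
    g <- strsplit(rd$gene_id[i] %||% "", ";")[[1]]
    r <- strsplit(rd$gene_region[i] %||% "", ";")[[1]]
    if (!length(g)) return(FALSE)
    if (length(r) == 1L) r <- rep(r, length(g))
    any(g %in% genes & r == region)
  }, logical(1))
  rownames(se)[hit]
}

`%||%` <- function(a, b)
  if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' Paired region-level methylation test between MA and BA clones
#'
#' Each probe of the requested gene-region annotation contributes one pair:
#' its mean beta over the MA-expressing clones versus its mean beta over
#' the biallelic sister clones. A Wilcoxon signed-rank test is applied to
#' the per-probe paired differences (zero differences dropped); exact by
#' convolution for up to \code{exactLimit} nonzero pairs, otherwise the
#' normal approximation with continuity correction. Direction follows the
#' sign of the median difference.
#'
#' @param se methylation \code{SummarizedExperiment}
#' @param genes gene set whose probes enter the comparison
#' @param region gene-region label (TSS1500, TSS200, 5UTR, 1stExon, Body,
#'   3UTR) or \code{"Island"} to select by CpG-island relation instead
#' @param maSamples,baSamples sample/clone id vectors for the two groups
#' @param exactLimit largest number of pairs for the exact null
#' @return one-row \code{data.frame}: \code{region}, \code{n_pairs} (nonzero
#'   pairs used), \code{statistic}, \code{p_value}, \code{direction}
#'   (MA_higher / BA_higher / none), \code{mean_difference}, \code{method}
#' @export
pairedRegionTest <- function(se, genes, region, maSamples, baSamples,
                             exactLimit = 50) {
  b <- assay(se, "beta")
  if (region == "Island") {
    rd <- as.data.frame(rowData(se))
    inGene <- vapply(rd$gene_id, function(g)
      any(strsplit(g %||% "", ";")[[1]] %in% genes), logical(1))
    ids <- rownames(se)[inGene & rd$island_relation == "Island"]
  } else ids <- regionProbeIds(se, genes, region)
  x <- rowMeans(b[ids, maSamples, drop = FALSE], na.rm = TRUE)
  y <- rowMeans(b[ids, baSamples, drop = FALSE], na.rm = TRUE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 1) stop("fewer than one usable probe pair for region ", region)
  d <- x - y
  nz <- d[d != 0]
  if (length(nz) == 0) {
    res <- list(statistic = NA_real_, p_value = 1, n = 0L)
    method <- "degenerate (all differences zero)"
  } else if (length(nz) <= exactLimit) {
    res <- exactSignedRank(d)
    method <- "exact signed-rank"
  } else {
    wt <- suppressWarnings(
      wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE))
    res <- list(statistic = unname(wt$statistic), p_value = wt$p.value,
                n = length(nz))
    method <- "signed-rank, normal approximation"
  }
  med <- median(d)
  direction <- if (length(nz) == 0 || med == 0) "none"
    else if (med > 0) "MA_higher" else "BA_higher"
  data.frame(region = region, n_pairs = res$n, statistic = res$statistic,
             p_value = res$p_value, direction = direction,
             mean_difference = mean(d), method = method,
             stringsAsFactors = FALSE)
}

#' Count differentially methylated positions between two conditions
#'
#' Probes whose absolute beta difference strictly exceeds the threshold
#' (default 0.3, i.e. >30 percentage points). Matrices are averaged across
#' their samples first; the probe universes are intersected.
#'
#' @param m1,m2 named beta vectors or probe x sample matrices
#' @param threshold strict cutoff on |beta1 - beta2|
#' @return list with \code{count} and \code{total} probes compared
#' @export
countDMPs <- function(m1, m2, threshold = 0.3) {
  v1 <- if (is.matrix(m1)) rowMeans(m1, na.rm = TRUE) else m1
  v2 <- if (is.matrix(m2)) rowMeans(m2, na.rm = TRUE) else m2
  common <- intersect(names(v1), names(v2))
  if (!length(common)) stop("the two matrices share no probes")
  d <- abs(v1[common] - v2[common])
  # strict inequality, guarded against binary representation error so that
  # a difference of exactly the threshold is never counted
  list(count = sum(d > threshold + 1e-12, na.rm = TRUE),
       total = length(common))
}

#' Per-sample summary of autosomal non-CpG methylation
#'
#' Mean and median beta over autosomal probes with
#' \code{site_class == "non-CpG"} (elevated non-CpG methylation is a
#' hallmark of the pluripotent state).
#'
#' @param se methylation \code{SummarizedExperiment}
#' @return \code{data.frame}: \code{sample_id}, \code{n_probes},
#'   \code{mean_beta}, \code{median_beta}
#' @export
nonCpGSummary <- function(se) {
  rd <- as.data.frame(rowData(se))
  keep <- rd$site_class == "non-CpG" &
    !rd$chromosome %in% c("X", "chrX", "Y", "chrY")
  if (!any(keep)) stop("no autosomal non-CpG probes in the matrix")
  b <- assay(se, "beta")[keep, , drop = FALSE]
  data.frame(sample_id = colnames(b), n_probes = nrow(b),
             mean_beta = colMeans(b, na.rm = TRUE),
             median_beta = apply(b, 2, median, na.rm = TRUE),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hierarchical clustering of methylation samples
#'
#' Average-linkage agglomeration on 1 - Pearson correlation between sample
#' beta vectors. Samples are ordered by id first so tie-breaking is
#' deterministic.
#'
#' @param se methylation \code{SummarizedExperiment} (>= 2 samples)
#' @return an \code{hclust} object
#' @export
clusterMethSamples <- function(se) {
  b <- assay(se, "beta")
  if (ncol(b) < 2) stop("clustering needs at least two samples")
  b <- b[, order(colnames(b)), drop = FALSE]
  sds <- apply(b, 2, sd, na.rm = TRUE)
  if (any(!is.finite(sds) | sds == 0))
    stop("constant beta vector, correlation undefined for sample(s): ",
         paste(colnames(b)[!is.finite(sds) | sds == 0], collapse = ", "))
  d <- as.dist(1 - cor(b, use = "pairwise.complete.obs"))
  hclust(d, method = "average")
}

#' Strand-aware promoter windows
#'
#' The promoter of a gene is the window from \code{upstream} bp before to
#' \code{downstream} bp after its transcription start site on the coding
#' strand (1-based, inclusive; defaults 1000/500). For minus-strand genes
#' upstream lies on the larger-coordinate side.
#'
#' @param tss TSS positions (1-based)
#' @param strand \code{"+"} or \code{"-"} per gene
#' @param chromosome chromosome names
#' @param upstream,downstream window extents in bp
#' @return a \code{GRanges} of promoter windows
#' @examples
#' promoterWindow(10000, "-", "chr1")  # 9500-11000
#' @export
promoterWindow <- function(tss, strand = "+", chromosome = "chr1",
                           upstream = 1000, downstream = 500) {
  gr <- GRanges(chromosome, IRanges(start = tss, width = 1L), strand = strand)
  # promoters() counts the TSS base itself in 'downstream'
  promoters(gr, upstream = upstream, downstream = downstream + 1L)
}

#' Compare promoter chromatin signal between MA-like and BA-like genes
#'
#' Unpaired Wilcoxon rank-sum test on per-gene promoter signals (e.g.
#' -log10 Poisson p-values of a chromatin mark); exact by convolution for
#' small groups, normal approximation with continuity correction otherwise.
#'
#' @param signal numeric per-gene values
#' @param labels factor/character with two levels, e.g. \code{"MA"} /
#'   \code{"BA"}, parallel to \code{signal}
#' @param exactLimit use the exact null when both groups are at most this
#'   large
#' @return list: \code{statistic} (Mann-Whitney W of the first level),
#'   \code{p_value}, \code{n}, \code{method}
#' @export
promoterSignalCompare <- function(signal, labels, exactLimit = 25) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two levels")
  x <- signal[labels == levels(labels)[1]]
  y <- signal[labels == levels(labels)[2]]
  if (!length(x) || !length(y))
    stop("both gene groups must be non-empty")
  if (length(x) <= exactLimit && length(y) <= exactLimit) {
    res <- exactRankSum(x, y)
    c(res, list(method = "exact rank-sum"))
  } else {
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    list(statistic = unname(wt$statistic), p_value = wt$p.value,
         n = c(length(x), length(y)),
         method = "rank-sum, normal approximation")
  }
}
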