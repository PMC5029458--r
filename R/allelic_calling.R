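## allelic_calling: genotypes, delta-beta, gene scores, BA/SK/MA classes.

#' Call genotypes from gDNA beta values
#'
#' Heterozygous iff the gDNA beta lies in \code{[hetLow, hetHigh]} and the
#' cell passes the intensity filter; homozygous A iff beta > \code{homAMin};
#' homozygous B iff beta < \code{homBMax}; otherwise (or when filtered /
#' missing) NO_CALL. The band defaults are array-platform conventions and
#' fully configurable.
#'
#' @param b gDNA [AllelicBetaSet-class]
#' @param hetLow,hetHigh heterozygote beta band (defaults 0.3, 0.7)
#' @param homAMin,homBMax homozygote bounds (defaults 0.8, 0.2)
#' @return character matrix probe x sample with values HOM_A / HET / HOM_B /
#'   NO_CALL
#' @export
callGenotypes <- function(b, hetLow = 0.3, hetHigh = 0.7,
                          homAMin = 0.8, homBMax = 0.2) {
  stopifnot(is(b, "AllelicBetaSet"))
  if (arrayMaterial(b) != "gDNA")
    stop("genotypes are called on the gDNA beta matrix")
  if (hetLow >= hetHigh) stop("hetLow must be < hetHigh")
  beta <- betaValues(b); pass <- passesFilter(b)
  g <- matrix("NO_CALL", nrow(beta), ncol(beta), dimnames = dimnames(beta))
  ok <- !is.na(beta) & pass
  g[ok & beta >= hetLow & beta <= hetHigh] <- "HET"
  g[ok & beta > homAMin] <- "HOM_A"
  g[ok & beta < homBMax] <- "HOM_B"
  g
}

#' Per-SNP delta-beta at heterozygous probes
#'
#' For every cDNA sample, at every probe heterozygous in its paired gDNA
#' sample and passing the cDNA intensity filter, delta-beta = beta_cDNA -
#' beta_gDNA. Positive values mean the A allele (channel X) is
#' over-expressed.
#'
#' @param betaCdna,betaGdna cDNA and gDNA [AllelicBetaSet-class] objects
#' @param genotypes matrix from [callGenotypes()]
#' @param samples sample manifest pairing each cDNA sample with its gDNA
#'   sample (\code{paired_gdna}) and clone (\code{clone_id})
#' @return \code{data.frame} with columns \code{probe_id}, \code{clone_id},
#'   \code{sample_id}, \code{delta_beta}, \code{abs_delta}
#' @export
computeSnpDelta <- function(betaCdna, betaGdna, genotypes, samples) {
  stopifnot(is(betaCdna, "AllelicBetaSet"), is(betaGdna, "AllelicBetaSet"))
  samples <- validateSampleManifest(samples)
  cd <- samples[samples$material == "cDNA" &
                samples$sample_id %in% colnames(betaValues(betaCdna)), ]
  if (!nrow(cd)) stop("no cDNA samples to process")
  bc <- betaValues(betaCdna); pc <- passesFilter(betaCdna)
  bg <- betaValues(betaGdna)
  out <- vector("list", nrow(cd))
  for (i in seq_len(nrow(cd))) {
    s <- cd$sample_id[i]; g <- cd$paired_gdna[i]
    if (!g %in% colnames(genotypes) || !g %in% colnames(bg))
      stop("cDNA sample '", s, "' is unpaired: gDNA sample '", g,
           "' has no genotype calls")
    common <- intersect(rownames(bc), rownames(genotypes))
    het <- common[genotypes[common, g] == "HET"]
    keep <- het[pc[het, s] & !is.na(bc[het, s]) & !is.na(bg[het, g])]
    if (!length(keep)) next
    d <- bc[keep, s] - bg[keep, g]
    out[[i]] <- data.frame(probe_id = keep, clone_id = cd$clone_id[i],
                           sample_id = s, delta_beta = unname(d),
                           abs_delta = abs(unname(d)),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(probe_id = character(), clone_id = character(),
                      sample_id = character(), delta_beta = numeric(),
                      abs_delta = numeric(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Penalty-weighting configuration for gene aggregation
#'
#' Hook to down-weight scores of large transcripts. The built-in rule is a
#' per-gene shrinkage score' = score * n/(n + k) on the number of
#' informative SNPs n; \code{k = 0} (or \code{enabled = FALSE}) leaves
#' scores untouched.
#'
#' @param enabled apply the penalty?
#' @param k shrinkage constant (>= 0)
#' @return a \code{penaltyConfig} list
#' @export
penaltyConfig <- function(enabled = FALSE, k = 0) {
  stopifnot(k >= 0)
  structure(list(enabled = isTRUE(enabled), k = k), class = "penaltyConfig")
}

#' Aggregate SNP delta-beta values to gene (or transcript) scores
#'
#' The score is the weighted mean absolute delta-beta over a gene's
#' informative SNPs (weights 1 unless a penalty is enabled). Direction is
#' taken from the common sign among SNPs with |delta-beta| >= \code{tSk};
#' DISCORDANT when those signs disagree, NA when no SNP reaches \code{tSk}.
#' Genes with no mapped informative probes are absent from the output (ND is
#' assigned later, at classification).
#'
#' @param deltas output of [computeSnpDelta()]
#' @param probes probe manifest with \code{gene_id}/\code{transcript_id}
#'   memberships (see [readProbeManifest()])
#' @param level aggregate per RefSeq gene or per isoform
#' @param penalty a [penaltyConfig()]
#' @param tSk skew threshold used for the direction call (default 0.1)
#' @return \code{data.frame} with \code{gene_id}, \code{clone_id},
#'   \code{n_informative}, \code{score}, \code{direction}
#' @export
aggregateGeneScores <- function(deltas, probes,
                                level = c("gene", "transcript"),
                                penalty = penaltyConfig(), tSk = 0.1) {
  level <- match.arg(level)
  idcol <- if (level == "gene") "gene_id" else "transcript_id"
  dt <- as.data.table(deltas)
  pm <- as.data.table(probes)[, c("probe_id", idcol), with = FALSE]
  setnames(pm, idcol, "id")
  pm <- unique(pm[!is.na(id)])
  dt <- merge(dt, pm, by = "probe_id", allow.cartesian = TRUE)
  if (!nrow(dt))
    return(data.frame(gene_id = character(), clone_id = character(),
                      n_informative = integer(), score = numeric(),
                      direction = character(), stringsAsFactors = FALSE))
  res <- dt[, {
    s <- sign(delta_beta[abs_delta >= tSk])
    dir <- if (!length(s)) NA_character_
           else if (all(s > 0)) "ALLELE_A"
           else if (all(s < 0)) "ALLELE_B"
           else "DISCORDANT"
    list(n_informative = .N, score = mean(abs_delta), direction = dir)
  }, by = .(id, clone_id)]
  if (penalty$enabled)
    res[, score := score * n_informative / (n_informative + penalty$k)]
  setnames(res, "id", "gene_id")
  out <- as.data.frame(res)
  out <- out[order(out$gene_id, out$clone_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify gene scores into allelic-expression classes
#'
#' Lower-closed score bands: BA for score < \code{tSk}, SK for
#' \code{[tSk, tMa)}, MA for score >= \code{tMa}; ND for gene x clone
#' combinations with fewer than \code{minInformative} informative SNPs.
#' Genes on the imprinted or protocadherin lists, and genes mapping to
#' chromosome X, are flagged via \code{excluded_reason} and never enter the
#' autosomal random-AEI summaries (chrX genes are kept for the X report).
#'
#' @param scores output of [aggregateGeneScores()]
#' @param clones clone annotation \code{data.frame} (\code{clone_id},
#'   \code{developmental_state})
#' @param probes optional probe manifest used to locate chrX genes
#' @param imprinted,protocadherin character vectors of gene ids to exclude
#'   (see [readGeneList()])
#' @param tSk,tMa class thresholds in delta-beta units (defaults 0.1, 0.2)
#' @param geneUniverse genes forming the call grid (default: genes present
#'   in \code{scores})
#' @param minInformative minimum informative SNPs for a non-ND call
#' @return a [GeneCallPanel-class]
#' @export
classifyCalls <- function(scores, clones, probes = NULL,
                          imprinted = character(),
                          protocadherin = character(),
                          tSk = 0.1, tMa = 0.2,
                          geneUniverse = NULL, minInformative = 1) {
  if (tSk >= tMa) stop("tSk must be < tMa")
  clones <- as.data.frame(clones)
  if (is.null(geneUniverse)) geneUniverse <- unique(scores$gene_id)
  grid <- as.data.frame(CJ(gene_id = sort(unique(geneUniverse)),
                           clone_id = clones$clone_id))
  calls <- merge(grid, scores, by = c("gene_id", "clone_id"), all.x = TRUE)
  calls$n_informative[is.na(calls$n_informative)] <- 0L
  nd <- calls$n_informative < minInformative
  calls$class <- ifelse(nd, "ND",
                 ifelse(calls$score < tSk, "BA",
                 ifelse(calls$score < tMa, "SK", "MA")))
  calls$score[nd] <- NA_real_
  calls$direction[nd] <- NA_character_
  calls$excluded_reason <- NA_character_
  chrx <- character()
  if (!is.null(probes)) {
    pm <- unique(probes[!is.na(probes$gene_id), c("gene_id", "chromosome")])
    chrx <- unique(pm$gene_id[pm$chromosome %in% c("X", "chrX", "23")])
  }
  calls$excluded_reason[calls$gene_id %in% chrx] <- "chrX"
  calls$excluded_reason[calls$gene_id %in% protocadherin] <- "protocadherin"
  calls$excluded_reason[calls$gene_id %in% imprinted] <- "imprinted"
  GeneCallPanel(calls, clones, thresholds = list(t_sk = tSk, t_ma = tMa))
}

#' Convert a delta-beta score to the major:minor allele fold ratio
#'
#' Assuming a heterozygous gDNA beta of 0.5, a gene-level absolute
#' delta-beta d corresponds to an allele ratio r = (0.5 + d)/(0.5 - d);
#' r(0) = 1 and r is strictly increasing on [0, 0.5). d >= 0.5 implies a
#' completely monoallelic signal and returns \code{Inf}.
#'
#' @param delta absolute delta-beta value(s), in [0, 1]
#' @return numeric fold ratio(s)
#' @examples
#' deltaToRatio(c(0, 0.1, 0.2))  # 1, 1.5, 2.33
#' @export
deltaToRatio <- function(delta) {
  if (any(delta < 0 | delta > 1, na.rm = TRUE))
    stop("delta must be an absolute delta-beta in [0, 1]")
  # scaled by 10 so decimal thresholds (0.1, 0.2) map to exact binary values
  ifelse(delta >= 0.5, Inf, (5 + 10 * delta) / (5 - 10 * delta))
}

#' Read a gene-list file
#'
#' One gene symbol per line; blank lines and \code{#} comments ignored.
#'
#' @param path file path
#' @return character vector
#' @export
readGeneList <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  unique(x[nzchar(x)])
}

#' Calls on chromosome X genes
#'
#' chrX genes are excluded from the autosomal summaries but kept for a
#' separate report; the X-inactivation |delta-beta| distribution (bimodal,
#' near 0.5) calibrates the MA threshold.
#'
#' @param panel a [GeneCallPanel-class]
#' @return the chrX subset of the call table
#' @export
chrXReport <- function(panel) {
  cc <- geneCalls(panel)
  cc[!is.na(cc$excluded_reason) & cc$excluded_reason == "chrX", , drop = FALSE]
}
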