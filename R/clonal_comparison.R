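## clonal_comparison: random-AEI detection, transitions, frequency estimators.

#' Percentage with an explicit rounding convention
#'
#' \code{"half-up"} rounds 0.5 away from zero at the requested precision;
#' \code{"down"} truncates. Genome-wide gene-frequency percentages in this
#' package are reported truncated at two decimals, coarser percentages
#' half-up (see the methods vignette for why both conventions exist).
#'
#' @param count,denom numerator and denominator
#' @param digits decimal places
#' @param mode rounding mode
#' @return numeric percentage; 0 with a warning when \code{denom} is 0
#' @export
aeiPercent <- function(count, denom, digits = 2,
                       mode = c("half-up", "down")) {
  mode <- match.arg(mode)
  if (denom == 0) {
    warning("percentage undefined for zero denominator; reporting 0")
    return(0)
  }
  x <- 100 * count / denom * 10^digits
  x <- x + 1e-9  # guard against binary representation just below an integer
  if (mode == "half-up") x <- x + 0.5
  floor(x) / 10^digits
}

cloneIdsOfState <- function(panel, group) {
  ci <- cloneInfo(panel)
  ids <- ci$clone_id[ci$developmental_state == group]
  if (!length(ids)) stop("no clones with developmental_state '", group, "'")
  ids
}

# non-excluded autosomal calls for a clone subset, as a gene x clone grid
panelCallsFor <- function(panel, cloneIds) {
  cc <- geneCalls(panel)
  cc <- cc[cc$clone_id %in% cloneIds & is.na(cc$excluded_reason), , drop = FALSE]
  cc
}

#' Detect random allelic expression imbalance across sister clones
#'
#' Per gene, over the clones of one developmental state:
#' \describe{
#'   \item{RANDOM_MA}{MA in two or more clones with opposite expressed
#'     alleles — both alleles seen across sister clones.}
#'   \item{RANDOM_AEI}{MA in at least one clone and BA in at least one
#'     sister clone.}
#'   \item{INDETERMINATE_MA}{MA somewhere but expression not reliably
#'     detected (ND) in every other clone — blocks the random call.}
#'   \item{CONSTANT_MA}{MA with a single direction wherever detected and no
#'     biallelic sister (cis-genetic candidate).}
#'   \item{NOT_MA}{no MA clone.}
#' }
#' Excluded (imprinted / protocadherin / chrX) genes are skipped.
#'
#' @param panel a [GeneCallPanel-class]
#' @param group developmental state defining the comparison group (>= 2
#'   clones required)
#' @return \code{data.frame}: \code{gene_id}, \code{category}, and per-gene
#'   class counts \code{n_ma}, \code{n_ba}, \code{n_sk}, \code{n_nd}
#' @export
detectRandomAEI <- function(panel, group) {
  ids <- cloneIdsOfState(panel, group)
  if (length(ids) < 2)
    stop("random AEI is undecidable with a single clone in group '",
         group, "'")
  cc <- panelCallsFor(panel, ids)
  dt <- as.data.table(cc)
  res <- dt[, {
    ma <- class == "MA"
    dirs <- unique(direction[ma & direction %in% c("ALLELE_A", "ALLELE_B")])
    cat <- if (!any(ma)) "NOT_MA"
      else if (length(dirs) == 2L) "RANDOM_MA"
      else if (any(class == "BA")) "RANDOM_AEI"
      else if (any(!ma) && all(class[!ma] == "ND")) "INDETERMINATE_MA"
      else "CONSTANT_MA"
    list(category = cat, n_ma = sum(ma), n_ba = sum(class == "BA"),
         n_sk = sum(class == "SK"), n_nd = sum(class == "ND"))
  }, by = gene_id]
  out <- as.data.frame(res)
  out[order(out$gene_id), , drop = FALSE]
}

#' Genome-wide frequency summary for a clone group (clonal estimator)
#'
#' Counts are over non-excluded autosomal genes expressed (non-ND) in at
#' least one clone of the group: how many show MA in any clone, and how many
#' of those qualify as random AEI (categories RANDOM_AEI or RANDOM_MA).
#' Percentages are of total expressed genes, truncated at two decimals (the
#' reporting convention for genome-wide gene frequencies; see
#' [aeiPercent()]).
#'
#' @param panel a [GeneCallPanel-class]
#' @param group developmental state
#' @param aei optional precomputed [detectRandomAEI()] table
#' @param digits,roundMode passed to [aeiPercent()]
#' @return one-row \code{data.frame} with counts, percentages and
#'   \code{estimator = "clonal"}
#' @export
summarizeFrequencies <- function(panel, group, aei = NULL, digits = 2,
                                 roundMode = "down") {
  ids <- cloneIdsOfState(panel, group)
  cc <- panelCallsFor(panel, ids)
  if (!nrow(cc)) {
    warning("empty panel for group '", group, "'")
    return(data.frame(group = group, n_expressed = 0L, n_ma_any_clone = 0L,
                      n_random_aei = 0L, pct_ma = 0, pct_random_aei = 0,
                      estimator = "clonal", stringsAsFactors = FALSE))
  }
  if (is.null(aei)) aei <- detectRandomAEI(panel, group)
  dt <- as.data.table(cc)
  byGene <- dt[, .(expressed = any(class != "ND"),
                   ma = any(class == "MA")), by = gene_id]
  nExpr <- sum(byGene$expressed)
  nMa <- sum(byGene$ma & byGene$expressed)
  randomGenes <- aei$gene_id[aei$category %in% c("RANDOM_AEI", "RANDOM_MA")]
  nRandom <- sum(byGene$gene_id[byGene$expressed] %in% randomGenes)
  data.frame(group = group, n_expressed = nExpr, n_ma_any_clone = nMa,
             n_random_aei = nRandom,
             pct_ma = aeiPercent(nMa, nExpr, digits, roundMode),
             pct_random_aei = aeiPercent(nRandom, nExpr, digits, roundMode),
             estimator = "clonal", stringsAsFactors = FALSE)
}

# state-level consensus class per gene: MA > SK > BA > ND
stateConsensus <- function(panel, state) {
  cc <- panelCallsFor(panel, cloneIdsOfState(panel, state))
  dt <- as.data.table(cc)
  res <- dt[, {
    cl <- if (any(class == "MA")) "MA"
      else if (any(class == "SK")) "SK"
      else if (any(class == "BA")) "BA" else "ND"
    list(class = cl)
  }, by = gene_id]
  as.data.frame(res)
}

transitionCategory <- function(before, after) {
  ifelse(before == "MA",
         ifelse(after == "BA", "RESET",
         ifelse(after == "MA", "RETAINED",
         ifelse(after == "SK", "TO_SKEWED", "LOST"))),
  ifelse(after == "MA", "DE_NOVO",
  ifelse(before == "BA" & after == "BA", "STABLE_BA", "OTHER")))
}

#' Allelic-class transitions between developmental states
#'
#' Per gene, the state-level consensus class before and after (MA if any
#' clone of the state is MA, else SK, else BA, else ND) and a transition
#' category: RESET (MA to BA), RETAINED (MA to MA), TO_SKEWED, LOST (MA to
#' ND), DE_NOVO (non-MA to MA), STABLE_BA, OTHER. The reset percentage is
#' reported both over all MA-before genes and over the subset still
#' detectably expressed afterwards (half-up, 0 decimals).
#'
#' @param panel a [GeneCallPanel-class] containing clones of both states
#' @param before,after developmental states
#' @param universe \code{"before-detected"} (genes non-ND in the before
#'   state; default) or \code{"all"}
#' @return list with \code{records} (per-gene table), \code{counts}
#'   (category table) and \code{summary} (MA-gene reset accounting)
#' @export
transitionAnalysis <- function(panel, before, after,
                               universe = c("before-detected", "all")) {
  universe <- match.arg(universe)
  cb <- stateConsensus(panel, before)
  ca <- stateConsensus(panel, after)
  rec <- merge(cb, ca, by = "gene_id", all = TRUE,
               suffixes = c("_before", "_after"))
  rec$class_before[is.na(rec$class_before)] <- "ND"
  rec$class_after[is.na(rec$class_after)] <- "ND"
  if (universe == "before-detected")
    rec <- rec[rec$class_before != "ND", , drop = FALSE]
  rec$category <- transitionCategory(rec$class_before, rec$class_after)
  counts <- table(factor(rec$category,
    levels = c("RESET", "RETAINED", "TO_SKEWED", "LOST", "DE_NOVO",
               "STABLE_BA", "OTHER")))
  maBefore <- rec[rec$class_before == "MA", , drop = FALSE]
  nMa <- nrow(maBefore)
  nDet <- sum(maBefore$class_after != "ND")
  nReset <- sum(maBefore$category == "RESET")
  summary <- data.frame(
    before = before, after = after,
    n_ma_before = nMa, n_ma_detected_after = nDet, n_reset = nReset,
    pct_reset_all = aeiPercent(nReset, max(nMa, 0L), 0, "half-up"),
    pct_reset_detected = aeiPercent(nReset, max(nDet, 0L), 0, "half-up"),
    stringsAsFactors = FALSE)
  structure(list(records = rec, counts = counts, summary = summary),
            class = "aeiTransitionAnalysis")
}

#' @export
print.aeiTransitionAnalysis <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Allelic transitions %s -> %s (%d genes)\n", s$before, s$after,
              nrow(x$records)))
  print(x$counts)
  cat(sprintf("MA before: %d; reset to BA: %d (%g%% of all, %g%% of the %d detected after)\n",
              s$n_ma_before, s$n_reset, s$pct_reset_all,
              s$pct_reset_detected, s$n_ma_detected_after))
  invisible(x)
}

#' Polyclonal estimator of the random-AEI frequency
#'
#' Random allele choice averages out in a polyclonal population, so a gene
#' MA in a clone but biallelic in the polyclonal sample is a random-AEI
#' candidate; a gene MA (or skewed) in the polyclonal sample as well is a
#' cis-genetic candidate. The estimator is the fraction of total expressed
#' genes that are clone-MA yet polyclonal-BA (truncated, two decimals).
#' When an AEI table is supplied, the fraction of clonally identified
#' random-AEI genes confirmed BA in the polyclonal sample is also reported
#' (half-up, 0 decimals).
#'
#' @param panel clonal [GeneCallPanel-class]
#' @param group developmental state of the clones
#' @param polyclonal calls for the polyclonal sample: a
#'   [GeneCallPanel-class] with one clone, or a \code{data.frame} with
#'   \code{gene_id} and \code{class}
#' @param aei optional [detectRandomAEI()] table for \code{group}
#' @return one-row \code{data.frame} with counts, percentages and
#'   \code{estimator = "polyclonal"}
#' @export
polyclonalEstimate <- function(panel, group, polyclonal, aei = NULL) {
  if (missing(polyclonal) || is.null(polyclonal))
    stop("polyclonal sample calls are required")
  if (is(polyclonal, "GeneCallPanel")) polyclonal <- geneCalls(polyclonal)
  polyclonal <- as.data.frame(polyclonal)
  stopifnot(all(c("gene_id", "class") %in% names(polyclonal)))
  ids <- cloneIdsOfState(panel, group)
  cc <- panelCallsFor(panel, ids)
  dt <- as.data.table(cc)
  byGene <- dt[, .(expressed = any(class != "ND"),
                   ma = any(class == "MA")), by = gene_id]
  nExpr <- sum(byGene$expressed)
  maGenes <- byGene$gene_id[byGene$ma & byGene$expressed]
  pcls <- setNames(polyclonal$class, polyclonal$gene_id)[maGenes]
  pcls[is.na(pcls)] <- "ND"
  nPolyExpr <- sum(pcls != "ND")
  nBa <- sum(pcls == "BA"); nMa <- sum(pcls == "MA"); nSk <- sum(pcls == "SK")
  out <- data.frame(group = group, n_expressed = nExpr,
                    n_clone_ma = length(maGenes),
                    n_poly_expressed = nPolyExpr,
                    n_poly_ba = nBa, n_poly_ma = nMa, n_poly_sk = nSk,
                    pct_random_aei = aeiPercent(nBa, nExpr, 2, "down"),
                    estimator = "polyclonal", stringsAsFactors = FALSE)
  if (!is.null(aei)) {
    randomGenes <- aei$gene_id[aei$category %in% c("RANDOM_AEI", "RANDOM_MA")]
    rcls <- setNames(polyclonal$class, polyclonal$gene_id)[randomGenes]
    rcls[is.na(rcls)] <- "ND"
    out$n_random_aei <- length(randomGenes)
    out$n_random_aei_poly_ba <- sum(rcls == "BA")
    out$pct_random_aei_poly_ba <-
      aeiPercent(out$n_random_aei_poly_ba, out$n_random_aei, 0, "half-up")
  }
  out
}

#' MA-call overlap between two clone sets
#'
#' Among genes MA in at least one clone of either panel and detectably
#' expressed in both panels, the fraction showing MA evidence in both
#' (half-up, one decimal).
#'
#' @param panelA,panelB [GeneCallPanel-class] objects (e.g. the clone sets
#'   derived from two different iPSC lines)
#' @return one-row \code{data.frame}: \code{n_ma_union_expressed_both},
#'   \code{n_ma_both}, \code{pct_ma_both}
#' @export
maOverlap <- function(panelA, panelB) {
  summ <- function(p) {
    dt <- as.data.table(panelCallsFor(p, cloneInfo(p)$clone_id))
    as.data.frame(dt[, .(expressed = any(class != "ND"),
                         ma = any(class == "MA")), by = gene_id])
  }
  a <- summ(panelA); b <- summ(panelB)
  m <- merge(a, b, by = "gene_id", all = TRUE, suffixes = c("_a", "_b"))
  m[is.na(m)] <- FALSE
  both <- m$expressed_a & m$expressed_b
  unionMa <- both & (m$ma_a | m$ma_b)
  shared <- both & m$ma_a & m$ma_b
  data.frame(n_ma_union_expressed_both = sum(unionMa),
             n_ma_both = sum(shared),
             pct_ma_both = aeiPercent(sum(shared), sum(unionMa), 1, "half-up"),
             stringsAsFactors = FALSE)
}

#' Exact hypergeometric overlap between an MA gene set and a hotspot set
#'
#' Builds the 2x2 table of membership against a background universe,
#' reports the fold enrichment observed/expected (expected =
#' |A||B|/|background|) and the two-tailed Fisher exact p-value (sum of
#' point probabilities not exceeding the observed table's, the
#' \code{stats::fisher.test} convention).
#'
#' @param maGenes,hotspotGenes gene sets (subsets of \code{background})
#' @param background the gene universe
#' @return list with \code{table}, \code{overlap}, \code{expected},
#'   \code{fold}, \code{p_value}
#' @export
hotspotOverlap <- function(maGenes, hotspotGenes, background) {
  background <- unique(background)
  if (!length(background)) stop("empty background gene universe")
  maGenes <- unique(maGenes); hotspotGenes <- unique(hotspotGenes)
  if (!all(maGenes %in% background) || !all(hotspotGenes %in% background))
    stop("gene sets must be subsets of the background")
  N <- length(background); a <- length(maGenes); b <- length(hotspotGenes)
  k <- length(intersect(maGenes, hotspotGenes))
  tab <- matrix(c(k, a - k, b - k, N - a - b + k), 2, 2,
                dimnames = list(inA = c("yes", "no"), inB = c("yes", "no")))
  expected <- a * b / N
  list(table = tab, overlap = k, expected = expected,
       fold = if (expected > 0) k / expected else NA_real_,
       p_value = fisher.test(tab, alternative = "two.sided")$p.value)
}
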