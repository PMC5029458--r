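## Worked-example call panels used in the documentation, regression tests
## and the acceptance script. These are hand-constructed fixture matrices
## whose marginal counts mirror a realistic clonal neural-stem-cell study
## design (five sister clones plus a polyclonal population, a
## reprogramming state pair, and two clone sets from different iPSC
## lines); they exercise the summary estimators at realistic scale without
## any array data.

maCall <- function(gene, clone, class, direction = NA_character_,
                   score = switch(class, MA = 0.4, SK = 0.15, BA = 0.02,
                                  ND = NA_real_)) {
  data.frame(gene_id = gene, clone_id = clone, n_informative =
               if (class == "ND") 0L else 3L,
             score = score, direction = direction, class = class,
             excluded_reason = NA_character_, stringsAsFactors = FALSE)
}

blockCalls <- function(genes, clones, classes, directions = NULL) {
  # classes: named per clone, recycled over genes
  out <- lapply(seq_along(clones), function(j) {
    cl <- classes[[j]]
    dir <- if (is.null(directions)) {
      ifelse(cl %in% c("MA", "SK"), "ALLELE_A", NA_character_)
    } else directions[[j]]
    do.call(rbind, lapply(genes, maCall, clone = clones[j], class = cl,
                          direction = dir))
  })
  do.call(rbind, out)
}

#' Worked-example clone panels
#'
#' Deterministic fixture [GeneCallPanel-class]s (no randomness, no array
#' data) whose summary counts match the worked examples used throughout the
#' package documentation: a five-clone panel with 7334 expressed genes of
#' which 126 are MA in at least one clone and 48 qualify as random AEI; a
#' matching polyclonal sample; a reprogramming state pair for the
#' random-AEI genes (23 MA before, 20 detected after, 17 reset) and for the
#' non-unequivocal MA genes (56 MA before, 26 reset, 20 retained, 5 skewed,
#' 5 lost); and two clone sets sharing 37 of 63 MA genes expressed in both.
#'
#' @return list with elements \code{nsc} (panel), \code{polyclonal} (call
#'   \code{data.frame}), \code{resetAEI} and \code{reset56} (state-pair
#'   panels), \code{cloneSetA}, \code{cloneSetB}
#' @examples
#' ex <- exampleStudyPanels()
#' summarizeFrequencies(ex$nsc, "iPSC_NSC")
#' @export
exampleStudyPanels <- function() {
  clones5 <- paste0("NSCc", 1:5)
  gRandom <- sprintf("RAEI%03d", 1:48)
  gConst <- sprintf("CMA%03d", 1:78)
  gBa <- sprintf("BA%04d", 1:7208)
  calls <- rbind(
    # random AEI: MA in clone 1, biallelic in the sisters
    blockCalls(gRandom, clones5,
               list("MA", "BA", "BA", "BA", "BA"),
               list("ALLELE_A", NA, NA, NA, NA)),
    # constant MA: same allele wherever detected
    blockCalls(gConst, clones5, list("MA", "MA", "MA", "MA", "MA"),
               as.list(rep("ALLELE_A", 5))),
    blockCalls(gBa, clones5, as.list(rep("BA", 5))))
  nsc <- GeneCallPanel(calls,
    data.frame(clone_id = clones5, developmental_state = "iPSC_NSC",
               stringsAsFactors = FALSE))

  # polyclonal sample: of the 126 clone-MA genes, 88 expressed there
  # (62 BA + 17 MA + 9 SK), 38 undetected; of the 48 random-AEI genes 42 BA
  polyClass <- c(rep("BA", 42), rep("ND", 4), "MA", "SK",        # 48 random
                 rep("BA", 20), rep("ND", 34), rep("MA", 16),    # 78 constant
                 rep("SK", 8))
  polyclonal <- data.frame(gene_id = c(gRandom, gConst),
                           class = polyClass, stringsAsFactors = FALSE)
  polyclonal <- rbind(polyclonal,
                      data.frame(gene_id = gBa, class = "BA",
                                 stringsAsFactors = FALSE))

  # reprogramming of the random-AEI genes: 23 MA before; after induced
  # pluripotency 20 detected of which 17 biallelic
  gA <- sprintf("R%02d", 1:23)
  resetAEI <- GeneCallPanel(rbind(
    blockCalls(gA, "SPC01", list("MA"), list("ALLELE_A")),
    blockCalls(gA[1:17], "iPS1", list("BA")),
    blockCalls(gA[18:20], "iPS1", list("MA"), list("ALLELE_A")),
    blockCalls(gA[21:23], "iPS1", list("ND"))),
    data.frame(clone_id = c("SPC01", "iPS1"),
               developmental_state = c("NSC_parental", "iPSC_early"),
               stringsAsFactors = FALSE))

  # the 56 additional MA genes: 26 reset, 20 retained, 5 skewed, 5 lost
  gB <- sprintf("M%02d", 1:56)
  reset56 <- GeneCallPanel(rbind(
    blockCalls(gB, "SPC01", list("MA"), list("ALLELE_A")),
    blockCalls(gB[1:26], "iPS1", list("BA")),
    blockCalls(gB[27:46], "iPS1", list("MA"), list("ALLELE_A")),
    blockCalls(gB[47:51], "iPS1", list("SK"), list("ALLELE_A")),
    blockCalls(gB[52:56], "iPS1", list("ND"))),
    data.frame(clone_id = c("SPC01", "iPS1"),
               developmental_state = c("NSC_parental", "iPSC_early"),
               stringsAsFactors = FALSE))

  # two clone sets: 37 genes MA in both; 15 MA only in A and 11 only in B
  # while expressed in the other (63 comparable MA genes in total); further
  # MA genes of each set are undetected in the other and drop out
  shared <- sprintf("S%02d", 1:37)
  aOnly <- sprintf("A%02d", 1:15); bOnly <- sprintf("B%02d", 1:11)
  aNd <- sprintf("AX%02d", 1:14); bNd <- sprintf("BX%02d", 1:48)
  backg <- sprintf("BG%04d", 1:3000)
  clonesA <- paste0("NSC1c", 1:3); clonesB <- paste0("NSC2c", 1:2)
  cloneSetA <- GeneCallPanel(rbind(
    blockCalls(c(shared, aOnly, aNd), clonesA,
               list("MA", "BA", "BA"), list("ALLELE_A", NA, NA)),
    blockCalls(c(bOnly, backg), clonesA, as.list(rep("BA", 3))),
    blockCalls(bNd, clonesA, as.list(rep("ND", 3)))),
    data.frame(clone_id = clonesA, developmental_state = "iPSC_NSC",
               stringsAsFactors = FALSE))
  cloneSetB <- GeneCallPanel(rbind(
    blockCalls(c(shared, bOnly, bNd), clonesB,
               list("MA", "BA"), list("ALLELE_A", NA)),
    blockCalls(c(aOnly, backg), clonesB, as.list(rep("BA", 2))),
    blockCalls(aNd, clonesB, as.list(rep("ND", 2)))),
    data.frame(clone_id = clonesB, developmental_state = "iPSC_NSC",
               stringsAsFactors = FALSE))

  list(nsc = nsc, polyclonal = polyclonal, resetAEI = resetAEI,
       reset56 = reset56, cloneSetA = cloneSetA, cloneSetB = cloneSetB)
}
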