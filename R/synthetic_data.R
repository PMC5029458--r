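## synthetic_data: seeded clone panels, polyclonal mixtures and methylation
## matrices with known ground truth.

#' Simulation configuration
#'
#' Returns the default configuration for the synthetic clone-panel
#' generator, optionally overridden via \code{...}. The defaults encode the
#' statistical structure the analysis assumes: heterozygous gDNA beta
#' centred on 0.5; biallelic cDNA at 0.5; cis-skewed genes at a fixed
#' per-gene allele ratio inside the skewed band; imprinted and random-MA
#' genes at a clear monoallelic ratio (r = 5); X-inactivated genes near
#' complete monoallelism (r = 99, the bimodal |delta-beta| ~ 0.5 pattern
#' used to calibrate the MA threshold); log-normal total intensities with a
#' configurable fraction pushed below the background filter; random-MA
#' allele choice an independent fair coin per gene and clone; and, in iPSC
#' states, a per-gene probability that a random-MA gene is reset to
#' biallelic expression. Class proportions deliberately enrich the rare
#' classes relative to genome-wide rates so truth-recovery statistics are
#' estimable on 1000-gene panels (see the methods vignette).
#'
#' @param ... overrides for any default field
#' @return a \code{simConfig} list
#' @export
simConfig <- function(...) {
  cfg <- list(
    nGenes = 1000,
    snpGeomProb = 0.5,        # SNPs per gene ~ 1 + Geom(p), capped
    maxSnpsPerGene = 8,
    classProportions = c(BA = 0.80, EQTL_SK = 0.05, IMPRINTED = 0.02,
                         RANDOM_MA = 0.08, X_INACTIVATED = 0.05),
    ratioSkRange = c(1.6, 2.2),  # within the skewed band, clear of both edges
    ratioMa = 5,                 # clear monoallelic expression
    ratioX = 99,                 # near-complete X inactivation
    nClones = c(NSC_parental = 5),
    foundersPerPolyclonal = 100,
    intensityMeanlog = log(3000),
    intensitySdlog = 0.4,
    fracLowIntensity = 0.05,  # cells engineered below the 750 filter
    pNotExpressed = 0.03,     # gene x clone dropout (cDNA below background)
    betaNoiseSd = 0.02,
    gdnaHetBiasSd = 0.01,
    pHomProbe = 0.15,         # probes homozygous in the genetic background
    homEps = 0.02,
    nIntergenicProbes = 20,
    resetProb = 0.85,         # random-MA genes reset to BA in iPSC states
    pMaCommit = 1,            # per-clone chance a random-MA gene commits to
                              # monoallelic expression (1 = classical model;
                              # < 1 leaves biallelic sister clones)
    methProbesPerRegion = c(TSS1500 = 2, TSS200 = 3, "5UTR" = 1,
                            "1stExon" = 2, Body = 4, "3UTR" = 1),
    methNoiseSd = 0.05,
    promoterEffect = 0.2,     # MA-clone hypermethylation at TSS200/1stExon/Island
    bodyEffect = 0.1,         # MA-clone hypomethylation in the gene body
    baselinePromoter = 0.2,
    baselineBody = 0.6,
    baselineOther = 0.5,
    nNonCpG = 200,
    nonCpGBaselineNSC = 0.02,
    nonCpGBaselineIPSC = 0.08,
    stateShiftSd = 0.02,      # shared per-state methylation deviation
    seed = 1
  )
  cfg <- modifyList(cfg, list(...))
  validateSimConfig(cfg)
}

validateSimConfig <- function(cfg) {
  p <- cfg$classProportions
  need <- c("BA", "EQTL_SK", "IMPRINTED", "RANDOM_MA", "X_INACTIVATED")
  if (!setequal(names(p), need))
    stop("classProportions must be named over: ", paste(need, collapse = ", "))
  if (abs(sum(p) - 1) > 1e-8) stop("classProportions must sum to 1")
  if (any(p < 0)) stop("classProportions must be nonnegative")
  sds <- c(cfg$betaNoiseSd, cfg$gdnaHetBiasSd, cfg$methNoiseSd,
           cfg$stateShiftSd)
  if (any(sds < 0)) stop("noise standard deviations must be >= 0")
  if (cfg$foundersPerPolyclonal < 1) stop("foundersPerPolyclonal must be >= 1")
  if (cfg$snpGeomProb <= 0 || cfg$snpGeomProb > 1)
    stop("snpGeomProb must be in (0, 1]")
  if (cfg$nGenes < 1) stop("nGenes must be >= 1")
  structure(cfg, class = "simConfig")
}

clipUnit <- function(x) pmin(pmax(x, 0), 1)

iPSCStates <- c("iPSC_early", "iPSC_late")

classBeta <- function(choice, ratio) {
  ifelse(choice == "BA", 0.5,
  ifelse(choice == "A", ratio / (ratio + 1), 1 / (ratio + 1)))
}

drawTotals <- function(n, cfg) {
  t <- rlnorm(n, cfg$intensityMeanlog, cfg$intensitySdlog)
  low <- runif(n) < cfg$fracLowIntensity
  t[low] <- runif(sum(low), 100, 740)
  t
}

#' Simulate a clonal allelic-expression panel with known truth
#'
#' Generates raw two-channel gDNA and cDNA intensity sets for a panel of
#' sister clones (and states), a probe manifest, a sample manifest pairing
#' every cDNA sample with its gDNA sample, and a truth table recording each
#' gene's class, ratio and per-clone expressed allele. Fully deterministic
#' under \code{cfg$seed}.
#'
#' @param cfg a [simConfig()]
#' @return an \code{aeiSimulation} list: \code{gdna}, \code{cdna}
#'   ([AllelicArraySet-class]s), \code{probes}, \code{samples},
#'   \code{truth}, \code{alleleChoices} (gene x clone matrix of
#'   \code{"A"}/\code{"B"}/\code{"BA"}), \code{expressed} (logical gene x
#'   clone), \code{config}
#' @export
simulatePanel <- function(cfg = simConfig()) {
  cfg <- validateSimConfig(cfg)
  set.seed(cfg$seed)
  n <- cfg$nGenes
  geneId <- sprintf("G%05d", seq_len(n))
  cls <- sample(names(cfg$classProportions), n, replace = TRUE,
                prob = cfg$classProportions)
  chrom <- ifelse(cls == "X_INACTIVATED", "X",
                  sample(as.character(1:22), n, replace = TRUE))
  ratio <- rep(1, n)
  ratio[cls == "EQTL_SK"] <- runif(sum(cls == "EQTL_SK"),
                                   cfg$ratioSkRange[1], cfg$ratioSkRange[2])
  ratio[cls %in% c("IMPRINTED", "RANDOM_MA")] <- cfg$ratioMa
  ratio[cls == "X_INACTIVATED"] <- cfg$ratioX
  fixedAllele <- ifelse(cls %in% c("EQTL_SK", "IMPRINTED"),
                        sample(c("A", "B"), n, replace = TRUE), NA)

  # the manifest's A/B labeling is arbitrary per SNP, so the haplotype
  # silenced by X inactivation maps to the A allele for some genes and the
  # B allele for others
  xFlip <- runif(n) < 0.5

  nsnp <- pmin(rgeom(n, cfg$snpGeomProb) + 1L, cfg$maxSnpsPerGene)
  probes <- data.frame(
    probe_id = sprintf("rs%06d", seq_len(sum(nsnp))),
    chromosome = rep(chrom, nsnp),
    position = sample.int(2e8, sum(nsnp)),
    allele_a = "A", allele_b = "B",
    gene_id = rep(geneId, nsnp),
    transcript_id = paste0(rep(geneId, nsnp), "_T1"),
    stringsAsFactors = FALSE)
  if (cfg$nIntergenicProbes > 0) {
    ig <- data.frame(
      probe_id = sprintf("rsIG%04d", seq_len(cfg$nIntergenicProbes)),
      chromosome = sample(as.character(1:22), cfg$nIntergenicProbes, TRUE),
      position = sample.int(2e8, cfg$nIntergenicProbes),
      allele_a = "A", allele_b = "B",
      gene_id = NA_character_, transcript_id = NA_character_,
      stringsAsFactors = FALSE)
    probes <- rbind(probes, ig)
  }
  np <- nrow(probes)
  het <- runif(np) >= cfg$pHomProbe
  homAllele <- ifelse(het, NA, sample(c("A", "B"), np, replace = TRUE))

  states <- rep(names(cfg$nClones), cfg$nClones)
  cloneId <- unlist(lapply(names(cfg$nClones), function(s)
    paste0(s, "_c", seq_len(cfg$nClones[[s]]))))
  nc <- length(cloneId)

  # per-clone expressed allele: the stochastic core of the generator
  choice <- matrix("BA", n, nc, dimnames = list(geneId, cloneId))
  for (j in seq_len(nc)) {
    st <- states[j]
    xChoice <- sample(c("A", "B"), 1)  # whole-X inactivation choice
    for (k in which(cls != "BA")) {
      choice[k, j] <- switch(cls[k],
        EQTL_SK = fixedAllele[k],
        IMPRINTED = fixedAllele[k],
        X_INACTIVATED = if (xFlip[k]) setdiff(c("A", "B"), xChoice)
          else xChoice,
        RANDOM_MA = if (runif(1) < cfg$pMaCommit)
          sample(c("A", "B"), 1) else "BA")
    }
    if (st %in% iPSCStates) {
      # epigenetic reprogramming resets most random-MA genes to biallelic
      reset <- cls == "RANDOM_MA" & runif(n) < cfg$resetProb
      choice[reset, j] <- "BA"
    }
  }
  expressed <- matrix(runif(n * nc) >= cfg$pNotExpressed, n, nc,
                      dimnames = list(geneId, cloneId))
  trueBeta <- matrix(classBeta(choice, ratio), n, nc,
                     dimnames = list(geneId, cloneId))

  gdnaId <- paste0(cloneId, "_gDNA")
  cdnaId <- paste0(cloneId, "_cDNA")
  samples <- rbind(
    data.frame(sample_id = gdnaId, material = "gDNA", clone_id = cloneId,
               developmental_state = states, paired_gdna = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(sample_id = cdnaId, material = "cDNA", clone_id = cloneId,
               developmental_state = states, paired_gdna = gdnaId,
               stringsAsFactors = FALSE))

  geneIdx <- match(probes$gene_id, geneId)  # NA for intergenic
  mkChannels <- function(beta, totals) {
    list(X = beta * totals, Y = (1 - beta) * totals)
  }
  homBeta <- function(idx) {
    b <- ifelse(homAllele[idx] == "A", 1 - cfg$homEps, cfg$homEps)
    clipUnit(b + rnorm(length(idx), 0, cfg$gdnaHetBiasSd))
  }
  Xg <- Yg <- matrix(NA_real_, np, nc, dimnames = list(probes$probe_id, gdnaId))
  Xc <- Yc <- matrix(NA_real_, np, nc, dimnames = list(probes$probe_id, cdnaId))
  for (j in seq_len(nc)) {
    bg <- numeric(np)
    bg[het] <- clipUnit(0.5 + rnorm(sum(het), 0, cfg$gdnaHetBiasSd))
    bg[!het] <- homBeta(which(!het))
    ch <- mkChannels(bg, drawTotals(np, cfg))
    Xg[, j] <- ch$X; Yg[, j] <- ch$Y

    bc <- numeric(np)
    gOfP <- geneIdx
    bc[het] <- clipUnit(
      ifelse(is.na(gOfP[het]), 0.5, trueBeta[cbind(gOfP[het], j)]) +
        rnorm(sum(het), 0, cfg$betaNoiseSd))
    bc[!het] <- homBeta(which(!het))
    tc <- drawTotals(np, cfg)
    off <- !is.na(gOfP) & !expressed[cbind(pmax(gOfP, 1L), j)]
    tc[off] <- runif(sum(off), 50, 400)
    ch <- mkChannels(bc, tc)
    Xc[, j] <- ch$X; Yc[, j] <- ch$Y
  }

  truth <- data.frame(gene_id = geneId, truth_class = cls,
                      chromosome = chrom, true_ratio = ratio,
                      fixed_allele = fixedAllele, n_snps = nsnp,
                      stringsAsFactors = FALSE)
  structure(list(
    gdna = AllelicArraySet(Xg, Yg, material = "gDNA"),
    cdna = AllelicArraySet(Xc, Yc, material = "cDNA"),
    probes = probes, samples = samples, truth = truth,
    alleleChoices = choice, expressed = expressed, trueBeta = trueBeta,
    config = cfg), class = "aeiSimulation")
}

#' @export
print.aeiSimulation <- function(x, ...) {
  cat(sprintf("aeiSimulation: %d genes, %d probes, %d clones (seed %d)\n",
              nrow(x$truth), nrow(x$probes), ncol(x$alleleChoices),
              x$config$seed))
  print(table(x$truth$truth_class))
  invisible(x)
}

#' Simulate a polyclonal cDNA sample from the panel's truth
#'
#' Every founder cell independently re-draws the clone-level allele choice
#' (fair coin for random-MA genes, one whole-X draw per founder for
#' X-inactivated genes; deterministic classes keep their value); the
#' polyclonal gene beta is the founder average, so random allele choices
#' mix toward the biallelic 0.5 while cis-driven skews persist.
#'
#' @param sim an \code{aeiSimulation} from [simulatePanel()]
#' @param founders number of founder cells (default from the config)
#' @return list with \code{gdna} and \code{cdna} single-sample
#'   [AllelicArraySet-class]s, the two \code{samples} manifest rows, and
#'   the per-gene \code{trueBeta}
#' @export
simulatePolyclonal <- function(sim, founders = sim$config$foundersPerPolyclonal) {
  cfg <- sim$config
  if (founders < 1) stop("founders must be >= 1")
  set.seed(cfg$seed + 1L)
  truth <- sim$truth
  n <- nrow(truth)
  betaA <- truth$true_ratio / (truth$true_ratio + 1)
  base <- ifelse(truth$truth_class == "BA", 0.5,
          ifelse(is.na(truth$fixed_allele), NA,
                 ifelse(truth$fixed_allele == "A", betaA, 1 - betaA)))
  k <- rbinom(n, founders, 0.5)
  rm <- truth$truth_class == "RANDOM_MA"
  base[rm] <- (k[rm] * betaA[rm] + (founders - k[rm]) * (1 - betaA[rm])) /
    founders
  kx <- rbinom(1, founders, 0.5)  # founders sharing one active X
  xi <- truth$truth_class == "X_INACTIVATED"
  base[xi] <- (kx * betaA[xi] + (founders - kx) * (1 - betaA[xi])) / founders

  probes <- sim$probes
  np <- nrow(probes)
  geneIdx <- match(probes$gene_id, truth$gene_id)
  # het status is a property of the genetic background: recover it from the
  # panel's first gDNA sample rather than re-drawing
  gBeta0 <- intensityX(sim$gdna)[, 1] /
    (intensityX(sim$gdna)[, 1] + intensityY(sim$gdna)[, 1])
  hetProbe <- gBeta0 > 0.3 & gBeta0 < 0.7
  bc <- numeric(np)
  bc[hetProbe] <- clipUnit(
    ifelse(is.na(geneIdx[hetProbe]), 0.5, base[geneIdx[hetProbe]]) +
      rnorm(sum(hetProbe), 0, cfg$betaNoiseSd))
  bc[!hetProbe] <- clipUnit(round(gBeta0[!hetProbe]) *
      (1 - 2 * cfg$homEps) + cfg$homEps +
      rnorm(sum(!hetProbe), 0, cfg$gdnaHetBiasSd))
  tc <- drawTotals(np, cfg)
  bg <- numeric(np)
  bg[hetProbe] <- clipUnit(0.5 + rnorm(sum(hetProbe), 0, cfg$gdnaHetBiasSd))
  bg[!hetProbe] <- bc[!hetProbe]
  tg <- drawTotals(np, cfg)
  gid <- "polyclonal_gDNA"; cid <- "polyclonal_cDNA"
  mk <- function(b, t, nm) {
    X <- matrix(b * t, np, 1, dimnames = list(probes$probe_id, nm))
    Y <- matrix((1 - b) * t, np, 1, dimnames = list(probes$probe_id, nm))
    list(X = X, Y = Y)
  }
  cg <- mk(bg, tg, gid); ccd <- mk(bc, tc, cid)
  samples <- data.frame(
    sample_id = c(gid, cid), material = c("gDNA", "cDNA"),
    clone_id = "polyclonal", developmental_state = "polyclonal",
    paired_gdna = c(NA, gid), stringsAsFactors = FALSE)
  list(gdna = AllelicArraySet(cg$X, cg$Y, material = "gDNA"),
       cdna = AllelicArraySet(ccd$X, ccd$Y, material = "cDNA"),
       samples = samples,
       trueBeta = setNames(base, truth$gene_id))
}

#' Simulate a methylation beta matrix matching the panel's allelic truth
#'
#' One methylation sample per clone. Promoter-proximal probes (TSS200,
#' first exon — annotated as CpG-island probes) of a gene are elevated by
#' \code{promoterEffect} in clones where that gene is monoallelically
#' expressed, while gene-body probes are reduced by \code{bodyEffect};
#' biallelic clones sit at baseline. Non-CpG probes are elevated in
#' iPSC-state clones. Beta noise is beta-distributed around the target
#' mean, and each developmental state carries a small shared probe-level
#' deviation so samples cluster by state.
#'
#' @param sim an \code{aeiSimulation}, or a list with elements
#'   \code{truth}, \code{alleleChoices} and \code{clones} (a
#'   \code{data.frame} with \code{clone_id}, \code{developmental_state})
#' @param cfg a [simConfig()] (default: the simulation's own)
#' @return a methylation \code{SummarizedExperiment} (see
#'   [makeMethylationSet()]) with samples named by clone
#' @export
simulateMethylation <- function(sim, cfg = sim$config) {
  cfg <- validateSimConfig(cfg)
  set.seed(cfg$seed + 2L)
  truth <- sim$truth
  choice <- sim$alleleChoices
  clones <- if (!is.null(sim$clones)) sim$clones else {
    sm <- sim$samples[sim$samples$material == "cDNA", ]
    data.frame(clone_id = sm$clone_id,
               developmental_state = sm$developmental_state,
               stringsAsFactors = FALSE)
  }
  ppr <- cfg$methProbesPerRegion
  regions <- rep(names(ppr), ppr)
  ngene <- nrow(truth)
  ann <- data.frame(
    cpg_id = paste0("cg_", rep(truth$gene_id, each = length(regions)), "_",
                    rep(regions, ngene),
                    rep(unlist(lapply(ppr, seq_len)), ngene)),
    chromosome = rep(truth$chromosome, each = length(regions)),
    position = sample.int(2e8, ngene * length(regions)),
    gene_region = rep(regions, ngene),
    gene_id = rep(truth$gene_id, each = length(regions)),
    island_relation = rep(ifelse(regions %in% c("TSS200", "1stExon", "5UTR"),
                                 "Island",
                          ifelse(regions == "TSS1500", "N_Shore", "OpenSea")),
                          ngene),
    site_class = "CpG", stringsAsFactors = FALSE)
  if (cfg$nNonCpG > 0) {
    ann <- rbind(ann, data.frame(
      cpg_id = sprintf("ch_%05d", seq_len(cfg$nNonCpG)),
      chromosome = sample(as.character(1:22), cfg$nNonCpG, TRUE),
      position = sample.int(2e8, cfg$nNonCpG),
      gene_region = "", gene_id = NA_character_,
      island_relation = "OpenSea", site_class = "non-CpG",
      stringsAsFactors = FALSE))
  }
  np <- nrow(ann)
  baseline <- ifelse(ann$site_class == "non-CpG", cfg$nonCpGBaselineNSC,
              ifelse(ann$gene_region %in% c("TSS1500", "TSS200", "5UTR",
                                            "1stExon"), cfg$baselinePromoter,
              ifelse(ann$gene_region == "Body", cfg$baselineBody,
                     cfg$baselineOther)))
  stateShift <- lapply(unique(clones$developmental_state), function(s)
    rnorm(np, 0, cfg$stateShiftSd))
  names(stateShift) <- unique(clones$developmental_state)

  geneIdx <- match(ann$gene_id, truth$gene_id)
  upProbe <- ann$gene_region %in% c("TSS200", "1stExon")
  bodyProbe <- ann$gene_region == "Body"
  beta <- matrix(NA_real_, np, nrow(clones),
                 dimnames = list(ann$cpg_id, clones$clone_id))
  for (j in seq_len(nrow(clones))) {
    cl <- clones$clone_id[j]; st <- clones$developmental_state[j]
    m <- baseline
    if (st %in% iPSCStates)
      m[ann$site_class == "non-CpG"] <- cfg$nonCpGBaselineIPSC
    maGene <- !is.na(geneIdx) & choice[cbind(pmax(geneIdx, 1L),
                                             match(cl, colnames(choice)))] %in%
      c("A", "B")
    m[maGene & upProbe] <- m[maGene & upProbe] + cfg$promoterEffect
    m[maGene & bodyProbe] <- m[maGene & bodyProbe] - cfg$bodyEffect
    m <- pmin(pmax(m + stateShift[[st]], 0.02), 0.98)
    phi <- pmax(m * (1 - m) / cfg$methNoiseSd^2 - 1, 2)
    beta[, j] <- rbeta(np, m * phi, (1 - m) * phi)
  }
  makeMethylationSet(beta, ann)
}
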