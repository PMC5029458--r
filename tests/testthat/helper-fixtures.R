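# Small in-code fixtures shared across test files.

writeIntensityTSV <- function(rows) {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("SNP Name\tSample ID\tX Raw\tY Raw", rows), tsv)
  tsv
}

oneSampleManifest <- function(clone = "S1") {
  data.frame(
    sample_id = c(paste0(clone, "_g"), paste0(clone, "_c")),
    material = c("gDNA", "cDNA"),
    clone_id = clone,
    developmental_state = "NSC_parental",
    paired_gdna = c(NA, paste0(clone, "_g")),
    stringsAsFactors = FALSE)
}

rawArraySet <- function(X, Y, material = "cDNA") {
  AllelicArraySet(X, Y, material = material, normalized = FALSE)
}

# run the calling stages of the pipeline on a simulation, optionally with a
# polyclonal sample appended
callSimPanel <- function(sim, poly = NULL, threshold = 750,
                         normalize = TRUE) {
  gdnaRaw <- sim$gdna; cdnaRaw <- sim$cdna; samples <- sim$samples
  if (!is.null(poly)) {
    gdnaRaw <- AllelicArraySet(cbind(intensityX(gdnaRaw), intensityX(poly$gdna)),
                               cbind(intensityY(gdnaRaw), intensityY(poly$gdna)),
                               material = "gDNA")
    cdnaRaw <- AllelicArraySet(cbind(intensityX(cdnaRaw), intensityX(poly$cdna)),
                               cbind(intensityY(cdnaRaw), intensityY(poly$cdna)),
                               material = "cDNA")
    samples <- rbind(samples, poly$samples)
  }
  if (normalize) {
    gdna <- computeBeta(quantileNormalizeChannels(gdnaRaw), threshold)
    cdna <- computeBeta(quantileNormalizeChannels(cdnaRaw), threshold)
  } else {
    # beta-level route: consume the generator's intensities as exact
    asBeta <- function(set, mat) {
      X <- intensityX(set); Y <- intensityY(set)
      makeBetaSet(X / (X + Y), X + Y, mat, threshold)
    }
    gdna <- asBeta(gdnaRaw, "gDNA")
    cdna <- asBeta(cdnaRaw, "cDNA")
  }
  gt <- callGenotypes(gdna)
  deltas <- computeSnpDelta(cdna, gdna, gt, samples)
  scores <- aggregateGeneScores(deltas, sim$probes)
  cloneTab <- unique(samples[samples$material == "cDNA",
                             c("clone_id", "developmental_state")])
  classifyCalls(scores, cloneTab, sim$probes,
                imprinted = sim$truth$gene_id[
                  sim$truth$truth_class == "IMPRINTED"])
}

methFixtureFromPairs <- function(x, y, region = "TSS200", gene = "GENE1") {
  n <- length(x)
  ann <- data.frame(cpg_id = paste0("cgp", seq_len(n)), chromosome = "1",
                    position = seq_len(n), gene_region = region,
                    gene_id = gene, island_relation = "OpenSea",
                    site_class = "CpG", stringsAsFactors = FALSE)
  beta <- cbind(ma1 = x, ba1 = y)
  rownames(beta) <- ann$cpg_id
  makeMethylationSet(beta, ann)
}

# panel from a compact class specification: list(clone = c(gene = "MA:A", ...))
specPanel <- function(spec, state = "NSC_parental") {
  rows <- list()
  for (cl in names(spec)) {
    v <- spec[[cl]]
    parts <- strsplit(v, ":", fixed = TRUE)
    cls <- vapply(parts, `[`, "", 1)
    dir <- vapply(parts, function(p) {
      if (length(p) > 1) paste0("ALLELE_", p[2]) else NA_character_
    }, "")
    rows[[cl]] <- data.frame(
      gene_id = names(v), clone_id = cl,
      n_informative = ifelse(cls == "ND", 0L, 2L),
      score = ifelse(cls == "MA", 0.4,
              ifelse(cls == "SK", 0.15, ifelse(cls == "BA", 0.02, NA_real_))),
      direction = dir, class = cls, excluded_reason = NA_character_,
      stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, rows)
  GeneCallPanel(calls, data.frame(clone_id = names(spec),
                                  developmental_state = state,
                                  stringsAsFactors = FALSE))
}
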