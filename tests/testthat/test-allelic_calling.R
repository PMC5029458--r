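betaSet1 <- function(beta, material = "gDNA", pass = TRUE) {
  b <- matrix(beta, length(beta), 1,
              dimnames = list(paste0("rs", seq_along(beta)), "s1"))
  tot <- b; tot[] <- ifelse(rep(pass, length.out = length(beta)), 1000, 100)
  makeBetaSet(b, tot, material = material)
}

test_that("genotype bands assign HET, HOM and NO_CALL correctly", {
  g <- callGenotypes(betaSet1(c(0.50, 0.05, 0.75, 0.95, 0.30, 0.70)))
  expect_equal(unname(g[, 1]),
               c("HET", "HOM_B", "NO_CALL", "HOM_A", "HET", "HET"))
  # cells failing the intensity filter are never called
  gf <- callGenotypes(betaSet1(0.5, pass = FALSE))
  expect_equal(unname(gf[, 1]), "NO_CALL")
  expect_error(callGenotypes(betaSet1(0.5), hetLow = 0.7, hetHigh = 0.3),
               "hetLow")
  expect_error(callGenotypes(betaSet1(0.5, material = "cDNA")), "gDNA")
})

deltaFixture <- function(cdnaBeta, cdnaPass = TRUE) {
  n <- length(cdnaBeta)
  probes <- paste0("rs", seq_len(n))
  gB <- matrix(0.5, n, 1, dimnames = list(probes, "S1_g"))
  gT <- gB; gT[] <- 1000
  cB <- matrix(cdnaBeta, n, 1, dimnames = list(probes, "S1_c"))
  cT <- cB; cT[] <- ifelse(rep(cdnaPass, length.out = n), 1000, 700)
  list(gdna = makeBetaSet(gB, gT, "gDNA"),
       cdna = makeBetaSet(cB, cT, "cDNA"),
       gt = matrix("HET", n, 1, dimnames = list(probes, "S1_g")),
       samples = oneSampleManifest())
}

test_that("delta-beta is cDNA minus heterozygous gDNA, A allele positive", {
  f <- deltaFixture(c(0.75, 0.50, 0.25))
  d <- computeSnpDelta(f$cdna, f$gdna, f$gt, f$samples)
  expect_equal(d$delta_beta, c(0.25, 0, -0.25))
  expect_equal(d$abs_delta, c(0.25, 0, 0.25))
  expect_equal(unique(d$clone_id), "S1")
})

test_that("filtered cDNA cells and unpaired samples are handled", {
  # HET probe whose cDNA total fails the background filter emits no record
  f <- deltaFixture(c(0.9, 0.9), cdnaPass = c(TRUE, FALSE))
  d <- computeSnpDelta(f$cdna, f$gdna, f$gt, f$samples)
  expect_equal(nrow(d), 1L)
  expect_equal(d$probe_id, "rs1")
  # non-HET probes contribute nothing
  f2 <- deltaFixture(c(0.9, 0.9))
  f2$gt[2, 1] <- "HOM_A"
  expect_equal(nrow(computeSnpDelta(f2$cdna, f2$gdna, f2$gt, f2$samples)), 1L)
  # cDNA sample whose paired gDNA has no genotype calls is fatal
  f3 <- deltaFixture(0.9)
  colnames(f3$gt) <- "OTHER_g"
  expect_error(computeSnpDelta(f3$cdna, f3$gdna, f3$gt, f3$samples),
               "unpaired")
})

scoreProbes <- data.frame(
  probe_id = paste0("rs", 1:4),
  chromosome = c("1", "1", "1", "X"),
  position = 1:4 * 100,
  gene_id = c("GENE1", "GENE1", "GENE1", "XGENE"),
  transcript_id = c("GENE1_T1", "GENE1_T1", "GENE1_T2", "XGENE_T1"),
  stringsAsFactors = FALSE)

mkDeltas <- function(deltas, probes = paste0("rs", seq_along(deltas)),
                     clone = "c1") {
  data.frame(probe_id = probes, clone_id = clone, sample_id = paste0(clone, "_c"),
             delta_beta = deltas, abs_delta = abs(deltas),
             stringsAsFactors = FALSE)
}

test_that("gene scores are mean absolute delta-beta with a direction call", {
  s <- aggregateGeneScores(mkDeltas(c(0.22, 0.18, 0.26)), scoreProbes)
  expect_equal(s$score[s$gene_id == "GENE1"], 0.22)
  expect_equal(s$direction[s$gene_id == "GENE1"], "ALLELE_A")
  expect_equal(s$n_informative[s$gene_id == "GENE1"], 3L)
  # mixed signs at or above the skew threshold are discordant
  s2 <- aggregateGeneScores(mkDeltas(c(0.2, -0.2), paste0("rs", 1:2)),
                            scoreProbes)
  expect_equal(s2$score, 0.2)
  expect_equal(s2$direction, "DISCORDANT")
  # single negative SNP
  s3 <- aggregateGeneScores(mkDeltas(-0.25, "rs1"), scoreProbes)
  expect_equal(s3$score, 0.25)
  expect_equal(s3$direction, "ALLELE_B")
  # sub-threshold SNPs do not vote on direction
  s4 <- aggregateGeneScores(mkDeltas(c(0.02, -0.03), paste0("rs", 1:2)),
                            scoreProbes)
  expect_true(is.na(s4$direction))
})

test_that("probes without gene membership vanish; isoform level works", {
  d <- mkDeltas(c(0.1, 0.2), c("rs1", "rsNOWHERE"))
  s <- aggregateGeneScores(d, scoreProbes)
  expect_equal(s$gene_id, "GENE1")
  expect_equal(s$n_informative, 1L)
  st <- aggregateGeneScores(mkDeltas(c(0.1, 0.2, 0.3), paste0("rs", 1:3)),
                            scoreProbes, level = "transcript")
  expect_setequal(st$gene_id, c("GENE1_T1", "GENE1_T2"))
  expect_equal(st$score[st$gene_id == "GENE1_T1"], 0.15)
  expect_equal(st$score[st$gene_id == "GENE1_T2"], 0.3)
})

test_that("the penalty hook shrinks scores by n/(n+k)", {
  d <- mkDeltas(c(0.2, 0.3))
  s0 <- aggregateGeneScores(d, scoreProbes)
  s1 <- aggregateGeneScores(d, scoreProbes, penalty = penaltyConfig(TRUE, 2))
  expect_equal(s1$score, s0$score * 2 / (2 + 2))
  # k = 0 leaves scores untouched even when enabled
  s2 <- aggregateGeneScores(d, scoreProbes, penalty = penaltyConfig(TRUE, 0))
  expect_equal(s2$score, s0$score)
  expect_error(penaltyConfig(TRUE, -1))
})

clonesDf <- data.frame(clone_id = "c1", developmental_state = "NSC_parental",
                       stringsAsFactors = FALSE)

test_that("classification bands are lower-closed and produce a partition", {
  sc <- data.frame(gene_id = paste0("g", 1:6), clone_id = "c1",
                   n_informative = 1L,
                   score = c(0.05, 0.15, 0.25, 0.1, 0.2, 0),
                   direction = "ALLELE_A", stringsAsFactors = FALSE)
  p <- classifyCalls(sc, clonesDf)
  cls <- setNames(geneCalls(p)$class, geneCalls(p)$gene_id)
  expect_equal(unname(cls[paste0("g", 1:6)]),
               c("BA", "SK", "MA", "SK", "MA", "BA"))
  # every gene x clone gets exactly one class
  expect_equal(nrow(geneCalls(p)), 6L)
})

test_that("exclusion lists and chrX routing are applied", {
  sc <- data.frame(gene_id = c("GENE1", "XGENE", "MEG3", "PCDHA1"),
                   clone_id = "c1", n_informative = 1L, score = 0.3,
                   direction = "ALLELE_A", stringsAsFactors = FALSE)
  probes <- rbind(scoreProbes,
                  data.frame(probe_id = c("rs5", "rs6"),
                             chromosome = c("14", "5"), position = c(1, 2),
                             gene_id = c("MEG3", "PCDHA1"),
                             transcript_id = NA, stringsAsFactors = FALSE))
  p <- classifyCalls(sc, clonesDf, probes, imprinted = "MEG3",
                     protocadherin = "PCDHA1")
  cc <- geneCalls(p)
  expect_equal(cc$excluded_reason[cc$gene_id == "MEG3"], "imprinted")
  expect_equal(cc$excluded_reason[cc$gene_id == "PCDHA1"], "protocadherin")
  expect_equal(cc$excluded_reason[cc$gene_id == "XGENE"], "chrX")
  expect_true(is.na(cc$excluded_reason[cc$gene_id == "GENE1"]))
  expect_equal(sort(unique(chrXReport(p)$gene_id)), "XGENE")
  # excluded genes never reach the autosomal AEI detector
  p2 <- classifyCalls(rbind(sc, within(sc, clone_id <- "c2")),
                      rbind(clonesDf,
                            data.frame(clone_id = "c2",
                                       developmental_state = "NSC_parental")),
                      probes, imprinted = "MEG3", protocadherin = "PCDHA1")
  aei <- detectRandomAEI(p2, "NSC_parental")
  expect_setequal(aei$gene_id, "GENE1")
})

test_that("genes below minInformative become ND with no score", {
  sc <- data.frame(gene_id = "g1", clone_id = "c1", n_informative = 1L,
                   score = 0.3, direction = "ALLELE_A",
                   stringsAsFactors = FALSE)
  p <- classifyCalls(sc, clonesDf, minInformative = 2)
  expect_equal(geneCalls(p)$class, "ND")
  expect_true(is.na(geneCalls(p)$score))
})

test_that("delta-to-ratio mapping hits the published anchors", {
  expect_identical(deltaToRatio(0.1), 1.5)
  expect_identical(deltaToRatio(0), 1)
  expect_equal(deltaToRatio(0.2), 7 / 3)  # ~2.33
  expect_identical(deltaToRatio(0.5), Inf)
  # strictly increasing on [0, 0.5)
  d <- seq(0, 0.49, by = 0.01)
  expect_true(all(diff(deltaToRatio(d)) > 0))
  expect_error(deltaToRatio(-0.1))
})

test_that("gene lists parse with comments stripped", {
  f <- tempfile()
  writeLines(c("# imprinted genes", "MEG3", "H19  ", "", "SNRPN # classic"), f)
  expect_equal(readGeneList(f), c("MEG3", "H19", "SNRPN"))
})
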