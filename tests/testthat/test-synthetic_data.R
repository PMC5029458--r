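test_that("simulation configs are validated", {
  expect_error(simConfig(classProportions = c(BA = 1)), "named over")
  expect_error(simConfig(classProportions = c(BA = 0.9, EQTL_SK = 0.2,
                                              IMPRINTED = 0, RANDOM_MA = 0,
                                              X_INACTIVATED = 0)), "sum to 1")
  expect_error(simConfig(betaNoiseSd = -0.1), ">= 0")
  expect_error(simConfig(foundersPerPolyclonal = 0), "founders")
  expect_error(simConfig(snpGeomProb = 0), "snpGeomProb")
})

test_that("the generator is fully deterministic under its seed", {
  cfg <- simConfig(nGenes = 80, seed = 5)
  s1 <- simulatePanel(cfg); s2 <- simulatePanel(cfg)
  expect_identical(intensityX(s1$cdna), intensityX(s2$cdna))
  expect_identical(intensityY(s1$gdna), intensityY(s2$gdna))
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$alleleChoices, s2$alleleChoices)
  p1 <- simulatePolyclonal(s1); p2 <- simulatePolyclonal(s2)
  expect_identical(intensityX(p1$cdna), intensityX(p2$cdna))
  m1 <- simulateMethylation(s1); m2 <- simulateMethylation(s2)
  expect_identical(SummarizedExperiment::assay(m1, "beta"),
                   SummarizedExperiment::assay(m2, "beta"))
  # a different seed gives different draws
  s3 <- simulatePanel(simConfig(nGenes = 80, seed = 6))
  expect_false(identical(intensityX(s1$cdna), intensityX(s3$cdna)))
})

test_that("random-MA allele choice is a fair coin, independent per clone", {
  cfg <- simConfig(nGenes = 200,
                   classProportions = c(BA = 0, EQTL_SK = 0, IMPRINTED = 0,
                                        RANDOM_MA = 1, X_INACTIVATED = 0),
                   nClones = c(NSC_parental = 5), seed = 9)
  sim <- simulatePanel(cfg)
  ch <- sim$alleleChoices
  expect_true(all(ch %in% c("A", "B")))
  fracA <- mean(ch == "A")
  n <- length(ch)  # 1000 gene x clone draws
  expect_equal(n, 1000L)
  expect_lt(abs(fracA - 0.5), 3 * sqrt(0.25 / n))
})

# expected class per gene x clone from the generator's truth
simExpectedClass <- function(sim) {
  bt <- sim$trueBeta
  d <- abs(bt - 0.5)
  cls <- ifelse(d < 0.1, "BA", ifelse(d < 0.2, "SK", "MA"))
  dimnames(cls) <- dimnames(bt)
  cls
}

test_that("zero-noise beta panels are classified exactly as generated", {
  cfg <- simConfig(nGenes = 150, betaNoiseSd = 0, gdnaHetBiasSd = 0,
                   fracLowIntensity = 0, pNotExpressed = 0,
                   nClones = c(NSC_parental = 3), seed = 13)
  sim <- simulatePanel(cfg)
  panel <- callSimPanel(sim, normalize = FALSE)
  cc <- geneCalls(panel)
  cc <- cc[cc$n_informative >= 1, ]
  expClass <- simExpectedClass(sim)
  expect_equal(cc$class, unname(expClass[cbind(cc$gene_id, cc$clone_id)]))
  # direction matches the chosen allele for monoallelic calls
  truthOf <- setNames(sim$truth$truth_class, sim$truth$gene_id)
  ma <- cc[cc$class == "MA" &
             truthOf[cc$gene_id] %in% c("RANDOM_MA", "IMPRINTED"), ]
  chosen <- sim$alleleChoices[cbind(ma$gene_id, ma$clone_id)]
  expect_equal(ma$direction, paste0("ALLELE_", chosen))
})

test_that("the raw-intensity route recovers >=98% of zero-noise classes", {
  # quantile normalization of degenerate (zero-variance) intensity clouds
  # misplaces a small fraction of probes across inter-cloud gaps; the
  # full pipeline therefore recovers slightly less than all classes even
  # at zero measurement noise (see the methods vignette)
  cfg <- simConfig(nGenes = 600, betaNoiseSd = 0, gdnaHetBiasSd = 0,
                   fracLowIntensity = 0, pNotExpressed = 0,
                   nClones = c(NSC_parental = 3), seed = 13)
  sim <- simulatePanel(cfg)
  cc <- geneCalls(callSimPanel(sim))
  cc <- cc[cc$n_informative >= 1, ]
  expClass <- simExpectedClass(sim)
  agree <- cc$class == expClass[cbind(cc$gene_id, cc$clone_id)]
  expect_gte(mean(agree), 0.98)
})

test_that("X-inactivated genes show the bimodal near-0.5 delta-beta", {
  cfg <- simConfig(nGenes = 200, seed = 17)
  sim <- simulatePanel(cfg)
  panel <- callSimPanel(sim)
  xr <- chrXReport(panel)
  xr <- xr[xr$class != "ND", ]
  expect_gt(nrow(xr), 0)
  expect_true(all(xr$score > 0.4))
  expect_true(all(xr$class == "MA"))
})

test_that("polyclonal mixtures behave as binomial founder averages", {
  cfg <- simConfig(nGenes = 120, seed = 19)
  sim <- simulatePanel(cfg)
  expect_error(simulatePolyclonal(sim, founders = 0), "founders")
  truth <- sim$truth
  rm <- truth$truth_class == "RANDOM_MA"
  sk <- truth$truth_class == "EQTL_SK"
  # a single founder reproduces the clone-level two-point distribution
  p1 <- simulatePolyclonal(sim, founders = 1)
  bA <- truth$true_ratio / (truth$true_ratio + 1)
  expect_true(all(abs(p1$trueBeta[rm] - bA[rm]) < 1e-9 |
                  abs(p1$trueBeta[rm] - (1 - bA[rm])) < 1e-9))
  # many founders average random choices toward the biallelic 0.5
  pBig <- simulatePolyclonal(sim, founders = 20000)
  expect_true(all(abs(pBig$trueBeta[rm] - 0.5) < 0.03))
  # cis-skewed genes keep their clonal value regardless of founders
  skBeta <- ifelse(truth$fixed_allele[sk] == "A", bA[sk], 1 - bA[sk])
  expect_equal(unname(pBig$trueBeta[sk]), skBeta)
})

test_that("simulated methylation carries the promoter/body allelic effects", {
  truth <- data.frame(gene_id = c("g1", "g2"), truth_class = "RANDOM_MA",
                      chromosome = "1", true_ratio = 5,
                      fixed_allele = NA, n_snps = 2,
                      stringsAsFactors = FALSE)
  choice <- matrix(c("A", "BA", "B", "BA"), 2, 2, byrow = TRUE,
                   dimnames = list(truth$gene_id, c("cMA", "cBA")))
  clones <- data.frame(clone_id = c("cMA", "cBA"),
                       developmental_state = "iPSC_NSC",
                       stringsAsFactors = FALSE)
  cfg <- simConfig(nGenes = 2, promoterEffect = 0.2, bodyEffect = 0.1,
                   methNoiseSd = 0.03,
                   methProbesPerRegion = c(TSS1500 = 0, TSS200 = 20,
                                           "5UTR" = 0, "1stExon" = 0,
                                           Body = 20, "3UTR" = 0),
                   nNonCpG = 50, seed = 23)
  se <- simulateMethylation(list(truth = truth, alleleChoices = choice,
                                 clones = clones), cfg)
  tss <- pairedRegionTest(se, truth$gene_id, "TSS200", "cMA", "cBA")
  expect_equal(tss$direction, "MA_higher")
  expect_lt(tss$p_value, 0.05)
  body <- pairedRegionTest(se, truth$gene_id, "Body", "cMA", "cBA")
  expect_equal(body$direction, "BA_higher")
  # the null construction: no effect, no difference in distribution
  cfg0 <- simConfig(nGenes = 2, promoterEffect = 0, bodyEffect = 0,
                    methNoiseSd = 0.03,
                    methProbesPerRegion = c(TSS1500 = 0, TSS200 = 20,
                                            "5UTR" = 0, "1stExon" = 0,
                                            Body = 0, "3UTR" = 0),
                    nNonCpG = 50, seed = 29)
  se0 <- simulateMethylation(list(truth = truth, alleleChoices = choice,
                                  clones = clones), cfg0)
  t0 <- pairedRegionTest(se0, truth$gene_id, "TSS200", "cMA", "cBA")
  expect_gt(t0$p_value, 0.05)
})

test_that("iPSC-state samples show elevated non-CpG methylation", {
  cfg <- simConfig(nGenes = 60,
                   nClones = c(NSC_parental = 2, iPSC_early = 2), seed = 31)
  sim <- simulatePanel(cfg)
  se <- simulateMethylation(sim)
  s <- nonCpGSummary(se)
  states <- setNames(sim$samples$developmental_state[
    sim$samples$material == "cDNA"], sim$samples$clone_id[
      sim$samples$material == "cDNA"])
  ipsc <- s$mean_beta[states[s$sample_id] == "iPSC_early"]
  nsc <- s$mean_beta[states[s$sample_id] == "NSC_parental"]
  expect_gt(min(ipsc), max(nsc))
  # and clustering separates the two developmental states
  hc <- clusterMethSamples(se)
  grp <- cutree(hc, 2)
  expect_equal(length(unique(grp[states[names(grp)] == "iPSC_early"])), 1L)
  expect_equal(length(unique(grp[states[names(grp)] == "NSC_parental"])), 1L)
  expect_false(grp[["iPSC_early_c1"]] == grp[["NSC_parental_c1"]])
})
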