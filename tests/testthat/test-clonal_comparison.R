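test_that("AEI categories follow the sister-clone evidence", {
  p <- specPanel(list(
    c1 = c(g1 = "MA:A", g2 = "MA:A", g3 = "MA:A", g4 = "MA:A", g5 = "BA",
           g6 = "MA:A"),
    c2 = c(g1 = "BA", g2 = "MA:B", g3 = "MA:A", g4 = "ND", g5 = "BA",
           g6 = "SK:A"),
    c3 = c(g1 = "BA", g2 = "BA", g3 = "MA:A", g4 = "ND", g5 = "BA",
           g6 = "MA:A")))
  aei <- detectRandomAEI(p, "NSC_parental")
  cat <- setNames(aei$category, aei$gene_id)
  expect_equal(unname(cat[paste0("g", 1:6)]),
               c("RANDOM_AEI",        # MA in one clone, BA sisters
                 "RANDOM_MA",         # both alleles seen in different clones
                 "CONSTANT_MA",       # same allele in every clone
                 "INDETERMINATE_MA",  # MA somewhere, only ND elsewhere
                 "NOT_MA",
                 "CONSTANT_MA"))      # MA + same-direction skew, no BA sister
  # categories partition the gene set
  expect_equal(nrow(aei), 6L)
  expect_false(any(duplicated(aei$gene_id)))
})

test_that("a single-clone group is undecidable", {
  p <- specPanel(list(c1 = c(g1 = "MA:A")))
  expect_error(detectRandomAEI(p, "NSC_parental"), "single clone")
})

test_that("frequency summaries count expressed, MA and random-AEI genes", {
  p <- specPanel(list(
    c1 = c(g1 = "MA:A", g2 = "BA", g3 = "ND", g4 = "MA:A"),
    c2 = c(g1 = "BA", g2 = "BA", g3 = "ND", g4 = "MA:A")))
  f <- summarizeFrequencies(p, "NSC_parental")
  expect_equal(f$n_expressed, 3L)       # g3 never detected
  expect_equal(f$n_ma_any_clone, 2L)
  expect_equal(f$n_random_aei, 1L)      # only g1 has a BA sister
  expect_equal(f$pct_ma, aeiPercent(2, 3, 2, "down"))
  # degenerate empty group warns and reports zeros
  pe <- specPanel(list(c1 = c(g1 = "BA"), c2 = c(g1 = "BA")))
  pe@calls <- pe@calls[0, ]
  expect_warning(fe <- summarizeFrequencies(pe, "NSC_parental"), "empty")
  expect_equal(fe$n_expressed, 0L)
  expect_equal(fe$pct_ma, 0)
})

test_that("transition categories map state-pair classes correctly", {
  p <- GeneCallPanel(rbind(
    specPanel(list(b1 = c(g1 = "MA:A", g2 = "BA", g3 = "MA:A", g4 = "MA:A",
                          g5 = "MA:A", g6 = "SK:A")))@calls,
    specPanel(list(a1 = c(g1 = "BA", g2 = "MA:B", g3 = "MA:A", g4 = "SK:A",
                          g5 = "ND", g6 = "BA")))@calls),
    data.frame(clone_id = c("b1", "a1"),
               developmental_state = c("NSC_parental", "iPSC_early"),
               stringsAsFactors = FALSE))
  tr <- transitionAnalysis(p, "NSC_parental", "iPSC_early")
  cat <- setNames(tr$records$category, tr$records$gene_id)
  expect_equal(unname(cat[paste0("g", 1:6)]),
               c("RESET", "DE_NOVO", "RETAINED", "TO_SKEWED", "LOST", "OTHER"))
  expect_equal(tr$summary$n_ma_before, 4L)
  expect_equal(tr$summary$n_reset, 1L)
  expect_equal(tr$summary$pct_reset_all, 25)
})

test_that("percentage rounding conventions match their printed forms", {
  expect_equal(aeiPercent(126, 7334, 2, "down"), 1.71)
  expect_equal(aeiPercent(126, 7334, 2, "half-up"), 1.72)
  expect_equal(aeiPercent(42, 48, 0, "half-up"), 88)
  expect_equal(aeiPercent(37, 63, 1, "half-up"), 58.7)
  expect_warning(z <- aeiPercent(1, 0), "zero")
  expect_equal(z, 0)
})

test_that("the polyclonal estimator separates random from cis-driven MA", {
  p <- specPanel(list(
    c1 = c(g1 = "MA:A", g2 = "MA:A", g3 = "BA", g4 = "MA:A"),
    c2 = c(g1 = "BA", g2 = "MA:A", g3 = "BA", g4 = "ND")))
  aei <- detectRandomAEI(p, "NSC_parental")
  poly <- data.frame(gene_id = paste0("g", 1:4),
                     class = c("BA", "MA", "BA", "ND"),
                     stringsAsFactors = FALSE)
  est <- polyclonalEstimate(p, "NSC_parental", poly, aei)
  expect_equal(est$n_expressed, 4L)
  expect_equal(est$n_clone_ma, 3L)
  expect_equal(est$n_poly_expressed, 2L)  # of the MA genes, g4 is ND there
  expect_equal(est$n_poly_ba, 1L)         # g1: random-AEI candidate
  expect_equal(est$n_poly_ma, 1L)         # g2: cis-genetic candidate
  expect_equal(est$pct_random_aei, aeiPercent(1, 4, 2, "down"))
  expect_equal(est$n_random_aei_poly_ba, 1L)
  expect_error(polyclonalEstimate(p, "NSC_parental", NULL), "required")
})

test_that("clone-set MA overlap uses genes expressed in both sets", {
  a <- specPanel(list(c1 = c(s1 = "MA:A", s2 = "MA:A", x1 = "MA:A",
                             y1 = "BA", z1 = "MA:A"),
                      c2 = c(s1 = "BA", s2 = "BA", x1 = "BA", y1 = "BA",
                             z1 = "BA")))
  b <- specPanel(list(d1 = c(s1 = "MA:B", s2 = "MA:A", x1 = "BA",
                             y1 = "MA:A", z1 = "ND"),
                      d2 = c(s1 = "BA", s2 = "BA", x1 = "BA", y1 = "BA",
                             z1 = "ND")))
  ov <- maOverlap(a, b)
  # z1 is undetected in set B and drops out; s1, s2 shared; x1, y1 one-sided
  expect_equal(ov$n_ma_union_expressed_both, 4L)
  expect_equal(ov$n_ma_both, 2L)
  expect_equal(ov$pct_ma_both, 50)
})

test_that("hotspot overlap reproduces tiny enumerable Fisher cases", {
  s <- overlapSets(1, 2, 2, 4)
  r <- hotspotOverlap(s$ma, s$hotspot, s$background)
  expect_equal(r$p_value, 1)
  expect_equal(r$overlap, 1L)
  s2 <- overlapSets(2, 2, 2, 4)
  r2 <- hotspotOverlap(s2$ma, s2$hotspot, s2$background)
  expect_equal(r2$p_value, 1 / 3)
  # fold enrichment: observed over |A||B|/N expectation
  expect_equal(r2$fold, 2 / (2 * 2 / 4))
  expect_error(hotspotOverlap("g1", "g1", character()), "empty")
  expect_error(hotspotOverlap("zz", s$hotspot, s$background), "subsets")
})

test_that("a realistic hotspot test shows ~2-fold but insignificant enrichment", {
  N <- 7000
  r <- hotspotOverlap(sprintf("g%04d", 1:22),
                      c(sprintf("g%04d", 1:5), sprintf("h%04d", 1:836)),
                      c(sprintf("g%04d", 1:22), sprintf("h%04d", 1:836),
                        sprintf("b%04d", seq_len(N - 22 - 836))))
  expect_equal(r$overlap, 5L)
  expect_gt(r$fold, 1.8)
  expect_lt(r$fold, 2.1)
  expect_gt(r$p_value, 0.05)
})
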