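## cli_report: pipeline orchestration and the report bundle.

#' Run the full allelic-expression analysis pipeline
#'
#' Executes the stages normalize -> call -> compare -> methylation ->
#' report on either a simulated dataset (config field \code{simulate},
#' passed to [simConfig()]) or files on disk (config field \code{files}
#' with \code{gdna_report}, \code{cdna_report}, \code{probe_manifest},
#' \code{sample_manifest} and optional gene-list paths). The run is
#' deterministic given an identical config (a single seed governs all
#' stochastic stages) and every reported percentage is re-derivable from
#' counts in the same bundle.
#'
#' @param config a named list, or the path of a YAML file holding one.
#'   Recognized top-level fields: \code{seed}, \code{simulate},
#'   \code{files}, \code{thresholds} (\code{t_sk}, \code{t_ma},
#'   \code{intensity}, \code{min_informative}), \code{groups} (states to
#'   summarize; default all states with >= 2 clones), \code{transitions}
#'   (list of \code{before}/\code{after} pairs), \code{polyclonal}
#'   (logical, simulated runs only), \code{methylation} (logical),
#'   \code{regions} (gene-region labels for the methylation tests).
#' @param quiet suppress stage messages
#' @return an \code{aeiReportBundle} list: \code{metadata}, \code{panel},
#'   \code{frequencies}, \code{aei}, \code{transitions},
#'   \code{polyclonal}, \code{methylation}, \code{xreport}
#' @export
runPipeline <- function(config = list(), quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  say <- function(...) if (!quiet) message("[raex] ", sprintf(...))
  thr <- modifyList(list(t_sk = 0.1, t_ma = 0.2, intensity = 750,
                         min_informative = 1), config$thresholds %||% list())
  seed <- config$seed %||% 1L

  stage <- "input"
  res <- tryCatch({
    sim <- NULL
    if (!is.null(config$files)) {
      f <- config$files
      say("reading inputs")
      samples <- readSampleManifest(f$sample_manifest)
      probes <- readProbeManifest(f$probe_manifest)
      gdnaRaw <- readIntensityReport(f$gdna_report, samples, "gDNA")
      cdnaRaw <- readIntensityReport(f$cdna_report, samples, "cDNA")
      imprinted <- if (!is.null(f$imprinted)) readGeneList(f$imprinted)
        else character()
      pcdh <- if (!is.null(f$protocadherin)) readGeneList(f$protocadherin)
        else character()
    } else {
      say("simulating panel (seed %d)", seed)
      simArgs <- config$simulate %||% list()
      simArgs$seed <- seed
      sim <- do.call(simConfig, simArgs)
      sim <- simulatePanel(sim)
      samples <- sim$samples; probes <- sim$probes
      gdnaRaw <- sim$gdna; cdnaRaw <- sim$cdna
      imprinted <- sim$truth$gene_id[sim$truth$truth_class == "IMPRINTED"]
      pcdh <- character()
      if (isTRUE(config$polyclonal)) {
        poly <- simulatePolyclonal(sim)
        gdnaRaw <- AllelicArraySet(
          cbind(intensityX(gdnaRaw), intensityX(poly$gdna)),
          cbind(intensityY(gdnaRaw), intensityY(poly$gdna)),
          material = "gDNA")
        cdnaRaw <- AllelicArraySet(
          cbind(intensityX(cdnaRaw), intensityX(poly$cdna)),
          cbind(intensityY(cdnaRaw), intensityY(poly$cdna)),
          material = "cDNA")
        samples <- rbind(samples, poly$samples)
      }
    }

    stage <- "normalize"
    say("quantile normalizing channels")
    gdna <- computeBeta(quantileNormalizeChannels(gdnaRaw), thr$intensity)
    cdna <- computeBeta(quantileNormalizeChannels(cdnaRaw), thr$intensity)

    stage <- "call"
    say("calling genotypes and allelic classes")
    gt <- callGenotypes(gdna)
    deltas <- computeSnpDelta(cdna, gdna, gt, samples)
    scores <- aggregateGeneScores(deltas, probes, tSk = thr$t_sk)
    cloneTab <- unique(samples[samples$material == "cDNA",
                               c("clone_id", "developmental_state")])
    panel <- classifyCalls(scores, cloneTab, probes, imprinted = imprinted,
                           protocadherin = pcdh, tSk = thr$t_sk,
                           tMa = thr$t_ma,
                           minInformative = thr$min_informative)

    stage <- "compare"
    stTab <- table(cloneTab$developmental_state)
    groups <- config$groups %||%
      setdiff(names(stTab)[stTab >= 2], "polyclonal")
    aei <- list(); freqs <- list()
    for (g in groups) {
      say("comparing clones of state %s", g)
      aei[[g]] <- detectRandomAEI(panel, g)
      freqs[[g]] <- summarizeFrequencies(panel, g, aei[[g]])
    }
    transitions <- lapply(config$transitions %||% list(), function(tp)
      transitionAnalysis(panel, tp$before, tp$after))
    polyEst <- NULL
    if ("polyclonal" %in% cloneTab$developmental_state && length(groups)) {
      say("polyclonal estimator")
      polyCalls <- geneCalls(panel)
      polyCalls <- polyCalls[polyCalls$clone_id == "polyclonal", ]
      polyEst <- polyclonalEstimate(panel, groups[1], polyCalls,
                                    aei[[groups[1]]])
    }

    stage <- "methylation"
    meth <- list(skipped = TRUE)
    doMeth <- if (!is.null(sim)) isTRUE(config$methylation) else FALSE
    if (doMeth && length(groups)) {
      say("methylation comparisons")
      mse <- simulateMethylation(sim)
      g1 <- groups[1]
      randomGenes <- aei[[g1]]$gene_id[
        aei[[g1]]$category %in% c("RANDOM_AEI", "RANDOM_MA")]
      regions <- config$regions %||% c("TSS200", "1stExon", "Body", "Island")
      tests <- aeiRegionTests(mse, panel, randomGenes, g1, regions)
      meth <- list(skipped = FALSE, region_tests = tests,
                   noncpg = nonCpGSummary(mse),
                   clustering = clusterMethSamples(mse))
    }

    stage <- "report"
    list(
      metadata = list(seed = seed, thresholds = thr,
                      config_hash = configHash(config),
                      package_version = as.character(
                        utils::packageVersion("raex"))),
      panel = panel,
      frequencies = do.call(rbind, freqs),
      aei = aei,
      transitions = transitions,
      polyclonal = polyEst,
      methylation = meth,
      xreport = chrXReport(panel))
  }, error = function(e)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE))
  structure(res, class = "aeiReportBundle")
}

configHash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tf))
}

#' Region tests pairing each gene's own MA clones against its BA sisters
#'
#' For every probe of a random-AEI gene in the requested region, the paired
#' value is (mean beta over the clones where that gene is MA, mean beta
#' over the clones where it is BA); the signed-rank test then runs over all
#' probes of the gene set. This is the within-sister-pair contrast the
#' clonal design affords.
#'
#' @param se methylation \code{SummarizedExperiment} with samples named by
#'   clone
#' @param panel a [GeneCallPanel-class]
#' @param genes gene set (typically random-AEI genes)
#' @param group developmental state whose clones are paired
#' @param regions gene-region labels (\code{"Island"} selects island
#'   probes)
#' @return \code{data.frame}, one row per region (see [pairedRegionTest()])
#' @export
aeiRegionTests <- function(se, panel, genes, group,
                           regions = c("TSS200", "1stExon", "Body", "Island")) {
  cc <- panelCallsFor(panel, cloneIdsOfState(panel, group))
  cc <- cc[cc$gene_id %in% genes, ]
  b <- assay(se, "beta")
  rd <- as.data.frame(rowData(se))
  rows <- lapply(regions, function(reg) {
    xs <- ys <- list()
    for (g in genes) {
      maCl <- cc$clone_id[cc$gene_id == g & cc$class == "MA"]
      baCl <- cc$clone_id[cc$gene_id == g & cc$class == "BA"]
      maCl <- intersect(maCl, colnames(b)); baCl <- intersect(baCl, colnames(b))
      if (!length(maCl) || !length(baCl)) next
      ids <- if (reg == "Island") {
        rd$cpg_id[!is.na(rd$gene_id) & rd$gene_id == g &
                  rd$island_relation == "Island"]
      } else regionProbeIds(se, g, reg)
      if (!length(ids)) next
      xs[[g]] <- rowMeans(b[ids, maCl, drop = FALSE], na.rm = TRUE)
      ys[[g]] <- rowMeans(b[ids, baCl, drop = FALSE], na.rm = TRUE)
    }
    x <- unlist(xs); y <- unlist(ys)
    if (length(x) < 1)
      return(data.frame(region = reg, n_pairs = 0L, statistic = NA_real_,
                        p_value = NA_real_, direction = "none",
                        mean_difference = NA_real_, method = "no usable pairs",
                        stringsAsFactors = FALSE))
    d <- x - y
    res <- if (sum(d != 0) <= 50) {
      c(exactSignedRank(d), method = "exact signed-rank")
    } else {
      wt <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = FALSE,
                                         correct = TRUE))
      list(statistic = unname(wt$statistic), p_value = wt$p.value,
           n = sum(d != 0), method = "signed-rank, normal approximation")
    }
    med <- median(d)
    data.frame(region = reg, n_pairs = res$n, statistic = res$statistic,
               p_value = res$p_value,
               direction = if (med > 0) "MA_higher" else if (med < 0)
                 "BA_higher" else "none",
               mean_difference = mean(d), method = res$method,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.aeiReportBundle <- function(x, ...) {
  cat("aeiReportBundle (seed ", x$metadata$seed, ")\n", sep = "")
  show(x$panel)
  if (!is.null(x$frequencies)) { cat("Frequencies:\n"); print(x$frequencies) }
  if (!is.null(x$polyclonal)) { cat("Polyclonal estimator:\n"); print(x$polyclonal) }
  for (tr in x$transitions) print(tr)
  if (!isTRUE(x$methylation$skipped)) {
    cat("Methylation region tests:\n"); print(x$methylation$region_tests)
  } else cat("Methylation section skipped\n")
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Deterministic TSV/JSON serialization: per-clone call table, frequency
#' and AEI tables, transition records, polyclonal estimate, methylation
#' test tables and a JSON summary. Rerunning the pipeline with an
#' identical config and seed reproduces these files byte for byte.
#'
#' @param bundle an \code{aeiReportBundle}
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
writeReportBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  wr <- function(obj, name) {
    p <- file.path(dir, name)
    fwrite(obj, p, sep = "\t")
    paths <<- c(paths, p)
  }
  wr(geneCalls(bundle$panel), "calls.tsv")
  if (!is.null(bundle$frequencies)) wr(bundle$frequencies, "frequencies.tsv")
  for (g in names(bundle$aei))
    wr(bundle$aei[[g]], paste0("aei_", g, ".tsv"))
  for (i in seq_along(bundle$transitions)) {
    tr <- bundle$transitions[[i]]
    wr(tr$records, sprintf("transitions_%s_to_%s.tsv",
                           tr$summary$before, tr$summary$after))
  }
  if (!is.null(bundle$polyclonal)) wr(bundle$polyclonal, "polyclonal.tsv")
  if (!isTRUE(bundle$methylation$skipped)) {
    wr(bundle$methylation$region_tests, "methylation_region_tests.tsv")
    wr(bundle$methylation$noncpg, "noncpg_summary.tsv")
  }
  js <- file.path(dir, "summary.json")
  jsonlite::write_json(list(
    metadata = bundle$metadata,
    frequencies = bundle$frequencies,
    polyclonal = bundle$polyclonal,
    transitions = lapply(bundle$transitions, `[[`, "summary")),
    js, auto_unbox = TRUE, digits = NA, force = TRUE, null = "null")
  paths <- c(paths, js)
  invisible(paths)
}
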