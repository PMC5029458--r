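## array_io: intensity report parsing, quantile normalization, beta values.

#' Read a probe manifest
#'
#' CSV with columns \code{probe_id}, \code{chromosome}, \code{position}
#' (1-based), \code{allele_a}, \code{allele_b} and the gene memberships
#' \code{gene_id}, \code{transcript_id}. A probe may appear on several rows
#' (one per transcript membership); intergenic probes carry \code{NA}
#' memberships. Probe coordinates must be consistent across rows.
#'
#' @param path file path
#' @return \code{data.frame}, one row per probe x membership
#' @export
readProbeManifest <- function(path) {
  pm <- as.data.frame(fread(path))
  need <- c("probe_id", "chromosome", "position")
  if (!all(need %in% names(pm)))
    stop("probe manifest must have columns: ", paste(need, collapse = ", "))
  if (any(pm$position < 1)) stop("probe positions must be >= 1")
  pos <- unique(pm[, c("probe_id", "chromosome", "position")])
  if (anyDuplicated(pos$probe_id))
    stop("probe manifest gives inconsistent coordinates for some probes")
  if (is.null(pm$gene_id)) pm$gene_id <- NA_character_
  if (is.null(pm$transcript_id)) pm$transcript_id <- NA_character_
  # empty fields are absent memberships (intergenic probes)
  pm$gene_id[!nzchar(pm$gene_id)] <- NA_character_
  pm$transcript_id[!nzchar(pm$transcript_id)] <- NA_character_
  pm
}

#' Read a sample manifest
#'
#' CSV with columns \code{sample_id}, \code{material} (gDNA/cDNA),
#' \code{clone_id}, \code{developmental_state} and, for cDNA rows,
#' \code{paired_gdna} naming the gDNA sample of the same genetic background.
#'
#' @param path file path
#' @return \code{data.frame}
#' @export
readSampleManifest <- function(path) {
  sm <- as.data.frame(fread(path))
  validateSampleManifest(sm)
}

#' @keywords internal
validateSampleManifest <- function(sm) {
  need <- c("sample_id", "material", "clone_id", "developmental_state")
  if (!all(need %in% names(sm)))
    stop("sample manifest must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(sm$sample_id)) stop("duplicated sample_id in manifest")
  if (!all(sm$material %in% c("gDNA", "cDNA")))
    stop("material must be 'gDNA' or 'cDNA'")
  states <- c("NSC_parental", "NSC_differentiated", "iPSC_early", "iPSC_late",
              "iPSC_NSC", "polyclonal")
  bad <- setdiff(unique(sm$developmental_state), states)
  if (length(bad))
    stop("unknown developmental_state: ", paste(bad, collapse = ", "))
  cd <- sm[sm$material == "cDNA", ]
  if (nrow(cd)) {
    if (is.null(sm$paired_gdna) || any(is.na(cd$paired_gdna)))
      stop("every cDNA sample needs a paired_gdna entry")
    miss <- setdiff(cd$paired_gdna, sm$sample_id[sm$material == "gDNA"])
    if (length(miss))
      stop("paired gDNA sample(s) absent from manifest: ",
           paste(miss, collapse = ", "))
  }
  sm
}

#' Read a two-channel intensity report
#'
#' Parses a GenomeStudio-final-report-like TSV with columns \code{SNP Name},
#' \code{Sample ID}, \code{X Raw} and \code{Y Raw} into a probe x sample
#' [AllelicArraySet-class]. Cells absent from the report are \code{NA}.
#'
#' @param path TSV path
#' @param samples sample manifest \code{data.frame} (see
#'   [readSampleManifest()]); only rows of the requested material are used.
#' @param material \code{"gDNA"} or \code{"cDNA"}
#' @return a raw (unnormalized) [AllelicArraySet-class]
#' @export
readIntensityReport <- function(path, samples, material = c("gDNA", "cDNA")) {
  material <- match.arg(material)
  samples <- validateSampleManifest(samples)
  rep <- fread(path, sep = "\t", header = TRUE, check.names = FALSE)
  need <- c("SNP Name", "Sample ID", "X Raw", "Y Raw")
  if (!all(need %in% names(rep)))
    stop("intensity report must have columns: ", paste(need, collapse = ", "))
  setnames(rep, need, c("probe_id", "sample_id", "X", "Y"))
  keepIds <- samples$sample_id[samples$material == material]
  unknown <- setdiff(unique(rep$sample_id), keepIds)
  if (length(unknown))
    stop("sample(s) not in the ", material, " manifest: ",
         paste(unknown, collapse = ", "))
  if (any(rep$X < 0 | rep$Y < 0, na.rm = TRUE))
    stop("negative intensities in report")
  if (anyDuplicated(rep[, c("probe_id", "sample_id")]))
    stop("duplicated (probe, sample) rows in report")
  probes <- sort(unique(rep$probe_id))
  smp <- keepIds[keepIds %in% rep$sample_id]
  X <- Y <- matrix(NA_real_, length(probes), length(smp),
                   dimnames = list(probes, smp))
  ip <- match(rep$probe_id, probes); is <- match(rep$sample_id, smp)
  X[cbind(ip, is)] <- rep$X
  Y[cbind(ip, is)] <- rep$Y
  AllelicArraySet(X, Y,
    sampleData = DataFrame(samples[match(smp, samples$sample_id), ],
                           row.names = smp),
    material = material, normalized = FALSE)
}

#' Quantile-normalize the two channels of an intensity set
#'
#' All (sample, channel) columns of one material type are pooled into a
#' single reference distribution (the mean of order statistics across
#' columns); each column is mapped onto it, preserving within-column ranks,
#' with ties resolved by average rank. gDNA and cDNA sets are normalized in
#' separate calls. Delegates to \code{limma::normalizeQuantiles}.
#'
#' @param x a raw [AllelicArraySet-class]
#' @return the normalized [AllelicArraySet-class]
#' @examples
#' x <- matrix(c(10, 20, 30), 3, 1, dimnames = list(paste0("p", 1:3), "s1"))
#' y <- matrix(c(30, 10, 50), 3, 1, dimnames = dimnames(x))
#' m <- AllelicArraySet(x, y, material = "cDNA")
#' intensityX(quantileNormalizeChannels(m))  # 10 25 40
#' @export
quantileNormalizeChannels <- function(x) {
  stopifnot(is(x, "AllelicArraySet"))
  if (isNormalized(x)) stop("intensity set is already normalized")
  X <- intensityX(x); Y <- intensityY(x)
  pooled <- cbind(X, Y)
  allNA <- colSums(!is.na(pooled)) == 0L
  if (any(allNA))
    stop("column(s) entirely missing: ",
         paste(rep(colnames(X), 2)[allNA], collapse = ", "))
  norm <- limma::normalizeQuantiles(pooled, ties = TRUE)
  n <- ncol(X)
  Xn <- norm[, seq_len(n), drop = FALSE]
  Yn <- norm[, n + seq_len(n), drop = FALSE]
  dimnames(Xn) <- dimnames(Yn) <- dimnames(X)
  AllelicArraySet(Xn, Yn, probeData = rowData(x), sampleData = colData(x),
                  material = arrayMaterial(x), normalized = TRUE)
}

#' Compute allelic beta values with the background-intensity filter
#'
#' beta = X/(X+Y) per probe and sample; the total intensity X+Y must
#' strictly exceed \code{intensityThreshold} for a cell to pass the
#' background filter. Cells with zero total or a missing channel get
#' \code{NA} beta (no 0/0 arithmetic).
#'
#' @param x a normalized [AllelicArraySet-class]
#' @param intensityThreshold background cutoff on X+Y (default 750;
#'   strictly "greater than")
#' @return an [AllelicBetaSet-class]
#' @export
computeBeta <- function(x, intensityThreshold = 750) {
  stopifnot(is(x, "AllelicArraySet"))
  if (!isNormalized(x))
    stop("intensity set must be quantile-normalized before computing beta")
  X <- intensityX(x); Y <- intensityY(x)
  total <- X + Y
  beta <- ifelse(!is.na(total) & total > 0, X / total, NA_real_)
  pass <- !is.na(total) & total > intensityThreshold
  se <- SummarizedExperiment(
    assays = list(beta = beta, total = total, pass = pass),
    rowData = rowData(x), colData = colData(x),
    metadata = list(material = arrayMaterial(x),
                    intensity_threshold = intensityThreshold))
  new("AllelicBetaSet", se)
}

#' Construct an AllelicBetaSet directly from beta and total matrices
#'
#' Convenience constructor for tests and externally computed beta values.
#'
#' @param beta,total probe x sample matrices
#' @param material \code{"gDNA"} or \code{"cDNA"}
#' @param intensityThreshold background cutoff applied to \code{total}
#' @return an [AllelicBetaSet-class]
#' @export
makeBetaSet <- function(beta, total = NULL,
                        material = c("gDNA", "cDNA"),
                        intensityThreshold = 750) {
  material <- match.arg(material)
  if (is.null(total)) {
    total <- beta; total[] <- intensityThreshold + 1
    total[is.na(beta)] <- 0
  }
  pass <- !is.na(total) & total > intensityThreshold
  se <- SummarizedExperiment(
    assays = list(beta = beta, total = total, pass = pass),
    metadata = list(material = material,
                    intensity_threshold = intensityThreshold))
  new("AllelicBetaSet", se)
}
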