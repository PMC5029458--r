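## S4 containers for the allelic-expression pipeline.

#' Two-channel SNP-array intensity container
#'
#' Extends \linkS4class{SummarizedExperiment} with two assays, \code{X} and
#' \code{Y}, holding the per-probe, per-sample raw or quantile-normalized
#' channel intensities for one material type (gDNA or cDNA). Probe metadata
#' lives in \code{rowData}, sample metadata in \code{colData}; absent
#' measurements are \code{NA}, never zero.
#'
#' @slot .Data see \linkS4class{SummarizedExperiment}
#' @seealso [AllelicArraySet()], [quantileNormalizeChannels()], [computeBeta()]
#' @export
setClass("AllelicArraySet", contains = "SummarizedExperiment")

setValidity("AllelicArraySet", function(object) {
  msg <- character()
  if (!all(c("X", "Y") %in% assayNames(object)))
    msg <- c(msg, "assays 'X' and 'Y' are required")
  else {
    for (a in c("X", "Y")) {
      v <- assay(object, a)
      if (any(v < 0, na.rm = TRUE))
        msg <- c(msg, sprintf("assay '%s' contains negative intensities", a))
    }
  }
  mat <- metadata(object)$material
  if (is.null(mat) || !mat %in% c("gDNA", "cDNA"))
    msg <- c(msg, "metadata 'material' must be 'gDNA' or 'cDNA'")
  if (!is.logical(metadata(object)$normalized))
    msg <- c(msg, "metadata 'normalized' must be logical")
  if (length(msg)) msg else TRUE
})

#' Construct an AllelicArraySet
#'
#' @param X,Y numeric probe x sample matrices of channel intensities
#'   (nonnegative; \code{NA} for absent cells). Dimnames are required and
#'   must agree between the two channels.
#' @param probeData optional \code{data.frame}/\code{DataFrame} of probe
#'   annotation, one row per probe.
#' @param sampleData optional sample annotation, one row per sample.
#' @param material \code{"gDNA"} or \code{"cDNA"}.
#' @param normalized logical; whether the values are already
#'   quantile-normalized.
#' @return An [AllelicArraySet-class] object.
#' @examples
#' x <- matrix(c(100, 900), 2, 1, dimnames = list(c("p1", "p2"), "s1"))
#' AllelicArraySet(X = x, Y = x[2:1, , drop = FALSE], material = "gDNA")
#' @export
AllelicArraySet <- function(X, Y, probeData = NULL, sampleData = NULL,
                            material = c("gDNA", "cDNA"), normalized = FALSE) {
  material <- match.arg(material)
  stopifnot(identical(dim(X), dim(Y)))
  if (is.null(rownames(X)) || is.null(colnames(X)))
    stop("intensity matrices must carry probe and sample dimnames")
  if (!identical(dimnames(X), dimnames(Y)))
    stop("X and Y dimnames disagree")
  if (is.null(probeData)) probeData <- DataFrame(row.names = rownames(X))
  if (is.null(sampleData)) sampleData <- DataFrame(row.names = colnames(X))
  se <- SummarizedExperiment(
    assays = list(X = X, Y = Y),
    rowData = probeData, colData = sampleData,
    metadata = list(material = material, normalized = normalized)
  )
  new("AllelicArraySet", se)
}

#' Beta-value container
#'
#' Extends \linkS4class{SummarizedExperiment} with assays \code{beta}
#' (A-allele intensity fraction X/(X+Y) in [0,1]), \code{total} (X+Y) and
#' \code{pass} (logical background-intensity filter, total strictly greater
#' than the threshold). Beta is \code{NA} wherever the total is zero or a
#' channel is missing.
#'
#' @seealso [computeBeta()]
#' @export
setClass("AllelicBetaSet", contains = "SummarizedExperiment")

setValidity("AllelicBetaSet", function(object) {
  msg <- character()
  if (!all(c("beta", "total", "pass") %in% assayNames(object)))
    msg <- c(msg, "assays 'beta', 'total' and 'pass' are required")
  else {
    b <- assay(object, "beta")
    if (any(b < 0 | b > 1, na.rm = TRUE))
      msg <- c(msg, "beta values outside [0,1]")
  }
  if (!is.numeric(metadata(object)$intensity_threshold))
    msg <- c(msg, "metadata 'intensity_threshold' must be numeric")
  if (length(msg)) msg else TRUE
})

#' Gene-level allelic-expression call panel
#'
#' Holds one allelic call per gene x clone (class BA / SK / MA / ND with
#' score, direction and exclusion flag) together with the clone annotation
#' (developmental state, lineage) and the classification thresholds used.
#'
#' @slot calls \code{data.frame} with columns \code{gene_id},
#'   \code{clone_id}, \code{n_informative}, \code{score}, \code{direction},
#'   \code{class}, \code{excluded_reason}.
#' @slot clones \code{data.frame} with columns \code{clone_id},
#'   \code{developmental_state} and optionally \code{lineage_parent}.
#' @slot thresholds named \code{list} (at least \code{t_sk}, \code{t_ma}).
#' @seealso [classifyCalls()], [detectRandomAEI()], [summarizeFrequencies()]
#' @export
setClass("GeneCallPanel",
  representation(calls = "data.frame", clones = "data.frame",
                 thresholds = "list"))

setValidity("GeneCallPanel", function(object) {
  msg <- character()
  need <- c("gene_id", "clone_id", "n_informative", "score", "direction",
            "class", "excluded_reason")
  if (!all(need %in% names(object@calls)))
    msg <- c(msg, paste("calls must have columns:", paste(need, collapse = ", ")))
  else {
    if (!all(object@calls$class %in% c("BA", "SK", "MA", "ND")))
      msg <- c(msg, "class must be one of BA, SK, MA, ND")
    if (anyDuplicated(object@calls[, c("gene_id", "clone_id")]))
      msg <- c(msg, "duplicated gene x clone call")
    bad <- !is.na(object@calls$excluded_reason) &
      !object@calls$excluded_reason %in% c("imprinted", "protocadherin", "chrX")
    if (any(bad)) msg <- c(msg, "invalid excluded_reason")
  }
  if (!all(c("clone_id", "developmental_state") %in% names(object@clones)))
    msg <- c(msg, "clones must have clone_id and developmental_state")
  if (!all(object@calls$clone_id %in% object@clones$clone_id))
    msg <- c(msg, "calls reference clones absent from the clone table")
  if (length(msg)) msg else TRUE
})

#' @rdname GeneCallPanel-class
#' @param calls,clones,thresholds see slots above.
#' @return a \code{GeneCallPanel}
#' @export
GeneCallPanel <- function(calls, clones,
                          thresholds = list(t_sk = 0.1, t_ma = 0.2)) {
  calls <- as.data.frame(calls, stringsAsFactors = FALSE)
  clones <- as.data.frame(clones, stringsAsFactors = FALSE)
  if (is.null(calls$excluded_reason)) calls$excluded_reason <- NA_character_
  if (is.null(calls$direction)) calls$direction <- NA_character_
  new("GeneCallPanel", calls = calls, clones = clones, thresholds = thresholds)
}
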