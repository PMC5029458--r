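## Accessor generics and show() methods.

#' Accessors for intensity and beta containers
#'
#' @param x an [AllelicArraySet-class] or [AllelicBetaSet-class]
#' @return \code{intensityX}/\code{intensityY}: numeric matrices;
#'   \code{arrayMaterial}: \code{"gDNA"} or \code{"cDNA"};
#'   \code{isNormalized}: logical; \code{betaValues}, \code{totalIntensity}:
#'   numeric matrices; \code{passesFilter}: logical matrix;
#'   \code{intensityThreshold}: the background filter threshold.
#' @name allelic-accessors
NULL

#' @rdname allelic-accessors
#' @export
setGeneric("intensityX", function(x) standardGeneric("intensityX"))
#' @rdname allelic-accessors
#' @export
setGeneric("intensityY", function(x) standardGeneric("intensityY"))
#' @rdname allelic-accessors
#' @export
setGeneric("arrayMaterial", function(x) standardGeneric("arrayMaterial"))
#' @rdname allelic-accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))
#' @rdname allelic-accessors
#' @export
setGeneric("betaValues", function(x) standardGeneric("betaValues"))
#' @rdname allelic-accessors
#' @export
setGeneric("totalIntensity", function(x) standardGeneric("totalIntensity"))
#' @rdname allelic-accessors
#' @export
setGeneric("passesFilter", function(x) standardGeneric("passesFilter"))
#' @rdname allelic-accessors
#' @export
setGeneric("intensityThreshold", function(x) standardGeneric("intensityThreshold"))

#' @rdname allelic-accessors
setMethod("intensityX", "AllelicArraySet", function(x) assay(x, "X"))
#' @rdname allelic-accessors
setMethod("intensityY", "AllelicArraySet", function(x) assay(x, "Y"))
#' @rdname allelic-accessors
setMethod("arrayMaterial", "AllelicArraySet",
          function(x) metadata(x)$material)
#' @rdname allelic-accessors
setMethod("arrayMaterial", "AllelicBetaSet",
          function(x) metadata(x)$material)
#' @rdname allelic-accessors
setMethod("isNormalized", "AllelicArraySet",
          function(x) isTRUE(metadata(x)$normalized))
#' @rdname allelic-accessors
setMethod("betaValues", "AllelicBetaSet", function(x) assay(x, "beta"))
#' @rdname allelic-accessors
setMethod("totalIntensity", "AllelicBetaSet", function(x) assay(x, "total"))
#' @rdname allelic-accessors
setMethod("passesFilter", "AllelicBetaSet", function(x) assay(x, "pass"))
#' @rdname allelic-accessors
setMethod("intensityThreshold", "AllelicBetaSet",
          function(x) metadata(x)$intensity_threshold)

setMethod("show", "AllelicArraySet", function(object) {
  cat(sprintf("AllelicArraySet: %d probes x %d samples [%s, %s]\n",
              nrow(object), ncol(object), arrayMaterial(object),
              if (isNormalized(object)) "normalized" else "raw"))
  invisible(NULL)
})

setMethod("show", "AllelicBetaSet", function(object) {
  p <- assay(object, "pass")
  cat(sprintf(
    "AllelicBetaSet: %d probes x %d samples [%s]\n  %d/%d cells pass the intensity filter (> %g)\n",
    nrow(object), ncol(object), arrayMaterial(object),
    sum(p, na.rm = TRUE), length(p), intensityThreshold(object)))
  invisible(NULL)
})

#' Accessors for GeneCallPanel
#'
#' @param x a [GeneCallPanel-class]
#' @return \code{geneCalls}: the per gene x clone call \code{data.frame};
#'   \code{cloneInfo}: the clone annotation; \code{callThresholds}: the
#'   classification thresholds.
#' @name panel-accessors
NULL

#' @rdname panel-accessors
#' @export
setGeneric("geneCalls", function(x) standardGeneric("geneCalls"))
#' @rdname panel-accessors
#' @export
setGeneric("cloneInfo", function(x) standardGeneric("cloneInfo"))
#' @rdname panel-accessors
#' @export
setGeneric("callThresholds", function(x) standardGeneric("callThresholds"))

#' @rdname panel-accessors
setMethod("geneCalls", "GeneCallPanel", function(x) x@calls)
#' @rdname panel-accessors
setMethod("cloneInfo", "GeneCallPanel", function(x) x@clones)
#' @rdname panel-accessors
setMethod("callThresholds", "GeneCallPanel", function(x) x@thresholds)

setMethod("show", "GeneCallPanel", function(object) {
  cc <- object@calls
  cat(sprintf("GeneCallPanel: %d genes x %d clones (%d calls)\n",
              length(unique(cc$gene_id)), nrow(object@clones), nrow(cc)))
  st <- table(object@clones$developmental_state)
  cat("  states:", paste(sprintf("%s (%d)", names(st), st), collapse = ", "), "\n")
  cl <- table(factor(cc$class, levels = c("BA", "SK", "MA", "ND")))
  cat("  calls: ", paste(sprintf("%s %d", names(cl), cl), collapse = ", "), "\n")
  nex <- sum(!is.na(cc$excluded_reason))
  if (nex) cat(sprintf("  %d calls flagged excluded\n", nex))
  invisible(NULL)
})
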