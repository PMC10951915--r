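#' Accessors for DevoProteomics classes
#'
#' Small accessor generics: \code{modality()} and \code{speciesLabel()} for
#' [StageExperiment-class]; \code{stageLabels()} and \code{entityIds()} for
#' matrix-like containers; \code{curveSlope()} / \code{curveIntercept()} for
#' [StandardCurve-class]; \code{orthologPairs()} for [OrthologMap-class];
#' \code{similarityValues()} and \code{simMetric()} for
#' [StageSimilarity-class].
#'
#' @param x an object of the documented class.
#' @return the corresponding slot value (see individual methods).
#' @name accessors
#' @examples
#' m <- matrix(1, 2, 2, dimnames = list(c("p1","p2"), c("unfE","larva")))
#' se <- StageExperiment(m, "protein_relative", "Ciona")
#' modality(se); speciesLabel(se); entityIds(se)
NULL

#' @rdname accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))
#' @rdname accessors
#' @export
setGeneric("speciesLabel", function(x) standardGeneric("speciesLabel"))
#' @rdname accessors
#' @export
setGeneric("stageLabels", function(x) standardGeneric("stageLabels"))
#' @rdname accessors
#' @export
setGeneric("entityIds", function(x) standardGeneric("entityIds"))
#' @rdname accessors
#' @export
setGeneric("curveSlope", function(x) standardGeneric("curveSlope"))
#' @rdname accessors
#' @export
setGeneric("curveIntercept", function(x) standardGeneric("curveIntercept"))
#' @rdname accessors
#' @export
setGeneric("orthologPairs", function(x) standardGeneric("orthologPairs"))
#' @rdname accessors
#' @export
setGeneric("similarityValues", function(x) standardGeneric("similarityValues"))
#' @rdname accessors
#' @export
setGeneric("simMetric", function(x) standardGeneric("simMetric"))

#' @rdname accessors
#' @export
setMethod("modality", "StageExperiment", function(x) x@modality)
#' @rdname accessors
#' @export
setMethod("speciesLabel", "StageExperiment", function(x) x@species)
#' @rdname accessors
#' @export
setMethod("stageLabels", "StageExperiment", function(x) colnames(x))
#' @rdname accessors
#' @export
setMethod("entityIds", "StageExperiment", function(x) rownames(x))
#' @rdname accessors
#' @export
setMethod("curveSlope", "StandardCurve", function(x) x@slope)
#' @rdname accessors
#' @export
setMethod("curveIntercept", "StandardCurve", function(x) x@intercept)
#' @rdname accessors
#' @export
setMethod("orthologPairs", "OrthologMap", function(x) x@pairs)
#' @rdname accessors
#' @export
setMethod("speciesLabel", "OrthologMap",
          function(x) c(A = x@speciesA, B = x@speciesB))
#' @rdname accessors
#' @export
setMethod("similarityValues", "StageSimilarity", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("simMetric", "StageSimilarity", function(x) x@metric)
#' @rdname accessors
#' @export
setMethod("stageLabels", "StageSimilarity",
          function(x) list(A = rownames(x@values), B = colnames(x@values)))

#' Number of ortholog pairs
#' @param x an [OrthologMap-class].
#' @return integer pair count.
#' @export
setMethod("length", "OrthologMap", function(x) nrow(x@pairs))

setMethod("show", "StageExperiment", function(object) {
  cat(sprintf("StageExperiment [%s, %s]: %d entities x %d stages\n",
              object@modality, object@species, nrow(object), ncol(object)))
  cat("  stages:", paste(colnames(object), collapse = " -> "), "\n")
  norm <- S4Vectors::metadata(object)$normalization
  if (!is.null(norm)) cat("  normalization:", norm, "\n")
})

setMethod("show", "StandardCurve", function(object) {
  cat(sprintf("StandardCurve (%s): slope %.6g, intercept %.6g (%d used, %d dropped)\n",
              object@fitSpace, object@slope, object@intercept,
              object@nPointsUsed, object@nDropped))
})

setMethod("show", "OrthologMap", function(object) {
  cat(sprintf("OrthologMap %s <-> %s: %d one-to-one pairs\n",
              object@speciesA, object@speciesB, nrow(object@pairs)))
})

setMethod("show", "StageSimilarity", function(object) {
  cat(sprintf("StageSimilarity (%s, n = %d orthologs): %d x %d stages\n",
              object@metric, object@nOrthologs,
              nrow(object@values), ncol(object@values)))
})
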