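#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
NULL

.MODALITIES <- c("protein_relative", "protein_absolute_nM", "rna_tpm")

#' StageExperiment: an expression matrix over an ordered developmental stage series
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass holding
#' non-negative abundances (relative protein signal, absolute nM, or TPM)
#' for entities (rows) across an ordered series of developmental stages
#' (columns). Column order *is* the stage order; stage labels such as
#' \code{"cell-16"} are never sorted lexically. Missing measurements are
#' \code{NA} and are distinct from zero.
#'
#' @slot modality one of \code{"protein_relative"},
#'   \code{"protein_absolute_nM"}, \code{"rna_tpm"}.
#' @slot species free-text species tag (e.g. \code{"Ciona"}).
#'
#' @seealso [StageExperiment()] for the constructor.
#' @export
setClass("StageExperiment",
  contains = "SummarizedExperiment",
  slots = c(modality = "character", species = "character")
)

setValidity("StageExperiment", function(object) {
  msg <- character()
  if (length(object@modality) != 1L || !object@modality %in% .MODALITIES)
    msg <- c(msg, sprintf("modality must be one of %s",
                          paste(.MODALITIES, collapse = ", ")))
  if (length(object@species) != 1L || !nzchar(object@species))
    msg <- c(msg, "species must be a single non-empty string")
  ids <- rownames(object)
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "entity ids (rownames) must be present and unique")
  stg <- colnames(object)
  if (is.null(stg) || anyDuplicated(stg))
    msg <- c(msg, "stage labels (colnames) must be present and unique")
  if (length(SummarizedExperiment::assayNames(object)) >= 1L) {
    a <- SummarizedExperiment::assay(object, 1L)
    if (any(a < 0, na.rm = TRUE))
      msg <- c(msg, "abundances must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a StageExperiment
#'
#' @param values numeric matrix, entities in rows, ordered stages in columns.
#'   Rownames (entity ids) and colnames (stage labels) are required and must
#'   be unique. Values must be non-negative; \code{NA} marks missing.
#' @param modality measurement type: \code{"protein_relative"},
#'   \code{"protein_absolute_nM"} or \code{"rna_tpm"}.
#' @param species species tag.
#' @param normalization normalization state recorded in
#'   \code{metadata()$normalization} (\code{"raw"},
#'   \code{"median_normalized"}, \code{"sum_to_one"}, \code{"log2"},
#'   \code{"quantile_normalized"}).
#'
#' @return a [StageExperiment-class] object.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(c("g1","g2","g3"), c("unfE","larva")))
#' se <- StageExperiment(m, modality = "rna_tpm", species = "Ciona")
#' stageLabels(se)
#' @export
StageExperiment <- function(values, modality, species,
                            normalization = "raw") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(abundance = values))
  out <- new("StageExperiment", se, modality = modality, species = species)
  S4Vectors::metadata(out)$normalization <- normalization
  validObject(out)
  out
}

#' StandardCurve: robust log10-log10 spike-in calibration line
#'
#' Result of a Theil-Sen fit of log10 measured MS signal against log10 known
#' spike-in amount: slope (dimensionless) and intercept (log10-signal units).
#'
#' @slot slope median of all pairwise slopes over distinct-amount pairs.
#' @slot intercept median of \code{y - slope * x} residual intercepts.
#' @slot nPointsUsed number of standards used in the fit.
#' @slot nDropped number of standards excluded (zero / missing signal).
#' @slot fitSpace fixed tag \code{"log10-log10"}.
#' @seealso [fitStandardCurve()]
#' @export
setClass("StandardCurve",
  slots = c(slope = "numeric", intercept = "numeric",
            nPointsUsed = "integer", nDropped = "integer",
            fitSpace = "character")
)

setValidity("StandardCurve", function(object) {
  msg <- character()
  if (!is.finite(object@slope)) msg <- c(msg, "slope must be finite")
  if (!is.finite(object@intercept)) msg <- c(msg, "intercept must be finite")
  if (object@nPointsUsed < 2L) msg <- c(msg, "curve must use >= 2 standards")
  if (length(msg)) msg else TRUE
})

#' OrthologMap: one-to-one cross-species entity pairs
#'
#' Pairs resolved by reciprocal best-hit orthology, with per-pair alignment
#' provenance (e-values and bit scores in both directions) when available.
#' Each id appears in at most one pair.
#'
#' @slot pairs a [S4Vectors::DataFrame] with at least columns \code{idA},
#'   \code{idB}; optionally \code{evalueAB}, \code{bitsAB}, \code{evalueBA},
#'   \code{bitsBA}.
#' @slot speciesA,speciesB species tags for the two sides.
#' @seealso [reciprocalBestHits()], [OrthologMap()]
#' @export
setClass("OrthologMap",
  slots = c(pairs = "DataFrame", speciesA = "character", speciesB = "character")
)

setValidity("OrthologMap", function(object) {
  p <- object@pairs
  msg <- character()
  if (!all(c("idA", "idB") %in% colnames(p)))
    msg <- c(msg, "pairs must have columns idA and idB")
  else {
    if (anyDuplicated(p$idA) || anyDuplicated(p$idB))
      msg <- c(msg, "map must be one-to-one: duplicated ids found")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an OrthologMap from paired ids
#'
#' @param idA,idB character vectors of equal length, each without duplicates.
#' @param speciesA,speciesB species tags.
#' @param ... additional per-pair provenance columns (e.g. \code{evalueAB}).
#' @return an [OrthologMap-class].
#' @examples
#' OrthologMap(c("a1","a2"), c("b1","b2"))
#' @export
OrthologMap <- function(idA, idB, speciesA = "A", speciesB = "B", ...) {
  p <- S4Vectors::DataFrame(idA = as.character(idA), idB = as.character(idB), ...)
  new("OrthologMap", pairs = p, speciesA = speciesA, speciesB = speciesB)
}

#' StageSimilarity: all-pairs cross-species stage similarity matrix
#'
#' Rows are species-A stages (in developmental order), columns species-B
#' stages; entries are the chosen similarity metric computed across mapped
#' ortholog pairs. Undefined entries (zero-variance stage vectors under
#' correlation metrics) are \code{NA}.
#'
#' @slot values numeric matrix, stages A x stages B.
#' @slot metric \code{"pearson"}, \code{"spearman"} or \code{"cosine"}.
#' @slot nOrthologs number of mapped ortholog pairs used.
#' @slot speciesA,speciesB species tags.
#' @seealso [stageSimilarity()]
#' @export
setClass("StageSimilarity",
  slots = c(values = "matrix", metric = "character",
            nOrthologs = "integer", speciesA = "character",
            speciesB = "character")
)

setValidity("StageSimilarity", function(object) {
  msg <- character()
  if (!object@metric %in% c("pearson", "spearman", "cosine"))
    msg <- c(msg, "metric must be pearson, spearman or cosine")
  v <- object@values
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "similarity matrix must carry stage labels as dimnames")
  if (object@metric %in% c("pearson", "spearman") &&
      any(abs(v) > 1 + 1e-8, na.rm = TRUE))
    msg <- c(msg, "correlation entries must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})
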