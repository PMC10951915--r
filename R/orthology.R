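#' Best hit per query from a tabular alignment file
#'
#' Discards hits with e-value above \code{evalueMax}, then selects per query
#' the subject with (1) lowest e-value and (2) highest bit score; any
#' remaining tie is broken by first occurrence in file order, and such
#' events are logged. This replicates single-best-target alignment
#' reporting independent of the aligner's internal quirks.
#'
#' @param hits hit data.frame as from [readBlastTab()].
#' @param evalueMax e-value ceiling (default 0.01).
#' @return data.frame with one row per query: \code{qseqid},
#'   \code{sseqid}, \code{evalue}, \code{bitscore}, ordered by query id.
#' @examples
#' h <- data.frame(qseqid = "a1", sseqid = c("b1","b2"),
#'                 pident = 90, length = 100, mismatch = 1, gapopen = 0,
#'                 qstart = 1, qend = 100, sstart = 1, send = 100,
#'                 evalue = c(1e-10, 1e-5), bitscore = c(200, 300))
#' bestHits(h)$sseqid  # "b1": e-value dominates the bit score
#' @export
bestHits <- function(hits, evalueMax = 0.01) {
  keep <- hits$evalue <= evalueMax
  h <- hits[keep, , drop = FALSE]
  if (!nrow(h))
    return(data.frame(qseqid = character(), sseqid = character(),
                      evalue = numeric(), bitscore = numeric(),
                      stringsAsFactors = FALSE))
  h$.row <- seq_len(nrow(h))
  ord <- order(h$qseqid, h$evalue, -h$bitscore, h$.row)
  h <- h[ord, , drop = FALSE]
  first <- !duplicated(h$qseqid)
  best <- h[first, , drop = FALSE]
  # log ambiguous winners: same query, e-value and bit score as the winner
  nxt <- which(first) + 1L
  nxt <- nxt[nxt <= nrow(h)]
  amb <- h$qseqid[nxt] == best$qseqid[seq_along(nxt)] &
    h$evalue[nxt] == best$evalue[seq_along(nxt)] &
    h$bitscore[nxt] == best$bitscore[seq_along(nxt)]
  if (any(amb))
    logNote("bestHits: %d quer(ies) tied on (e-value, bit score); first file occurrence kept",
            sum(amb))
  out <- best[order(best$qseqid), c("qseqid", "sseqid", "evalue", "bitscore")]
  rownames(out) <- NULL
  out
}

#' Reciprocal best-hit ortholog resolution
#'
#' Keeps the pair \code{(a, b)} iff \code{a}'s best hit in the A-to-B table
#' is \code{b} *and* \code{b}'s best hit in the B-to-A table is \code{a}.
#' The result is one-to-one by construction and sorted by species-A id.
#'
#' @param hitsAB,hitsBA hit tables for the two alignment directions.
#' @param evalueMax e-value ceiling applied in both directions
#'   (default 0.01).
#' @param speciesA,speciesB species tags recorded on the map.
#' @return an [OrthologMap-class] with per-pair provenance columns
#'   \code{evalueAB}, \code{bitsAB}, \code{evalueBA}, \code{bitsBA}.
#' @export
reciprocalBestHits <- function(hitsAB, hitsBA, evalueMax = 0.01,
                               speciesA = "A", speciesB = "B") {
  bAB <- bestHits(hitsAB, evalueMax)
  bBA <- bestHits(hitsBA, evalueMax)
  if (!nrow(bAB) || !nrow(bBA))
    return(OrthologMap(character(), character(),
                       speciesA = speciesA, speciesB = speciesB,
                       evalueAB = numeric(), bitsAB = numeric(),
                       evalueBA = numeric(), bitsBA = numeric()))
  m <- match(bAB$sseqid, bBA$qseqid)
  ok <- !is.na(m) & bBA$sseqid[m] == bAB$qseqid
  pairs <- bAB[ok, , drop = FALSE]
  back <- bBA[m[ok], , drop = FALSE]
  ord <- order(pairs$qseqid)
  OrthologMap(pairs$qseqid[ord], pairs$sseqid[ord],
              speciesA = speciesA, speciesB = speciesB,
              evalueAB = pairs$evalue[ord], bitsAB = pairs$bitscore[ord],
              evalueBA = back$evalue[ord], bitsBA = back$bitscore[ord])
}

#' Project a protein-level ortholog map to gene level
#'
#' Protein pairs are projected through the two isoform-to-gene maps;
#' duplicate projections of the same gene pair collapse to one. Gene pairs
#' that would break one-to-one-ness (a gene matched to two or more distinct
#' partner genes) are dropped and logged.
#'
#' @param map protein-level [OrthologMap-class].
#' @param isoToGeneA,isoToGeneB named character vectors mapping protein ids
#'   to gene ids for each species; every mapped protein id must be present.
#' @return gene-level [OrthologMap-class].
#' @export
collapseToGeneLevel <- function(map, isoToGeneA, isoToGeneB) {
  p <- as.data.frame(orthologPairs(map))
  sp <- speciesLabel(map)
  if (!nrow(p))
    return(OrthologMap(character(), character(),
                       speciesA = sp[["A"]], speciesB = sp[["B"]]))
  unA <- setdiff(p$idA, names(isoToGeneA))
  unB <- setdiff(p$idB, names(isoToGeneB))
  if (length(unA) || length(unB))
    stop("unmapped protein id(s): ",
         paste(c(unA, unB), collapse = ", "))
  g <- unique(data.frame(idA = unname(isoToGeneA[p$idA]),
                         idB = unname(isoToGeneB[p$idB]),
                         stringsAsFactors = FALSE))
  conflictA <- g$idA %in% g$idA[duplicated(g$idA)]
  conflictB <- g$idB %in% g$idB[duplicated(g$idB)]
  drop <- conflictA | conflictB
  if (any(drop))
    logNote("collapseToGeneLevel: %d conflicting gene pair(s) dropped to preserve one-to-one mapping",
            sum(drop))
  g <- g[!drop, , drop = FALSE]
  g <- g[order(g$idA), , drop = FALSE]
  OrthologMap(g$idA, g$idB, speciesA = sp[["A"]], speciesB = sp[["B"]])
}
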