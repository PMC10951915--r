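#' Rule-based in-silico proteolysis of one sequence
#'
#' Trypsin cleaves C-terminal to K or R except when the next residue is P;
#' LysC cleaves C-terminal to K including before P. With
#' \code{missedCleavages = m}, every union of up to \code{m + 1}
#' consecutive fully-cleaved fragments is emitted; length filters are
#' applied last. With \code{m = 0} and no length filter, concatenating the
#' returned peptides in order reconstructs the input sequence.
#'
#' @param sequence a single amino-acid string (canonical residues plus X
#'   and U).
#' @param protease \code{"trypsin"} or \code{"lysC"}.
#' @param missedCleavages maximum missed cleavages (default 0).
#' @param minLen,maxLen peptide length filter (defaults keep everything).
#' @return character vector of peptides, ordered by start position then
#'   span.
#' @examples
#' digestProtein("MKRPGK")            # "MK", "RPGK" (no cleavage before P)
#' digestProtein("MKRPGK", missedCleavages = 1)
#' @export
digestProtein <- function(sequence, protease = c("trypsin", "lysC"),
                          missedCleavages = 0L, minLen = 1L,
                          maxLen = Inf) {
  protease <- match.arg(protease)
  stopIfNot(is.character(sequence) && length(sequence) == 1L &&
              nzchar(sequence), "sequence must be a non-empty string")
  stopIfNot(missedCleavages >= 0, "missedCleavages must be >= 0")
  bad <- regexpr(sprintf("[^%s]", paste(.AA_ALPHABET, collapse = "")),
                 sequence)
  if (bad > 0)
    stop(sprintf("invalid residue '%s' at position %d",
                 substr(sequence, bad, bad), bad))
  pat <- if (protease == "trypsin") "(?<=[KR])(?!P)" else "(?<=K)"
  cut <- gregexpr(pat, sequence, perl = TRUE)[[1L]]
  cut <- cut[cut > 0]
  n <- nchar(sequence)
  cut <- cut[cut <= n]           # no cut after the final residue
  starts <- c(1L, cut)
  ends <- c(cut - 1L, n)
  nf <- length(starts)
  peps <- character(0)
  for (i in seq_len(nf)) {
    jmax <- min(nf, i + missedCleavages)
    for (j in i:jmax) {
      L <- ends[j] - starts[i] + 1L
      if (L >= minLen && L <= maxLen)
        peps <- c(peps, substr(sequence, starts[i], ends[j]))
    }
  }
  peps
}

#' Digest a sequence set into a peptide set
#'
#' @param sequences an [Biostrings::AAStringSet] or named character vector.
#' @param protease,missedCleavages,minLen,maxLen see [digestProtein()].
#' @param sourceId label for the source database.
#' @return a \code{"PeptideSet"}: list with \code{sourceId},
#'   \code{protease}, \code{missedCleavages}, \code{peptides} (per-parent
#'   list, in order) and \code{distinct} (unique peptide strings).
#' @export
digestSet <- function(sequences, protease = c("trypsin", "lysC"),
                      missedCleavages = 0L, minLen = 1L, maxLen = Inf,
                      sourceId = "db") {
  protease <- match.arg(protease)
  seqs <- as.character(sequences)
  if (is.null(names(seqs))) names(seqs) <- names(sequences)
  stopIfNot(!is.null(names(seqs)) && all(nzchar(names(seqs))),
            "sequences must be named")
  peps <- lapply(seqs, digestProtein, protease = protease,
                 missedCleavages = missedCleavages, minLen = minLen,
                 maxLen = maxLen)
  structure(list(sourceId = sourceId, protease = protease,
                 missedCleavages = missedCleavages, peptides = peps,
                 distinct = unique(unlist(peps, use.names = FALSE))),
            class = "PeptideSet")
}

#' @export
print.PeptideSet <- function(x, ...) {
  cat(sprintf("PeptideSet '%s' (%s, %d missed): %d parents, %d distinct peptides\n",
              x$sourceId, x$protease, x$missedCleavages,
              length(x$peptides), length(x$distinct)))
  invisible(x)
}

#' Overlap between two peptide sets
#'
#' Fractions are taken over the union of distinct peptide strings:
#' \code{shared = |A intersect B| / |A union B|}, with the unique fractions
#' defined analogously, so the three fractions sum to one. Comparing sets
#' digested under different protease settings is an error.
#'
#' @param setA,setB \code{"PeptideSet"} objects from [digestSet()].
#' @return named numeric vector \code{sharedFraction},
#'   \code{uniqueAFraction}, \code{uniqueBFraction}.
#' @examples
#' a <- digestSet(c(p1 = "MKRPGKAA"))
#' b <- digestSet(c(p1 = "MKRPGKCC"))
#' peptideOverlap(a, b)
#' @export
peptideOverlap <- function(setA, setB) {
  if (!identical(setA$protease, setB$protease) ||
      !identical(setA$missedCleavages, setB$missedCleavages))
    stop("invalid comparison: peptide sets use different protease settings")
  A <- setA$distinct
  B <- setB$distinct
  uni <- union(A, B)
  stopIfNot(length(uni) > 0, "both peptide sets are empty")
  shared <- length(intersect(A, B))
  c(sharedFraction = shared / length(uni),
    uniqueAFraction = length(setdiff(A, B)) / length(uni),
    uniqueBFraction = length(setdiff(B, A)) / length(uni))
}

#' SNP-robustness report for two sequence database batches
#'
#' Restricts both batches to sequences with identical identifiers, digests
#' each in silico under the same protease settings, and reports the
#' shared / unique peptide fractions over the union of distinct peptides,
#' together with shared-id and per-batch peptide counts. Low unique
#' fractions indicate that sequence polymorphism between the batches has
#' minimal influence on peptide-level identification.
#'
#' @param batch1,batch2 [Biostrings::AAStringSet] objects (or named
#'   character vectors).
#' @param protease,missedCleavages see [digestProtein()].
#' @return list with \code{nSharedIds}, \code{nPeptides1},
#'   \code{nPeptides2}, \code{sharedFraction}, \code{uniqueFraction1},
#'   \code{uniqueFraction2} (fractions in percent of the union).
#' @examples
#' sim <- simulateSnpBatches(20, 100, snpRate = 0, seed = 1)
#' snpRobustnessReport(sim$batch1, sim$batch2)$sharedFraction  # 100
#' @export
snpRobustnessReport <- function(batch1, batch2,
                                protease = c("trypsin", "lysC"),
                                missedCleavages = 0L) {
  protease <- match.arg(protease)
  s1 <- as.character(batch1)
  s2 <- as.character(batch2)
  shared <- intersect(names(s1), names(s2))
  if (!length(shared))
    stop("no shared sequence identifiers between the batches")
  d1 <- digestSet(s1[shared], protease = protease,
                  missedCleavages = missedCleavages, sourceId = "batch1")
  d2 <- digestSet(s2[shared], protease = protease,
                  missedCleavages = missedCleavages, sourceId = "batch2")
  ov <- peptideOverlap(d1, d2)
  list(nSharedIds = length(shared),
       nPeptides1 = length(d1$distinct),
       nPeptides2 = length(d2$distinct),
       sharedFraction = unname(ov["sharedFraction"]) * 100,
       uniqueFraction1 = unname(ov["uniqueAFraction"]) * 100,
       uniqueFraction2 = unname(ov["uniqueBFraction"]) * 100)
}
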