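#' @importFrom utils read.delim write.table
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet width
NULL

.AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "U")

#' Read an expression matrix from TSV
#'
#' First column holds entity ids; remaining columns are developmental stages
#' in column (not lexical) order. Blank cells and \code{"NA"} are parsed as
#' missing; negative values and duplicated ids are rejected.
#'
#' @param path path to a tab-separated file with a header row.
#' @param modality,species passed to [StageExperiment()].
#' @return a [StageExperiment-class].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("id\tunfE\tlarva", "g1\t1\t2", "g2\t3\tNA"), tf)
#' readExpressionTsv(tf, "rna_tpm", "Ciona")
#' @export
readExpressionTsv <- function(path, modality, species) {
  stopIfNot(file.exists(path), "file not found: %s", path)
  if (file.size(path) == 0L) stop("format error: empty file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          na.strings = c("", "NA"), quote = "")
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("format error: expression file needs an id column and >= 1 stage: ",
         path)
  ids <- df[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("format error: duplicated entity id(s): ",
         paste(unique(dup), collapse = ", "))
  vals <- as.matrix(df[-1L])
  suppressWarnings(storage.mode(vals) <- "double")
  bad <- which(vals < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("format error: negative value at entity '%s', stage '%s'",
                 ids[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]]))
  rownames(vals) <- ids
  StageExperiment(vals, modality = modality, species = species)
}

#' Write an expression matrix to TSV
#'
#' Values are serialized in linear space with 15 significant digits; missing
#' values are written as \code{"NA"}. The writer/reader pair is a lossless
#' round trip at that precision.
#'
#' @param x a [StageExperiment-class].
#' @param path output path.
#' @param idColumn header for the id column.
#' @return invisibly, \code{path}.
#' @export
writeExpressionTsv <- function(x, path, idColumn = "id") {
  v <- exprValues(x)
  chr <- matrix(sprintf("%.15g", v), nrow(v), ncol(v))
  chr[is.na(v)] <- "NA"
  lines <- c(paste(c(idColumn, colnames(v)), collapse = "\t"),
             paste(rownames(v), apply(chr, 1L, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a protein FASTA file
#'
#' Headers are truncated to their first whitespace token and must be unique.
#' Sequences are upper-cased; a single trailing \code{*} stop character is
#' stripped; residues are validated against the 20 canonical amino acids
#' plus \code{X} and \code{U} (selenocysteine).
#'
#' @param path FASTA path.
#' @return a [Biostrings::AAStringSet].
#' @export
readProteinFasta <- function(path) {
  stopIfNot(file.exists(path), "file not found: %s", path)
  aa <- withCallingHandlers(
    Biostrings::readAAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        stop("format error: invalid residue code(s) in ", path,
             call. = FALSE)
      invokeRestart("muffleWarning")
    })
  nm <- sub("\\s.*$", "", names(aa))
  dup <- nm[duplicated(nm)]
  if (length(dup))
    stop("format error: duplicated FASTA header token(s): ",
         paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(aa))
  seqs <- sub("\\*$", "", seqs)
  if (any(!nzchar(seqs)))
    stop("format error: empty sequence for: ",
         paste(nm[!nzchar(seqs)], collapse = ", "))
  badPat <- sprintf("[^%s]", paste(.AA_ALPHABET, collapse = ""))
  off <- grepl(badPat, seqs)
  if (any(off))
    stop(sprintf("format error: invalid residue '%s' in sequence '%s'",
                 regmatches(seqs[off][1L], regexpr(badPat, seqs[off][1L])),
                 nm[off][1L]))
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- nm
  out
}

#' Write protein sequences to FASTA
#' @param x an [Biostrings::AAStringSet] (or named character vector).
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeProteinFasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::AAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

.BLAST_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Read a 12-column tabular alignment hit file
#'
#' Standard headerless "outfmt 6" layout: query id, subject id, percent
#' identity, alignment length, mismatches, gap opens, query/subject
#' start/end, e-value, bit score. Row order is preserved.
#'
#' @param path path to the tab-separated hit table.
#' @return a data.frame with columns \code{qseqid, sseqid, pident, length,
#'   mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore}.
#' @export
readBlastTab <- function(path) {
  stopIfNot(file.exists(path), "file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- as.data.frame(stats::setNames(
      c(list(character(), character()), rep(list(numeric()), 10L)),
      .BLAST_COLS))
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L))
    stop(sprintf("format error: expected 12 columns but found %d at line %d",
                 nf[nf != 12L][1L], which(nf != 12L)[1L]))
  m <- matrix(unlist(parts), ncol = 12L, byrow = TRUE)
  out <- data.frame(qseqid = m[, 1L], sseqid = m[, 2L],
                    stringsAsFactors = FALSE)
  for (j in 3:12) out[[.BLAST_COLS[j]]] <- as.numeric(m[, j])
  if (any(!is.finite(out$evalue)) || any(out$evalue < 0))
    stop("format error: e-values must be finite and >= 0")
  if (any(!is.finite(out$bitscore)))
    stop("format error: bit scores must be finite")
  out
}

#' Write a hit table in 12-column tabular layout
#' @param hits data.frame as returned by [readBlastTab()].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeBlastTab <- function(hits, path) {
  stopIfNot(all(.BLAST_COLS %in% names(hits)),
            "hit table must have the 12 standard columns")
  df <- hits[.BLAST_COLS]
  df$evalue <- sprintf("%.6g", df$evalue)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a protein-complex membership catalog
#'
#' TSV with three columns: complex id, complex name, and members as a
#' \code{';'}-separated id list. Complexes with fewer than two members are
#' rejected.
#'
#' @param path catalog path (no header).
#' @return data.frame with columns \code{complexId}, \code{complexName} and
#'   list-column \code{members}.
#' @export
readComplexCatalog <- function(path) {
  stopIfNot(file.exists(path), "file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(complexId = character(), complexName = character(),
                      members = I(list())))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3L))
    stop(sprintf("format error: expected 3 columns at line %d",
                 which(lengths(parts) != 3L)[1L]))
  m <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
  members <- strsplit(m[, 3L], ";", fixed = TRUE)
  members <- lapply(members, function(x) x[nzchar(x)])
  small <- lengths(members) < 2L
  if (any(small))
    stop("format error: complex with < 2 members: ",
         paste(m[small, 1L], collapse = ", "))
  data.frame(complexId = m[, 1L], complexName = m[, 2L],
             members = I(members), stringsAsFactors = FALSE)
}

#' Write a protein-complex catalog
#' @param catalog data.frame as from [readComplexCatalog()].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeComplexCatalog <- function(catalog, path) {
  writeLines(paste(catalog$complexId, catalog$complexName,
                   vapply(catalog$members, paste, "", collapse = ";"),
                   sep = "\t"), path)
  invisible(path)
}

#' Read an annotation id list (one id per line)
#'
#' @param path file with one entity id per line.
#' @param category one of \code{"TF"}, \code{"SM"}, \code{"kinase"},
#'   \code{"phosphatase"}.
#' @return character vector of unique ids with attribute \code{category};
#'   repeated ids are de-duplicated with a warning.
#' @export
readAnnotationList <- function(path, category = c("TF", "SM", "kinase",
                                                  "phosphatase")) {
  category <- match.arg(category)
  stopIfNot(file.exists(path), "file not found: %s", path)
  ids <- readLines(path)
  ids <- trimws(ids)
  ids <- ids[nzchar(ids)]
  if (anyDuplicated(ids)) {
    warning(sprintf("annotation list '%s': %d repeated id(s) de-duplicated",
                    category, sum(duplicated(ids))))
    ids <- unique(ids)
  }
  structure(ids, category = category)
}

#' Read / write a spike-in standards table
#'
#' TSV with header and columns \code{standard_id}, \code{known_amount},
#' \code{measured_signal}. Known amounts must be positive; a zero measured
#' signal means "undetected" and is excluded from curve fitting downstream.
#'
#' @param path file path.
#' @return data.frame with the three columns above.
#' @export
readSpikeInTsv <- function(path) {
  stopIfNot(file.exists(path), "file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, quote = "")
  need <- c("standard_id", "known_amount", "measured_signal")
  stopIfNot(all(need %in% names(df)),
            "format error: spike-in table needs columns %s",
            paste(need, collapse = ", "))
  df$known_amount <- as.numeric(df$known_amount)
  df$measured_signal <- as.numeric(df$measured_signal)
  if (any(!is.finite(df$known_amount)) || any(df$known_amount <= 0))
    stop("format error: known_amount must be positive")
  if (any(df$measured_signal < 0, na.rm = TRUE))
    stop("format error: measured_signal must be >= 0")
  df[need]
}

#' @rdname readSpikeInTsv
#' @param spikeins data.frame with the three spike-in columns.
#' @export
writeSpikeInTsv <- function(spikeins, path) {
  df <- spikeins[c("standard_id", "known_amount", "measured_signal")]
  df$known_amount <- sprintf("%.15g", df$known_amount)
  df$measured_signal <- sprintf("%.15g", df$measured_signal)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an ortholog map to TSV
#' @param map an [OrthologMap-class].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeOrthologMap <- function(map, path) {
  df <- as.data.frame(orthologPairs(map))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
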