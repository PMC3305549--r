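# Codon alignment construction and sanitation: translation, protein-to-codon
# back-mapping, gap-column deletion, pairwise shared sites.

#' Construct a codon alignment
#'
#' @param seqs named character vector or [Biostrings::DNAStringSet] of
#'   equal-length aligned coding sequences (length a multiple of 3).
#' @param columnMap optional integer map from current codon columns to the
#'   codon columns of a parent alignment; defaults to the identity.
#' @return a [CodonAlignment].
#' @export
CodonAlignment <- function(seqs, columnMap = NULL) {
  if (!is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  nc <- if (length(seqs)) Biostrings::width(seqs)[1] %/% 3 else 0L
  if (is.null(columnMap)) columnMap <- seq_len(nc)
  new("CodonAlignment", seqs = seqs, columnMap = as.integer(columnMap))
}

#' @describeIn CodonAlignment number of codon columns.
#' @param x a [CodonAlignment].
#' @export
codonLength <- function(x) {
  stopifnot(is(x, "CodonAlignment"))
  if (!length(x@seqs)) 0L else Biostrings::width(x@seqs)[1] %/% 3L
}

#' @describeIn CodonAlignment the aligned sequences as a
#'   [Biostrings::DNAStringSet].
#' @export
alignedSeqs <- function(x) x@seqs

#' @describeIn CodonAlignment map from current codon columns to original
#'   alignment columns.
#' @export
columnMap <- function(x) x@columnMap

setMethod("show", "CodonAlignment", function(object) {
  cat("CodonAlignment:", length(object@seqs), "sequences x",
      codonLength(object), "codon columns\n")
})

setMethod("length", "CodonAlignment", function(x) length(x@seqs))

#' Translate a coding sequence
#'
#' Standard genetic code. A terminal stop codon is dropped; an internal stop
#' is an error, as are sequences whose length is not a multiple of three or
#' that contain characters outside ACGT/N. Codons containing N translate
#' to X.
#'
#' @param cds a character string, [Biostrings::DNAString] or a vector /
#'   [Biostrings::DNAStringSet] (translated element-wise).
#' @return character protein sequence(s).
#' @export
translateCDS <- function(cds) {
  if (is(cds, "DNAStringSet")) cds <- as.character(cds)
  if (is(cds, "DNAString")) cds <- as.character(cds)
  out <- vapply(cds, function(s) {
    s <- toupper(s)
    if (nchar(s) %% 3 != 0)
      stop("CDS length not a multiple of 3 (", nchar(s), ")")
    if (grepl("[^ACGTN]", s)) stop("CDS contains characters outside ACGT/N")
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    aa <- ifelse(grepl("N", codons), "X",
                 Biostrings::GENETIC_CODE[codons])
    if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
    if (any(aa == "*")) stop("internal stop codon in CDS")
    paste(aa, collapse = "")
  }, character(1))
  if (is.null(names(cds))) unname(out) else out
}

#' Map a protein alignment back onto codons
#'
#' Expands each aligned amino-acid column into one codon column: residues
#' become the corresponding CDS codon, protein gaps become `---`. Each
#' ungapped protein row must equal the translation of its paired CDS.
#'
#' @param proteinAln named character vector or [Biostrings::AAStringSet] of
#'   aligned protein rows (gaps as `-`).
#' @param cdsRecords named character vector or [Biostrings::DNAStringSet] of
#'   unaligned coding sequences, names matching `proteinAln`.
#' @return a [CodonAlignment] (may contain gap columns; see
#'   [stripGapColumns()]).
#' @export
backmapCodons <- function(proteinAln, cdsRecords) {
  if (is(proteinAln, "AAStringSet")) proteinAln <- as.character(proteinAln)
  if (is(cdsRecords, "DNAStringSet")) cdsRecords <- as.character(cdsRecords)
  if (is.null(names(proteinAln)) || !all(names(proteinAln) %in% names(cdsRecords)))
    stop("protein rows must be named and present in cdsRecords")
  rows <- vapply(names(proteinAln), function(nm) {
    prot <- strsplit(proteinAln[[nm]], "")[[1]]
    cds <- toupper(cdsRecords[[nm]])
    # drop a terminal stop codon if present
    if (nchar(cds) %% 3 == 0) {
      last <- substring(cds, nchar(cds) - 2, nchar(cds))
      if (!is.na(Biostrings::GENETIC_CODE[last]) &&
          Biostrings::GENETIC_CODE[last] == "*")
        cds <- substring(cds, 1, nchar(cds) - 3)
    }
    if (translateCDS(cds) != gsub("-", "", proteinAln[[nm]]))
      stop("protein row ", nm, " does not match the translation of its CDS")
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    out <- character(length(prot))
    out[prot == "-"] <- "---"
    out[prot != "-"] <- codons
    paste(out, collapse = "")
  }, character(1))
  CodonAlignment(rows)
}

#' Delete codon columns containing gaps or ambiguity
#'
#' Removes every codon column in which any row carries a gap, a stop codon,
#' or an ambiguous base (N/X treated as missing), preserving column order.
#' The returned alignment's column map gives, for each retained column, its
#' index in `aln`'s coordinates (composed with `aln`'s own map), so site
#' reports can refer to original alignment positions.
#'
#' @param aln a [CodonAlignment].
#' @return a gap-free [CodonAlignment]; the operation is idempotent.
#' @export
stripGapColumns <- function(aln) {
  stopifnot(is(aln, "CodonAlignment"))
  ct <- codonTable()
  cm <- codonCharMatrix(aln)
  keep <- apply(cm, 2, function(col) all(col %in% ct$codons))
  seqs <- Biostrings::DNAStringSet(apply(
    cm[, keep, drop = FALSE], 1, paste, collapse = ""))
  if (!sum(keep)) seqs <- Biostrings::DNAStringSet(
    setNames(rep("", nrow(cm)), rownames(cm)))
  names(seqs) <- rownames(cm)
  CodonAlignment(seqs, columnMap = aln@columnMap[keep])
}

#' Write the codon column map of an alignment
#'
#' Two-column TSV mapping each current codon column to its position in the
#' original alignment (before gap-column deletion).
#'
#' @param aln a [CodonAlignment].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeColumnMap <- function(aln, path) {
  write.table(data.frame(column = seq_along(aln@columnMap),
                         original = aln@columnMap),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sites shared by two aligned rows under pairwise deletion
#'
#' Indices of alignment positions at which both rows are ungapped and
#' unambiguous. Works on protein or nucleotide rows (character strings of
#' equal length); ambiguity characters `N` and `X` count as missing.
#'
#' @param rowA,rowB equal-length aligned sequence strings.
#' @return integer vector of shared site indices.
#' @export
pairwiseSharedSites <- function(rowA, rowB) {
  a <- strsplit(as.character(rowA), "")[[1]]
  b <- strsplit(as.character(rowB), "")[[1]]
  if (length(a) != length(b)) stop("rows must have equal length")
  bad <- c("-", ".", "N", "X", "n", "x", "?")
  which(!(a %in% bad) & !(b %in% bad))
}

#' Read and write FASTA sequence files
#'
#' Thin wrappers over Biostrings' FASTA I/O used throughout the package.
#'
#' @param path file path.
#' @param type `"AA"` or `"DNA"`.
#' @return `readFasta`: an `AAStringSet` or `DNAStringSet`.
#' @export
readFasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  if (type == "AA") Biostrings::readAAStringSet(path)
  else Biostrings::readDNAStringSet(path)
}

#' @rdname readFasta
#' @param seqs an `XStringSet` (or named character vector) to write.
#' @export
writeFasta <- function(seqs, path) {
  if (is.character(seqs))
    seqs <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
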