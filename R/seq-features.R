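## Sequence-level computations: CDS translation, transit-peptide cleavage,
## ionogenic-residue censuses.

#' Construct a coding sequence
#'
#' @param nucleotides string over A/C/G/T; must start with ATG, end with a
#'   stop codon, and have length divisible by 3
#' @param id identifier
#' @return a \linkS4class{CodingSequence}
#' @export
codingSequence <- function(nucleotides, id = "cds") {
  new("CodingSequence", nucleotides = toupper(gsub("\\s", "", nucleotides)),
      id = id)
}

#' Read a CDS from FASTA or plain text
#'
#' @param file FASTA (first record) or plain nucleotide text
#' @return a \linkS4class{CodingSequence}
#' @export
readCds <- function(file) {
  lines <- readLines(file, warn = FALSE)
  id <- "cds"
  if (length(lines) && startsWith(lines[1], ">")) {
    id <- sub("^>\\s*", "", strsplit(lines[1], "\\s+")[[1]][1])
    id <- sub(">", "", id)
    lines <- lines[-1]
    lines <- lines[!startsWith(lines, ">")]
  }
  codingSequence(paste(lines, collapse = ""), id = id)
}

#' Translate a coding sequence
#'
#' Standard genetic code; the terminal stop is removed. Internal stop codons
#' raise an error with the offending codon index.
#'
#' @param cds a \linkS4class{CodingSequence}
#' @return a \linkS4class{ProteinRecord} (transit peptide unannotated)
#' @export
translateCds <- function(cds) {
  nt <- cds@nucleotides
  ncod <- nchar(nt) / 3
  codons <- substring(nt, 3 * (seq_len(ncod) - 1) + 1, 3 * seq_len(ncod))
  internalStop <- which(codons[-ncod] %in% c("TAA", "TAG", "TGA"))
  if (length(internalStop))
    stop("internal stop codon at codon index ", internalStop[1])
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt)))
  aa <- sub("\\*$", "", aa)
  new("ProteinRecord", sequence = aa, transitPeptideLength = NA_integer_,
      matureStart = 1L)
}

#' Cleave an N-terminal transit peptide
#'
#' Removes the first \code{n} residues. Reports keep full-precursor
#' numbering, so residue labels (e.g. Glu-87) include the transit-peptide
#' offset.
#'
#' @param protein a \linkS4class{ProteinRecord}
#' @param n transit-peptide length in residues (41 for the chloroplast
#'   precursor studied here)
#' @return the mature sequence (character); the input record annotated via
#'   \code{attr(, "record")}
#' @export
cleaveTransitPeptide <- function(protein, n = 41L) {
  len <- nchar(protein@sequence)
  if (n >= len) stop("transit peptide length ", n,
                     " must be smaller than protein length ", len)
  mature <- substr(protein@sequence, n + 1, len)
  rec <- protein
  rec@transitPeptideLength <- as.integer(n)
  rec@matureStart <- as.integer(n + 1)
  attr(mature, "record") <- rec
  mature
}

#' Census of ionogenic residues
#'
#' Counts R, K, Y, E, D (the total is over these five) plus H and C in a
#' 1-letter sequence.
#'
#' @param sequence 1-letter amino-acid string
#' @return named list: counts per letter and \code{total} over R/K/Y/E/D
#' @export
ionogenicCensus <- function(sequence) {
  seqchars <- strsplit(toupper(sequence), "")[[1]]
  valid <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  bad <- setdiff(seqchars, valid)
  if (length(bad))
    stop("invalid residue letters: ", paste(unique(bad), collapse = ", "))
  letters_ <- c("R", "K", "Y", "E", "D", "H", "C")
  counts <- vapply(letters_, function(l) sum(seqchars == l), 0L)
  c(as.list(counts), list(total = sum(counts[c("R", "K", "Y", "E", "D")])))
}
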