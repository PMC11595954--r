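#' @useDynLib mitomarker, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

check_dna <- function(sequence, what = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L)
    stop(what, " must be a single character string", call. = FALSE)
  s <- toupper(sequence)
  bad <- setdiff(unique(strsplit(s, "", fixed = TRUE)[[1]]), DNA_ALPHABET)
  if (length(bad) > 0L)
    stop("illegal character(s) in ", what, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  s
}

#' GC content of a nucleotide sequence
#'
#' Fraction (G+C)/(A+C+G+T). `N` bases are excluded from both numerator
#' and denominator, so the value reflects resolved bases only.
#'
#' @param sequence A nucleotide string over A/C/G/T/N (case-insensitive).
#' @return Fraction in \[0, 1\].
#' @examples
#' gc_content("GGCC")  # 1
#' gc_content("ATAT")  # 0
#' @export
gc_content <- function(sequence) {
  s <- check_dna(sequence)
  if (nchar(s) == 0L)
    stop("GC content undefined for an empty sequence", call. = FALSE)
  gc <- nchar(gsub("[^GC]", "", s))
  acgt <- nchar(gsub("[^ACGT]", "", s))
  if (acgt == 0L)
    stop("GC content undefined: sequence contains no A/C/G/T bases",
         call. = FALSE)
  gc / acgt
}

#' Reverse complement
#'
#' @param sequence A nucleotide string over A/C/G/T/N.
#' @return The reverse complement, uppercase.
#' @export
reverse_complement <- function(sequence) {
  s <- check_dna(sequence)
  if (nchar(s) == 0L) return(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' A genetic code as a 64-entry codon table
#'
#' Wraps an NCBI translation table as a plain named vector mapping codons
#' to one-letter amino acids, with `*` marking stops. The default is
#' table 4 (mold mitochondrial; TGA read as tryptophan), the conventional
#' code for fungal mitochondria.
#'
#' @param table_id NCBI translation-table number (e.g. 1, 4).
#' @return An object of class `genetic_code`: list with `table_id` and
#'   `codon_map` (named character vector of length 64).
#' @export
genetic_code <- function(table_id = 4) {
  map <- Biostrings::getGeneticCode(as.character(table_id))
  map <- map[order(names(map))]
  stopifnot(length(map) == 64L, any(map == "*"))
  structure(list(table_id = table_id, codon_map = map),
            class = "genetic_code")
}

#' Translate a coding sequence
#'
#' In `complete` mode the sequence must be a whole CDS: length divisible
#' by three, exactly one stop codon, located at the end; the translation
#' excludes that stop, so a 222 bp CDS yields 73 residues and a 267 bp
#' CDS yields 88. In `fragment` mode any in-frame piece is translated and
#' no stop is required.
#'
#' @param sequence Nucleotide string, length divisible by 3.
#' @param code A [genetic_code()].
#' @param mode `"complete"` or `"fragment"`.
#' @return Amino-acid string (stop excluded in complete mode).
#' @export
translate_cds <- function(sequence, code = genetic_code(4),
                          mode = c("complete", "fragment")) {
  mode <- match.arg(mode)
  s <- check_dna(sequence, "CDS")
  n <- nchar(s)
  if (n == 0L || n %% 3L != 0L)
    stop("frame error: CDS length ", n, " is not a positive multiple of 3",
         call. = FALSE)
  codons <- substring(s, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
  aa <- unname(code$codon_map[codons])
  aa[is.na(aa)] <- "X"  # codons containing N are untranslatable
  if (mode == "complete") {
    stops <- which(aa == "*")
    if (length(stops) == 0L)
      stop("complete CDS lacks a terminal stop codon", call. = FALSE)
    if (stops[1] != length(aa))
      stop("premature stop codon at codon ", stops[1], call. = FALSE)
    aa <- aa[-length(aa)]
  }
  paste(aa, collapse = "")
}
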