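#' Reverse complement of a nucleotide string
#'
#' @param seq string over `{A,C,G,T,N}` (case-insensitive).
#' @return The reverse complement, upper case. `reverse_complement` is an
#'   involution: applying it twice returns the input.
#' @export
reverse_complement <- function(seq) {
  seq <- toupper(as.character(seq))
  if (grepl("[^ACGTN]", seq)) stop("sequence contains characters outside {A,C,G,T,N}")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' G+C content as a percentage
#'
#' Computed over non-N bases only; `N`s are excluded from the denominator.
#'
#' @param seq nucleotide string over `{A,C,G,T,N}`.
#' @param digits decimals to round to (default 1, the conventional reporting
#'   precision for plastome GC).
#' @return GC percentage (0--100).
#' @export
gc_content <- function(seq, digits = 1L) {
  seq <- toupper(as.character(seq))
  if (grepl("[^ACGTN]", seq)) stop("sequence contains characters outside {A,C,G,T,N}")
  x <- charToRaw(seq)
  gc <- sum(x == charToRaw("G") | x == charToRaw("C"))
  acgt <- sum(x != charToRaw("N"))
  if (acgt == 0L) return(NA_real_)
  round(100 * gc / acgt, digits)
}

#' Conceptual translation of a plastid CDS
#'
#' Uses the bacterial/plant-plastid genetic code (translation table 11).
#' Stops are rendered as `*`; codons containing `N` translate to `X`;
#' a partial trailing codon is ignored.
#'
#' @param seq nucleotide string.
#' @param codon_start reading-frame offset 1, 2 or 3 (GenBank convention:
#'   translation begins at this base).
#' @return Amino-acid string (possibly empty for degenerate input).
#' @export
translate_cds <- function(seq, codon_start = 1L) {
  seq <- toupper(as.character(seq))
  stopifnot(codon_start %in% 1:3)
  if (nchar(seq) >= codon_start) seq <- substring(seq, codon_start) else seq <- ""
  n <- nchar(seq) - nchar(seq) %% 3L
  if (n < 3L) return("")
  seq <- substring(seq, 1L, n)
  as.character(Biostrings::translate(Biostrings::DNAString(seq),
                                     genetic.code = Biostrings::getGeneticCode("11"),
                                     if.fuzzy.codon = "X"))
}

#' Extract the (spliced, stranded) sequence of a feature
#'
#' Exons are spliced in their stored genomic order and the concatenation is
#' reverse-complemented for minus-strand features; origin-wrapping exons on
#' circular records are handled.
#'
#' @param record a [plastome_record()].
#' @param feature a [gene_feature()] whose intervals are valid for `record`.
#' @return Nucleotide string of the feature, 5' to 3'.
#' @export
extract_feature_sequence <- function(record, feature) {
  L <- record$length
  for (ex in feature$exons)
    if (ex$start > L || ex$end > L) stop("feature interval out of range")
  spl <- paste(vapply(feature$exons, function(ex) interval_seq(record, ex), ""),
               collapse = "")
  if (feature$strand == "-") spl <- reverse_complement(spl)
  spl
}

# raw-byte complement lookup used by the repeat/IR scanners
.comp_lookup <- local({
  tab <- raw(256)
  from <- charToRaw("ACGTN"); to <- charToRaw("TGCAN")
  tab[as.integer(from) + 1L] <- to
  tab
})

comp_raw <- function(x) .comp_lookup[as.integer(x) + 1L]

# raw codes that never match anything (N and padding)
.raw_N <- charToRaw("N")
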