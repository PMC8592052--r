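#' Annotated (circular) plastome record
#'
#' The central container of the package: a nucleotide sequence over
#' `{A,C,G,T,N}` plus typed, stranded, possibly multi-exon gene annotations.
#' Circular genomes are represented linearised at their deposited origin;
#' features that cross the origin carry wrapping exon intervals rather than
#' being split silently.
#'
#' @param id accession or sample name.
#' @param seq nucleotide string; lower case is accepted and upper-cased.
#' @param circular logical, is the molecule circular?
#' @param features list of [gene_feature()] annotations.
#' @return An object of class `plastome_record` with fields `id`, `seq`,
#'   `circular`, `features` and `length`.
#' @export
plastome_record <- function(id, seq, circular = TRUE, features = list()) {
  seq <- toupper(as.character(seq))
  if (nchar(seq) == 0L) stop("empty sequence")
  if (grepl("[^ACGTN]", seq)) stop("sequence contains characters outside {A,C,G,T,N}")
  L <- nchar(seq)
  rec <- structure(list(id = as.character(id), seq = seq,
                        circular = isTRUE(circular),
                        features = features, length = L),
                   class = "plastome_record")
  validate_record(rec)
  rec
}

validate_record <- function(rec) {
  L <- rec$length
  for (f in rec$features) {
    for (ex in f$exons) {
      if (ex$start > L || ex$end > L)
        stop(sprintf("feature '%s' has exon outside [1, %d]", f$name, L))
      if (ex$wraps && !rec$circular)
        stop(sprintf("feature '%s' wraps the origin of a linear record", f$name))
    }
  }
  invisible(rec)
}

#' @export
print.plastome_record <- function(x, ...) {
  cat(sprintf("plastome_record '%s': %s bp, %s, %d features\n",
              x$id, format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear", length(x$features)))
  invisible(x)
}

#' Gene feature annotation
#'
#' @param name gene symbol (e.g. `"ycf1"`, `"ndhH"`).
#' @param kind one of `"CDS"`, `"tRNA"`, `"rRNA"`, `"misc"`.
#' @param strand `"+"` or `"-"`.
#' @param exons list of [interval()]s in ascending genomic order (a wrapping
#'   exon may occur on circular records).
#' @param codon_start reading-frame offset 1, 2 or 3 (GenBank convention).
#' @param pseudo_flag annotated as a pseudogene?
#' @return An object of class `gene_feature`.
#' @export
gene_feature <- function(name, kind = c("CDS", "tRNA", "rRNA", "misc"),
                         strand = c("+", "-"), exons,
                         codon_start = 1L, pseudo_flag = FALSE) {
  kind <- match.arg(kind)
  strand <- match.arg(strand)
  if (inherits(exons, "pp_interval")) exons <- list(exons)
  if (length(exons) == 0L) stop("feature needs at least one exon")
  stopifnot(codon_start %in% 1:3)
  structure(list(name = as.character(name), kind = kind, strand = strand,
                 exons = exons, codon_start = as.integer(codon_start),
                 pseudo_flag = isTRUE(pseudo_flag)),
            class = "gene_feature")
}

#' @export
print.gene_feature <- function(x, ...) {
  locs <- vapply(x$exons, function(e)
    sprintf("%d..%d%s", e$start, e$end, if (e$wraps) "(w)" else ""), "")
  cat(sprintf("%s%s [%s, %s] %s\n", if (x$pseudo_flag) "ψ" else "",
              x$name, x$kind, x$strand, paste(locs, collapse = ",")))
  invisible(x)
}

# spliced length of a feature in bp
feature_length <- function(f, L) {
  sum(vapply(f$exons, interval_length, 0L, L = L))
}

# overall span of a feature as one interval (assumes the feature occupies a
# contiguous arc much shorter than the genome; true for plastome genes)
feature_span <- function(f, L) {
  if (length(f$exons) == 1L) return(f$exons[[1]])
  s <- f$exons[[1]]$start
  e <- f$exons[[length(f$exons)]]$end
  wraps <- any(vapply(f$exons, function(x) x$wraps, TRUE)) || e < s
  interval(s, e, wraps = wraps)
}

# bp of a feature's exons falling inside a region interval
feature_bp_in <- function(f, region, L) {
  sum(vapply(f$exons, function(ex) interval_intersect_len(ex, region, L), 0L))
}

#' Rotate a circular record so that position `offset + 1` becomes position 1
#'
#' Feature coordinates are remapped; exons that come to cross the origin are
#' flagged as wrapping.
#'
#' @param record a [plastome_record()].
#' @param offset number of leading bases moved to the end (0 = no-op).
#' @return A rotated `plastome_record`.
#' @export
rotate_record <- function(record, offset) {
  L <- record$length
  offset <- as.integer(offset %% L)
  if (offset == 0L) return(record)
  if (!record$circular) stop("cannot rotate a linear record")
  seq2 <- paste0(substring(record$seq, offset + 1L, L),
                 substring(record$seq, 1L, offset))
  feats <- lapply(record$features, function(f) {
    f$exons <- lapply(f$exons, function(ex) {
      s <- circ_pos(ex$start - offset, L)
      e <- circ_pos(ex$end - offset, L)
      interval(s, e, wraps = e < s)
    })
    f
  })
  plastome_record(record$id, seq2, circular = TRUE, features = feats)
}

#' Reverse-complement a whole record, remapping its annotations
#'
#' @param record a [plastome_record()].
#' @return The flipped `plastome_record`: strands are inverted and exon
#'   coordinates mirrored.
#' @export
flip_record <- function(record) {
  L <- record$length
  seq2 <- reverse_complement(record$seq)
  feats <- lapply(record$features, function(f) {
    f$strand <- if (f$strand == "+") "-" else "+"
    f$exons <- rev(lapply(f$exons, function(ex) {
      interval(circ_pos(L - ex$end + 1L, L), circ_pos(L - ex$start + 1L, L),
               wraps = ex$wraps)
    }))
    f
  })
  plastome_record(record$id, seq2, circular = record$circular, features = feats)
}

# sequence of an interval (wrap-aware)
interval_seq <- function(record, iv) {
  if (!iv$wraps) return(substring(record$seq, iv$start, iv$end))
  if (!record$circular) stop("wrapping interval on a linear record")
  paste0(substring(record$seq, iv$start, record$length),
         substring(record$seq, 1L, iv$end))
}

#' Delete a (non-wrapping) region from a record
#'
#' Bases are removed and downstream feature coordinates shifted. Exons fully
#' inside the deletion are dropped; exons straddling a deletion edge are
#' truncated; features losing all exons are removed.
#'
#' @param record a [plastome_record()].
#' @param iv region to delete as an [interval()] (must not wrap).
#' @return The shortened `plastome_record`.
#' @export
delete_region <- function(record, iv) {
  if (iv$wraps) stop("delete_region does not support wrapping intervals")
  L <- record$length
  dlen <- interval_length(iv)
  seq2 <- paste0(substring(record$seq, 1L, iv$start - 1L),
                 substring(record$seq, iv$end + 1L, L))
  shift <- function(p) if (p > iv$end) p - dlen else p
  feats <- list()
  for (f in record$features) {
    kept <- list()
    drop_feature <- FALSE
    for (ex in f$exons) {
      if (ex$wraps) { drop_feature <- TRUE; break }
      if (ex$start >= iv$start && ex$end <= iv$end) next    # fully deleted
      s <- ex$start; e <- ex$end
      if (s >= iv$start && s <= iv$end) s <- iv$end + 1L    # left edge cut
      if (e >= iv$start && e <= iv$end) e <- iv$start - 1L  # right edge cut
      if (s <= iv$end && e >= iv$start && s < iv$start && e > iv$end) {
        # exon spans the whole deletion: merge flanks
        kept[[length(kept) + 1L]] <- interval(s, shift(e))
        next
      }
      kept[[length(kept) + 1L]] <- interval(shift(s), shift(e))
    }
    if (drop_feature || length(kept) == 0L) next
    f$exons <- kept
    feats[[length(feats) + 1L]] <- f
  }
  plastome_record(record$id, seq2, circular = record$circular, features = feats)
}
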