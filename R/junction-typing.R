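#' Type the IRa--SSC junction (J_SA) as A, B or C
#'
#' Type C: *ycf1* lies entirely within the inverted repeat. Otherwise Type B
#' when at least `ab_threshold` bp of *ycf1* sit inside IRa, else Type A.
#' The threshold defaults to 2,000 bp, bisecting the gap between the
#' observed Type A (about 925--1,066 bp) and Type B (about 2,649--2,737 bp)
#' ranges; the raw bp is always reported so relabelling is trivial.
#'
#' @param profile the `J_SA` entry of [junction_profiles()].
#' @param map a found [detect_quadripartite()] result.
#' @param record the corresponding [plastome_record()].
#' @param ab_threshold bp of *ycf1* in IRa at or above which a partially
#'   held *ycf1* is called Type B.
#' @return A `jsa_type`: `type` (`"A"`, `"B"`, `"C"` or `"unclassifiable"`),
#'   `ycf1_bp_in_ira`, `ycf1_fully_in_ir`, `extra_ir_genes`.
#' @export
classify_jsa <- function(profile, map, record, ab_threshold = 2000L) {
  stopifnot(map$found)
  canon <- canonicalize_plastome(record, map)
  L <- canon$length
  ycf <- Filter(function(f) tolower(f$name) == "ycf1" && !f$pseudo_flag,
                canon$features)
  if (length(ycf) == 0L)
    ycf <- Filter(function(f) tolower(f$name) == "ycf1", canon$features)
  if (length(ycf) == 0L) {
    return(structure(list(type = "unclassifiable",
                          ycf1_bp_in_ira = NA_integer_,
                          ycf1_fully_in_ir = NA,
                          extra_ir_genes = character(0),
                          diagnostic = "no ycf1 annotation on this record"),
                     class = "jsa_type"))
  }
  # the copy with the most sequence in IRa is the J_SA-spanning one
  bp <- vapply(ycf, function(f) feature_bp_in(f, map$ira, L), 0L)
  f <- ycf[[which.max(bp)]]
  bp_ira <- max(bp)
  fully <- bp_ira == feature_length(f, L)
  type <- if (fully) "C" else if (bp_ira >= ab_threshold) "B" else "A"
  extra <- setdiff(profile$genes_fully_in_ir_adjacent,
                   c("ycf1", "ψycf1"))
  structure(list(type = type, ycf1_bp_in_ira = bp_ira,
                 ycf1_fully_in_ir = fully, extra_ir_genes = extra,
                 ab_threshold = ab_threshold),
            class = "jsa_type")
}

#' @export
print.jsa_type <- function(x, ...) {
  cat(sprintf("J_SA type %s (ycf1 bp in IRa: %s%s)\n", x$type,
              x$ycf1_bp_in_ira,
              if (isTRUE(x$ycf1_fully_in_ir)) ", fully in IR" else ""))
  invisible(x)
}

#' Short repeats shared between two windows (candidate recombination sites)
#'
#' Restricts the dispersed-repeat scan to pairs with one copy in each
#' window, both forward and inverted, at the screening parameters used for
#' junction analysis (minimum 16 bp, 10% mismatch).
#'
#' @param record a [plastome_record()].
#' @param window1,window2 [interval()]s (clamped to the genome).
#' @param min_len,mismatch_frac scan parameters.
#' @return The [scan_short_repeats()] hit `data.frame`.
#' @export
find_mediating_repeats <- function(record, window1, window2, min_len = 16L,
                                   mismatch_frac = 0.10) {
  L <- record$length
  clamp <- function(w) interval(max(1L, w$start), min(L, w$end))
  scan_short_repeats(record, windows = list(clamp(window1), clamp(window2)),
                     min_len = min_len, mismatch_frac = mismatch_frac)
}

#' Locate the origin of a sequence segment in a reference plastome
#'
#' Smith--Waterman local alignment (match +1, mismatch -1, gap open -2,
#' gap extend -1) of the segment against both strands of the reference;
#' returns the top-scoring placement together with the feature context at
#' that placement (a gene name, or `"geneLeft-geneRight spacer"` for an
#' intergenic placement, in reference gene order).
#'
#' @param segment nucleotide string (>= 16 bp).
#' @param reference a [plastome_record()].
#' @param min_identity minimum identity of the winning alignment; below it
#'   the result is unplaced.
#' @param min_cols_frac minimum fraction of the segment that must be
#'   covered by the alignment (guards against spurious micro-alignments of
#'   unrelated segments).
#' @return A `segment_placement`: `placed`, `interval` (reference
#'   coordinates), `strand`, `identity`, `aligned_columns`, `context`.
#' @export
map_segment_origin <- function(segment, reference, min_identity = 0.8,
                               min_cols_frac = 0.6) {
  segment <- toupper(segment)
  if (nchar(segment) < 16L) stop("segment must be at least 16 bp")
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = FALSE)
  L <- reference$length
  best <- NULL; best_strand <- "+"
  for (strand in c("+", "-")) {
    subj <- if (strand == "+") reference$seq else reverse_complement(reference$seq)
    pa <- Biostrings::pairwiseAlignment(segment, subj, type = "local",
                                        substitutionMatrix = sm,
                                        gapOpening = 1, gapExtension = 1)
    if (is.null(best) || Biostrings::score(pa) > Biostrings::score(best)) {
      best <- pa; best_strand <- strand
    }
  }
  sr <- methods::slot(methods::slot(best, "subject"), "range")
  identity <- Biostrings::pid(best) / 100
  ncols <- Biostrings::nchar(best)
  if (length(IRanges::start(sr)) == 0L || identity < min_identity ||
      ncols < min_cols_frac * nchar(segment)) {
    return(structure(list(placed = FALSE), class = "segment_placement"))
  }
  s <- IRanges::start(sr); e <- IRanges::end(sr)
  if (best_strand == "-") { tmp <- s; s <- L - e + 1L; e <- L - tmp + 1L }
  iv <- interval(s, e)
  structure(list(placed = TRUE, interval = iv, strand = best_strand,
                 identity = identity, aligned_columns = ncols,
                 context = feature_context(reference, iv)),
            class = "segment_placement")
}

# gene or intergenic-spacer label at an interval of a reference record
feature_context <- function(reference, iv) {
  L <- reference$length
  mid <- circ_pos(iv$start + (interval_length(iv, L) %/% 2L), L)
  for (f in reference$features) {
    if (interval_contains(feature_span(f, L), mid, L))
      return(paste0(if (f$pseudo_flag) "ψ" else "", f$name))
  }
  if (length(reference$features) == 0L) return("intergenic")
  spans <- lapply(reference$features, feature_span, L = L)
  d_before <- vapply(spans, function(sp) (mid - sp$end) %% L, 0)
  d_after <- vapply(spans, function(sp) (sp$start - mid) %% L, 0)
  left <- reference$features[[which.min(d_before)]]
  right <- reference$features[[which.min(d_after)]]
  sprintf("%s-%s spacer", left$name, right$name)
}

#' @export
print.segment_placement <- function(x, ...) {
  if (!x$placed) cat("unplaced segment\n")
  else cat(sprintf("placed at %d..%d (%s), identity %.3f, context %s\n",
                   x$interval$start, x$interval$end, x$strand, x$identity,
                   x$context))
  invisible(x)
}

#' Reconstruct IR-expansion events of a target plastome against a reference
#'
#' Compares the IRa of the target with that of an ancestral-like reference:
#' the portion of the target IRa (at the J_SA end) absent from the
#' reference IR is the incorporated sequence. It is segmented into maximal
#' collinear blocks by exact anchored matching against the reference
#' genome; each block is one expansion event, ordered 5' to 3' along IRa
#' (most recent first). An event is labelled `repeat_mediated` when at
#' least one qualifying short repeat (16 bp / 10%) spans windows of 500 bp
#' around its outer and inner junction positions, and `dsb_or_other`
#' otherwise.
#'
#' @param target_record,target_map the expanded plastome and its map.
#' @param ref_record,ref_map the reference plastome and its map.
#' @param window window half-width for mediating-repeat screening (bp).
#' @return List of `expansion_event`s: `segment` (target canonical
#'   coordinates), `size`, `mapped`, `ref_interval`, `strand`,
#'   `genes_incorporated`, `mechanism_hypothesis`, `mediating_repeats`.
#' @export
diff_junctions <- function(target_record, target_map, ref_record, ref_map,
                           window = 500L) {
  stopifnot(target_map$found, ref_map$found)
  tc <- canonicalize_plastome(target_record, target_map)
  rc <- canonicalize_plastome(ref_record, ref_map)
  t_ira <- interval_seq(tc, target_map$ira)
  r_ira <- interval_seq(rc, ref_map$ira)
  # the IR grows at its J_SA (5') end; the J_LA end is stable, so the
  # shared part is the longest common suffix
  ta <- charToRaw(t_ira); ra <- charToRaw(r_ira)
  nmax <- min(length(ta), length(ra))
  if (nmax == 0L) return(list())
  eq <- rev(ta)[seq_len(nmax)] == rev(ra)[seq_len(nmax)]
  common <- if (all(eq)) nmax else which(!eq)[1] - 1L
  extra_len <- length(ta) - common
  if (extra_len <= 0L) return(list())
  extra <- substring(t_ira, 1L, extra_len)
  jsa <- target_map$junctions[["J_SA"]]

  refs <- list("+" = Biostrings::DNAString(rc$seq),
               "-" = Biostrings::DNAString(reverse_complement(rc$seq)))
  refraw <- list("+" = charToRaw(rc$seq),
                 "-" = charToRaw(reverse_complement(rc$seq)))
  Lr <- rc$length
  xraw <- charToRaw(extra)

  blocks <- list()
  pos <- 1L
  pending_unmapped <- 0L
  flush_unmapped <- function(upto) {
    if (pending_unmapped > 0L) {
      blocks[[length(blocks) + 1L]] <<- list(pos = upto - pending_unmapped,
                                             len = pending_unmapped,
                                             mapped = FALSE)
      pending_unmapped <<- 0L
    }
  }
  anchor_k <- 20L
  while (pos <= extra_len) {
    alen <- min(anchor_k, extra_len - pos + 1L)
    anchor <- substring(extra, pos, pos + alen - 1L)
    hit <- NULL
    for (strand in c("+", "-")) {
      m <- Biostrings::matchPattern(anchor, refs[[strand]])
      if (length(m) > 0L) { hit <- list(strand = strand, at = IRanges::start(m)[1]); break }
    }
    if (is.null(hit) || alen < min(anchor_k, 8L)) {
      pending_unmapped <- pending_unmapped + 1L
      pos <- pos + 1L
      next
    }
    flush_unmapped(pos)
    # extend the exact match rightwards
    blen <- alen
    g <- refraw[[hit$strand]]
    while (pos + blen <= extra_len && hit$at + blen <= Lr &&
           xraw[pos + blen] == g[hit$at + blen] &&
           xraw[pos + blen] != .raw_N) blen <- blen + 1L
    ref_local <- c(hit$at, hit$at + blen - 1L)
    ref_iv <- if (hit$strand == "+") interval(ref_local[1], ref_local[2])
              else interval(Lr - ref_local[2] + 1L, Lr - ref_local[1] + 1L)
    blocks[[length(blocks) + 1L]] <- list(pos = pos, len = blen, mapped = TRUE,
                                          strand = hit$strand, ref_iv = ref_iv)
    pos <- pos + blen
  }
  flush_unmapped(pos)

  lapply(blocks, function(bk) {
    seg <- interval(jsa + bk$pos - 1L, jsa + bk$pos + bk$len - 2L)
    genes <- character(0)
    if (bk$mapped) {
      for (f in rc$features) {
        if (feature_bp_in(f, bk$ref_iv, Lr) > 0L)
          genes <- c(genes, paste0(if (f$pseudo_flag) "ψ" else "", f$name))
      }
    }
    outer_j <- jsa + bk$pos - 1L
    inner_j <- jsa + bk$pos + bk$len - 1L
    reps <- find_mediating_repeats(tc,
                                   interval(max(1L, outer_j - window),
                                            min(tc$length, outer_j + window)),
                                   interval(max(1L, inner_j - window),
                                            min(tc$length, inner_j + window)))
    structure(list(segment = seg, size = bk$len, mapped = bk$mapped,
                   ref_interval = if (bk$mapped) bk$ref_iv else NULL,
                   strand = if (bk$mapped) bk$strand else NA_character_,
                   genes_incorporated = unique(genes),
                   mechanism_hypothesis = if (nrow(reps) > 0L) "repeat_mediated"
                                          else "dsb_or_other",
                   mediating_repeats = reps),
              class = "expansion_event")
  })
}

#' @export
print.expansion_event <- function(x, ...) {
  cat(sprintf("expansion event: %d bp at %d..%d, %s, genes [%s], %s\n",
              x$size, x$segment$start, x$segment$end,
              if (x$mapped) "mapped" else "unmapped (no reference homolog)",
              paste(x$genes_incorporated, collapse = ","),
              x$mechanism_hypothesis))
  invisible(x)
}
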