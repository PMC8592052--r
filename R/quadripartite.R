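#' Detect the inverted repeat and partition a plastome into LSC/IRb/SSC/IRa
#'
#' Finds the longest pair of disjoint exact inverted repeats of length at
#' least `min_ir_len` (seed-and-extend over shared k-mers between the
#' sequence and its reverse complement, then maximal extension along the
#' anti-diagonal), labels the two single-copy gaps LSC (longer) and SSC
#' (shorter), and fixes a canonical orientation in which traversal order is
#' LSC, IRb, SSC, IRa; when a *ycf1* annotation is present the frame is
#' chosen so that its 5' end lies in IRa.
#'
#' Junctions are reported as the IR-side base adjacent to each single-copy
#' region: `J_LB` = first base of IRb, `J_SB` = last base of IRb, `J_SA` =
#' first base of IRa, `J_LA` = last base of IRa (all in canonical
#' coordinates).
#'
#' @param record a circular [plastome_record()].
#' @param min_ir_len minimum IR length to report (default 1,000 bp: well
#'   below the 26--33 kb IRs of photosynthetic angiosperms, above incidental
#'   repeats).
#' @param k seed k-mer size (default 21).
#' @return A `quadripartite_map`: either `found = FALSE` (no qualifying IR)
#'   or region intervals in canonical coordinates, the four junction
#'   positions, region lengths, the `frame` (flip/rotation) taking the input
#'   record to canonical orientation, and the region intervals mapped back
#'   to the input coordinates (`regions_original`).
#' @export
detect_quadripartite <- function(record, min_ir_len = 1000L, k = 21L) {
  stopifnot(inherits(record, "plastome_record"))
  if (!record$circular) stop("detect_quadripartite requires a circular record")
  L <- record$length
  no_ir <- structure(list(found = FALSE, record_id = record$id,
                          genome_length = L, min_ir_len = min_ir_len),
                     class = "quadripartite_map")
  if (L < 2L * k || min_ir_len < k) return(no_ir)

  sraw <- charToRaw(record$seq)
  craw <- comp_raw(sraw)
  s2 <- paste0(record$seq, record$seq)
  km <- substring(s2, 1:L, (1:L) + k - 1L)
  rckm <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(km)))

  m1 <- match(rckm, km)   # for each reverse-complement k-mer, a forward hit
  q1 <- which(!is.na(m1)); i1 <- m1[q1]
  m2 <- match(km, rckm)   # and the converse
  i2 <- which(!is.na(m2)); q2 <- m2[i2]
  diags <- c((i1 + q1 + k - 1L) %% L, (i2 + q2 + k - 1L) %% L)
  if (length(diags) == 0L) return(no_ir)
  tab <- sort(table(diags), decreasing = TRUE)
  cand <- utils::head(as.integer(names(tab)), 200L)
  # seeded anti-diagonals are the candidates; strongest first
  best <- NULL; tie <- FALSE
  for (C0 in cand) {
    t <- seq_len(L)
    p <- ((C0 - t - 1L) %% L) + 1L
    m <- (sraw == craw[p]) & (sraw != .raw_N)
    if (!any(m)) next
    r <- rle(c(m, m))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- r$values & starts <= L
    for (idx in which(ok)) {
      len <- min(r$lengths[idx], L)
      a1 <- starts[idx]
      if (len < min_ir_len) next             # sub-threshold chance runs
      if (a1 == 1L && m[L] && len < L) next  # continuation of a wrapped run
      e1 <- a1 + len - 1L
      # mirror arc start (position pairing t <-> p(t) reverses orientation)
      a2 <- ((C0 - e1 - 1L) %% L) + 1L
      if (a2 == circ_pos(a1, L)) {
        # self-mirror (palindromic) run: take disjoint halves
        half <- len %/% 2L
        if (half < 1L) next
        len <- half
        e1 <- a1 + len - 1L
        a2 <- ((C0 - e1 - 1L) %% L) + 1L
      } else {
        # process each unordered pair once
        if (circ_pos(a2, L) < circ_pos(a1, L)) next
      }
      if (len < min_ir_len) next             # palindromic half fell below
      cnd <- list(len = len, a1 = circ_pos(a1, L), a2 = circ_pos(a2, L))
      if (is.null(best) || cnd$len > best$len ||
          (cnd$len == best$len && cnd$a1 < best$a1)) {
        if (!is.null(best) && cnd$len == best$len &&
            !(cnd$a1 == best$a1 && cnd$a2 == best$a2)) tie <- TRUE
        best <- cnd
      } else if (cnd$len == best$len &&
                 !(cnd$a1 == best$a1 && cnd$a2 == best$a2)) tie <- TRUE
    }
  }
  if (is.null(best) || best$len < min_ir_len) return(no_ir)
  if (tie)
    warning("multiple maximal inverted-repeat pairs of equal length; ",
            "keeping the pair with the smallest start coordinate")

  ir <- best$len
  e1 <- circ_pos(best$a1 + ir - 1L, L)
  e2 <- circ_pos(best$a2 + ir - 1L, L)
  g1 <- (best$a2 - e1 - 1L) %% L   # gap after copy1
  g2 <- (best$a1 - e2 - 1L) %% L   # gap after copy2
  stopifnot(g1 + g2 + 2L * ir == L)
  if (g1 >= g2) {
    lsc_len <- g1; ssc_len <- g2
    lsc_start <- circ_pos(e1 + 1L, L)   # LSC runs e1+1 .. a2-1
  } else {
    lsc_len <- g2; ssc_len <- g1
    lsc_start <- circ_pos(e2 + 1L, L)
  }

  frame_unflipped <- list(flip = FALSE, offset = (lsc_start - 1L) %% L)
  # flipped frame: LSC end position maps to L - end + 1 in flipped coords
  lsc_end <- circ_pos(lsc_start + lsc_len - 1L, L)
  frame_flipped <- list(flip = TRUE, offset = (L - lsc_end) %% L)

  frame <- frame_unflipped
  ycf <- Filter(function(f) tolower(f$name) == "ycf1" && !f$pseudo_flag,
                record$features)
  if (length(ycf) == 0L)
    ycf <- Filter(function(f) tolower(f$name) == "ycf1", record$features)
  if (length(ycf) > 0L) {
    f <- ycf[[1]]
    fe5 <- if (f$strand == "+") f$exons[[1]]$start
           else f$exons[[length(f$exons)]]$end
    ira_lo <- lsc_len + ir + ssc_len + 1L
    in_ira <- function(fr) {
      p <- fe5
      if (fr$flip) p <- L - p + 1L
      p <- circ_pos(p - fr$offset, L)
      p >= ira_lo
    }
    if (!in_ira(frame_unflipped) && in_ira(frame_flipped)) frame <- frame_flipped
  }

  lsc_iv <- interval(1L, lsc_len)
  irb_iv <- interval(lsc_len + 1L, lsc_len + ir)
  ssc_iv <- interval(lsc_len + ir + 1L, lsc_len + ir + ssc_len)
  ira_iv <- interval(lsc_len + ir + ssc_len + 1L, L)
  regions <- list(lsc = lsc_iv, irb = irb_iv, ssc = ssc_iv, ira = ira_iv)
  structure(list(
    found = TRUE, record_id = record$id, genome_length = L,
    frame = frame,
    lsc = lsc_iv, irb = irb_iv, ssc = ssc_iv, ira = ira_iv,
    junctions = c(J_LB = lsc_len + 1L, J_SB = lsc_len + ir,
                  J_SA = lsc_len + ir + ssc_len + 1L, J_LA = L),
    lsc_len = lsc_len, ssc_len = ssc_len, ir_len = ir,
    regions_original = lapply(regions, canonical_to_original, frame = frame, L = L),
    min_ir_len = min_ir_len, k = k, tie = tie
  ), class = "quadripartite_map")
}

#' @export
print.quadripartite_map <- function(x, ...) {
  if (!x$found) {
    cat(sprintf("quadripartite_map '%s': no inverted repeat >= %d bp\n",
                x$record_id, x$min_ir_len))
    return(invisible(x))
  }
  cat(sprintf("quadripartite_map '%s' (%s bp): LSC %s | IR %s | SSC %s\n",
              x$record_id, format(x$genome_length, big.mark = ","),
              format(x$lsc_len, big.mark = ","),
              format(x$ir_len, big.mark = ","),
              format(x$ssc_len, big.mark = ",")))
  invisible(x)
}

# canonical-frame position -> original coordinates
canonical_pos_to_original <- function(p, frame, L) {
  p <- circ_pos(p + frame$offset, L)
  if (frame$flip) p <- L - p + 1L
  p
}

# original position -> canonical coordinates
original_pos_to_canonical <- function(p, frame, L) {
  if (frame$flip) p <- L - p + 1L
  circ_pos(p - frame$offset, L)
}

canonical_to_original <- function(iv, frame, L) {
  s <- canonical_pos_to_original(iv$start, frame, L)
  e <- canonical_pos_to_original(iv$end, frame, L)
  if (frame$flip) { tmp <- s; s <- e; e <- tmp }
  interval(s, e, wraps = e < s)
}

#' Rotate/flip a record into the canonical LSC-IRb-SSC-IRa frame of a map
#'
#' @param record the [plastome_record()] the map was computed from.
#' @param map a found [detect_quadripartite()] result.
#' @return The record re-linearised so position 1 is the first base of the
#'   LSC and *ycf1*'s 5' end (when annotated) lies in IRa.
#' @export
canonicalize_plastome <- function(record, map) {
  stopifnot(map$found)
  out <- record
  if (map$frame$flip) out <- flip_record(out)
  if (map$frame$offset != 0L) out <- rotate_record(out, map$frame$offset)
  out
}

#' Profile the four IR junctions of a partitioned plastome
#'
#' For each junction, identifies the annotated gene spanning it (if any) and
#' decomposes that gene's spliced length into the part inside the IR and the
#' part inside the adjacent single-copy region; also lists the genes lying
#' wholly inside the IR copy, ordered by distance from the junction.
#'
#' @param map a found [detect_quadripartite()] result.
#' @param record the [plastome_record()] the map was computed from.
#' @return Named list of four `junction_profile`s (`J_LB`, `J_SB`, `J_SA`,
#'   `J_LA`), each with `overlapping_gene`, `bp_in_ir`, `bp_in_sc` and
#'   `genes_fully_in_ir_adjacent` (pseudogenes are ψ-prefixed).
#' @export
junction_profiles <- function(map, record) {
  stopifnot(inherits(map, "quadripartite_map"))
  if (!map$found) stop("cannot profile junctions: no IR was found")
  canon <- canonicalize_plastome(record, map)
  L <- canon$length
  spec <- list(
    J_LB = list(ir = map$irb, sc = map$lsc, at = map$junctions[["J_LB"]]),
    J_SB = list(ir = map$irb, sc = map$ssc, at = map$junctions[["J_SB"]]),
    J_SA = list(ir = map$ira, sc = map$ssc, at = map$junctions[["J_SA"]]),
    J_LA = list(ir = map$ira, sc = map$lsc, at = map$junctions[["J_LA"]])
  )
  out <- lapply(names(spec), function(jn) {
    sp <- spec[[jn]]
    span_gene <- NULL; best_bp <- 0L
    fully <- list()
    for (f in canon$features) {
      in_ir <- feature_bp_in(f, sp$ir, L)
      in_sc <- feature_bp_in(f, sp$sc, L)
      flen <- feature_length(f, L)
      if (in_ir > 0L && in_sc > 0L && in_ir + in_sc >= best_bp) {
        # gene crosses this junction (contiguous arc crossing the boundary)
        sp_iv <- feature_span(f, L)
        if (interval_contains(sp_iv, sp$at, L) &&
            interval_contains(sp_iv, circ_pos(sp$at + if (jn %in% c("J_LB", "J_SA")) -1L else 1L, L), L)) {
          span_gene <- f; best_bp <- in_ir + in_sc
        }
      }
      if (in_ir == flen) fully[[length(fully) + 1L]] <- f
    }
    dist_from <- function(f) {
      sv <- feature_span(f, L)
      if (jn %in% c("J_LB", "J_SA"))   # junction at IR start
        (sv$start - sp$at) %% L
      else                             # junction at IR end
        (sp$at - sv$end) %% L
    }
    if (length(fully) > 0L) {
      ord <- order(vapply(fully, dist_from, 0))
      fully <- fully[ord]
    }
    labels <- vapply(fully, function(f)
      paste0(if (f$pseudo_flag) "ψ" else "", f$name), "")
    structure(list(
      junction = jn,
      overlapping_gene = if (is.null(span_gene)) NA_character_ else span_gene$name,
      gene_pseudo = if (is.null(span_gene)) NA else span_gene$pseudo_flag,
      gene_length = if (is.null(span_gene)) NA_integer_ else feature_length(span_gene, L),
      bp_in_ir = if (is.null(span_gene)) 0L else feature_bp_in(span_gene, sp$ir, L),
      bp_in_sc = if (is.null(span_gene)) 0L else feature_bp_in(span_gene, sp$sc, L),
      genes_fully_in_ir_adjacent = labels
    ), class = "junction_profile")
  })
  names(out) <- names(spec)
  out
}

#' @export
print.junction_profile <- function(x, ...) {
  if (is.na(x$overlapping_gene)) {
    cat(sprintf("%s: no spanning gene\n", x$junction))
  } else {
    cat(sprintf("%s: %s (%d bp in IR / %d bp in SC)\n", x$junction,
                x$overlapping_gene, x$bp_in_ir, x$bp_in_sc))
  }
  invisible(x)
}
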