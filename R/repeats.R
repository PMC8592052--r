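#' Mismatch count between two repeat copies
#'
#' Hamming distance between equal-length sequences; for `direction =
#' "inverted"` the second sequence is reverse-complemented first. `N` never
#' matches anything (including another `N`).
#'
#' @param seq1,seq2 equal-length nucleotide strings.
#' @param direction `"forward"` or `"inverted"`.
#' @return Integer mismatch count.
#' @export
compare_pair <- function(seq1, seq2, direction = c("forward", "inverted")) {
  direction <- match.arg(direction)
  seq1 <- toupper(seq1); seq2 <- toupper(seq2)
  if (nchar(seq1) != nchar(seq2)) stop("sequences must have equal length")
  if (direction == "inverted") seq2 <- reverse_complement(seq2)
  a <- charToRaw(seq1); b <- charToRaw(seq2)
  sum(a != b | a == .raw_N | b == .raw_N)
}

# --- maximal mismatch-budget window enumeration ------------------------------
#
# Along one (anti-)diagonal, positions lo..hi carry a logical match vector.
# A reported window [a,b] must satisfy: b-a+1 >= min_len, mismatches <=
# floor(frac * len), and be non-extendable by one position on either side
# (extension is blocked by the segment edge or because it would exceed the
# budget at the grown length). Since extending over a *matching* base never
# violates the budget, every maximal window abuts a mismatch (or the edge)
# on both sides; enumeration therefore runs over mismatch boundaries.
enumerate_budget_windows <- function(mvec, lo, min_len, frac) {
  n <- length(mvec)
  if (n < min_len) return(NULL)
  mis <- which(!mvec)
  B0 <- c(0L, mis, n + 1L)            # boundary positions (local coords)
  K <- length(B0)
  gaps <- diff(B0) - 1L
  mg <- max(gaps)
  if (mg == 0L) return(NULL)
  A <- frac * (mg + 1)
  g_cap <- if (A < 1) floor(frac * mg / (1 - A)) else floor(frac * n)
  g_cap <- min(g_cap, floor(frac * n), K - 2L)
  out <- vector("list", g_cap + 1L)
  for (g in 0:g_cap) {
    ii <- seq_len(K - g - 1L)
    a <- B0[ii] + 1L
    b <- B0[ii + g + 1L] - 1L
    len <- b - a + 1L
    keep <- len >= min_len & g <= floor(frac * len)
    if (!any(keep)) next
    a <- a[keep]; b <- b[keep]; len <- len[keep]
    left_blocked <- a == 1L | (g + 1L) > floor(frac * (len + 1))
    right_blocked <- b == n | (g + 1L) > floor(frac * (len + 1))
    keep2 <- left_blocked & right_blocked
    if (!any(keep2)) next
    out[[g + 1L]] <- data.frame(a = a[keep2] + lo - 1L, b = b[keep2] + lo - 1L,
                                mismatches = g)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

# contiguous TRUE-segments of a logical vector, as (start, end) pairs
true_segments <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(starts[r$values], ends[r$values])
}

#' Scan for dispersed (forward and inverted) repeats with a mismatch budget
#'
#' Reports all maximal ungapped repeat pairs of length at least `min_len`
#' whose Hamming mismatch count does not exceed `floor(mismatch_frac *
#' length)` (the budget that accepts 1 mismatch at 17--18 bp and rejects 2
#' at 17 bp). Maximal means extension by one base on either side would
#' exceed the budget at the grown length or leave the search windows.
#' Self-pairs and fully-overlapping placements are excluded; each unordered
#' pair is reported once with `start1 < start2`. `N` never matches.
#'
#' @param record a [plastome_record()] (or plain character sequence).
#' @param windows `NULL` (whole genome), one [interval()], or a list of two
#'   intervals, in which case only pairs with one copy in each window are
#'   reported.
#' @param min_len minimum repeat length (default 16 bp).
#' @param mismatch_frac allowed mismatch fraction (default 0.10).
#' @param directions subset of `c("forward", "inverted")`.
#' @return `data.frame` with columns `seq1, seq2, direction, length, start1,
#'   end1, start2, end2, mismatches`, ordered by position.
#' @export
scan_short_repeats <- function(record, windows = NULL, min_len = 16L,
                               mismatch_frac = 0.10,
                               directions = c("forward", "inverted")) {
  stopifnot(min_len >= 8L)
  seq <- if (inherits(record, "plastome_record")) record$seq else toupper(record)
  x <- charToRaw(seq)
  cx <- comp_raw(x)
  L <- length(x)
  if (is.null(windows)) windows <- list(interval(1L, L))
  if (inherits(windows, "pp_interval")) windows <- list(windows)
  stopifnot(length(windows) %in% 1:2)
  for (w in windows) if (w$wraps) stop("scan windows must not wrap the origin")
  w1 <- windows[[1]]
  w2 <- if (length(windows) == 2L) windows[[2]] else windows[[1]]
  has_N <- any(x == .raw_N)
  # merge one or two [lo,hi] candidate ranges into disjoint valid segments
  merge_ranges <- function(r1, r2) {
    rs <- Filter(function(r) r[2] >= r[1], list(r1, r2))
    if (length(rs) == 0L) return(NULL)
    if (length(rs) == 1L) return(rs)
    rs <- rs[order(vapply(rs, `[`, 0, 1L))]
    if (rs[[2]][1] <= rs[[1]][2] + 1L)
      return(list(c(rs[[1]][1], max(rs[[1]][2], rs[[2]][2]))))
    rs
  }

  hits <- list()
  add_hits <- function(df, s2start, direction, diag_id) {
    # df columns a,b in copy-1 coordinates
    if (is.null(df) || nrow(df) == 0L) return()
    for (r in seq_len(nrow(df))) {
      a <- df$a[r]; b <- df$b[r]
      if (direction == "forward") {
        p2s <- a + diag_id; p2e <- b + diag_id
      } else {
        p2s <- diag_id - b; p2e <- diag_id - a
      }
      if (p2s == a && p2e == b) next               # fully-overlapping placement
      if (p2s < a || (p2s == a && p2e < b)) next   # canonical orientation only
      hits[[length(hits) + 1L]] <<- data.frame(
        seq1 = substring(seq, a, b), seq2 = substring(seq, p2s, p2e),
        direction = direction, length = b - a + 1L,
        start1 = a, end1 = b, start2 = p2s, end2 = p2e,
        mismatches = df$mismatches[r], stringsAsFactors = FALSE)
    }
  }

  if ("forward" %in% directions) {
    rng <- function(lo, hi) if (hi >= lo) lo:hi else integer(0)
    ds <- sort(unique(c(rng(max(1L, w2$start - w1$end), w2$end - w1$start),
                        rng(max(1L, w1$start - w2$end), w1$end - w2$start))))
    ds <- ds[ds >= 1L & ds <= L - min_len]
    for (d in ds) {
      segs <- merge_ranges(c(max(w1$start, w2$start - d, 1L),
                             min(w1$end, w2$end - d, L - d)),
                           c(max(w2$start, w1$start - d, 1L),
                             min(w2$end, w1$end - d, L - d)))
      for (sg in segs) {
        a <- sg[1]; b <- sg[2]
        if (b - a + 1L < min_len) next
        t <- a:b
        m <- x[t] == x[t + d]
        if (has_N) m <- m & x[t] != .raw_N & x[t + d] != .raw_N
        df <- enumerate_budget_windows(m, a, min_len, mismatch_frac)
        add_hits(df, NULL, "forward", d)
      }
    }
  }

  if ("inverted" %in% directions) {
    cs <- (w1$start + w2$start):(w1$end + w2$end)
    for (cc in cs) {
      segs <- merge_ranges(c(max(w1$start, cc - w2$end, cc - L, 1L),
                             min(w1$end, cc - w2$start, cc - 1L, L)),
                           c(max(w2$start, cc - w1$end, cc - L, 1L),
                             min(w2$end, cc - w1$start, cc - 1L, L)))
      for (sg in segs) {
        a <- sg[1]; b <- sg[2]
        if (b - a + 1L < min_len) next
        t <- a:b
        m <- x[t] == cx[cc - t]
        if (has_N) m <- m & x[t] != .raw_N & x[cc - t] != .raw_N
        df <- enumerate_budget_windows(m, a, min_len, mismatch_frac)
        add_hits(df, NULL, "inverted", cc)
      }
    }
  }

  if (length(hits) == 0L) {
    return(data.frame(seq1 = character(), seq2 = character(),
                      direction = character(), length = integer(),
                      start1 = integer(), end1 = integer(),
                      start2 = integer(), end2 = integer(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- unique(out)
  out[order(out$start1, out$start2, out$direction), , drop = FALSE]
}

#' Perfect tandem repeat detection
#'
#' Finds maximal perfectly periodic arrays with primitive units between
#' `unit_min` and `unit_max` bp and at least `min_copies` full copies.
#' Hidden-repeat removal discards any array whose span lies within another
#' reported array's span (at equal span the smaller unit is preferred).
#'
#' @param record a [plastome_record()] or character sequence.
#' @param unit_min,unit_max unit length bounds (defaults 2 and 1,000 bp).
#' @param min_copies minimum number of full copies (default 2).
#' @return List with `repeats` (`data.frame`: `unit, unit_len, copies, start,
#'   end, total_len`) and `summary` (`count`, `total_bp`,
#'   `percent_of_genome`).
#' @export
scan_tandem_repeats <- function(record, unit_min = 2L, unit_max = 1000L,
                                min_copies = 2L) {
  seq <- if (inherits(record, "plastome_record")) record$seq else toupper(record)
  x <- charToRaw(seq)
  L <- length(x)
  okbase <- x != .raw_N
  res <- list()
  u_hi <- min(unit_max, L %/% min_copies)
  for (u in seq(from = max(2L, unit_min), length.out = max(0L, u_hi - max(2L, unit_min) + 1L))) {
    t_idx <- seq_len(L - u)
    m <- (x[t_idx] == x[t_idx + u]) & okbase[t_idx] & okbase[t_idx + u]
    segs <- true_segments(m)
    if (is.null(dim(segs)) || nrow(segs) == 0L) next
    run_len <- segs[, 2] - segs[, 1] + 1L
    keep <- run_len >= u * (min_copies - 1L)
    if (!any(keep)) next
    for (sg in which(keep)) {
      a <- segs[sg, 1]
      b <- segs[sg, 2] + u          # periodic region
      unit <- substring(seq, a, a + u - 1L)
      if (!is_primitive_unit(unit)) next
      res[[length(res) + 1L]] <- data.frame(
        unit = unit, unit_len = u,
        copies = (b - a + 1L) %/% u,
        start = a, end = b, total_len = b - a + 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0L) {
    reps <- data.frame(unit = character(), unit_len = integer(),
                       copies = integer(), start = integer(), end = integer(),
                       total_len = integer(), stringsAsFactors = FALSE)
  } else {
    reps <- do.call(rbind, res)
    # hidden-repeat removal: sweep spans sorted by start asc, end desc,
    # unit asc; anything not reaching past the running furthest end is
    # contained in an earlier (kept or larger) span
    reps <- reps[order(reps$start, -reps$end, reps$unit_len), , drop = FALSE]
    max_end <- -1L
    keep <- logical(nrow(reps))
    for (i in seq_len(nrow(reps))) {
      if (reps$end[i] > max_end) {
        keep[i] <- TRUE
        max_end <- reps$end[i]
      }
    }
    reps <- reps[keep, , drop = FALSE]
    rownames(reps) <- NULL
  }
  list(repeats = reps,
       summary = list(count = nrow(reps),
                      total_bp = sum(reps$total_len),
                      percent_of_genome = 100 * sum(reps$total_len) / L))
}

# a unit is primitive when it is not a whole-number repetition of a shorter unit
is_primitive_unit <- function(unit) {
  u <- nchar(unit)
  if (u <= 1L) return(TRUE)
  for (p in seq_len(u %/% 2L)) {
    if (u %% p == 0L && unit == strrep(substring(unit, 1L, p), u %/% p))
      return(FALSE)
  }
  TRUE
}
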