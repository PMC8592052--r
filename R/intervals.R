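#' 1-based inclusive genomic interval, optionally wrapping the origin
#'
#' All user-facing coordinates in plastopart are 1-based and inclusive.
#' On circular genomes an interval may wrap the origin, in which case
#' `start > end` and `wraps = TRUE`; it then covers `start..L` followed by
#' `1..end` for a genome of length `L`.
#'
#' @param start,end 1-based inclusive endpoints.
#' @param wraps logical; does the interval cross the origin?
#' @return An object of class `pp_interval`.
#' @export
interval <- function(start, end, wraps = FALSE) {
  stopifnot(length(start) == 1L, length(end) == 1L,
            is.finite(start), is.finite(end), start >= 1, end >= 1)
  if (!wraps && end < start)
    stop("interval end < start for a non-wrapping interval")
  structure(list(start = as.integer(start), end = as.integer(end),
                 wraps = isTRUE(wraps)),
            class = "pp_interval")
}

#' @export
print.pp_interval <- function(x, ...) {
  cat(sprintf("[%d..%d]%s\n", x$start, x$end, if (x$wraps) " (wraps origin)" else ""))
  invisible(x)
}

#' Length in bp of an interval on a genome of length L
#'
#' @param iv a [interval()].
#' @param L genome length (required when `iv$wraps`).
#' @export
interval_length <- function(iv, L = NULL) {
  if (iv$wraps) {
    if (is.null(L)) stop("genome length L required for a wrapping interval")
    (L - iv$start + 1L) + iv$end
  } else {
    iv$end - iv$start + 1L
  }
}

# map any integer position onto 1..L circularly
circ_pos <- function(p, L) ((p - 1L) %% L) + 1L

# split an interval into 1 or 2 linear (non-wrapping) pieces
linear_pieces <- function(iv, L) {
  if (!iv$wraps) return(list(c(iv$start, iv$end)))
  list(c(iv$start, L), c(1L, iv$end))
}

# bp of overlap between two intervals on a circle of length L
interval_intersect_len <- function(a, b, L) {
  pa <- linear_pieces(a, L); pb <- linear_pieces(b, L)
  tot <- 0L
  for (x in pa) for (y in pb) {
    lo <- max(x[1], y[1]); hi <- min(x[2], y[2])
    if (hi >= lo) tot <- tot + (hi - lo + 1L)
  }
  tot
}

# does interval contain position p?
interval_contains <- function(iv, p, L) {
  interval_intersect_len(iv, interval(p, p), L) > 0L
}

# all positions covered by an interval (small intervals only)
interval_positions <- function(iv, L) {
  if (!iv$wraps) return(iv$start:iv$end)
  c(iv$start:L, seq_len(iv$end))
}
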