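# Independent oracles used by the test suite. These deliberately use
# different algorithmic routes from the package implementation: direct
# per-window checks instead of boundary enumeration, an explicit all-pairs
# extension scan instead of k-mer seeding, and a hand-written codon table
# instead of Biostrings.

oracle_comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

oracle_revcomp <- function(s) {
  paste(rev(oracle_comp[strsplit(toupper(s), "")[[1]]]), collapse = "")
}

# hand-written plastid/bacterial codon table (table 11 shares all codon
# translations with the standard table; they differ only in permitted
# initiators, which translation itself does not use)
oracle_codon_table <- local({
  b <- c("T", "C", "A", "G")
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",   # TTT..TGG
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  nm <- character(64)
  k <- 0
  for (b1 in b) for (b2 in b) for (b3 in b) { k <- k + 1; nm[k] <- paste0(b1, b2, b3) }
  names(aa) <- nm
  aa
})

oracle_translate <- function(seq, codon_start = 1) {
  seq <- toupper(seq)
  seq <- substring(seq, codon_start)
  n <- nchar(seq) %/% 3
  if (n == 0) return("")
  out <- character(n)
  for (i in seq_len(n)) {
    cod <- substring(seq, 3 * i - 2, 3 * i)
    out[i] <- if (grepl("N", cod)) "X" else oracle_codon_table[[cod]]
  }
  paste(out, collapse = "")
}

# direct check of every candidate window on every diagonal (both
# directions), using the same reported semantics as the scanner:
# len >= min_len, mismatches <= floor(frac*len), non-extendable by one
# position within the sequence, each unordered pair once, no
# fully-overlapping placements, N never matches
oracle_scan_repeats <- function(seq, min_len = 16, frac = 0.10) {
  s <- strsplit(toupper(seq), "")[[1]]
  L <- length(s)
  match_fwd <- function(i, j) s[i] == s[j] && s[i] != "N"
  match_inv <- function(i, j) s[i] == oracle_comp[[s[j]]] && s[i] != "N" && s[j] != "N"
  hits <- list()
  budget <- function(len) floor(frac * len)
  # for one diagonal's local match vector mv (local coords 1..n mapping to
  # genome positions off+0..), check every window of every start directly
  scan_diag <- function(mv, off, direction, pos2) {
    n <- length(mv)
    if (n < min_len) return()
    cs <- c(0, cumsum(!mv))
    for (a in 1:(n - min_len + 1)) {
      b <- (a + min_len - 1):n
      len <- b - a + 1
      mm <- cs[b + 1] - cs[a]
      valid <- mm <= budget(len)
      ext_l <- if (a > 1) (cs[b + 1] - cs[a - 1]) <= budget(len + 1)
               else rep(FALSE, length(b))
      ext_r <- c((cs[b[-length(b)] + 2] - cs[a]) <= budget(len[-length(b)] + 1),
                 FALSE)
      keep <- valid & !ext_l & !ext_r
      for (bb in b[keep]) {
        ga <- off + a - 1; gb <- off + bb - 1
        pp <- pos2(ga, gb)
        if (pp[1] == ga && pp[2] == gb) next
        if (pp[1] < ga || (pp[1] == ga && pp[2] < gb)) next
        hits[[length(hits) + 1]] <<- data.frame(
          seq1 = paste(s[ga:gb], collapse = ""),
          seq2 = paste(s[pp[1]:pp[2]], collapse = ""),
          direction = direction, length = gb - ga + 1,
          start1 = ga, end1 = gb, start2 = pp[1], end2 = pp[2],
          mismatches = cs[bb + 1] - cs[a], stringsAsFactors = FALSE)
      }
    }
  }
  for (d in 1:(L - min_len)) {
    n <- L - d
    mv <- vapply(1:n, function(t) match_fwd(t, t + d), TRUE)
    scan_diag(mv, 1, "forward", function(ga, gb) c(ga + d, gb + d))
  }
  for (cc in 3:(2 * L - 1)) {
    tlo <- max(1, cc - L); thi <- min(L, cc - 1)
    if (thi - tlo + 1 < min_len) next
    mv <- vapply(tlo:thi, function(t) match_inv(t, cc - t), TRUE)
    scan_diag(mv, tlo, "inverted", function(ga, gb) c(cc - gb, cc - ga))
  }
  if (length(hits) == 0) {
    return(data.frame(seq1 = character(), seq2 = character(),
                      direction = character(), length = integer(),
                      start1 = integer(), end1 = integer(),
                      start2 = integer(), end2 = integer(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  }
  out <- unique(do.call(rbind, hits))
  out[order(out$start1, out$start2, out$direction), , drop = FALSE]
}

# brute-force longest disjoint exact inverted repeat on a linear sequence:
# explicit extension from every (start1, end2) anchor pair
oracle_longest_inverted <- function(seq) {
  s <- strsplit(toupper(seq), "")[[1]]
  L <- length(s)
  best <- list(len = 0, a1 = NA, a2 = NA)
  for (i in 1:(L - 1)) {
    for (j in (i + 1):L) {
      if (s[i] != oracle_comp[[s[j]]]) next
      if (i > 1 && j < L && s[i - 1] == oracle_comp[[s[j + 1]]]) next # not maximal
      e <- 0
      while (i + e <= L && j - e >= 1 && s[i + e] == oracle_comp[[s[j - e]]]) e <- e + 1
      # run covers copy1 [i, i+e-1] and copy2 [j-e+1, j]; truncate to keep
      # the copies disjoint
      len <- min(e, (j - i + 1) %/% 2)
      if (len > best$len) best <- list(len = len, a1 = i, a2 = j - len + 1)
    }
  }
  best
}

# simple fixture: a circular toy genome with one planted exact IR pair,
# guard bases blocking chance extension at all four junction flanks
make_toy_ir_genome <- function(seed, L = 1500, ir = 120, lsc = 800) {
  set.seed(seed)
  ssc <- L - lsc - 2 * ir
  stopifnot(ssc > 10)
  bases <- c("A", "C", "G", "T")
  s <- sample(bases, L, replace = TRUE)
  ira <- sample(bases, ir, replace = TRUE)
  irb <- rev(oracle_comp[ira])
  s[(lsc + 1):(lsc + ir)] <- irb
  s[(L - ir + 1):L] <- ira
  # guards: LSC last vs LSC first; SSC first vs SSC last
  if (s[lsc] == oracle_comp[[s[1]]])
    s[lsc] <- setdiff(bases, c(oracle_comp[[s[1]]]))[1]
  sf <- lsc + ir + 1; sl <- lsc + ir + ssc
  if (s[sf] == oracle_comp[[s[sl]]])
    s[sf] <- setdiff(bases, c(oracle_comp[[s[sl]]]))[1]
  list(seq = paste(s, collapse = ""), lsc = lsc, ir = ir, ssc = ssc)
}
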