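test_that("pairwise mismatch counts reproduce the published repeat table", {
  # the three printed junction-repeat pairs
  expect_equal(compare_pair("TCATTATTAGGTTTATA", "TATAAACCCAATAATGA",
                            "inverted"), 1L)
  expect_equal(compare_pair("TCATTATTAGGTTTATA", "TATAAACCCAATAATTA",
                            "inverted"), 2L)
  expect_equal(compare_pair("TTCATTTTTCTCTTCTTT", "TTCATTTTCCTCTTCTTT",
                            "forward"), 1L)
  expect_equal(compare_pair("ACGTACGT", "ACGTACGT", "forward"), 0L)
  expect_error(compare_pair("ACGT", "ACG", "forward"), "equal length")
  # N never matches, not even another N
  expect_equal(compare_pair("ANGT", "ANGT", "forward"), 1L)
})

test_that("the 10% budget accepts 1 mismatch at 17 bp and rejects 2", {
  s1 <- "TCATTATTAGGTTTATA"
  pm <- "TATAAACCCAATAATGA"   # 1 mismatch against s1 (inverted)
  np <- "TATAAACCCAATAATTA"   # 2 mismatches
  set.seed(80)
  spacer <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
                  collapse = "")
  for (case in list(list(copy = pm, hits = 1L), list(copy = np, hits = 0L))) {
    sq <- paste0(s1, spacer, case$copy)
    got <- scan_short_repeats(sq, windows = list(interval(1, 17),
                                                 interval(98, 114)),
                              min_len = 16, mismatch_frac = 0.10)
    expect_equal(nrow(got), case$hits)
    if (case$hits == 1L) {
      expect_equal(got$direction, "inverted")
      expect_equal(got$length, 17L)
      expect_equal(got$mismatches, 1L)
    }
  }
})

test_that("the scanner equals the brute-force all-pairs oracle", {
  set.seed(81)
  bases <- c("A", "C", "G", "T")
  for (s in 1:25) {
    set.seed(s)
    L <- sample(60:150, 1)
    v <- sample(bases, L, replace = TRUE)
    if (s %% 3 == 0) {
      core <- sample(bases, 18, replace = TRUE)
      v[5:22] <- core; v[(L - 25):(L - 8)] <- core
    } else if (s %% 3 == 1) {
      core <- sample(bases, 17, replace = TRUE)
      v[5:21] <- core; v[(L - 24):(L - 8)] <- rev(oracle_comp[core])
    }
    sq <- paste(v, collapse = "")
    imp <- scan_short_repeats(sq)
    ora <- oracle_scan_repeats(sq)
    rownames(imp) <- rownames(ora) <- NULL
    expect_equal(imp, ora, info = sprintf("seed %d", s))
  }
})

test_that("every reported hit re-validates against its own invariants", {
  set.seed(82)
  b <- build_plastome(synth_spec(
    seed = 82,
    planted_dispersed = list(list(direction = "inverted", length = 17L,
                                  mismatches = 1L),
                             list(direction = "forward", length = 18L,
                                  mismatches = 1L))))
  tr <- b$truth$dispersed
  for (i in seq_len(nrow(tr))) {
    got <- scan_short_repeats(
      b$record,
      windows = list(interval(tr$window1_start[i], tr$window1_end[i]),
                     interval(tr$window2_start[i], tr$window2_end[i])))
    expect_equal(nrow(got), 1L)
    expect_equal(got$start1, tr$start1[i])
    expect_equal(got$start2, tr$start2[i])
    expect_equal(got$mismatches, tr$mismatches[i])
    # budget and Hamming re-validation
    expect_lte(got$mismatches, floor(0.10 * got$length))
    expect_equal(compare_pair(got$seq1, got$seq2, got$direction),
                 got$mismatches)
  }
})

test_that("inverted hits are invariant under reverse-complementing the genome", {
  set.seed(83)
  bases <- c("A", "C", "G", "T")
  v <- sample(bases, 300, replace = TRUE)
  core <- sample(bases, 17, replace = TRUE)
  core[9] <- setdiff(bases, core[9])[1]
  v[21:37] <- core
  mut <- core; mut[5] <- setdiff(bases, mut[5])[1]
  v[221:237] <- rev(oracle_comp[mut])
  sq <- paste(v, collapse = "")
  fwd <- scan_short_repeats(sq, directions = "inverted")
  rc <- reverse_complement(sq)
  bwd <- scan_short_repeats(rc, directions = "inverted")
  expect_equal(nrow(fwd), nrow(bwd))
  if (nrow(fwd) > 0) {
    L <- nchar(sq)
    # positions mirror: [s,e] -> [L-e+1, L-s+1], pair order swaps
    expect_setequal(paste(L - bwd$end2 + 1, L - bwd$start2 + 1,
                          L - bwd$end1 + 1, L - bwd$start1 + 1),
                    paste(fwd$start1, fwd$end1, fwd$start2, fwd$end2))
  }
})

test_that("perfect tandem arrays are found with primitive units", {
  got <- scan_tandem_repeats("GGACACACACGG")
  expect_equal(nrow(got$repeats), 1L)
  expect_equal(got$repeats$unit, "AC")
  expect_equal(got$repeats$copies, 4L)
  expect_equal(c(got$repeats$start, got$repeats$end), c(3L, 10L))

  # a trailing partial copy extends the span but not the full-copy count
  got2 <- scan_tandem_repeats("GGACACACAGG")
  expect_equal(got2$repeats$unit, "AC")
  expect_equal(got2$repeats$copies, 3L)
  expect_equal(c(got2$repeats$start, got2$repeats$end), c(3L, 9L))

  # mononucleotide runs are excluded by unit_min = 2 and primitivity
  expect_equal(nrow(scan_tandem_repeats("AAAAAA")$repeats), 0L)

  # spans re-validate: every reported span begins with floor(copies) units
  set.seed(84)
  sq <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
              collapse = "")
  res <- scan_tandem_repeats(sq, unit_max = 30)
  for (i in seq_len(nrow(res$repeats))) {
    r <- res$repeats[i, ]
    expect_identical(substring(sq, r$start, r$start + r$unit_len * r$copies - 1L),
                     strrep(r$unit, r$copies))
    expect_true(is_primitive <- !any(vapply(
      seq_len(r$unit_len %/% 2), function(p)
        r$unit_len %% p == 0 &&
        r$unit == strrep(substring(r$unit, 1, p), r$unit_len / p), TRUE)))
  }
  # no two reported arrays are span-nested
  sp <- res$repeats
  if (nrow(sp) > 1) {
    for (i in seq_len(nrow(sp))) {
      others <- sp[-i, ]
      expect_false(any(others$start <= sp$start[i] & others$end >= sp$end[i]))
    }
  }
})

test_that("planted primitive arrays are all recovered without nesting", {
  for (s in c(85, 86)) {
    sim <- simulate_tandem_genome(s, length = 8000, n = 20)
    res <- scan_tandem_repeats(sim$seq, unit_max = 40)
    for (i in seq_len(nrow(sim$truth))) {
      tt <- sim$truth[i, ]
      hit <- res$repeats[res$repeats$start == tt$start &
                         res$repeats$unit_len == tt$unit_len, ]
      expect_equal(nrow(hit), 1L,
                   info = sprintf("seed %d array %d", s, i))
      expect_equal(hit$copies, tt$copies)
      expect_identical(hit$unit, tt$unit)
    }
    expect_equal(res$summary$count, nrow(res$repeats))
    expect_equal(res$summary$total_bp, sum(res$repeats$total_len))
  }
})
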