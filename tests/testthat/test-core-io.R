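test_that("GenBank round-trip preserves sequence and annotations exactly", {
  feats <- list(
    gene_feature("petB", "CDS", "-", list(interval(10, 24), interval(40, 60)),
                 codon_start = 2),
    gene_feature("trnX", "tRNA", "+", list(interval(70, 90))),
    gene_feature("oriX", "CDS", "+", list(interval(95, 5, wraps = TRUE)),
                 pseudo_flag = TRUE))
  rec <- plastome_record("toy1", strrep("ACGTT", 20), circular = TRUE,
                         features = feats)
  f <- withr::local_tempfile(fileext = ".gb")
  write_genbank(rec, f)
  back <- read_genbank(f)[[1]]
  expect_identical(back$seq, rec$seq)
  expect_identical(back$circular, TRUE)
  expect_equal(back$features, rec$features)

  # generator output re-parses losslessly, features equal the truth table
  b <- build_plastome(synth_spec(seed = 101, jsa_type = "A"))
  f2 <- withr::local_tempfile(fileext = ".gb")
  write_genbank(b$record, f2)
  back2 <- read_genbank(f2)[[1]]
  expect_identical(back2$seq, b$record$seq)
  expect_equal(back2$features, b$record$features)
  got <- do.call(rbind, lapply(back2$features, function(fe) {
    data.frame(name = fe$name, kind = fe$kind, strand = fe$strand,
               start = fe$exons[[1]]$start, end = fe$exons[[1]]$end,
               pseudo = fe$pseudo_flag, stringsAsFactors = FALSE)
  }))
  expect_equal(got, b$truth$features)
})

test_that("malformed GenBank input raises a parse error naming the problem", {
  f <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS garbled", "ORIGIN", "//"), f)
  expect_error(read_genbank(f), "LOCUS")
  writeLines(c("LOCUS       x 10 bp DNA circular", "no origin here"), f)
  expect_error(read_genbank(f), "ORIGIN")
})

test_that("feature extraction splices, strands and wraps correctly", {
  rec <- plastome_record("t", "ATGTAAGG", circular = FALSE)
  f <- gene_feature("x", "CDS", "+", list(interval(1, 6)))
  expect_identical(extract_feature_sequence(rec, f), "ATGTAA")

  # minus-strand extraction of a printed repeat copy is its reverse complement
  rec2 <- plastome_record("t2", "TATAAACCCAATAATGA", circular = FALSE)
  f2 <- gene_feature("y", "misc", "-", list(interval(1, 17)))
  expect_identical(extract_feature_sequence(rec2, f2), "TCATTATTGGGTTTATA")

  # wrapping exon on a circular toy equals extraction after rotation
  set.seed(5)
  s <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = "")
  rec3 <- plastome_record("t3", s, circular = TRUE)
  fw <- gene_feature("z", "misc", "+", list(interval(16, 5, wraps = TRUE)))
  rot <- rotate_record(rec3, 15)   # wrap becomes plain interval 1..10
  fl <- gene_feature("z", "misc", "+", list(interval(1, 10)))
  expect_identical(extract_feature_sequence(rec3, fw),
                   extract_feature_sequence(rot, fl))

  # minus-strand equals reverse complement of the plus-strand extraction
  set.seed(6)
  for (i in 1:20) {
    a <- sample(1:15, 1); b <- a + sample(0:4, 1)
    fp <- gene_feature("p", "misc", "+", list(interval(a, b)))
    fm <- gene_feature("m", "misc", "-", list(interval(a, b)))
    expect_identical(extract_feature_sequence(rec3, fm),
                     reverse_complement(extract_feature_sequence(rec3, fp)))
  }

  f_bad <- gene_feature("w", "misc", "+", list(interval(15, 30)))
  expect_error(extract_feature_sequence(rec3, f_bad), "range")
})

test_that("plastid CDS translation matches an independent codon-table oracle", {
  expect_identical(translate_cds("ATGTAA"), "M*")
  expect_identical(translate_cds("ATGTGATAA"), "M**")
  expect_identical(translate_cds("ATGNNNTAA"), "MX*")
  expect_identical(translate_cds("AT"), "")
  expect_identical(translate_cds("CATGTAA", codon_start = 2), "M*")

  set.seed(7)
  bases <- c("A", "C", "G", "T")
  # 300-codon random ORF and ~1000 further random codons incl. N
  for (rep in 1:4) {
    n <- if (rep == 1) 900 else 750
    v <- sample(c(bases, "N"), n, replace = TRUE,
                prob = c(rep(0.24, 4), 0.04))
    sq <- paste(v, collapse = "")
    cs <- sample(1:3, 1)
    expect_identical(translate_cds(sq, cs), oracle_translate(sq, cs))
  }
})

test_that("reverse complement is an involution and GC excludes N", {
  expect_identical(reverse_complement("TATAAACCCAATAATGA"), "TCATTATTGGGTTTATA")
  set.seed(8)
  for (i in 1:20) {
    sq <- paste(sample(c("A", "C", "G", "T", "N"), 50, replace = TRUE),
                collapse = "")
    expect_identical(reverse_complement(reverse_complement(sq)), sq)
  }
  expect_equal(gc_content("ATGC"), 50.0)
  expect_equal(gc_content("GCNN"), 100.0)   # N excluded from denominator
  expect_error(reverse_complement("ACGU"), "outside")
  expect_error(gc_content("ACGX"), "outside")
})

test_that("record validation rejects out-of-range features and bad alphabets", {
  expect_error(plastome_record("e", "ACGTQ"), "outside")
  expect_error(plastome_record("e", ""), "empty")
  expect_error(
    plastome_record("e", "ACGTACGT", features = list(
      gene_feature("g", "CDS", "+", list(interval(5, 12))))),
    "outside")
})
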