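# a minimal intact CDS of a given length (multiple of 3); aperiodic body so
# that partial copies cannot masquerade as full coverage
toy_cds <- function(len) {
  set.seed(len)
  sense <- c("GCT", "GAA", "TTC", "GGA", "CAT", "AAA", "CCG", "TGG", "ATC",
             "CTG", "TCA", "GTT")
  paste0("ATG", paste(sample(sense, len / 3 - 2, replace = TRUE),
                      collapse = ""), "TAA")
}

toy_record_with <- function(id, genes) {
  # genes: named list of CDS strings, laid head-to-tail with 40 bp spacers
  set.seed(nchar(id) + 1000)
  parts <- character(0); feats <- list(); pos <- 1L
  for (g in names(genes)) {
    sp <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")
    parts <- c(parts, sp, genes[[g]])
    a <- pos + 40L
    feats[[length(feats) + 1L]] <- gene_feature(g, "CDS", "+",
                                                list(interval(a, a + nchar(genes[[g]]) - 1L)))
    pos <- a + nchar(genes[[g]])
  }
  parts <- c(parts, strrep("ACGT", 10))
  plastome_record(id, paste(parts, collapse = ""), circular = FALSE,
                  features = feats)
}

test_that("the reference panel picks the modal intact length, ties to longest", {
  recs <- list(toy_record_with("r1", list(tst = toy_cds(900))),
               toy_record_with("r2", list(tst = toy_cds(900))),
               toy_record_with("r3", list(tst = toy_cds(903))))
  panel <- build_reference_panel(recs)
  expect_equal(panel$tst$length, 900L)
  expect_false(panel$tst$flagged)

  # single-record panel: that record's lengths verbatim
  p1 <- build_reference_panel(recs[1])
  expect_equal(p1$tst$length, 900L)
  expect_identical(p1$tst$seq, toy_cds(900))

  # equal-frequency tie broken by the longest
  recs2 <- list(toy_record_with("r1", list(tst = toy_cds(900))),
                toy_record_with("r2", list(tst = toy_cds(903))))
  expect_equal(build_reference_panel(recs2)$tst$length, 903L)
})

test_that("presence coverage is exact for verbatim and truncated genes", {
  b <- build_plastome(synth_spec(seed = 71, jsa_type = "A"))
  panel <- build_reference_panel(list(b$record))
  pres <- assess_presence(panel$rbcL$seq, b$record)
  expect_equal(pres$coverage, 1.0)

  b2 <- build_plastome(synth_spec(
    seed = 72, jsa_type = "A",
    planted_status = list(list(gene = "ndhA", lesion = "truncate", frac = 0.25))))
  pres2 <- assess_presence(panel$ndhA$seq, b2$record)
  expect_equal(pres2$coverage, 0.25, tolerance = 0.02)

  expect_error(assess_presence("ATGTAA", b$record), "30")
})

test_that("the tile and alignment presence routes agree on small fixtures", {
  ref <- toy_cds(300)
  host <- toy_record_with("h", list(tst = ref))
  t1 <- assess_presence(ref, host, method = "tile")
  t2 <- assess_presence(ref, host, method = "align")
  expect_equal(t1$coverage, 1.0)
  expect_equal(t2$coverage, 1.0)

  # half the gene replaced by unrelated sequence
  set.seed(73)
  half <- paste0(substring(ref, 1, 150),
                 paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
                       collapse = ""))
  host2 <- toy_record_with("h2", list(tst = half))
  c1 <- assess_presence(ref, host2, method = "tile")$coverage
  c2 <- assess_presence(ref, host2, method = "align")$coverage
  expect_equal(c1, 0.5, tolerance = 0.05)
  # the alignment route's acceptance rule (>= 30 columns at >= 70%
  # identity) can admit one short chance block on random background
  expect_lt(abs(c2 - 0.5), 0.12)
})

test_that("planted lesions are classified with the right evidence", {
  pl <- list(list(gene = "ndhJ", lesion = "internal_stop"),
             list(gene = "ndhK", lesion = "missing_stop"),
             list(gene = "cemA", lesion = "frameshift"),
             list(gene = "ndhA", lesion = "truncate", frac = 0.5),
             list(gene = "ndhG", lesion = "truncate", frac = 0.2),
             list(gene = "ndhE", lesion = "delete"),
             list(gene = "rbcL", lesion = "n_run"))
  b <- build_plastome(synth_spec(seed = 74, jsa_type = "A", planted_status = pl))
  panel <- build_reference_panel(list(
    build_plastome(synth_spec(seed = 75, jsa_type = "A"))$record))
  ev_of <- function(g) classify_gene(g, b$record, panel)
  expect_equal(ev_of("ndhJ")$status, "pseudogene")
  expect_true("internal_stop" %in% vapply(ev_of("ndhJ")$evidence, `[[`, "", "type"))
  expect_equal(ev_of("ndhK")$status, "pseudogene")
  expect_true("missing_stop" %in% vapply(ev_of("ndhK")$evidence, `[[`, "", "type"))
  expect_equal(ev_of("cemA")$status, "pseudogene")
  expect_true("frameshift" %in% vapply(ev_of("cemA")$evidence, `[[`, "", "type"))
  st5 <- ev_of("ndhA")
  expect_equal(st5$status, "pseudogene")   # 50% left, stop gone
  expect_equal(st5$coverage, 0.5, tolerance = 0.02)
  expect_equal(ev_of("ndhG")$status, "lost")
  expect_equal(ev_of("ndhE")$status, "lost")
  expect_equal(ev_of("ndhE")$coverage, 0)
  st8 <- ev_of("rbcL")
  expect_equal(st8$status, "uncertain")
  expect_true("contains_N" %in% vapply(st8$evidence, `[[`, "", "type"))
  expect_equal(ev_of("psbA")$status, "intact")

  # full truth-table agreement
  sm <- status_matrix(list(b$record), panel)
  merged <- merge(sm$statuses, b$truth$gene_status, by = "gene")
  expect_equal(merged$status.x, merged$status.y)
})

test_that("the 30% lost threshold is strict: exactly 30% is not lost", {
  # ndhA is 1080 bp; truncation to 0.30 keeps exactly 324 bp
  b <- build_plastome(synth_spec(
    seed = 76, jsa_type = "A",
    planted_status = list(list(gene = "ndhA", lesion = "truncate", frac = 0.30))))
  panel <- build_reference_panel(list(
    build_plastome(synth_spec(seed = 75, jsa_type = "A"))$record))
  st <- classify_gene("ndhA", b$record, panel)
  expect_gte(st$coverage, 0.30)
  expect_equal(st$status, "pseudogene")
})

test_that("an IR-held pseudogene pair is counted once with copy_count 2", {
  # Type C: ndhH duplicated into both IR copies at 592/1182 bp, stop missing
  b <- build_plastome(synth_spec(seed = 77, jsa_type = "C"))
  panel <- build_reference_panel(list(
    build_plastome(synth_spec(seed = 75, jsa_type = "A"))$record))
  st <- classify_gene("ndhH", b$record, panel)
  expect_equal(st$status, "pseudogene")
  expect_equal(st$copy_count, 2L)
  expect_equal(st$coverage, 592 / 1182, tolerance = 0.02)
  expect_true("missing_stop" %in% vapply(st$evidence, `[[`, "", "type"))
  # full-length ycf1 is duplicated and intact
  sy <- classify_gene("ycf1", b$record, panel)
  expect_equal(sy$status, "intact")
  expect_equal(sy$copy_count, 2L)
})

test_that("gene status is invariant to genome rotation", {
  pl <- list(list(gene = "ndhJ", lesion = "internal_stop"))
  b <- build_plastome(synth_spec(seed = 78, jsa_type = "A", planted_status = pl))
  panel <- build_reference_panel(list(b$record))
  s0 <- classify_gene("ndhJ", b$record, panel)
  rot <- rotate_record(b$record, 17000)
  s1 <- classify_gene("ndhJ", rot, panel)
  expect_equal(s1$status, s0$status)
  expect_equal(s1$coverage, s0$coverage)
})

test_that("status matrix counts match an all-intact inventory", {
  b <- build_plastome(synth_spec(seed = 79, jsa_type = "A"))
  sm <- status_matrix(list(b$record))
  expect_equal(sm$counts$pseudogene, 0L)
  expect_equal(sm$counts$lost, 0L)
  expect_equal(sm$counts$uncertain, 0L)
  expect_equal(sm$counts$intact_unique, 17L)  # 16 single-copy CDS + ycf1
})
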