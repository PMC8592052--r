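classify_built <- function(b) {
  map <- detect_quadripartite(b$record)
  classify_jsa(junction_profiles(map, b$record)$J_SA, map, b$record)
}

test_that("J_SA types follow the ycf1-in-IRa decomposition", {
  # observed Type A range ~1,000 bp; Type B ~2,600-2,700 bp; C = containment
  jA <- classify_built(build_plastome(synth_spec(seed = 61, jsa_type = "A")))
  expect_equal(jA$type, "A")
  expect_equal(jA$ycf1_bp_in_ira, 1000L)
  expect_false(jA$ycf1_fully_in_ir)

  jB <- classify_built(build_plastome(synth_spec(seed = 61, jsa_type = "B")))
  expect_equal(jB$type, "B")
  expect_equal(jB$ycf1_bp_in_ira, 2600L)

  jC <- classify_built(build_plastome(synth_spec(seed = 61, jsa_type = "C")))
  expect_equal(jC$type, "C")
  expect_true(jC$ycf1_fully_in_ir)
  expect_true(all(c("ψndhH", "rps15") %in% jC$extra_ir_genes))
})

test_that("the A/B label is monotone in the ycf1 portion and C needs containment", {
  labels <- vapply(c(500L, 1500L, 1999L, 2000L, 2600L), function(bp) {
    b <- build_plastome(synth_spec(seed = 62, jsa_type = "A",
                                   ycf1_bp_in_ira = bp))
    classify_built(b)$type
  }, "")
  expect_equal(labels, c("A", "A", "A", "B", "B"))
  # once B, increasing bp never drops back to A; C arises only by containment
  expect_false("C" %in% labels)
})

test_that("a record without ycf1 is unclassifiable with a diagnostic", {
  b <- build_plastome(synth_spec(seed = 63, jsa_type = "A"))
  rec <- b$record
  rec$features <- Filter(function(f) f$name != "ycf1", rec$features)
  map <- detect_quadripartite(rec)
  j <- classify_jsa(junction_profiles(map, rec)$J_SA, map, rec)
  expect_equal(j$type, "unclassifiable")
  expect_match(j$diagnostic, "ycf1")
})

test_that("diff_junctions of a genome against itself is empty", {
  for (tp in c("A", "C")) {
    b <- build_plastome(synth_spec(seed = 64, jsa_type = tp))
    m <- detect_quadripartite(b$record)
    expect_length(diff_junctions(b$record, m, b$record, m), 0)
  }
})

test_that("a single DSB-style expansion is recovered as one event", {
  bA <- build_plastome(synth_spec(seed = 65, jsa_type = "A"))
  bC <- build_plastome(synth_spec(seed = 65, jsa_type = "C"))
  mA <- detect_quadripartite(bA$record)
  mC <- detect_quadripartite(bC$record)
  ev <- diff_junctions(bC$record, mC, bA$record, mA)
  expect_length(ev, 1)
  expect_equal(ev[[1]]$size, bC$truth$events[[1]]$extent)
  expect_true(all(c("ndhH", "rps15", "ycf1") %in% ev[[1]]$genes_incorporated))
  expect_equal(ev[[1]]$mechanism_hypothesis, "dsb_or_other")
})

test_that("the two-event expansion history is reconstructed in order", {
  set.seed(66)
  sc <- simulate_type_c_two_events(66)
  mA <- detect_quadripartite(sc$ancestor)
  mD <- detect_quadripartite(sc$derived)
  ev <- diff_junctions(sc$derived, mD, sc$ancestor, mA)
  expect_length(ev, 2)
  # ordered 5' to 3' along IRa: most recent (short) event first
  expect_equal(vapply(ev, function(e) e$size, 0L), sc$truth$event_sizes)
  expect_true(all(c("ndhH", "rps15", "ycf1") %in% ev[[2]]$genes_incorporated))
  expect_true(ev[[1]]$mapped)
  # the short segment originates in an intergenic spacer of the reference
  canon <- canonicalize_plastome(sc$derived, mD)
  seg <- substring(canon$seq, mD$junctions[["J_SA"]],
                   mD$junctions[["J_SA"]] + ev[[1]]$size - 1L)
  pl <- map_segment_origin(seg, sc$ancestor)
  expect_true(pl$placed)
  expect_match(pl$context, "spacer")
})

test_that("a planted junction repeat labels the expansion repeat-mediated", {
  set.seed(67)
  sb <- simulate_type_b_expansion(67)
  mA <- detect_quadripartite(sb$ancestor)
  mD <- detect_quadripartite(sb$derived)
  j <- classify_jsa(junction_profiles(mD, sb$derived)$J_SA, mD, sb$derived)
  expect_equal(j$type, "B")
  ev <- diff_junctions(sb$derived, mD, sb$ancestor, mA)
  expect_length(ev, 1)
  expect_equal(ev[[1]]$size, sb$truth$extent)
  expect_equal(ev[[1]]$mechanism_hypothesis, "repeat_mediated")
  expect_gte(nrow(ev[[1]]$mediating_repeats), 1)
})

test_that("mediating-repeat screening finds exactly a pair straddling windows", {
  set.seed(68)
  bases <- c("A", "C", "G", "T")
  v <- sample(bases, 400, replace = TRUE)
  core <- sample(bases, 16, replace = TRUE)
  v[1:16] <- core
  v[385:400] <- rev(oracle_comp[core])
  rec <- plastome_record("toy", paste(v, collapse = ""), circular = FALSE)
  got <- find_mediating_repeats(rec, interval(1, 16), interval(385, 400))
  expect_equal(nrow(got), 1)
  expect_equal(got$direction, "inverted")
  expect_equal(c(got$start1, got$end1, got$start2, got$end2),
               c(1L, 16L, 385L, 400L))
  expect_equal(got$mismatches, 0L)
})

test_that("segment placement recovers origin, identity and context", {
  b <- build_plastome(synth_spec(seed = 69, jsa_type = "A"))
  ref <- b$record
  seg <- substring(ref$seq, 2001, 2045)
  pl <- map_segment_origin(seg, ref)
  expect_true(pl$placed)
  expect_equal(c(pl$interval$start, pl$interval$end), c(2001L, 2045L))
  expect_equal(pl$identity, 1.0)

  # two substitutions: same placement, identity about 43/45
  seg2 <- seg
  substr(seg2, 10, 10) <- if (substring(seg2, 10, 10) == "A") "C" else "A"
  substr(seg2, 30, 30) <- if (substring(seg2, 30, 30) == "G") "T" else "G"
  pl2 <- map_segment_origin(seg2, ref)
  expect_true(pl2$placed)
  expect_equal(c(pl2$interval$start, pl2$interval$end), c(2001L, 2045L))
  expect_equal(pl2$identity, 43 / 45, tolerance = 0.01)

  # an unrelated random segment stays unplaced
  set.seed(70)
  rand <- paste(sample(c("A", "C", "G", "T"), 45, replace = TRUE),
                collapse = "")
  expect_false(map_segment_origin(rand, ref)$placed)
  expect_error(map_segment_origin("ACGTACGT", ref), "16")
})
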