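#' Specification for a synthetic annotated plastome
#'
#' The generator's defaults emulate a reduced-scale photosynthetic plastome
#' (12 kb LSC / 7 kb IR / 9 kb SSC, GC 37.8%) whose gene complement mirrors
#' the canonical layout: a junction-spanning *ycf1* with its 5' portion in
#' IRa, the *ndh* suite and *rps15* in the SSC, rRNAs and *trnN* in the IR.
#' *ndhH* keeps its real 1,182 bp length so 50%-truncation scenarios are
#' exact. Reduced scale keeps the construct-and-recover suites fast while
#' preserving every structural relation the pipeline measures.
#'
#' @param seed integer seed; fully determines the genome.
#' @param lsc_len,ir_len,ssc_len compartment sizes in bp.
#' @param gc_target background GC fraction.
#' @param jsa_type `"A"`, `"B"` or `"C"`. A and B are built directly with
#'   the requested *ycf1* portion in IRa; C is built as a Type A genome
#'   followed by a double-strand-break-style expansion that incorporates
#'   the rest of *ycf1*, *rps15* and 592 bp of *ndhH* into the IR.
#' @param ycf1_bp_in_ira bp of *ycf1* inside IRa (defaults: A 1,000; B 2,600).
#' @param ycf1_len total *ycf1* length (default 3,600 bp).
#' @param gene_inventory `data.frame(name, kind, strand, length,
#'   compartment)`; defaults to [default_gene_inventory()].
#' @param planted_status list of lesion requests, each
#'   `list(gene=, lesion=, ...)` with lesion one of `internal_stop`,
#'   `missing_stop`, `frameshift`, `truncate` (takes `frac`), `delete`,
#'   `n_run`.
#' @param planted_dispersed list of `list(direction=, length=, mismatches=)`
#'   dispersed-repeat requests (planted into LSC spacers).
#' @param planted_tandem list of `list(unit_len=, copies=)` tandem-array
#'   requests (planted into LSC/SSC spacers).
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(seed = 1L, lsc_len = 12000L, ir_len = 7000L,
                       ssc_len = 9000L, gc_target = 0.378,
                       jsa_type = c("A", "B", "C"), ycf1_bp_in_ira = NULL,
                       ycf1_len = 3600L, gene_inventory = NULL,
                       planted_status = list(), planted_dispersed = list(),
                       planted_tandem = list(), family_seed = 42L) {
  jsa_type <- match.arg(jsa_type)
  if (is.null(ycf1_bp_in_ira))
    ycf1_bp_in_ira <- switch(jsa_type, A = 1000L, B = 2600L, C = 1000L)
  structure(list(seed = as.integer(seed), lsc_len = as.integer(lsc_len),
                 ir_len = as.integer(ir_len), ssc_len = as.integer(ssc_len),
                 gc_target = gc_target, jsa_type = jsa_type,
                 ycf1_bp_in_ira = as.integer(ycf1_bp_in_ira),
                 ycf1_len = as.integer(ycf1_len),
                 gene_inventory = gene_inventory %||% default_gene_inventory(),
                 planted_status = planted_status,
                 planted_dispersed = planted_dispersed,
                 planted_tandem = planted_tandem,
                 family_seed = as.integer(family_seed)),
            class = "synth_spec")
}

# gene sequences are drawn from a gene-specific RNG stream keyed by the
# family seed, so records with different seeds share a conserved gene
# complement (homologs) while their spacers and backgrounds diverge
gene_content <- function(name, kind, len, family_seed, gc) {
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed((family_seed * 1009L + sum(utf8ToInt(name)) * 131L) %% 2147483L)
  if (kind == "CDS") make_cds(len, gc) else random_dna(len, gc)
}

#' Default reduced-scale plastome gene inventory
#'
#' @return `data.frame` of gene name, kind, strand, length and compartment.
#' @export
default_gene_inventory <- function() {
  data.frame(
    name = c("psbA", "matK", "rbcL", "ndhC", "ndhJ", "ndhK", "cemA", "rps2",
             "trnH", "trnK",
             "ndhF", "rpl32", "ndhE", "ndhG", "ndhI", "ndhA", "ndhH", "rps15",
             "trnN", "rrn5", "rrn16", "rrn23"),
    kind = c(rep("CDS", 8), "tRNA", "tRNA", rep("CDS", 8),
             "tRNA", "rRNA", "rRNA", "rRNA"),
    strand = c("+", "-", "+", "-", "-", "-", "+", "-", "+", "-",
               "-", "+", "-", "-", "-", "-", "-", "+",
               "-", "+", "+", "+"),
    length = c(1062L, 1500L, 1428L, 363L, 477L, 678L, 690L, 711L, 74L, 72L,
               1200L, 174L, 306L, 531L, 501L, 1080L, 1182L, 273L,
               72L, 121L, 1491L, 1800L),
    compartment = c(rep("LSC", 10), rep("SSC", 8), rep("IR", 4)),
    stringsAsFactors = FALSE)
}

.dna_bases <- c("A", "C", "G", "T")
.stop_codons <- c("TAA", "TAG", "TGA")

random_dna <- function(n, gc = 0.378) {
  if (n <= 0L) return("")
  paste(sample(.dna_bases, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

all_codons <- function() {
  g <- expand.grid(.dna_bases, .dna_bases, .dna_bases, stringsAsFactors = FALSE)
  paste0(g[[3]], g[[2]], g[[1]])
}

make_cds <- function(len, gc = 0.378) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  sense <- setdiff(all_codons(), .stop_codons)
  # codon frequencies follow the target base composition
  bp <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  w <- vapply(strsplit(sense, ""), function(b) prod(bp[b]), 0)
  paste0("ATG",
         paste(sample(sense, len / 3L - 2L, replace = TRUE, prob = w),
               collapse = ""),
         "TAA")
}

str_write <- function(s, at, content) {
  substr(s, at, at + nchar(content) - 1L) <- content
  s
}

# deterministic "different base" choice
other_base <- function(b, avoid = character(0)) {
  setdiff(.dna_bases, c(b, avoid))[1]
}

# ensure s[free_pos] != complement(s[partner_pos]) by rewriting free_pos
fix_junction_guard <- function(s, free_pos, partner_pos) {
  cur <- substring(s, free_pos, free_pos)
  bad <- comp_base(substring(s, partner_pos, partner_pos))
  if (cur != bad) return(s)
  str_write(s, free_pos, other_base(bad))
}

comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A", N = "N")[[b]]

#' Build a synthetic annotated plastome with a machine-readable truth table
#'
#' Deterministic for a given seed. The background is i.i.d. at the target
#' GC; IRb is emitted as the exact reverse complement of IRa; *ycf1* is
#' placed across J_SA according to the requested junction type; lesions,
#' dispersed repeats and tandem arrays are planted as requested and their
#' realised coordinates recorded.
#'
#' @param spec a [synth_spec()].
#' @return List with `record` (a [plastome_record()]) and `truth` (realised
#'   region lengths, junctions, J_SA type, per-gene expected status,
#'   dispersed-repeat and tandem-array tables, and the expansion event for
#'   Type C).
#' @export
build_plastome <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  inv <- spec$gene_inventory
  gc <- spec$gc_target
  ycf_ira <- spec$ycf1_bp_in_ira
  ycf_ssc <- spec$ycf1_len - ycf_ira
  stopifnot(ycf_ssc > 0L)

  lay_compartment <- function(genes, comp_len, tail_reserved = 0L) {
    # sequential layout: [gap gene gap gene ... gap][tail_reserved]
    glen <- sum(genes$length)
    free <- comp_len - glen - tail_reserved
    ngap <- nrow(genes) + 1L
    if (free < ngap) stop("infeasible packing: genes exceed compartment")
    gap <- free %/% ngap
    extra <- free - gap * ngap
    pos <- 0L
    out <- genes
    out$start <- NA_integer_
    spacers <- list()
    for (i in seq_len(nrow(genes))) {
      pos <- pos + gap
      spacers[[i]] <- c(pos - gap + 1L, pos)
      out$start[i] <- pos + 1L
      pos <- pos + genes$length[i]
    }
    spacers[[ngap]] <- c(pos + 1L, pos + gap + extra)
    list(genes = out, spacers = spacers, used = pos + gap + extra)
  }

  lsc_genes <- inv[inv$compartment == "LSC", ]
  ssc_genes <- inv[inv$compartment == "SSC", ]
  ir_genes <- inv[inv$compartment == "IR", ]

  lsc_lay <- lay_compartment(lsc_genes, spec$lsc_len)
  ssc_lay <- lay_compartment(ssc_genes, spec$ssc_len, tail_reserved = ycf_ssc)
  ira_lay <- lay_compartment(ir_genes, spec$ir_len - ycf_ira)

  # compartment sequences
  build_comp <- function(lay, comp_len) {
    s <- random_dna(comp_len, gc)
    contents <- list()
    for (i in seq_len(nrow(lay$genes))) {
      g <- lay$genes[i, ]
      content <- gene_content(g$name, g$kind, g$length, spec$family_seed, gc)
      genomic <- if (g$strand == "-") reverse_complement(content) else content
      s <- str_write(s, g$start, genomic)
      contents[[g$name]] <- content
    }
    list(seq = s, contents = contents)
  }
  lsc_b <- build_comp(lsc_lay, spec$lsc_len)
  ssc_b <- build_comp(ssc_lay, spec$ssc_len - ycf_ssc)
  ira_b <- build_comp(ira_lay, spec$ir_len - ycf_ira)

  # ycf1 across J_SA: minus strand, 5' end IRa-most; genomic span content is
  # the reverse complement of the CDS, split SSC-tail | IRa-head
  ycf_cds <- gene_content("ycf1", "CDS", spec$ycf1_len, spec$family_seed, gc)
  ycf_genomic <- reverse_complement(ycf_cds)
  ssc_seq <- paste0(ssc_b$seq, substring(ycf_genomic, 1L, ycf_ssc))
  ira_seq <- paste0(substring(ycf_genomic, ycf_ssc + 1L), ira_b$seq)
  stopifnot(nchar(ssc_seq) == spec$ssc_len,
            nchar(ira_seq) == spec$ir_len)
  irb_seq <- reverse_complement(ira_seq)
  genome <- paste0(lsc_b$seq, irb_seq, ssc_seq, ira_seq)

  # junction guards: break chance complementarity at the IR flanks so the
  # realised maximal inverted repeat is exactly the planted one. Both guard
  # positions are spacer bases (first/last LSC base, first SSC base).
  genome <- fix_junction_guard(genome, spec$lsc_len, 1L)
  genome <- fix_junction_guard(genome,
                               spec$lsc_len + spec$ir_len + 1L,
                               spec$lsc_len + spec$ir_len + spec$ssc_len)

  lsc_off <- 0L
  irb_off <- spec$lsc_len
  ssc_off <- irb_off + spec$ir_len
  ira_off <- ssc_off + spec$ssc_len
  L <- ira_off + spec$ir_len

  feats <- list()
  add_feat <- function(name, kind, strand, start, end, codon_start = 1L,
                       pseudo = FALSE) {
    feats[[length(feats) + 1L]] <<- gene_feature(name, kind, strand,
                                                 list(interval(start, end)),
                                                 codon_start, pseudo)
  }
  for (i in seq_len(nrow(lsc_lay$genes))) {
    g <- lsc_lay$genes[i, ]
    add_feat(g$name, g$kind, g$strand, g$start, g$start + g$length - 1L)
  }
  for (i in seq_len(nrow(ssc_lay$genes))) {
    g <- ssc_lay$genes[i, ]
    add_feat(g$name, g$kind, g$strand, ssc_off + g$start,
             ssc_off + g$start + g$length - 1L)
  }
  # ycf1 spanning SSC/IRa
  add_feat("ycf1", "CDS", "-", ira_off - ycf_ssc + 1L, ira_off + ycf_ira)
  # IRa resident genes (offset past the ycf1 head) and their IRb mirrors
  for (i in seq_len(nrow(ira_lay$genes))) {
    g <- ira_lay$genes[i, ]
    a <- ira_off + ycf_ira + g$start
    b <- a + g$length - 1L
    add_feat(g$name, g$kind, g$strand, a, b)
    # mirror in IRb: IR offset o maps to irb_off + ir_len - o + 1
    oa <- a - ira_off; ob <- b - ira_off
    add_feat(g$name, g$kind, if (g$strand == "+") "-" else "+",
             irb_off + spec$ir_len - ob + 1L, irb_off + spec$ir_len - oa + 1L)
  }

  truth <- list(seed = spec$seed,
                regions = list(lsc_len = spec$lsc_len, ir_len = spec$ir_len,
                               ssc_len = spec$ssc_len, genome_len = L),
                junctions = c(J_LB = irb_off + 1L, J_SB = irb_off + spec$ir_len,
                              J_SA = ira_off + 1L, J_LA = L),
                jsa = list(type = spec$jsa_type, ycf1_bp_in_ira = ycf_ira),
                events = list())

  rec <- plastome_record(sprintf("synth%04d%s", spec$seed, spec$jsa_type),
                         genome, circular = TRUE, features = feats)

  # ---- Type C: expansion incorporating ycf1 remainder, rps15, 592 bp ndhH
  if (spec$jsa_type == "C") {
    ndhH <- Filter(function(f) f$name == "ndhH", rec$features)[[1]]
    cut <- ndhH$exons[[1]]$end - 592L + 1L   # keep 592 bp from the start codon
    extent <- (ssc_off + spec$ssc_len) - cut + 1L
    exp1 <- apply_ir_expansion(rec, mechanism = "dsb_long", extent = extent,
                               erode_remnant = TRUE,
                               layout = list(lsc_len = spec$lsc_len,
                                             ir_len = spec$ir_len,
                                             ssc_len = spec$ssc_len))
    rec <- exp1$record
    truth$events <- list(exp1$log)
    truth$regions$ir_len <- spec$ir_len + extent
    truth$regions$ssc_len <- spec$ssc_len - extent
    truth$regions$genome_len <- L + extent
    # the SSC tail stays in place, so J_SA keeps its absolute position
    truth$junctions <- c(J_LB = irb_off + 1L,
                         J_SB = irb_off + spec$ir_len + extent,
                         J_SA = ira_off + 1L,
                         J_LA = L + extent)
    truth$jsa <- list(type = "C", ycf1_bp_in_ira = spec$ycf1_len)
  }

  # ---- planted gene lesions -------------------------------------------------
  status_rows <- list()
  expect_status <- function(lesion, frac) {
    switch(lesion,
           internal_stop = , missing_stop = , frameshift = "pseudogene",
           truncate = if (frac < 0.30) "lost" else "pseudogene",
           delete = "lost",
           n_run = "uncertain",
           stop("unknown lesion"))
  }
  for (pl in spec$planted_status) {
    frac_real <- pl$frac %||% 1
    if (pl$lesion == "truncate") {
      # the realised coverage is floor(n * frac) / n; with the strict < 0.30
      # rule the expected status follows the realised value, not the request
      f0 <- Filter(function(f) f$kind == "CDS" && f$name == pl$gene &&
                     !f$pseudo_flag, rec$features)[[1]]
      n0 <- interval_length(f0$exons[[1]])
      frac_real <- floor(n0 * pl$frac) / n0
    }
    les <- apply_lesion(rec, pl)
    rec <- les$record
    status_rows[[length(status_rows) + 1L]] <- data.frame(
      gene = pl$gene, lesion = pl$lesion,
      status = expect_status(pl$lesion, frac_real),
      stringsAsFactors = FALSE)
  }
  planted <- vapply(spec$planted_status, function(p) p$gene, "")
  cds_names <- unique(vapply(Filter(function(f) f$kind == "CDS", rec$features),
                             function(f) f$name, ""))
  intact_rows <- data.frame(gene = setdiff(cds_names, planted), lesion = "none",
                            status = "intact", stringsAsFactors = FALSE)
  if (spec$jsa_type == "C")
    intact_rows$status[intact_rows$gene == "ndhH"] <- "pseudogene"
  truth$gene_status <- rbind(if (length(status_rows) > 0L)
    do.call(rbind, status_rows), intact_rows)

  # ---- planted dispersed repeats (LSC spacers) ------------------------------
  slots <- lapply(lsc_lay$spacers, function(sp) sp + lsc_off)
  slots <- Filter(function(sp) sp[2] - sp[1] + 1L >= 80L, slots)
  slot_i <- 1L
  take_slot <- function() {
    if (slot_i > length(slots)) stop("not enough spacer slots for planting")
    s <- slots[[slot_i]]; slot_i <<- slot_i + 1L; s
  }
  disp_rows <- list()
  for (pd in spec$planted_dispersed) {
    len <- pd$length; mm <- pd$mismatches; dir <- pd$direction
    stopifnot(mm >= 1L, mm <= floor(0.10 * len),
              floor(0.10 * (len + 1L)) <= mm)
    s1 <- take_slot(); s2 <- take_slot()
    p1 <- s1[1] + ((s1[2] - s1[1] - len) %/% 2L)
    p2 <- s2[1] + ((s2[2] - s2[1] - len) %/% 2L)
    for (try in 1:10) {
      core <- random_dna(len, gc)
      mut <- core
      mpos <- sort(sample(3:(len - 2L), mm))
      for (q in mpos) {
        b <- substring(mut, q, q)
        substr(mut, q, q) <- other_base(b)
      }
      placed2 <- if (dir == "inverted") reverse_complement(mut) else mut
      g <- rec$seq
      # fresh background in both host spacers so a retry can clear chance hits
      g <- str_write(g, s1[1], random_dna(s1[2] - s1[1] + 1L, gc))
      g <- str_write(g, s2[1], random_dna(s2[2] - s2[1] + 1L, gc))
      g <- str_write(g, p1, core)
      g <- str_write(g, p2, placed2)
      # anti-match zone: force mismatches at the 9 flanking alignment
      # columns on both sides, so no window larger than the planted one can
      # stay within the 10% budget (an extension of k gains k mismatches,
      # and a budget of m+k needs length >= 10(m+k) > len + 2*9)
      for (o in 1:9) {
        if (dir == "forward") {
          g <- str_write(g, p2 - o, other_base(substring(g, p1 - o, p1 - o)))
          g <- str_write(g, p2 + len - 1L + o,
                         other_base(substring(g, p1 + len - 1L + o,
                                              p1 + len - 1L + o)))
        } else {
          g <- str_write(g, p2 - o,
                         other_base(comp_base(substring(g, p1 + len - 1L + o,
                                                        p1 + len - 1L + o))))
          g <- str_write(g, p2 + len - 1L + o,
                         other_base(comp_base(substring(g, p1 - o, p1 - o))))
        }
      }
      cand <- plastome_record(rec$id, g, TRUE, rec$features)
      w1 <- interval(max(1L, p1 - 60L), p1 + len + 59L)
      w2 <- interval(max(1L, p2 - 60L), p2 + len + 59L)
      got <- scan_short_repeats(cand, windows = list(w1, w2), min_len = 16L,
                                mismatch_frac = 0.10)
      if (nrow(got) == 1L && got$start1 == p1 && got$start2 == p2 &&
          got$length == len && got$mismatches == mm) {
        rec <- cand
        disp_rows[[length(disp_rows) + 1L]] <- data.frame(
          direction = dir, length = len, mismatches = mm,
          start1 = p1, end1 = p1 + len - 1L,
          start2 = p2, end2 = p2 + len - 1L,
          window1_start = w1$start, window1_end = w1$end,
          window2_start = w2$start, window2_end = w2$end,
          stringsAsFactors = FALSE)
        break
      }
      if (try == 10L) stop("failed to plant dispersed repeat cleanly")
    }
  }
  truth$dispersed <- if (length(disp_rows) > 0L) do.call(rbind, disp_rows)
                     else NULL

  # ---- planted tandem arrays ------------------------------------------------
  ssc_slots <- lapply(ssc_lay$spacers, function(sp) sp + ssc_off)
  slots <- c(slots[seq.int(slot_i, length.out = max(0L, length(slots) - slot_i + 1L))],
             Filter(function(sp) sp[2] - sp[1] + 1L >= 60L, ssc_slots))
  slot_i <- 1L
  tan_rows <- list()
  for (pt in spec$planted_tandem) {
    u <- pt$unit_len; cp <- pt$copies
    sl <- take_slot()
    stopifnot(sl[2] - sl[1] + 1L >= u * cp + 4L)
    a <- sl[1] + 2L
    repeat {
      unit <- random_dna(u, gc)
      if (is_primitive_unit(unit)) break
    }
    arr <- strrep(unit, cp)
    g <- str_write(rec$seq, a, arr)
    b <- a + u * cp - 1L
    # break periodicity at both edges
    g <- str_write(g, a - 1L, other_base(substring(unit, u, u)))
    g <- str_write(g, b + 1L, other_base(substring(unit, (b + 1L - a) %% u + 1L,
                                                   (b + 1L - a) %% u + 1L)))
    rec <- plastome_record(rec$id, g, TRUE, rec$features)
    tan_rows[[length(tan_rows) + 1L]] <- data.frame(
      unit = unit, unit_len = u, copies = cp, start = a, end = b,
      total_len = u * cp, stringsAsFactors = FALSE)
  }
  truth$tandem <- if (length(tan_rows) > 0L) do.call(rbind, tan_rows) else NULL

  truth$features <- do.call(rbind, lapply(rec$features, function(f) {
    data.frame(name = f$name, kind = f$kind, strand = f$strand,
               start = f$exons[[1]]$start, end = f$exons[[1]]$end,
               pseudo = f$pseudo_flag, stringsAsFactors = FALSE)
  }))
  list(record = rec, truth = truth)
}

# apply one gene lesion; features are single-exon in generator output
apply_lesion <- function(rec, pl) {
  feats <- Filter(function(f) f$kind == "CDS" && f$name == pl$gene &&
                    !f$pseudo_flag, rec$features)
  if (length(feats) == 0L) stop(sprintf("lesion target '%s' not found", pl$gene))
  f <- feats[[1]]
  ex <- f$exons[[1]]
  n <- interval_length(ex)
  cds <- extract_feature_sequence(rec, f)
  g <- rec$seq
  write_back <- function(content, new_start = ex$start, new_end = ex$end) {
    genomic <- if (f$strand == "-") reverse_complement(content) else content
    stopifnot(nchar(genomic) == new_end - new_start + 1L)
    g <<- str_write(g, new_start, genomic)
    for (i in seq_along(rec$features)) {
      fi <- rec$features[[i]]
      if (fi$kind == "CDS" && fi$name == pl$gene && !fi$pseudo_flag &&
          fi$exons[[1]]$start == ex$start) {
        fi$exons[[1]] <- interval(new_start, new_end)
        rec$features[[i]] <<- fi
        break
      }
    }
  }
  drop_feature <- function() {
    keep <- !vapply(rec$features, function(fi)
      fi$kind == "CDS" && fi$name == pl$gene &&
        fi$exons[[1]]$start == ex$start, TRUE)
    rec$features <<- rec$features[keep]
  }
  switch(pl$lesion,
    internal_stop = {
      ci <- max(2L, floor(n / 3L * 0.4))
      substr(cds, 3L * ci - 2L, 3L * ci) <- "TAA"
      write_back(cds)
    },
    missing_stop = {
      substr(cds, n - 2L, n) <- "GAA"
      write_back(cds)
    },
    frameshift = {
      k <- max(4L, floor(n * 0.3))
      newc <- paste0(substring(cds, 1L, k - 1L), substring(cds, k + 1L, n))
      if (f$strand == "+") {
        g <- str_write(g, ex$start, paste0(newc, "A"))
        # re-randomise the freed base then shrink the annotation
        write_back(newc, ex$start, ex$end - 1L)
      } else {
        write_back(newc, ex$start + 1L, ex$end)
      }
    },
    truncate = {
      keep <- floor(n * pl$frac)
      stopifnot(keep >= 1L, keep < n)
      kept <- substring(cds, 1L, keep)
      filler <- random_dna(n - keep, 0.378)
      if (f$strand == "+") {
        g <- str_write(g, ex$start + keep, filler)
        write_back(kept, ex$start, ex$start + keep - 1L)
      } else {
        g <- str_write(g, ex$start, filler)
        write_back(kept, ex$end - keep + 1L, ex$end)
      }
    },
    delete = {
      g <- str_write(g, ex$start, random_dna(n, 0.378))
      drop_feature()
    },
    n_run = {
      at <- max(4L, 3L * floor(n / 6L) + 1L)
      substr(cds, at, at + 8L) <- "NNNNNNNNN"
      write_back(cds)
    },
    stop("unknown lesion type"))
  list(record = plastome_record(rec$id, g, TRUE, rec$features))
}

#' Expand the inverted repeat into the SSC at J_SA
#'
#' Moves the IRa--SSC junction into the SSC by `extent` bp: the SSC tail
#' segment keeps its place (relabelled IRa) and its reverse complement is
#' inserted at the IRb--SSC junction, so the two IR copies stay exact
#' mirror images. Genes falling wholly inside the incorporated segment (or
#' already continuing into IRa, like *ycf1*) gain a full mirrored copy in
#' IRb; a gene bisected by the new junction gains a truncated ψ copy, and
#' with `erode_remnant = TRUE` its single-copy remainder is overwritten
#' with background sequence and the annotation truncated (mimicking
#' post-expansion decay of the stranded fragment).
#'
#' @param record a canonical-orientation [plastome_record()] (as produced
#'   by [build_plastome()] or [canonicalize_plastome()]).
#' @param mechanism `"gene_conversion_short"` (extent capped at 200 bp) or
#'   `"dsb_long"` (uncapped): the two classes of expansion event.
#' @param extent bp of SSC to incorporate; 0 returns the record unchanged.
#' @param erode_remnant see above.
#' @param map optional [detect_quadripartite()] result; computed when absent.
#' @param layout optional `list(lsc_len, ir_len, ssc_len)` bypassing
#'   detection when the geometry is already known.
#' @return List with `record` (expanded) and `log` (`data.frame`:
#'   mechanism, extent, segment coordinates, genes incorporated).
#' @export
apply_ir_expansion <- function(record, mechanism = c("gene_conversion_short",
                                                     "dsb_long"),
                               extent, erode_remnant = TRUE, map = NULL,
                               layout = NULL) {
  mechanism <- match.arg(mechanism)
  stopifnot(extent >= 0L)
  if (extent == 0L)
    return(list(record = record, log = data.frame()))
  if (mechanism == "gene_conversion_short" && extent > 200L)
    stop("gene_conversion_short is restricted to extents of at most 200 bp")
  if (is.null(layout)) {
    if (is.null(map)) map <- detect_quadripartite(record)
    stopifnot(map$found, map$frame$offset == 0L, !map$frame$flip)
    layout <- list(lsc_len = map$lsc_len, ir_len = map$ir_len,
                   ssc_len = map$ssc_len)
  }
  if (extent >= layout$ssc_len)
    stop("expansion extent would consume the entire SSC")
  L <- record$length
  P <- layout$lsc_len + layout$ir_len           # IRb end
  ssc_end <- P + layout$ssc_len
  seg_start <- ssc_end - extent + 1L
  seg_seq <- substring(record$seq, seg_start, ssc_end)
  newseq <- paste0(substring(record$seq, 1L, P),
                   reverse_complement(seg_seq),
                   substring(record$seq, P + 1L, L))
  mirror <- function(p) P + (ssc_end - p) + 1L   # old coords -> new IRb coords
  shift <- function(p) if (p > P) p + extent else p

  genes_log <- character(0)
  newfeats <- list()
  eroded <- NULL
  for (f in record$features) {
    ex <- f$exons[[1]]
    if (length(f$exons) > 1L || ex$wraps) {
      warning(sprintf("feature '%s' skipped by expansion (multi-exon/wrap)", f$name))
      next
    }
    a <- ex$start; b <- ex$end
    overlaps_seg <- b >= seg_start && a <= ssc_end
    f2 <- f
    if (overlaps_seg && a >= seg_start) {
      # wholly within segment (possibly continuing into old IRa): full mirror
      mf <- f
      mf$strand <- if (f$strand == "+") "-" else "+"
      mf$exons <- list(interval(mirror(b), mirror(a)))
      newfeats[[length(newfeats) + 1L]] <- mf
      genes_log <- c(genes_log, f$name)
    } else if (overlaps_seg) {
      # bisected by the new junction: truncated pseudo mirror
      part_a <- max(a, seg_start)
      part_b <- b
      mf <- f
      mf$pseudo_flag <- TRUE
      mf$strand <- if (f$strand == "+") "-" else "+"
      mf$exons <- list(interval(mirror(part_b), mirror(part_a)))
      newfeats[[length(newfeats) + 1L]] <- mf
      genes_log <- c(genes_log, paste0(f$name, "(partial)"))
      if (erode_remnant) {
        eroded <- c(a, seg_start - 1L)
        f2$pseudo_flag <- TRUE
        f2$exons <- list(interval(part_a, part_b))
      }
    }
    f2$exons <- list(interval(shift(f2$exons[[1]]$start),
                              shift(f2$exons[[1]]$end)))
    newfeats[[length(newfeats) + 1L]] <- f2
  }
  if (!is.null(eroded)) {
    newseq <- str_write(newseq, shift(eroded[1]),
                        random_dna(eroded[2] - eroded[1] + 1L, 0.378))
  }
  # junction guard at the shrunken SSC: its first base (a spacer in the
  # generator's layouts) must not complement its last, or the realised IR
  # would extend one base past the intended junction
  newseq <- fix_junction_guard(newseq, P + extent + 1L,
                               layout$lsc_len + layout$ir_len + layout$ssc_len)
  out <- plastome_record(record$id, newseq, TRUE, newfeats)
  list(record = out,
       log = data.frame(mechanism = mechanism, extent = extent,
                        seg_start = seg_start, seg_end = ssc_end,
                        genes = paste(genes_log, collapse = ","),
                        stringsAsFactors = FALSE))
}

#' Random sequence with planted primitive tandem arrays
#'
#' A light-weight fixture generator: `n` non-overlapping perfect tandem
#' arrays with primitive units are planted in i.i.d. background, with
#' periodicity broken at both edges so each planted array is maximal.
#'
#' @param seed integer seed.
#' @param length sequence length.
#' @param n number of arrays.
#' @param unit_range,copy_range inclusive ranges to sample unit length and
#'   copy number from.
#' @return List with `seq` (character) and `truth` (`data.frame`: unit,
#'   unit_len, copies, start, end, total_len).
#' @export
simulate_tandem_genome <- function(seed, length = 20000L, n = 50L,
                                   unit_range = c(2L, 30L),
                                   copy_range = c(2L, 6L)) {
  set.seed(seed)
  s <- random_dna(length, 0.378)
  slot_w <- length %/% n
  rows <- list()
  for (i in seq_len(n)) {
    u <- sample(unit_range[1]:unit_range[2], 1L)
    cp <- sample(copy_range[1]:copy_range[2], 1L)
    lo <- (i - 1L) * slot_w + 2L
    hi <- i * slot_w - 1L
    if (hi - lo + 1L < u * cp + 2L) { u <- 2L; cp <- 2L }
    a <- lo + sample.int(hi - lo - u * cp, 1L)
    repeat {
      unit <- random_dna(u, 0.378)
      if (is_primitive_unit(unit)) break
    }
    arr <- strrep(unit, cp)
    s <- str_write(s, a, arr)
    b <- a + u * cp - 1L
    s <- str_write(s, a - 1L, other_base(substring(unit, u, u)))
    nxt <- (b + 1L - a) %% u + 1L
    s <- str_write(s, b + 1L, other_base(substring(unit, nxt, nxt)))
    rows[[i]] <- data.frame(unit = unit, unit_len = u, copies = cp,
                            start = a, end = b, total_len = u * cp,
                            stringsAsFactors = FALSE)
  }
  list(seq = s, truth = do.call(rbind, rows))
}

#' Simulate the two-event Type C history against its Type A ancestor
#'
#' Reproduces the inferred history of the most derived junction type as a
#' checkable construction: (1) a long DSB-style expansion incorporates the
#' SSC portion of *ycf1*, *rps15* and 592 bp of *ndhH* into the IR, the
#' stranded *ndhH* remnant eroding; (2) the degraded *ndhA*--remnant block
#' is lost from the SSC; (3) a short gene-conversion-style expansion
#' incorporates a further 45 bp of the exposed intergenic spacer. The
#' ancestor and the derived genome are returned with the planted event
#' sizes, most recent first (their 5' to 3' order along IRa).
#'
#' @param seed integer seed.
#' @param second_extent size of the short second expansion (default 45 bp).
#' @return List: `ancestor`, `derived` (both [plastome_record()]s) and
#'   `truth` (`event_sizes`, `dsb_extent`).
#' @export
simulate_type_c_two_events <- function(seed, second_extent = 45L) {
  b <- build_plastome(synth_spec(seed = seed, jsa_type = "A"))
  anc <- b$record
  lay <- list(lsc_len = b$truth$regions$lsc_len,
              ir_len = b$truth$regions$ir_len,
              ssc_len = b$truth$regions$ssc_len)
  ndhH <- Filter(function(f) f$name == "ndhH", anc$features)[[1]]
  ssc_end <- lay$lsc_len + lay$ir_len + lay$ssc_len
  cut <- ndhH$exons[[1]]$end - 592L + 1L
  ext1 <- ssc_end - cut + 1L
  e1 <- apply_ir_expansion(anc, "dsb_long", ext1, erode_remnant = TRUE,
                           layout = lay)
  rec <- e1$record
  # SSC degradation: lose ndhA, its spacers and the eroded ndhH remnant
  ndhA <- Filter(function(f) f$name == "ndhA", rec$features)[[1]]
  new_ssc_end <- lay$lsc_len + lay$ir_len + lay$ssc_len  # unchanged absolute
  rec <- delete_region(rec, interval(ndhA$exons[[1]]$start, new_ssc_end))
  deleted <- new_ssc_end - ndhA$exons[[1]]$start + 1L
  lay2 <- list(lsc_len = lay$lsc_len, ir_len = lay$ir_len + ext1,
               ssc_len = lay$ssc_len - ext1 - deleted)
  e2 <- apply_ir_expansion(rec, "gene_conversion_short", second_extent,
                           erode_remnant = FALSE, layout = lay2)
  # boundary slack: where the ancestor sequence after the short segment's
  # donor happens to equal the first bases of the DSB segment, the event
  # boundary is collinearly ambiguous and any reconstruction will place it
  # after the shared prefix; the truth records that realised boundary
  aw <- charToRaw(anc$seq)
  ndhA_anc <- ndhA$exons[[1]]$start - ext1   # back to ancestor coordinates
  k <- 0L
  while (aw[ndhA_anc + k] == aw[cut + k]) k <- k + 1L
  list(ancestor = anc, derived = e2$record,
       truth = list(event_sizes = c(second_extent + k, ext1 - k),
                    dsb_extent = ext1, boundary_slack = k))
}

#' Simulate a repeat-mediated Type B expansion against its Type A ancestor
#'
#' Plants a short inverted repeat pair (17 bp, 1 mismatch) with one copy
#' near the future junction position and one near the current J_SA --
#' inside *ycf1*, as observed in real Type B plastomes -- then applies the
#' expansion. The planted pair survives in the derived genome on both
#' sides of the incorporated segment, so event reconstruction can label
#' the expansion repeat-mediated.
#'
#' @param seed integer seed.
#' @param extent expansion size (default 1,600 bp: from about 1,000 to
#'   about 2,600 bp of *ycf1* in IRa).
#' @return List: `ancestor`, `derived`, `truth` (`extent`, `repeat_pair`).
#' @export
simulate_type_b_expansion <- function(seed, extent = 1600L) {
  b <- build_plastome(synth_spec(seed = seed, jsa_type = "A"))
  rec0 <- b$record
  lay <- list(lsc_len = b$truth$regions$lsc_len,
              ir_len = b$truth$regions$ir_len,
              ssc_len = b$truth$regions$ssc_len)
  ssc_end <- lay$lsc_len + lay$ir_len + lay$ssc_len
  outer <- ssc_end - extent        # future junction: SSC side base
  len <- 17L
  ycf <- Filter(function(f) f$name == "ycf1" && !f$pseudo_flag, rec0$features)[[1]]
  planted <- NULL
  for (try in 1:50) {
    core <- random_dna(len, 0.378)
    mut <- core
    q <- sample(3:(len - 2L), 1L)
    substr(mut, q, q) <- other_base(substring(mut, q, q))
    p1 <- outer - 60L - len
    p2 <- ssc_end - 60L - len
    g <- rec0$seq
    g <- str_write(g, p1, core)
    g <- str_write(g, p2, reverse_complement(mut))
    for (o in 1:9) {
      g <- str_write(g, p2 - o,
                     other_base(comp_base(substring(g, p1 + len - 1L + o,
                                                    p1 + len - 1L + o))))
      g <- str_write(g, p2 + len - 1L + o,
                     other_base(comp_base(substring(g, p1 - o, p1 - o))))
    }
    cand <- plastome_record(rec0$id, g, TRUE, rec0$features)
    if (!is_intact_cds(extract_feature_sequence(cand, ycf))) next
    w1 <- interval(outer - 500L, outer + 500L)
    w2 <- interval(ssc_end - 500L, ssc_end + 500L)
    got <- scan_short_repeats(cand, windows = list(w1, w2))
    if (nrow(got) == 1L && got$direction == "inverted" &&
        got$start1 == p1 && got$start2 == p2) {
      planted <- list(rec = cand, p1 = p1, p2 = p2, mismatches = 1L)
      break
    }
  }
  if (is.null(planted)) stop("failed to plant the mediating repeat cleanly")
  e <- apply_ir_expansion(planted$rec, "dsb_long", extent,
                          erode_remnant = FALSE, layout = lay)
  list(ancestor = planted$rec, derived = e$record,
       truth = list(extent = extent,
                    repeat_pair = data.frame(start1 = planted$p1,
                                             start2 = planted$p2,
                                             length = len, mismatches = 1L)))
}
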