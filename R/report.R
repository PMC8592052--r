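#' One-row comparative summary of a plastome
#'
#' Orchestrates partitioning, junction typing, gene-status classification
#' and tandem-repeat scanning into a single comparison-table row (total and
#' LSC/SSC/IR lengths, GC%, tandem counts, intact/pseudogene/lost counts,
#' tRNA/rRNA counts, J_SA type). When partitioning fails the structural
#' fields carry `NA` and `no_ir = TRUE`; sequence-level fields are still
#' computed.
#'
#' @param record a [plastome_record()].
#' @param panel optional [build_reference_panel()]; defaults to a panel
#'   built from the record itself (self-referential: lesions detectable
#'   only against other samples then go unseen).
#' @param min_ir_len,ab_threshold,tandem_unit_max tunables passed through.
#' @return One-row `data.frame` with a frozen column order.
#' @export
summarize_plastome <- function(record, panel = NULL, min_ir_len = 1000L,
                               ab_threshold = 2000L, tandem_unit_max = 1000L) {
  map <- detect_quadripartite(record, min_ir_len = min_ir_len)
  # sequence-level scans run in the canonical frame so that summaries are
  # identical across rotations/flips of the same circular molecule
  scan_rec <- if (map$found) canonicalize_plastome(record, map) else record
  tan <- scan_tandem_repeats(scan_rec, unit_max = tandem_unit_max)
  has_genes <- length(record$features) > 0L
  if (has_genes && is.null(panel))
    panel <- suppressWarnings(build_reference_panel(list(record)))
  counts <- if (has_genes) status_matrix(list(record), panel)$counts else NULL
  jsa <- if (map$found && has_genes)
    classify_jsa(junction_profiles(map, record)$J_SA, map, record,
                 ab_threshold = ab_threshold) else NULL
  kind_count <- function(kind) {
    fs <- Filter(function(f) f$kind == kind, record$features)
    c(total = length(fs), unique = length(unique(vapply(fs, function(f) f$name, ""))))
  }
  trna <- kind_count("tRNA"); rrna <- kind_count("rRNA")
  data.frame(
    sample = record$id,
    total_len = record$length,
    lsc_len = if (map$found) map$lsc_len else NA_integer_,
    ssc_len = if (map$found) map$ssc_len else NA_integer_,
    ir_len = if (map$found) map$ir_len else NA_integer_,
    no_ir = !map$found,
    gc_percent = gc_content(record$seq),
    tandem_count = tan$summary$count,
    tandem_total_bp = tan$summary$total_bp,
    tandem_percent = round(tan$summary$percent_of_genome, 2),
    intact_total = if (has_genes) counts$intact_total else NA_integer_,
    intact_unique = if (has_genes) counts$intact_unique else NA_integer_,
    pseudogene = if (has_genes) counts$pseudogene else NA_integer_,
    lost = if (has_genes) counts$lost else NA_integer_,
    uncertain = if (has_genes) counts$uncertain else NA_integer_,
    trna_total = trna[["total"]], trna_unique = trna[["unique"]],
    rrna_total = rrna[["total"]], rrna_unique = rrna[["unique"]],
    jsa_type = if (!is.null(jsa)) jsa$type else NA_character_,
    ycf1_bp_in_ira = if (!is.null(jsa)) jsa$ycf1_bp_in_ira else NA_integer_,
    stringsAsFactors = FALSE)
}

#' Extract per-gene CDS sets shared (intact) across all samples
#'
#' A gene is shared when it is classified intact in every record; its
#' unaligned CDS sequences (one per sample, IR duplicates emitted once) are
#' returned per gene, ready for external alignment and phylogenetics.
#' Genes that are pseudogenised, lost or uncertain in any sample are
#' excluded.
#'
#' @param records list of (at least 2) [plastome_record()]s.
#' @param panel optional [build_reference_panel()].
#' @param out_dir optional directory; when given, one FASTA per gene is
#'   written there.
#' @return List with `shared_genes` (character) and `sequences` (named list
#'   of per-sample named character vectors).
#' @export
extract_shared_cds <- function(records, panel = NULL, out_dir = NULL) {
  stopifnot(length(records) >= 2L)
  if (is.null(panel)) panel <- build_reference_panel(records)
  sm <- status_matrix(records, panel)$statuses
  shared <- names(panel)[vapply(names(panel), function(g)
    all(sm$status[sm$gene == g] == "intact"), TRUE)]
  seqs <- lapply(shared, function(g) {
    out <- vapply(records, function(r) {
      feats <- Filter(function(f) f$kind == "CDS" && f$name == g &&
                        !f$pseudo_flag, r$features)
      extract_feature_sequence(r, feats[[1]])
    }, "")
    names(out) <- vapply(records, function(r) r$id, "")
    out
  })
  names(seqs) <- shared
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (g in shared)
      write_fasta(seqs[[g]], file.path(out_dir, paste0(g, ".fasta")))
  }
  list(shared_genes = shared, sequences = seqs)
}

#' Plain-text rendering of the SSC junctions (J_SB, J_SA)
#'
#' Deterministic fixed-width diagram of the two IR--SSC junctions with the
#' spanning gene's bp decomposition and the genes held wholly in the IR;
#' pseudogenes are marked with ψ.
#'
#' @param record a [plastome_record()].
#' @param map a found [detect_quadripartite()] result.
#' @return Character vector of diagram lines (also printed invisibly).
#' @export
junction_diagram <- function(record, map) {
  prof <- junction_profiles(map, record)
  line <- function(jn, left, right) {
    p <- prof[[jn]]
    g <- if (is.na(p$overlapping_gene)) "|" else
      sprintf("%s%s", if (isTRUE(p$gene_pseudo)) "ψ" else "", p$overlapping_gene)
    desc <- if (is.na(p$overlapping_gene))
      sprintf("%s  %s ]========[ %s   no spanning gene", jn, left, right)
    else
      sprintf("%s  %s ]===%s===[ %s   %d bp in IR | %d bp in SC",
              jn, left, g, right, p$bp_in_ir, p$bp_in_sc)
    extras <- p$genes_fully_in_ir_adjacent
    extras <- extras[!extras %in% c(g)]
    if (length(extras) > 0L)
      desc <- paste0(desc, "   [in IR: ", paste(extras, collapse = ", "), "]")
    desc
  }
  out <- c(sprintf("junction structure of %s (LSC %d | IR %d | SSC %d)",
                   record$id, map$lsc_len, map$ir_len, map$ssc_len),
           line("J_SB", "IRb", "SSC"),
           line("J_SA", "SSC", "IRa"))
  out
}

#' Write a data.frame as TSV
#'
#' @param df data.frame.
#' @param path output file.
#' @export
write_tsv_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
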