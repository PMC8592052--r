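#' Read a GenBank flat file into plastome records
#'
#' A minimal reader for LOCUS/FEATURES/ORIGIN blocks. `CDS`, `tRNA` and
#' `rRNA` features are captured with strand, join-exons, `/gene`,
#' `/codon_start` and `/pseudo`; the circular flag is taken from the LOCUS
#' line. Within a `join(...)`, an element ending at the sequence length
#' followed by one starting at 1 is interpreted as a single origin-wrapping
#' exon.
#'
#' @param path GenBank flat file (may hold several records separated by `//`).
#' @return List of [plastome_record()]s.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    while (i <= n && !startsWith(lines[i], "LOCUS")) {
      if (nchar(trimws(lines[i])) > 0L)
        stop(sprintf("GenBank parse error at line %d: expected LOCUS, got '%s'",
                     i, lines[i]))
      i <- i + 1L
    }
    if (i > n) break
    locus <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(locus) < 3L || is.na(suppressWarnings(as.integer(locus[3]))))
      stop(sprintf("GenBank parse error at line %d: malformed LOCUS line", i))
    id <- locus[2]
    declared_len <- as.integer(locus[3])
    circular <- any(tolower(locus) == "circular")
    i <- i + 1L
    # skip to FEATURES
    while (i <= n && !startsWith(lines[i], "FEATURES") &&
           !startsWith(lines[i], "ORIGIN")) i <- i + 1L
    feat_lines <- character()
    if (i <= n && startsWith(lines[i], "FEATURES")) {
      i <- i + 1L
      while (i <= n && !startsWith(lines[i], "ORIGIN") &&
             !startsWith(lines[i], "//")) {
        feat_lines <- c(feat_lines, lines[i])
        i <- i + 1L
      }
    }
    if (i > n || !startsWith(lines[i], "ORIGIN"))
      stop(sprintf("GenBank parse error near line %d: ORIGIN block missing", i))
    i <- i + 1L
    seq_chunks <- character()
    while (i <= n && !startsWith(lines[i], "//")) {
      seq_chunks <- c(seq_chunks, gsub("[^A-Za-z]", "", lines[i]))
      i <- i + 1L
    }
    i <- i + 1L  # past //
    seq <- toupper(paste(seq_chunks, collapse = ""))
    if (nchar(seq) != declared_len)
      warning(sprintf("record '%s': LOCUS declares %d bp but ORIGIN holds %d",
                      id, declared_len, nchar(seq)))
    feats <- parse_feature_table(feat_lines, nchar(seq))
    recs[[length(recs) + 1L]] <- plastome_record(id, seq, circular, feats)
  }
  recs
}

parse_feature_table <- function(feat_lines, L) {
  # group raw lines into features: a new feature starts with a key in col 6
  feats <- list()
  cur_key <- NULL; cur_loc <- ""; cur_quals <- character()
  flush <- function() {
    if (is.null(cur_key)) return()
    if (cur_key %in% c("CDS", "tRNA", "rRNA")) {
      feats[[length(feats) + 1L]] <<- build_feature(cur_key, cur_loc, cur_quals, L)
    }
  }
  for (ln in feat_lines) {
    if (grepl("^ {5}\\S", ln)) {
      flush()
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      cur_key <- parts[1]
      cur_loc <- if (length(parts) > 1L) paste(parts[-1], collapse = "") else ""
      cur_quals <- character()
    } else {
      x <- trimws(ln)
      if (startsWith(x, "/")) cur_quals <- c(cur_quals, x)
      else if (length(cur_quals) == 0L) cur_loc <- paste0(cur_loc, x)
      else cur_quals[length(cur_quals)] <- paste0(cur_quals[length(cur_quals)], x)
    }
  }
  flush()
  feats
}

build_feature <- function(key, loc, quals, L) {
  strand <- if (grepl("complement", loc)) "-" else "+"
  inner <- gsub("complement\\(|join\\(|order\\(|\\)", "", loc)
  inner <- gsub("[<>]", "", inner)
  elems <- strsplit(inner, ",")[[1]]
  ivs <- lapply(elems, function(e) {
    m <- regmatches(e, regexec("^(\\d+)(?:\\.\\.(\\d+))?$", e))[[1]]
    if (length(m) == 0L) stop(sprintf("cannot parse location element '%s'", e))
    s <- as.integer(m[2]); en <- if (m[3] == "") s else as.integer(m[3])
    c(s, en)
  })
  # merge tail+head pairs into wrapping exons
  exons <- list(); j <- 1L
  while (j <= length(ivs)) {
    if (j < length(ivs) && ivs[[j]][2] == L && ivs[[j + 1L]][1] == 1L) {
      exons[[length(exons) + 1L]] <- interval(ivs[[j]][1], ivs[[j + 1L]][2], wraps = TRUE)
      j <- j + 2L
    } else {
      exons[[length(exons) + 1L]] <- interval(ivs[[j]][1], ivs[[j]][2])
      j <- j + 1L
    }
  }
  getq <- function(name) {
    hit <- grep(sprintf("^/%s=", name), quals, value = TRUE)
    if (length(hit) == 0L) return(NULL)
    gsub('"', "", sub(sprintf("^/%s=", name), "", hit[1]))
  }
  gene_feature(name = getq("gene") %||% paste0(key, "_unnamed"),
               kind = key, strand = strand, exons = exons,
               codon_start = as.integer(getq("codon_start") %||% "1"),
               pseudo_flag = any(quals == "/pseudo"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write plastome records as a GenBank flat file
#'
#' Emits LOCUS/FEATURES/ORIGIN blocks that [read_genbank()] reads back
#' losslessly (sequence, feature count, strands and exon intervals).
#'
#' @param records a [plastome_record()] or list of them.
#' @param path output file.
#' @export
write_genbank <- function(records, path) {
  if (inherits(records, "plastome_record")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    L <- rec$length
    writeLines(sprintf("LOCUS       %s %d bp    DNA     %s PLN 01-JAN-2000",
                       rec$id, L, if (rec$circular) "circular" else "linear"), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", L), con)
    for (f in rec$features) {
      elems <- unlist(lapply(f$exons, function(ex) {
        if (ex$wraps) c(sprintf("%d..%d", ex$start, L), sprintf("1..%d", ex$end))
        else sprintf("%d..%d", ex$start, ex$end)
      }))
      loc <- if (length(elems) > 1L) sprintf("join(%s)", paste(elems, collapse = ","))
             else elems
      if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     %-15s %s", f$kind, loc), con)
      writeLines(sprintf('                     /gene="%s"', f$name), con)
      if (f$kind == "CDS")
        writeLines(sprintf("                     /codon_start=%d", f$codon_start), con)
      if (f$pseudo_flag)
        writeLines("                     /pseudo", con)
    }
    writeLines("ORIGIN", con)
    s <- tolower(rec$seq)
    starts <- seq(1L, L, by = 60L)
    for (st in starts) {
      chunk <- substring(s, st, min(st + 59L, L))
      tens <- substring(chunk, seq(1, nchar(chunk), 10), pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      writeLines(sprintf("%9d %s", st, paste(tens, collapse = " ")), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

#' Read a FASTA file into (annotation-free) plastome records
#'
#' @param path FASTA file.
#' @param circular treat sequences as circular? Default `TRUE` (plastomes).
#' @return List of [plastome_record()]s with empty feature lists.
#' @export
read_fasta_plastome <- function(path, circular = TRUE) {
  ss <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(ss), function(i) {
    plastome_record(strsplit(names(ss)[i], "\\s+")[[1]][1],
                    as.character(ss[[i]]), circular = circular)
  })
}

#' Write named sequences to FASTA
#'
#' @param seqs named character vector or list of nucleotide strings.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
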