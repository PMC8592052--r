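#!/usr/bin/env Rscript
# Optional helper: download the deposited plastome GenBank records into
# tests/testthat/accessions/ so the accession-gated tests can run. Nothing
# in the package depends on this script; it needs network access.
# Usage: Rscript scripts/fetch_accessions.R [outdir]

args <- commandArgs(trailingOnly = TRUE)
outdir <- if (length(args) >= 1) args[1] else "tests/testthat/accessions"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

accessions <- c("MN539611", "MN539612", "MN539613", "MN539614", "MN539615",
                "MH706763")
base <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
               "?db=nuccore&rettype=gbwithparts&retmode=text&id=")
for (acc in accessions) {
  dest <- file.path(outdir, paste0(acc, ".gb"))
  if (file.exists(dest)) next
  message("fetching ", acc)
  utils::download.file(paste0(base, acc), dest, quiet = TRUE, mode = "wb")
  Sys.sleep(0.5)
}
message("done; files in ", outdir)
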