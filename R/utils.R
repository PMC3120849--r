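#' @keywords internal
"_PACKAGE"

#' @importFrom stats as.dist cor cutree hclust median p.adjust phyper
#'   rbinom rlnorm rmultinom sd setNames
#' @importFrom utils read.delim write.table
NULL

TAG_LEN <- 21L
ANCHOR <- "CATG"

## Reverse complement for plain uppercase DNA character vectors.
## Biostrings handles file I/O; for tight inner loops on short strings a
## chartr round-trip is faster than DNAStringSet construction.
revcomp <- function(x) {
  out <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(out, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

assert_dna <- function(seqs, ids, allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, seqs)
  if (any(bad)) {
    stop("sequence for record '", ids[which(bad)[1]],
         "' contains characters outside {A,C,G,T",
         if (allow_n) ",N", "}", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a transcriptome from a FASTA file
#'
#' Reads a multi-FASTA of transcript (Unigene) sequences, given in sense
#' (5'->3') orientation, into the plain data frame the tag-library builder
#' consumes.
#'
#' @param path Path to a (possibly multi-record) FASTA file.
#' @return A data frame with columns `gene_id`, `sequence` (uppercase) and
#'   `length`.
#' @export
read_transcriptome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  data.frame(gene_id = ids,
             sequence = toupper(as.character(ss)),
             length = Biostrings::width(ss),
             stringsAsFactors = FALSE)
}

#' Read raw tag reads from a FASTQ file
#'
#' Quality strings are ignored: tag filtering is purely sequence-based
#' (N content, length, copy number), so only the read sequences are kept.
#'
#' @param path Path to a FASTQ file of raw tag reads (nominally 35 nt).
#' @return Character vector of uppercase read sequences.
#' @export
read_tag_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  unname(toupper(as.character(ss)))
}

#' Write tag reads to a FASTQ file
#'
#' Emits a minimal FASTQ with constant maximal quality ("I"), since the
#' cleaning pipeline never consults qualities.
#'
#' @param reads Character vector of read sequences.
#' @param path Output path.
#' @param prefix Read-name prefix.
#' @return Invisibly, `path`.
#' @export
write_tag_fastq <- function(reads, path, prefix = "read") {
  n <- length(reads)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (n > 0) {
    recs <- paste0("@", prefix, seq_len(n), "\n", reads, "\n+\n",
                   strrep("I", nchar(reads)))
    writeLines(recs, con)
  }
  invisible(path)
}

#' Write a data frame as a tab-separated file
#'
#' @param x Data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
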