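#' Build the virtual reference tag library
#'
#' Enumerates every possible 21-nt tag (the CATG anchor plus 17 downstream
#' bases, the NlaIII/MmeI geometry) on both strands of every transcript,
#' and flags tag sequences occurring in more than one gene as ambiguous.
#' Antisense placements are reported in sense-strand coordinates so that
#' sense and antisense tags of a transcript can be joined positionally.
#'
#' CATG sites with fewer than 17 downstream bases produce no tag (the MmeI
#' cut requires the full 17-base extension), and candidate tags containing
#' N are dropped: clean sequencing tags can never contain N, so such
#' reference tags are unreachable. All sites are indexed, not only the
#' 3'-most one; the bead-capture bias towards the 3'-most site is a
#' property of the wet protocol and is modelled in the read simulator
#' instead.
#'
#' @param transcripts Data frame with columns `gene_id` (unique) and
#'   `sequence` (uppercase DNA over A,C,G,T,N), e.g. from
#'   [read_transcriptome_fasta()].
#' @return An object of class `tag_library`: a list with
#'   \describe{
#'     \item{placements}{data frame `tag_sequence`, `gene_id`, `strand`
#'       ("sense"/"antisense"), `offset` (0-based start of the CATG on the
#'       sense strand), `ambiguous`.}
#'     \item{n_reference_tags}{distinct tag sequences (both strands).}
#'     \item{n_unambiguous}{distinct tag sequences confined to one gene.}
#'     \item{genes_with_site}{genes with at least one sense tag.}
#'     \item{n_transcripts}{number of input transcripts.}
#'   }
#' @examples
#' tx <- data.frame(gene_id = "g1", sequence = "AACATGACGTACGTACGTACGTAGG")
#' lib <- build_tag_library(tx)
#' lib$placements
#' @export
build_tag_library <- function(transcripts) {
  stopifnot(is.data.frame(transcripts),
            all(c("gene_id", "sequence") %in% names(transcripts)))
  if (nrow(transcripts) == 0) stop("empty transcriptome", call. = FALSE)
  if (anyDuplicated(transcripts$gene_id)) {
    stop("duplicate gene_id: ",
         transcripts$gene_id[duplicated(transcripts$gene_id)][1],
         call. = FALSE)
  }
  seqs <- toupper(transcripts$sequence)
  assert_dna(seqs, transcripts$gene_id)

  scan_strand <- function(seqv) {
    hits <- gregexpr(ANCHOR, seqv, fixed = TRUE)
    lens <- nchar(seqv)
    res <- vector("list", length(seqv))
    for (i in seq_along(seqv)) {
      pos <- hits[[i]]
      pos <- pos[pos > 0]
      pos <- pos[pos + TAG_LEN - 1L <= lens[i]]
      if (length(pos)) {
        res[[i]] <- data.frame(
          row = i,
          start = pos,  # 1-based start on the scanned strand
          tag = substring(seqv[i], pos, pos + TAG_LEN - 1L),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, res[lengths(res) > 0])
  }

  sense <- scan_strand(seqs)
  rcs <- revcomp(seqs)
  anti <- scan_strand(rcs)

  mk <- function(df, strand) {
    if (is.null(df) || nrow(df) == 0) {
      return(data.frame(tag_sequence = character(), gene_id = character(),
                        strand = character(), offset = integer(),
                        stringsAsFactors = FALSE))
    }
    L <- nchar(seqs)[df$row]
    offset <- if (strand == "sense") df$start - 1L else L - TAG_LEN - (df$start - 1L)
    data.frame(tag_sequence = df$tag,
               gene_id = transcripts$gene_id[df$row],
               strand = strand,
               offset = as.integer(offset),
               stringsAsFactors = FALSE)
  }
  pl <- rbind(mk(sense, "sense"), mk(anti, "antisense"))
  pl <- pl[!grepl("N", pl$tag_sequence, fixed = TRUE), , drop = FALSE]
  rownames(pl) <- NULL

  if (nrow(pl)) {
    genes_per_tag <- tapply(pl$gene_id, pl$tag_sequence,
                            function(g) length(unique(g)))
    pl$ambiguous <- unname(genes_per_tag[pl$tag_sequence] > 1L)
    n_ref <- length(genes_per_tag)
    n_unamb <- sum(genes_per_tag == 1L)
    genes_with_site <- length(unique(pl$gene_id[pl$strand == "sense"]))
  } else {
    pl$ambiguous <- logical(0)
    n_ref <- 0L
    n_unamb <- 0L
    genes_with_site <- 0L
  }

  structure(list(placements = pl,
                 n_reference_tags = as.integer(n_ref),
                 n_unambiguous = as.integer(n_unamb),
                 genes_with_site = as.integer(genes_with_site),
                 n_transcripts = nrow(transcripts)),
            class = "tag_library")
}

#' @export
print.tag_library <- function(x, ...) {
  cat("Virtual reference tag library\n")
  cat("  transcripts:            ", x$n_transcripts, "\n")
  cat("  distinct reference tags:", x$n_reference_tags, "\n")
  cat("  unambiguous tags:       ", x$n_unambiguous, "\n")
  cat("  genes with CATG site:   ", x$genes_with_site, "\n")
  invisible(x)
}

#' Summarise a reference tag library
#'
#' Reports the distinct/unambiguous reference tag counts and the fraction
#' of genes carrying at least one CATG tag site, both overall and
#' sense-strand-only (the two conventions differ and publications rarely
#' say which they use, so both are reported).
#'
#' @param library A `tag_library` from [build_tag_library()].
#' @param n_transcripts Number of transcripts the library was built from;
#'   defaults to the count recorded in the library.
#' @return A list with `n_reference_tags`, `n_unambiguous`,
#'   `fraction_unambiguous`, `genes_with_site`, `fraction_genes_with_site`,
#'   and the sense-strand-only counts `n_sense_tags`,
#'   `n_sense_unambiguous`.
#' @export
library_summary <- function(library, n_transcripts = library$n_transcripts) {
  stopifnot(inherits(library, "tag_library"))
  pl <- library$placements
  if (nrow(pl)) {
    sense_tags <- unique(pl$tag_sequence[pl$strand == "sense"])
    genes_per_tag <- tapply(pl$gene_id, pl$tag_sequence,
                            function(g) length(unique(g)))
    n_sense_unamb <- sum(genes_per_tag[sense_tags] == 1L)
  } else {
    sense_tags <- character(0)
    n_sense_unamb <- 0L
  }
  nref <- library$n_reference_tags
  list(
    n_reference_tags = nref,
    n_unambiguous = library$n_unambiguous,
    fraction_unambiguous = if (nref > 0) library$n_unambiguous / nref else 0,
    genes_with_site = library$genes_with_site,
    fraction_genes_with_site =
      if (n_transcripts > 0) library$genes_with_site / n_transcripts else 0,
    n_sense_tags = length(sense_tags),
    n_sense_unambiguous = as.integer(n_sense_unamb)
  )
}

#' Write a tag library to disk
#'
#' @param library A `tag_library`.
#' @param prefix Output path prefix; writes `<prefix>.tags.tsv` and, when
#'   the jsonlite package is available, `<prefix>.summary.json`.
#' @return Invisibly, the paths written.
#' @export
write_tag_library <- function(library, prefix) {
  stopifnot(inherits(library, "tag_library"))
  paths <- paste0(prefix, ".tags.tsv")
  write_tsv(library$placements, paths)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jp <- paste0(prefix, ".summary.json")
    jsonlite::write_json(library_summary(library), jp,
                         auto_unbox = TRUE, digits = NA)
    paths <- c(paths, jp)
  }
  invisible(paths)
}
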