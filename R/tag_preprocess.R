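#' Clean raw tag reads into 21-nt clean tags
#'
#' Applies, in order, the five standard DGE filtering rules to raw reads
#' (nominally 35 nt = 21-nt tag + 3' adaptor): (1) 3' adaptor removal,
#' (2) removal of empty (adaptor-only) reads, (3) removal of tags
#' containing N, (4) removal of tags that are not exactly 21 nt long or
#' are not CATG-anchored, (5) removal of tags with copy number 1
#' (probable sequencing error).
#'
#' Adaptor removal is positional: the tag occupies read positions 1-21
#' and the adaptor starts at position 22, so trimming keeps the first 21
#' bases and verifies that the remainder of the read matches a prefix of
#' the adaptor with at most one mismatch. A read whose start matches the
#' adaptor (again allowing one mismatch) is classed adaptor-only; a read
#' shorter than 21 nt, not starting with CATG, or whose tail fails the
#' adaptor check is classed bad_length. Every legitimate tag is
#' CATG-anchored by the NlaIII digest, so non-CATG reads are malformed by
#' construction.
#'
#' @param reads Character vector of raw read sequences (uppercase DNA,
#'   possibly containing N), or a path handled by [read_tag_fastq()]
#'   upstream.
#' @param adaptor 3' adaptor sequence (uppercase DNA, no N).
#' @return An object of class `clean_tag_set`: a list with
#'   \describe{
#'     \item{counts}{data frame `tag_sequence`, `count` (all >= 2),
#'       sorted by decreasing count.}
#'     \item{total_clean}{sum of clean-tag copy numbers (the TPM
#'       denominator).}
#'     \item{distinct_clean}{number of distinct clean tags.}
#'     \item{total_raw, distinct_raw}{raw totals; distinct_raw counts
#'       distinct 21-nt tag sequences before the copy-number filter.}
#'     \item{filter_stats}{reads removed per rule: `adaptor_only`,
#'       `contains_N`, `bad_length`, `singleton`.}
#'   }
#' @examples
#' adaptor <- "TCGTATGCCGTCTTCTGCTTG"
#' tag <- "CATGAAACCCGGGTTTACGTA"
#' reads <- c(rep(paste0(tag, substr(adaptor, 1, 14)), 2),
#'            substr(adaptor, 1, 21))
#' clean_raw_tags(reads, adaptor)
#' @export
clean_raw_tags <- function(reads, adaptor) {
  stopifnot(is.character(adaptor), length(adaptor) == 1, nzchar(adaptor))
  adaptor <- toupper(adaptor)
  if (grepl("N", adaptor, fixed = TRUE)) {
    stop("adaptor sequence must not contain N", call. = FALSE)
  }
  reads <- toupper(as.character(reads))
  n_raw <- length(reads)
  stats <- c(adaptor_only = 0L, contains_N = 0L, bad_length = 0L,
             singleton = 0L)
  empty <- function() {
    structure(list(counts = data.frame(tag_sequence = character(),
                                       count = integer()),
                   total_clean = 0L, distinct_clean = 0L,
                   total_raw = n_raw, distinct_raw = 0L,
                   filter_stats = stats),
              class = "clean_tag_set")
  }
  if (n_raw == 0) return(empty())

  mism_prefix <- function(x, ref) {
    ## mismatches between x and the same-length prefix of ref,
    ## vectorized position-by-position (<= nchar(ref) passes)
    k <- pmin(nchar(x), nchar(ref))
    out <- integer(length(x))
    maxk <- if (length(k)) max(k) else 0L
    if (maxk == 0L) return(out)
    refc <- substring(ref, seq_len(maxk), seq_len(maxk))
    for (j in seq_len(maxk)) {
      active <- k >= j
      out[active] <- out[active] +
        (substr(x[active], j, j) != refc[j])
    }
    out
  }

  ## rule 1+2: adaptor-only reads (the read starts with the adaptor)
  is_adaptor_only <- mism_prefix(reads, adaptor) <= 1L &
    !startsWith(reads, ANCHOR)
  stats["adaptor_only"] <- sum(is_adaptor_only)
  reads <- reads[!is_adaptor_only]

  ## rule 4a: too short to contain a full tag
  too_short <- nchar(reads) < TAG_LEN
  ## rule 1: positional trim -- tag is the first 21 bases
  tag <- substr(reads, 1L, TAG_LEN)
  tail_seq <- substr(reads, TAG_LEN + 1L, nchar(reads))
  bad_tail <- nchar(tail_seq) > 0L & mism_prefix(tail_seq, adaptor) > 1L
  not_anchored <- !startsWith(tag, ANCHOR)
  bad_len <- too_short | not_anchored | bad_tail
  has_n <- !bad_len & grepl("N", tag, fixed = TRUE)

  stats["contains_N"] <- sum(has_n)
  stats["bad_length"] <- sum(bad_len)
  tag <- tag[!(bad_len | has_n)]

  if (length(tag) == 0) return(empty())
  tab <- table(tag)
  distinct_raw <- length(tab)
  singletons <- tab == 1L
  stats["singleton"] <- sum(tab[singletons])
  tab <- tab[!singletons]
  counts <- data.frame(tag_sequence = names(tab),
                       count = as.integer(tab),
                       stringsAsFactors = FALSE)
  counts <- counts[order(-counts$count, counts$tag_sequence), , drop = FALSE]
  rownames(counts) <- NULL
  structure(list(counts = counts,
                 total_clean = sum(counts$count),
                 distinct_clean = nrow(counts),
                 total_raw = n_raw,
                 distinct_raw = distinct_raw,
                 filter_stats = stats),
            class = "clean_tag_set")
}

#' @export
print.clean_tag_set <- function(x, ...) {
  cat("Clean tag set\n")
  cat("  raw reads:        ", x$total_raw, "\n")
  cat("  clean tags total: ", x$total_clean, "\n")
  cat("  distinct clean:   ", x$distinct_clean, "\n")
  cat("  removed:", paste(names(x$filter_stats), x$filter_stats,
                          sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Construct a clean tag set from a pre-counted tag table
#'
#' For workflows starting from tag->count tables rather than raw reads.
#' The copy-number-1 rule is still applied.
#'
#' @param counts Data frame with columns `tag_sequence`, `count`.
#' @return A `clean_tag_set`.
#' @export
clean_tag_set_from_counts <- function(counts) {
  stopifnot(all(c("tag_sequence", "count") %in% names(counts)))
  counts$tag_sequence <- toupper(counts$tag_sequence)
  ok <- nchar(counts$tag_sequence) == TAG_LEN &
    startsWith(counts$tag_sequence, ANCHOR) &
    !grepl("N", counts$tag_sequence, fixed = TRUE)
  if (!all(ok)) {
    stop("tag table contains malformed tags, e.g. ",
         counts$tag_sequence[!ok][1], call. = FALSE)
  }
  total_raw <- sum(counts$count)
  distinct_raw <- nrow(counts)
  singles <- counts$count < 2L
  n_single <- sum(counts$count[singles])
  counts <- counts[!singles, c("tag_sequence", "count"), drop = FALSE]
  counts <- counts[order(-counts$count, counts$tag_sequence), , drop = FALSE]
  rownames(counts) <- NULL
  structure(list(counts = counts,
                 total_clean = sum(counts$count),
                 distinct_clean = nrow(counts),
                 total_raw = total_raw,
                 distinct_raw = distinct_raw,
                 filter_stats = c(adaptor_only = 0L, contains_N = 0L,
                                  bad_length = 0L,
                                  singleton = as.integer(n_single))),
            class = "clean_tag_set")
}

#' Tabulate tag copies over abundance categories
#'
#' Bins clean tags by copy number, reporting both the total tag copies
#' and the number of distinct tags per bin — the standard diagnostic for
#' the heavy-tailed abundance structure of DGE libraries (a few tags at
#' very high copy number, most tags rare).
#'
#' @param tags A `clean_tag_set`.
#' @param bin_lower Strictly increasing vector of lower copy-number
#'   bounds; each bin runs to the next bound minus one, the last bin is
#'   open-ended. The default reproduces the conventional categories
#'   `[1]`, `[2,5]`, `[6,10]`, `[11,20]`, `[21,50]`, `[51,100]`, `>100`.
#' @return Data frame `bin`, `lower`, `upper`, `total_copies`,
#'   `distinct_tags`, plus fraction columns.
#' @export
abundance_distribution <- function(tags,
                                   bin_lower = c(1, 2, 6, 11, 21, 51, 101)) {
  stopifnot(inherits(tags, "clean_tag_set"),
            all(diff(bin_lower) > 0), all(bin_lower >= 1))
  upper <- c(bin_lower[-1] - 1, Inf)
  lab <- ifelse(is.infinite(upper), paste0(">", bin_lower - 1),
                ifelse(bin_lower == upper, paste0("[", bin_lower, "]"),
                       paste0("[", bin_lower, ",", upper, "]")))
  cnt <- tags$counts$count
  idx <- findInterval(cnt, bin_lower)
  keep <- idx >= 1L  # counts below the first bound are not binned
  total <- vapply(seq_along(bin_lower),
                  function(b) sum(cnt[keep & idx == b]), numeric(1))
  distinct <- vapply(seq_along(bin_lower),
                     function(b) sum(keep & idx == b), numeric(1))
  data.frame(bin = lab, lower = bin_lower, upper = upper,
             total_copies = total, distinct_tags = distinct,
             frac_total = if (tags$total_clean > 0)
               total / tags$total_clean else 0,
             frac_distinct = if (tags$distinct_clean > 0)
               distinct / tags$distinct_clean else 0,
             stringsAsFactors = FALSE)
}
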