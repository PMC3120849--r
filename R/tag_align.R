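#' Map clean tags to a reference tag library
#'
#' Assigns each distinct clean tag to a gene by exact lookup in the
#' virtual reference tag library, falling back to a 1-mismatch search
#' when no exact hit exists. Exact matches always take priority over
#' mismatch matches, mismatches are allowed only in the 17 variable
#' bases (the CATG anchor is fixed by the restriction enzyme), and a tag
#' whose best-tier hits span more than one gene is filtered as
#' ambiguous. A tag hitting a single gene on both strands is counted as
#' sense.
#'
#' @param tags A `clean_tag_set` from [clean_raw_tags()], or a character
#'   vector of distinct 21-nt tags (then all copy numbers are taken as 1).
#' @param library A `tag_library` from [build_tag_library()].
#' @return Data frame with one row per distinct clean tag:
#'   `tag_sequence`, `count`, `status` (one of `perfect_unique`,
#'   `mismatch1_unique`, `ambiguous_multi_gene`, `unmapped`), `gene_id`
#'   (NA unless uniquely assigned), `strand`, `mismatch_count`.
#' @export
map_tags <- function(tags, library) {
  stopifnot(inherits(library, "tag_library"))
  if (inherits(tags, "clean_tag_set")) {
    tagseq <- tags$counts$tag_sequence
    count <- tags$counts$count
  } else {
    tagseq <- as.character(tags)
    count <- rep(1L, length(tagseq))
  }
  if (any(nchar(tagseq) != TAG_LEN)) {
    stop("all tags must be ", TAG_LEN, " nt; offending tag: ",
         tagseq[nchar(tagseq) != TAG_LEN][1], call. = FALSE)
  }
  pl <- library$placements
  if (nrow(pl) == 0) {
    return(data.frame(tag_sequence = tagseq, count = count,
                      status = rep("unmapped", length(tagseq)),
                      gene_id = NA_character_, strand = NA_character_,
                      mismatch_count = NA_integer_,
                      stringsAsFactors = FALSE))
  }

  ## per distinct reference tag: gene count, unique gene, sense presence
  key <- paste0(pl$tag_sequence, "\r", pl$gene_id)
  tg <- pl[!duplicated(key), c("tag_sequence", "gene_id", "strand")]
  sense_key <- unique(key[pl$strand == "sense"])
  ord <- order(tg$tag_sequence)
  tg <- tg[ord, ]
  rlx <- rle(tg$tag_sequence)
  lib_tags <- rlx$values
  lib_ngenes <- rlx$lengths
  first <- cumsum(c(1L, rlx$lengths[-length(rlx$lengths)]))
  lib_gene <- ifelse(lib_ngenes == 1L, tg$gene_id[first], NA_character_)
  ## for single-gene tags: does that (tag, gene) have a sense placement?
  lib_sense <- !is.na(lib_gene) &
    paste0(lib_tags, "\r", lib_gene) %in% sense_key

  n <- length(tagseq)
  status <- rep("unmapped", n)
  gene <- rep(NA_character_, n)
  strand <- rep(NA_character_, n)
  mm <- rep(NA_integer_, n)

  hit <- match(tagseq, lib_tags)
  exact <- !is.na(hit)
  multi <- exact & lib_ngenes[hit] > 1L
  uniq <- exact & !multi
  status[multi] <- "ambiguous_multi_gene"
  mm[multi] <- 0L
  status[uniq] <- "perfect_unique"
  gene[uniq] <- lib_gene[hit[uniq]]
  strand[uniq] <- ifelse(lib_sense[hit[uniq]], "sense", "antisense")
  mm[uniq] <- 0L

  ## 1-mismatch tier for tags without an exact hit
  todo <- which(!exact)
  if (length(todo)) {
    base_tags <- tagseq[todo]
    bases <- c("A", "C", "G", "T")
    var_rows <- integer(0)
    var_hits <- integer(0)
    for (p in (nchar(ANCHOR) + 1L):TAG_LEN) {
      orig <- substr(base_tags, p, p)
      left <- substr(base_tags, 1L, p - 1L)
      right <- substr(base_tags, p + 1L, TAG_LEN)
      for (b in bases) {
        sel <- orig != b
        if (!any(sel)) next
        v <- paste0(left[sel], b, right[sel])
        h <- match(v, lib_tags)
        ok <- !is.na(h)
        if (any(ok)) {
          var_rows <- c(var_rows, which(sel)[ok])
          var_hits <- c(var_hits, h[ok])
        }
      }
    }
    if (length(var_rows)) {
      ## per queried tag, union of genes over all 1-mismatch reference hits
      hit_tab <- data.frame(row = var_rows, lib = var_hits)
      by_row <- split(hit_tab$lib, hit_tab$row)
      for (rn in names(by_row)) {
        r <- as.integer(rn)
        libs <- by_row[[rn]]
        genes_here <- unique(tg$gene_id[unlist(lapply(libs, function(l)
          seq.int(first[l], length.out = lib_ngenes[l])))])
        i <- todo[r]
        if (length(genes_here) > 1L) {
          status[i] <- "ambiguous_multi_gene"
          mm[i] <- 1L
        } else {
          status[i] <- "mismatch1_unique"
          gene[i] <- genes_here
          mm[i] <- 1L
          keys <- paste0(lib_tags[libs], "\r", genes_here)
          strand[i] <- if (any(keys %in% sense_key)) "sense" else "antisense"
        }
      }
    }
  }

  data.frame(tag_sequence = tagseq, count = count, status = status,
             gene_id = gene, strand = strand, mismatch_count = mm,
             stringsAsFactors = FALSE)
}

#' Quantify per-gene expression from tag assignments
#'
#' Credits each uniquely assigned tag's full copy number to its gene and
#' strand, and normalises to TPM (transcripts per million clean tags).
#' Ambiguous and unmapped tags contribute nothing. The TPM denominator
#' is the library's total clean tag count, not the mapped count, per the
#' definition of the unit.
#'
#' @param assignments Data frame from [map_tags()].
#' @param total_clean Library total clean tags (the TPM denominator),
#'   e.g. `tags$total_clean`.
#' @param gene_ids Optional character vector giving the gene universe;
#'   genes without tags get zero rows. Defaults to the genes present in
#'   `assignments`.
#' @param library_id Label for the library (tissue) column.
#' @return Data frame `gene_id`, `library`, `sense_count`,
#'   `antisense_count`, `sense_tpm`, `antisense_tpm`, `total_clean`.
#' @export
count_expression <- function(assignments, total_clean, gene_ids = NULL,
                             library_id = "lib1") {
  if (is.null(total_clean) || total_clean <= 0) {
    stop("total_clean must be positive", call. = FALSE)
  }
  ok <- assignments$status %in% c("perfect_unique", "mismatch1_unique")
  a <- assignments[ok, , drop = FALSE]
  if (is.null(gene_ids)) gene_ids <- sort(unique(a$gene_id))
  sense <- setNames(rep(0, length(gene_ids)), gene_ids)
  anti <- sense
  if (nrow(a)) {
    s <- tapply(a$count[a$strand == "sense"], a$gene_id[a$strand == "sense"],
                sum)
    sense[names(s)] <- s
    t <- tapply(a$count[a$strand == "antisense"],
                a$gene_id[a$strand == "antisense"], sum)
    anti[names(t)] <- t
  }
  data.frame(gene_id = gene_ids,
             library = library_id,
             sense_count = as.numeric(sense),
             antisense_count = as.numeric(anti),
             sense_tpm = as.numeric(sense) / total_clean * 1e6,
             antisense_tpm = as.numeric(anti) / total_clean * 1e6,
             total_clean = total_clean,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Reads per kilobase of transcript per million mapped reads
#'
#' RPKM = 10^9 * C / (N * L), with C reads mapped to the gene, N total
#' mapped reads in the library and L the gene length in bases. Used for
#' full-length mRNA-seq reads, where tag-based TPM does not apply.
#'
#' @param C Reads mapped to the gene (vectorised).
#' @param N Total mapped reads in the library.
#' @param L Gene length in bases.
#' @return RPKM value(s).
#' @examples
#' compute_rpkm(1000, 1e6, 1000)  # 1000
#' @export
compute_rpkm <- function(C, N, L) {
  if (any(N <= 0)) stop("N must be positive", call. = FALSE)
  if (any(L <= 0)) stop("L must be positive", call. = FALSE)
  if (any(C < 0)) stop("C must be non-negative", call. = FALSE)
  1e9 * C / (N * L)
}

#' Summarise tag-to-gene mapping
#'
#' Reproduces the standard library-quality panel: total and distinct
#' clean tags mapped to genes (any status short of unmapped), the
#' unambiguous subset, and the number of genes detected by at least one
#' unambiguous sense tag.
#'
#' @param assignments Data frame from [map_tags()].
#' @param tags The `clean_tag_set` that was mapped.
#' @param n_ref_genes Number of genes in the reference transcriptome.
#' @return A list of counts and percentages (percentages on the 0-100
#'   scale).
#' @export
mapping_summary <- function(assignments, tags, n_ref_genes) {
  stopifnot(inherits(tags, "clean_tag_set"))
  mapped <- assignments$status != "unmapped"
  unamb <- assignments$status %in% c("perfect_unique", "mismatch1_unique")
  tot <- tags$total_clean
  dis <- tags$distinct_clean
  genes <- unique(assignments$gene_id[unamb & assignments$strand == "sense"])
  pct <- function(a, b) if (b > 0) 100 * a / b else 0
  list(
    all_mapped_total = sum(assignments$count[mapped]),
    all_mapped_pct = pct(sum(assignments$count[mapped]), tot),
    distinct_mapped = sum(mapped),
    distinct_mapped_pct = pct(sum(mapped), dis),
    unambiguous_total = sum(assignments$count[unamb]),
    unambiguous_distinct = sum(unamb),
    genes_detected = length(genes),
    genes_detected_pct = pct(length(genes), n_ref_genes)
  )
}

#' Saturation analysis of gene detection versus sequencing depth
#'
#' Subsamples the clean-tag multiset without replacement at increasing
#' depths and counts, at each depth, the genes detected by at least one
#' unambiguous sense tag. A single seeded permutation is used and depths
#' are taken as its prefixes, so the curve is non-decreasing by
#' construction and exactly reproducible.
#'
#' @param assignments Data frame from [map_tags()] (carries per-tag copy
#'   numbers and gene assignments).
#' @param n_points Number of evenly spaced depths (>= 2).
#' @param seed Integer seed for the subsampling permutation (required).
#' @return Data frame `tags_sampled`, `genes_detected`.
#' @export
saturation_analysis <- function(assignments, n_points = 10, seed) {
  stopifnot(n_points >= 2)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  informative <- assignments$status %in%
    c("perfect_unique", "mismatch1_unique") &
    assignments$strand == "sense"
  gene_per_copy <- rep(ifelse(informative, assignments$gene_id,
                              NA_character_),
                       assignments$count)
  total <- length(gene_per_copy)
  depths <- unique(round(seq(0, total, length.out = n_points + 1)))[-1]
  if (total == 0) {
    return(data.frame(tags_sampled = 0, genes_detected = 0L))
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  perm <- sample.int(total)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  g <- gene_per_copy[perm]
  firstpos <- which(!duplicated(g) & !is.na(g))
  data.frame(
    tags_sampled = depths,
    genes_detected = vapply(depths, function(d) sum(firstpos <= d),
                            integer(1)))
}

#' Map unassigned tags to auxiliary genomic sequences
#'
#' Exact-matches transcriptome-unmapped clean tags against genomic
#' sequences (for instance fosmid end sequences or a related species'
#' genome) on both strands, reporting tags that hit exactly one genomic
#' position as candidate novel transcripts. Multi-position hits are
#' flagged non-unique and excluded from the novel list.
#'
#' @param unmapped Character vector of unmapped 21-nt tag sequences, or
#'   an assignment data frame from [map_tags()] (rows with status
#'   `unmapped` are taken).
#' @param genomic Data frame with columns `gene_id` (or `target_id`) and
#'   `sequence`, e.g. from [read_transcriptome_fasta()].
#' @return Data frame `tag_sequence`, `target_id`, `position` (0-based
#'   start on the forward strand of the target), `strand`, `n_hits`,
#'   `unique`. Tags with no hit are omitted; tags with several hits get
#'   one row with NA coordinates and `unique = FALSE`.
#' @export
detect_novel_transcripts <- function(unmapped, genomic) {
  if (is.data.frame(unmapped)) {
    unmapped <- unmapped$tag_sequence[unmapped$status == "unmapped"]
  }
  unmapped <- unique(as.character(unmapped))
  idcol <- if ("target_id" %in% names(genomic)) "target_id" else "gene_id"
  subj <- Biostrings::DNAStringSet(toupper(genomic$sequence))
  names(subj) <- genomic[[idcol]]
  res <- vector("list", length(unmapped))
  for (i in seq_along(unmapped)) {
    tag <- unmapped[i]
    hits <- list()
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") tag else revcomp(tag)
      m <- Biostrings::vmatchPattern(pat, subj)
      starts <- Biostrings::startIndex(m)
      for (j in seq_along(starts)) {
        st <- starts[[j]]
        if (length(st)) {
          hits[[length(hits) + 1L]] <- data.frame(
            target_id = names(subj)[j],
            position = st - 1L,  # 0-based forward-strand start
            strand = strand, stringsAsFactors = FALSE)
        }
      }
    }
    if (!length(hits)) next
    h <- do.call(rbind, hits)
    if (nrow(h) == 1L) {
      res[[i]] <- data.frame(tag_sequence = tag, h, n_hits = 1L,
                             unique = TRUE, stringsAsFactors = FALSE)
    } else {
      res[[i]] <- data.frame(tag_sequence = tag, target_id = NA_character_,
                             position = NA_integer_, strand = NA_character_,
                             n_hits = nrow(h), unique = FALSE,
                             stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res[lengths(res) > 0])
  if (is.null(out)) {
    out <- data.frame(tag_sequence = character(), target_id = character(),
                      position = integer(), strand = character(),
                      n_hits = integer(), unique = logical(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
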