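#' Run the tag-profiling pipeline over several libraries
#'
#' Convenience wrapper chaining the standard stages for a set of raw
#' read libraries against one reference transcriptome: build the
#' virtual tag library, clean each library's reads, map clean tags with
#' at most one mismatch, and quantify per-gene sense/antisense counts
#' and TPM. Differential expression, antisense summaries, enrichment
#' and clustering are then run on the returned expression table with
#' [call_degs()], [antisense_table()], [enrich()] and
#' [build_pattern_matrix()].
#'
#' @param transcripts Transcriptome data frame (see
#'   [build_tag_library()]).
#' @param reads_by_library Named list of raw read character vectors,
#'   one per library (tissue).
#' @param adaptor 3' adaptor sequence.
#' @return A list with `library` (the `tag_library`), and per input
#'   library `clean` (`clean_tag_set`), `assignments`, `summary`
#'   ([mapping_summary()]), plus the combined `expression` table.
#' @export
run_dge_pipeline <- function(transcripts, reads_by_library, adaptor) {
  stopifnot(is.list(reads_by_library), length(reads_by_library) >= 1,
            !is.null(names(reads_by_library)))
  lib <- build_tag_library(transcripts)
  out <- list(library = lib, clean = list(), assignments = list(),
              summary = list())
  expr <- NULL
  for (lb in names(reads_by_library)) {
    cts <- clean_raw_tags(reads_by_library[[lb]], adaptor)
    asg <- map_tags(cts, lib)
    expr <- rbind(expr, count_expression(
      asg, cts$total_clean, gene_ids = transcripts$gene_id,
      library_id = lb))
    out$clean[[lb]] <- cts
    out$assignments[[lb]] <- asg
    out$summary[[lb]] <- mapping_summary(asg, cts,
                                         n_ref_genes = nrow(transcripts))
  }
  out$expression <- expr
  out
}
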