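#' Hypergeometric enrichment p-value
#'
#' Upper-tail hypergeometric probability used for GO-term and pathway
#' enrichment of a differentially-expressed gene set against an
#' annotated background:
#' \deqn{P = 1 - \sum_{i=0}^{m-1} \frac{\binom{M}{i}\binom{N-M}{n-i}}
#'   {\binom{N}{n}}}
#' with `N` annotated genes in the background, `n` DEGs among them, `M`
#' genes annotated to the term and `m` DEGs annotated to the term.
#' Computed in log space through [stats::phyper()].
#'
#' @param N,n,M,m Integer margins (vectorised); require `m <= min(n, M)`,
#'   `n <= N`, `M <= N`.
#' @return Upper-tail probability `P(X >= m)`.
#' @examples
#' hypergeom_p(N = 10, n = 5, M = 4, m = 3)  # 66/252
#' @export
hypergeom_p <- function(N, n, M, m) {
  k <- max(length(N), length(n), length(M), length(m))
  N <- rep_len(N, k); n <- rep_len(n, k)
  M <- rep_len(M, k); m <- rep_len(m, k)
  if (any(m > pmin(n, M)) || any(n > N) || any(M > N) ||
      any(c(N, n, M, m) < 0)) {
    stop("invalid margins: require 0 <= m <= min(n, M), n <= N, M <= N",
         call. = FALSE)
  }
  phyper(m - 1, M, N - M, n, lower.tail = FALSE)
}

#' Term enrichment of a DEG set against an annotated background
#'
#' Tests every annotation term for over-representation of
#' differentially expressed genes relative to the background, with the
#' upper-tail hypergeometric test and Benjamini-Hochberg q-values.
#' GO terms and pathways share this code path: the annotation is any
#' flat term-to-gene table (assumed pre-propagated; no ontology graph
#' handling). Terms with no background gene are skipped.
#'
#' @param deg_genes Character vector of DEG identifiers (must be a
#'   subset of `background`).
#' @param background Character vector of annotated background gene
#'   identifiers.
#' @param annotation Data frame with columns `term_id`, `gene_id` and
#'   optionally `term_name`. Genes outside the background are ignored.
#' @param q_cut Significance threshold on the q-value (default 0.05).
#' @return Data frame sorted by p-value: `term_id` (+ `term_name` when
#'   supplied), `N`, `n`, `M`, `m`, `p_value`, `q_value`, `significant`.
#' @export
enrich <- function(deg_genes, background, annotation, q_cut = 0.05) {
  deg_genes <- unique(as.character(deg_genes))
  background <- unique(as.character(background))
  missing_ids <- setdiff(deg_genes, background)
  if (length(missing_ids)) {
    stop("DEG gene absent from background: ", missing_ids[1],
         call. = FALSE)
  }
  stopifnot(all(c("term_id", "gene_id") %in% names(annotation)))
  ann <- annotation[annotation$gene_id %in% background, , drop = FALSE]
  if (nrow(ann) == 0) {
    return(data.frame(term_id = character(), N = integer(), n = integer(),
                      M = integer(), m = integer(), p_value = numeric(),
                      q_value = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  }
  N <- length(background)
  n <- length(deg_genes)
  key <- paste0(ann$term_id, "\r", ann$gene_id)
  ann <- ann[!duplicated(key), , drop = FALSE]
  M <- tapply(ann$gene_id, ann$term_id, length)
  is_deg <- ann$gene_id %in% deg_genes
  m <- tapply(is_deg, ann$term_id, sum)
  terms <- names(M)
  p <- hypergeom_p(N, n, as.integer(M), as.integer(m))
  q <- bh_fdr(p)
  out <- data.frame(term_id = terms, N = N, n = n,
                    M = as.integer(M), m = as.integer(m),
                    p_value = p, q_value = q,
                    significant = q <= q_cut,
                    stringsAsFactors = FALSE)
  if ("term_name" %in% names(annotation)) {
    nm <- annotation[!duplicated(annotation$term_id),
                     c("term_id", "term_name")]
    out$term_name <- nm$term_name[match(out$term_id, nm$term_id)]
    out <- out[, c("term_id", "term_name", "N", "n", "M", "m",
                   "p_value", "q_value", "significant")]
  }
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
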