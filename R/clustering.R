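#' Build a gene-by-comparison log2-ratio pattern matrix
#'
#' Assembles, from several pairwise differential-expression result
#' tables, the matrix clustered to find co-regulated expression
#' patterns: one row per gene, one column per tissue-pair comparison,
#' values the comparison's log2 ratio. `mode = "intersection"` keeps
#' genes significant in every comparison, `"union"` genes significant
#' in any. A retained gene absent from some comparison's table (zero
#' counts in both of its libraries) gets ratio 0, the value the
#' zero-substituted TPMs imply.
#'
#' @param deg_tables Named list (>= 2) of [call_degs()] results; names
#'   label the comparisons.
#' @param mode `"intersection"` or `"union"` of DEG sets.
#' @return Numeric matrix, rownames genes, colnames comparisons.
#' @export
build_pattern_matrix <- function(deg_tables,
                                 mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  stopifnot(is.list(deg_tables), length(deg_tables) >= 2)
  if (is.null(names(deg_tables))) {
    names(deg_tables) <- paste0("comparison", seq_along(deg_tables))
  }
  sig <- lapply(deg_tables, function(d)
    d$gene_id[d$call != "not_significant"])
  genes <- if (mode == "intersection") Reduce(intersect, sig)
           else Reduce(union, sig)
  if (length(genes) == 0) {
    stop("no genes retained under mode '", mode, "'", call. = FALSE)
  }
  genes <- sort(genes)
  mat <- sapply(deg_tables, function(d) {
    v <- d$log2_ratio[match(genes, d$gene_id)]
    v[is.na(v)] <- 0
    v
  })
  mat <- matrix(mat, nrow = length(genes),
                dimnames = list(genes, names(deg_tables)))
  mat
}

## Pairwise distance matrix for expression patterns.
## uncentered_correlation: 1 - sum(xy)/sqrt(sum(x^2) sum(y^2)), the
## default similarity of the Eisen Cluster program; pearson: 1 - cor.
## Rows with zero variance (pearson) or zero norm (uncentered) cannot be
## correlated and are pushed to the maximal distance 2 with a warning.
pattern_dist <- function(mat, distance) {
  n <- nrow(mat)
  if (distance == "uncentered_correlation") {
    norms <- sqrt(rowSums(mat^2))
    degenerate <- norms == 0
    cp <- tcrossprod(mat)
    denom <- tcrossprod(norms)
    sim <- ifelse(denom > 0, cp / denom, -1)
  } else {
    sds <- apply(mat, 1, stats::sd)
    degenerate <- sds == 0
    sim <- suppressWarnings(stats::cor(t(mat)))
    sim[!is.finite(sim)] <- -1
  }
  if (any(degenerate)) {
    warning(sum(degenerate), " constant/zero row(s) assigned maximal ",
            "distance under ", distance, " distance")
  }
  d <- 1 - sim
  diag(d) <- 0
  dimnames(d) <- list(rownames(mat), rownames(mat))
  as.dist(d)
}

#' Hierarchical clustering of expression patterns
#'
#' Average-linkage hierarchical clustering under an uncentered-Pearson
#' (default, the Eisen Cluster convention) or centered Pearson
#' correlation distance. Identical rows are at distance 0 and merge
#' first; a row of zeros (or a constant row under Pearson) has no
#' defined correlation and is assigned the maximal distance 2 to every
#' other row, with a warning.
#'
#' @param mat Pattern matrix from [build_pattern_matrix()] (>= 2 rows).
#' @param distance `"uncentered_correlation"` or `"pearson"`.
#' @param linkage Agglomeration method; only `"average"` is offered.
#' @return A list of class `pattern_clust`: `hclust` (the merge tree),
#'   `dist` (the distance object), `distance`, `linkage`.
#' @export
hierarchical_cluster <- function(mat,
                                 distance = c("uncentered_correlation",
                                              "pearson"),
                                 linkage = "average") {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage, "average")
  stopifnot(is.matrix(mat), nrow(mat) >= 2)
  d <- pattern_dist(mat, distance)
  hc <- hclust(d, method = linkage)
  structure(list(hclust = hc, dist = d, distance = distance,
                 linkage = linkage),
            class = "pattern_clust")
}

#' @export
print.pattern_clust <- function(x, ...) {
  cat("Hierarchical clustering of", length(x$hclust$labels),
      "expression patterns\n")
  cat("  distance:", x$distance, " linkage:", x$linkage, "\n")
  invisible(x)
}

## Default flat cut: number of clusters at the largest gap between
## consecutive merge heights (cutting just below the largest jump).
default_k <- function(hc) {
  h <- hc$height
  if (length(h) < 2) return(if (length(h)) 2L else 1L)
  gaps <- diff(h)
  ## merging n leaves takes n-1 steps; cutting above merge i leaves n-i
  ## clusters. The largest gap sits after merge which(max) -> keep
  ## n - which.max(gaps) clusters.
  length(h) + 1L - which.max(gaps)
}

#' Flat clusters containing given seed genes
#'
#' Cuts the dendrogram into flat clusters and reports every cluster
#' containing at least one seed gene (for instance known
#' taxane-biosynthesis genes), with its full membership — the screen
#' used to nominate co-regulated candidates for a pathway.
#'
#' @param result A `pattern_clust` from [hierarchical_cluster()].
#' @param seed_genes Character vector of seed gene identifiers; must be
#'   among the clustered genes.
#' @param k Number of flat clusters; default picks the cut at the
#'   largest merge-height gap.
#' @param h Alternatively, a cut height (overrides `k`).
#' @return A list with `clusters` (data frame `cluster_id`, `gene_id`,
#'   `is_seed` for clusters intersecting the seeds), `assignment` (full
#'   cluster membership of all genes) and `k` used.
#' @export
clusters_containing <- function(result, seed_genes, k = NULL, h = NULL) {
  stopifnot(inherits(result, "pattern_clust"))
  hc <- result$hclust
  seed_genes <- unique(as.character(seed_genes))
  outside <- setdiff(seed_genes, hc$labels)
  if (length(outside) && length(seed_genes)) {
    stop("seed gene not among clustered genes: ", outside[1],
         call. = FALSE)
  }
  cl <- if (!is.null(h)) cutree(hc, h = h)
        else cutree(hc, k = if (is.null(k)) default_k(hc) else k)
  assignment <- data.frame(gene_id = names(cl),
                           cluster_id = as.integer(cl),
                           stringsAsFactors = FALSE)
  hit_clusters <- sort(unique(cl[seed_genes]))
  sel <- assignment[assignment$cluster_id %in% hit_clusters, , drop = FALSE]
  sel$is_seed <- sel$gene_id %in% seed_genes
  sel <- sel[order(sel$cluster_id, sel$gene_id),
             c("cluster_id", "gene_id", "is_seed")]
  rownames(sel) <- NULL
  list(clusters = sel, assignment = assignment,
       k = length(unique(cl)))
}

#' Serialise a dendrogram as Newick text
#'
#' @param result A `pattern_clust`.
#' @return Single Newick string (with branch lengths from merge
#'   heights).
#' @export
cluster_newick <- function(result) {
  stopifnot(inherits(result, "pattern_clust"))
  hc <- result$hclust
  rec <- function(i, parent_h) {
    if (i < 0) {
      lab <- hc$labels[-i]
      paste0(lab, ":", format(parent_h, digits = 10))
    } else {
      h <- hc$height[i]
      paste0("(", rec(hc$merge[i, 1], h), ",", rec(hc$merge[i, 2], h),
             "):", format(parent_h - h, digits = 10))
    }
  }
  n <- nrow(hc$merge)
  top <- hc$height[n]
  paste0("(", rec(hc$merge[n, 1], top), ",", rec(hc$merge[n, 2], top),
         ");")
}
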