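## Poisson exact test for tag-count differential expression
## (Audic & Claverie 1997 style, generalised to unequal library sizes).
##
## Model: the count x of a gene in a library of N total clean tags is
## Poisson with intensity proportional to the gene's true transcript
## abundance. Conditioning on x in sample 1 and integrating the unknown
## intensity out with a flat prior gives the probability of observing y
## tags in sample 2 (library total N2) when the gene is expressed equally:
##
##   P(y | x) = (N2/N1)^y * (x+y)! / ( x! y! (1 + N2/N1)^(x+y+1) )
##
## All tail arithmetic is done in log space via lgamma.

log_cond_prob <- function(y, x, N1, N2) {
  r <- N2 / N1
  y * log(r) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
    (x + y + 1) * log1p(r)
}

#' Equal-expression probability of a tag count pair
#'
#' The probability P(y | x) of observing `y` tags for a gene in a
#' library of `N2` total clean tags, given `x` tags in a library of `N1`
#' total, under the null hypothesis of equal expression, with the
#' Poisson intensity integrated out. Over y = 0, 1, 2, ... these
#' probabilities sum to one.
#'
#' @param y,x Non-negative integer tag counts (vectorised).
#' @param N1,N2 Total clean tags of the two libraries (positive).
#' @return Probability value(s) in `[0, 1]`.
#' @examples
#' conditional_probability(0, 0, 1e6, 1e6)  # 0.5
#' @export
conditional_probability <- function(y, x, N1, N2) {
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative",
                                     call. = FALSE)
  if (any(N1 <= 0) || any(N2 <= 0)) stop("library totals must be positive",
                                         call. = FALSE)
  exp(log_cond_prob(y, x, N1, N2))
}

## lower tail sum_{i=0..y} P(i|x), via log-sum-exp; scalar.
lower_tail <- function(y, x, N1, N2) {
  if (y < 0) return(0)
  lp <- log_cond_prob(0:y, x, N1, N2)
  m <- max(lp)
  exp(m + log(sum(exp(lp - m))))
}

## upper tail sum_{i=y..Inf} P(i|x): direct summation anchored at the
## first term, truncated when a term falls below 1e-30 of the running
## sum. Only invoked when this is the smaller tail, where the series
## decays geometrically from the start.
upper_tail <- function(y, x, N1, N2) {
  r <- N2 / N1
  lead <- exp(log_cond_prob(y, x, N1, N2))
  term <- 1
  s <- 1
  i <- y
  repeat {
    term <- term * r * (x + i + 1) / ((1 + r) * (i + 1))
    if (!is.finite(term) || term < 1e-30 * s) break
    s <- s + term
    i <- i + 1
  }
  lead * s
}

#' Two-sided Poisson exact p-value for differential tag counts
#'
#' Tests whether a gene's tag counts `x` (library total `N1`) and `y`
#' (library total `N2`) are compatible with equal expression, using the
#' exact conditional distribution of `y` given `x`. The two-sided
#' p-value is twice the smaller of the lower and upper tails of P(.|x)
#' at `y`, capped at 1. The lower tail is summed in log space; the
#' infinite upper tail, when it is the smaller one, is summed directly
#' by a multiplicative term recurrence truncated once a term drops
#' below 1e-30 of the running sum, avoiding the cancellation a
#' complement would incur for extreme counts.
#'
#' @param x,y Non-negative integer tag counts (vectorised).
#' @param N1,N2 Total clean tags of the two libraries.
#' @return p-value(s) in `[0, 1]`, symmetric under
#'   `(x, N1) <-> (y, N2)`.
#' @examples
#' audic_claverie_p(5, 50, 1e6, 1e6)
#' @export
audic_claverie_p <- function(x, y, N1, N2) {
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative",
                                     call. = FALSE)
  if (any(N1 <= 0) || any(N2 <= 0)) stop("library totals must be positive",
                                         call. = FALSE)
  n <- max(length(x), length(y), length(N1), length(N2))
  x <- rep_len(x, n); y <- rep_len(y, n)
  N1 <- rep_len(N1, n); N2 <- rep_len(N2, n)
  p <- numeric(n)
  for (i in seq_len(n)) {
    lo <- lower_tail(y[i], x[i], N1[i], N2[i])
    if (lo <= 0.5) {
      ## the upper tail is then >= 0.5, so the lower tail is the minimum
      p[i] <- min(1, 2 * lo)
    } else {
      hi <- upper_tail(y[i], x[i], N1[i], N2[i])
      p[i] <- min(1, 2 * min(lo, hi))
    }
  }
  p
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment of a p-value vector; output order matches input
#' order. Provided as the package's canonical multiple-testing control
#' for differential-expression calls (a thin wrapper over
#' [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values (FDR) in input order.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Call differentially expressed genes between two libraries
#'
#' Runs the Poisson exact test on raw unambiguous sense tag counts for
#' every gene detected in at least one of the two libraries, adjusts by
#' Benjamini-Hochberg, and calls a gene up- (or down-) regulated when
#' `fdr <= fdr_cut` and `log2_ratio >= lfc_cut` (resp. `<= -lfc_cut`).
#' The log2 ratio is oriented library 2 over library 1 and computed on
#' TPM with `zero_sub` substituted for zero TPM values, so a gene absent
#' from one library still gets a finite fold change.
#'
#' @param expr Expression table from [count_expression()] rows for (at
#'   least) the two libraries, bound together.
#' @param pair Character vector of the two library labels,
#'   `c(lib1, lib2)`.
#' @param fdr_cut FDR threshold for significance (default 0.001).
#' @param lfc_cut Absolute log2-ratio threshold (default 1).
#' @param zero_sub TPM value substituted for 0 (default 0.001).
#' @return Data frame of class `dge_result`: `gene_id`, `x`, `y`,
#'   `tpm1`, `tpm2`, `log2_ratio`, `p_value`, `fdr`, `call` (one of
#'   `up`, `down`, `not_significant`). Genes with zero counts in both
#'   libraries are excluded (no evidence).
#' @export
call_degs <- function(expr, pair, fdr_cut = 0.001, lfc_cut = 1,
                      zero_sub = 0.001) {
  stopifnot(length(pair) == 2)
  e1 <- expr[expr$library == pair[1], , drop = FALSE]
  e2 <- expr[expr$library == pair[2], , drop = FALSE]
  if (nrow(e1) == 0 || nrow(e2) == 0) {
    stop("library not present in expression table: ",
         pair[c(nrow(e1) == 0, nrow(e2) == 0)][1], call. = FALSE)
  }
  genes <- union(e1$gene_id, e2$gene_id)
  i1 <- match(genes, e1$gene_id)
  i2 <- match(genes, e2$gene_id)
  x <- ifelse(is.na(i1), 0, e1$sense_count[i1])
  y <- ifelse(is.na(i2), 0, e2$sense_count[i2])
  tpm1 <- ifelse(is.na(i1), 0, e1$sense_tpm[i1])
  tpm2 <- ifelse(is.na(i2), 0, e2$sense_tpm[i2])
  N1 <- e1$total_clean[which(!is.na(i1))[1]]
  N2 <- e2$total_clean[which(!is.na(i2))[1]]
  keep <- x + y > 0
  genes <- genes[keep]; x <- x[keep]; y <- y[keep]
  tpm1 <- tpm1[keep]; tpm2 <- tpm2[keep]
  l2r <- log2(pmax(tpm2, zero_sub) / pmax(tpm1, zero_sub))
  p <- audic_claverie_p(x, y, N1, N2)
  fdr <- bh_fdr(p)
  call <- ifelse(fdr <= fdr_cut & l2r >= lfc_cut, "up",
                 ifelse(fdr <= fdr_cut & l2r <= -lfc_cut, "down",
                        "not_significant"))
  out <- data.frame(gene_id = genes, x = x, y = y, tpm1 = tpm1, tpm2 = tpm2,
                    log2_ratio = l2r, p_value = p, fdr = fdr, call = call,
                    stringsAsFactors = FALSE)
  out <- out[order(out$fdr, out$p_value, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pair") <- pair
  attr(out, "totals") <- c(N1, N2)
  class(out) <- c("dge_result", "data.frame")
  out
}

#' Sense/antisense expression table for one library
#'
#' For every gene with detectable antisense transcription
#' (antisense TPM > 0), reports sense TPM, antisense TPM and their
#' ratio TPM(+)/TPM(-), with the summary tallies used to judge
#' sense-antisense regulation. A ratio below 1 (including the
#' antisense-only, sense-zero case, ratio 0) marks genes whose antisense
#' strand dominates.
#'
#' @param expr Expression table from [count_expression()].
#' @param library_id Library (tissue) to summarise.
#' @return A list with `records` (data frame `gene_id`, `tpm_plus`,
#'   `tpm_minus`, `ratio`) and `summary` (`n_with_antisense`,
#'   `ratio_min`, `ratio_max`, `ratio_median`, `n_ratio_lt1`,
#'   `n_ratio_ge1`).
#' @export
antisense_table <- function(expr, library_id) {
  e <- expr[expr$library == library_id & expr$antisense_tpm > 0, ,
            drop = FALSE]
  rec <- data.frame(gene_id = e$gene_id,
                    tpm_plus = e$sense_tpm,
                    tpm_minus = e$antisense_tpm,
                    ratio = e$sense_tpm / e$antisense_tpm,
                    stringsAsFactors = FALSE)
  rec <- rec[order(rec$gene_id), , drop = FALSE]
  rownames(rec) <- NULL
  s <- if (nrow(rec)) {
    list(n_with_antisense = nrow(rec),
         ratio_min = min(rec$ratio), ratio_max = max(rec$ratio),
         ratio_median = median(rec$ratio),
         n_ratio_lt1 = sum(rec$ratio < 1),
         n_ratio_ge1 = sum(rec$ratio >= 1))
  } else {
    list(n_with_antisense = 0L, ratio_min = NA_real_, ratio_max = NA_real_,
         ratio_median = NA_real_, n_ratio_lt1 = 0L, n_ratio_ge1 = 0L)
  }
  list(records = rec, summary = s)
}
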