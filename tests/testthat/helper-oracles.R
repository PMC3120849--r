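## Independent brute-force oracles used to validate the package's
## implementations on small instances. Each deliberately takes the most
## naive route available and shares no code with the functions it checks.

## --- tag library: quadratic position-by-position scanner ----------------
naive_tag_scan <- function(transcripts) {
  rc1 <- function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]),
          collapse = "")
  }
  rows <- list()
  for (i in seq_len(nrow(transcripts))) {
    s <- toupper(transcripts$sequence[i])
    L <- nchar(s)
    for (strand in c("sense", "antisense")) {
      str <- if (strand == "sense") s else rc1(s)
      if (L < 21) next
      for (p in 1:(L - 20)) {
        if (substr(str, p, p + 3) == "CATG") {
          tag <- substr(str, p, p + 20)
          if (grepl("N", tag, fixed = TRUE)) next
          off <- if (strand == "sense") p - 1L else L - 21L - (p - 1L)
          rows[[length(rows) + 1L]] <- data.frame(
            tag_sequence = tag, gene_id = transcripts$gene_id[i],
            strand = strand, offset = off, stringsAsFactors = FALSE)
        }
      }
    }
  }
  pl <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tag_sequence = character(), gene_id = character(),
               strand = character(), offset = integer())
  if (nrow(pl)) {
    ng <- sapply(split(pl$gene_id, pl$tag_sequence),
                 function(g) length(unique(g)))
    pl$ambiguous <- unname(ng[pl$tag_sequence] > 1)
  } else pl$ambiguous <- logical(0)
  pl
}

## --- tag mapping: all-pairs Hamming scan --------------------------------
hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

naive_map <- function(tagseq, placements) {
  lib <- unique(placements$tag_sequence)
  out <- data.frame(tag_sequence = tagseq, status = "unmapped",
                    gene_id = NA_character_, strand = NA_character_,
                    mismatch_count = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(tagseq)) {
    d <- vapply(lib, hamming, integer(1), a = tagseq[i])
    ## anchor must match for a 1-mismatch hit to count
    anchor_ok <- substr(lib, 1, 4) == substr(tagseq[i], 1, 4)
    tier <- if (any(d == 0)) 0L else if (any(d == 1 & anchor_ok)) 1L else NA
    if (is.na(tier)) next
    hits <- lib[if (tier == 0) d == 0 else (d == 1 & anchor_ok)]
    pls <- placements[placements$tag_sequence %in% hits, ]
    genes <- unique(pls$gene_id)
    if (length(genes) > 1) {
      out$status[i] <- "ambiguous_multi_gene"
      out$mismatch_count[i] <- tier
    } else {
      out$status[i] <- if (tier == 0) "perfect_unique" else
        "mismatch1_unique"
      out$gene_id[i] <- genes
      out$strand[i] <- if (any(pls$strand == "sense")) "sense" else
        "antisense"
      out$mismatch_count[i] <- tier
    }
  }
  out
}

## --- Audic-Claverie: multiplicative term recurrence ---------------------
ac_oracle_terms <- function(x, N1, N2, upto) {
  r <- N2 / N1
  t <- numeric(upto + 1)
  t[1] <- (1 + r)^-(x + 1)
  if (upto > 0) for (i in 1:upto) {
    t[i + 1] <- t[i] * r * (x + i) / ((1 + r) * i)
  }
  t
}

ac_oracle_p <- function(x, y, N1, N2) {
  r <- N2 / N1
  t <- ac_oracle_terms(x, N1, N2, y)
  lower <- sum(t)
  ## upper: extend until terms vanish
  term <- t[y + 1]
  upper <- term
  i <- y
  while (term > 1e-30 * upper && term > 0) {
    term <- term * r * (x + i + 1) / ((1 + r) * (i + 1))
    upper <- upper + term
    i <- i + 1
  }
  min(1, 2 * min(lower, upper))
}

## --- BH step-up: literal textbook rule ----------------------------------
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- ps * n / seq_len(n)
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

## --- hypergeometric: exact rational sum of binomials --------------------
hyper_oracle <- function(N, n, M, m) {
  ii <- m:min(n, M)
  sum(choose(M, ii) * choose(N - M, n - ii)) / choose(N, n)
}

## --- average-linkage agglomeration: O(n^3) with explicit cluster lists --
naive_average_linkage_cophenetic <- function(D) {
  ## D: symmetric distance matrix; returns cophenetic distance matrix
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  active <- rep(TRUE, n)
  Dm <- D
  while (sum(active) > 1) {
    idx <- which(active)
    best <- c(NA, NA)
    bestd <- Inf
    for (a in idx) for (b in idx) {
      if (a < b && Dm[a, b] < bestd) { bestd <- Dm[a, b]; best <- c(a, b) }
    }
    a <- best[1]; b <- best[2]
    for (i in clusters[[a]]) for (j in clusters[[b]]) {
      coph[i, j] <- coph[j, i] <- bestd
    }
    merged <- c(clusters[[a]], clusters[[b]])
    ## unweighted average linkage: mean pairwise original distance
    for (k in idx) {
      if (k == a || k == b) next
      Dm[a, k] <- Dm[k, a] <-
        mean(D[merged, clusters[[k]], drop = FALSE])
    }
    clusters[[a]] <- merged
    active[b] <- FALSE
    Dm[b, ] <- Dm[, b] <- Inf
  }
  coph
}

## --- tiny deterministic transcriptome builders --------------------------
random_transcriptome <- function(n_genes, len_range = c(60, 500),
                                 seed = 1) {
  set.seed(seed)
  lens <- sample(len_range[1]:len_range[2], n_genes, replace = TRUE)
  data.frame(
    gene_id = paste0("g", seq_len(n_genes)),
    sequence = vapply(lens, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
            collapse = ""), character(1)),
    stringsAsFactors = FALSE)
}
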