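## Seeded generators for transcriptomes, tissue expression profiles and
## raw DGE tag reads with ground truth, emulating the statistical
## structure of a three-tissue plant DGE experiment: a few-million-tag
## library per tissue, heavy-tailed per-gene abundance, a minority of
## antisense transcription, per-base sequencing error producing
## singleton tags, and roughly 82% of genes carrying a CATG site.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Simulation configuration
#'
#' Bundles and validates every tunable of the DGE simulator. Defaults
#' describe the study conditions the package is designed around: three
#' tissue libraries of about 3.2 million 21-nt tags each, a reference
#' of heavy-tailed log-normally abundant genes at 45.5% GC with 81.5%
#' of genes carrying a CATG restriction site, 10% of genes
#' differentially expressed at 4-fold, a quarter of genes with antisense
#' transcription at about one seventh of the sense level, and a 0.1%
#' per-base substitution error rate.
#'
#' @param n_genes Number of genes.
#' @param len_min,len_max Transcript length range (uniform), bases.
#' @param gc_content Target GC fraction.
#' @param frac_with_site Fraction of genes guaranteed at least one
#'   sense CATG tag site; the remainder have sense CATG sites scrubbed.
#' @param tissues Character vector of library (tissue) labels.
#' @param abundance_sdlog Log-normal sdlog of baseline abundance
#'   (heavy tail).
#' @param de_fraction Fraction of genes differentially expressed.
#' @param log2fc Absolute log2 fold change given to DE genes (sign and
#'   target tissue drawn per gene).
#' @param antisense_fraction Fraction of genes with antisense
#'   transcription.
#' @param antisense_level Antisense abundance relative to sense.
#' @param depth Total emitted tags per library.
#' @param error_rate Per-base substitution error rate on reads.
#' @param singleton_rate Noise reads (random one-off tags) as a
#'   fraction of depth.
#' @param adaptor 3' adaptor sequence appended to tags.
#' @param seed Integer seed (mandatory; all stages derive their streams
#'   from it).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000,
                       len_min = 300, len_max = 2000,
                       gc_content = 0.455,
                       frac_with_site = 0.815,
                       tissues = c("root", "stem", "leaf"),
                       abundance_sdlog = 1.6,
                       de_fraction = 0.1,
                       log2fc = 2,
                       antisense_fraction = 0.25,
                       antisense_level = 0.15,
                       depth = 3.2e6,
                       error_rate = 0.001,
                       singleton_rate = 0.01,
                       adaptor = "TCGTATGCCGTCTTCTGCTTG",
                       seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  cfg <- list(n_genes = as.integer(n_genes), len_min = as.integer(len_min),
              len_max = as.integer(len_max), gc_content = gc_content,
              frac_with_site = frac_with_site, tissues = tissues,
              abundance_sdlog = abundance_sdlog,
              de_fraction = de_fraction, log2fc = log2fc,
              antisense_fraction = antisense_fraction,
              antisense_level = antisense_level, depth = depth,
              error_rate = error_rate, singleton_rate = singleton_rate,
              adaptor = toupper(adaptor), seed = as.integer(seed))
  stopifnot(cfg$n_genes >= 1, cfg$len_min >= TAG_LEN,
            cfg$len_max >= cfg$len_min,
            cfg$gc_content > 0, cfg$gc_content < 1,
            cfg$frac_with_site >= 0, cfg$frac_with_site <= 1,
            length(cfg$tissues) >= 1,
            cfg$de_fraction >= 0, cfg$de_fraction <= 1,
            cfg$antisense_fraction >= 0, cfg$antisense_fraction <= 1,
            cfg$antisense_level >= 0,
            cfg$depth >= 1,
            cfg$error_rate >= 0, cfg$error_rate < 1,
            cfg$singleton_rate >= 0)
  class(cfg) <- "sim_config"
  cfg
}

## 3'-most CATG site with a full 17-base extension on a strand; NA if
## none. Returns the tag sequence.
canonical_tag <- function(seqv) {
  hits <- gregexpr(ANCHOR, seqv, fixed = TRUE)
  lens <- nchar(seqv)
  out <- rep(NA_character_, length(seqv))
  for (i in seq_along(seqv)) {
    pos <- hits[[i]]
    pos <- pos[pos > 0 & pos + TAG_LEN - 1L <= lens[i]]
    if (length(pos)) {
      p <- max(pos)
      out[i] <- substr(seqv[i], p, p + TAG_LEN - 1L)
    }
  }
  out
}

#' Simulate a transcriptome with controlled CATG site content
#'
#' Draws random transcript sequences at the target GC content, then
#' enforces the configured fraction of genes with a usable sense CATG
#' tag site: site-guaranteed genes get a CATG planted when none arose
#' by chance, the rest have all sense CATG occurrences scrubbed (so
#' they drop out of tag profiling, as real site-less genes do).
#'
#' @param config A `sim_config`.
#' @return List with `transcripts` (data frame `gene_id`, `sequence`,
#'   `length`) and `truth` (data frame `gene_id`, `length`, `has_site`,
#'   `sense_tag` — the 3'-most sense CATG+17 tag the bead-captured
#'   protocol would emit — and `antisense_tag`).
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_genes
    lens <- sample(config$len_min:config$len_max, n, replace = TRUE)
    g <- config$gc_content
    probs <- c(A = (1 - g) / 2, C = g / 2, G = g / 2, T = (1 - g) / 2)
    seqs <- vapply(lens, function(L)
      paste(sample(names(probs), L, replace = TRUE, prob = probs),
            collapse = ""), character(1))
    n_site <- round(config$frac_with_site * n)
    site_genes <- sample.int(n, n_site)
    scrub <- setdiff(seq_len(n), site_genes)
    ## scrub: remove every sense CATG (re-scan, replacement is CAAG)
    for (i in scrub) {
      while (grepl(ANCHOR, seqs[i], fixed = TRUE)) {
        seqs[i] <- gsub(ANCHOR, "CAAG", seqs[i], fixed = TRUE)
      }
    }
    ## guarantee: plant a CATG with a full 17-base extension if absent
    for (i in site_genes) {
      hits <- gregexpr(ANCHOR, seqs[i], fixed = TRUE)[[1]]
      if (!any(hits > 0 & hits + TAG_LEN - 1L <= lens[i])) {
        pos <- sample.int(lens[i] - TAG_LEN + 1L, 1)
        substr(seqs[i], pos, pos + 3L) <- ANCHOR
      }
    }
    ids <- sprintf("gene%05d", seq_len(n))
    tx <- data.frame(gene_id = ids, sequence = seqs, length = lens,
                     stringsAsFactors = FALSE)
    sense_tag <- canonical_tag(seqs)
    anti_tag <- canonical_tag(revcomp(seqs))
    truth <- data.frame(gene_id = ids, length = lens,
                        has_site = !is.na(sense_tag),
                        sense_tag = sense_tag,
                        antisense_tag = anti_tag,
                        stringsAsFactors = FALSE)
    list(transcripts = tx, truth = truth)
  })
}

#' Simulate per-tissue expression with planted differential expression
#'
#' Baseline abundance is log-normal (heavy-tailed) and shared across
#' tissues; each differentially expressed gene receives a 2^(log2fc)
#' multiplicative effect, with random sign, in one randomly chosen
#' tissue. Antisense genes transcribe their antisense strand at
#' `antisense_level` times the sense abundance.
#'
#' @param config A `sim_config`.
#' @param transcriptome Result of [simulate_transcriptome()].
#' @return List with `sense` and `antisense` abundance matrices (genes
#'   x tissues) and `truth` (data frame `gene_id`, `is_de`,
#'   `de_tissue`, `log2fc` signed, `has_antisense`).
#' @export
simulate_expression <- function(config, transcriptome) {
  stopifnot(inherits(config, "sim_config"))
  ids <- transcriptome$transcripts$gene_id
  n <- length(ids)
  tissues <- config$tissues
  with_seed(config$seed + 1L, {
    base <- rlnorm(n, meanlog = 2, sdlog = config$abundance_sdlog)
    sense <- matrix(base, nrow = n, ncol = length(tissues),
                    dimnames = list(ids, tissues))
    n_de <- round(config$de_fraction * n)
    de_genes <- if (n_de > 0) sample.int(n, n_de) else integer(0)
    de_tissue <- rep(NA_character_, n)
    lfc <- rep(0, n)
    if (n_de > 0) {
      tis <- sample(tissues, n_de, replace = TRUE)
      sign <- sample(c(-1, 1), n_de, replace = TRUE)
      de_tissue[de_genes] <- tis
      lfc[de_genes] <- sign * config$log2fc
      sense[cbind(de_genes, match(tis, tissues))] <-
        base[de_genes] * 2^(lfc[de_genes])
    }
    n_as <- round(config$antisense_fraction * n)
    as_genes <- if (n_as > 0) sample.int(n, n_as) else integer(0)
    anti <- matrix(0, nrow = n, ncol = length(tissues),
                   dimnames = list(ids, tissues))
    if (n_as > 0) anti[as_genes, ] <- sense[as_genes, , drop = FALSE] *
      config$antisense_level
    truth <- data.frame(gene_id = ids,
                        is_de = seq_len(n) %in% de_genes,
                        de_tissue = de_tissue,
                        log2fc = lfc,
                        has_antisense = seq_len(n) %in% as_genes,
                        stringsAsFactors = FALSE)
    list(sense = sense, antisense = anti, truth = truth)
  })
}

mutate_reads <- function(reads, error_rate, read_len) {
  if (error_rate <= 0 || length(reads) == 0) return(reads)
  n_err <- rbinom(length(reads), read_len, error_rate)
  idx <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(read_len, n_err[i])
    for (p in pos) {
      cur <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(bases, cur), 1)
    }
  }
  reads
}

#' Simulate raw DGE tag reads for every library
#'
#' Emits, per tissue, `depth` reads by multinomial sampling of gene
#' strands proportional to abundance. Each read is the gene's
#' bead-captured tag — the 3'-most sense CATG+17 tag, or the antisense
#' analogue for antisense emissions — followed by the adaptor,
#' truncated to 35 nt. Genes without a usable site silently drop out,
#' as in the real protocol. Per-base substitution errors are applied at
#' the configured rate, and one-off random noise tags are appended to
#' exercise the copy-number filter.
#'
#' @param config A `sim_config`.
#' @param transcriptome Result of [simulate_transcriptome()].
#' @param expression Result of [simulate_expression()].
#' @return List with `reads` (named list of character vectors, one per
#'   tissue) and `emitted` (data frame `gene_id`, `tissue`,
#'   `sense_emitted`, `antisense_emitted`: true pre-error, pre-noise
#'   emission counts).
#' @export
simulate_tag_reads <- function(config, transcriptome, expression) {
  stopifnot(inherits(config, "sim_config"))
  tr <- transcriptome$truth
  read_len <- 35L
  adaptor_fill <- substr(config$adaptor, 1L, read_len - TAG_LEN)
  with_seed(config$seed + 2L, {
    reads <- list()
    emitted <- list()
    for (t in config$tissues) {
      w_sense <- expression$sense[, t] * as.numeric(tr$has_site)
      w_anti <- expression$antisense[, t] *
        as.numeric(!is.na(tr$antisense_tag))
      w <- c(w_sense, w_anti)
      if (sum(w) <= 0) stop("no expressible gene has a tag site",
                            call. = FALSE)
      cnt <- as.vector(rmultinom(1, config$depth, w))
      ns <- cnt[seq_along(w_sense)]
      na_ <- cnt[-seq_along(w_sense)]
      tags <- c(rep(tr$sense_tag, ns), rep(tr$antisense_tag, na_))
      n_noise <- round(config$singleton_rate * config$depth)
      if (n_noise > 0) {
        noise <- vapply(seq_len(n_noise), function(i)
          paste0(ANCHOR, paste(sample(c("A", "C", "G", "T"),
                                      TAG_LEN - 4L, replace = TRUE),
                               collapse = "")), character(1))
        tags <- c(tags, noise)
      }
      rd <- substr(paste0(tags, adaptor_fill), 1L, read_len)
      rd <- mutate_reads(rd, config$error_rate, read_len)
      reads[[t]] <- rd
      emitted[[t]] <- data.frame(gene_id = tr$gene_id, tissue = t,
                                 sense_emitted = ns,
                                 antisense_emitted = na_,
                                 stringsAsFactors = FALSE)
    }
    list(reads = reads, emitted = do.call(rbind, emitted))
  })
}

#' Simulate a term annotation with one planted enriched term
#'
#' Generates random term-to-gene annotations of varied sizes plus one
#' term whose members are drawn preferentially from a given gene set
#' (e.g. the true DE genes) with configurable odds, for exercising
#' enrichment analysis against a known answer.
#'
#' @param config A `sim_config`.
#' @param genes Character vector of all gene identifiers (background).
#' @param favored_genes Genes the planted term favours.
#' @param n_terms Number of random terms (besides the planted one).
#' @param term_size_range Size range for every term.
#' @param planted_odds Sampling odds of a favoured gene relative to any
#'   other in the planted term (1 = no enrichment).
#' @return List with `annotation` (data frame `term_id`, `gene_id`) and
#'   `planted_term` (its id).
#' @export
simulate_annotation <- function(config, genes, favored_genes,
                                n_terms = 50,
                                term_size_range = c(10, 100),
                                planted_odds = 20) {
  stopifnot(inherits(config, "sim_config"))
  genes <- as.character(genes)
  with_seed(config$seed + 3L, {
    sizes <- sample(term_size_range[1]:term_size_range[2], n_terms + 1,
                    replace = TRUE)
    sizes <- pmin(sizes, length(genes))
    ann <- lapply(seq_len(n_terms), function(i)
      data.frame(term_id = sprintf("term%03d", i),
                 gene_id = sample(genes, sizes[i]),
                 stringsAsFactors = FALSE))
    w <- ifelse(genes %in% favored_genes, planted_odds, 1)
    planted <- data.frame(term_id = "term_planted",
                          gene_id = sample(genes, sizes[n_terms + 1],
                                           prob = w),
                          stringsAsFactors = FALSE)
    list(annotation = rbind(do.call(rbind, ann), planted),
         planted_term = "term_planted")
  })
}

#' Run the full simulator
#'
#' Convenience wrapper chaining [simulate_transcriptome()],
#' [simulate_expression()] and [simulate_tag_reads()].
#'
#' @param config A `sim_config`.
#' @return List `transcriptome`, `expression`, `reads_out` (the
#'   [simulate_tag_reads()] result).
#' @export
simulate_dge_experiment <- function(config) {
  tx <- simulate_transcriptome(config)
  ex <- simulate_expression(config, tx)
  rd <- simulate_tag_reads(config, tx, ex)
  list(transcriptome = tx, expression = ex, reads_out = rd)
}
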