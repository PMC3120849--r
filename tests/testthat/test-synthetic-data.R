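test_that("simulation is deterministic under the seed and leaves the global RNG alone", {
  cfg <- sim_config(n_genes = 50, depth = 5000, seed = 5)
  set.seed(1234)
  before <- runif(1)
  set.seed(1234)
  a <- simulate_transcriptome(cfg)
  b <- simulate_transcriptome(cfg)
  after <- runif(1)
  expect_identical(a, b)
  expect_equal(before, after)  # with_seed restored the caller's stream
  expect_error(sim_config(n_genes = 10), "seed")
})

test_that("site fraction and GC content are honoured", {
  cfg <- sim_config(n_genes = 300, len_min = 300, len_max = 800,
                    frac_with_site = 1, seed = 8)
  tx <- simulate_transcriptome(cfg)
  expect_true(all(tx$truth$has_site))
  cfg2 <- sim_config(n_genes = 400, frac_with_site = 0.815, seed = 9)
  tx2 <- simulate_transcriptome(cfg2)
  expect_equal(mean(tx2$truth$has_site), 0.815, tolerance = 0.01)
  gc <- sum(vapply(strsplit(tx2$transcripts$sequence, ""),
                   function(ch) sum(ch %in% c("G", "C")), numeric(1))) /
    sum(nchar(tx2$transcripts$sequence))
  expect_equal(gc, cfg2$gc_content, tolerance = 0.02)
  expect_error(sim_config(n_genes = 5, len_min = 10, seed = 1))
})

test_that("genes denied a site really have no usable sense CATG tag", {
  cfg <- sim_config(n_genes = 200, frac_with_site = 0.5, seed = 21)
  tx <- simulate_transcriptome(cfg)
  lib <- build_tag_library(tx$transcripts)
  genes_in_lib <- unique(
    lib$placements$gene_id[lib$placements$strand == "sense"])
  expect_setequal(genes_in_lib,
                  tx$truth$gene_id[tx$truth$has_site])
})

test_that("expression truth reflects the planted effects and heavy tail", {
  cfg <- sim_config(n_genes = 2000, de_fraction = 0.1, log2fc = 2,
                    antisense_fraction = 0.25, antisense_level = 0.15,
                    seed = 12)
  tx <- simulate_transcriptome(cfg)
  ex <- simulate_expression(cfg, tx)
  expect_equal(sum(ex$truth$is_de), 200)
  expect_equal(sum(ex$truth$has_antisense), 500)
  de <- which(ex$truth$is_de)
  for (i in de[1:20]) {
    t <- ex$truth$de_tissue[i]
    others <- setdiff(cfg$tissues, t)
    expect_equal(ex$sense[i, t] / ex$sense[i, others[1]],
                 2^ex$truth$log2fc[i], tolerance = 1e-9)
  }
  ## antisense level proportional to sense
  as_genes <- which(ex$truth$has_antisense)
  expect_equal(ex$antisense[as_genes, 1],
               ex$sense[as_genes, 1] * cfg$antisense_level)
  expect_true(all(ex$antisense[-as_genes, ] == 0))
  ## heavy tail: top 1% of genes carry at least a quarter of the mass
  tot <- sort(ex$sense[, 1], decreasing = TRUE)
  expect_gte(sum(tot[1:20]) / sum(tot), 0.25)
})

test_that("de_fraction zero leaves all tissues at baseline", {
  cfg <- sim_config(n_genes = 100, de_fraction = 0, seed = 3)
  tx <- simulate_transcriptome(cfg)
  ex <- simulate_expression(cfg, tx)
  expect_true(all(ex$sense[, 1] == ex$sense[, 2]))
})

test_that("with no error and no noise the pipeline recovers the emitted tag multiset minus singletons", {
  cfg <- sim_config(n_genes = 150, depth = 4e4, error_rate = 0,
                    singleton_rate = 0, antisense_fraction = 0.2,
                    seed = 44)
  sim <- simulate_dge_experiment(cfg)
  lib <- build_tag_library(sim$transcriptome$transcripts)
  tr <- sim$transcriptome$truth
  pl <- lib$placements
  unamb <- function(tag) {
    !is.na(tag) & tag %in% pl$tag_sequence[!pl$ambiguous]
  }
  sense_pl <- unique(pl$tag_sequence[pl$strand == "sense"])
  for (t in cfg$tissues[1:2]) {
    cts <- clean_raw_tags(sim$reads_out$reads[[t]], cfg$adaptor)
    asg <- map_tags(cts, lib)
    expr <- count_expression(asg, cts$total_clean,
                             gene_ids = tr$gene_id, library_id = t)
    em <- sim$reads_out$emitted
    em <- em[em$tissue == t, ]
    ## sense side: canonical tag unambiguous, and the gene's antisense
    ## emissions (if any) cannot fold into the sense count via a
    ## sense-strand placement of the antisense tag
    ok <- unamb(tr$sense_tag) &
      (em$antisense_emitted == 0 | !(tr$antisense_tag %in% sense_pl))
    want <- ifelse(em$sense_emitted >= 2, em$sense_emitted, 0)
    expect_equal(expr$sense_count[ok], want[ok])
    ## antisense side: the tag must have no sense-strand placement,
    ## which would win by the sense-priority rule
    ok_a <- unamb(tr$antisense_tag) & !(tr$antisense_tag %in% sense_pl)
    want_a <- ifelse(em$antisense_emitted >= 2, em$antisense_emitted, 0)
    expect_equal(expr$antisense_count[ok_a], want_a[ok_a])
  }
})

test_that("antisense_fraction zero produces no antisense counts downstream", {
  cfg <- sim_config(n_genes = 100, depth = 2e4, antisense_fraction = 0,
                    error_rate = 0, singleton_rate = 0, seed = 6)
  sim <- simulate_dge_experiment(cfg)
  lib <- build_tag_library(sim$transcriptome$transcripts)
  cts <- clean_raw_tags(sim$reads_out$reads[[1]], cfg$adaptor)
  asg <- map_tags(cts, lib)
  expr <- count_expression(asg, cts$total_clean,
                           gene_ids = sim$transcriptome$truth$gene_id)
  expect_true(all(expr$antisense_count == 0))
})

test_that("sequencing errors create mismatch-carrying tags that 1-mismatch mapping rescues", {
  cfg <- sim_config(n_genes = 60, depth = 6e4, error_rate = 0.01,
                    singleton_rate = 0, antisense_fraction = 0, seed = 71)
  sim <- simulate_dge_experiment(cfg)
  lib <- build_tag_library(sim$transcriptome$transcripts)
  cts <- clean_raw_tags(sim$reads_out$reads[[1]], cfg$adaptor)
  asg <- map_tags(cts, lib)
  rescued <- asg[asg$status == "mismatch1_unique", ]
  expect_gt(nrow(rescued), 0)
  ## every rescued tag is credited to the gene whose canonical tag it
  ## derives from
  tr <- sim$transcriptome$truth
  canon <- setNames(tr$gene_id, tr$sense_tag)
  hd <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  for (i in seq_len(min(10, nrow(rescued)))) {
    src <- tr$sense_tag[!is.na(tr$sense_tag) &
                          tr$gene_id == rescued$gene_id[i]]
    expect_equal(hd(rescued$tag_sequence[i], src), 1)
  }
})

test_that("singleton noise reads are removed by the copy-number filter", {
  cfg <- sim_config(n_genes = 50, depth = 1e4, error_rate = 0,
                    singleton_rate = 0.05, antisense_fraction = 0,
                    seed = 19)
  sim <- simulate_dge_experiment(cfg)
  cts <- clean_raw_tags(sim$reads_out$reads[[1]], cfg$adaptor)
  ## noise tags are random 17-mers: the chance any repeats is negligible
  expect_gte(sum(cts$filter_stats["singleton"]),
             0.9 * round(cfg$singleton_rate * cfg$depth))
  expect_equal(cts$total_clean + sum(cts$filter_stats),
               length(sim$reads_out$reads[[1]]))
})

test_that("emitted counts per library sum to the configured depth", {
  cfg <- sim_config(n_genes = 40, depth = 5e3, seed = 2)
  sim <- simulate_dge_experiment(cfg)
  em <- sim$reads_out$emitted
  for (t in cfg$tissues) {
    e <- em[em$tissue == t, ]
    expect_equal(sum(e$sense_emitted) + sum(e$antisense_emitted),
                 cfg$depth)
  }
})

test_that("FASTQ round trip preserves reads", {
  cfg <- sim_config(n_genes = 30, depth = 500, seed = 13)
  sim <- simulate_dge_experiment(cfg)
  fq <- tempfile(fileext = ".fastq")
  write_tag_fastq(sim$reads_out$reads[[1]], fq)
  back <- read_tag_fastq(fq)
  expect_identical(back, sim$reads_out$reads[[1]])
  unlink(fq)
})
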