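## A small fixed reference used across mapping tests: unique sense tags
## for g1/g2, one tag shared by g3 and g4.
align_fixture <- function() {
  t1 <- "CATGAAAAACCCCCGGGGGTT"
  t2 <- "CATGTTTTTGGGGGCCCCCAA"
  shared <- "CATGACACACACACACACACA"
  tx <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    sequence = c(paste0("AA", t1, "AA"),
                 paste0("CC", t2),
                 paste0(shared, "GG"),
                 paste0("TT", shared)),
    stringsAsFactors = FALSE)
  list(tx = tx, lib = build_tag_library(tx), t1 = t1, t2 = t2,
       shared = shared)
}

test_that("exact, one-mismatch and multi-gene tags are classified as expected", {
  fx <- align_fixture()
  mm1 <- fx$t1
  substr(mm1, 10, 10) <- "T"  # Hamming 1 from t1 in the variable region
  asg <- map_tags(c(fx$t1, mm1, fx$shared, "CATGCGCGCGCGCGCGCGCGC"),
                  fx$lib)
  expect_equal(asg$status,
               c("perfect_unique", "mismatch1_unique",
                 "ambiguous_multi_gene", "unmapped"))
  expect_equal(asg$gene_id[1:2], c("g1", "g1"))
  expect_equal(asg$mismatch_count[1:3], c(0L, 1L, 0L))
})

test_that("a perfect hit takes priority over mismatch hits and bad tags are rejected", {
  fx <- align_fixture()
  ## t1 has an exact hit in g1 and is also at Hamming distance 1 from
  ## nothing else here; mutate the library side instead: add a gene
  ## whose tag is 1 mismatch away from t1, so t1 has both a perfect hit
  ## (g1) and a 1-mismatch hit (g5) -- the perfect tier must win
  near <- fx$t1
  substr(near, 21, 21) <- "A"
  tx <- rbind(fx$tx, data.frame(gene_id = "g5", sequence = near))
  lib <- build_tag_library(tx)
  asg <- map_tags(fx$t1, lib)
  expect_equal(asg$status, "perfect_unique")
  expect_equal(asg$gene_id, "g1")
  expect_error(map_tags("CATGAAA", fx$lib), "21")
})

test_that("1-mismatch hits in two different genes are filtered as ambiguous", {
  ## two genes whose tags are at Hamming distance 2 from each other;
  ## a query midway (distance 1 from both) must be ambiguous
  a <- "CATGAAAAAAAAAAAAAAAAA"
  b <- "CATGAAAAAAAAAAAAAAGGA"
  q <- "CATGAAAAAAAAAAAAAAAGA"
  tx <- data.frame(gene_id = c("x", "y"), sequence = c(a, b))
  lib <- build_tag_library(tx)
  asg <- map_tags(q, lib)
  expect_equal(asg$status, "ambiguous_multi_gene")
  expect_equal(asg$mismatch_count, 1L)
})

test_that("mapping agrees with the all-pairs Hamming oracle on random instances", {
  set.seed(23)
  for (rep in 1:3) {
    tx <- random_transcriptome(15, len_range = c(40, 200),
                               seed = 100 + rep)
    lib <- build_tag_library(tx)
    if (lib$n_reference_tags == 0) next
    ## queries: some library tags, some mutated, some random
    base <- sample(unique(lib$placements$tag_sequence),
                   min(10, lib$n_reference_tags))
    mutated <- vapply(base, function(t) {
      p <- sample(5:21, 1)
      substr(t, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(t, p, p)), 1)
      t
    }, character(1))
    rnd <- replicate(5, paste0("CATG", paste(
      sample(c("A", "C", "G", "T"), 17, replace = TRUE), collapse = "")))
    qry <- unique(c(base, mutated, rnd))
    got <- map_tags(qry, lib)
    want <- naive_map(qry, lib$placements)
    expect_equal(got$status, want$status)
    expect_equal(got$gene_id, want$gene_id)
    expect_equal(got$strand, want$strand)
    expect_equal(got$mismatch_count, want$mismatch_count)
  }
})

test_that("every clean tag lands in exactly one status class and copies are conserved", {
  cfg <- sim_config(n_genes = 80, depth = 2e4, seed = 31,
                    singleton_rate = 0.02, error_rate = 0.002)
  sim <- simulate_dge_experiment(cfg)
  lib <- build_tag_library(sim$transcriptome$transcripts)
  cts <- clean_raw_tags(sim$reads_out$reads[[1]], cfg$adaptor)
  asg <- map_tags(cts, lib)
  expect_true(all(asg$status %in% c("perfect_unique", "mismatch1_unique",
                                    "ambiguous_multi_gene", "unmapped")))
  expr <- count_expression(asg, cts$total_clean,
                           gene_ids = sim$transcriptome$truth$gene_id,
                           library_id = "root")
  assigned <- sum(expr$sense_count) + sum(expr$antisense_count)
  other <- sum(asg$count[asg$status %in%
                           c("ambiguous_multi_gene", "unmapped")])
  expect_equal(assigned + other, cts$total_clean)
})

test_that("TPM is linear in counts and inversely proportional to library size", {
  asg <- data.frame(tag_sequence = "CATGAAAAACCCCCGGGGGTT",
                    count = 100L, status = "perfect_unique",
                    gene_id = "g1", strand = "sense",
                    mismatch_count = 0L)
  e1 <- count_expression(asg, 1e6)
  expect_equal(e1$sense_tpm, 100)
  e2 <- count_expression(asg, 2e6)
  expect_equal(e1$sense_tpm / e2$sense_tpm, 2)
  expect_error(count_expression(asg, 0), "positive")
})

test_that("antisense-only genes get zero sense TPM but positive antisense TPM", {
  asg <- data.frame(tag_sequence = "CATGAAAAACCCCCGGGGGTT",
                    count = 3L, status = "perfect_unique",
                    gene_id = "g9", strand = "antisense",
                    mismatch_count = 0L)
  e <- count_expression(asg, 1e5, gene_ids = "g9")
  expect_equal(e$sense_tpm, 0)
  expect_gt(e$antisense_tpm, 0)
})

test_that("RPKM follows its defining formula", {
  expect_equal(compute_rpkm(1000, 1e6, 1000), 1000)
  expect_equal(compute_rpkm(0, 1e6, 500), 0)
  expect_equal(compute_rpkm(50, 2e6, 500), 50)
  expect_error(compute_rpkm(1, 0, 100), "positive")
  expect_error(compute_rpkm(1, 100, 0), "positive")
})

test_that("mapping summary equals a direct recount of the assignment list", {
  fx <- align_fixture()
  reads_tags <- c(rep(fx$t1, 5), rep(fx$t2, 3), rep(fx$shared, 4),
                  rep("CATGCGCGCGCGCGCGCGCGC", 2))
  cts <- clean_tag_set_from_counts(
    as.data.frame(table(tag_sequence = reads_tags),
                  responseName = "count"))
  asg <- map_tags(cts, fx$lib)
  s <- mapping_summary(asg, cts, n_ref_genes = 4)
  expect_equal(s$all_mapped_total, 12)     # 5 + 3 + 4
  expect_equal(s$unambiguous_total, 8)     # 5 + 3
  expect_equal(s$unambiguous_distinct, 2)
  expect_equal(s$genes_detected, 2)
  expect_equal(s$genes_detected_pct, 50)
  expect_equal(s$all_mapped_pct, 100 * 12 / 14)
})

test_that("saturation curve is non-decreasing, seeded, and ends at the full detection count", {
  cfg <- sim_config(n_genes = 120, depth = 3e4, seed = 17,
                    error_rate = 0, singleton_rate = 0)
  sim <- simulate_dge_experiment(cfg)
  lib <- build_tag_library(sim$transcriptome$transcripts)
  cts <- clean_raw_tags(sim$reads_out$reads[[1]], cfg$adaptor)
  asg <- map_tags(cts, lib)
  sat <- saturation_analysis(asg, n_points = 8, seed = 99)
  expect_true(all(diff(sat$genes_detected) >= 0))
  s <- mapping_summary(asg, cts, n_ref_genes = cfg$n_genes)
  expect_equal(sat$genes_detected[nrow(sat)], s$genes_detected)
  sat2 <- saturation_analysis(asg, n_points = 8, seed = 99)
  expect_identical(sat, sat2)
  expect_error(saturation_analysis(asg, n_points = 8), "seed")
})

test_that("novel-transcript search reports unique genomic hits only", {
  tag <- "CATGAAAAACCCCCGGGGGTT"
  twice <- "CATGTTTTTGGGGGCCCCCAA"
  genome <- data.frame(
    target_id = c("fes1", "fes2"),
    sequence = c(paste0("GGGG", tag, "TTTT", twice),
                 paste0(twice, "AAAA")))
  hits <- detect_novel_transcripts(c(tag, twice, "CATGCGCGCGCGCGCGCGCGC"),
                                   genome)
  u <- hits[hits$unique, ]
  expect_equal(u$tag_sequence, tag)
  expect_equal(u$target_id, "fes1")
  expect_equal(u$position, 4L)  # 0-based
  expect_equal(hits$n_hits[hits$tag_sequence == twice], 2L)
  expect_false(any(hits$tag_sequence == "CATGCGCGCGCGCGCGCGCGC"))
})

test_that("reverse-strand genomic hits are found with forward coordinates", {
  tag <- "CATGAAAAACCCCCGGGGGTT"
  genome <- data.frame(target_id = "c1",
                       sequence = paste0("TT", dgetag:::revcomp(tag), "AA"))
  hits <- detect_novel_transcripts(tag, genome)
  expect_equal(hits$strand, "-")
  expect_equal(hits$position, 2L)
  expect_true(hits$unique)
})
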