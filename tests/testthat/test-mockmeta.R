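test_that("mutate_genome substitutes at the requested rate and logs exactly", {
  anc <- Biostrings::DNAStringSet(c(chr = random_dna(1e5, seed = 11)))
  m <- mutate_genome(anc, sub_rate = 0.005, seed = 1)
  n <- nrow(m$mutation_log)
  # observed fraction within 3 binomial SD of the rate
  expect_lt(abs(n / 1e5 - 0.005), 3 * sqrt(0.005 * 0.995 / 1e5))
  # strain differs from the ancestor exactly at the logged positions
  a <- strsplit(as.character(anc[[1]]), "")[[1]]
  s <- strsplit(as.character(m$seq[[1]]), "")[[1]]
  expect_equal(which(a != s) - 1L, m$mutation_log$position)
  expect_equal(a[m$mutation_log$position + 1L], m$mutation_log$ref,
               ignore_attr = TRUE)
  expect_equal(s[m$mutation_log$position + 1L], m$mutation_log$alt,
               ignore_attr = TRUE)
})

test_that("mutate_genome edge cases: zero rate, determinism, bad rate", {
  anc <- Biostrings::DNAStringSet(c(chr = random_dna(5000, seed = 3)))
  m0 <- mutate_genome(anc, 0, seed = 5)
  expect_equal(as.character(m0$seq), as.character(anc))
  expect_equal(nrow(m0$mutation_log), 0L)

  m1 <- mutate_genome(anc, 0.01, seed = 9)
  m2 <- mutate_genome(anc, 0.01, seed = 9)
  expect_identical(as.character(m1$seq), as.character(m2$seq))

  expect_error(mutate_genome(anc, 0.3, seed = 1), "sub_rate")
  expect_error(mutate_genome(anc, -0.1, seed = 1), "sub_rate")
})

test_that("mutation-log ANI identity holds exactly", {
  cm <- make_mock_community(genome_len = 2e4, seed = 13)
  for (id in names(cm$strains))
    expect_equal(truth_ani(cm, id),
                 100 * (1 - nrow(cm$mutation_logs[[id]]) / cm$genome_len))
})

test_that("long reads match expected counts, labels, and sequences", {
  cm <- make_mock_community(n_strains = 1L, long_depths = 10,
                            genome_len = 1e5, divergence = 0.001, seed = 21)
  lr <- simulate_long_reads(cm, mean_len = 10000, len_sd = 1000,
                            error_rate = 0, seed = 4)
  n <- length(lr$reads)
  expect_lt(abs(n - 100), 4 * sqrt(100))  # Poisson around depth*G/mean_len
  expect_equal(nrow(lr$truth), n)         # every read labelled once
  expect_setequal(lr$truth$read_id, names(lr$reads))
  # with error_rate 0 every read is an exact substring of the (circular)
  # strain, up to strand
  doubled <- strrep(as.character(cm$strains[["strain01"]]), 2)
  for (i in head(seq_len(n), 10)) {
    r <- as.character(lr$reads[[i]])
    if (lr$layout$strand[i] == "-")
      r <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r)))
    expect_equal(r, substr(doubled, lr$layout$start[i] + 1L,
                           lr$layout$start[i] + lr$layout$length[i]))
  }
})

test_that("per-strain long-read counts track abundances", {
  cm <- make_mock_community(n_strains = 2L, long_depths = c(50, 10),
                            divergence = 0.001, genome_len = 1e5, seed = 31)
  lr <- simulate_long_reads(cm, mean_len = 5000, len_sd = 500, seed = 8)
  counts <- table(lr$truth$strain_id)
  ratio <- counts[["strain01"]] / counts[["strain02"]]
  expect_gt(ratio, 3.5)
  expect_lt(ratio, 7)
})

test_that("short-read pairs obey geometry, counts and error model", {
  cm <- make_mock_community(n_strains = 1L, short_depths = 20,
                            divergence = 0.001, genome_len = 1e5, seed = 41)
  sr <- simulate_short_reads(cm, read_len = 100L, insert = 150L,
                             base_error = 0, seed = 2)
  n <- nrow(sr$layout)
  expect_lt(abs(n - 10000), 4 * sqrt(10000))  # depth*G/(2*read_len)
  expect_equal(length(sr$r1), n)
  expect_equal(length(sr$r2), n)
  # error-free mates are exact substrings of the circular strain
  doubled <- strrep(as.character(cm$strains[["strain01"]]), 2)
  for (i in 1:5) {
    s <- sr$layout$start[i]
    expect_equal(as.character(sr$r1[[i]]), substr(doubled, s + 1, s + 100))
    expect_equal(as.character(Biostrings::reverseComplement(sr$r2[[i]])),
                 substr(doubled, s + 51, s + 150))
  }
  expect_error(simulate_short_reads(cm, read_len = 200L, insert = 150L),
               "insert")
})

test_that("error injection hits the requested rate", {
  cm <- make_mock_community(n_strains = 1L, short_depths = 20,
                            divergence = 0, genome_len = 5e4, seed = 43)
  sr <- simulate_short_reads(cm, base_error = 0.01, seed = 3)
  doubled <- strrep(as.character(cm$strains[["strain01"]]), 2)
  truth1 <- substring(doubled, sr$layout$start + 1, sr$layout$start + 100)
  obs <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
                as.character(sr$r1), truth1)
  rate <- sum(obs) / (100 * length(obs))
  expect_lt(abs(rate - 0.01), 3 * sqrt(0.01 * 0.99 / (100 * length(obs))))
})

test_that("mock outputs are byte-identical under the same seed", {
  cm <- make_mock_community(n_strains = 2L, long_depths = c(20, 10),
                            short_depths = 10, genome_len = 2e4, seed = 7)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_mock_community(cm, d1, seed = 99, mean_len = 2000, len_sd = 200)
  write_mock_community(cm, d2, seed = 99, mean_len = 2000, len_sd = 200)
  for (f in list.files(d1))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
})

test_that("align_by_truth recruits essentially all mates at high coverage", {
  cm <- make_mock_community(n_strains = 1L, long_depths = 30,
                            short_depths = 10, divergence = 0.001,
                            genome_len = 5e4, seed = 51)
  lr <- simulate_long_reads(cm, mean_len = 5000, len_sd = 500, seed = 6)
  sr <- simulate_short_reads(cm, seed = 6)
  aln <- align_by_truth(lr$layout, sr$layout, genome_len = cm$genome_len,
                        seed = 6)
  # one record per recruited mate, each fully aligned within its target
  expect_lte(nrow(aln), 2L * nrow(sr$layout))
  expect_gt(nrow(aln), 1.9 * nrow(sr$layout))  # few coverage gaps at 30x
  expect_true(all(aln$aligned_query_bases == 100L))
  len <- setNames(lr$layout$length, lr$layout$read_id)
  expect_true(all(aln$target_end <= len[aln$target_id]))
  expect_true(all(aln$target_start >= 0L))
  expect_equal(anyDuplicated(aln$query_id), 0L)
})

test_that("planted annotations respect class counts and packing limits", {
  pa <- plant_annotations(n_core = 30, n_specific = 0, te_enrichment = 3,
                          seed = 5)
  expect_equal(nrow(pa$classes), 30L)
  expect_true(all(pa$classes$class == "core"))
  genes <- pa$features[pa$features$feature_class == "cds", ]
  expect_equal(nrow(genes), 30L)
  expect_true(all(genes$end <= pa$contig_len))

  expect_error(plant_annotations(n_core = 100, n_specific = 100,
                                 genome_len = 1e4, seed = 1),
               "infeasible packing")
})

test_that("null TE enrichment gives balanced flank densities", {
  pa <- plant_annotations(n_core = 120, n_specific = 120, te_enrichment = 1,
                          seed = 17)
  fd <- flank_density(pa$features, pa$classes$gene_id,
                      contig_lengths = c(chr1 = pa$contig_len))
  cls <- setNames(pa$classes$class, pa$classes$gene_id)[fd$gene_id]
  ht <- rank_sum_test(fd$te_density[cls == "specific"],
                      fd$te_density[cls == "core"])
  expect_gt(ht$p_value, 0.05)
})
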