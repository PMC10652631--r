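# Presence/absence matrix builder: orthologs x genomes.
presence_matrix <- function(rows) {
  m <- do.call(rbind, rows)
  rownames(m) <- sprintf("OG%03d", seq_len(nrow(m)))
  colnames(m) <- sprintf("G%02d", seq_len(ncol(m)))
  m
}

test_that("core calling applies the strict >90% rule", {
  m <- presence_matrix(list(
    c(rep(1L, 26), 0L, 0L),   # 26/28 = 92.9%  -> core
    c(rep(1L, 25), 0L, 0L, 0L),  # 25/28 = 89.3% -> not core
    rep(1L, 28),              # all present -> core
    rep(0L, 28)))
  expect_setequal(call_core(m), c("OG001", "OG003"))
  expect_true("OG003" %in% call_core(m, threshold = 0.999))
  expect_error(call_core(m[0, , drop = FALSE]), "empty")
})

test_that("one-sided Fisher p equals the hypergeometric tail", {
  # 10/10 present in the clade, 0/18 outside
  m <- presence_matrix(list(c(rep(1L, 10), rep(0L, 18)),
                            rep(1L, 28)))
  clades <- setNames(rep(c("vent", "seep"), c(10, 18)), colnames(m))
  gc <- call_clade_specific(m, clades)
  t1 <- gc$tests[gc$tests$ortholog_id == "OG001" & gc$tests$clade == "vent", ]
  # oracle: exhaustive hypergeometric tail mass, P(X >= 10) drawing 10
  # present genomes out of 10/28
  oracle <- sum(dhyper(10:10, m = 10, n = 18, k = 10))
  expect_equal(t1$fisher_p, oracle, tolerance = 1e-12)
  expect_true(t1$specific)
  expect_true("OG001" %in% gc$specific$vent)
})

test_that("uniqueness is required regardless of significance", {
  # strong enrichment but one copy outside the clade
  m <- presence_matrix(list(c(rep(1L, 10), 1L, rep(0L, 17)),
                            rep(1L, 28)))
  clades <- setNames(rep(c("vent", "seep"), c(10, 18)), colnames(m))
  gc <- call_clade_specific(m, clades)
  expect_false(any(gc$tests$specific[gc$tests$ortholog_id == "OG001"]))
  # uniform presence: nothing specific anywhere
  expect_true(all(lengths(gc$specific[["seep"]]) == 0))
})

test_that("core and specific classifications are disjoint", {
  withr::with_seed(42, {
    m <- matrix(rbinom(50 * 12, 1, 0.6), nrow = 50,
                dimnames = list(sprintf("OG%03d", 1:50),
                                sprintf("G%02d", 1:12)))
  })
  clades <- setNames(rep(c("a", "b", "c"), each = 4), colnames(m))
  gc <- call_clade_specific(m, clades)
  expect_length(intersect(gc$core, unlist(gc$specific)), 0L)
  cls <- gc$classification
  expect_setequal(names(cls), rownames(m))
  expect_equal(sum(cls == "core"), length(gc$core))
})

test_that("clade input validation", {
  m <- presence_matrix(list(rep(1L, 4)))
  expect_error(call_clade_specific(m, setNames(rep("a", 4), colnames(m))),
               "at least 2 clades")
  expect_error(call_clade_specific(
    m, setNames(c("a", "a", "a", "b"), colnames(m))), "fewer than 2")
})

test_that("potential sites: TTT worked example and conservation", {
  ps <- potential_sites("TTT")
  expect_equal(ps[["S_pot"]], 1 / 3)
  expect_equal(ps[["N_pot"]], 8 / 3)
  for (s in c(random_cds(10, seed = 1), random_cds(33, seed = 2)))
    expect_equal(sum(potential_sites(s)), 3 * (nchar(s) / 3))
  expect_error(potential_sites("TTTTAAGGG"), "internal stop")
  expect_error(potential_sites("TTTT"), "multiple of 3")
})

test_that("potential sites match an all-nine-mutations enumeration oracle", {
  code <- Biostrings::getGeneticCode("11")
  oracle <- function(cds) {
    n_s <- 0
    for (i in seq(1, nchar(cds), 3)) {
      codon <- substr(cds, i, i + 2)
      aa <- code[[codon]]
      for (pos in 1:3) for (b in c("A", "C", "G", "T")) {
        if (b == substr(codon, pos, pos)) next
        mut <- codon; substr(mut, pos, pos) <- b
        if (code[[mut]] == aa) n_s <- n_s + 1 / 3
      }
    }
    c(N_pot = nchar(cds) - n_s, S_pot = n_s)
  }
  for (seed in 1:20) {
    cds <- random_cds(30, seed = seed)
    expect_equal(potential_sites(cds), oracle(cds))
  }
})

test_that("variant classification follows the code table", {
  expect_equal(classify_variant("TTT", 2, "C"), "synonymous")     # TTT->TTC
  expect_equal(classify_variant("TTT", 2, "A"), "nonsynonymous")  # Phe->Leu
  expect_equal(classify_variant("TGC", 2, "A"), "nonsynonymous")  # Cys->stop
  expect_error(classify_variant("TTT", 0, "T"), "alt equals")
  expect_error(classify_variant("TTT", 3, "A"), "outside CDS")
})

test_that("pN/pS arithmetic, +1 correction, and degenerate cases", {
  expect_equal(pnps_ratio(7, 1, 700, 200), 1.0)
  cds <- random_cds(50, seed = 9)
  none <- compute_pnps(cds, data.frame(position = integer(),
                                       alt = character()))
  expect_equal(none$pnps, 0)
  expect_equal(none$S_obs, 0)
  expect_error(pnps_ratio(1, 1, 0, 10), "positive")
})

test_that("pN/pS matches a hand recount on planted variants", {
  cds <- random_cds(100, seed = 33)
  withr::with_seed(14, {
    pos <- sample(0:(nchar(cds) - 1), 25)
    ref <- substring(cds, pos + 1, pos + 1)
    alt <- vapply(ref, function(b) sample(setdiff(c("A","C","G","T"), b), 1), "")
  })
  variants <- data.frame(position = pos, alt = alt)
  st <- compute_pnps(cds, variants)
  cls <- vapply(seq_len(25), function(i)
    classify_variant(cds, pos[i], alt[i]), "")
  expect_equal(st$N_obs, sum(cls == "nonsynonymous"))
  expect_equal(st$S_obs, sum(cls == "synonymous"))
  pot <- potential_sites(cds)
  expect_equal(st$pnps, (st$N_obs / pot[["N_pot"]]) /
                 ((st$S_obs + 1) / pot[["S_pot"]]))
})

test_that("pN/pS is monotone in added variants", {
  cds <- random_cds(60, seed = 41)
  base <- data.frame(position = c(0, 4), alt = c("G", "G"))
  base <- base[vapply(seq_len(2), function(i)
    substr(cds, base$position[i] + 1, base$position[i] + 1) != "G", TRUE), ]
  p0 <- compute_pnps(cds, base)$pnps
  # find one synonymous and one nonsynonymous addition
  found_s <- found_n <- FALSE
  for (p in 0:(nchar(cds) - 1)) {
    refb <- substr(cds, p + 1, p + 1)
    for (b in setdiff(c("A", "C", "G", "T"), refb)) {
      cl <- classify_variant(cds, p, b)
      add <- rbind(base, data.frame(position = p, alt = b))
      pn <- compute_pnps(cds, add)$pnps
      if (cl == "synonymous" && !found_s) { expect_lte(pn, p0); found_s <- TRUE }
      if (cl == "nonsynonymous" && !found_n) { expect_gte(pn, p0); found_n <- TRUE }
      if (found_s && found_n) break
    }
    if (found_s && found_n) break
  }
  expect_true(found_s && found_n)
})

test_that("dN/dS outlier filter keeps the stated open/closed interval", {
  v <- c(a = 0.5, b = 4.5, c = 0.0001)
  expect_equal(filter_rate_outliers(v), c(a = 0.5))
  expect_equal(filter_rate_outliers(c(x = 4.0)), c(x = 4.0))  # boundary kept
  expect_length(filter_rate_outliers(numeric()), 0L)
})

test_that("concatenation sampling is uniform, distinct and conserving", {
  aln <- lapply(setNames(1:30, sprintf("OG%02d", 1:30)), function(i)
    setNames(rep(strrep("ACGT", i), 3), c("t1", "t2", "t3")))
  cs <- sample_concatenations(aln, n_sets = 40, set_size = 5, seed = 6)
  expect_length(cs$concatenations, 40L)
  expect_true(all(lengths(lapply(cs$members, unique)) == 5L))
  for (i in c(1, 40)) {
    width <- sum(vapply(aln[cs$members[[i]]], function(a) nchar(a[[1]]), 0))
    expect_true(all(nchar(cs$concatenations[[i]]) == width))
    expect_equal(names(cs$concatenations[[i]]), c("t1", "t2", "t3"))
  }
  # set_size = total -> every set identical
  all_sets <- sample_concatenations(aln, n_sets = 3, set_size = 30, seed = 1)
  expect_equal(all_sets$concatenations[[1]], all_sets$concatenations[[2]])
  expect_error(sample_concatenations(aln, set_size = 31), "set_size")
  expect_identical(sample_concatenations(aln, 5, 4, seed = 2)$members,
                   sample_concatenations(aln, 5, 4, seed = 2)$members)
})

test_that("Hudson FST: fixed difference, null, and label symmetry", {
  fixed <- data.frame(position = 0, alt_count_a = 50, total_count_a = 50,
                      alt_count_b = 0, total_count_b = 50)
  expect_equal(gene_fst(fixed)$fst, 1)

  null <- data.frame(position = 0:9, alt_count_a = 25, total_count_a = 50,
                     alt_count_b = 25, total_count_b = 50)
  expect_lte(gene_fst(null)$fst, 0)

  withr::with_seed(3, {
    v <- data.frame(position = 0:49,
                    alt_count_a = rbinom(50, 40, 0.3), total_count_a = 40,
                    alt_count_b = rbinom(50, 60, 0.6), total_count_b = 60)
  })
  swapped <- data.frame(position = v$position,
                        alt_count_a = v$alt_count_b,
                        total_count_a = v$total_count_b,
                        alt_count_b = v$alt_count_a,
                        total_count_b = v$total_count_a)
  expect_equal(gene_fst(v)$fst, gene_fst(swapped)$fst)
  expect_lte(gene_fst(v)$fst, 1)

  mono <- data.frame(position = 0, alt_count_a = 0, total_count_a = 50,
                     alt_count_b = 0, total_count_b = 50)
  expect_error(gene_fst(mono), "no usable site")
  expect_error(gene_fst(fixed[0, ]), "no sites")
  bad <- transform(fixed, total_count_b = 1)
  expect_error(gene_fst(bad), "total_count")
})

test_that("rank-sum test: ties, exact extremes, and path agreement", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # most extreme arrangement at n = 3 vs 3: exact two-sided p = 2/choose(6,3)
  ht <- rank_sum_test(c(1, 2, 3), c(10, 11, 12))
  expect_equal(ht$p_value, 2 / choose(6, 3))
  # exact and normal paths agree to ~0.01 at n = 8
  withr::with_seed(10, {
    a <- rnorm(8); b <- rnorm(8, 0.8)
  })
  exact_p <- rank_sum_test(a, b)$p_value
  norm_p <- suppressWarnings(wilcox.test(a, b, exact = FALSE,
                                         correct = TRUE)$p.value)
  expect_lt(abs(exact_p - norm_p), 0.01)
  expect_error(rank_sum_test(1:2, 1:5), "at least 3")
})

test_that("fragment ANI recovers mutation-log truth on mock strains", {
  anc <- Biostrings::DNAStringSet(c(chr = random_dna(3e4, seed = 61)))
  m <- mutate_genome(anc, 0.005, seed = 8)
  ani <- pairwise_ani(anc, m$seq)
  truth <- 100 * (1 - nrow(m$mutation_log) / 3e4)
  expect_lt(abs(as.numeric(ani) - truth), 0.1)
  # identical genomes
  expect_equal(as.numeric(pairwise_ani(anc, anc)), 100)
  # near-symmetry
  expect_lt(abs(as.numeric(pairwise_ani(m$seq, anc)) -
                as.numeric(ani)), 0.2)
})

test_that("ANI decreases monotonically with planted divergence", {
  anc <- Biostrings::DNAStringSet(c(chr = random_dna(2e4, seed = 62)))
  anis <- vapply(c(0.001, 0.005, 0.01), function(r)
    as.numeric(pairwise_ani(anc, mutate_genome(anc, r, seed = 9)$seq)), 0)
  expect_true(all(diff(anis) < 0))
  expect_error(pairwise_ani("ACGT", "ACGT"), "10 kb")
})
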