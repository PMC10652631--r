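# Pangenome partitioning and evolutionary statistics: core / clade-specific
# ortholog calling, Nei-Gojobori pN/pS, dN/dS output filtering and
# concatenation sampling, per-gene Hudson FST, and the shared rank-sum test.

# --- core / clade-specific calling ---------------------------------------

check_ortholog_matrix <- function(matrix) {
  matrix <- as.matrix(matrix)
  if (!nrow(matrix) || !ncol(matrix)) stop_("empty ortholog matrix")
  if (ncol(matrix) < 2L) stop_("need at least 2 genomes")
  if (any(matrix < 0) || any(matrix != round(matrix)))
    stop_("ortholog matrix must hold non-negative integer copy numbers")
  matrix
}

#' Call core orthologs
#'
#' An ortholog is core iff it is present (copy number >= 1) in strictly
#' more than `threshold` of all genomes (default: shared in more than 90%).
#'
#' @param matrix Numeric matrix of copy numbers, orthologs x genomes.
#' @param threshold Presence fraction that must be strictly exceeded.
#' @return Character vector of core ortholog ids.
#' @export
call_core <- function(matrix, threshold = 0.90) {
  matrix <- check_ortholog_matrix(matrix)
  frac <- rowMeans(matrix >= 1L)
  rownames(matrix)[frac > threshold]
}

#' Call clade-specific orthologs
#'
#' For every (ortholog, clade) pair a one-sided Fisher exact test (presence
#' enriched in the clade) is computed on the 2x2 presence table, adjusted by
#' Benjamini-Hochberg within each clade across orthologs. An ortholog is
#' specific to a clade iff the adjusted p-value is below `alpha`, it is
#' present in at least one genome of the clade, and absent from every
#' genome outside it (enrichment and uniqueness must both hold).
#'
#' @param matrix Numeric matrix of copy numbers, orthologs x genomes.
#' @param clades Named character vector `genome_id -> clade label`; at least
#'   2 clades with at least 2 genomes each.
#' @param alpha Adjusted significance level.
#' @param core_threshold Threshold forwarded to [call_core()] for the
#'   combined classification.
#' @return An object of class `gene_classification`: list with `tests`
#'   (per ortholog x clade: presence counts, `fisher_p`, `adjusted_p`,
#'   `specific`), `specific` (named list clade -> ortholog ids), `core`
#'   (ortholog ids) and `classification` (named vector: `"core"`,
#'   `"specific:<clade>"` or `"neither"`).
#' @export
call_clade_specific <- function(matrix, clades, alpha = 0.05,
                                core_threshold = 0.90) {
  matrix <- check_ortholog_matrix(matrix)
  genomes <- colnames(matrix)
  if (is.null(genomes) || !all(genomes %in% names(clades)))
    stop_("every genome column needs a clade label")
  clades <- clades[genomes]
  labels <- unique(clades)
  if (length(labels) < 2L) stop_("need at least 2 clades")
  sizes <- table(clades)
  if (any(sizes < 2L))
    stop_("clade(s) with fewer than 2 genomes: %s",
          paste(names(sizes)[sizes < 2L], collapse = ", "))
  present <- matrix >= 1L
  tests <- do.call(rbind, lapply(labels, function(cl) {
    inc <- clades == cl
    p_in <- rowSums(present[, inc, drop = FALSE])
    p_out <- rowSums(present[, !inc, drop = FALSE])
    n_in <- sum(inc); n_out <- sum(!inc)
    p <- vapply(seq_len(nrow(matrix)), function(i) {
      fisher.test(matrix(c(p_in[i], n_in - p_in[i],
                           p_out[i], n_out - p_out[i]), nrow = 2L),
                  alternative = "greater")$p.value
    }, 0)
    data.frame(ortholog_id = rownames(matrix), clade = cl,
               present_in = p_in, n_in = n_in,
               present_out = p_out, n_out = n_out,
               fisher_p = p, adjusted_p = p.adjust(p, method = "BH"),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  tests$specific <- tests$adjusted_p < alpha & tests$present_in >= 1L &
    tests$present_out == 0L
  specific <- lapply(setNames(labels, labels), function(cl)
    tests$ortholog_id[tests$clade == cl & tests$specific])
  core <- call_core(matrix, threshold = core_threshold)
  classification <- setNames(rep("neither", nrow(matrix)), rownames(matrix))
  classification[core] <- "core"
  for (cl in labels)
    classification[specific[[cl]]] <- paste0("specific:", cl)
  structure(list(tests = tests, specific = specific, core = core,
                 classification = classification, alpha = alpha),
            class = "gene_classification")
}

#' @export
print.gene_classification <- function(x, ...) {
  cat(sprintf("gene_classification: %d core, %s specific\n",
              length(x$core),
              paste(sprintf("%s=%d", names(x$specific),
                            lengths(x$specific)), collapse = ", ")))
  invisible(x)
}

# --- pN/pS ----------------------------------------------------------------

translate_codon <- function(codon, code) {
  aa <- code[codon]
  if (is.na(aa)) stop_("untranslatable codon: %s", codon)
  unname(aa)
}

check_cds <- function(cds, code) {
  if (is(cds, "DNAString") || is(cds, "DNAStringSet"))
    cds <- as.character(cds)[[1L]]
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n == 0L || n %% 3L != 0L)
    stop_("CDS length (%d) must be a positive multiple of 3", n)
  if (grepl("[^ACGT]", cds)) stop_("CDS must contain only A/C/G/T")
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  internal_stop <- which(code[codons] == "*" &
                           seq_along(codons) < length(codons))
  if (length(internal_stop))
    stop_("internal stop codon at codon index %d", internal_stop[1L])
  codons
}

#' Potential synonymous and nonsynonymous site counts of a CDS
#'
#' Nei-Gojobori style: each codon position contributes the fraction of its
#' three possible single-base substitutions that are synonymous (to S) or
#' nonsynonymous (to N); substitutions creating a stop codon count as
#' nonsynonymous. `N_pot + S_pot = 3 * number of codons` exactly.
#'
#' @param cds In-frame coding sequence (character, `DNAString`, or
#'   `DNAStringSet` of length 1); internal stop codons are an error.
#' @param code_id Genetic code table id (default `"11"`, bacterial).
#' @return Named numeric vector `c(N_pot = ..., S_pot = ...)`.
#' @export
potential_sites <- function(cds, code_id = "11") {
  code <- Biostrings::getGeneticCode(code_id)
  codons <- check_cds(cds, code)
  s_tab <- codon_s_table(code_id)
  s_pot <- sum(s_tab[codons])
  total <- 3 * length(codons)
  c(N_pot = total - s_pot, S_pot = s_pot)
}

# Synonymous-site contribution of every codon (sum over the 9 single-base
# changes of 1/3 per synonymous change; stop-gaining changes are
# nonsynonymous because '*' never equals an amino acid). Cached per code.
.codon_s_cache <- new.env(parent = emptyenv())
codon_s_table <- function(code_id) {
  if (!is.null(.codon_s_cache[[code_id]])) return(.codon_s_cache[[code_id]])
  code <- Biostrings::getGeneticCode(code_id)
  bases <- c("A", "C", "G", "T")
  codons <- names(code)
  tab <- vapply(codons, function(codon) {
    aa <- code[[codon]]
    s <- 0
    for (pos in 1:3) {
      ref <- substr(codon, pos, pos)
      for (b in setdiff(bases, ref)) {
        alt_codon <- codon
        substr(alt_codon, pos, pos) <- b
        if (code[[alt_codon]] == aa) s <- s + 1 / 3
      }
    }
    s
  }, 0)
  .codon_s_cache[[code_id]] <- tab
  tab
}

#' Classify a single-nucleotide variant as synonymous or nonsynonymous
#'
#' Translates the affected codon before and after the substitution; an
#' unchanged amino acid is synonymous. Changes creating or destroying a stop
#' codon are nonsynonymous.
#'
#' @param cds In-frame coding sequence.
#' @param position 0-based position of the variant within the CDS.
#' @param alt Alternative base (must differ from the reference base).
#' @param code_id Genetic code table id.
#' @return `"synonymous"` or `"nonsynonymous"`.
#' @export
classify_variant <- function(cds, position, alt, code_id = "11") {
  code <- Biostrings::getGeneticCode(code_id)
  codons <- check_cds(cds, code)
  n <- 3L * length(codons)
  if (position < 0L || position >= n)
    stop_("position %d outside CDS of length %d", position, n)
  alt <- toupper(alt)
  if (!alt %in% c("A", "C", "G", "T")) stop_("alt must be one of A/C/G/T")
  ci <- position %/% 3L + 1L
  offset <- position %% 3L + 1L
  codon <- codons[ci]
  ref <- substr(codon, offset, offset)
  if (alt == ref) stop_("alt equals the reference base at position %d", position)
  alt_codon <- codon
  substr(alt_codon, offset, offset) <- alt
  aa_ref <- translate_codon(codon, code)
  aa_alt <- translate_codon(alt_codon, code)
  if (aa_ref == aa_alt) "synonymous" else "nonsynonymous"
}

#' pN/pS ratio from observed and potential counts
#'
#' `pnps = (N_obs / N_pot) / ((S_obs + 1) / S_pot)`; the +1 on the observed
#' synonymous count keeps the ratio defined for genes without synonymous
#' variants (a gene with no variants at all therefore has pN/pS of 0, not
#' NaN).
#'
#' @param N_obs,S_obs Observed nonsynonymous / synonymous variant counts.
#' @param N_pot,S_pot Potential site counts (both > 0).
#' @return The pN/pS ratio.
#' @export
pnps_ratio <- function(N_obs, S_obs, N_pot, S_pot) {
  if (any(N_pot <= 0) || any(S_pot <= 0))
    stop_("potential site counts must be positive")
  (N_obs / N_pot) / ((S_obs + 1) / S_pot)
}

#' pN/pS of one gene from its variants
#'
#' Observed variants are classified with [classify_variant()] and counted by
#' presence (any `alt_count > 0`); with `weight_by_frequency = TRUE` each
#' variant instead contributes its pooled alternative-allele frequency.
#' Counts are normalised by the potential site counts, and 1 is added to the
#' observed synonymous count so the ratio is always defined:
#' `pnps = (N_obs / N_pot) / ((S_obs + 1) / S_pot)`.
#'
#' @param cds In-frame coding sequence of the gene.
#' @param variants Data frame with 0-based `position` and `alt` (optionally
#'   `alt_count`, `total_count` for frequency weighting); may have 0 rows.
#' @param code_id Genetic code table id.
#' @param weight_by_frequency Weight variants by pooled allele frequency
#'   instead of presence.
#' @return An object of class `selection_stats`: list with `N_obs`, `S_obs`,
#'   `N_pot`, `S_pot` and `pnps`.
#' @export
compute_pnps <- function(cds, variants, code_id = "11",
                         weight_by_frequency = FALSE) {
  pot <- potential_sites(cds, code_id)
  if (pot[["N_pot"]] <= 0 || pot[["S_pot"]] <= 0)
    stop_("potential site count of zero; pN/pS undefined")
  n_obs <- 0; s_obs <- 0
  if (!is.null(variants) && nrow(variants)) {
    assert_df_cols(variants, c("position", "alt"), "variant table")
    w <- if (weight_by_frequency) {
      assert_df_cols(variants, c("alt_count", "total_count"), "variant table")
      variants$alt_count / variants$total_count
    } else rep(1, nrow(variants))
    cls <- vapply(seq_len(nrow(variants)), function(i)
      classify_variant(cds, variants$position[i], variants$alt[i], code_id), "")
    n_obs <- sum(w[cls == "nonsynonymous"])
    s_obs <- sum(w[cls == "synonymous"])
  }
  structure(list(N_obs = n_obs, S_obs = s_obs,
                 N_pot = pot[["N_pot"]], S_pot = pot[["S_pot"]],
                 pnps = pnps_ratio(n_obs, s_obs,
                                   pot[["N_pot"]], pot[["S_pot"]])),
            class = "selection_stats")
}

#' @export
print.selection_stats <- function(x, ...) {
  cat(sprintf("pN/pS = %.4f  (N %s/%.2f, S %s/%.2f, +1 correction on S)\n",
              x$pnps, format(x$N_obs), x$N_pot, format(x$S_obs), x$S_pot))
  invisible(x)
}

# --- dN/dS output handling ------------------------------------------------

#' Filter outlier dN/dS values
#'
#' Keeps `v` iff `low < v <= high` (defaults: drop values <= 0.0001 or > 4,
#' the standard outlier filter applied to codeml-style outputs).
#'
#' @param values Named numeric vector `gene -> dN/dS`.
#' @param low,high Exclusive lower / inclusive upper bound.
#' @return The retained subset of `values`.
#' @export
filter_rate_outliers <- function(values, low = 0.0001, high = 4) {
  values[!is.na(values) & values > low & values <= high]
}

#' Sample random ortholog concatenations
#'
#' Draws `n_sets` independent sets of `set_size` distinct orthologs
#' (uniformly, without replacement within a set) and concatenates their
#' alignments taxon-wise, preserving row order. Used to stabilise per-clade
#' evolutionary-rate estimates (default 1000 concatenations of 25
#' orthologs).
#'
#' @param alignments Named list of aligned [Biostrings::DNAStringSet]s (or
#'   character vectors), all sharing the same taxon names.
#' @param n_sets Number of concatenations.
#' @param set_size Orthologs per concatenation.
#' @param seed Integer seed.
#' @return A list with `members` (list of ortholog-id vectors) and
#'   `concatenations` (list of named character vectors, taxon -> sequence).
#' @export
sample_concatenations <- function(alignments, n_sets = 1000L, set_size = 25L,
                                  seed = 1L) {
  if (length(alignments) < set_size)
    stop_("only %d ortholog alignments available but set_size is %d",
          length(alignments), set_size)
  if (is.null(names(alignments))) stop_("alignments must be named by ortholog")
  aln <- lapply(alignments, function(a) {
    a <- if (is.character(a)) a else as.character(a)
    if (is.null(names(a))) stop_("each alignment must have taxon names")
    a
  })
  taxa <- names(aln[[1L]])
  for (a in aln)
    if (!identical(sort(names(a)), sort(taxa)))
      stop_("all alignments must share the same taxon set")
  with_seed(seed, {
    members <- lapply(seq_len(n_sets), function(i)
      names(aln)[sample.int(length(aln), set_size)])
    concatenations <- lapply(members, function(ids) {
      parts <- lapply(aln[ids], function(a) a[taxa])
      setNames(do.call(paste0, parts), taxa)
    })
    list(members = members, concatenations = concatenations)
  })
}

# --- FST ------------------------------------------------------------------

#' Per-gene Hudson FST from allele counts in two populations
#'
#' Per site: `num = (p1 - p2)^2 - p1 (1 - p1) / (n1 - 1) - p2 (1 - p2) /
#' (n2 - 1)` and `den = p1 (1 - p2) + p2 (1 - p1)`; the gene-level estimate
#' is the ratio of averages `sum(num) / sum(den)` (Hudson estimator,
#' ratio-of-averages form). Sites with `den = 0` (monomorphic in both
#' populations) are skipped; a gene with no usable site is an error,
#' distinct from an estimate of 0. The estimate is invariant under swapping
#' the population labels and is at most 1.
#'
#' @param variants Data frame for one gene with columns `position`,
#'   `alt_count_a`, `total_count_a`, `alt_count_b`, `total_count_b` (counts
#'   of the alternative allele and of all sampled alleles per population).
#' @return An object of class `fst_result`: list with `fst` and `n_sites`.
#' @export
gene_fst <- function(variants) {
  assert_df_cols(variants, c("position", "alt_count_a", "total_count_a",
                             "alt_count_b", "total_count_b"), "variant table")
  if (!nrow(variants)) stop_("no sites supplied")
  n1 <- variants$total_count_a; n2 <- variants$total_count_b
  if (any(n1 < 2L) || any(n2 < 2L))
    stop_("every site needs total_count >= 2 in both populations")
  if (any(variants$alt_count_a > n1) || any(variants$alt_count_b > n2))
    stop_("alt_count exceeds total_count")
  p1 <- variants$alt_count_a / n1
  p2 <- variants$alt_count_b / n2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  use <- den > 0
  if (!any(use))
    stop_("no usable site: all sites are monomorphic in both populations")
  structure(list(fst = sum(num[use]) / sum(den[use]),
                 n_sites = sum(use)),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("Hudson FST = %.4f over %d site(s)\n", x$fst, x$n_sites))
  invisible(x)
}

# --- rank-sum test --------------------------------------------------------

#' Wilcoxon rank-sum test (two-sided)
#'
#' Thin wrapper over [stats::wilcox.test()]: exact enumeration when both
#' samples have at most 8 observations and no ties are present, otherwise
#' the tie-corrected normal approximation with continuity correction.
#'
#' @param sample_a,sample_b Numeric samples, each of size >= 3.
#' @return A list with `statistic` (rank-sum W) and `p_value`.
#' @export
rank_sum_test <- function(sample_a, sample_b) {
  if (length(sample_a) < 3L || length(sample_b) < 3L)
    stop_("each sample needs at least 3 observations")
  exact <- length(sample_a) <= 8L && length(sample_b) <= 8L &&
    !anyDuplicated(c(sample_a, sample_b))
  ht <- suppressWarnings(wilcox.test(sample_a, sample_b, exact = exact,
                                     correct = TRUE,
                                     alternative = "two.sided"))
  list(statistic = unname(ht$statistic), p_value = min(1, ht$p.value))
}
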