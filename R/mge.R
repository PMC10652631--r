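# Mobile-genetic-element analytics: flanking gene/transposase densities,
# plasmid-candidate filtering, and abundance normalisations.

#' Gene and transposase density in the flanks of focal genes
#'
#' For each focal gene the window is `[start - flank, start) U
#' [end, end + flank)`, clipped to the contig bounds; a feature counts if it
#' overlaps the window by at least `min_overlap` bp (the focal gene itself
#' never counts). Densities are per kb of the flank actually available
#' (`flank_bp_used`), so genes near contig edges are not biased downward.
#'
#' @param annotations Feature annotation `data.frame`
#'   (see [feature_annotations()]).
#' @param focal_ids Gene ids of the focal genes (must exist in
#'   `annotations`).
#' @param contig_lengths Named vector of contig lengths (bp) covering every
#'   focal gene's contig.
#' @param flank Flank size (bp) on each side.
#' @param min_overlap Minimum overlap (bp) for a feature to count.
#' @return A `data.frame` with `gene_id`, `flank_bp_used`, `n_genes`,
#'   `n_te`, `gene_density` and `te_density` (per kb).
#' @export
flank_density <- function(annotations, focal_ids, contig_lengths,
                          flank = 3000L, min_overlap = 1L) {
  annotations <- validate_features(annotations)
  missing <- setdiff(focal_ids, annotations$gene_id)
  if (length(missing))
    stop_("focal gene(s) absent from annotations: %s",
          paste(head(missing, 5L), collapse = ", "))
  idx <- match(focal_ids, annotations$gene_id)
  ctg <- annotations$contig_id[idx]
  no_len <- setdiff(unique(ctg), names(contig_lengths))
  if (length(no_len))
    stop_("contig length unknown for: %s", paste(no_len, collapse = ", "))
  out <- lapply(seq_along(focal_ids), function(i) {
    g <- annotations[idx[i], ]
    clen <- contig_lengths[[g$contig_id]]
    left <- c(max(0L, g$start - flank), g$start)
    right <- c(g$end, min(clen, g$end + flank))
    used <- (left[2L] - left[1L]) + (right[2L] - right[1L])
    same <- annotations$contig_id == g$contig_id &
      annotations$gene_id != g$gene_id
    ov <- function(s, e) pmax(0L, pmin(annotations$end, e) -
                                pmax(annotations$start, s))
    overlap <- ov(left[1L], left[2L]) + ov(right[1L], right[2L])
    counts <- same & overlap >= min_overlap
    data.frame(gene_id = g$gene_id, flank_bp_used = used,
               n_genes = sum(counts & annotations$feature_class == "cds"),
               n_te = sum(counts & annotations$feature_class == "transposase"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$gene_density <- out$n_genes / (out$flank_bp_used / 1000)
  out$te_density <- out$n_te / (out$flank_bp_used / 1000)
  out
}

PLASMID_RULES <- c("no_genes", "few_target_genes", "low_target_proportion",
                   "too_short", "low_coverage", "not_plasmid_predicted",
                   "phage_predicted")

#' Filter contigs to plasmid candidates
#'
#' A contig is kept iff it carries strictly more than `min_genes` target
#' genes, its target-gene proportion strictly exceeds `min_prop`, it is at
#' least `min_len` bp (short contigs are removed), its coverage is at least
#' `cov_frac` of the genome coverage (low-coverage contigs are removed), it
#' is positively predicted as plasmid and negatively predicted as phage.
#' Each rejected contig carries the first failed rule as its reason; the
#' outcome is order-independent because all rules are conjunctive.
#'
#' @param contigs Data frame with `contig_id`, `length`, `coverage`,
#'   `n_genes`, `n_target_genes`, `plasmid_pred`, `phage_pred`.
#' @param genome_coverage Coverage (x) of the chromosomal genome.
#' @param min_genes Target-gene count that must be strictly exceeded.
#' @param min_prop Target-gene proportion that must be strictly exceeded.
#' @param min_len Minimum contig length kept (bp).
#' @param cov_frac Minimum coverage as a fraction of `genome_coverage`.
#' @return A list with `kept` (contig ids) and `rejected` (data frame
#'   `contig_id`, `reason`).
#' @export
plasmid_filter <- function(contigs, genome_coverage, min_genes = 3L,
                           min_prop = 0.30, min_len = 5000L,
                           cov_frac = 1 / 3) {
  assert_df_cols(contigs, c("contig_id", "length", "coverage", "n_genes",
                            "n_target_genes", "plasmid_pred", "phage_pred"),
                 "contig table")
  if (genome_coverage <= 0) stop_("genome_coverage must be positive")
  if (any(contigs$n_target_genes > contigs$n_genes))
    stop_("n_target_genes exceeds n_genes")
  reason <- rep(NA_character_, nrow(contigs))
  fail <- function(cond, why) {
    hit <- is.na(reason) & cond
    reason[hit] <<- why
  }
  fail(contigs$n_genes == 0L, "no_genes")
  fail(contigs$n_target_genes <= min_genes, "few_target_genes")
  fail(contigs$n_target_genes / contigs$n_genes <= min_prop,
       "low_target_proportion")
  fail(contigs$length < min_len, "too_short")
  fail(contigs$coverage < cov_frac * genome_coverage, "low_coverage")
  fail(!contigs$plasmid_pred, "not_plasmid_predicted")
  fail(contigs$phage_pred, "phage_predicted")
  list(kept = contigs$contig_id[is.na(reason)],
       rejected = data.frame(contig_id = contigs$contig_id[!is.na(reason)],
                             reason = reason[!is.na(reason)],
                             stringsAsFactors = FALSE))
}

#' Reads per kilobase of genome per gigabase of metagenome
#'
#' `RPKG = mapped_reads / (mag_len / 1e3) / (metagenome_bases / 1e9)`:
#' linear in the read count, halves when the metagenome size doubles.
#'
#' @param mapped_reads Reads mapped to the MAG.
#' @param mag_len MAG length (bp), > 0.
#' @param metagenome_bases Total bases sequenced in the metagenome, > 0.
#' @return RPKG value(s).
#' @export
rpkg <- function(mapped_reads, mag_len, metagenome_bases) {
  if (any(mag_len <= 0)) stop_("mag_len must be positive")
  if (any(metagenome_bases <= 0)) stop_("metagenome_bases must be positive")
  if (any(mapped_reads < 0)) stop_("mapped_reads must be non-negative")
  mapped_reads / (mag_len / 1e3) / (metagenome_bases / 1e9)
}

#' Depth- and length-normalised gene frequencies
#'
#' RPKG-style per-gene normalisation of read counts:
#' `freq(g) = counts(g) / (gene_len(g) / 1e3) / (sample_bases / 1e9)`.
#'
#' @param counts Named numeric vector `gene -> mapped reads`.
#' @param gene_len Named numeric vector `gene -> length (bp)` covering every
#'   counted gene.
#' @param sample_bases Total bases sequenced in the sample, > 0.
#' @return Named numeric vector of normalised frequencies.
#' @export
gene_frequency <- function(counts, gene_len, sample_bases) {
  unknown <- setdiff(names(counts), names(gene_len))
  if (length(unknown))
    stop_("count(s) for unknown gene(s): %s", paste(unknown, collapse = ", "))
  if (any(gene_len <= 0)) stop_("gene lengths must be positive")
  if (sample_bases <= 0) stop_("sample_bases must be positive")
  len <- as.numeric(gene_len[names(counts)])
  setNames(counts / (len / 1e3) / (sample_bases / 1e9), names(counts))
}
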