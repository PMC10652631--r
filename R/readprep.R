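# Target-read selection and per-read feature extraction.
#
# Three features drive the downstream clustering: short-read recruitment
# depth, GC content and canonical tetranucleotide composition. The
# recruitment filters mirror a strict mapping regime for near-identical
# strains: fewer than three mismatches, primary hits only, highest mapping
# score per query.

# 136 canonical 4-mer classes: each 4-mer collapsed with its reverse
# complement, represented by the lexicographic minimum.
canonical_kmers <- function(k = 4L) {
  all <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(all)))
  sort(unique(pmin(all, rc)))
}

#' Exclude reads hitting blocklisted taxa
#'
#' A read is removed iff it has at least one alignment to a blocklisted
#' taxon passing both the identity and the query-coverage thresholds
#' (defaults 98% identity, 80% coverage); reads with no alignments are kept.
#' Identity is `1 - (substitutions + indel_bases) / aligned_query_bases`;
#' coverage is `aligned_query_bases / query_len`.
#'
#' @param alignments Alignment `data.frame` of long reads versus a reference
#'   database (see [alignment_records()]).
#' @param taxa Named character vector mapping every `target_id` to a taxon
#'   label.
#' @param blocklist Taxon labels whose hits disqualify a read (host and
#'   non-target microbes).
#' @param read_ids All candidate read ids (reads without alignments are
#'   retained); defaults to the reads seen in `alignments`.
#' @param min_identity,min_coverage Thresholds a hit must pass to count.
#' @return Character vector of retained read ids.
#' @export
filter_target_reads <- function(alignments, taxa, blocklist,
                                read_ids = unique(alignments$query_id),
                                min_identity = 0.98, min_coverage = 0.80) {
  alignments <- validate_alignments(alignments)
  unknown <- setdiff(unique(alignments$target_id), names(taxa))
  if (length(unknown))
    stop_("alignment target(s) with unknown taxon label: %s",
          paste(unknown, collapse = ", "))
  identity <- 1 - (alignments$substitutions + alignments$indel_bases) /
    alignments$aligned_query_bases
  coverage <- alignments$aligned_query_bases / alignments$query_len
  hit <- taxa[alignments$target_id] %in% blocklist &
    identity >= min_identity & coverage >= min_coverage
  setdiff(read_ids, unique(alignments$query_id[hit]))
}

#' Retain strictly recruited short-read alignments
#'
#' Keeps records with `substitutions < max_substitutions + 1` (default:
#' mismatch < 3) that are primary and carry the query's maximum score, at
#' most one record per query (ties broken by input order). The output is a
#' subset of the input and the operation is idempotent.
#'
#' @param alignments Alignment `data.frame`.
#' @param max_substitutions Maximum substitutions allowed (default 2,
#'   i.e. mismatch < 3).
#' @return The retained subset of `alignments`.
#' @export
recruit_short_reads <- function(alignments, max_substitutions = 2L) {
  if (!nrow(alignments)) return(alignments)
  alignments <- validate_alignments(alignments)
  keep <- alignments[alignments$substitutions <= max_substitutions &
                       alignments$is_primary, , drop = FALSE]
  if (!nrow(keep)) return(keep)
  dt <- data.table::as.data.table(keep)
  dt[, ord_ := .I]
  data.table::setorder(dt, query_id, -score, ord_)
  best <- dt[!duplicated(query_id)]
  data.table::setorder(best, ord_)
  out <- as.data.frame(best)
  out$ord_ <- NULL
  rownames(out) <- NULL
  out
}

#' Per-read depth from recruited alignments
#'
#' `depth(r)` is the aligned-base mass recruited onto read `r` divided by
#' its length: the mean per-base short-read coverage. Reads with no
#' alignments get depth 0. Depth is exactly linear in the alignment set.
#'
#' @param alignments Retained alignment `data.frame` (targets are long
#'   reads).
#' @param read_lengths Named numeric vector of long-read lengths (bp).
#' @return Named numeric vector `read_id -> depth` covering every read in
#'   `read_lengths`.
#' @export
compute_depth <- function(alignments, read_lengths) {
  if (is.null(names(read_lengths)))
    stop_("read_lengths must be named by read id")
  unknown <- setdiff(unique(alignments$target_id), names(read_lengths))
  if (length(unknown))
    stop_("alignment(s) to unknown read(s): %s", paste(unknown, collapse = ", "))
  mass <- tapply(alignments$aligned_query_bases, alignments$target_id, sum)
  depth <- setNames(numeric(length(read_lengths)), names(read_lengths))
  depth[names(mass)] <- mass
  depth / as.numeric(read_lengths)
}

#' GC content and canonical tetranucleotide composition of sequences
#'
#' GC is computed over non-N bases. 4-mers are counted over each sequence
#' with windows containing N skipped, collapsed into the 136 canonical
#' strand-symmetric classes, and normalised to frequencies; the vector is
#' therefore invariant under reverse complement.
#'
#' @param seqs A [Biostrings::DNAStringSet] (or character vector) of
#'   sequences, each of length >= 4.
#' @return A list with `gc` (numeric vector), `kmer_freq` (matrix, rows =
#'   sequences, 136 columns) and `n_kmers` (valid windows per sequence).
#' @export
compute_composition <- function(seqs) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (any(Biostrings::width(seqs) < 4L))
    stop_("all sequences must have length >= 4 for 4-mer composition")
  base_counts <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
  acgt <- rowSums(base_counts[, c("A", "C", "G", "T"), drop = FALSE])
  if (any(acgt == 0)) stop_("sequence with no A/C/G/T bases")
  gc <- rowSums(base_counts[, c("C", "G"), drop = FALSE]) / acgt
  raw <- Biostrings::oligonucleotideFrequency(seqs, width = 4L)
  kmers <- colnames(raw)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  canon <- pmin(kmers, rc)
  classes <- canonical_kmers(4L)
  counts <- matrix(0, nrow = length(seqs), ncol = length(classes),
                   dimnames = list(names(seqs), classes))
  for (j in seq_along(kmers))
    counts[, canon[j]] <- counts[, canon[j]] + raw[, j]
  n_kmers <- rowSums(counts)
  if (any(n_kmers == 0)) stop_("sequence with no N-free 4-mer window")
  list(gc = setNames(gc, names(seqs)),
       kmer_freq = counts / n_kmers,
       n_kmers = setNames(n_kmers, names(seqs)))
}

#' Assemble the per-read feature table
#'
#' @param reads A named [Biostrings::DNAStringSet] of long reads.
#' @param depth Named numeric vector from [compute_depth()].
#' @return A `data.frame` with columns `read_id`, `length`, `depth`, `gc`,
#'   `n_kmers` and the 136 canonical 4-mer frequency columns `k0001..k0136`.
#' @export
read_features <- function(reads, depth) {
  if (is.null(names(reads))) stop_("reads must be named")
  missing <- setdiff(names(reads), names(depth))
  if (length(missing))
    stop_("no depth for read(s): %s", paste(head(missing, 5L), collapse = ", "))
  comp <- compute_composition(reads)
  kf <- comp$kmer_freq
  colnames(kf) <- sprintf("k%04d", seq_len(ncol(kf)))
  out <- data.frame(read_id = names(reads),
                    length = Biostrings::width(reads),
                    depth = as.numeric(depth[names(reads)]),
                    gc = as.numeric(comp$gc),
                    n_kmers = as.numeric(comp$n_kmers),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(kf, row.names = NULL))
}

#' Build the clustering feature matrix
#'
#' Column 1 is `log10(depth + depth_pseudocount)`; the remaining columns are
#' the centred log-ratio (CLR) transform of the canonical 4-mer counts after
#' adding `kmer_pseudocount` to each count. Every CLR row sums to zero.
#'
#' @param features Feature table from [read_features()] (>= 2 rows).
#' @param depth_pseudocount Added to depth before the log (keeps depth-0
#'   reads finite).
#' @param kmer_pseudocount Added to each 4-mer count before the CLR.
#' @return An object of class `feature_matrix`: a list with `x` (numeric
#'   matrix, rows = reads) and `meta` (the transform parameters).
#' @export
build_feature_matrix <- function(features, depth_pseudocount = 0.1,
                                 kmer_pseudocount = 1) {
  assert_df_cols(features, c("read_id", "depth", "n_kmers"), "feature table")
  if (nrow(features) < 2L) stop_("need at least 2 reads")
  if (any(features$depth < 0)) stop_("negative depth encountered")
  kcols <- grep("^k\\d{4}$", names(features), value = TRUE)
  if (length(kcols) != 136L) stop_("expected 136 kmer columns, found %d",
                                   length(kcols))
  counts <- as.matrix(features[, kcols]) * features$n_kmers + kmer_pseudocount
  freq <- counts / rowSums(counts)
  lf <- log(freq)
  clr <- lf - rowMeans(lf)
  colnames(clr) <- paste0("clr_", kcols)
  x <- cbind(log_depth = log10(features$depth + depth_pseudocount), clr)
  rownames(x) <- features$read_id
  structure(list(x = x,
                 meta = list(depth_pseudocount = depth_pseudocount,
                             kmer_pseudocount = kmer_pseudocount,
                             log_base_depth = 10, clr_base = exp(1))),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d reads x %d features\n",
              nrow(x$x), ncol(x$x)))
  invisible(x)
}
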