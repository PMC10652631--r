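# Seeded generator of synthetic strain communities with ground truth.
#
# The generator emulates a within-species mock design: one ancestor genome,
# several strains at controlled divergence from it, HiFi-like long reads
# (low, substitution-only error) and error-bearing paired short reads at
# controlled per-strain depths, plus complete read-to-strain truth labels.
# Indels are not simulated: truth ANI then follows analytically from the
# mutation log.

#' Substitute sites of a genome at a fixed per-site rate
#'
#' Each site is independently substituted with probability `sub_rate` to a
#' uniformly chosen different base. Deterministic under `seed`.
#'
#' @param ancestor A [Biostrings::DNAStringSet] of length 1 (or a single
#'   character string).
#' @param sub_rate Per-site substitution probability in `[0, 0.25)`.
#' @param seed Integer seed.
#' @return A list with `seq` (a `DNAStringSet` of length 1) and
#'   `mutation_log`, a data frame of 0-based `position`, `ref` and `alt`.
#' @export
mutate_genome <- function(ancestor, sub_rate, seed) {
  if (is.character(ancestor)) ancestor <- Biostrings::DNAStringSet(ancestor)
  stopifnot(length(ancestor) == 1L)
  if (!is.numeric(sub_rate) || sub_rate < 0 || sub_rate >= 0.25)
    stop_("sub_rate must be in [0, 0.25), got %s", format(sub_rate))
  n <- Biostrings::width(ancestor)
  with_seed(seed, {
    hit <- which(runif(n) < sub_rate)
    chars <- strsplit(as.character(ancestor[[1L]]), "", fixed = TRUE)[[1L]]
    ref <- chars[hit]
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
    chars[hit] <- alt
    out <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
    names(out) <- names(ancestor)
    list(seq = out,
         mutation_log = data.frame(position = hit - 1L, ref = ref, alt = alt,
                                   row.names = NULL, stringsAsFactors = FALSE))
  })
}

#' Build a mock strain community with ground truth
#'
#' Generates (or accepts) an ancestor genome and derives `n_strains` strain
#' genomes at the given per-site divergences. Long-read and short-read
#' target depths are recorded per strain. Short-read depths default to a
#' uniform value across strains: the per-long-read depth signal used for
#' binning is the ratio of short-read mass to long-read redundancy, so it
#' separates strains exactly when the short-read composition differs from
#' the long-read composition (the two platforms sequence different samples).
#'
#' @param n_strains Number of strains.
#' @param divergence Per-strain per-site substitution rate from the ancestor
#'   (recycled to `n_strains`). Defaults give pairwise strain ANIs in the
#'   99.5--99.9% band typical of within-species variants.
#' @param long_depths Per-strain long-read depth (x).
#' @param short_depths Per-strain short-read depth (x); recycled.
#' @param genome_len Ancestor length (bp) when `ancestor` is `NULL`.
#' @param gc GC fraction of the generated ancestor.
#' @param ancestor Optional ancestor sequence ([Biostrings::DNAStringSet] of
#'   length 1); generated randomly when `NULL`.
#' @param seed Integer seed controlling everything.
#' @return An object of class `mock_community`: list with `ancestor`,
#'   `strains` (a `DNAStringSet`), `mutation_logs`, `abundances` (data frame
#'   of `strain_id`, `long_depth`, `short_depth`), `genome_len` and `seed`.
#' @export
make_mock_community <- function(n_strains = 3L,
                                divergence = c(0.0025, 0.001, 0.0005),
                                long_depths = c(80, 30, 10),
                                short_depths = 100,
                                genome_len = 1e5, gc = 0.45,
                                ancestor = NULL, seed = 1L) {
  stopifnot(n_strains >= 1L)
  divergence <- rep_len(divergence, n_strains)
  long_depths <- rep_len(long_depths, n_strains)
  short_depths <- rep_len(short_depths, n_strains)
  if (any(long_depths <= 0) || any(short_depths <= 0))
    stop_("strain depths must be positive")
  if (is.null(ancestor)) {
    ancestor <- with_seed(child_seed(seed, 1L), {
      p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
      Biostrings::DNAStringSet(paste(
        sample(names(p), genome_len, replace = TRUE, prob = p), collapse = ""))
    })
    names(ancestor) <- "ancestor"
  } else {
    if (is.character(ancestor)) ancestor <- Biostrings::DNAStringSet(ancestor)
    stopifnot(length(ancestor) == 1L)
    genome_len <- Biostrings::width(ancestor)
  }
  ids <- sprintf("strain%02d", seq_len(n_strains))
  muts <- vector("list", n_strains)
  seqs <- vector("list", n_strains)
  for (i in seq_len(n_strains)) {
    m <- mutate_genome(ancestor, divergence[i], child_seed(seed, 10L + i))
    seqs[[i]] <- m$seq[[1L]]
    muts[[i]] <- m$mutation_log
  }
  strains <- Biostrings::DNAStringSet(seqs)
  names(strains) <- names(muts) <- ids
  structure(list(ancestor = ancestor, strains = strains,
                 mutation_logs = muts,
                 abundances = data.frame(strain_id = ids,
                                         long_depth = long_depths,
                                         short_depth = short_depths,
                                         stringsAsFactors = FALSE),
                 genome_len = as.integer(genome_len), seed = seed),
            class = "mock_community")
}

#' @export
print.mock_community <- function(x, ...) {
  cat(sprintf("mock_community: %d strain(s), %d bp ancestor, seed %s\n",
              length(x$strains), x$genome_len, format(x$seed)))
  print(x$abundances)
  invisible(x)
}

#' Truth ANI of a strain to the ancestor from its mutation log
#'
#' With substitution-only mutations, ANI is exactly
#' `1 - nrow(mutation_log) / genome_len`.
#'
#' @param community A `mock_community`.
#' @param strain_id Strain id.
#' @return ANI as a percentage.
#' @export
truth_ani <- function(community, strain_id) {
  log <- community$mutation_logs[[strain_id]]
  if (is.null(log)) stop_("unknown strain id: %s", strain_id)
  100 * (1 - nrow(log) / community$genome_len)
}

# Inject substitution errors at `rate` into a character vector of sequences.
# Per-read error counts are Binomial(length, rate) with distinct positions;
# the replacement base is uniform over the three alternatives.
inject_substitutions <- function(seqs, rate, seed) {
  if (rate == 0 || !length(seqs)) return(seqs)
  alt_tab <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                   G = c("A", "C", "T"), T = c("A", "C", "G"))
  with_seed(seed, {
    len <- nchar(seqs)
    n_err <- rbinom(length(seqs), len, rate)
    idx <- rep(seq_along(seqs), n_err)  # sorted by construction
    pos <- integer(length(idx))
    ends <- cumsum(n_err)
    one <- which(n_err == 1L)
    pos[ends[one]] <- floor(runif(length(one)) * len[one]) + 1L
    multi <- which(n_err > 1L)
    if (length(multi)) {
      slice <- sequence(n_err[multi], from = ends[multi] - n_err[multi] + 1L)
      pos[slice] <- unlist(lapply(multi, function(i)
        sample.int(len[i], n_err[i])), use.names = FALSE)
    }
    # apply one error per read per round so vectorised substr<- never
    # touches the same string twice in a round
    round_of <- sequence(n_err[n_err > 0L])
    pick <- floor(runif(length(idx)) * 3) + 1L
    for (r in seq_len(max(round_of, 0L))) {
      sel <- round_of == r
      i <- idx[sel]; p <- pos[sel]
      ref <- substr(seqs[i], p, p)
      alt <- alt_tab[cbind(match(ref, rownames(alt_tab)), pick[sel])]
      substr(seqs[i], p, p) <- alt
    }
    seqs
  })
}

#' Simulate HiFi-like long reads from a mock community
#'
#' Per-strain read counts are Poisson-drawn around
#' `long_depth * genome_len / mean_len`; start positions are uniform;
#' lengths are truncated-normal (minimum 500 bp, maximum the genome length);
#' reads are reverse-complemented with probability 1/2; errors are
#' substitution-only at `error_rate` (HiFi reads are simulated directly at a
#' low error rate rather than via a CLR multi-pass model, since the binning
#' method consumes only sequences and depths).
#'
#' @param community A `mock_community`.
#' @param mean_len,len_sd Mean and SD of read length (bp); `mean_len >= 1000`.
#' @param error_rate Substitution error rate in `[0, 0.02]`.
#' @param seed Integer seed.
#' @return A list with `reads` (a named `DNAStringSet`), `truth` (data frame
#'   `read_id`, `strain_id`) and `layout` (data frame `read_id`, `strain_id`,
#'   `start` (0-based), `length`, `strand`).
#' @export
simulate_long_reads <- function(community, mean_len = 10000, len_sd = 1500,
                                error_rate = 0.002, seed = 1L) {
  stopifnot(is(community, "mock_community"))
  if (mean_len < 1000) stop_("mean_len must be >= 1000")
  if (error_rate < 0 || error_rate > 0.02)
    stop_("error_rate must be in [0, 0.02]")
  if (!length(community$strains)) stop_("empty community")
  g <- community$genome_len
  ab <- community$abundances
  with_seed(child_seed(seed, 2L), {
    layout <- do.call(rbind, lapply(seq_len(nrow(ab)), function(i) {
      n <- rpois(1L, ab$long_depth[i] * g / mean_len)
      if (n == 0L) return(NULL)
      len <- pmin(g, pmax(500L, as.integer(round(rnorm(n, mean_len, len_sd)))))
      # genomes are circular: starts are uniform over the whole chromosome
      # and reads may wrap the origin, so coverage is stationary
      start <- sample.int(g, n, replace = TRUE) - 1L
      data.frame(strain_id = ab$strain_id[i], start = start, length = len,
                 strand = sample(c("+", "-"), n, replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(layout)) stop_("no long reads generated; increase depth")
    layout$read_id <- sprintf("lr%06d", seq_len(nrow(layout)))
    doubled <- setNames(strrep(as.character(community$strains), 2L),
                        names(community$strains))
    seqs <- substring(doubled[layout$strain_id], layout$start + 1L,
                      layout$start + layout$length)
    rc <- layout$strand == "-"
    if (any(rc))
      seqs[rc] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[rc])))
    seqs <- inject_substitutions(seqs, error_rate, child_seed(seed, 3L))
    reads <- Biostrings::DNAStringSet(seqs)
    names(reads) <- layout$read_id
    list(reads = reads,
         truth = data.frame(read_id = layout$read_id,
                            strain_id = layout$strain_id,
                            stringsAsFactors = FALSE),
         layout = layout[, c("read_id", "strain_id", "start", "length", "strand")])
  })
}

#' Simulate paired short reads from a mock community
#'
#' Proper innie pairs: a fragment of length `insert` is drawn uniformly from
#' a strain genome; R1 is its first `read_len` bases, R2 the reverse
#' complement of its last `read_len` bases. Base-call errors are
#' substitution-only at `base_error` (default 0.01, insert 150 bp, matching
#' a standard wgsim-style simulation). Qualities are a constant Q30
#' placeholder when written with [write_fastq()].
#'
#' @param community A `mock_community`.
#' @param read_len Read length (bp).
#' @param insert Insert (fragment) size; must be `>= read_len`.
#' @param base_error Per-base error rate.
#' @param seed Integer seed.
#' @return A list with `r1`, `r2` (named `DNAStringSet`s) and `layout`
#'   (data frame `pair_id`, `strain_id`, `start` (0-based fragment start)).
#' @export
simulate_short_reads <- function(community, read_len = 100L, insert = 150L,
                                 base_error = 0.01, seed = 1L) {
  stopifnot(is(community, "mock_community"))
  if (insert < read_len) stop_("insert size (%d) must be >= read_len (%d)",
                               insert, read_len)
  if (!length(community$strains)) stop_("empty community")
  g <- community$genome_len
  if (insert > g) stop_("insert size exceeds genome length")
  ab <- community$abundances
  with_seed(child_seed(seed, 4L), {
    layout <- do.call(rbind, lapply(seq_len(nrow(ab)), function(i) {
      n <- rpois(1L, ab$short_depth[i] * g / (2 * read_len))
      if (n == 0L) return(NULL)
      # circular chromosome: fragments may wrap the origin
      data.frame(strain_id = ab$strain_id[i],
                 start = sample.int(g, n, replace = TRUE) - 1L,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(layout)) stop_("no short reads generated; increase depth")
    layout$pair_id <- sprintf("sr%07d", seq_len(nrow(layout)))
    doubled <- setNames(strrep(as.character(community$strains), 2L),
                        names(community$strains))
    genome <- doubled[layout$strain_id]
    frag1 <- substring(genome, layout$start + 1L, layout$start + read_len)
    frag2 <- substring(genome, layout$start + insert - read_len + 1L,
                       layout$start + insert)
    frag1 <- inject_substitutions(frag1, base_error, child_seed(seed, 5L))
    frag2 <- inject_substitutions(frag2, base_error, child_seed(seed, 6L))
    r1 <- Biostrings::DNAStringSet(frag1)
    r2 <- Biostrings::reverseComplement(Biostrings::DNAStringSet(frag2))
    names(r1) <- paste0(layout$pair_id, "/1")
    names(r2) <- paste0(layout$pair_id, "/2")
    list(r1 = r1, r2 = r2,
         layout = layout[, c("pair_id", "strain_id", "start")])
  })
}

#' Idealized recruitment of short reads onto long reads from ground truth
#'
#' Emulates the external short-to-long aligner on mock data: every short-read
#' mate is assigned to one uniformly chosen long read of its own strain whose
#' interval fully contains the mate (mates in coverage gaps stay unaligned).
#' Mismatch counts are drawn as Binomial(`aligned bases`,
#' `base_error + long_error`), reflecting errors on both sequences. This is
#' synthetic plumbing standing in for running an aligner, which is outside
#' the toolkit's scope; records are emitted in [alignment_records()] form so
#' the real recruitment filters apply unchanged.
#'
#' @param long_layout `layout` from [simulate_long_reads()].
#' @param short_layout `layout` from [simulate_short_reads()].
#' @param read_len,insert Short-read geometry used in the simulation.
#' @param base_error,long_error Error rates used to draw mismatch counts.
#' @param genome_len Chromosome length; when given, containment is computed
#'   on the circular chromosome (reads may wrap the origin, as the
#'   simulators emit them). `NULL` treats coordinates as linear.
#' @param seed Integer seed.
#' @return An alignment `data.frame` (see [alignment_records()]) with long
#'   reads as targets.
#' @export
align_by_truth <- function(long_layout, short_layout, read_len = 100L,
                           insert = 150L, base_error = 0.01,
                           long_error = 0.002, genome_len = NULL,
                           seed = 1L) {
  mates <- data.frame(
    query_id = c(paste0(short_layout$pair_id, "/1"),
                 paste0(short_layout$pair_id, "/2")),
    strain_id = rep(short_layout$strain_id, 2L),
    start = c(short_layout$start,
              short_layout$start + insert - read_len),
    stringsAsFactors = FALSE)
  with_seed(child_seed(seed, 7L), {
    per_strain <- lapply(split(seq_len(nrow(mates)), mates$strain_id),
                         function(mi) {
      li <- which(long_layout$strain_id == mates$strain_id[mi[1L]])
      if (!length(li)) return(NULL)
      # on a circular chromosome a mate can fall into a long read that
      # wraps the origin; testing the mate at both its position and its
      # position shifted by one genome length covers every wrap case
      starts <- mates$start[mi]
      if (!is.null(genome_len)) {
        qs <- c(starts, starts + genome_len)
        orig <- rep(seq_along(mi), 2L)
      } else {
        qs <- starts
        orig <- seq_along(mi)
      }
      q <- IRanges::IRanges(start = qs + 1L, width = read_len)
      t <- IRanges::IRanges(start = long_layout$start[li] + 1L,
                            width = long_layout$length[li])
      # only fully containing long reads are candidates (an aligner would
      # clip or reject partial end overlaps); mates in coverage gaps stay
      # unaligned
      ov <- IRanges::findOverlaps(q, t, type = "within")
      if (!length(ov)) return(NULL)
      qh <- orig[S4Vectors::queryHits(ov)]
      th <- S4Vectors::subjectHits(ov)
      ts <- qs[S4Vectors::queryHits(ov)] - long_layout$start[li][th]
      dt <- data.table::data.table(q = qh, t = th, ts = ts,
                                   key_ = runif(length(qh)))
      best <- dt[dt[, .I[which.max(key_)], by = q]$V1]
      data.frame(mate_row = mi[best$q], long_row = li[best$t],
                 t_start = best$ts, stringsAsFactors = FALSE)
    })
    hits <- do.call(rbind, per_strain)
    if (is.null(hits) || !nrow(hits)) stop_("no short read could be recruited")
    t_start <- hits$t_start
    subs <- rbinom(nrow(hits), read_len, base_error + long_error)
    alignment_records(
      query_id = mates$query_id[hits$mate_row],
      target_id = long_layout$read_id[hits$long_row],
      query_len = read_len,
      target_start = t_start,
      target_end = t_start + read_len,
      strand = "+",
      aligned_query_bases = read_len,
      substitutions = subs,
      indel_bases = 0L,
      score = read_len - 5 * subs,
      is_primary = TRUE)
  })
}

#' Plant gene and transposase annotations with a controlled flank enrichment
#'
#' Lays out `n_core + n_specific` genes on a single contig with flanks that
#' never overlap neighbouring genes, then scatters transposase features into
#' the 2 x `flank` bp flank windows: Poisson counts at `bg_te_rate` per kb
#' around core genes and `te_enrichment` times that around clade-specific
#' genes. The planted truth makes the flank-density comparison testable end
#' to end.
#'
#' @param n_core,n_specific Number of genes per class.
#' @param te_enrichment Fold enrichment of transposases around specific genes.
#' @param flank Flank size (bp) on each side of a gene.
#' @param bg_te_rate Background transposase rate (per kb of flank).
#' @param gene_len,te_len Feature lengths (bp).
#' @param genome_len Contig length; computed to fit when `NULL`; an explicit
#'   value too small for the layout is an error.
#' @param seed Integer seed.
#' @return A list with `features` (a [feature_annotations()] data frame),
#'   `classes` (data frame `gene_id`, `class`), `contig_len` and the planted
#'   `te_rates` per class (per kb).
#' @export
plant_annotations <- function(n_core, n_specific, te_enrichment = 1,
                              flank = 3000L, bg_te_rate = 0.1,
                              gene_len = 900L, te_len = 300L,
                              genome_len = NULL, seed = 1L) {
  n_genes <- n_core + n_specific
  if (n_genes < 1L) stop_("need at least one gene")
  slot <- gene_len + 2L * flank + 2L * te_len + 200L
  need <- n_genes * slot + flank
  if (is.null(genome_len)) genome_len <- need
  if (genome_len < need)
    stop_("infeasible packing: %d genes need %d bp, genome_len is %d",
          n_genes, need, genome_len)
  with_seed(seed, {
    class <- sample(c(rep("core", n_core), rep("specific", n_specific)))
    gene_start <- flank + (seq_len(n_genes) - 1L) * slot
    gene_id <- sprintf("g%04d", seq_len(n_genes))
    rate <- bg_te_rate * ifelse(class == "specific", te_enrichment, 1)
    te <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
      n_te <- rpois(1L, rate[i] * 2 * flank / 1000)
      if (n_te == 0L) return(NULL)
      # flank windows exclude the gene body; sample TE starts within them
      left <- gene_start[i] - flank
      right <- gene_start[i] + gene_len
      starts <- integer(0)
      for (k in seq_len(n_te)) {
        for (try in 1:50) {
          side <- sample(c("l", "r"), 1L)
          s <- if (side == "l") left + sample.int(flank - te_len, 1L) - 1L
               else right + sample.int(flank - te_len, 1L) - 1L
          if (!length(starts) || all(abs(starts - s) >= te_len)) {
            starts <- c(starts, s); break
          }
        }
      }
      data.frame(gene = i, start = starts, stringsAsFactors = FALSE)
    }))
    feats <- feature_annotations(
      contig_id = "chr1",
      start = gene_start, end = gene_start + gene_len,
      strand = "+", feature_class = "cds", gene_id = gene_id,
      ortholog_id = sprintf("OG%04d", seq_len(n_genes)),
      product = "hypothetical protein")
    if (!is.null(te) && nrow(te)) {
      feats <- rbind(feats, feature_annotations(
        contig_id = "chr1",
        start = te$start, end = te$start + te_len,
        strand = ".", feature_class = "transposase",
        gene_id = sprintf("te%04d", seq_len(nrow(te))),
        ortholog_id = NA_character_,
        product = "IS family transposase"))
    }
    list(features = validate_features(feats),
         classes = data.frame(gene_id = gene_id, class = class,
                              stringsAsFactors = FALSE),
         contig_len = as.integer(genome_len),
         te_rates = c(core = bg_te_rate, specific = bg_te_rate * te_enrichment))
  })
}

#' Write a mock community and its reads to a directory
#'
#' Produces `strains.fa`, `long.fa`, `short_R1.fq`, `short_R2.fq`,
#' `truth.tsv` and `community.json`. Identical seeds give byte-identical
#' outputs.
#'
#' @param community A `mock_community`.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed for read simulation.
#' @param ... Passed on to [simulate_long_reads()] and
#'   [simulate_short_reads()] (`mean_len`, `error_rate`, `read_len`, ...).
#' @return The output directory, invisibly.
#' @export
write_mock_community <- function(community, dir, seed = 1L, ...) {
  dots <- list(...)
  take <- function(f) dots[intersect(names(dots), names(formals(f)))]
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lr <- do.call(simulate_long_reads,
                c(list(community = community, seed = seed),
                  take(simulate_long_reads)))
  sr <- do.call(simulate_short_reads,
                c(list(community = community, seed = seed),
                  take(simulate_short_reads)))
  write_fasta(community$strains, file.path(dir, "strains.fa"))
  write_fasta(lr$reads, file.path(dir, "long.fa"))
  write_fastq(sr$r1, file.path(dir, "short_R1.fq"))
  write_fastq(sr$r2, file.path(dir, "short_R2.fq"))
  write.table(lr$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(seed = community$seed, genome_len = community$genome_len,
         abundances = community$abundances,
         n_mutations = vapply(community$mutation_logs, nrow, 0L)),
    file.path(dir, "community.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
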