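# Shared fixture builders. Everything is generated in code; no binary data.

random_dna <- function(n, seed = NULL, gc = 0.5) {
  gen <- function() {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Random in-frame CDS without internal stops (code table 11).
random_cds <- function(n_codons, seed = NULL) {
  gen <- function() {
    code <- Biostrings::getGeneticCode("11")
    sense <- names(code)[code != "*"]
    paste(sample(sense, n_codons, replace = TRUE), collapse = "")
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

write_tmp_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".txt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Small deterministic feature table for build_feature_matrix tests.
toy_features <- function(depths, seqs = NULL, seed = 7) {
  n <- length(depths)
  if (is.null(seqs))
    seqs <- vapply(seq_len(n) + seed * 1000, function(s)
      random_dna(2000, seed = s), "")
  reads <- Biostrings::DNAStringSet(seqs)
  names(reads) <- sprintf("r%03d", seq_len(n))
  read_features(reads, setNames(depths, names(reads)))
}
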