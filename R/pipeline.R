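# End-to-end convenience wrapper: mock community -> reads -> recruitment ->
# features -> clustering -> scoring. This is the pipeline the validation
# experiments (and the command-line interface) run.

#' Run the full binning pipeline on a mock community
#'
#' Simulates long and paired short reads, recruits the short reads onto the
#' long reads with the idealized truth-based aligner, applies the strict
#' recruitment filter (mismatch < 3, primary, top score), computes per-read
#' depth and composition features, clusters the long reads and scores the
#' assignment against the ground truth.
#'
#' @param community A `mock_community` from [make_mock_community()].
#' @param seed Integer seed driving every stochastic stage.
#' @param mean_len,len_sd,long_error Long-read simulation parameters.
#' @param read_len,insert,base_error Short-read simulation parameters.
#' @param k_max,n_init,composition_weight,min_posterior Clustering
#'   parameters (see [cluster_reads()]).
#' @return A list with `assignment` (`bin_assignment`), `score`
#'   (`bin_score`), `features`, `matrix`, `reads`, `truth` and
#'   `n_input_reads`.
#' @export
run_mock_binning <- function(community, seed = 1L,
                             mean_len = 10000, len_sd = 1500,
                             long_error = 0.002,
                             read_len = 100L, insert = 150L,
                             base_error = 0.01,
                             k_max = 8L, n_init = 10L,
                             composition_weight = 0.05, min_posterior = 0) {
  lr <- simulate_long_reads(community, mean_len = mean_len, len_sd = len_sd,
                            error_rate = long_error, seed = seed)
  sr <- simulate_short_reads(community, read_len = read_len, insert = insert,
                             base_error = base_error, seed = seed)
  aln <- align_by_truth(lr$layout, sr$layout, read_len = read_len,
                        insert = insert, base_error = base_error,
                        long_error = long_error,
                        genome_len = community$genome_len, seed = seed)
  kept <- recruit_short_reads(aln)
  depth <- compute_depth(kept, setNames(Biostrings::width(lr$reads),
                                        names(lr$reads)))
  feats <- read_features(lr$reads, depth)
  fm <- build_feature_matrix(feats)
  assignment <- cluster_reads(fm, k_max = k_max, n_init = n_init,
                              seed = child_seed(seed, 20L),
                              composition_weight = composition_weight,
                              min_posterior = min_posterior)
  score <- score_bins(assignment, lr$truth,
                      n_input_reads = length(lr$reads))
  list(assignment = assignment, score = score, features = feats,
       matrix = fm, reads = lr$reads, truth = lr$truth,
       n_input_reads = length(lr$reads))
}
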