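# Strain binning: cluster long reads into per-strain subdatasets from the
# depth/composition feature matrix.
#
# The clusterer is a full-covariance Gaussian mixture fitted by EM in a
# PCA-reduced feature space, with the number of strains chosen by BIC over a
# k range. It is implemented in-package (not delegated to an external
# binning tool) so the computation is explicit and testable against an
# exhaustive-search oracle.

# --- Gaussian mixture internals ------------------------------------------

# Per-component Gaussian log-densities; S regularised upstream.
gauss_logdens <- function(x, mu, chol_s) {
  xc <- sweep(x, 2L, mu)
  z <- backsolve(chol_s, t(xc), transpose = TRUE)
  -0.5 * (ncol(x) * log(2 * pi) + 2 * sum(log(diag(chol_s))) + colSums(z^2))
}

safe_chol <- function(s, reg) {
  d <- nrow(s)
  for (i in 0:8) {
    r <- tryCatch(chol(s + diag(reg * 10^i, d)), error = function(e) NULL)
    if (!is.null(r)) return(r)
  }
  stop_("covariance could not be regularised")
}

weighted_cov <- function(x, mu, w) {
  xc <- sweep(x, 2L, mu)
  crossprod(xc * sqrt(w)) / sum(w)
}

# EM for a k-component full-covariance Gaussian mixture.
fit_gmm <- function(x, k, init_labels, reg = 1e-6, tol = 1e-4,
                    max_iter = 500L) {
  n <- nrow(x); d <- ncol(x)
  mu <- matrix(0, k, d); chols <- vector("list", k); pi_k <- numeric(k)
  for (j in seq_len(k)) {
    rows <- which(init_labels == j)
    if (length(rows) < 1L) rows <- sample.int(n, 1L)
    mu[j, ] <- colMeans(x[rows, , drop = FALSE])
    s <- if (length(rows) > 1L)
      cov(x[rows, , drop = FALSE]) * (length(rows) - 1) / length(rows)
    else diag(0, d)
    chols[[j]] <- safe_chol(s, reg)
    pi_k[j] <- length(rows) / n
  }
  pi_k <- pi_k / sum(pi_k)
  ll_old <- -Inf; logdens <- matrix(0, n, k)
  for (iter in seq_len(max_iter)) {
    for (j in seq_len(k))
      logdens[, j] <- log(pi_k[j]) + gauss_logdens(x, mu[j, ], chols[[j]])
    m <- apply(logdens, 1L, max)
    lse <- m + log(rowSums(exp(logdens - m)))
    ll <- sum(lse)
    resp <- exp(logdens - lse)
    nk <- colSums(resp)
    for (j in seq_len(k)) {
      if (nk[j] < 1e-8) {
        # collapsed component: restart it on a random observation
        row <- sample.int(n, 1L)
        mu[j, ] <- x[row, ]
        chols[[j]] <- safe_chol(weighted_cov(x, colMeans(x), rep(1 / n, n)), reg)
        pi_k[j] <- 1 / n
        next
      }
      mu[j, ] <- colSums(resp[, j] * x) / nk[j]
      chols[[j]] <- safe_chol(weighted_cov(x, mu[j, ], resp[, j]), reg)
      pi_k[j] <- nk[j] / n
    }
    pi_k <- pi_k / sum(pi_k)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  for (j in seq_len(k))
    logdens[, j] <- log(pi_k[j]) + gauss_logdens(x, mu[j, ], chols[[j]])
  m <- apply(logdens, 1L, max)
  lse <- m + log(rowSums(exp(logdens - m)))
  resp <- exp(logdens - lse)
  n_params <- (k - 1) + k * d + k * d * (d + 1) / 2
  list(loglik = sum(lse), resp = resp, labels = max.col(resp),
       posterior = resp[cbind(seq_len(n), max.col(resp))],
       mu = mu, pi = pi_k, k = k, n_params = n_params,
       bic = -2 * sum(lse) + n_params * log(n), iter = iter)
}

init_labels_for <- function(x, k) {
  if (k == 1L) return(rep(1L, nrow(x)))
  km <- tryCatch(kmeans(x, centers = k, nstart = 1L, iter.max = 25L),
                 error = function(e) NULL)
  if (!is.null(km)) return(km$cluster)
  # fewer distinct points than centers: random assignment
  sample.int(k, nrow(x), replace = TRUE)
}

# --- public operations ----------------------------------------------------

#' Cluster long reads into strain bins
#'
#' Projects the feature matrix onto the leading principal components
#' (components explaining at least `pca_var` of the variance, capped at
#' `max_pc`; see the methods vignette for why the cap matters for
#' within-species data), fits a full-covariance Gaussian mixture by EM for
#' each `k` in `k_min:k_max` with `n_init` seeded restarts, and selects `k`
#' by minimum BIC. Mixture components whose mean depths differ by less than
#' `merge_depth_ratio` are then consolidated into one strain bin
#' (average-linkage clustering of component mean log-depths): reads of one
#' strain share a
#' sequencing depth up to local coverage fluctuation, so components closer
#' in depth than that threshold model within-strain structure, not distinct
#' strains. Reads are hard-assigned to their maximum-a-posteriori bin;
#' `min_posterior > 0` diverts low-confidence reads to an unassigned pool
#' (`bin = NA`).
#'
#' @param matrix A `feature_matrix` from [build_feature_matrix()] (or a bare
#'   numeric matrix with read-id rownames, used as-is).
#' @param composition_weight Multiplier applied to the CLR composition
#'   columns of a `feature_matrix` before PCA. Depth is the primary
#'   within-species binning signal; the composition block is down-weighted
#'   so that it enters the reduced space only when compositional structure
#'   rivals the depth spread (e.g. cross-species mixtures). See the methods
#'   vignette for the rationale.
#' @param k_min,k_max Range of candidate strain counts; `k_max` must not
#'   exceed the number of reads.
#' @param n_init Restarts per `k`.
#' @param seed Integer seed; identical invocations are bit-reproducible.
#' @param pca_var Minimum fraction of variance the retained components must
#'   explain.
#' @param max_pc Upper bound on retained components.
#' @param reg Ridge added to component covariance diagonals.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap.
#' @param merge_depth_ratio Depth ratio below which two mixture components
#'   are treated as the same strain (set to 1 to disable consolidation).
#'   Requires a `log_depth` column, i.e. a `feature_matrix` input.
#' @param min_posterior Posterior threshold below which a read is left
#'   unassigned.
#' @return An object of class `bin_assignment`: list with `assign` (data
#'   frame `read_id`, `bin`, `posterior`), `model` (per-k `loglik`, `bic`,
#'   `n_params`), `raw_k` (BIC minimiser), `chosen_k` (strain bins after
#'   depth consolidation; bins are numbered by decreasing mean depth), and
#'   `pca` (components retained and variance explained).
#' @export
cluster_reads <- function(matrix, k_min = 1L, k_max = 8L, n_init = 10L,
                          seed = 1L, composition_weight = 0.05,
                          pca_var = 0.90, max_pc = 10L,
                          reg = 1e-6, tol = 1e-4, max_iter = 500L,
                          merge_depth_ratio = 2, min_posterior = 0) {
  x <- if (is(matrix, "feature_matrix")) {
    xm <- matrix$x
    clr <- grep("^clr_", colnames(xm))
    if (length(clr)) xm[, clr] <- xm[, clr] * composition_weight
    xm
  } else as.matrix(matrix)
  if (is.null(rownames(x))) stop_("feature matrix must have read-id rownames")
  n <- nrow(x)
  if (k_max > n) stop_("k_max (%d) exceeds number of reads (%d)", k_max, n)
  if (k_min < 1L || k_min > k_max) stop_("need 1 <= k_min <= k_max")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  cum <- cumsum(ev) / sum(ev)
  m <- min(which(cum >= pca_var))
  m <- max(1L, min(m, max_pc, n - 1L))
  scores <- pc$x[, seq_len(m), drop = FALSE]
  ks <- seq.int(k_min, k_max)
  fits <- vector("list", length(ks))
  with_seed(seed, {
    for (i in seq_along(ks)) {
      k <- ks[i]
      best <- NULL
      for (r in seq_len(n_init)) {
        fit <- fit_gmm(scores, k, init_labels_for(scores, k),
                       reg = reg, tol = tol, max_iter = max_iter)
        if (is.null(best) || fit$loglik > best$loglik) best <- fit
        if (k == 1L) break  # deterministic fit; restarts are redundant
      }
      fits[[i]] <- best
    }
  })
  model <- data.frame(k = ks,
                      loglik = vapply(fits, `[[`, 0, "loglik"),
                      n_params = vapply(fits, `[[`, 0, "n_params"),
                      bic = vapply(fits, `[[`, 0, "bic"))
  raw_k <- ks[which.min(model$bic)]
  fit <- fits[[which(ks == raw_k)]]
  # consolidate components that share a depth into one strain bin
  group <- seq_len(raw_k)
  if (merge_depth_ratio > 1 && raw_k > 1L && "log_depth" %in% colnames(x)) {
    ld <- x[, "log_depth"]
    mu_d <- vapply(seq_len(raw_k), function(j) {
      w <- fit$resp[, j]
      sum(w * ld) / sum(w)
    }, 0)
    hc <- stats::hclust(stats::dist(mu_d), method = "average")
    group <- stats::cutree(hc, h = log10(merge_depth_ratio))
  }
  resp_bin <- sapply(split(seq_len(raw_k), group), function(js)
    rowSums(fit$resp[, js, drop = FALSE]))
  if (is.null(dim(resp_bin))) resp_bin <- matrix(resp_bin, ncol = 1L)
  # stable numbering: bins ordered by decreasing mean depth when known
  ord <- if ("log_depth" %in% colnames(x))
    order(-vapply(seq_len(ncol(resp_bin)), function(b) {
      w <- resp_bin[, b]
      sum(w * x[, "log_depth"]) / sum(w)
    }, 0))
  else seq_len(ncol(resp_bin))
  resp_bin <- resp_bin[, ord, drop = FALSE]
  bin <- max.col(resp_bin)
  post <- resp_bin[cbind(seq_len(nrow(x)), bin)]
  if (min_posterior > 0) bin[post < min_posterior] <- NA_integer_
  structure(list(assign = data.frame(read_id = rownames(x), bin = bin,
                                     posterior = post,
                                     stringsAsFactors = FALSE),
                 model = model, raw_k = raw_k,
                 chosen_k = ncol(resp_bin),
                 pca = list(n_components = m, explained = cum[m]),
                 seed = seed),
            class = "bin_assignment")
}

#' @export
print.bin_assignment <- function(x, ...) {
  cat(sprintf("bin_assignment: %d reads, chosen_k = %d (%d PCs, %.1f%% var)\n",
              nrow(x$assign), x$chosen_k, x$pca$n_components,
              100 * x$pca$explained))
  print(table(bin = x$assign$bin, useNA = "ifany"))
  invisible(x)
}

#' Export per-bin read FASTAs and a manifest
#'
#' Writes each assigned read to exactly one `bin_<label>.fa`; unassigned
#' reads (when a posterior threshold was applied) go to `unassigned.fa`.
#' Bins smaller than `min_bin_reads` are flagged `small` in the manifest but
#' still written.
#'
#' @param reads Named [Biostrings::DNAStringSet] containing every assigned
#'   read.
#' @param assignment A `bin_assignment`.
#' @param dir Output directory.
#' @param min_bin_reads Size below which a bin is flagged small.
#' @param features Optional feature table from [read_features()]; adds mean
#'   bin depth to the manifest.
#' @return The manifest `data.frame`, invisibly (also written to
#'   `manifest.tsv`).
#' @export
export_bins <- function(reads, assignment, dir, min_bin_reads = 50L,
                        features = NULL) {
  stopifnot(is(assignment, "bin_assignment"))
  asn <- assignment$assign
  missing <- setdiff(asn$read_id, names(reads))
  if (length(missing))
    stop_("assigned read(s) missing from FASTA: %s",
          paste(head(missing, 5L), collapse = ", "))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  depth <- if (!is.null(features))
    setNames(features$depth, features$read_id) else NULL
  groups <- split(asn$read_id, asn$bin, drop = TRUE)
  manifest <- do.call(rbind, lapply(names(groups), function(b) {
    ids <- groups[[b]]
    write_fasta(reads[ids], file.path(dir, sprintf("bin_%s.fa", b)))
    data.frame(bin = as.integer(b), n_reads = length(ids),
               mean_depth = if (is.null(depth)) NA_real_
                            else mean(depth[ids]),
               small = length(ids) < min_bin_reads,
               stringsAsFactors = FALSE)
  }))
  un <- asn$read_id[is.na(asn$bin)]
  if (length(un)) write_fasta(reads[un], file.path(dir, "unassigned.fa"))
  manifest <- manifest[order(manifest$bin), , drop = FALSE]
  rownames(manifest) <- NULL
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Score a bin assignment against truth labels
#'
#' ARI is computed on the (bin, strain) contingency table of assigned reads;
#' per-bin precision is the majority-strain fraction of the bin; per-strain
#' recall is the fraction of the strain's assigned reads falling in its
#' majority bin; the recovery rate is the fraction of input reads that were
#' assigned at all. All scores are invariant under bin relabelling.
#'
#' @param assignment A `bin_assignment` (or its `assign` data frame).
#' @param truth Data frame with `read_id` and `strain_id` covering every
#'   assigned read.
#' @param n_input_reads Total reads fed to the pipeline (defaults to the
#'   number of rows in the assignment).
#' @return An object of class `bin_score`: list with `ari`, `per_bin`,
#'   `per_strain` and `recovery_rate`.
#' @export
score_bins <- function(assignment, truth, n_input_reads = NULL) {
  asn <- if (is(assignment, "bin_assignment")) assignment$assign
         else assignment
  assert_df_cols(asn, c("read_id", "bin"), "assignment")
  assert_df_cols(truth, c("read_id", "strain_id"), "truth labels")
  if (is.null(n_input_reads)) n_input_reads <- nrow(asn)
  assigned <- asn[!is.na(asn$bin), , drop = FALSE]
  if (!nrow(assigned)) stop_("empty assignment: no read has a bin label")
  missing <- setdiff(assigned$read_id, truth$read_id)
  if (length(missing))
    stop_("truth labels missing for read(s): %s",
          paste(head(missing, 5L), collapse = ", "))
  strain <- setNames(truth$strain_id, truth$read_id)[assigned$read_id]
  tab <- table(bin = assigned$bin, strain = strain)
  per_bin <- data.frame(bin = as.integer(rownames(tab)),
                        n_reads = as.integer(rowSums(tab)),
                        majority_strain = colnames(tab)[max.col(tab)],
                        precision = apply(tab, 1L, max) / rowSums(tab),
                        stringsAsFactors = FALSE, row.names = NULL)
  per_strain <- data.frame(strain_id = colnames(tab),
                           n_reads = as.integer(colSums(tab)),
                           majority_bin = as.integer(
                             rownames(tab)[max.col(t(tab))]),
                           recall = apply(tab, 2L, max) / colSums(tab),
                           stringsAsFactors = FALSE, row.names = NULL)
  structure(list(ari = mclust::adjustedRandIndex(assigned$bin, strain),
                 per_bin = per_bin, per_strain = per_strain,
                 recovery_rate = nrow(assigned) / n_input_reads),
            class = "bin_score")
}

#' @export
print.bin_score <- function(x, ...) {
  cat(sprintf("bin_score: ARI = %.3f, recovery rate = %.3f\n",
              x$ari, x$recovery_rate))
  print(x$per_bin)
  invisible(x)
}
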