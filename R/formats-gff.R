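# GFF3 feature annotation I/O.
#
# Internally every interval is 0-based half-open; the 1-based inclusive GFF3
# convention is applied only at the serialization boundary (start0 = start-1,
# end0 = end). Transposase classification is keyword-driven from the product
# attribute, case-insensitively matching "transposase" or
# "insertion sequence": upstream IS predictors are consumed, not
# reimplemented.

FEATURE_COLS <- c("contig_id", "start", "end", "strand", "feature_class",
                  "gene_id", "ortholog_id", "product")

TRANSPOSASE_RE <- "transposase|insertion sequence"

#' Construct a feature annotation table
#'
#' @param contig_id Contig ids.
#' @param start,end 0-based half-open coordinates.
#' @param strand `"+"`, `"-"` or `"."`.
#' @param feature_class `"cds"` or `"transposase"`.
#' @param gene_id Unique gene ids.
#' @param ortholog_id Ortholog group ids (`NA` allowed).
#' @param product Free-text product description (drives transposase
#'   classification on GFF read).
#' @return A validated `data.frame` of features.
#' @export
feature_annotations <- function(contig_id, start, end, strand = "+",
                                feature_class = "cds", gene_id,
                                ortholog_id = NA_character_,
                                product = NA_character_) {
  df <- data.frame(contig_id = as.character(contig_id),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   feature_class = as.character(feature_class),
                   gene_id = as.character(gene_id),
                   ortholog_id = as.character(ortholog_id),
                   product = as.character(product),
                   stringsAsFactors = FALSE)
  validate_features(df)
}

validate_features <- function(df) {
  assert_df_cols(df, FEATURE_COLS, "feature annotation table")
  bad <- which(df$start < 0L | df$end <= df$start)
  if (length(bad))
    stop_("invalid feature interval for gene '%s': start=%d end=%d",
          df$gene_id[bad[1L]], df$start[bad[1L]], df$end[bad[1L]])
  if (!all(df$strand %in% c("+", "-", ".")))
    stop_("feature strand must be one of '+', '-', '.'")
  if (!all(df$feature_class %in% c("cds", "transposase")))
    stop_("feature_class must be 'cds' or 'transposase'")
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup))
    stop_("duplicate gene_id(s): %s", paste(dup, collapse = ", "))
  df
}

#' Read feature annotations from GFF3
#'
#' Coordinates are converted from 1-based inclusive to 0-based half-open.
#' Features whose `product` attribute matches the transposase keywords
#' (case-insensitive "transposase" / "insertion sequence") are classified as
#' `transposase`, all others as `cds`.
#'
#' @param path Path to a GFF3 file.
#' @return A feature annotation `data.frame` (see [feature_annotations()]).
#' @export
read_gff <- function(path) {
  if (!file.exists(path)) stop_("GFF file does not exist: %s", path)
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  pick <- function(col) {
    if (col %in% names(mc)) as.character(mc[[col]]) else
      rep(NA_character_, length(gr))
  }
  product <- pick("product")
  gene_id <- pick("ID")
  if (anyNA(gene_id)) stop_("GFF feature(s) without an ID attribute in %s", path)
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  feature_annotations(
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = strand,
    feature_class = ifelse(!is.na(product) &
                             grepl(TRANSPOSASE_RE, product, ignore.case = TRUE),
                           "transposase", "cds"),
    gene_id = gene_id,
    ortholog_id = pick("ortholog"),
    product = product)
}

#' Write feature annotations to GFF3
#'
#' Inverse of [read_gff()]: 0-based half-open intervals are serialized as
#' 1-based inclusive, and `read_gff(write_gff(x))` is record-equivalent to
#' `x`.
#'
#' @param features A feature annotation `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(features, path) {
  features <- validate_features(features)
  strand <- features$strand
  strand[strand == "."] <- "*"
  product <- features$product
  # keep classification stable through a round trip even when no product
  # string was supplied
  product[is.na(product)] <- ifelse(
    features$feature_class[is.na(product)] == "transposase",
    "transposase", "hypothetical protein")
  gr <- GenomicRanges::GRanges(
    seqnames = features$contig_id,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = strand)
  S4Vectors::mcols(gr)$source <- "strainscope"
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$phase <- 0L
  S4Vectors::mcols(gr)$ID <- features$gene_id
  S4Vectors::mcols(gr)$product <- product
  S4Vectors::mcols(gr)$ortholog <- features$ortholog_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
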