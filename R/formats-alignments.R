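# Tab-separated alignment record I/O.
#
# Two dialects are supported (see README for the full column contract):
#  * paf_like  - the 12 standard PAF columns, plus optional SAM-style tags
#                (tp:A:P/S for primary/secondary, AS:i for score).
#                Substitutions and indel bases are derived from the column
#                arithmetic M = qspan + tspan - alnlen, I = alnlen - tspan,
#                D = alnlen - qspan, substitutions = M - nmatch.
#  * sam_like  - the 11 mandatory SAM columns (text, no header) plus optional
#                NM:i / AS:i tags; the CIGAR string supplies the aligned
#                spans and indel bases.
# Internally all coordinates are 0-based half-open on the target.

ALN_COLS <- c("query_id", "target_id", "query_len", "target_start",
              "target_end", "strand", "aligned_query_bases", "substitutions",
              "indel_bases", "score", "is_primary")

#' Construct a set of alignment records
#'
#' Builds the validated data frame the recruitment/filter operations consume.
#' Coordinates are 0-based half-open on the target.
#'
#' @param query_id,target_id Character ids.
#' @param query_len Full query length (bp).
#' @param target_start,target_end 0-based half-open target interval.
#' @param strand `"+"` or `"-"`.
#' @param aligned_query_bases Number of query bases in aligned columns.
#' @param substitutions Substitution (mismatch) count; indels excluded.
#' @param indel_bases Total inserted plus deleted bases.
#' @param score Alignment score (higher is better).
#' @param is_primary Logical primary-alignment flag.
#' @return A `data.frame` with one row per alignment.
#' @export
alignment_records <- function(query_id, target_id, query_len, target_start,
                              target_end, strand = "+",
                              aligned_query_bases = query_len,
                              substitutions = 0L, indel_bases = 0L,
                              score = aligned_query_bases - substitutions,
                              is_primary = TRUE) {
  df <- data.frame(query_id = as.character(query_id),
                   target_id = as.character(target_id),
                   query_len = as.integer(query_len),
                   target_start = as.integer(target_start),
                   target_end = as.integer(target_end),
                   strand = as.character(strand),
                   aligned_query_bases = as.integer(aligned_query_bases),
                   substitutions = as.integer(substitutions),
                   indel_bases = as.integer(indel_bases),
                   score = as.numeric(score),
                   is_primary = as.logical(is_primary),
                   stringsAsFactors = FALSE)
  validate_alignments(df)
}

validate_alignments <- function(df, line = NULL) {
  assert_df_cols(df, ALN_COLS, "alignment table")
  where <- function(i) if (is.null(line)) sprintf("record %d", i)
           else sprintf("line %d", line[i])
  bad <- which(df$target_start < 0L | df$target_end <= df$target_start)
  if (length(bad))
    stop_("invalid target interval (%s): start=%d end=%d", where(bad[1L]),
          df$target_start[bad[1L]], df$target_end[bad[1L]])
  bad <- which(df$aligned_query_bases > df$query_len)
  if (length(bad))
    stop_("aligned_query_bases exceeds query_len (%s)", where(bad[1L]))
  bad <- which(df$substitutions < 0L | df$indel_bases < 0L)
  if (length(bad))
    stop_("negative edit counts (%s)", where(bad[1L]))
  if (!all(df$strand %in% c("+", "-")))
    stop_("strand must be '+' or '-'")
  df
}

tag_value <- function(tags, prefix) {
  hit <- regmatches(tags, regexpr(paste0(prefix, "[^\t]*"), tags))
  out <- rep(NA_character_, length(tags))
  out[grepl(prefix, tags)] <- sub(prefix, "", hit)
  out
}

#' Read tab-separated alignments
#'
#' @param path Path to a tab-separated alignment file.
#' @param dialect `"paf_like"` or `"sam_like"` (see README for the column
#'   contracts; both are plain-text subsets of the community formats).
#' @return A validated alignment `data.frame` (see [alignment_records()]),
#'   with target coordinates converted to 0-based half-open.
#' @export
read_alignments <- function(path, dialect = c("paf_like", "sam_like")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_("alignment file does not exist: %s", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (!length(lines))
    return(alignment_records(character(), character(), integer(),
                             integer(), integer())[0, ])
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nmin <- if (dialect == "paf_like") 12L else 11L
  nf <- lengths(fields)
  if (any(nf < nmin))
    stop_("malformed %s record at line %d: %d column(s), expected >= %d",
          dialect, which(nf < nmin)[1L], nf[which(nf < nmin)[1L]], nmin)
  tags <- vapply(fields, function(f) paste(f[-seq_len(nmin)], collapse = "\t"), "")
  col <- function(i) vapply(fields, `[[`, "", i)
  num <- function(i) suppressWarnings(as.numeric(col(i)))
  if (dialect == "paf_like") {
    qlen <- num(2L); qstart <- num(3L); qend <- num(4L)
    tstart <- num(8L); tend <- num(9L)
    nmatch <- num(10L); alnlen <- num(11L)
    if (anyNA(c(qlen, qstart, qend, tstart, tend, nmatch, alnlen)))
      stop_("non-numeric coordinate field in %s", path)
    qspan <- qend - qstart; tspan <- tend - tstart
    m <- qspan + tspan - alnlen
    bad <- which(m < 0 | m < nmatch - 1e-9)
    if (length(bad))
      stop_("inconsistent PAF spans at line %d", bad[1L])
    score <- suppressWarnings(as.numeric(tag_value(tags, "AS:i:")))
    tp <- tag_value(tags, "tp:A:")
    df <- data.frame(query_id = col(1L), target_id = col(6L),
                     query_len = as.integer(qlen),
                     target_start = as.integer(tstart),
                     target_end = as.integer(tend),
                     strand = col(5L),
                     aligned_query_bases = as.integer(qspan),
                     substitutions = as.integer(round(m - nmatch)),
                     indel_bases = as.integer(round(2 * alnlen - qspan - tspan)),
                     score = ifelse(is.na(score), nmatch, score),
                     is_primary = is.na(tp) | tp == "P",
                     stringsAsFactors = FALSE)
  } else {
    flag <- suppressWarnings(as.integer(col(2L)))
    pos <- suppressWarnings(as.numeric(col(4L)))
    if (anyNA(flag) || anyNA(pos)) stop_("non-numeric FLAG/POS field in %s", path)
    cig <- lapply(col(6L), parse_cigar)
    qaln <- vapply(cig, `[[`, 0, "query_aln")
    tspan <- vapply(cig, `[[`, 0, "target_span")
    clip <- vapply(cig, `[[`, 0, "clipped")
    indel <- vapply(cig, `[[`, 0, "indel")
    nm <- suppressWarnings(as.numeric(tag_value(tags, "NM:i:")))
    nm[is.na(nm)] <- indel[is.na(nm)]
    score <- suppressWarnings(as.numeric(tag_value(tags, "AS:i:")))
    bad <- which(pos < 1 | tspan <= 0)
    if (length(bad))
      stop_("invalid position/span at line %d", bad[1L])
    df <- data.frame(query_id = col(1L), target_id = col(3L),
                     query_len = as.integer(qaln + clip),
                     target_start = as.integer(pos - 1),
                     target_end = as.integer(pos - 1 + tspan),
                     strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
                     aligned_query_bases = as.integer(qaln),
                     substitutions = as.integer(pmax(0, round(nm - indel))),
                     indel_bases = as.integer(indel),
                     score = ifelse(is.na(score),
                                    suppressWarnings(as.numeric(col(5L))), score),
                     is_primary = bitwAnd(flag, 256L) == 0L &
                                  bitwAnd(flag, 2048L) == 0L,
                     stringsAsFactors = FALSE)
  }
  validate_alignments(df, line = seq_along(lines))
}

# Minimal CIGAR accounting: spans along query/target, clipped and indel bases.
parse_cigar <- function(cigar) {
  if (cigar == "*") stop_("CIGAR '*' (unaligned record) is not supported")
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  if (!length(ops) || nchar(paste(ops, collapse = "")) != nchar(cigar))
    stop_("malformed CIGAR string: %s", cigar)
  n <- as.numeric(sub("[MIDNSHP=X]", "", ops))
  op <- sub("\\d+", "", ops)
  list(query_aln = sum(n[op %in% c("M", "=", "X", "I")]),
       target_span = sum(n[op %in% c("M", "=", "X", "D", "N")]),
       clipped = sum(n[op %in% c("S", "H")]),
       indel = sum(n[op %in% c("I", "D")]))
}

#' Write alignment records in the paf_like dialect
#'
#' Inverse of [read_alignments()] for `dialect = "paf_like"`: the 12 PAF
#' columns are reconstructed from the record fields and the `tp:A`/`AS:i`
#' tags carry the primary flag and score.
#'
#' @param df An alignment `data.frame` (see [alignment_records()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(df, path) {
  df <- validate_alignments(df)
  qspan <- df$aligned_query_bases
  tspan <- df$target_end - df$target_start
  m <- (qspan + tspan - df$indel_bases) / 2
  if (any(m != round(m)))
    stop_("inconsistent span/indel fields: cannot serialise")
  alnlen <- m + df$indel_bases
  lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d\ttp:A:%s\tAS:i:%d",
                   df$query_id, df$query_len, 0L, qspan, df$strand,
                   df$target_id, df$target_end, df$target_start, df$target_end,
                   as.integer(m - df$substitutions), as.integer(alnlen), 255L,
                   ifelse(df$is_primary, "P", "S"), as.integer(df$score))
  writeLines(lines, path)
  invisible(path)
}
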