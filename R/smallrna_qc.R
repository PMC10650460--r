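# Small-RNA QC: FASTQ ingestion, length/quality filtering, collapsing of
# identical sequences into counted unique reads.

#' QC parameters for small-RNA reads
#'
#' The length window follows the standard small-RNA analysis rule: reads
#' shorter than 15 nt are background, reads longer than 30 nt are not
#' mature-miRNA sized. The mean-Phred floor is a conventional quality cutoff;
#' it is a configurable default, not a biological constant.
#'
#' @param min_len,max_len Inclusive length window (defaults 15 and 30 nt).
#' @param min_mean_q Minimum mean Phred quality (default 20).
#' @return An object of class `qc_params`.
#' @export
qc_params <- function(min_len = 15L, max_len = 30L, min_mean_q = 20) {
  min_len <- as.integer(min_len); max_len <- as.integer(max_len)
  if (!(min_len > 0L && min_len <= max_len)) {
    stop("need 0 < min_len <= max_len", call. = FALSE)
  }
  if (min_mean_q < 0) stop("min_mean_q must be >= 0", call. = FALSE)
  structure(list(min_len = min_len, max_len = max_len,
                 min_mean_q = min_mean_q), class = "qc_params")
}

#' Read a Phred+33 FASTQ file
#'
#' Expects plain 4-line records. Sequences are normalized to RNA (`T` to
#' `U`); qualities are decoded to integer Phred scores. A file whose line
#' count is not a multiple of 4, or whose header/separator markers are
#' malformed, raises a parse error naming the record index.
#'
#' @param path FASTQ file path.
#' @return A data frame with columns `read_id`, `sequence` (RNA) and
#'   `quality` (list column of integer Phred vectors).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  n_lines <- length(readLines(path, warn = FALSE))
  if (n_lines == 0L) {
    return(data.frame(read_id = character(), sequence = character(),
                      quality = I(list()), stringsAsFactors = FALSE))
  }
  if (n_lines %% 4L != 0L) {
    stop("truncated FASTQ record at record ", n_lines %/% 4L + 1L,
         " in '", path, "'", call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  idx <- seq(1L, n_lines, by = 4L)
  bad <- which(substr(lines[idx], 1L, 1L) != "@" |
                 substr(lines[idx + 2L], 1L, 1L) != "+")
  if (length(bad)) {
    stop("malformed FASTQ record ", bad[1], " in '", path,
         "' (missing @/+ marker)", call. = FALSE)
  }
  set <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
  quals <- methods::as(Biostrings::PhredQuality(S4Vectors::mcols(set)$qualities),
                       "IntegerList")
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[[`, character(1), 1L)
  seqs <- chartr("T", "U", toupper(as.character(set)))
  data.frame(read_id = ids, sequence = unname(seqs),
             quality = I(as.list(quals)), stringsAsFactors = FALSE)
}

#' Filter reads by length window and mean quality
#'
#' A read is kept iff `min_len <= length <= max_len` and its mean Phred
#' score is at least `min_mean_q`. The rejection statistics partition the
#' input exactly: `kept + too_short + too_long + low_quality == n` reads.
#' Length is checked before quality, so an out-of-window read is never
#' counted as low-quality.
#'
#' @param reads Data frame from [read_fastq()].
#' @param params A [qc_params()] object.
#' @return A list with `kept` (the surviving rows) and `stats` (named
#'   integer vector: `kept`, `too_short`, `too_long`, `low_quality`).
#' @export
filter_reads <- function(reads, params = qc_params()) {
  stopifnot(inherits(params, "qc_params"))
  len <- nchar(reads$sequence)
  mean_q <- vapply(reads$quality, function(q) {
    if (length(q) == 0L) 0 else mean(q)
  }, numeric(1))
  too_short <- len < params$min_len
  too_long <- !too_short & len > params$max_len
  low_quality <- !too_short & !too_long & mean_q < params$min_mean_q
  keep <- !too_short & !too_long & !low_quality
  stats <- c(kept = sum(keep), too_short = sum(too_short),
             too_long = sum(too_long), low_quality = sum(low_quality))
  list(kept = reads[keep, , drop = FALSE], stats = stats)
}

#' Collapse identical read sequences into counted unique reads
#'
#' @param reads Data frame with a `sequence` column (e.g. the `kept` element
#'   of [filter_reads()]), or a character vector of sequences.
#' @return A data frame with columns `sequence` and `count`, ordered by
#'   count (descending) then sequence (lexicographic); the counts sum to the
#'   number of input reads.
#' @export
collapse_reads <- function(reads) {
  seqs <- if (is.character(reads)) reads else reads$sequence
  if (length(seqs) == 0L) {
    return(data.frame(sequence = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(seqs)
  df <- data.frame(sequence = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$sequence), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a QC report TSV
#'
#' @param stats Named counts from [filter_reads()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_qc_report <- function(stats, path) {
  utils::write.table(
    data.frame(reason = names(stats), count = as.integer(stats)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write collapsed reads as count-suffix FASTA
#'
#' Headers follow the `>seq{i}_x{count}` dialect used by small-RNA
#' collapsing tools. Sequences are written in the DNA alphabet (`U` to `T`).
#'
#' @param collapsed Data frame from [collapse_reads()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_collapsed_fasta <- function(collapsed, path) {
  set <- Biostrings::DNAStringSet(chartr("U", "T", collapsed$sequence))
  names(set) <- sprintf("seq%d_x%d", seq_len(nrow(collapsed)),
                        collapsed$count)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a count-suffix collapsed FASTA
#'
#' Inverse of [write_collapsed_fasta()]: headers must end in `_x{count}`.
#'
#' @param path FASTA path.
#' @return Data frame with `sequence` (RNA) and `count`.
#' @export
read_collapsed_fasta <- function(path) {
  df <- read_hairpin_fasta(path)
  counts <- suppressWarnings(as.integer(sub("^.*_x(\\d+)$", "\\1",
                                            df$hairpin_id)))
  if (anyNA(counts)) {
    stop("collapsed FASTA headers must end in _x<count>", call. = FALSE)
  }
  data.frame(sequence = df$sequence, count = counts, stringsAsFactors = FALSE)
}
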