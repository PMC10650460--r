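# IsomiR caller: deterministic anchored decomposition of a read against a
# mature-within-hairpin annotation.
#
# A read is anchored at hairpin position (mature start + shift5) for every
# candidate 5' shift. Within the mature-overlapping span the core anchor
# region must match exactly and at most max_mismatch substitutions are
# allowed elsewhere. The 3' overhang beyond the mature end is split by
# greedy maximal templated matching against the downstream hairpin context:
# the matched prefix is the templated extension (ext3), the remainder the
# non-templated tail. Candidates are scored by total edits
# (|shift5| + trim3 + ext3 + |tail| + #substitutions); the lowest-scoring
# candidate wins, ties broken by smaller |shift5|, then smaller |tail|,
# then lexicographic mature_id, then signed shift5.

#' Caller parameters
#'
#' Tolerances of the anchored decomposition. The defaults are this
#' package's operational choices (reproducible and explicit), not values
#' with biological meaning. The core anchor region is given 0-based within
#' the mature and must contain the seed (mature positions 1-7, 0-based), so
#' no accepted call ever carries a seed substitution.
#'
#' @param max_5p_shift Maximum |5' offset| in either direction (default 2).
#' @param max_3p_trim Maximum templated 3' trim length (default 5).
#' @param max_3p_ext Maximum templated 3' extension length and also the
#'   maximum non-templated tail length (default 5).
#' @param max_mismatch Maximum substitutions outside the core (default 1).
#' @param core_start,core_end Core anchor region, 0-based half-open within
#'   the mature (defaults 1 and 18); clamped to the mature length at call
#'   time for short matures.
#' @param allow_mixed_trim_tail Permit calls combining a 3' trim with a
#'   non-templated tail (default `FALSE`; the common isoform vocabulary
#'   never combines them).
#' @return An object of class `caller_params`.
#' @export
caller_params <- function(max_5p_shift = 2L, max_3p_trim = 5L,
                          max_3p_ext = 5L, max_mismatch = 1L,
                          core_start = 1L, core_end = 18L,
                          allow_mixed_trim_tail = FALSE) {
  p <- list(max_5p_shift = as.integer(max_5p_shift),
            max_3p_trim = as.integer(max_3p_trim),
            max_3p_ext = as.integer(max_3p_ext),
            max_mismatch = as.integer(max_mismatch),
            core_start = as.integer(core_start),
            core_end = as.integer(core_end),
            allow_mixed_trim_tail = isTRUE(allow_mixed_trim_tail))
  if (any(vapply(p[1:4], `<`, logical(1), 0L))) {
    stop("caller limits must be >= 0", call. = FALSE)
  }
  if (p$core_start < 0L || p$core_end <= p$core_start) {
    stop("need 0 <= core_start < core_end", call. = FALSE)
  }
  if (!(p$core_start <= 1L && p$core_end >= 8L)) {
    stop("core region must contain the seed (mature positions 1-7)",
         call. = FALSE)
  }
  structure(p, class = "caller_params")
}

# Longest common prefix length of two strings.
.lcp <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- strsplit(substr(a, 1L, n), "", fixed = TRUE)[[1]]
  bv <- strsplit(substr(b, 1L, n), "", fixed = TRUE)[[1]]
  neq <- which(av != bv)
  if (length(neq) == 0L) n else neq[1] - 1L
}

# Candidate comparison: score, |shift5|, |tail|, mature_id, signed shift5.
.call_key <- function(call) {
  list(call$score, abs(call$shift5), nchar(call$tail), call$mature_id,
       call$shift5)
}

.call_better <- function(a, b) {
  ka <- .call_key(a); kb <- .call_key(b)
  for (i in seq_along(ka)) {
    if (is.character(ka[[i]])) {
      if (ka[[i]] < kb[[i]]) return(TRUE)
      if (ka[[i]] > kb[[i]]) return(FALSE)
    } else {
      if (ka[[i]] < kb[[i]]) return(TRUE)
      if (ka[[i]] > kb[[i]]) return(FALSE)
    }
  }
  FALSE
}

# Evaluate one anchored candidate at a fixed shift5. Returns NULL when the
# candidate violates a limit, else an unlabelled call record.
.eval_candidate <- function(seq_chars, seq, hp_chars, hp_id, s, e, sh,
                            params, mature_id) {
  len <- length(seq_chars)
  a <- s + sh                      # 0-based hairpin position of read base 1
  if (a < 0L) return(NULL)
  p_end <- a + len                 # one-past-end hairpin position
  L <- length(hp_chars)
  # mature-overlapping span: read positions mapping into [a, min(p_end, e))
  nmat <- min(p_end, e) - a
  if (nmat <= 0L) return(NULL)
  core_lo <- s + params$core_start                       # hairpin frame
  core_hi <- s + min(params$core_end, e - s)             # clamped
  # substitutions over a read prefix aligned to hairpin [a, a + n); NULL
  # when a core mismatch or the mismatch budget rules the span out
  span_subs <- function(n) {
    n <- min(n, L - a)
    if (n <= 0L) return(list(subs = NULL, nsub = 0L))
    hp_span <- hp_chars[(a + 1L):(a + n)]
    rd_span <- seq_chars[1:n]
    mis <- which(hp_span != rd_span)
    if (length(mis) == 0L) return(list(subs = NULL, nsub = 0L))
    hp_pos <- a + mis - 1L                               # 0-based
    if (any(hp_pos >= core_lo & hp_pos < core_hi)) return(NULL)
    if (length(mis) > params$max_mismatch) return(NULL)
    list(subs = data.frame(pos = mis, ref = hp_span[mis], alt = rd_span[mis],
                           stringsAsFactors = FALSE),
         nsub = length(mis))
  }
  make_call <- function(trim3, ext3, tail, sp) {
    score <- abs(sh) + trim3 + ext3 + nchar(tail) + sp$nsub
    list(sequence = seq, mature_id = mature_id, hairpin_id = hp_id,
         shift5 = as.integer(sh), trim3 = as.integer(trim3),
         ext3 = as.integer(ext3), tail = tail,
         substitutions = sp$subs, n_sub = sp$nsub, score = score)
  }
  out <- list()
  sp_full <- span_subs(nmat)
  if (!is.null(sp_full)) {
    if (p_end <= e) {
      trim3 <- e - p_end
      if (trim3 <= params$max_3p_trim) {
        out[[length(out) + 1L]] <- make_call(trim3, 0L, "", sp_full)
      }
    } else {
      over <- substr(seq, nmat + 1L, len)
      ctx <- if (e < L) {
        paste(hp_chars[(e + 1L):L], collapse = "")
      } else ""
      k <- .lcp(over, ctx)                   # greedy maximal templated match
      ext3 <- min(k, params$max_3p_ext)
      tail <- substr(over, ext3 + 1L, nchar(over))
      if (nchar(tail) <= params$max_3p_ext) {
        out[[length(out) + 1L]] <- make_call(0L, ext3, tail, sp_full)
      }
    }
  }
  if (params$allow_mixed_trim_tail) {
    # read suffix of length m re-read as a non-templated tail occupying the
    # positions of t trimmed mature bases (and any overhang); requires a
    # mismatch at the first tail base (else it would align as template) and
    # must not reach into the core anchor
    for (t in seq_len(params$max_3p_trim)) {
      m <- t - (e - p_end)
      if (m < 1L || m > len - 1L || m > params$max_3p_ext) next
      cut <- e - t                           # hairpin pos of first tail base
      if (cut < core_hi) next
      n2 <- cut - a
      if (n2 <= 0L) next
      tail <- substr(seq, len - m + 1L, len)
      if (cut < L && hp_chars[cut + 1L] == substr(tail, 1L, 1L)) next
      sp <- span_subs(n2)
      if (is.null(sp)) next
      out[[length(out) + 1L]] <- make_call(t, 0L, tail, sp)
    }
  }
  out
}

#' Decompose a read against a mature-within-hairpin annotation
#'
#' Runs the anchored decomposition described in the package overview and
#' returns the minimum-edit call, or `NULL` (no-call) when no candidate is
#' within the parameter limits.
#'
#' @param seq Read sequence, RNA or DNA alphabet, length 15-30 nt.
#' @param hairpin One hairpin row (as from [read_hairpin_fasta()]).
#' @param annot One mature annotation row (as from [locate_mature()]).
#' @param params A [caller_params()] object.
#' @return An object of class `isomir_call` (fields `sequence`,
#'   `mature_id`, `shift5`, `trim3`, `ext3`, `tail`, `substitutions`,
#'   `label`, `score`) or `NULL`.
#' @examples
#' hp <- data.frame(hairpin_id = "h1",
#'                  sequence = "CGUAUCCCUGAGACCCUAACUUGUGAGCUAG",
#'                  species_tag = "sim")
#' ann <- data.frame(mature_id = "m1", hairpin_id = "h1",
#'                   start = 4L, end = 26L, arm = "5p")
#' decompose("UCCCUGAGACCCUAACUUGUGAA", hp, ann, caller_params())$label
#' @export
decompose <- function(seq, hairpin, annot, params = caller_params()) {
  seq <- .normalize_rna(seq, "read")
  len <- nchar(seq)
  if (len < 15L || len > 30L) {
    stop("read length must be in [15, 30], got ", len, call. = FALSE)
  }
  stopifnot(inherits(params, "caller_params"))
  seq_chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hp_chars <- strsplit(hairpin$sequence, "", fixed = TRUE)[[1]]
  s <- as.integer(annot$start); e <- as.integer(annot$end)
  best <- NULL
  for (sh in seq.int(-params$max_5p_shift, params$max_5p_shift)) {
    cands <- .eval_candidate(seq_chars, seq, hp_chars, hairpin$hairpin_id,
                             s, e, sh, params, annot$mature_id)
    for (cand in cands) {
      if (is.null(best) || .call_better(cand, best)) best <- cand
    }
  }
  if (is.null(best)) return(NULL)
  best$mature_seq <- paste(hp_chars[(s + 1L):e], collapse = "")
  best$label <- label_call(best)
  class(best) <- "isomir_call"
  best
}

# Decompose against every mature in a reference set; lowest key wins.
.decompose_multi <- function(seq, ref, params) {
  best <- NULL
  for (i in seq_len(nrow(ref$matures))) {
    m <- ref$matures[i, ]
    hp <- .get_hairpin(ref, m$hairpin_id)
    cand <- decompose(seq, hp, m, params)
    if (!is.null(cand) && (is.null(best) || .call_better(cand, best))) {
      best <- cand
    }
  }
  best
}

#' Label an isomiR call
#'
#' Produces the field-standard label: `"canonical"` for the unmodified
#' mature; `"Plus <tail>"` for a pure non-templated addition; `"Trim <bases>"`
#' for a pure 3' trim, the removed bases listed from the 3' terminus inward
#' (a mature ending `...UGA` trimmed by 2 is `"Trim AG"`); `"Ext+<n>"` for a
#' templated extension; a `"5p+<n>"`/`"5p-<n>"` prefix for 5' variants
#' (positive = 5' trim); and a `";sub<pos><ref>><alt>"` suffix per
#' substitution (1-based position within the read). Compound labels
#' concatenate 5', 3' and substitution parts in that order, separated by
#' `";"`.
#'
#' @param call An `isomir_call` (or the internal candidate record).
#' @param ref Optional `reference_set`; only needed when the call does not
#'   carry its mature sequence.
#' @return A label string.
#' @export
label_call <- function(call, ref = NULL) {
  mature_seq <- call$mature_seq
  if (is.null(mature_seq)) {
    if (is.null(ref)) stop("call lacks mature_seq; supply ref", call. = FALSE)
    mature_seq <- mature_sequence(ref, call$mature_id)
  }
  parts <- character()
  if (call$shift5 != 0L) {
    parts <- c(parts, sprintf("5p%+d", call$shift5))
  }
  if (call$trim3 > 0L) {
    L <- nchar(mature_seq)
    removed <- substr(mature_seq, L - call$trim3 + 1L, L)
    removed <- paste(rev(strsplit(removed, "", fixed = TRUE)[[1]]),
                     collapse = "")
    parts <- c(parts, paste("Trim", removed))
  }
  if (call$ext3 > 0L) {
    parts <- c(parts, sprintf("Ext+%d", call$ext3))
  }
  if (nzchar(call$tail)) {
    parts <- c(parts, paste("Plus", call$tail))
  }
  base <- if (length(parts)) paste(parts, collapse = ";") else "canonical"
  if (!is.null(call$substitutions) && nrow(call$substitutions) > 0L) {
    subs <- call$substitutions
    sub_str <- sprintf("sub%d%s>%s", subs$pos, subs$ref, subs$alt)
    base <- paste(c(base, sub_str), collapse = ";")
  }
  base
}

#' Rebuild a read from its isomiR call
#'
#' Round-trip oracle: reconstructs the read from the reference and the call
#' fields (5' shift, 3' trim/extension, substitutions, tail). An error is
#' raised when the call fields are internally inconsistent (e.g. both
#' `trim3` and `ext3` nonzero) or when the rebuilt string does not equal
#' `call$sequence`.
#'
#' @param call An `isomir_call`.
#' @param ref The `reference_set` the call was made against.
#' @return The reconstructed RNA string (identical to `call$sequence`).
#' @export
reconstruct <- function(call, ref) {
  if (call$trim3 > 0L && call$ext3 > 0L) {
    stop("inconsistent call: both trim3 and ext3 nonzero", call. = FALSE)
  }
  if (call$trim3 < 0L || call$ext3 < 0L) {
    stop("inconsistent call: negative trim3/ext3", call. = FALSE)
  }
  m <- .get_mature(ref, call$mature_id)
  hp <- .get_hairpin(ref, m$hairpin_id)
  s <- m$start; e <- m$end
  a <- s + call$shift5
  if (a < 0L) stop("inconsistent call: read start before hairpin", call. = FALSE)
  core <- substr(hp$sequence, a + 1L, e - call$trim3)
  if (call$ext3 > 0L) {
    ctx <- substr(hp$sequence, e + 1L, e + call$ext3)
    if (nchar(ctx) < call$ext3) {
      stop("inconsistent call: ext3 runs past the hairpin end", call. = FALSE)
    }
    core <- paste0(core, ctx)
  }
  chars <- strsplit(core, "", fixed = TRUE)[[1]]
  if (!is.null(call$substitutions) && nrow(call$substitutions) > 0L) {
    for (i in seq_len(nrow(call$substitutions))) {
      sb <- call$substitutions[i, ]
      if (sb$pos < 1L || sb$pos > length(chars)) {
        stop("inconsistent call: substitution position ", sb$pos,
             " outside the templated span", call. = FALSE)
      }
      if (chars[sb$pos] != sb$ref) {
        stop("inconsistent call: substitution ref base mismatch at position ",
             sb$pos, call. = FALSE)
      }
      chars[sb$pos] <- sb$alt
    }
  }
  out <- paste0(paste(chars, collapse = ""), call$tail)
  if (!is.null(call$sequence) && !identical(out, call$sequence)) {
    stop("reconstruction mismatch: rebuilt '", out, "' vs call sequence '",
         call$sequence, "'", call. = FALSE)
  }
  out
}

#' @export
print.isomir_call <- function(x, ...) {
  cat(sprintf("isomir_call: %s -> %s (%s)\n", x$sequence, x$label,
              x$mature_id))
  cat(sprintf("  shift5=%d trim3=%d ext3=%d tail='%s' n_sub=%d score=%d\n",
              x$shift5, x$trim3, x$ext3, x$tail, x$n_sub, x$score))
  invisible(x)
}

#' Call isomiR profiles for one sample
#'
#' Decomposes each unique sequence once against every mature in the
#' reference set, resolving multi-mapping by the global candidate ordering,
#' and accumulates read counts per (mature, label). Reads with no candidate
#' within limits are counted as unassigned. RPM is computed over assigned
#' reads and sums to 1e6 when any read is assigned.
#'
#' @param collapsed Data frame of `sequence`/`count` from [collapse_reads()]
#'   (or [read_collapsed_fasta()]).
#' @param ref A `reference_set`.
#' @param params A [caller_params()] object.
#' @param sample_id Sample label stored in the profile.
#' @return An object of class `isomir_profile`: list with `sample_id`,
#'   `entries` (data frame: `mature_id`, `label`, `shift5`, `trim3`, `ext3`,
#'   `tail`, `n_sub`, `count`, `rpm`), `total_assigned`, `total_unassigned`.
#' @export
call_sample <- function(collapsed, ref, params = caller_params(),
                        sample_id = "sample") {
  stopifnot(inherits(ref, "reference_set"))
  if (nrow(ref$matures) == 0L) {
    stop("reference set has no mature annotations", call. = FALSE)
  }
  entries <- list()
  total_assigned <- 0L
  total_unassigned <- 0L
  for (i in seq_len(nrow(collapsed))) {
    seq <- collapsed$sequence[i]
    cnt <- collapsed$count[i]
    call <- .decompose_multi(seq, ref, params)
    if (is.null(call)) {
      total_unassigned <- total_unassigned + cnt
      next
    }
    key <- paste(call$mature_id, call$label, sep = "\r")
    if (is.null(entries[[key]])) {
      entries[[key]] <- data.frame(
        mature_id = call$mature_id, label = call$label,
        shift5 = call$shift5, trim3 = call$trim3, ext3 = call$ext3,
        tail = call$tail, n_sub = call$n_sub, count = cnt,
        stringsAsFactors = FALSE)
    } else {
      entries[[key]]$count <- entries[[key]]$count + cnt
    }
    total_assigned <- total_assigned + cnt
  }
  df <- if (length(entries)) {
    do.call(rbind, unname(entries))
  } else {
    data.frame(mature_id = character(), label = character(),
               shift5 = integer(), trim3 = integer(), ext3 = integer(),
               tail = character(), n_sub = integer(), count = integer(),
               stringsAsFactors = FALSE)
  }
  df <- df[order(-df$count, df$mature_id, df$label), , drop = FALSE]
  rownames(df) <- NULL
  df$rpm <- if (total_assigned > 0L) df$count / total_assigned * 1e6 else numeric(nrow(df))
  structure(list(sample_id = sample_id, entries = df,
                 total_assigned = total_assigned,
                 total_unassigned = total_unassigned),
            class = "isomir_profile")
}

#' @export
print.isomir_profile <- function(x, n = 10L, ...) {
  cat(sprintf("isomir_profile '%s': %d assigned, %d unassigned reads, %d isoform(s)\n",
              x$sample_id, x$total_assigned, x$total_unassigned,
              nrow(x$entries)))
  print(utils::head(x$entries, n))
  invisible(x)
}

#' @export
summary.isomir_profile <- function(object, ...) {
  e <- object$entries
  cat(sprintf("Sample '%s'\n", object$sample_id))
  cat(sprintf("  assigned reads:   %d\n", object$total_assigned))
  cat(sprintf("  unassigned reads: %d\n", object$total_unassigned))
  for (m in unique(e$mature_id)) {
    sub <- e[e$mature_id == m, ]
    cat(sprintf("  %s: %d isoform(s); top: %s (%.1f%% of assigned)\n",
                m, nrow(sub), sub$label[which.max(sub$count)],
                100 * max(sub$count) / object$total_assigned))
  }
  invisible(object)
}

#' Top-ranked isoforms of a mature miRNA in a profile
#'
#' @param profile An `isomir_profile`.
#' @param mature_id Mature id (must carry at least one entry or be known to
#'   the profile through zero entries).
#' @param n Number of isoforms to return (>= 1); fewer when the profile has
#'   fewer entries.
#' @return Data frame of `label`, `count` ordered by count (descending),
#'   ties broken lexicographically by label.
#' @export
rank_isoforms <- function(profile, mature_id, n = 5L) {
  stopifnot(inherits(profile, "isomir_profile"), n >= 1L)
  e <- profile$entries[profile$entries$mature_id == mature_id, , drop = FALSE]
  if (nrow(e) == 0L && !(mature_id %in% profile$entries$mature_id)) {
    # distinguish "no reads for a known mature" from a typo'd id: the
    # profile itself carries no reference, so an empty result is returned
    # only when the caller opts in via allow_empty behaviour of
    # compare_profiles(); here an unknown id with no entries is an error.
    stop("no entries for mature id '", mature_id, "' in profile '",
         profile$sample_id, "'", call. = FALSE)
  }
  e <- e[order(-e$count, e$label), , drop = FALSE]
  out <- utils::head(e[, c("label", "count")], n)
  rownames(out) <- NULL
  out
}

#' Write an isomiR profile as TSV
#'
#' One row per isoform: `sample_id`, `mature_id`, `label`, `shift5`,
#' `trim3`, `ext3`, `tail`, `n_sub`, `count`, `rpm`.
#'
#' @param profile An `isomir_profile`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  df <- profile$entries
  df <- cbind(sample_id = profile$sample_id, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an isomiR profile TSV written by [write_profile_tsv()]
#'
#' @param path TSV path.
#' @return An `isomir_profile` (totals recomputed from the counts; the
#'   unassigned total is not stored in the TSV and is set to 0).
#' @export
read_profile_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(tail = "character"))
  df$tail[is.na(df$tail)] <- ""
  sample_id <- if (nrow(df)) df$sample_id[1] else "sample"
  entries <- df[, setdiff(names(df), "sample_id"), drop = FALSE]
  structure(list(sample_id = sample_id, entries = entries,
                 total_assigned = sum(entries$count),
                 total_unassigned = 0L),
            class = "isomir_profile")
}
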