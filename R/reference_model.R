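# Reference model: miRBase-dialect hairpin/mature references and the
# mature-within-hairpin coordinate frame.
#
# All coordinates are 0-based, half-open, on the hairpin 5'->3' strand.
# Sequences are held as RNA (U, not T); FASTA input in either alphabet is
# accepted and normalized on load.

.RNA_ALPHABET <- c("A", "C", "G", "U")

# Uppercase, T->U, and validate alphabet; `what` names the record in errors.
.normalize_rna <- function(seq, what = "sequence") {
  seq <- chartr("t", "T", toupper(seq))
  seq <- chartr("T", "U", seq)
  bad <- regexpr("[^ACGU]", seq)
  if (bad > 0L) {
    stop(sprintf("invalid base '%s' at position %d in %s (alphabet is A/C/G/U)",
                 substr(seq, bad, bad), bad, what), call. = FALSE)
  }
  if (!nzchar(seq)) stop(sprintf("empty sequence in %s", what), call. = FALSE)
  seq
}

#' Read a miRBase-dialect hairpin FASTA
#'
#' Parses a (pre-miRNA) hairpin FASTA file. Record ids are the first
#' whitespace-delimited token of each header. Sequences are uppercased and
#' normalized to the RNA alphabet (`T` becomes `U`); any other character is
#' rejected with the offending record and position named. Duplicate ids are
#' an error.
#'
#' @param path Path to a FASTA file.
#' @param species_tag Optional species tag (e.g. `"rno"`, `"oar"`) applied to
#'   all records. When `NULL` the tag is taken from the id prefix before the
#'   first `"-"` if one exists, otherwise `"unknown"`.
#' @return A data frame with columns `hairpin_id`, `sequence` (RNA) and
#'   `species_tag`, one row per record.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">rno-mir-125b-1", "TCCCTGAGACCCTAACTTGTGA"), fa)
#' read_hairpin_fasta(fa)
#' @export
read_hairpin_fasta <- function(path, species_tag = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate hairpin id(s) in '", path, "': ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  seqs <- as.character(set)
  seqs <- vapply(seq_along(seqs), function(i) {
    .normalize_rna(seqs[[i]], what = sprintf("record '%s'", ids[[i]]))
  }, character(1))
  tag <- if (is.null(species_tag)) {
    vapply(ids, function(id) {
      if (grepl("-", id, fixed = TRUE)) sub("-.*$", "", id) else "unknown"
    }, character(1), USE.NAMES = FALSE)
  } else {
    rep_len(as.character(species_tag), length(ids))
  }
  data.frame(hairpin_id = ids, sequence = unname(seqs), species_tag = tag,
             stringsAsFactors = FALSE)
}

#' Read a mature miRNA FASTA
#'
#' Same parsing and normalization rules as [read_hairpin_fasta()]; returns
#' `mature_id` and `sequence` columns. miRBase mature FASTA carries no
#' coordinates; use [locate_mature()] or [reference_from_fastas()] to recover
#' the interval inside the hairpin.
#'
#' @inheritParams read_hairpin_fasta
#' @return A data frame with columns `mature_id` and `sequence`.
#' @export
read_mature_fasta <- function(path) {
  df <- read_hairpin_fasta(path)
  data.frame(mature_id = df$hairpin_id, sequence = df$sequence,
             stringsAsFactors = FALSE)
}

#' Locate a mature sequence inside its hairpin
#'
#' Finds the leftmost exact occurrence of `mature_seq` in the hairpin and
#' returns the mature annotation in 0-based half-open hairpin coordinates.
#' If the mature occurs more than once a warning is issued and the leftmost
#' interval is used. The arm is `"5p"` when the interval midpoint falls in
#' the first half of the hairpin, else `"3p"`.
#'
#' @param mature_seq Mature RNA sequence (15-30 nt; `T` accepted).
#' @param hairpin A single row of the data frame returned by
#'   [read_hairpin_fasta()] (or any list with `hairpin_id` and `sequence`).
#' @param mature_id Id to record; defaults to `<hairpin_id>-mature`.
#' @return A one-row data frame with columns `mature_id`, `hairpin_id`,
#'   `start`, `end` (0-based half-open) and `arm`.
#' @export
locate_mature <- function(mature_seq, hairpin, mature_id = NULL) {
  mature_seq <- .normalize_rna(mature_seq, "mature sequence")
  n <- nchar(mature_seq)
  if (n < 15L || n > 30L) {
    stop("mature sequence length must be in [15, 30], got ", n, call. = FALSE)
  }
  hp_seq <- hairpin$sequence
  hp_id <- hairpin$hairpin_id
  hits <- gregexpr(mature_seq, hp_seq, fixed = TRUE)[[1]]
  if (hits[1] == -1L) {
    stop("mature sequence not found in hairpin '", hp_id, "'", call. = FALSE)
  }
  if (length(hits) > 1L) {
    warning("mature sequence occurs ", length(hits), " times in hairpin '",
            hp_id, "'; using the leftmost occurrence", call. = FALSE)
  }
  start <- as.integer(hits[1]) - 1L     # to 0-based
  end <- start + n
  mid <- (start + end) / 2
  arm <- if (mid < nchar(hp_seq) / 2) "5p" else "3p"
  if (is.null(mature_id)) mature_id <- paste0(hp_id, "-mature")
  data.frame(mature_id = mature_id, hairpin_id = hp_id,
             start = start, end = as.integer(end), arm = arm,
             stringsAsFactors = FALSE)
}

#' Bundle hairpins and mature annotations into a reference set
#'
#' Validates the cross-references and interval invariants: every mature
#' annotation must resolve to a loaded hairpin, lie inside it, and have a
#' length in \[15, 30\].
#'
#' @param hairpins Data frame from [read_hairpin_fasta()].
#' @param matures Data frame of mature annotations (as from
#'   [locate_mature()]): `mature_id`, `hairpin_id`, `start`, `end`, `arm`.
#' @return An object of class `reference_set`.
#' @export
reference_set <- function(hairpins, matures) {
  stopifnot(is.data.frame(hairpins), is.data.frame(matures))
  if (anyDuplicated(hairpins$hairpin_id)) {
    stop("duplicate hairpin ids in reference set", call. = FALSE)
  }
  if (anyDuplicated(matures$mature_id)) {
    stop("duplicate mature ids in reference set", call. = FALSE)
  }
  missing <- setdiff(matures$hairpin_id, hairpins$hairpin_id)
  if (length(missing)) {
    stop("mature annotation(s) refer to unknown hairpin(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(matures))) {
    m <- matures[i, ]
    hp <- hairpins$sequence[hairpins$hairpin_id == m$hairpin_id]
    if (!(m$start >= 0 && m$start < m$end && m$end <= nchar(hp))) {
      stop("mature '", m$mature_id, "' interval [", m$start, ", ", m$end,
           ") outside hairpin of length ", nchar(hp), call. = FALSE)
    }
    len <- m$end - m$start
    if (len < 15L || len > 30L) {
      stop("mature '", m$mature_id, "' length ", len,
           " outside [15, 30]", call. = FALSE)
    }
  }
  structure(list(hairpins = hairpins, matures = matures),
            class = "reference_set")
}

#' Build a reference set from hairpin and mature FASTA files
#'
#' The minimal miRBase distribution is a hairpin FASTA plus a mature FASTA
#' with no coordinates. Each mature is located inside the hairpins by exact
#' substring search: the first hairpin (in file order) containing the mature
#' is used, with a warning when several do.
#'
#' @param hairpin_path,mature_path FASTA file paths.
#' @param gff3_path Optional GFF3 file of mature coordinates (attributes
#'   `ID` and `Derives_from`, 1-based inclusive coordinates on the hairpin);
#'   when given it overrides substring search for the matures it covers.
#' @return A `reference_set`.
#' @export
reference_from_fastas <- function(hairpin_path, mature_path,
                                  gff3_path = NULL) {
  hairpins <- read_hairpin_fasta(hairpin_path)
  matures <- read_mature_fasta(mature_path)
  gff <- if (!is.null(gff3_path)) read_mature_gff3(gff3_path) else NULL
  ann <- do.call(rbind, lapply(seq_len(nrow(matures)), function(i) {
    mid <- matures$mature_id[i]
    mseq <- matures$sequence[i]
    if (!is.null(gff) && mid %in% gff$mature_id) {
      g <- gff[gff$mature_id == mid, , drop = FALSE][1, ]
      hp <- hairpins[hairpins$hairpin_id == g$hairpin_id, , drop = FALSE]
      if (nrow(hp) == 0L) {
        stop("GFF3 mature '", mid, "' derives from unknown hairpin '",
             g$hairpin_id, "'", call. = FALSE)
      }
      mid_pt <- (g$start + g$end) / 2
      arm <- if (mid_pt < nchar(hp$sequence) / 2) "5p" else "3p"
      return(data.frame(mature_id = mid, hairpin_id = g$hairpin_id,
                        start = g$start, end = g$end, arm = arm,
                        stringsAsFactors = FALSE))
    }
    holders <- which(vapply(hairpins$sequence, function(h) {
      grepl(mseq, h, fixed = TRUE)
    }, logical(1)))
    if (length(holders) == 0L) {
      stop("mature '", mid, "' not found in any hairpin", call. = FALSE)
    }
    if (length(holders) > 1L) {
      warning("mature '", mid, "' occurs in ", length(holders),
              " hairpins; using '", hairpins$hairpin_id[holders[1]], "'",
              call. = FALSE)
    }
    locate_mature(mseq, hairpins[holders[1], ], mature_id = mid)
  }))
  reference_set(hairpins, ann)
}

#' Read mature coordinates from a GFF3-style file
#'
#' Minimal reader for hairpin-relative mature coordinates: column 1 is the
#' hairpin id (or the attribute `Derives_from` when present), columns 4-5
#' the 1-based inclusive interval, and the attribute `ID` (or `Name`) the
#' mature id. Coordinates are converted to the package's 0-based half-open
#' frame.
#'
#' @param path GFF3 file path.
#' @return Data frame with columns `mature_id`, `hairpin_id`, `start`, `end`.
#' @export
read_mature_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(mature_id = character(), hairpin_id = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 9L)
  if (length(bad)) {
    stop("GFF3 line ", bad[1], " has fewer than 9 tab-separated fields",
         call. = FALSE)
  }
  attr_get <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(paste0("(^|;)", key, "=[^;]+"), attrs))
    if (length(m) == 0L || !nzchar(m)) NA_character_ else sub(paste0("^;?", key, "="), "", m)
  }
  do.call(rbind, lapply(fields, function(f) {
    attrs <- f[[9]]
    mid <- attr_get(attrs, "ID")
    if (is.na(mid)) mid <- attr_get(attrs, "Name")
    if (is.na(mid)) stop("GFF3 record lacks ID/Name attribute", call. = FALSE)
    hp <- attr_get(attrs, "Derives_from")
    if (is.na(hp)) hp <- f[[1]]
    data.frame(mature_id = mid, hairpin_id = hp,
               start = as.integer(f[[4]]) - 1L,  # to 0-based
               end = as.integer(f[[5]]),
               stringsAsFactors = FALSE)
  }))
}

.get_mature <- function(ref, mature_id) {
  i <- match(mature_id, ref$matures$mature_id)
  if (is.na(i)) stop("unknown mature id: ", mature_id, call. = FALSE)
  ref$matures[i, ]
}

.get_hairpin <- function(ref, hairpin_id) {
  i <- match(hairpin_id, ref$hairpins$hairpin_id)
  if (is.na(i)) stop("unknown hairpin id: ", hairpin_id, call. = FALSE)
  ref$hairpins[i, ]
}

#' Mature sequence from a reference set
#'
#' @param ref A `reference_set`.
#' @param mature_id Mature id to look up.
#' @return The mature RNA sequence (the hairpin slice `[start, end)`).
#' @export
mature_sequence <- function(ref, mature_id) {
  m <- .get_mature(ref, mature_id)
  hp <- .get_hairpin(ref, m$hairpin_id)
  substr(hp$sequence, m$start + 1L, m$end)
}

#' Hairpin context downstream of the mature 3' end
#'
#' Returns up to `k` hairpin nucleotides immediately 3' of the mature end —
#' the templated universe for 3' extensions. Shorter than `k` (possibly
#' empty) when the mature abuts the hairpin's 3' terminus.
#'
#' @param ref A `reference_set`.
#' @param mature_id Mature id.
#' @param k Maximum number of bases (>= 0).
#' @return An RNA string of length at most `k`.
#' @export
downstream_context <- function(ref, mature_id, k) {
  stopifnot(k >= 0)
  m <- .get_mature(ref, mature_id)
  hp <- .get_hairpin(ref, m$hairpin_id)
  if (k == 0L) return("")
  substr(hp$sequence, m$end + 1L, min(nchar(hp$sequence), m$end + k))
}

#' @export
print.reference_set <- function(x, ...) {
  cat("reference_set:", nrow(x$hairpins), "hairpin(s),",
      nrow(x$matures), "mature annotation(s)\n")
  for (i in seq_len(nrow(x$matures))) {
    m <- x$matures[i, ]
    cat(sprintf("  %s  %s[%d,%d) arm=%s\n", m$mature_id, m$hairpin_id,
                m$start, m$end, m$arm))
  }
  invisible(x)
}

#' Write a reference summary table
#'
#' Writes one row per mature annotation (`hairpin_id`, `mature_id`, `start`,
#' `end`, `arm`, `mature_seq`) as TSV.
#'
#' @param ref A `reference_set`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_reference_summary <- function(ref, path) {
  df <- ref$matures
  df$mature_seq <- vapply(df$mature_id, function(id) {
    mature_sequence(ref, id)
  }, character(1), USE.NAMES = FALSE)
  df <- df[, c("hairpin_id", "mature_id", "start", "end", "arm", "mature_seq")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
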