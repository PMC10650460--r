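# Cross-sample and cross-species comparison of isomiR profiles.

#' Compare two isomiR profiles for one mature miRNA
#'
#' Descriptive comparison (no inference): the labels shared by both
#' profiles, the per-label counts and RPM side by side, and the top-n rank
#' agreement `|top-n(a) intersect top-n(b)| / n`. Comparison is on RPM-scaled
#' abundance for display, but ranking uses counts with the deterministic
#' tie-break of [rank_isoforms()].
#'
#' @param a,b `isomir_profile` objects.
#' @param mature_id Mature id to compare.
#' @param n Rank depth for the agreement fraction (default 5, the usual
#'   "top five isoforms" comparison).
#' @return An object of class `profile_comparison`: `left_sample`,
#'   `right_sample`, `shared_labels`, `rank_agreement_at_n`, `n`, and a
#'   `table` data frame (`label`, `count_left`, `count_right`, `rpm_left`,
#'   `rpm_right`).
#' @export
compare_profiles <- function(a, b, mature_id, n = 5L) {
  stopifnot(inherits(a, "isomir_profile"), inherits(b, "isomir_profile"),
            n >= 1L)
  ea <- a$entries[a$entries$mature_id == mature_id, , drop = FALSE]
  eb <- b$entries[b$entries$mature_id == mature_id, , drop = FALSE]
  labels <- sort(union(ea$label, eb$label))
  get <- function(e, lab, col) {
    i <- match(lab, e$label)
    ifelse(is.na(i), 0, e[[col]][i])
  }
  tab <- data.frame(
    label = labels,
    count_left = vapply(labels, get, numeric(1), e = ea, col = "count"),
    count_right = vapply(labels, get, numeric(1), e = eb, col = "count"),
    rpm_left = vapply(labels, get, numeric(1), e = ea, col = "rpm"),
    rpm_right = vapply(labels, get, numeric(1), e = eb, col = "rpm"),
    row.names = NULL, stringsAsFactors = FALSE)
  shared <- sort(intersect(ea$label, eb$label))
  top_a <- if (nrow(ea)) rank_isoforms(a, mature_id, n)$label else character()
  top_b <- if (nrow(eb)) rank_isoforms(b, mature_id, n)$label else character()
  agree <- length(intersect(top_a, top_b)) / n
  structure(list(left_sample = a$sample_id, right_sample = b$sample_id,
                 mature_id = mature_id, shared_labels = shared,
                 rank_agreement_at_n = agree, n = as.integer(n),
                 table = tab),
            class = "profile_comparison")
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat(sprintf("profile_comparison: '%s' vs '%s' for %s\n",
              x$left_sample, x$right_sample, x$mature_id))
  cat(sprintf("  shared labels: %d; top-%d rank agreement: %.2f\n",
              length(x$shared_labels), x$n, x$rank_agreement_at_n))
  print(x$table)
  invisible(x)
}

#' Express one species' mature miRNA as an isoform of another's
#'
#' Decomposes `mature_a` as if it were a read against species b's
#' reference, yielding the cross-species isoform relation: e.g. a mature
#' that equals another minus its terminal base is that species' "Trim"
#' isoform of the other, and a mature carrying a 3' base absent from the
#' other's hairpin is its "Plus" isoform. This is [decompose()] applied to
#' a mature sequence, so the two are consistent by construction.
#'
#' @param mature_a RNA sequence of the query mature (15-30 nt).
#' @param hairpin_b Hairpin row of the target species.
#' @param annot_b Mature annotation row of the target species.
#' @param params A [caller_params()] object.
#' @return The `isomir_call`, or the string `"unrelated"` when no
#'   decomposition exists within the parameter limits.
#' @export
relabel_against <- function(mature_a, hairpin_b, annot_b,
                            params = caller_params()) {
  call <- decompose(mature_a, hairpin_b, annot_b, params)
  if (is.null(call)) return("unrelated")
  call
}

#' Write a profile comparison report as TSV
#'
#' @param comparison A `profile_comparison`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_comparison_tsv <- function(comparison, path) {
  tab <- comparison$table
  tab <- cbind(left_sample = comparison$left_sample,
               right_sample = comparison$right_sample,
               mature_id = comparison$mature_id, tab)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
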