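# Downstream gene-set machinery: BH adjustment, fold-change/FDR gene sets,
# miR-vs-isomiR set differences, Venn partitions, 2^(-ddCt) quantification,
# and a naive count test so the synthetic pipeline runs end to end.

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (delegated to
#' [stats::p.adjust()] with `method = "BH"`), with domain validation:
#' every input must lie in \[0, 1\]. Values are returned in input order.
#'
#' @param pvalues Numeric vector of p-values.
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric())
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1] with no NA", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Build up/down regulated gene sets from a differential-expression table
#'
#' A gene is up-regulated when its adjusted p-value passes `alpha` and its
#' fold change is at least `fc_threshold` (down-regulated: at most
#' `1/fc_threshold`). Following the usual printed form of the rule
#' (">= 1.5-fold change with p(adj) < 0.05"), the fold-change comparator is
#' inclusive and the adjusted-p comparator strict; `padj_inclusive = TRUE`
#' switches the latter to `<=`. The fold-change comparison is evaluated on
#' the log2 scale, `log2fc >= log2(fc_threshold)`, so a table row built as
#' `log2fc = log2(1.5)` sits exactly on the inclusive boundary.
#'
#' When a table has no `padj` column (or NA entries), adjusted values are
#' computed from `pvalue` via [bh_adjust()] over the whole table; rows
#' carrying `padj` already (e.g. exported from an external DE tool) are
#' used as-is.
#'
#' @param table Data frame with columns `gene_id`, `log2fc`, and at least
#'   one of `pvalue`, `padj`.
#' @param fc_threshold Linear fold-change threshold (> 1; default 1.5).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param padj_inclusive Use `padj <= alpha` instead of `< alpha`.
#' @return List with character vectors `up` and `down` (disjoint).
#' @export
de_sets <- function(table, fc_threshold = 1.5, alpha = 0.05,
                    padj_inclusive = FALSE) {
  stopifnot(is.data.frame(table), fc_threshold > 1)
  need <- c("gene_id", "log2fc")
  if (!all(need %in% names(table))) {
    stop("table needs columns gene_id and log2fc", call. = FALSE)
  }
  if (anyDuplicated(table$gene_id)) {
    stop("gene_id must be unique within a table", call. = FALSE)
  }
  has_p <- "pvalue" %in% names(table)
  has_q <- "padj" %in% names(table)
  if (!has_p && !has_q) {
    stop("table needs a pvalue or padj column", call. = FALSE)
  }
  padj <- if (has_q) table$padj else rep(NA_real_, nrow(table))
  if (anyNA(padj)) {
    if (!has_p || any(is.na(table$pvalue) & is.na(padj))) {
      stop("row(s) missing both pvalue and padj", call. = FALSE)
    }
    adj <- bh_adjust(table$pvalue)
    padj[is.na(padj)] <- adj[is.na(padj)]
  }
  sig <- if (padj_inclusive) padj <= alpha else padj < alpha
  lfc_cut <- log2(fc_threshold)
  up <- table$gene_id[sig & table$log2fc >= lfc_cut]
  down <- table$gene_id[sig & table$log2fc <= -lfc_cut]
  list(up = up, down = down)
}

#' Three-way difference of a reference gene set against another
#'
#' Splits `ref_set` and `iso_set` into the genes shared by both, those only
#' in the isomiR set, and those only in the reference set — the direct
#' miR-vs-isomiR comparison of regulated genes.
#'
#' @param ref_set,iso_set Character vectors of gene ids.
#' @return List with `shared`, `iso_only`, `ref_only` (an exact partition
#'   of the union).
#' @export
diff_vs_reference <- function(ref_set, iso_set) {
  ref_set <- unique(as.character(ref_set))
  iso_set <- unique(as.character(iso_set))
  list(shared = intersect(ref_set, iso_set),
       iso_only = setdiff(iso_set, ref_set),
       ref_only = setdiff(ref_set, iso_set))
}

#' Venn partition of two or three named gene sets
#'
#' Partitions the union of the input sets into the 2^k - 1 disjoint Venn
#' regions, labelled by the set names (e.g. `"miR only"`,
#' `"miR∩PlusA"`, `"miR∩PlusA∩TrimA"`). Every region label is present,
#' possibly with an empty set.
#'
#' @param named_sets Named list of 2 or 3 character vectors.
#' @return An object of class `gene_set_partition`: list with `sets` (the
#'   named regions) and `universe` (the union).
#' @export
venn_partition <- function(named_sets) {
  k <- length(named_sets)
  if (!(k %in% c(2L, 3L)) || is.null(names(named_sets)) ||
      any(!nzchar(names(named_sets)))) {
    stop("venn_partition supports 2 or 3 named sets", call. = FALSE)
  }
  named_sets <- lapply(named_sets, function(s) unique(as.character(s)))
  universe <- unique(unlist(named_sets, use.names = FALSE))
  nm <- names(named_sets)
  membership <- vapply(named_sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  regions <- list()
  # all nonempty subsets of the k sets, by inclusion pattern
  for (code in seq_len(2^k - 1L)) {
    inset <- as.logical(bitwAnd(code, 2^(seq_len(k) - 1L)))
    label <- if (sum(inset) == 1L) {
      paste(nm[inset], "only")
    } else {
      paste(nm[inset], collapse = "∩")
    }
    if (length(universe) == 0L) {
      regions[[label]] <- character()
    } else {
      match_rows <- apply(membership, 1L, function(row) all(row == inset))
      regions[[label]] <- universe[match_rows]
    }
  }
  structure(list(sets = regions, universe = universe),
            class = "gene_set_partition")
}

#' @export
print.gene_set_partition <- function(x, ...) {
  cat("gene_set_partition over", length(x$universe), "gene(s):\n")
  for (nm in names(x$sets)) {
    cat(sprintf("  %-30s %d\n", nm, length(x$sets[[nm]])))
  }
  invisible(x)
}

#' Write a gene-set partition report as TSV
#'
#' @param partition A `gene_set_partition`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_partition_tsv <- function(partition, path) {
  df <- data.frame(region = names(partition$sets),
                   n_genes = lengths(partition$sets),
                   genes = vapply(partition$sets, paste, character(1),
                                  collapse = ","),
                   row.names = NULL, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Relative quantification by the 2^(-ddCt) method
#'
#' Per-row delta-Ct is `target_ct - ref_ct`; the delta-delta-Ct is the mean
#' treated delta-Ct minus the mean control delta-Ct; the fold change of the
#' target in treated relative to control is `2^(-ddCt)`.
#'
#' @param ct Data frame with columns `sample`, `group` (values `"control"`
#'   and `"treated"`), `target_ct`, `ref_ct`; all Ct values positive and
#'   finite, at least one row per group.
#' @return The fold change (a single number).
#' @export
ddct_fold_change <- function(ct) {
  need <- c("sample", "group", "target_ct", "ref_ct")
  if (!is.data.frame(ct) || !all(need %in% names(ct))) {
    stop("ct table needs columns sample, group, target_ct, ref_ct",
         call. = FALSE)
  }
  if (!all(ct$group %in% c("control", "treated"))) {
    stop("group must be 'control' or 'treated'", call. = FALSE)
  }
  vals <- c(ct$target_ct, ct$ref_ct)
  if (anyNA(vals) || any(!is.finite(vals)) || any(vals <= 0)) {
    stop("Ct values must be positive and finite", call. = FALSE)
  }
  if (!all(c("control", "treated") %in% ct$group)) {
    stop("need at least one control and one treated row", call. = FALSE)
  }
  dct <- ct$target_ct - ct$ref_ct
  ddct <- mean(dct[ct$group == "treated"]) - mean(dct[ct$group == "control"])
  2^(-ddct)
}

#' Read a Ct table from CSV
#'
#' @param path CSV with columns `sample`, `group`, `target_ct`, `ref_ct`.
#' @return The validated data frame.
#' @export
read_ct_csv <- function(path) {
  ct <- utils::read.csv(path, stringsAsFactors = FALSE)
  ddct_fold_change(ct)   # validation side effect
  ct
}

#' Naive per-gene count test (pipeline stand-in)
#'
#' A deliberately simple two-group comparison so the synthetic pipeline can
#' run end to end: per-gene log2 fold change of library-size-normalized
#' (counts-per-million) means, and a two-sided Welch t-test on
#' `log2(CPM + 1)`. This is plumbing, not a negative-binomial
#' differential-expression model — no dispersion estimation, no shrinkage —
#' and should not be used for real inference.
#'
#' Degenerate inputs are resolved deterministically: when both groups have
#' zero within-group variance the p-value is 0 if the group means differ
#' and 1 if they are equal (noise-free simulated counts hit this case).
#' Zero mean counts are offset by 0.5 on the affected side only, so exact
#' ratios between positive means are preserved.
#'
#' @param counts_a,counts_b Numeric matrices (genes x replicates, >= 2
#'   replicates each) with identical rownames; group b is the treatment.
#' @return A data frame of class `de_result` with columns `gene_id`,
#'   `log2fc` (b vs a), `pvalue`, `padj` (BH).
#' @export
naive_count_test <- function(counts_a, counts_b) {
  counts_a <- as.matrix(counts_a); counts_b <- as.matrix(counts_b)
  if (is.null(rownames(counts_a)) || is.null(rownames(counts_b)) ||
      !identical(rownames(counts_a), rownames(counts_b))) {
    stop("count matrices must carry identical gene rownames", call. = FALSE)
  }
  if (ncol(counts_a) < 2L || ncol(counts_b) < 2L) {
    stop("need >= 2 replicates per group", call. = FALSE)
  }
  cpm <- function(m) sweep(m, 2L, colSums(m) / 1e6, "/")
  ca <- cpm(counts_a); cb <- cpm(counts_b)
  ma <- rowMeans(ca); mb <- rowMeans(cb)
  log2fc <- ifelse(ma > 0 & mb > 0, log2(mb / ma),
                   log2((mb + 0.5) / (ma + 0.5)))
  la <- log2(ca + 1); lb <- log2(cb + 1)
  pvalue <- vapply(seq_len(nrow(ca)), function(i) {
    xa <- la[i, ]; xb <- lb[i, ]
    if (stats::var(xa) == 0 && stats::var(xb) == 0) {
      return(if (isTRUE(all.equal(mean(xa), mean(xb)))) 1 else 0)
    }
    tryCatch(stats::t.test(xa, xb)$p.value, error = function(e) NA_real_)
  }, numeric(1))
  pvalue[is.na(pvalue)] <- 1
  out <- data.frame(gene_id = rownames(counts_a), log2fc = log2fc,
                    pvalue = pvalue, padj = bh_adjust(pvalue),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Read a differential-expression result table from TSV
#'
#' @param path TSV with columns `gene_id`, `log2fc` and at least one of
#'   `pvalue`, `padj`.
#' @return Data frame of class `de_result`.
#' @export
read_de_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "log2fc") %in% names(df)) ||
      !any(c("pvalue", "padj") %in% names(df))) {
    stop("DE table needs gene_id, log2fc and pvalue and/or padj",
         call. = FALSE)
  }
  class(df) <- c("de_result", "data.frame")
  df
}
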