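# Synthetic data: seeded generators for references, isomiR-bearing reads
# with a known generative distribution, and negative-binomial count
# matrices with planted differential gene sets.

.sim_default_proportions <- function() {
  c("canonical" = 0.30, "Trim A" = 0.25, "Plus A" = 0.15,
    "Trim AG" = 0.12, "Trim AGU" = 0.10, "Ext+1" = 0.08)
}

#' Configuration for synthetic small-RNA reads
#'
#' The defaults emulate a deeply sequenced miRNA locus whose isoform
#' repertoire matches the commonly observed 3' vocabulary (canonical,
#' non-templated +A, and 1-3 nt 3' trims, with trimmed forms rivalling the
#' canonical in abundance), plus a minor templated extension class.
#' Supported class labels: `"canonical"`, `"Plus <bases>"`,
#' `"Trim <bases>"` (bases listed from the 3' terminus inward, 1-3 nt),
#' `"Ext+<n>"`, `"5p+1"`, `"5p-1"`, `"sub"`.
#'
#' @param seed Integer seed fixing all randomness.
#' @param n_reads Number of reads to generate (default 10000).
#' @param isomir_proportions Named probability vector over class labels;
#'   must sum to 1 (tolerance 1e-9).
#' @param seq_error_rate Per-base substitution error probability
#'   (default 0: substitution-only error model, no indels).
#' @param phred_mean,phred_sd Phred quality distribution (truncated normal,
#'   clamped to \[2, 41\]; defaults 35 and 3).
#' @param mature_len Mature length (default 22, in \[20, 24\]).
#' @param flank5,flank3 Hairpin flank lengths around the mature (>= 3 each;
#'   defaults 8); the 3' flank is the templated-extension context.
#' @param mature_3p_end Forced 3' suffix of the simulated mature (default
#'   `"UGA"`), so trim classes have well-defined removed-base names.
#' @param tail_nt Non-templated tail nucleotide (default `"A"`); the
#'   reference generator guarantees the hairpin base 3'-adjacent to the
#'   mature differs from it, making `Plus <tail_nt>` non-templated by
#'   construction.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_reads = 10000L,
                       isomir_proportions = .sim_default_proportions(),
                       seq_error_rate = 0, phred_mean = 35, phred_sd = 3,
                       mature_len = 22L, flank5 = 8L, flank3 = 8L,
                       mature_3p_end = "UGA", tail_nt = "A") {
  if (abs(sum(isomir_proportions) - 1) > 1e-9) {
    stop("isomir_proportions must sum to 1", call. = FALSE)
  }
  if (any(isomir_proportions < 0)) {
    stop("isomir_proportions must be >= 0", call. = FALSE)
  }
  if (is.null(names(isomir_proportions)) ||
      any(!nzchar(names(isomir_proportions)))) {
    stop("isomir_proportions must be named by class label", call. = FALSE)
  }
  if (mature_len < 20L || mature_len > 24L) {
    stop("mature_len must be in [20, 24]", call. = FALSE)
  }
  if (flank5 < 3L || flank3 < 3L) {
    stop("flank5 and flank3 must be >= 3 (templated context required)",
         call. = FALSE)
  }
  if (seq_error_rate < 0 || seq_error_rate > 1) {
    stop("seq_error_rate must be in [0, 1]", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_reads = as.integer(n_reads),
                 isomir_proportions = isomir_proportions,
                 seq_error_rate = seq_error_rate, phred_mean = phred_mean,
                 phred_sd = phred_sd, mature_len = as.integer(mature_len),
                 flank5 = as.integer(flank5), flank3 = as.integer(flank3),
                 mature_3p_end = .normalize_rna(mature_3p_end, "mature_3p_end"),
                 tail_nt = .normalize_rna(tail_nt, "tail_nt")),
            class = "sim_config")
}

#' Generate a random hairpin reference with an annotated mature
#'
#' Hairpin = 5' flank + mature + 3' flank, all uniform over A/C/G/U,
#' reproducible under the config seed. The mature's 3' suffix is forced to
#' `config$mature_3p_end` and the hairpin base immediately 3' of the mature
#' is guaranteed to differ from `config$tail_nt`, so a `Plus <tail_nt>`
#' read is non-templated by construction. No secondary structure is
#' modelled: the caller uses only sequence and coordinates.
#'
#' @param config A [sim_config()] object.
#' @return A `reference_set` with one hairpin (`sim-hairpin-1`) and one
#'   mature annotation (`sim-mir-1`).
#' @export
make_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  draw <- function(n) paste(sample(.RNA_ALPHABET, n, replace = TRUE),
                            collapse = "")
  suffix <- config$mature_3p_end
  mature <- paste0(draw(config$mature_len - nchar(suffix)), suffix)
  flank5 <- draw(config$flank5)
  # first context base must differ from the tail nucleotide
  first_ctx <- sample(setdiff(.RNA_ALPHABET, config$tail_nt), 1L)
  flank3 <- paste0(first_ctx, draw(config$flank3 - 1L))
  hairpin <- paste0(flank5, mature, flank3)
  hairpins <- data.frame(hairpin_id = "sim-hairpin-1", sequence = hairpin,
                         species_tag = "sim", stringsAsFactors = FALSE)
  ann <- locate_mature(mature, hairpins[1, ], mature_id = "sim-mir-1")
  reference_set(hairpins, ann)
}

# Build the exact (error-free) read for one class label.
.class_sequence <- function(class, mature, ctx, prev5) {
  L <- nchar(mature)
  if (class == "canonical") return(mature)
  if (grepl("^Plus ", class)) {
    return(paste0(mature, sub("^Plus ", "", class)))
  }
  if (grepl("^Trim ", class)) {
    bases <- sub("^Trim ", "", class)
    k <- nchar(bases)
    if (k < 1L || k > 3L) stop("Trim class must remove 1-3 bases", call. = FALSE)
    removed <- paste(rev(strsplit(substr(mature, L - k + 1L, L), "",
                                  fixed = TRUE)[[1]]), collapse = "")
    if (removed != bases) {
      stop("Trim class '", class, "' inconsistent with mature 3' end (",
           removed, ")", call. = FALSE)
    }
    return(substr(mature, 1L, L - k))
  }
  if (grepl("^Ext\\+", class)) {
    n <- as.integer(sub("^Ext\\+", "", class))
    if (n < 1L || n > nchar(ctx)) {
      stop("Ext class exceeds templated context", call. = FALSE)
    }
    return(paste0(mature, substr(ctx, 1L, n)))
  }
  if (class == "5p+1") return(substr(mature, 2L, L))
  if (class == "5p-1") {
    if (!nzchar(prev5)) stop("5p-1 class needs a 5' flank", call. = FALSE)
    return(paste0(prev5, mature))
  }
  if (class == "sub") return(NA_character_)   # handled by caller (random)
  stop("unknown simulation class: ", class, call. = FALSE)
}

#' Simulate isomiR-bearing reads with a known truth table
#'
#' Each read's class is drawn from `isomir_proportions`; the exact class
#' sequence is built from the reference; per-base substitution errors are
#' applied at `seq_error_rate`; Phred qualities are drawn from a truncated
#' normal clamped to \[2, 41\]. The `"sub"` class plants one random
#' substitution at a mature position outside the default core anchor
#' region (position 1 or positions 19+, 0-based).
#'
#' @param config A [sim_config()] object.
#' @param ref The `reference_set` from [make_reference()] (regenerated from
#'   the config when omitted).
#' @return A list: `reads` (data frame `read_id`, `sequence`, `quality`
#'   list column) and `truth` (data frame `read_id`, `class`, `label` —
#'   the label [decompose()] assigns to the error-free class sequence —
#'   and `n_errors`).
#' @export
sample_reads <- function(config, ref = make_reference(config)) {
  stopifnot(inherits(config, "sim_config"), inherits(ref, "reference_set"))
  mature <- mature_sequence(ref, ref$matures$mature_id[1])
  ctx <- downstream_context(ref, ref$matures$mature_id[1], 10L)
  m <- ref$matures[1, ]
  hp <- .get_hairpin(ref, m$hairpin_id)
  prev5 <- if (m$start > 0L) substr(hp$sequence, m$start, m$start) else ""
  L <- nchar(mature)
  set.seed(config$seed + 1L)
  classes <- sample(names(config$isomir_proportions), config$n_reads,
                    replace = TRUE, prob = config$isomir_proportions)
  # precompute class sequences and their error-free labels
  uniq <- unique(classes)
  base_seq <- vapply(uniq, .class_sequence, character(1), mature = mature,
                     ctx = ctx, prev5 = prev5)
  names(base_seq) <- uniq
  params <- caller_params()
  base_label <- vapply(uniq, function(cl) {
    if (cl == "sub") return(NA_character_)
    call <- decompose(base_seq[[cl]], hp, m, params)
    if (is.null(call)) NA_character_ else call$label
  }, character(1))
  names(base_label) <- uniq
  sub_positions <- c(1L, seq.int(19L, L))    # 1-based, outside default core
  n <- config$n_reads
  seqs <- character(n)
  labels <- character(n)
  n_err <- integer(n)
  for (i in seq_len(n)) {
    cl <- classes[i]
    if (cl == "sub") {
      pos <- sample(sub_positions, 1L)
      refb <- substr(mature, pos, pos)
      alt <- sample(setdiff(.RNA_ALPHABET, refb), 1L)
      s <- mature
      substr(s, pos, pos) <- alt
      labels[i] <- sprintf("canonical;sub%d%s>%s", pos, refb, alt)
    } else {
      s <- base_seq[[cl]]
      labels[i] <- base_label[[cl]]
    }
    if (config$seq_error_rate > 0) {
      chars <- strsplit(s, "", fixed = TRUE)[[1]]
      hit <- which(stats::runif(length(chars)) < config$seq_error_rate)
      for (j in hit) {
        chars[j] <- sample(setdiff(.RNA_ALPHABET, chars[j]), 1L)
      }
      n_err[i] <- length(hit)
      if (length(hit)) s <- paste(chars, collapse = "")
    }
    seqs[i] <- s
  }
  lens <- nchar(seqs)
  quality <- lapply(lens, function(l) {
    q <- as.integer(round(stats::rnorm(l, config$phred_mean, config$phred_sd)))
    pmin(pmax(q, 2L), 41L)
  })
  ids <- sprintf("simread%06d", seq_len(n))
  list(reads = data.frame(read_id = ids, sequence = seqs,
                          quality = I(quality), stringsAsFactors = FALSE),
       truth = data.frame(read_id = ids, class = classes, label = labels,
                          n_errors = n_err, stringsAsFactors = FALSE))
}

#' Write reads as Phred+33 FASTQ
#'
#' Sequences are written in the DNA alphabet (`U` to `T`), so the file
#' round-trips through [read_fastq()].
#'
#' @param reads Data frame with `read_id`, `sequence`, `quality`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual_str <- vapply(reads$quality, function(q) {
    intToUtf8(as.integer(q) + 33L)
  }, character(1))
  lines <- as.vector(rbind(paste0("@", reads$read_id),
                           chartr("U", "T", reads$sequence),
                           "+", qual_str))
  writeLines(lines, path)
  invisible(path)
}

#' Default planted differential-expression design
#'
#' Emulates a concordance structure across five treatments against a mimic
#' control: three concordant treatments (`miR`, `PlusA`, `TrimA`) share a
#' large core of regulated genes with small private sets, while two
#' divergent treatments (`TrimAG`, `TrimAGU`) share a separate block that
#' barely overlaps the concordant trio.
#'
#' @param n_genes Size of the gene universe (ids `g000001`...).
#' @return Named list (one element per treatment) of lists with `up` and
#'   `down` character vectors.
#' @export
default_planted_design <- function(n_genes = 2000L) {
  if (n_genes < 1000L) stop("need >= 1000 genes for the default design",
                            call. = FALSE)
  ids <- sprintf("g%06d", seq_len(n_genes))
  cursor <- 0L
  take <- function(k) {
    out <- ids[(cursor + 1L):(cursor + k)]
    cursor <<- cursor + k
    out
  }
  trio_down <- take(120L); trio_up <- take(90L)
  priv_down <- lapply(1:3, function(i) take(15L))
  priv_up <- lapply(1:3, function(i) take(10L))
  bridge_down <- take(10L)                 # shared by all five treatments
  pair_down <- c(take(170L), bridge_down)
  pair_up <- take(140L)
  pair_priv_down <- lapply(1:2, function(i) take(40L))
  pair_priv_up <- lapply(1:2, function(i) take(30L))
  trio_down <- c(trio_down, bridge_down)
  list(
    miR = list(up = c(trio_up, priv_up[[1]]),
               down = c(trio_down, priv_down[[1]])),
    PlusA = list(up = c(trio_up, priv_up[[2]]),
                 down = c(trio_down, priv_down[[2]])),
    TrimA = list(up = c(trio_up, priv_up[[3]]),
                 down = c(trio_down, priv_down[[3]])),
    TrimAG = list(up = c(pair_up, pair_priv_up[[1]]),
                  down = c(pair_down, pair_priv_down[[1]])),
    TrimAGU = list(up = c(pair_up, pair_priv_up[[2]]),
                   down = c(pair_down, pair_priv_down[[2]]))
  )
}

#' Configuration for synthetic count matrices
#'
#' @param seed Integer seed.
#' @param n_genes Gene universe size (default 2000).
#' @param n_replicates Replicates per group (default 3, the usual
#'   triplicate design).
#' @param groups Treatment labels; the first is the control
#'   (default `MC`, `miR`, `PlusA`, `TrimA`, `TrimAG`, `TrimAGU`).
#' @param planted_sets Named list (per non-control group) of `up`/`down`
#'   gene-id vectors; defaults to [default_planted_design()].
#' @param baseline_mean Mean baseline expression (default 100).
#' @param dispersion Negative-binomial dispersion; 0 gives deterministic
#'   (noise-free) counts (default 0.05).
#' @param lfc_magnitude Planted |log2 fold change| (default 2).
#' @return An object of class `count_sim_config`.
#' @export
count_sim_config <- function(seed = 1L, n_genes = 2000L, n_replicates = 3L,
                             groups = c("MC", "miR", "PlusA", "TrimA",
                                        "TrimAG", "TrimAGU"),
                             planted_sets = NULL, baseline_mean = 100,
                             dispersion = 0.05, lfc_magnitude = 2) {
  if (length(groups) < 2L) stop("need a control plus >= 1 treatment",
                                call. = FALSE)
  if (is.null(planted_sets)) planted_sets <- default_planted_design(n_genes)
  ids <- sprintf("g%06d", seq_len(n_genes))
  treatments <- groups[-1]
  if (!all(names(planted_sets) %in% treatments)) {
    stop("planted_sets names must be treatment groups", call. = FALSE)
  }
  for (nm in names(planted_sets)) {
    s <- planted_sets[[nm]]
    if (!all(c(s$up, s$down) %in% ids)) {
      stop("planted genes for '", nm, "' outside the gene universe",
           call. = FALSE)
    }
    if (length(intersect(s$up, s$down))) {
      stop("planted up and down sets overlap for '", nm, "'", call. = FALSE)
    }
  }
  if (dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  if (n_replicates < 2L) stop("need >= 2 replicates per group", call. = FALSE)
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 n_replicates = as.integer(n_replicates), groups = groups,
                 planted_sets = planted_sets, baseline_mean = baseline_mean,
                 dispersion = dispersion, lfc_magnitude = lfc_magnitude,
                 gene_ids = ids),
            class = "count_sim_config")
}

#' Simulate count matrices with planted differential gene sets
#'
#' Per-gene baseline means are drawn once (log-normal around
#' `baseline_mean`) and shared by all groups; planted genes' means are
#' scaled by `2^lfc_magnitude` (up) or `2^-lfc_magnitude` (down) in their
#' treatment groups. Counts are negative-binomial with the configured
#' dispersion; at `dispersion = 0` counts are the rounded means
#' (deterministic, for exact-recovery checks).
#'
#' @param config A [count_sim_config()] object.
#' @return List with `counts` (genes x samples matrix, columns named
#'   `<group>_<replicate>`), `group` (factor of column groups), `truth`
#'   (the planted sets) and `config`.
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "count_sim_config"))
  set.seed(config$seed + 2L)
  ng <- config$n_genes
  base_mu <- stats::rlnorm(ng, meanlog = log(config$baseline_mean),
                           sdlog = 0.5)
  groups <- config$groups
  reps <- config$n_replicates
  cols <- as.vector(vapply(groups, function(g) paste0(g, "_", seq_len(reps)),
                           character(reps)))
  counts <- matrix(0, nrow = ng, ncol = length(cols),
                   dimnames = list(config$gene_ids, cols))
  group_vec <- factor(rep(groups, each = reps), levels = groups)
  fc <- 2^config$lfc_magnitude
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    mu <- base_mu
    s <- config$planted_sets[[g]]
    if (!is.null(s)) {
      mu[match(s$up, config$gene_ids)] <- mu[match(s$up, config$gene_ids)] * fc
      mu[match(s$down, config$gene_ids)] <-
        mu[match(s$down, config$gene_ids)] / fc
    }
    for (r in seq_len(reps)) {
      j <- (gi - 1L) * reps + r
      counts[, j] <- if (config$dispersion == 0) {
        round(mu)
      } else {
        stats::rnbinom(ng, size = 1 / config$dispersion, mu = mu)
      }
    }
  }
  list(counts = counts, group = group_vec, truth = config$planted_sets,
       config = config)
}

#' Write a count matrix as TSV
#'
#' @param sim Result of [simulate_counts()] (or any matrix).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_counts_tsv <- function(sim, path) {
  m <- if (is.list(sim)) sim$counts else sim
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
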