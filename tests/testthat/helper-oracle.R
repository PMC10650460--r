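# Independent oracles and small generators shared across tests.
#
# The decomposition oracle enumerates EVERY candidate decomposition within
# the parameter limits by brute force (all 5' shifts, all templated/
# non-templated splits of the 3' overhang) and picks the minimum under the
# ordering (score, |shift5|, |tail|, mature_id, signed shift5). It shares
# no code with decompose().

oracle_rna <- c("A", "C", "G", "U")

# All candidate decompositions of `seq` against one (hairpin, annot).
oracle_candidates <- function(seq, hp_seq, mature_id, s, e, params) {
  sc <- strsplit(seq, "", fixed = TRUE)[[1]]
  hc <- strsplit(hp_seq, "", fixed = TRUE)[[1]]
  len <- length(sc)
  L <- length(hc)
  core_lo <- s + params$core_start
  core_hi <- s + min(params$core_end, e - s)
  out <- list()
  for (sh in seq.int(-params$max_5p_shift, params$max_5p_shift)) {
    a <- s + sh
    if (a < 0) next
    p_end <- a + len
    if (min(p_end, e) - a <= 0) next
    # substitution positions of the read prefix aligned to [a, a + n),
    # or NULL when the span breaks the core or the mismatch budget
    span_mis <- function(n) {
      n <- min(n, L - a)
      if (n <= 0) return(integer(0))
      mis <- which(hc[(a + 1):(a + n)] != sc[1:n])
      hp_pos <- a + mis - 1
      if (any(hp_pos >= core_lo & hp_pos < core_hi)) return(NULL)
      if (length(mis) > params$max_mismatch) return(NULL)
      mis
    }
    add <- function(trim3, ext3, tail, subs_idx) {
      score <- abs(sh) + trim3 + ext3 + nchar(tail) + length(subs_idx)
      out[[length(out) + 1]] <<- list(
        shift5 = sh, trim3 = trim3, ext3 = ext3, tail = tail,
        n_sub = length(subs_idx), sub_pos = subs_idx,
        mature_id = mature_id, score = score)
    }
    subs <- span_mis(min(p_end, e) - a)
    if (!is.null(subs)) {
      if (p_end <= e) {
        trim3 <- e - p_end
        if (trim3 <= params$max_3p_trim) add(trim3, 0L, "", subs)
      } else {
        over <- substr(seq, (e - a) + 1, len)
        ctx <- if (e < L) paste(hc[(e + 1):L], collapse = "") else ""
        m <- nchar(over)
        for (k in 0:min(m, nchar(ctx), params$max_3p_ext)) {
          if (k > 0 && substr(over, 1, k) != substr(ctx, 1, k)) next
          tail <- substr(over, k + 1, m)
          if (nchar(tail) > params$max_3p_ext) next
          add(0L, as.integer(k), tail, subs)
        }
      }
    }
    if (params$allow_mixed_trim_tail) {
      for (t in seq_len(params$max_3p_trim)) {
        m <- t - (e - p_end)
        if (m < 1 || m > len - 1 || m > params$max_3p_ext) next
        cut <- e - t
        if (cut < core_hi) next
        n2 <- cut - a
        if (n2 <= 0) next
        tail <- substr(seq, len - m + 1, len)
        if (cut < L && hc[cut + 1] == substr(tail, 1, 1)) next
        mis2 <- span_mis(n2)
        if (is.null(mis2)) next
        add(t, 0L, tail, mis2)
      }
    }
  }
  out
}

# Minimum-candidate selection under the stated tie-break.
oracle_best <- function(cands) {
  if (length(cands) == 0) return(NULL)
  keys <- lapply(cands, function(c) {
    list(c$score, abs(c$shift5), nchar(c$tail), c$mature_id, c$shift5)
  })
  best <- 1
  for (i in seq_along(cands)[-1]) {
    a <- keys[[i]]; b <- keys[[best]]
    for (j in seq_along(a)) {
      if (a[[j]] < b[[j]]) { best <- i; break }
      if (a[[j]] > b[[j]]) break
    }
  }
  cands[[best]]
}

oracle_decompose <- function(seq, hairpin, annot, params) {
  oracle_best(oracle_candidates(seq, hairpin$sequence, annot$mature_id,
                                annot$start, annot$end, params))
}

# Brute-force Benjamini-Hochberg step-up: sort ascending, q_i = p_i * n / i,
# monotonize from the largest down, cap at 1, restore input order.
oracle_bh <- function(p) {
  n <- length(p)
  if (n == 0) return(numeric())
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  if (n > 1) {
    for (i in (n - 1):1) q[i] <- min(q[i], q[i + 1])
  }
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# Toy reference used throughout: 22-nt mature inside a 31-nt hairpin.
toy_reference <- function() {
  M <- "UCCCUGAGACCCUAACUUGUGA"
  hp <- data.frame(hairpin_id = "h1",
                   sequence = paste0("CGUA", M, "GCUAG"),
                   species_tag = "toy", stringsAsFactors = FALSE)
  ann <- locate_mature(M, hp[1, ], mature_id = "m1")
  list(mature = M, hairpins = hp, annot = ann,
       ref = reference_set(hp, ann))
}

# Random reference + read pair generator for oracle-equivalence checks.
# Mixes planted-class reads, perturbed reads and fully random reads.
random_ref_read <- function() {
  cfg <- sim_config(
    seed = sample.int(1e6, 1), n_reads = 1L,
    mature_len = sample(20:24, 1),
    flank5 = sample(3:12, 1), flank3 = sample(3:12, 1))
  ref <- make_reference(cfg)
  hp <- ref$hairpins[1, ]
  ann <- ref$matures[1, ]
  mature <- mature_sequence(ref, ann$mature_id)
  L <- nchar(mature)
  kind <- sample(c("class", "perturbed", "random"), 1,
                 prob = c(0.4, 0.4, 0.2))
  seq <- if (kind == "random") {
    paste(sample(oracle_rna, sample(15:30, 1), replace = TRUE),
          collapse = "")
  } else {
    s <- mature
    # 3' edit
    op <- sample(c("none", "trim", "ext", "tail"), 1)
    if (op == "trim") {
      s <- substr(s, 1, L - sample(1:6, 1))
    } else if (op == "ext") {
      ctx <- downstream_context(ref, ann$mature_id, 6L)
      k <- sample(seq_len(nchar(ctx)), 1)
      s <- paste0(s, substr(ctx, 1, k))
    } else if (op == "tail") {
      s <- paste0(s, paste(sample(oracle_rna, sample(1:6, 1),
                                  replace = TRUE), collapse = ""))
    }
    # 5' edit
    sh <- sample(-3:3, 1)
    if (sh > 0) {
      s <- substr(s, sh + 1, nchar(s))
    } else if (sh < 0) {
      pre <- substr(hp$sequence, ann$start + sh + 1, ann$start)
      s <- paste0(pre, s)
    }
    if (kind == "perturbed" && nchar(s) > 0) {
      # up to 2 random substitutions anywhere, core included
      for (i in seq_len(sample(0:2, 1))) {
        pos <- sample(nchar(s), 1)
        substr(s, pos, pos) <- sample(oracle_rna, 1)
      }
    }
    s
  }
  n <- nchar(seq)
  if (n < 15) seq <- paste0(seq, paste(sample(oracle_rna, 15 - n,
                                              replace = TRUE), collapse = ""))
  if (nchar(seq) > 30) seq <- substr(seq, 1, 30)
  list(ref = ref, hairpin = hp, annot = ann, seq = seq)
}

# Field-wise comparison of an isomir_call with an oracle candidate.
expect_same_call <- function(call, oracle) {
  if (is.null(oracle)) {
    expect_null(call)
    return(invisible())
  }
  expect_false(is.null(call))
  expect_identical(call$shift5, as.integer(oracle$shift5))
  expect_identical(call$trim3, as.integer(oracle$trim3))
  expect_identical(call$ext3, as.integer(oracle$ext3))
  expect_identical(call$tail, oracle$tail)
  expect_identical(call$n_sub, as.integer(oracle$n_sub))
}

# Strip substitution parts from a caller label, leaving the 5'/3' structure.
structural_label <- function(label) {
  parts <- strsplit(label, ";", fixed = TRUE)[[1]]
  parts <- parts[!grepl("^sub", parts)]
  if (length(parts) == 0) "canonical" else paste(parts, collapse = ";")
}
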