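# Anchored decomposition, labelling, reconstruction and per-sample profiles.

test_that("the canonical read and the four 3' isoforms decompose correctly", {
  toy <- toy_reference()
  p <- caller_params()
  M <- toy$mature

  canon <- decompose(M, toy$hairpins[1, ], toy$annot, p)
  expect_identical(canon$label, "canonical")
  expect_identical(canon$score, 0L)

  # +A where the next hairpin base is G: non-templated tail
  plus_a <- decompose(paste0(M, "A"), toy$hairpins[1, ], toy$annot, p)
  expect_identical(plus_a$label, "Plus A")
  expect_identical(plus_a$ext3, 0L)
  expect_identical(plus_a$tail, "A")

  # +G where the next hairpin base is G: templated extension
  ext <- decompose(paste0(M, "G"), toy$hairpins[1, ], toy$annot, p)
  expect_identical(ext$label, "Ext+1")
  expect_identical(ext$ext3, 1L)
  expect_identical(ext$tail, "")

  # 3' trims named by the removed bases, terminus inward (mature ends ...UGA)
  expect_identical(decompose(substr(M, 1, 21), toy$hairpins[1, ],
                             toy$annot, p)$label, "Trim A")
  expect_identical(decompose(substr(M, 1, 20), toy$hairpins[1, ],
                             toy$annot, p)$label, "Trim AG")
  expect_identical(decompose(substr(M, 1, 19), toy$hairpins[1, ],
                             toy$annot, p)$label, "Trim AGU")
})

test_that("Plus A and templated extension are confirmed by enumeration", {
  toy <- toy_reference()
  p <- caller_params()
  # +A: the enumeration has a unique minimum-edit decomposition
  plus_seq <- paste0(toy$mature, "A")
  cands <- oracle_candidates(plus_seq, toy$hairpins$sequence, "m1",
                             toy$annot$start, toy$annot$end, p)
  scores <- sort(vapply(cands, `[[`, numeric(1), "score"))
  expect_true(length(scores) == 1 || scores[2] > scores[1])
  expect_same_call(decompose(plus_seq, toy$hairpins[1, ], toy$annot, p),
                   oracle_best(cands))

  # +G: templated split (ext 1, empty tail) ties with a pure-tail reading
  # on edit count; the smaller-tail tie-break picks the templated one
  ext_seq <- paste0(toy$mature, "G")
  cands_g <- oracle_candidates(ext_seq, toy$hairpins$sequence, "m1",
                               toy$annot$start, toy$annot$end, p)
  min_score <- min(vapply(cands_g, `[[`, numeric(1), "score"))
  tied <- Filter(function(c) c$score == min_score, cands_g)
  expect_identical(length(tied), 2L)
  best_g <- oracle_best(cands_g)
  expect_identical(best_g$ext3, 1L)
  expect_identical(best_g$tail, "")
  expect_same_call(decompose(ext_seq, toy$hairpins[1, ], toy$annot, p),
                   best_g)
})

test_that("5' variants and substitutions are labelled in 5',3',sub order", {
  toy <- toy_reference()
  p <- caller_params()
  M <- toy$mature

  p5 <- decompose(substr(M, 2, 22), toy$hairpins[1, ], toy$annot, p)
  expect_identical(p5$label, "5p+1")
  expect_identical(p5$shift5, 1L)

  pre <- substr(toy$hairpins$sequence, 4, 4)   # base 5' of the mature
  m5 <- decompose(paste0(pre, M), toy$hairpins[1, ], toy$annot, p)
  expect_identical(m5$label, "5p-1")
  expect_identical(m5$shift5, -1L)

  # substitution outside the core anchor (read position 20, 0-based 19)
  sub_seq <- M
  substr(sub_seq, 20, 20) <- "C"   # U -> C
  sub_call <- decompose(sub_seq, toy$hairpins[1, ], toy$annot, p)
  expect_identical(sub_call$label, "canonical;sub20U>C")

  # compound: 5' trim + 3' trim + substitution
  comp_seq <- substr(M, 2, 21)
  substr(comp_seq, 18, 18) <- "A"  # mature position 19 (0-based 18), G -> A
  comp <- decompose(comp_seq, toy$hairpins[1, ], toy$annot, p)
  expect_identical(comp$label, "5p+1;Trim A;sub18G>A")
})

test_that("seed-region mismatches are never absorbed as substitutions", {
  toy <- toy_reference()
  p <- caller_params()
  seed_seq <- toy$mature
  substr(seed_seq, 3, 3) <- "A"    # mature position 3 (0-based 2): core
  expect_null(decompose(seed_seq, toy$hairpins[1, ], toy$annot, p))
})

test_that("reads outside the length window are a precondition error", {
  toy <- toy_reference()
  expect_error(decompose("ACGUACGUACGUAC", toy$hairpins[1, ], toy$annot),
               "\\[15, 30\\]")
})

test_that("reconstruct is the exact inverse on calls and rejects bad fields", {
  toy <- toy_reference()
  p <- caller_params()
  M <- toy$mature
  seqs <- c(M, paste0(M, "A"), paste0(M, "G"), substr(M, 1, 20),
            substr(M, 2, 22))
  for (s in seqs) {
    call <- decompose(s, toy$hairpins[1, ], toy$annot, p)
    expect_identical(reconstruct(call, toy$ref), s)
  }

  # trim3 = 2 on a mature ending ...GUGA ends ...GU
  tr <- decompose(substr(M, 1, 20), toy$hairpins[1, ], toy$annot, p)
  expect_identical(substr(reconstruct(tr, toy$ref), 19, 20), "GU")

  # a substitution call differs from the mature at exactly one position
  sub_seq <- M
  substr(sub_seq, 20, 20) <- "C"
  rebuilt <- reconstruct(decompose(sub_seq, toy$hairpins[1, ], toy$annot, p),
                         toy$ref)
  diffs <- sum(strsplit(rebuilt, "")[[1]] != strsplit(M, "")[[1]])
  expect_identical(diffs, 1L)

  bad <- decompose(M, toy$hairpins[1, ], toy$annot, p)
  bad$trim3 <- 1L
  bad$ext3 <- 1L
  expect_error(reconstruct(bad, toy$ref), "both trim3 and ext3")
})

test_that("no produced tail starts with the next templated base", {
  set.seed(23)
  p <- caller_params()
  for (i in 1:150) {
    pair <- random_ref_read()
    call <- decompose(pair$seq, pair$hairpin, pair$annot, p)
    if (is.null(call) || !nzchar(call$tail)) next
    ctx <- downstream_context(pair$ref, pair$annot$mature_id,
                              call$ext3 + 1L)
    next_base <- if (nchar(ctx) > call$ext3) {
      substr(ctx, call$ext3 + 1L, call$ext3 + 1L)
    } else ""
    if (call$ext3 < p$max_3p_ext && nzchar(next_base)) {
      expect_false(substr(call$tail, 1, 1) == next_base)
    }
  }
})

test_that("mixed trim-plus-tail calls are off by default and flag-gated", {
  toy <- toy_reference()
  M <- toy$mature
  # trim 2 then a 2-nt non-templated tail; as substitutions this needs 2
  # mismatches, above the default budget
  mixed_seq <- paste0(substr(M, 1, 20), "CC")   # replaces terminal GA
  expect_null(decompose(mixed_seq, toy$hairpins[1, ], toy$annot,
                        caller_params()))
  # with a zero mismatch budget the only valid reading is trim-then-tail
  call <- decompose(mixed_seq, toy$hairpins[1, ], toy$annot,
                    caller_params(max_mismatch = 0,
                                  allow_mixed_trim_tail = TRUE))
  expect_identical(call$trim3, 2L)
  expect_identical(call$tail, "CC")
  expect_identical(call$label, "Trim AG;Plus CC")
  expect_identical(reconstruct(call, toy$ref), mixed_seq)
})

test_that("caller params validate limits and the seed-in-core rule", {
  expect_error(caller_params(max_3p_trim = -1), ">= 0")
  expect_error(caller_params(core_start = 3), "seed")
  expect_error(caller_params(core_end = 6), "seed")
  expect_silent(caller_params(core_start = 0, core_end = 8))
})

test_that("call_sample conserves reads, normalizes RPM and is order-invariant", {
  toy <- toy_reference()
  p <- caller_params()
  M <- toy$mature
  reads <- c(rep(M, 900), rep(paste0(M, "A"), 100))
  prof <- call_sample(collapse_reads(reads), toy$ref, p, "s1")
  expect_identical(prof$total_assigned, 1000L)
  expect_identical(prof$total_unassigned, 0L)
  e <- prof$entries
  expect_identical(e$count[e$label == "canonical"], 900L)
  expect_identical(e$count[e$label == "Plus A"], 100L)
  expect_equal(e$rpm[e$label == "canonical"], 9e5)
  expect_equal(e$rpm[e$label == "Plus A"], 1e5)
  expect_equal(sum(e$rpm), 1e6)

  # shuffled input gives the identical profile
  set.seed(9)
  prof2 <- call_sample(collapse_reads(sample(reads)), toy$ref, p, "s1")
  expect_identical(prof, prof2)

  # reads matching nothing
  junk <- collapse_reads(rep("GGGGGGGGGGGGGGGG", 5))
  prof3 <- call_sample(junk, toy$ref, p, "s3")
  expect_identical(prof3$total_assigned, 0L)
  expect_identical(nrow(prof3$entries), 0L)

  empty_ref <- structure(list(hairpins = toy$hairpins,
                              matures = toy$ref$matures[0, ]),
                         class = "reference_set")
  expect_error(call_sample(junk, empty_ref, p), "no mature annotations")
})

test_that("rank_isoforms orders by count with lexicographic tie-break", {
  toy <- toy_reference()
  M <- toy$mature
  reads <- c(rep(M, 5), rep(substr(M, 1, 21), 10),
             rep(paste0(M, "A"), 5))
  prof <- call_sample(collapse_reads(reads), toy$ref, caller_params(), "s")
  top1 <- rank_isoforms(prof, "m1", 1)
  expect_identical(top1$label, "Trim A")     # an isoform can outrank canonical
  expect_identical(top1$count, 10L)

  all_ranked <- rank_isoforms(prof, "m1", 99)
  expect_identical(nrow(all_ranked), 3L)
  # canonical and Plus A tie at 5; "Plus A" sorts before "canonical"
  expect_identical(all_ranked$label, c("Trim A", "Plus A", "canonical"))

  expect_error(rank_isoforms(prof, "nope", 1), "no entries")
})

test_that("profiles round-trip through the TSV interface", {
  toy <- toy_reference()
  reads <- c(rep(toy$mature, 30), rep(paste0(toy$mature, "A"), 10))
  prof <- call_sample(collapse_reads(reads), toy$ref, caller_params(), "s9")
  tsv <- tempfile(fileext = ".tsv")
  write_profile_tsv(prof, tsv)
  back <- read_profile_tsv(tsv)
  expect_identical(back$sample_id, "s9")
  expect_identical(back$entries$label, prof$entries$label)
  expect_identical(back$entries$count, prof$entries$count)
  expect_equal(back$entries$rpm, prof$entries$rpm)
})
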