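test_that("global_align handles identity, single indels, and long blocks", {
  s <- "ACGTACGTACGT"
  aln <- global_align(s, s)
  expect_equal(aln$score, 2 * nchar(s))
  expect_identical(aln$a, aln$b)

  aln2 <- global_align("ACGTACGT", "ACGACGT")
  expect_equal(aln2$score, 7 * 2 - 7)  # 7 matches, one 1-nt gap (5 + 2)
  expect_equal(nchar(gsub("[^-]", "", aln2$b)), 1L)

  set.seed(21)
  big <- random_seq(2000)
  cut <- paste0(substr(big, 1, 900), substr(big, 923, 2000))
  aln3 <- global_align(big, cut)
  gaps <- gregexpr("-+", aln3$b)[[1]]
  expect_equal(length(gaps), 1L)
  expect_equal(attr(gaps, "match.length"), 22L)
  expect_error(global_align("", "ACGT"), "input error")
})

test_that("global_align score equals the exhaustive DP oracle on small pairs", {
  set.seed(33)
  for (i in 1:40) {
    a <- random_seq(sample(3:12, 1))
    b <- random_seq(sample(3:12, 1))
    expect_equal(global_align(a, b)$score, gotoh_score(a, b),
                 info = paste(a, b))
  }
})

test_that("call_variants recovers planted substitutions and round-trips edits", {
  set.seed(55)
  gm <- gene_model("t", random_seq(300), cbind(1, 300),
                   cds_start = 61, cds_end = 240)
  anc <- spliced_transcript(gm)

  # pure substitutions: calls must equal the planted list exactly
  for (i in 1:60) {
    k <- sample(1:10, 1)
    mut <- mutate_subs(anc, k)
    aln <- global_align(anc, mut$seq)
    vars <- call_variants(aln, gm)
    expect_equal(nrow(vars), k)
    expect_equal(vars$tstart, mut$truth$pos)
    expect_equal(vars$ancestral, mut$truth$ancestral)
    expect_equal(vars$derived, mut$truth$derived)
    expect_true(all(vars$kind == "substitution"))
  }

  # mixed edits: the apply/call round-trip must regenerate the derived row
  for (i in 1:140) {
    v <- strsplit(anc, "")[[1]]
    n_ed <- sample(1:6, 1)
    for (e in seq_len(n_ed)) {
      op <- sample(c("sub", "del", "ins"), 1)
      p <- sample(length(v), 1)
      if (op == "sub") v[p] <- sample(setdiff(BASES4, v[p]), 1)
      else if (op == "del" && length(v) > 50) v <- v[-(p:min(p + 2, length(v)))]
      else v <- append(v, sample(BASES4, sample(1:3, 1), replace = TRUE), p)
    }
    der <- paste(v, collapse = "")
    vars <- call_variants(global_align(anc, der), gm)
    expect_identical(apply_variants(anc, vars), der)
  }

  # no differences -> empty table
  expect_equal(nrow(call_variants(global_align(anc, anc), gm)), 0L)
})

test_that("variant labels use coding coordinates with the ancestral allele first", {
  gm <- gene_model("t", random_seq(300), cbind(1, 300),
                   cds_start = 61, cds_end = 240)
  anc <- spliced_transcript(gm)
  v <- strsplit(anc, "")[[1]]
  v[204] <- setdiff(BASES4, v[204])[1]  # CDS position 144
  vars <- call_variants(global_align(anc, paste(v, collapse = "")), gm)
  expect_equal(vars$position, "144")
  expect_equal(vars$label,
               paste0("144", vars$ancestral, " > ", vars$derived))
  expect_equal(vars$region, "CDS")
})

test_that("variant count is invariant to input order up to polarity flip", {
  set.seed(77)
  gm <- gene_model("t", random_seq(200), cbind(1, 200),
                   cds_start = 31, cds_end = 150)
  anc <- spliced_transcript(gm)
  der <- mutate_subs(anc, 5)$seq
  v1 <- call_variants(global_align(anc, der), gm, polarity = "a")
  v2 <- call_variants(global_align(der, anc), gm, polarity = "b")
  expect_equal(nrow(v1), nrow(v2))
  expect_equal(v1$position, v2$position)
  expect_equal(v1$ancestral, v2$ancestral)
  expect_equal(v1$derived, v2$derived)
})

test_that("normalize_repeats re-expresses indels inside mononucleotide runs", {
  # 3' UTR with a 15-T run starting at *11
  set.seed(88)
  pre <- paste0(substr(random_seq(120), 1, 100), "CG")
  run <- strrep("T", 15)
  post <- "CGCA"
  anc <- paste0(pre, run, post)          # run occupies 103..117
  gm <- gene_model("t", anc, cbind(1, nchar(anc)),
                   cds_start = 31, cds_end = 90)  # run at *13.. in UTR3
  run_start_label <- format(transcript_to_coding(103, gm))

  # delete 3 T's at every possible placement in the run: identical output
  outs <- lapply(0:12, function(off) {
    a_row <- anc
    gap_start <- 103 + off
    der <- paste0(substr(anc, 1, gap_start - 1), substr(anc, gap_start + 3,
                                                        nchar(anc)))
    aln <- as_pair_alignment(
      anc, paste0(substr(der, 1, gap_start - 1), "---",
                  substr(der, gap_start, nchar(der))))
    normalize_repeats(call_variants(aln, gm), anc, gm)
  })
  for (o in outs) {
    expect_equal(o$kind, "repeat_length")
    expect_equal(o$label, paste0(run_start_label, "T(12-15)"))
    expect_equal(o$ancestral, "repeat:15")
    expect_equal(o$derived, "repeat:12")
  }

  # an indel not adjacent to any run is left unchanged
  der2 <- paste0(substr(anc, 1, 49), substr(anc, 52, nchar(anc)))
  v2 <- call_variants(global_align(anc, der2), gm)
  n2 <- normalize_repeats(v2, anc, gm)
  expect_equal(n2$kind, v2$kind)
  expect_false(any(n2$kind == "repeat_length"))
})
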