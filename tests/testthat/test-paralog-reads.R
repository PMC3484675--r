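make_family <- function(n = 6, len = 300, divergence = 0.02) {
  base <- random_seq(len)
  members <- vapply(seq_len(n), function(i) {
    v <- strsplit(base, "")[[1]]
    k <- rbinom(1, len, divergence)
    pos <- sample(len, k)
    for (p in pos) v[p] <- sample(setdiff(BASES4, v[p]), 1)
    paste(v, collapse = "")
  }, "")
  names(members) <- paste0("P", seq_len(n))
  members
}

test_that("find_diagnostic_sites returns exactly the focal-unique columns", {
  m <- c(A = "ACGTACGT", B = "ACGTACGT", C = "ACCTACGT")
  d <- find_diagnostic_sites(paralog_set(m, "C"))
  expect_equal(d$column, 3L)
  expect_equal(unname(d$allele), "C")
  # focal sharing its allele with one non-focal member excludes the column
  m2 <- c(A = "ACGTACGT", B = "ACCTACGT", C = "ACCTACGT")
  expect_equal(nrow(find_diagnostic_sites(paralog_set(m2, "C"))), 0L)
  expect_error(find_diagnostic_sites(paralog_set(c(A = "ACGT"), "A")),
               "input error")

  # random families vs a per-column brute-force scan
  set.seed(13)
  for (rep in 1:10) {
    fam <- make_family()
    pset <- paralog_set(fam, "P1")
    d <- find_diagnostic_sites(pset)
    mat <- do.call(rbind, strsplit(unname(fam), ""))
    oracle <- which(vapply(seq_len(ncol(mat)), function(j)
      all(mat[1, j] != mat[-1, j]), logical(1)))
    expect_equal(d$column, oracle)
  }
  # empty iff focal identical to some other member
  fam2 <- make_family(n = 3)
  fam2[["P3"]] <- fam2[["P1"]]
  expect_equal(nrow(find_diagnostic_sites(paralog_set(fam2, "P1"))), 0L)
})

test_that("assign_read verdicts match a brute-force placement oracle", {
  set.seed(29)
  fam <- make_family(n = 4, len = 400, divergence = 0.03)
  pset <- paralog_set(fam, "P1")
  for (rep in 1:120) {
    origin <- sample(names(fam), 1)
    len <- sample(25:60, 1)
    start <- sample(400 - len + 1, 1)
    read <- substr(fam[[origin]], start, start + len - 1)
    if (runif(1) < 0.5) read <- revcomp(read)
    a <- assign_read(read, pset, read_id = origin)
    oracle <- vapply(fam, function(mem) brute_read_distance(read, mem),
                     numeric(1))
    expect_equal(a$per_member_mismatches, oracle)
    best <- min(oracle)
    winners <- names(oracle)[oracle == best]
    expect_setequal(a$best, winners)
    if (a$verdict == "unique") {
      expect_length(winners, 1)
      # error-free reads assigned uniquely must name their true origin
      expect_equal(a$best, origin)
    }
    if (length(winners) > 1) expect_equal(a$verdict, "tied")
  }
})

test_that("tied reads and margin behavior mirror the splice-site logic", {
  # a read equidistant from two members cannot be conclusively assigned
  m <- c(P8 = "ACGTACGTACGTACGTACGTGGGG", P9 = "ACGTACGTACGTACGTACGTCCCC",
         P7 = "ATGTACGAACGTACGTACGTCCCC")
  pset <- paralog_set(m, "P8")
  tied <- assign_read(substr(m[["P8"]], 1, 20), pset)
  expect_equal(tied$verdict, "tied")
  expect_setequal(tied$best, c("P8", "P9"))
  # a read with a diagnostic base is unique at margin 1
  uni <- assign_read(m[["P8"]], pset, margin = 1)
  expect_equal(uni$verdict, "unique")
  expect_equal(uni$best, "P8")
  # increasing the margin never converts tied/unassigned into unique
  for (mg in 2:6) {
    a <- assign_read(m[["P8"]], pset, margin = mg)
    expect_true(a$verdict != "unique" ||
                  assign_read(m[["P8"]], pset, margin = mg - 1)$verdict ==
                  "unique")
  }
  # reverse-complement invariance
  a1 <- assign_read(m[["P8"]], pset)
  a2 <- assign_read(revcomp(m[["P8"]]), pset)
  expect_equal(a1$per_member_mismatches, a2$per_member_mismatches)
  expect_equal(a1$verdict, a2$verdict)
  # N matches nothing and pushes toward tied
  rN <- paste0(substr(m[["P8"]], 1, 19), "N")
  aN <- assign_read(rN, pset)
  oracleN <- vapply(m, function(mem) brute_read_distance(rN, mem),
                    numeric(1))
  expect_equal(aN$per_member_mismatches, oracleN)
  expect_error(assign_read("ACGTACGTACG", pset), "input error")
})

test_that("spans_junction demands the configured overhang on both sides", {
  set.seed(31)
  ref <- random_seq(400)
  j <- 200L
  # a 57-nt read centered on the junction spans it
  r <- substr(ref, j - 28 + 1, j + 29)
  res <- spans_junction(r, ref, j, min_overhang = 15)
  expect_true(res$spans)
  expect_equal(res$start, j - 27L)
  # a read ending exactly at the junction does not span it
  r2 <- substr(ref, j - 40, j)
  expect_false(spans_junction(r2, ref, j, min_overhang = 1)$spans)
  # reverse-strand reads are placed correctly
  expect_true(spans_junction(revcomp(r), ref, j, min_overhang = 15)$spans)
  # exhaustive agreement over all placements of a 30-nt read
  for (start in seq(160, 240, by = 4)) {
    rd <- substr(ref, start, start + 29)
    res <- spans_junction(rd, ref, j, min_overhang = 10)
    expect_equal(res$start, start)
    expect_equal(res$spans,
                 (j - (start - 1) >= 10) && ((start + 29) - j >= 10))
  }
})
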