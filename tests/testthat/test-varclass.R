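test_that("the published parent/retrocopy ledger yields exactly 3 fixed differences, 2 in frame", {
  led <- read_variant_ledger(ledger_path())
  calls <- classify_fixation(led$parent, led$retro)
  fixed <- calls$position[calls$status == "fixed_difference"]
  expect_setequal(fixed, c("144", "759", "*606"))
  k_all <- count_fixed_differences(calls, led$positions)
  expect_equal(k_all$k, 3L)
  k_rf <- count_fixed_differences(calls,
                                  led$positions[led$in_reading_frame])
  expect_equal(k_rf$k, 2L)
  # the repeat tracts are never fixed differences
  expect_true(all(calls$status[calls$position %in% c("*184", "*223")] ==
                    "polymorphic_in_both"))
})

test_that("classify_fixation matches a brute-force allele-set oracle", {
  set.seed(101)
  n_sites <- 500
  rows_p <- list(); rows_r <- list()
  truth <- character(n_sites)
  for (i in seq_len(n_sites)) {
    pos <- as.character(i)
    pa <- sample(BASES4, sample(1:2, 1))
    ra <- sample(BASES4, sample(1:2, 1))
    obs_p <- sample(pa, 6, replace = TRUE)
    obs_r <- sample(ra, 6, replace = TRUE)
    rows_p[[i]] <- data.frame(position = pos, allele = obs_p,
                              individual = paste0("p", 1:6))
    rows_r[[i]] <- data.frame(position = pos, allele = obs_r,
                              individual = paste0("r", 1:6))
    up <- unique(obs_p); ur <- unique(obs_r)
    truth[i] <- if (length(up) > 1 && length(ur) > 1) "polymorphic_in_both"
      else if (length(up) > 1) "polymorphic_in_parent"
      else if (length(ur) > 1) "polymorphic_in_retrocopy"
      else if (up == ur) "shared_invariant" else "fixed_difference"
  }
  pp <- do.call(rbind, rows_p); rr <- do.call(rbind, rows_r)
  calls <- classify_fixation(
    site_panel("parent", pp$position, pp$individual, pp$allele),
    site_panel("retro", rr$position, rr$individual, rr$allele))
  expect_equal(calls$status[match(as.character(1:n_sites), calls$position)],
               truth)
})

test_that("classification invariances: relabeling and duplicate observations", {
  pp <- site_panel("parent", c("10", "10", "20"), c("a", "b", "a"),
                   c("G", "A", "C"))
  rr <- site_panel("retro", c("10", "20"), c("x", "x"), c("G", "T"))
  base <- classify_fixation(pp, rr)
  # duplicating an observation never changes a call
  pp2 <- rbind(pp, pp[1, ]); pp2$individual[4] <- "dup"
  again <- classify_fixation(site_panel("parent", pp2$position,
                                        pp2$individual, pp2$allele), rr)
  expect_equal(base$status, again$status)
  # a position seen in only one paralog is unresolved
  rr3 <- site_panel("retro", c("10", "20", "30"), c("x", "x", "x"),
                    c("G", "T", "A"))
  calls3 <- classify_fixation(pp, rr3)
  expect_equal(calls3$status[calls3$position == "30"], "unresolved")
  expect_error(classify_fixation(pp[0, ], rr), "input error")
  # N observations are ignored, never counted as an allele
  ppN <- site_panel("parent", c("5", "5"), c("a", "b"), c("G", "N"))
  rrN <- site_panel("retro", "5", "x", "A")
  expect_equal(classify_fixation(ppN, rrN)$status, "fixed_difference")
})

test_that("false fixation by panel sampling is rare at MAF >= 0.2, n = 20", {
  set.seed(202)
  n_sites <- 500
  false_fixed <- 0L
  for (i in seq_len(n_sites)) {
    maf <- runif(1, 0.2, 0.5)
    alleles <- sample(c("A", "G"), 20, replace = TRUE, prob = c(1 - maf, maf))
    pp <- site_panel("parent", "1", paste0("p", 1:20), alleles)
    rr <- site_panel("retro", "1", paste0("r", 1:20), rep("C", 20))
    if (classify_fixation(pp, rr)$status == "fixed_difference")
      false_fixed <- false_fixed + 1L
  }
  expect_lt(false_fixed / n_sites, 0.05)
})

test_that("assign_ancestral applies outgroup unanimity", {
  a <- assign_ancestral("246", c("T", "G"),
                        c(chimp = "G", gorilla = "G", orangutan = "G"))
  expect_equal(a$state, "G")
  expect_equal(assign_ancestral("1", "A", c(x = "G", y = "A"))$state,
               "ambiguous")
  expect_equal(assign_ancestral("1", "A", c(x = NA, y = "N"))$state,
               "unresolved")
  # repeat-length sites are never polarized
  expect_equal(assign_ancestral("*184", "repeat:15",
                                c(x = "repeat:15", y = "repeat:15"),
                                is_repeat = TRUE)$state, "ambiguous")
})

test_that("reconstruct_parent recovers the true ancestor at discordant sites", {
  set.seed(303)
  for (rep in 1:200) {
    gm <- gene_model("t", random_seq(60), cbind(1, 60),
                     cds_start = 11, cds_end = 40)
    anc <- spliced_transcript(gm)
    m1 <- mutate_subs(anc, sample(0:3, 1))
    # ensure disjoint mutated sites between the two references
    repeat {
      m2 <- mutate_subs(anc, sample(0:3, 1))
      if (!length(intersect(m1$truth$pos, m2$truth$pos))) break
    }
    truthdf <- rbind(m1$truth, m2$truth)
    calls <- data.frame(
      position = vapply(truthdf$pos, function(p)
        format(transcript_to_coding(p, gm)), ""),
      state = truthdf$ancestral)
    rec <- reconstruct_parent(m1$seq, m2$seq, calls, gm)
    expect_identical(rec$sequence, anc)
    expect_false(rec$flagged)
  }
  # identical references reconstruct to themselves
  gm <- gene_model("t", random_seq(60), cbind(1, 60), 11, 40)
  s <- spliced_transcript(gm)
  expect_identical(reconstruct_parent(s, s, data.frame(position = character(),
                                                       state = character()),
                                      gm)$sequence, s)
})

test_that("ambiguous ancestral states become N; indel discordance is flagged", {
  gm <- gene_model("t", strrep("ACGT", 15), cbind(1, 60), 11, 40)
  s <- spliced_transcript(gm)
  v <- strsplit(s, "")[[1]]; v[5] <- setdiff(BASES4, v[5])[1]
  s2 <- paste(v, collapse = "")
  pos5 <- format(transcript_to_coding(5, gm))
  rec <- reconstruct_parent(s, s2, data.frame(position = pos5,
                                              state = "ambiguous"), gm)
  expect_equal(substr(rec$sequence, 5, 5), "N")
  expect_equal(rec$n_ambiguous, 1L)
  # deletion in the second reference: flagged, region recorded
  s3 <- paste0(substr(s, 1, 20), substr(s, 26, 60))
  rec2 <- reconstruct_parent(s, s3, data.frame(position = character(),
                                               state = character()), gm)
  expect_true(rec2$flagged)
  expect_equal(nrow(rec2$excluded_regions), 1L)
})

test_that("count_fixed_differences respects masks, polarization, monotonicity", {
  led <- read_variant_ledger(ledger_path())
  calls <- classify_fixation(led$parent, led$retro)
  expect_equal(count_fixed_differences(calls, character(0)),
               list(k = 0L, L = 0L))
  # k is monotone non-decreasing in mask size
  ks <- vapply(seq_along(led$positions), function(n)
    count_fixed_differences(calls, led$positions[seq_len(n)])$k, integer(1))
  expect_true(all(diff(ks) >= 0))
  expect_equal(max(ks), 3L)
  # polarization: count only retrocopy-derived fixed differences
  anc <- data.frame(position = c("144", "759", "*606"),
                    state = c("G", "G", "T"))  # parent carries ancestral
  expect_equal(count_fixed_differences(calls, led$positions,
                                       polarize_to = anc)$k, 3L)
  anc2 <- anc; anc2$state[1] <- "A"  # retrocopy allele ancestral at 144
  expect_equal(count_fixed_differences(calls, led$positions,
                                       polarize_to = anc2)$k, 2L)
})

test_that("site panels round-trip through TSV", {
  led <- read_variant_ledger(ledger_path())
  tmp <- tempfile(fileext = ".tsv")
  write_site_panel(led$parent, tmp)
  back <- read_site_panel(tmp)
  expect_equal(as.data.frame(back), as.data.frame(led$parent))
})
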