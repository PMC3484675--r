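test_that("FASTA read/write normalizes wrapping and case losslessly", {
  tmp <- tempfile(fileext = ".fasta")
  writeLines(c(">seq1", "acgtACGTac", "GTNa", ">seq2 description",
               "TTTT"), tmp)
  seqs <- read_fasta(tmp)
  expect_equal(unname(seqs), c("ACGTACGTACGTNA", "TTTT"))
  out <- tempfile(fileext = ".fasta")
  write_fasta(seqs, out)
  expect_identical(read_fasta(out), seqs)
  # long sequences wrap at 60 columns
  write_fasta(c(long = strrep("ACGT", 40)), out)
  expect_equal(max(nchar(readLines(out)[-1])), 60L)
  expect_error(read_fasta(tempfile()), "input error")
})

test_that("FASTQ reads load with qualities ignored", {
  tmp <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGTACGTACGTACGTACGTACGT", "+",
               strrep("I", 24)), tmp)
  expect_equal(unname(read_reads(tmp)), "ACGTACGTACGTACGTACGTACGT")
})

test_that("TSV round-trips and the plain-text config parser behaves", {
  df <- data.frame(a = c("x", "y"), b = c(1L, 2L), c = c(0.5, 2.25))
  tmp <- tempfile(fileext = ".tsv")
  write_tsv(df, tmp)
  expect_equal(read_tsv(tmp), df)

  cfgp <- tempfile(fileext = ".txt")
  writeLines(c("# comment", "rate.point = 1.25e-9",
               "rate.low = 0.5e-9", "rate.high = 1.35e-9",
               "presence.neanderthal = present 2.7e5 8.0e5",
               "presence.chimpanzee = absent 5.5e6 7e6"), cfgp)
  cfg <- read_config(cfgp)
  expect_equal(cfg$rate.point, 1.25e-9)
  rm <- rate_model_from_config(cfg)
  expect_equal(rm$low, 0.5e-9)
  tab <- presence_table_from_config(cfg)
  expect_equal(nrow(tab), 2L)
  expect_equal(presence_bounds(tab)$upper, 7e6)
  expect_error(read_config(cfgp, allowed = "rate.point"), "unknown config key")
  bad <- tempfile(); writeLines("no equals sign here", bad)
  expect_error(read_config(bad), "malformed")
})

test_that("bundles round-trip through a directory and the pipeline", {
  cfg <- sim_config(seed = 31)
  b <- simulate_history(cfg)
  dir <- tempfile("bundle")
  write_bundle(b, dir)
  lb <- load_bundle(dir)
  presence <- data.frame(taxon = c("neanderthal", "chimpanzee"),
                         status = c("present", "absent"),
                         div_low = c(2.7e5, 5.5e6),
                         div_high = c(8.0e5, 7e6))
  p1 <- run_pipeline(b, presence = presence)
  p2 <- run_pipeline(lb, presence = presence)
  expect_equal(p2$k, p1$k)
  expect_equal(p2$L, p1$L)
  expect_equal(p2$clock$point_age, p1$clock$point_age)
  expect_equal(p2$features$tsd$length, p1$features$tsd$length)
  expect_error(load_bundle(tempfile("nope")), "input error")
})

test_that("the pipeline summary matches the generator's truth", {
  cfg <- sim_config(seed = 47)
  b <- simulate_history(cfg)
  reads <- simulate_reads(b, cfg, junction_targeted = TRUE)
  presence <- data.frame(taxon = c("neanderthal", "chimpanzee"),
                         status = c("present", "absent"),
                         div_low = c(2.7e5, 5.5e6),
                         div_high = c(8.0e5, 7e6))
  out_dir <- tempfile("pipe")
  res <- run_pipeline(b, presence = presence, reads = reads,
                      out_dir = out_dir)
  expect_equal(res$k, sum(b$truth$class == "fixed_retro" &
                            b$truth$position %in% b$mask))
  expect_equal(res$L, length(b$mask))
  expect_equal(res$features$tsd$length, b$tsd$length)
  expect_equal(res$features$polya_length, b$polya_length)
  expect_equal(res$features$orientation, "reverse")
  expect_true(all(res$junction_reads$spans_junction))
  # the 22-nt parent-allele deletion surfaces as a called deletion variant
  dels <- res$variants[res$variants$kind == "deletion", ]
  expect_true(any(nchar(dels$ancestral) == 22))
  # deterministic: a second run gives the same summary
  res2 <- run_pipeline(b, presence = presence)
  expect_equal(res2$k, res$k)
  expect_equal(res2$clock$point_age, res$clock$point_age)
  expect_true(file.exists(file.path(out_dir, "summary.json")))
  js <- jsonlite::read_json(file.path(out_dir, "summary.json"))
  expect_equal(js$k, res$k)
})

test_that("CLI subcommands honor --seed and --out", {
  withr::with_tempdir({
    # date
    cfgp <- "clock.txt"
    writeLines(c("rate.point = 1.25e-9", "rate.low = 0.5e-9",
                 "rate.high = 1.35e-9"), cfgp)
    st <- retrodate_cli(c("date", "2", "1622", "--config", cfgp,
                          "--out", "age.tsv"))
    expect_equal(st, 0L)
    age <- read_tsv("age.tsv")
    expect_equal(age$point_age_my, 1)
    expect_equal(c(age$age_low_my, age$age_high_my), c(0.9, 2.5))
    # popfreq
    st2 <- retrodate_cli(c("popfreq",
                           system.file("extdata", "genotype_counts.tsv",
                                       package = "retrodate"),
                           "--out", "pf.tsv"))
    expect_equal(st2, 0L)
    pf <- read_tsv("pf.tsv")
    expect_equal(round(pf$freq_ancestral[pf$population == "Total"], 4),
                 0.5840)
    # classify, via the shipped ledger split into two panel files
    led <- read_variant_ledger(ledger_path())
    write_site_panel(led$parent, "pp.tsv")
    write_site_panel(led$retro, "rp.tsv")
    st3 <- retrodate_cli(c("classify", "pp.tsv", "rp.tsv", "--out",
                           "calls.tsv"))
    expect_equal(st3, 0L)
    calls <- read_tsv("calls.tsv")
    expect_equal(sum(calls$status == "fixed_difference"), 3L)
    # unknown subcommand fails cleanly
    expect_equal(suppressMessages(retrodate_cli("frobnicate")), 1L)
  })
})
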