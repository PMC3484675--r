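# Independent oracles and fixture builders used across the suite.

BASES4 <- c("A", "C", "G", "T")

random_seq <- function(n) paste(sample(BASES4, n, replace = TRUE),
                                collapse = "")

# Exhaustive affine-gap global alignment score (Gotoh, score only).
# Gap of length g costs gap_open + g * gap_extend, matching global_align.
gotoh_score <- function(a, b, match = 2, mismatch = -3, gap_open = -5,
                        gap_extend = -2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (a consumed)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a (b consumed)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- gap_open + i * gap_extend
  for (j in seq_len(m)) Y[1, j + 1] <- gap_open + j * gap_extend
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] + gap_open + gap_extend,
                             X[i, j + 1] + gap_extend,
                             Y[i, j + 1] + gap_open + gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] + gap_open + gap_extend,
                             Y[i + 1, j] + gap_extend,
                             X[i + 1, j] + gap_open + gap_extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Toy gene model with the given element lengths; sequence is random.
toy_model <- function(utr5 = 6, cds_len = 12, utr3 = 9,
                      intron_lengths = c(10, 8), name = "toy") {
  sl <- utr5 + cds_len + utr3
  n_ex <- length(intron_lengths) + 1
  # split the spliced length into n_ex exon chunks (each >= 2)
  cuts <- sort(sample(seq(2, sl - 2), n_ex - 1))
  lens <- diff(c(0, cuts, sl))
  pos <- 1; starts <- integer(n_ex); ends <- integer(n_ex)
  for (i in seq_len(n_ex)) {
    starts[i] <- pos; ends[i] <- pos + lens[i] - 1
    pos <- ends[i] + 1 + if (i < n_ex) intron_lengths[i] else 0
  }
  glen <- sl + sum(intron_lengths)
  gene_model(name, random_seq(glen), cbind(starts, ends),
             cds_start = utr5 + 1, cds_end = utr5 + cds_len)
}

# Brute-force gapless read placement: minimum Hamming distance over all
# offsets and both orientations; N in the read matches nothing.
brute_read_distance <- function(read, member) {
  memv <- strsplit(member, "")[[1]]
  one <- function(rd) {
    rv <- strsplit(rd, "")[[1]]
    len <- length(rv); n <- length(memv)
    if (len > n) return(Inf)
    min(vapply(seq_len(n - len + 1), function(s)
      sum(memv[s:(s + len - 1)] != rv | rv == "N"), numeric(1)))
  }
  min(one(read), one(revcomp(read)))
}

# Naive IUPAC motif scan oracle via regex.
iupac_regex <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]",
                 Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]",
                 M = "[AC]", B = "[CGT]", D = "[AGT]", H = "[ACT]",
                 V = "[ACG]", N = "[ACGT]")
naive_motif_starts <- function(seq, motif) {
  pat <- paste(iupac_regex[strsplit(motif, "")[[1]]], collapse = "")
  m <- gregexpr(paste0("(?=", pat, ")"), seq, perl = TRUE)[[1]]
  if (m[1] < 0) integer(0) else as.integer(m)
}

# Apply k random substitutions to a sequence, returning truth.
mutate_subs <- function(seq, k) {
  v <- strsplit(seq, "")[[1]]
  pos <- sort(sample(length(v), k))
  anc <- v[pos]
  der <- vapply(anc, function(b) sample(setdiff(BASES4, b), 1), "")
  v[pos] <- der
  list(seq = paste(v, collapse = ""),
       truth = data.frame(pos = pos, ancestral = anc, derived = unname(der)))
}

# Plant an element into a random locus with an exact TSD of length t,
# guarding against chance extension of the duplication.
plant_tsd <- function(element_len = 80, tsd_len = 15, flank = 60) {
  repeat {
    pre <- strsplit(random_seq(2 * flank + tsd_len), "")[[1]]
    q <- flank
    block <- strsplit(random_seq(element_len), "")[[1]]
    locus <- c(pre[1:(q + tsd_len)], block, pre[(q + 1):length(pre)])
    es <- q + tsd_len + 1L
    ee <- q + tsd_len + element_len
    ok <- TRUE
    for (len in seq.int(30L, tsd_len + 1L)) {
      if (es - len < 1 || ee + len > length(locus)) next
      if (all(locus[(es - len):(es - 1)] == locus[(ee + 1):(ee + len)])) {
        ok <- FALSE; break
      }
    }
    if (ok)
      return(list(locus = paste(locus, collapse = ""),
                  interval = c(es, ee),
                  tsd = paste(pre[(q + 1):(q + tsd_len)], collapse = "")))
  }
}

ledger_path <- function() {
  system.file("extdata", "nanog_nanogp8_ledger.tsv", package = "retrodate")
}
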