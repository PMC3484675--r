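#' Configuration for the synthetic retrocopy history generator
#'
#' Defaults emulate the study system this package targets: a four-exon
#' parent gene with a 197-nt 5' UTR, a 918-nt reading frame (stop
#' included), and a 967-nt 3' UTR carrying two long poly(T) tracts and a
#' polymorphic 22-nt deletion; a retrocopy of age `retro_age` inserted in
#' reverse orientation into a host element with a 15-nt target-site
#' duplication and a poly(A) remnant; outgroup orthologs at hominid-like
#' divergence times; and panel polymorphism in both paralogs.
#'
#' @param seed Integer seed; identical seeds give identical bundles.
#' @param gene List: `exon_lengths` (spliced), `intron_lengths`, `utr5`,
#'   `cds_len` (multiple of 3, stop included).
#' @param rate Substitutions per site per year (0 allowed, for null
#'   configurations).
#' @param outgroup_times Named numeric vector of divergence times (years),
#'   all greater than `retro_age`.
#' @param retro_age True age of the retrocopy (years).
#' @param tsd_len,polya_len Planted hallmark lengths.
#' @param host List: `length`, `insertion_point` (within the host),
#'   `flank` (locus flank on each side of the host).
#' @param polymorphism List: `n_sites` per paralog, `maf` range,
#'   `panel_n` sequences per paralog.
#' @param parent_deletion List: `length`, `utr3_start` (3' UTR coordinate
#'   of the first deleted base), `freq` (derived-allele frequency in the
#'   parent); `NULL` disables it.
#' @param repeats List: `utr3_starts`, `lengths` of planted poly(T)
#'   tracts; `NULL` disables them.
#' @param reads List: `n`, `length_range`, `error_rate`.
#' @param motif Motif planted (reverse-oriented) upstream of the
#'   retrocopy's initiation codon.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       gene = list(exon_lengths = c(290L, 160L, 150L, 1482L),
                                   intron_lengths = c(300L, 250L, 400L),
                                   utr5 = 197L, cds_len = 918L),
                       rate = 1.25e-9,
                       outgroup_times = c(chimpanzee = 6e6, gorilla = 8e6,
                                          orangutan = 13e6),
                       retro_age = 1e6,
                       tsd_len = 15L, polya_len = 16L,
                       host = list(length = 3000L, insertion_point = 1500L,
                                   flank = 500L),
                       polymorphism = list(n_sites = 8L, maf = c(0.1, 0.5),
                                           panel_n = 94L),
                       parent_deletion = list(length = 22L,
                                              utr3_start = 552L,
                                              freq = 0.416),
                       repeats = list(utr3_starts = c(184L, 223L),
                                      lengths = c(15L, 18L)),
                       reads = list(n = 40L, length_range = c(36L, 78L),
                                    error_rate = 0.005),
                       motif = "GGGCGG") {
  sl <- sum(gene$exon_lengths)
  if (gene$cds_len %% 3L != 0L) stop("config error: cds_len not a codon multiple")
  if (gene$utr5 + gene$cds_len >= sl)
    stop("config error: UTRs and CDS exceed the spliced length")
  if (length(gene$intron_lengths) != length(gene$exon_lengths) - 1L)
    stop("config error: need one intron fewer than exons")
  if (rate < 0) stop("config error: negative rate")
  if (retro_age >= min(outgroup_times))
    stop("config error: retrocopy age must predate no outgroup divergence")
  if (!is.null(parent_deletion) &&
      (parent_deletion$freq <= 0 || parent_deletion$freq >= 1))
    stop("config error: deletion frequency must be in (0,1)")
  structure(list(seed = as.integer(seed), gene = gene, rate = rate,
                 outgroup_times = sort(outgroup_times, decreasing = TRUE),
                 retro_age = retro_age, tsd_len = as.integer(tsd_len),
                 polya_len = as.integer(polya_len), host = host,
                 polymorphism = polymorphism,
                 parent_deletion = parent_deletion, repeats = repeats,
                 reads = reads, motif = toupper(motif)),
            class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

random_bases <- function(n) sample(BASES, n, replace = TRUE)

other_base <- function(b) sample(setdiff(BASES, b), 1L)

#' Simulate a retrocopy insertion history with recorded truth
#'
#' Draws a uniform-random ancestor gene, evolves outgroup orthologs and the
#' focal lineage under a uniform (Jukes-Cantor-like) substitution model with
#' Poisson counts per branch, creates the retrocopy at `retro_age` years ago
#' (spliced transcript of the parent allele, poly(A) appended,
#' reverse-complemented, inserted into a host element with a target-site
#' duplication), lets retrocopy and parent diverge independently to the
#' present, and plants panel polymorphism at stated frequencies. An
#' infinite-sites approximation is enforced (positions are drawn without
#' replacement from a shared pool), so planted counts are exact at these
#' divergences. Deterministic under `cfg$seed`.
#'
#' @param cfg A `sim_config`.
#' @return A list of class `truth_bundle`; see the package vignette for the
#'   full inventory (sequences, gene models, panels, outgroup states, the
#'   planted-variant table, hallmark truth, and the comparison-region
#'   mask).
#' @export
simulate_history <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  gene <- cfg$gene
  sl <- sum(gene$exon_lengths)
  cds_start <- gene$utr5 + 1L
  cds_end <- gene$utr5 + gene$cds_len
  # exon intervals on the genomic sequence
  glen <- sl + sum(gene$intron_lengths)
  ex_start <- integer(length(gene$exon_lengths))
  ex_end <- integer(length(gene$exon_lengths))
  pos <- 1L
  for (i in seq_along(gene$exon_lengths)) {
    ex_start[i] <- pos
    ex_end[i] <- pos + gene$exon_lengths[i] - 1L
    pos <- ex_end[i] + 1L + if (i < length(gene$exon_lengths))
      gene$intron_lengths[i] else 0L
  }
  exons <- cbind(ex_start, ex_end)
  map <- unlist(lapply(seq_len(nrow(exons)), function(i)
    seq.int(exons[i, 1], exons[i, 2])))

  g <- random_bases(glen)
  g[map[cds_start:(cds_start + 2L)]] <- c("A", "T", "G")
  g[map[(cds_end - 2L):cds_end]] <- c("T", "A", "A")
  # planted landmark regions (transcript coordinates)
  repeat_t <- integer(0)
  if (!is.null(cfg$repeats))
    for (i in seq_along(cfg$repeats$utr3_starts)) {
      tt <- cds_end + cfg$repeats$utr3_starts[i] +
        seq_len(cfg$repeats$lengths[i]) - 1L
      g[map[tt]] <- "T"
      repeat_t <- c(repeat_t, tt)
    }
  del_t <- integer(0)
  if (!is.null(cfg$parent_deletion))
    del_t <- cds_end + cfg$parent_deletion$utr3_start +
      seq_len(cfg$parent_deletion$length) - 1L
  tail_guard_t <- (sl - 9L):sl          # keep the 3' end A-free so the
  g[map[tail_guard_t]][g[map[tail_guard_t]] == "A"] <- "C"  # poly(A) truth is exact
  landmark_t <- c(cds_start:(cds_start + 2L), (cds_end - 2L):cds_end,
                  repeat_t, del_t, tail_guard_t)
  mutable_t <- setdiff(seq_len(sl), landmark_t)
  mutable_g <- setdiff(seq_len(glen), map[landmark_t])

  used <- integer(0)   # genomic positions already mutated (infinite sites)
  draw_positions <- function(pool_g, time, len) {
    pool <- setdiff(pool_g, used)
    n <- stats::rpois(1L, len * cfg$rate * time)
    if (n > length(pool)) stop("config error: mutation load exceeds free sites")
    p <- if (n) sort(sample(pool, n)) else integer(0)
    used <<- c(used, p)
    p
  }
  mutate_at <- function(seqv, positions) {
    for (p in positions) seqv[p] <- other_base(seqv[p])
    seqv
  }

  # lineage walk from the oldest outgroup divergence to the present
  ancestor_g <- g
  current <- g
  outgroups <- list()
  times <- cfg$outgroup_times
  prev <- times[1]
  for (i in seq_along(times)) {
    tx <- names(times)[i]
    if (i > 1L) {
      seg <- prev - times[i]
      current <- mutate_at(current, draw_positions(mutable_g, seg, glen))
      prev <- times[i]
    }
    outgroups[[tx]] <- mutate_at(current,
                                 draw_positions(mutable_g, times[i], glen))
  }
  # focal lineage continues to the retrotransposition time
  current <- mutate_at(current,
                       draw_positions(mutable_g, prev - cfg$retro_age, glen))
  p_origin_g <- current

  # post-origin branches (transcript coordinates; intronic drift untracked)
  parent_mut_t <- match(draw_positions(map[mutable_t], cfg$retro_age, sl), map)
  retro_mut_t <- match(draw_positions(map[mutable_t], cfg$retro_age, sl), map)
  parent_g <- mutate_at(p_origin_g, map[parent_mut_t])
  origin_t <- p_origin_g[map]          # transcript at origin (char vector)
  parent_t <- parent_g[map]
  retro_t <- mutate_at(origin_t, retro_mut_t)  # full-frame retro transcript

  model <- gene_model("parent", paste(ancestor_g, collapse = ""), exons,
                      cds_start, cds_end)
  label_of <- function(t) coding_labels(t, model)

  # planted polymorphic sites
  pm <- cfg$polymorphism
  poly_rows <- list()
  panels <- list(parent = list(), retro = list())
  for (paralog in c("parent", "retro")) {
    n_sites <- pm$n_sites
    if (n_sites > 0L) {
      pool <- setdiff(map[mutable_t], used)
      sites_g <- sort(sample(pool, n_sites))
      used <- c(used, sites_g)
      sites_t <- match(sites_g, map)
      for (t in sites_t) {
        anc <- if (paralog == "parent") parent_t[t] else retro_t[t]
        der <- other_base(anc)
        f <- stats::runif(1L, pm$maf[1], pm$maf[2])
        poly_rows[[length(poly_rows) + 1L]] <- data.frame(
          position = label_of(t), tpos = t, paralog = paralog,
          kind = "substitution", ancestral = anc, derived = der,
          class = paste0("polymorphic_", paralog), freq = f)
      }
    }
  }
  truth_rows <- c(
    lapply(parent_mut_t, function(t) data.frame(
      position = label_of(t), tpos = t, paralog = "parent",
      kind = "substitution", ancestral = origin_t[t], derived = parent_t[t],
      class = "fixed_parent", freq = 1)),
    lapply(retro_mut_t, function(t) data.frame(
      position = label_of(t), tpos = t, paralog = "retro",
      kind = "substitution", ancestral = origin_t[t], derived = retro_t[t],
      class = "fixed_retro", freq = 1)),
    poly_rows)
  truth <- if (length(truth_rows))
    do.call(rbind, c(truth_rows, list(make.row.names = FALSE)))
  else data.frame(position = character(), tpos = integer(),
                  paralog = character(), kind = character(),
                  ancestral = character(), derived = character(),
                  class = character(), freq = numeric())

  # retrocopy: spliced transcript of the deletion allele + poly(A),
  # reverse-complemented into the host element
  retro_mrna_v <- if (length(del_t)) retro_t[-del_t] else retro_t
  retro_mrna <- paste(retro_mrna_v, collapse = "")
  block <- revcomp(paste0(retro_mrna, strrep("A", cfg$polya_len)))

  ins <- plant_insertion(block, cfg)
  locus <- ins$locus
  element_interval <- ins$element_interval
  ee <- element_interval[2]
  # motif planted forward in the locus beyond the element's 3' side, which
  # is reverse-oriented and upstream in the retrocopy's mRNA frame
  motif_locus_start <- ee + 250L
  locus_v <- strsplit(locus, "")[[1]]
  scrub <- scrub_motif(locus_v, cfg$motif,
                       from = ee + cfg$tsd_len + 1L, to = ee + 620L)
  locus_v <- scrub
  w <- nchar(cfg$motif)
  locus_v[motif_locus_start:(motif_locus_start + w - 1L)] <-
    strsplit(cfg$motif, "")[[1]]
  # planting can create chance overlapping occurrences with neighboring
  # bases; scrub the immediate neighborhood, sparing the planted copy
  locus_v <- scrub_motif(locus_v, cfg$motif,
                         from = motif_locus_start - w - 4L,
                         to = motif_locus_start + 2L * w + 3L,
                         spare = c(motif_locus_start,
                                   motif_locus_start + w - 1L))
  locus <- paste(locus_v, collapse = "")
  upstream_window <- 600L
  motif_context_pos <- upstream_window + 1L -
    (motif_locus_start + nchar(cfg$motif) - 1L - ee)
  motif_anchor <- upstream_window + cds_start

  # panels: observations at every planted variant position
  panel_rows <- function(df, paralog, seq_t) {
    pn <- pm$panel_n
    if (!nrow(df))
      return(data.frame(position = character(), allele = character(),
                        individual = character()))
    rows <- lapply(seq_len(nrow(df)), function(i) {
      v <- df[i, ]
      alleles <- if (v$paralog == paralog && startsWith(v$class, "poly")) {
        nd <- stats::rbinom(1L, pn, v$freq)
        sample(c(rep(v$derived, nd), rep(v$ancestral, pn - nd)))
      } else rep(seq_t[v$tpos], pn)
      data.frame(position = v$position, allele = alleles,
                 individual = paste0(paralog, "_", seq_len(pn)))
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  sub_truth <- truth[truth$kind == "substitution", , drop = FALSE]
  pp <- panel_rows(sub_truth, "parent", parent_t)
  rp <- panel_rows(sub_truth, "retro", retro_t)
  # the polymorphic parent-allele deletion and the repeat tracts
  if (length(del_t)) {
    pn <- pm$panel_n
    nd <- stats::rbinom(1L, pn, cfg$parent_deletion$freq)
    del_label <- label_of(del_t[1])
    pp <- rbind(pp, data.frame(
      position = del_label,
      allele = sample(c(rep("del", nd), rep(parent_t[del_t[1]], pn - nd))),
      individual = paste0("parent_", seq_len(pn))))
    rp <- rbind(rp, data.frame(position = del_label, allele = "del",
                               individual = paste0("retro_", seq_len(pn))))
  }
  if (!is.null(cfg$repeats)) {
    pn <- pm$panel_n
    for (i in seq_along(cfg$repeats$utr3_starts)) {
      lab <- label_of(cds_end + cfg$repeats$utr3_starts[i])
      len0 <- cfg$repeats$lengths[i]
      pp <- rbind(pp, data.frame(
        position = lab,
        allele = paste0("repeat:", len0 + sample(-2:2, pn, replace = TRUE)),
        individual = paste0("parent_", seq_len(pn))))
      rp <- rbind(rp, data.frame(
        position = lab,
        allele = paste0("repeat:", len0 + sample(-2:2, pn, replace = TRUE)),
        individual = paste0("retro_", seq_len(pn))))
    }
  }
  parent_panel <- site_panel("parent", pp$position, pp$individual, pp$allele)
  retro_panel <- site_panel("retro", rp$position, rp$individual, rp$allele)

  # outgroup states at every panel position
  positions_t <- sort(unique(c(sub_truth$tpos,
                               if (length(del_t)) del_t[1],
                               if (!is.null(cfg$repeats))
                                 cds_end + cfg$repeats$utr3_starts)))
  og_states <- do.call(rbind, c(lapply(positions_t, function(t) {
    states <- vapply(outgroups, function(o) o[map[t]], "")
    data.frame(position = label_of(t), t(states))
  }), list(make.row.names = FALSE)))

  # present-day parent reference haplotypes (primary carries the deletion)
  draw_ref <- function(with_del) {
    v <- parent_t
    for (i in which(sub_truth$class == "polymorphic_parent")) {
      r <- sub_truth[i, ]
      if (stats::runif(1L) < r$freq) v[r$tpos] <- r$derived
    }
    if (with_del && length(del_t)) v <- v[-del_t]
    paste(v, collapse = "")
  }
  ref_primary <- draw_ref(TRUE)
  ref_alternate <- draw_ref(FALSE)

  # comparison-region mask: transcript positions minus repeat tracts and
  # the deletion region (indel columns excluded from L by construction)
  mask_t <- setdiff(seq_len(sl), c(repeat_t, del_t))
  mask <- coding_labels(mask_t, model)

  structure(list(
    cfg = cfg, model = model,
    sequences = list(
      ancestor_genomic = paste(ancestor_g, collapse = ""),
      parent_genomic = paste(parent_g, collapse = ""),
      parent_transcript = paste(parent_t, collapse = ""),
      origin_transcript = paste(origin_t, collapse = ""),
      retro_transcript_frame = paste(retro_t, collapse = ""),
      retro_mrna = retro_mrna, block = block, locus = locus,
      ref_primary = ref_primary, ref_alternate = ref_alternate,
      outgroups_genomic = vapply(outgroups, paste, "", collapse = "")),
    truth = truth,
    panels = list(parent = parent_panel, retro = retro_panel),
    outgroup_states = og_states,
    tsd = list(sequence = ins$tsd_seq, length = cfg$tsd_len),
    polya_length = cfg$polya_len,
    orientation = "reverse",
    element_interval = element_interval,
    junction = ee,                       # 0-based cut at the mRNA-5' boundary
    junction_es = element_interval[1] - 1L,
    motif = list(motif = cfg$motif, orientation = "reverse",
                 context_window = upstream_window,
                 context_start = motif_context_pos,
                 anchor = motif_anchor,
                 rel_start = motif_context_pos - motif_anchor),
    del_t = del_t, repeat_t = repeat_t, mask = mask,
    n_mutable_sites = length(mutable_t),
    true_age = cfg$retro_age), class = "truth_bundle")
}

# Insert `block` into the host locus with an exact TSD whose planted length
# is unambiguous: no longer duplication may match, and no motif occurrence
# may sit on the element boundary.
plant_insertion <- function(block, cfg, max_scan = 30L) {
  flank <- cfg$host$flank
  tsd <- cfg$tsd_len
  for (attempt in 1:50) {
    host <- random_bases(cfg$host$length)
    pre <- c(random_bases(flank), host, random_bases(flank))
    q <- flank + cfg$host$insertion_point
    tsd_seq <- pre[(q + 1L):(q + tsd)]
    locus_v <- c(pre[1:(q + tsd)], strsplit(block, "")[[1]],
                 pre[(q + 1L):length(pre)])
    es <- q + tsd + 1L
    ee <- q + tsd + nchar(block)
    ok <- TRUE
    for (len in seq.int(max_scan, tsd + 1L)) {
      left <- locus_v[(es - len):(es - 1L)]
      right <- locus_v[(ee + 1L):(ee + len)]
      if (all(left == right)) { ok <- FALSE; break }
    }
    near <- paste(locus_v[(ee + 1L):(ee + tsd + 5L)], collapse = "")
    if (grepl(cfg$motif, near, fixed = TRUE) ||
        grepl(revcomp(cfg$motif), near, fixed = TRUE)) ok <- FALSE
    if (ok)
      return(list(locus = paste(locus_v, collapse = ""),
                  element_interval = c(es, ee),
                  tsd_seq = paste(tsd_seq, collapse = "")))
  }
  stop("failed to plant an unambiguous TSD after 50 attempts")
}

# Remove chance occurrences of a motif (either orientation) in a region by
# mutating one base of each occurrence; `spare` protects a planted copy.
scrub_motif <- function(locus_v, motif, from, to, spare = NULL) {
  from <- max(from, 1L)
  to <- min(to, length(locus_v))
  pats <- unique(c(motif, revcomp(motif)))
  repeat {
    region <- paste(locus_v[from:to], collapse = "")
    hit <- NULL
    for (p in pats) {
      ms <- gregexpr(paste0("(?=", p, ")"), region, perl = TRUE)[[1]]
      for (m in ms) {
        if (m < 0) next
        st <- from + m - 1L
        if (!is.null(spare) && st == spare[1]) next
        hit <- c(st, nchar(p)); break
      }
      if (!is.null(hit)) break
    }
    if (is.null(hit)) return(locus_v)
    # mutate a base of the occurrence lying outside the spared copy
    cand <- hit[1]:(hit[1] + hit[2] - 1L)
    if (!is.null(spare)) cand <- cand[cand < spare[1] | cand > spare[2]]
    mid <- cand[(length(cand) + 1L) %/% 2L]
    locus_v[mid] <- other_base(locus_v[mid])
  }
}

#' Simulate short reads from the synthetic locus with recorded origins
#'
#' Reads are sampled uniformly over the retrocopy locus and, as
#' confounders, over the parent gene locus; strand is random and per-base
#' errors are applied at the configured rate. In junction-targeted mode
#' every read is constrained to span the retrocopy's 5'-insertion boundary
#' with the stated overhang.
#'
#' @param bundle A `truth_bundle`.
#' @param cfg The `sim_config` used to build it.
#' @param junction_targeted Constrain reads to the insertion boundary.
#' @param min_overhang Overhang for junction-targeted mode (default 10).
#' @return Data frame: `read_id`, `sequence`, `origin`
#'   (`retro_locus`/`parent_locus`), `start`, `strand`.
#' @export
simulate_reads <- function(bundle, cfg, junction_targeted = FALSE,
                           min_overhang = 10L) {
  set.seed(cfg$seed + 7919L)
  sources <- list(retro_locus = bundle$sequences$locus,
                  parent_locus = bundle$sequences$parent_genomic)
  n <- cfg$reads$n
  rows <- lapply(seq_len(n), function(i) {
    len <- sample(seq.int(cfg$reads$length_range[1],
                          cfg$reads$length_range[2]), 1L)
    origin <- if (junction_targeted) "retro_locus"
              else names(sources)[1L + (i %% 2L)]
    src <- sources[[origin]]
    if (junction_targeted) {
      j <- bundle$junction
      lo <- max(1L, j - len + min_overhang + 1L)
      hi <- min(nchar(src) - len + 1L, j - min_overhang + 1L)
      start <- sample(seq.int(lo, hi), 1L)
    } else {
      start <- sample(nchar(src) - len + 1L, 1L)
    }
    s <- substr(src, start, start + len - 1L)
    v <- strsplit(s, "")[[1]]
    errs <- which(stats::runif(len) < cfg$reads$error_rate)
    for (e in errs) v[e] <- other_base(v[e])
    strand <- sample(c("+", "-"), 1L)
    seqc <- paste(v, collapse = "")
    if (strand == "-") seqc <- revcomp(seqc)
    data.frame(read_id = sprintf("read%04d", i), sequence = seqc,
               origin = origin, start = start, strand = strand,
               n_errors = length(errs))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Date a synthetic bundle with the package's own classification path
#'
#' Compares the present-day parent and retrocopy mRNA sequences, classifies
#' every panel site for fixation, polarizes fixed differences with the
#' outgroup states, counts retrocopy-derived fixed substitutions over the
#' comparison mask, and applies the molecular clock.
#'
#' @param bundle A `truth_bundle`.
#' @param rate A `rate_model`.
#' @param L_target Optional number of mask positions to use (emulating a
#'   partially sequenced comparison region); default uses the full mask.
#' @return List: `k`, `L`, `estimate` (an `age_estimate`), `calls`,
#'   `ancestral`.
#' @export
date_bundle <- function(bundle, rate = rate_model(1.25e-9, 0.5e-9, 1.35e-9),
                        L_target = NULL) {
  calls <- classify_fixation(bundle$panels$parent, bundle$panels$retro)
  og <- bundle$outgroup_states
  taxa <- setdiff(names(og), "position")
  anc <- data.frame(position = og$position,
                    state = vapply(seq_len(nrow(og)), function(i) {
                      assign_ancestral(og$position[i], character(0),
                                       unlist(og[i, taxa]))$state
                    }, ""))
  mask <- bundle$mask
  if (!is.null(L_target)) mask <- mask[seq_len(min(L_target, length(mask)))]
  kl <- count_fixed_differences(calls, mask, polarize_to = anc)
  list(k = kl$k, L = kl$L,
       estimate = age_interval(kl$k, kl$L, rate),
       calls = calls, ancestral = anc)
}

#' Parameter-recovery experiment for the molecular clock
#'
#' Runs `simulate_history` -> fixation/ancestral classification ->
#' clock dating on independent replicates and reports bias, RMSE, and the
#' fraction of replicates whose rate-interval age bracket covers the true
#' age.
#'
#' @param cfg A `sim_config` (its seed anchors the replicate seeds).
#' @param replicates Number of replicates (>= 100 for coverage claims).
#' @param rate A `rate_model` used for dating.
#' @param L_target Mask positions used per replicate (default 1622,
#'   emulating a partially sequenced comparison region).
#' @return List: `table` (per-replicate true age, k, L, estimate,
#'   interval, coverage flag), `bias`, `rmse`, `coverage`.
#' @export
recovery_experiment <- function(cfg, replicates = 100L,
                                rate = rate_model(1.25e-9, 0.5e-9, 1.35e-9),
                                L_target = 1622L) {
  rows <- lapply(seq_len(replicates), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i
    b <- simulate_history(cfg_i)
    d <- date_bundle(b, rate, L_target)
    data.frame(replicate = i, true_age = b$true_age, k = d$k, L = d$L,
               estimate = d$estimate$point_age,
               age_low = d$estimate$age_low,
               age_high = d$estimate$age_high,
               covered = d$estimate$age_low <= b$true_age &
                 b$true_age <= d$estimate$age_high)
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  err <- tab$estimate - tab$true_age
  list(table = tab, bias = mean(err), rmse = sqrt(mean(err^2)),
       coverage = mean(tab$covered))
}

#' Write a truth bundle to a directory of FASTA and TSV files
#'
#' @param bundle A `truth_bundle`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- bundle$sequences
  write_fasta(c(parent_genomic = s$parent_genomic,
                parent_transcript = s$parent_transcript,
                retro_mrna = s$retro_mrna, retro_locus = s$locus,
                ref_primary = s$ref_primary,
                ref_alternate = s$ref_alternate,
                s$outgroups_genomic),
              file.path(dir, "sequences.fasta"))
  write_fasta(stats::setNames(bundle$model$sequence, bundle$model$name),
              file.path(dir, "model.fasta"))
  writeLines(c(paste("exon", bundle$model$exons[, 1], bundle$model$exons[, 2],
                     sep = "\t"),
               paste("cds_start", bundle$model$cds_start, sep = "\t"),
               paste("cds_end", bundle$model$cds_end, sep = "\t")),
             file.path(dir, "model.tsv"))
  write_tsv(bundle$truth, file.path(dir, "truth_variants.tsv"))
  write_site_panel(bundle$panels$parent, file.path(dir, "parent_panel.tsv"))
  write_site_panel(bundle$panels$retro, file.path(dir, "retro_panel.tsv"))
  write_tsv(bundle$outgroup_states, file.path(dir, "outgroup_states.tsv"))
  write_tsv(data.frame(key = c("tsd_length", "polya_length", "orientation",
                               "element_start", "element_end", "junction",
                               "true_age"),
                       value = c(bundle$tsd$length, bundle$polya_length,
                                 bundle$orientation,
                                 bundle$element_interval[1],
                                 bundle$element_interval[2],
                                 bundle$junction, bundle$true_age)),
            file.path(dir, "truth_summary.tsv"))
  writeLines(vapply(bundle$mask, identity, ""), file.path(dir, "mask.txt"))
  invisible(dir)
}
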