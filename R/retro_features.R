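#' Detect a target-site duplication flanking an inserted element
#'
#' Retroelement insertion by target-primed reverse transcription leaves a
#' short direct repeat (TSD) immediately flanking the element. The scan
#' compares the sequence immediately 5' of the element with the sequence
#' immediately 3' of it, longest candidate first, and reports the longest
#' duplication with at most `max_mismatch` mismatches; recent insertions
#' carry intact TSDs, so the default is exact matching.
#'
#' @param locus Nucleotide string containing the element and flanks.
#' @param element_interval 1-based closed interval `c(start, end)` of the
#'   inserted element within `locus`.
#' @param max_len Longest TSD length scanned (default 30).
#' @param max_mismatch Allowed mismatches (default 0).
#' @param min_len Shortest reportable TSD (default 6); shorter matches are
#'   indistinguishable from chance.
#' @return List: `sequence` (5' copy; `""` when none), `length`.
#' @export
detect_tsd <- function(locus, element_interval, max_len = 30L,
                       max_mismatch = 0L, min_len = 6L) {
  locus <- toupper(locus)
  start <- element_interval[1]; end <- element_interval[2]
  if (start - 1L < max_len || nchar(locus) - end < max_len)
    stop("input error: flanks shorter than max_len on one side")
  lv <- strsplit(substr(locus, start - max_len, start - 1L), "")[[1]]
  rv <- strsplit(substr(locus, end + 1L, end + max_len), "")[[1]]
  for (len in seq.int(max_len, min_len)) {
    left <- lv[(max_len - len + 1L):max_len]
    right <- rv[seq_len(len)]
    if (sum(left != right) <= max_mismatch)
      return(list(sequence = paste(left, collapse = ""), length = len))
  }
  list(sequence = "", length = 0L)
}

#' Detect a poly(A) remnant near the 3' end of a retrocopy
#'
#' Searches the 3'-terminal window for the longest A-rich tract meeting the
#' length and purity thresholds. The tract is trimmed to start and end on
#' an A; interior non-A bases are tolerated up to the purity limit and the
#' full tract length (interruptions included) is reported. Thresholds
#' default to values suitable for detecting decayed remnants rather than
#' pristine tails.
#'
#' @param seq Nucleotide string (retrocopy, sense strand).
#' @param search_window 3'-terminal window scanned (default 50).
#' @param min_len Minimum tract length (default 8).
#' @param min_purity Minimum A fraction (default 0.8).
#' @return Integer tract length (0 when none qualifies).
#' @export
detect_polya <- function(seq, search_window = 50L, min_len = 8L,
                         min_purity = 0.8) {
  seq <- toupper(seq)
  n <- nchar(seq)
  win <- substr(seq, max(1L, n - search_window + 1L), n)
  v <- strsplit(win, "")[[1]] == "A"
  m <- length(v)
  best <- 0L
  for (i in seq_len(m)) {
    if (!v[i]) next
    for (j in seq.int(m, i)) {
      if (!v[j]) next
      len <- j - i + 1L
      if (len <= best) break
      if (len >= min_len && sum(v[i:j]) / len >= min_purity) {
        best <- len
        break
      }
    }
  }
  best
}

#' Verify intron loss at each parent splice junction
#'
#' A retrocopy derives from the spliced mRNA, so each of the parent's
#' exon-exon junctions should occur as a contiguous fused 2k-mer in the
#' retrocopy while the corresponding exon-intron junction k-mers should
#' not. For each parent intron the status is `lost` (fused junction
#' present, both exon-intron junctions absent), `retained` (the reverse),
#' or `unknown`. Both strands of the retrocopy are searched, since
#' retrocopies commonly insert in reverse orientation.
#'
#' @param retrocopy Nucleotide string (retrocopy locus or mRNA copy).
#' @param parent A `gene_model` with at least one intron.
#' @param k Half-width of the junction k-mers (default 18: long enough to
#'   be locus-specific in a 10-kb context, short enough to tolerate nearby
#'   substitutions).
#' @return Data frame: `intron`, `status`.
#' @export
verify_intron_loss <- function(retrocopy, parent, k = 18L) {
  if (n_introns(parent) < 1L) stop("parent model has no introns")
  retrocopy <- toupper(retrocopy)
  target <- paste(retrocopy, revcomp(retrocopy), sep = "NNNN")
  ex <- parent$exons
  g <- parent$sequence
  rows <- lapply(seq_len(n_introns(parent)), function(i) {
    up_len <- ex[i, 2] - ex[i, 1] + 1L
    dn_len <- ex[i + 1L, 2] - ex[i + 1L, 1] + 1L
    if (k > up_len || k > dn_len)
      stop("input error: k exceeds a flanking exon length at intron ", i)
    exon_up <- substr(g, ex[i, 2] - k + 1L, ex[i, 2])
    exon_dn <- substr(g, ex[i + 1L, 1], ex[i + 1L, 1] + k - 1L)
    intr_start <- substr(g, ex[i, 2] + 1L, ex[i, 2] + k)
    intr_end <- substr(g, ex[i + 1L, 1] - k, ex[i + 1L, 1] - 1L)
    fused <- paste0(exon_up, exon_dn)
    ei <- paste0(exon_up, intr_start)
    ie <- paste0(intr_end, exon_dn)
    has <- function(p) grepl(p, target, fixed = TRUE)
    status <- if (has(fused) && !has(ei) && !has(ie)) "lost"
    else if (!has(fused) && has(ei) && has(ie)) "retained"
    else "unknown"
    data.frame(intron = i, status = status)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

IUPAC_REGEX <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
                 S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
                 B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]",
                 N = "[ACGT]")

#' Scan a sequence for an IUPAC motif, strand-aware
#'
#' Reports every exact IUPAC match on the forward strand and, when
#' `both_strands`, every match of the reverse complement (labeled
#' `reverse`). Positions are reported relative to a user-supplied anchor
#' (typically the start codon): the base immediately 5' of the anchor is
#' -1, the anchor base itself +1.
#'
#' @param seq Nucleotide string.
#' @param motif Motif over IUPAC codes, length >= 4.
#' @param both_strands Also scan the reverse strand (default TRUE).
#' @param anchor 1-based position in `seq` that positions are reported
#'   relative to (default 1).
#' @return Data frame: `start`, `end` (1-based in `seq`), `rel_start`,
#'   `rel_end` (anchored), `orientation` (`forward`/`reverse`).
#' @export
motif_scan <- function(seq, motif, both_strands = TRUE, anchor = 1L) {
  seq <- toupper(seq); motif <- toupper(motif)
  if (nchar(motif) < 4L) stop("motif must be at least 4 nt")
  codes <- strsplit(motif, "")[[1]]
  if (!all(codes %in% names(IUPAC_REGEX)))
    stop("invalid IUPAC code(s): ",
         paste(unique(codes[!codes %in% names(IUPAC_REGEX)]), collapse = ","))
  hits_of <- function(m, orientation) {
    mp <- Biostrings::matchPattern(m, Biostrings::DNAString(seq),
                                   fixed = FALSE)
    s <- Biostrings::start(mp); e <- Biostrings::end(mp)
    if (!length(s))
      return(data.frame(start = integer(), end = integer(),
                        rel_start = integer(), rel_end = integer(),
                        orientation = character()))
    data.frame(start = s, end = e,
               rel_start = ifelse(s >= anchor, s - anchor + 1L, s - anchor),
               rel_end = ifelse(e >= anchor, e - anchor + 1L, e - anchor),
               orientation = orientation)
  }
  out <- hits_of(motif, "forward")
  if (both_strands)
    out <- rbind(out, hits_of(revcomp(motif), "reverse"))
  out[order(out$start), , drop = FALSE]
}

#' Annotate the retrocopy hallmarks of a locus
#'
#' Bundles [detect_tsd()], [detect_polya()], [verify_intron_loss()], and
#' orientation inference (strand of the best alignment of the retrocopy
#' block to the spliced parent transcript) into one annotation.
#'
#' @param locus Nucleotide string of the insertion locus.
#' @param element_interval 1-based closed interval of the inserted block.
#' @param parent A `gene_model`.
#' @param k Junction k-mer half-width for intron-loss checks.
#' @param tsd_max_len,polya_window Passed through to the detectors.
#' @return List of class `retro_annotation`: `tsd`, `polya_length`,
#'   `junctions`, `orientation`.
#' @export
annotate_retrocopy <- function(locus, element_interval, parent, k = 18L,
                               tsd_max_len = 30L, polya_window = 50L) {
  locus <- toupper(locus)
  block <- substr(locus, element_interval[1], element_interval[2])
  transcript <- spliced_transcript(parent)
  # orientation: strand on which the parent transcript matches the block best
  fwd <- global_align(transcript, block)$score
  rev <- global_align(transcript, revcomp(block))$score
  orientation <- if (rev > fwd) "reverse" else "forward"
  mrna_copy <- if (orientation == "reverse") revcomp(block) else block
  structure(list(
    tsd = detect_tsd(locus, element_interval, max_len = tsd_max_len),
    polya_length = detect_polya(mrna_copy, search_window = polya_window),
    junctions = verify_intron_loss(block, parent, k = k),
    orientation = orientation), class = "retro_annotation")
}

#' @export
print.retro_annotation <- function(x, ...) {
  cat(sprintf(
    "<retro_annotation> TSD %d nt (%s), poly(A) %d nt, orientation %s; introns: %s\n",
    x$tsd$length, x$tsd$sequence, x$polya_length, x$orientation,
    paste(x$junctions$status, collapse = ", ")))
  invisible(x)
}
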