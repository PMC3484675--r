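#' Global alignment of two near-identical sequences
#'
#' Needleman-Wunsch global alignment with affine gap penalties, tuned for
#' paralog pairs that are >99% identical. The default scoring is
#' megablast-like; a gap of length g costs `gap_open + g * gap_extend`.
#' The engine is `Biostrings::pairwiseAlignment`, which is deterministic.
#'
#' @param seq_a,seq_b Nucleotide strings (A,C,G,T,N).
#' @param scoring Named list with `match`, `mismatch`, `gap_open`,
#'   `gap_extend` (penalties negative).
#' @param seq_a_name,seq_b_name Row names carried into the result.
#' @return An object of class `pair_alignment` with aligned rows `a` and
#'   `b` (gap character `-`) and the optimal `score`.
#' @examples
#' aln <- global_align("ACGTACGT", "ACGACGT")
#' aln$score
#' @export
global_align <- function(seq_a, seq_b,
                         scoring = list(match = 2, mismatch = -3,
                                        gap_open = -5, gap_extend = -2),
                         seq_a_name = "a", seq_b_name = "b") {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("input error: empty sequence")
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (grepl("[^ACGTN]", seq_a) || grepl("[^ACGTN]", seq_b))
    stop("input error: sequences must be over {A,C,G,T,N}")
  # N scores as a mismatch against everything, including N
  letters5 <- c("A", "C", "G", "T", "N")
  sm <- matrix(scoring$mismatch, 5, 5, dimnames = list(letters5, letters5))
  diag(sm)[1:4] <- scoring$match
  pa <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, type = "global", substitutionMatrix = sm,
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend)
  out <- structure(list(
    seq_a_name = seq_a_name, seq_b_name = seq_b_name,
    a = as.character(Biostrings::alignedPattern(pa)),
    b = as.character(Biostrings::alignedSubject(pa)),
    score = Biostrings::score(pa)), class = "pair_alignment")
  stopifnot(nchar(out$a) == nchar(out$b),
            gsub("-", "", out$a, fixed = TRUE) == seq_a,
            gsub("-", "", out$b, fixed = TRUE) == seq_b)
  out
}

#' @export
print.pair_alignment <- function(x, ...) {
  cat(sprintf("<pair_alignment> %s vs %s: %d columns, score %.1f\n",
              x$seq_a_name, x$seq_b_name, nchar(x$a), x$score))
  invisible(x)
}

#' Stack two pre-aligned equal-length rows into a pair_alignment
#' @param a,b Aligned rows (may contain `-`), equal length.
#' @param seq_a_name,seq_b_name Row names.
#' @return A `pair_alignment` (score `NA`).
#' @export
as_pair_alignment <- function(a, b, seq_a_name = "a", seq_b_name = "b") {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("aligned rows must have equal length")
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  if (any(ca == "-" & cb == "-")) stop("gap/gap column in alignment")
  structure(list(seq_a_name = seq_a_name, seq_b_name = seq_b_name,
                 a = a, b = b, score = NA_real_),
            class = "pair_alignment")
}

#' Call variants from a pairwise alignment
#'
#' Walks the alignment columns, merging runs of adjacent gap columns into
#' single indel events; every other non-identical column yields one
#' substitution (adjacent substitutions are *not* merged into MNPs).
#' Variants are reported with the ancestral allele first and positioned in
#' HGVS-style coding coordinates of the ancestral row's transcript. Indels
#' are left-aligned (shifted 5') before reporting; see
#' [normalize_repeats()] for mononucleotide-run handling.
#'
#' @param aln A `pair_alignment`.
#' @param model A `gene_model` whose spliced transcript the ancestral row
#'   represents (possibly at an offset).
#' @param polarity `"a"` or `"b"`: which row is the ancestral sequence.
#' @param transcript_offset Ancestral-row position 1 corresponds to spliced
#'   transcript position `transcript_offset + 1`.
#' @param left_align Shift indels 5' within repeated context (default TRUE;
#'   HGVS prescribes 3'-most normalization, the convention here follows the
#'   ledger style of ancestral-first variant tables).
#' @return A data frame of class `variant_table` with columns `label`,
#'   `region`, `position`, `kind`, `ancestral`, `derived`, and transcript
#'   anchors `tstart`, `tend` used by [apply_variants()].
#' @export
call_variants <- function(aln, model, polarity = c("a", "b"),
                          transcript_offset = 0L, left_align = TRUE) {
  polarity <- match.arg(polarity)
  anc <- strsplit(if (polarity == "a") aln$a else aln$b, "")[[1]]
  der <- strsplit(if (polarity == "a") aln$b else aln$a, "")[[1]]
  anc_seq <- paste(anc[anc != "-"], collapse = "")
  n_anc <- nchar(anc_seq)
  if (n_anc + transcript_offset > spliced_length(model))
    stop("coordinate error: ancestral row does not fit the model transcript")
  # ancestral-sequence position of each column (position of last anc base seen)
  apos <- cumsum(anc != "-")
  events <- list()
  i <- 1L; ncol <- length(anc)
  while (i <= ncol) {
    if (anc[i] != "-" && der[i] != "-") {
      if (anc[i] != der[i] && anc[i] != "N" && der[i] != "N")
        events[[length(events) + 1L]] <-
          list(kind = "substitution", astart = apos[i], aend = apos[i],
               ancestral = anc[i], derived = der[i])
      i <- i + 1L
    } else if (der[i] == "-") {            # deletion of ancestral bases
      j <- i
      while (j < ncol && der[j + 1L] == "-" && anc[j + 1L] != "-") j <- j + 1L
      events[[length(events) + 1L]] <-
        list(kind = "deletion", astart = apos[i], aend = apos[j],
             ancestral = paste(anc[i:j], collapse = ""), derived = "")
      i <- j + 1L
    } else {                               # insertion relative to ancestral
      j <- i
      while (j < ncol && anc[j + 1L] == "-" && der[j + 1L] != "-") j <- j + 1L
      events[[length(events) + 1L]] <-
        list(kind = "insertion", astart = apos[i], aend = apos[i],
             ancestral = "", derived = paste(der[i:j], collapse = ""))
      i <- j + 1L
    }
  }
  if (left_align) events <- lapply(events, left_align_event, anc_seq = anc_seq)
  rows <- lapply(events, function(e)
    variant_row(e, model, transcript_offset, n_anc))
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(label = character(), region = character(),
                      position = character(), kind = character(),
                      ancestral = character(), derived = character(),
                      tstart = integer(), tend = integer())
  class(out) <- c("variant_table", "data.frame")
  out
}

# Shift an indel event 5' by rotation (standard left-alignment). A deletion
# at a..b may shift left when the base at a-1 equals the last deleted base;
# an insertion anchored after base a may shift when the base at a equals the
# last inserted base.
left_align_event <- function(e, anc_seq) {
  if (e$kind == "substitution") return(e)
  alt <- if (e$kind == "deletion") e$ancestral else e$derived
  while (e$astart > 1L) {
    chk_pos <- if (e$kind == "deletion") e$astart - 1L else e$astart
    chk <- substr(anc_seq, chk_pos, chk_pos)
    if (chk != substr(alt, nchar(alt), nchar(alt))) break
    alt <- paste0(chk, substr(alt, 1L, nchar(alt) - 1L))
    e$astart <- e$astart - 1L
    e$aend <- e$aend - 1L
  }
  if (e$kind == "deletion") e$ancestral <- alt else e$derived <- alt
  e
}

variant_row <- function(e, model, offset, n_anc) {
  tstart <- e$astart + offset
  tend <- e$aend + offset
  p1 <- transcript_to_coding(tstart, model)
  region <- p1$region
  if (e$kind == "substitution") {
    label <- paste0(format(p1), e$ancestral, " > ", e$derived)
    pos <- format(p1)
  } else if (e$kind == "deletion") {
    p2 <- transcript_to_coding(tend, model)
    pos <- format(p1)
    label <- if (tstart == tend) paste0(format(p1), "del")
             else paste0(format(p1), "_", format(p2), "del")
  } else {
    p2 <- transcript_to_coding(min(tstart + 1L, n_anc + offset), model)
    pos <- format(p1)
    label <- paste0(format(p1), "_", format(p2), "ins", e$derived)
  }
  data.frame(label = label, region = region, position = pos, kind = e$kind,
             ancestral = e$ancestral, derived = e$derived,
             tstart = tstart, tend = tend)
}

#' Re-express indels inside long mononucleotide runs as repeat-length variants
#'
#' An insertion or deletion consisting of a single repeated base, flanked in
#' the ancestral sequence by a mononucleotide run of at least `min_run`
#' copies of that base, is re-labeled as a repeat-length variant carrying
#' the run's observed copy-number range (e.g. `*184T(12-15)`); such tracts
#' are conventionally excluded from substitution counts because their
#' length varies within and among species.
#'
#' @param variants A `variant_table` from [call_variants()].
#' @param ancestral_seq The ancestral (transcript) sequence the variants are
#'   anchored on.
#' @param model The `gene_model` used for coordinates.
#' @param transcript_offset As in [call_variants()].
#' @param min_run Minimum ancestral run length to trigger normalization.
#' @return The variant table with qualifying indels replaced by
#'   `repeat_length` rows (position anchored at the run's first base).
#' @export
normalize_repeats <- function(variants, ancestral_seq, model,
                              transcript_offset = 0L, min_run = 8L) {
  if (!nrow(variants)) return(variants)
  ancestral_seq <- toupper(ancestral_seq)
  chars <- strsplit(ancestral_seq, "")[[1]]
  out <- variants
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (!v$kind %in% c("deletion", "insertion")) next
    alt <- if (v$kind == "deletion") v$ancestral else v$derived
    base <- substr(alt, 1L, 1L)
    if (nchar(gsub(base, "", alt, fixed = TRUE)) > 0L) next  # not mononucleotide
    apos <- v$tstart - transcript_offset
    # extent of the ancestral run of `base` around the event
    lo <- apos
    if (v$kind == "insertion") lo <- apos + 1L  # insertion anchored before run
    while (lo > 1L && chars[lo - 1L] == base) lo <- lo - 1L
    hi <- if (v$kind == "deletion") v$tend - transcript_offset else apos
    while (hi < length(chars) && chars[hi + 1L] == base) hi <- hi + 1L
    run_len <- sum(chars[lo:hi] == base)
    if (run_len != hi - lo + 1L) next  # interrupted; treat as plain indel
    if (run_len < min_run) next
    n_anc <- run_len
    n_der <- if (v$kind == "deletion") n_anc - nchar(alt) else n_anc + nchar(alt)
    rng <- sort(c(n_anc, n_der))
    p <- transcript_to_coding(lo + transcript_offset, model)
    out$kind[i] <- "repeat_length"
    out$ancestral[i] <- paste0("repeat:", n_anc)
    out$derived[i] <- paste0("repeat:", n_der)
    out$position[i] <- format(p)
    out$region[i] <- p$region
    out$label[i] <- paste0(format(p), base, "(", rng[1], "-", rng[2], ")")
    out$tstart[i] <- lo + transcript_offset
    out$tend[i] <- hi + transcript_offset
  }
  out
}

#' Apply a variant table to the ancestral sequence
#'
#' Reconstructs the derived sequence from the ancestral row and the calls;
#' `apply_variants(anc, call_variants(aln, ...))` recovers the derived row
#' exactly, which the test suite asserts as a round-trip property.
#'
#' @param ancestral_seq Ancestral transcript sequence.
#' @param variants A `variant_table` (substitutions/deletions/insertions;
#'   repeat-length rows are rejected because the range form is lossy).
#' @param transcript_offset As in [call_variants()].
#' @return The derived nucleotide string.
#' @export
apply_variants <- function(ancestral_seq, variants, transcript_offset = 0L) {
  if (any(variants$kind == "repeat_length"))
    stop("repeat_length variants are not invertible; apply before normalization")
  s <- strsplit(toupper(ancestral_seq), "")[[1]]
  out <- as.list(s)
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    a <- v$tstart - transcript_offset
    if (v$kind == "substitution") {
      if (out[[a]] != v$ancestral) stop("ancestral allele mismatch at ", v$label)
      out[[a]] <- v$derived
    } else if (v$kind == "deletion") {
      for (p in (v$tstart:v$tend) - transcript_offset) out[[p]] <- ""
    } else {
      out[[a]] <- paste0(out[[a]], v$derived)
    }
  }
  paste(unlist(out), collapse = "")
}

#' Write / read a variant table as TSV
#'
#' Columns: label, region, position, kind, ancestral, derived, tstart, tend.
#' @param variants A `variant_table`.
#' @param path Output path.
#' @export
write_variants <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' @rdname write_variants
#' @export
read_variants <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c(rep("character", 6L),
                                          rep("integer", 2L)))
  class(out) <- c("variant_table", "data.frame")
  out
}
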