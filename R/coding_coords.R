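#' HGVS-style coding coordinates
#'
#' Positions are expressed relative to the reading frame: `c.1` is the A of
#' the initiation codon, 5' UTR positions count backward with a leading minus
#' (`c.-212`), 3' UTR positions count forward from the first base past the
#' stop codon with a leading asterisk (`c.*543`), and intronic positions carry
#' a signed offset from the nearest exonic anchor (`c.502-64`, `c.88+5`).
#'
#' @param region One of "UTR5", "CDS", "UTR3", "INTRON".
#' @param anchor Positive integer anchor (see Details).
#' @param intron_offset Signed integer, non-zero exactly when
#'   `region == "INTRON"`.
#' @return An object of class `coding_position`.
#' @export
coding_position <- function(region, anchor, intron_offset = 0L) {
  region <- match.arg(region, c("UTR5", "CDS", "UTR3", "INTRON"))
  anchor <- as.integer(anchor)
  intron_offset <- as.integer(intron_offset)
  if (is.na(anchor) || anchor < 1L) stop("anchor must be a positive integer")
  if ((intron_offset == 0L) == (region == "INTRON"))
    stop("intron_offset must be non-zero exactly when region is INTRON")
  structure(list(region = region, anchor = anchor,
                 intron_offset = intron_offset),
            class = "coding_position")
}

#' @export
format.coding_position <- function(x, ..., prefix = FALSE) {
  body <- switch(x$region,
    UTR5   = paste0("-", x$anchor),
    CDS    = as.character(x$anchor),
    UTR3   = paste0("*", x$anchor),
    INTRON = paste0(x$anchor,
                    if (x$intron_offset > 0L) "+" else "-",
                    abs(x$intron_offset)))
  if (prefix) paste0("c.", body) else body
}

#' @export
as.character.coding_position <- function(x, ...) format(x)

#' @export
print.coding_position <- function(x, ...) {
  cat("<coding_position> c.", format(x), "\n", sep = "")
  invisible(x)
}

#' Parse an HGVS-style coding coordinate label
#'
#' Accepts an optional leading `c.` and normalizes typographic dashes.
#' Grammar: `-a` (5' UTR), `a` (CDS), `*a` (3' UTR), `a+m` / `a-m` (intron,
#' offset from exonic anchor `a`).
#'
#' @param label Coordinate label, e.g. `"c.-212"`, `"759"`, `"*606"`,
#'   `"502-64"`.
#' @return A `coding_position`.
#' @examples
#' parse_coding_label("c.-212")
#' parse_coding_label("c.502-64")
#' @export
parse_coding_label <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  raw <- label
  x <- gsub("–|−|—", "-", trimws(label))
  x <- sub("^c\\.", "", x)
  m <- regmatches(x, regexec("^(-|\\*)?([0-9]+)([+-][0-9]+)?$", x))[[1]]
  if (!length(m))
    stop("malformed coding label: '", raw, "'")
  sigil <- m[2]; anchor <- as.integer(m[3]); off <- m[4]
  if (nzchar(off)) {
    if (nzchar(sigil))
      stop("malformed coding label (offset on UTR anchor): '", raw, "'")
    return(coding_position("INTRON", anchor, as.integer(off)))
  }
  region <- switch(sigil, "-" = "UTR5", "*" = "UTR3", "CDS")
  if (is.null(region)) region <- "CDS"
  coding_position(region, anchor)
}

#' Convert a coding position to a transcript (or genomic) index
#'
#' Exonic positions map to 1-based indices into the spliced transcript.
#' Intronic positions have no spliced-transcript image and are returned as
#' 1-based indices into the genomic sequence of the model.
#'
#' @param pos A `coding_position` (or label string).
#' @param model A `gene_model`.
#' @return Integer index; attribute `"space"` is `"transcript"` or
#'   `"genomic"`.
#' @export
coding_to_transcript <- function(pos, model) {
  if (is.character(pos)) pos <- parse_coding_label(pos)
  stopifnot(inherits(pos, "coding_position"), inherits(model, "gene_model"))
  sl <- spliced_length(model)
  t <- switch(pos$region,
    UTR5 = {
      if (pos$anchor > model$cds_start - 1L)
        stop("coordinate error: 5' UTR anchor ", pos$anchor,
             " exceeds UTR length ", model$cds_start - 1L)
      model$cds_start - pos$anchor
    },
    CDS = {
      if (pos$anchor > model$cds_end - model$cds_start + 1L)
        stop("coordinate error: CDS anchor ", pos$anchor, " exceeds CDS length")
      model$cds_start + pos$anchor - 1L
    },
    UTR3 = {
      if (model$cds_end + pos$anchor > sl)
        stop("coordinate error: 3' UTR anchor ", pos$anchor,
             " exceeds UTR length ", sl - model$cds_end)
      model$cds_end + pos$anchor
    },
    INTRON = {
      anchor_t <- coding_to_transcript(
        coding_position("CDS", pos$anchor), model)
      g <- transcript_to_genomic_map(model)[anchor_t]
      gi <- g + pos$intron_offset
      if (gi < 1L || gi > nchar(model$sequence))
        stop("coordinate error: intronic offset leaves the genomic sequence")
      if (gi %in% transcript_to_genomic_map(model))
        stop("coordinate error: intronic coordinate lands inside an exon")
      attr(gi, "space") <- "genomic"
      return(gi)
    })
  attr(t, "space") <- "transcript"
  t
}

#' Convert a spliced-transcript index back to a coding position
#'
#' Exact inverse of [coding_to_transcript()] for exonic positions.
#'
#' @param t 1-based index into the spliced transcript.
#' @param model A `gene_model`.
#' @return A `coding_position`.
#' @export
transcript_to_coding <- function(t, model) {
  t <- as.integer(t)
  sl <- spliced_length(model)
  if (is.na(t) || t < 1L || t > sl)
    stop("coordinate error: transcript index ", t, " outside [1, ", sl, "]")
  if (t < model$cds_start)
    coding_position("UTR5", model$cds_start - t)
  else if (t <= model$cds_end)
    coding_position("CDS", t - model$cds_start + 1L)
  else
    coding_position("UTR3", t - model$cds_end)
}

#' Convert a genomic index to a coding position (handles introns)
#'
#' Intronic positions are anchored to the nearer exon boundary; the 5' half
#' of an intron uses `+` offsets from the upstream exon, the 3' half `-`
#' offsets from the downstream exon (ties go to the upstream exon).
#'
#' @param g 1-based index into the model's genomic sequence.
#' @param model A `gene_model`.
#' @return A `coding_position`.
#' @export
genomic_to_coding <- function(g, model) {
  g <- as.integer(g)
  if (g < 1L || g > nchar(model$sequence))
    stop("coordinate error: genomic index outside the sequence")
  map <- transcript_to_genomic_map(model)
  hit <- match(g, map)
  if (!is.na(hit)) return(transcript_to_coding(hit, model))
  ex <- model$exons
  prev <- max(which(ex[, 2] < g))
  d5 <- g - ex[prev, 2]
  d3 <- ex[prev + 1L, 1] - g
  if (d5 <= d3) {
    anchor_t <- match(ex[prev, 2], map)
    anchor <- transcript_to_coding(anchor_t, model)
    coding_position("INTRON", cds_anchor(anchor, model), d5)
  } else {
    anchor_t <- match(ex[prev + 1L, 1], map)
    anchor <- transcript_to_coding(anchor_t, model)
    coding_position("INTRON", cds_anchor(anchor, model), -d3)
  }
}

# Intron anchors are CDS-numbered in this package (matching usages such as
# c.502-64); UTR-exonic anchors are converted to the nearest CDS coordinate
# representation by transcript position.
cds_anchor <- function(pos, model) {
  if (pos$region == "CDS") return(pos$anchor)
  t <- coding_to_transcript(pos, model)
  t - model$cds_start + 1L
}

# Vectorized coding labels for exonic transcript positions (hot path for
# the synthetic-data generator; semantics match transcript_to_coding +
# format on each element).
coding_labels <- function(t, model) {
  cs <- model$cds_start; ce <- model$cds_end
  out <- character(length(t))
  u5 <- t < cs; cc <- t >= cs & t <= ce; u3 <- t > ce
  out[u5] <- paste0("-", cs - t[u5])
  out[cc] <- as.character(t[cc] - cs + 1L)
  out[u3] <- paste0("*", t[u3] - ce)
  out
}

#' Codon and frame of a CDS coordinate
#'
#' @param cds_pos 1-based position within the reading frame (vectorized).
#' @param cds_length Optional CDS length for range checking.
#' @return Data frame with columns `codon` and `frame` (frame in 1:3).
#' @examples
#' codon_index(759)  # codon 253, third position
#' @export
codon_index <- function(cds_pos, cds_length = NULL) {
  cds_pos <- as.integer(cds_pos)
  if (any(is.na(cds_pos)) || any(cds_pos < 1L))
    stop("coordinate error: CDS position must be >= 1")
  if (!is.null(cds_length) && any(cds_pos > cds_length))
    stop("coordinate error: CDS position beyond CDS length")
  data.frame(codon = (cds_pos - 1L) %/% 3L + 1L,
             frame = (cds_pos - 1L) %% 3L + 1L)
}

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", "*" = "Ter")

translate_codon <- function(codon) {
  if (grepl("N", codon)) stop("codon contains N; effect call would be ambiguous")
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) stop("invalid codon: ", codon)
  aa
}

#' Coarse protein-effect label for a variant
#'
#' Substitutions inside the reading frame are translated with the standard
#' genetic code and labeled synonymous, missense, or stop-affecting;
#' insertions/deletions whose length is not a multiple of three are
#' frameshifts (multiples of three are labeled `inframe_indel`); variants
#' outside the reading frame are `noncoding`.
#'
#' @param position A `coding_position` (or label) for the variant's first
#'   affected base.
#' @param kind One of "substitution", "deletion", "insertion",
#'   "repeat_length".
#' @param ancestral,derived Allele strings (ancestral first).
#' @param cds_sequence Reading-frame nucleotide sequence (stop included).
#' @return A list with `type` and, for missense/stop calls, `aa_from`,
#'   `aa_to`, `codon`.
#' @examples
#' # third-base G>C in codon 253 of a CDS whose codon is CAG: Gln -> His
#' @export
protein_effect <- function(position, kind, ancestral, derived, cds_sequence) {
  if (is.character(position)) position <- parse_coding_label(position)
  stopifnot(inherits(position, "coding_position"))
  kind <- match.arg(kind, c("substitution", "deletion", "insertion",
                            "repeat_length"))
  if (position$region != "CDS")
    return(list(type = "noncoding"))
  if (kind == "repeat_length")
    return(list(type = "noncoding"))
  cds_sequence <- toupper(cds_sequence)
  n <- nchar(cds_sequence)
  if (position$anchor > n)
    stop("coordinate error: variant beyond CDS length")
  if (kind == "substitution") {
    if (nchar(ancestral) != 1L || nchar(derived) != 1L)
      stop("substitutions must be single-base")
    ci <- codon_index(position$anchor, n)
    codon_start <- (ci$codon - 1L) * 3L + 1L
    codon <- substr(cds_sequence, codon_start, codon_start + 2L)
    if (substr(codon, ci$frame, ci$frame) != ancestral)
      stop("ancestral allele does not match the CDS sequence at c.",
           position$anchor)
    mutated <- codon
    substr(mutated, ci$frame, ci$frame) <- derived
    aa_from <- translate_codon(codon)
    aa_to <- translate_codon(mutated)
    if (aa_from == aa_to)
      return(list(type = "synonymous", codon = ci$codon))
    if (aa_from == "*" || aa_to == "*")
      return(list(type = "stop_affecting", aa_from = AA3[[aa_from]],
                  aa_to = AA3[[aa_to]], codon = ci$codon))
    list(type = "missense", aa_from = AA3[[aa_from]], aa_to = AA3[[aa_to]],
         codon = ci$codon)
  } else {
    len <- if (kind == "deletion") nchar(ancestral) else nchar(derived)
    if (len %% 3L != 0L)
      list(type = "frameshift", codon = codon_index(position$anchor, n)$codon)
    else
      list(type = "inframe_indel", codon = codon_index(position$anchor, n)$codon)
  }
}
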