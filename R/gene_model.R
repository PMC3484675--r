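#' Construct a gene model
#'
#' A gene model anchors every coordinate conversion in the package. It holds
#' the genomic sequence of the transcribed region (transcribed strand,
#' introns included), the exon structure, and the CDS boundaries in spliced
#' transcript space. The CDS interval includes the termination codon, so a
#' reading frame of 918 nucleotide pairs spans 305 amino-acid codons plus the
#' stop.
#'
#' @param name Gene name.
#' @param sequence Nucleotide string over A,C,G,T,N: the transcribed strand in
#'   genomic orientation, introns included.
#' @param exons Two-column matrix or data.frame of 1-based closed exon
#'   intervals on `sequence`, sorted and non-overlapping.
#' @param cds_start,cds_end 1-based positions in spliced-transcript space
#'   delimiting the reading frame, stop codon included.
#' @return An object of class `gene_model`.
#' @examples
#' gm <- gene_model("toy", paste(rep("ACGT", 30), collapse = ""),
#'                  exons = cbind(c(1, 61), c(40, 120)),
#'                  cds_start = 10, cds_end = 69)
#' spliced_length(gm)
#' @export
gene_model <- function(name, sequence, exons, cds_start, cds_end) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    stop("sequence contains characters outside {A,C,G,T,N}")
  exons <- as.matrix(exons)
  if (ncol(exons) != 2L) stop("exons must have two columns (start, end)")
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  n <- nchar(sequence)
  if (any(exons[, 1] > exons[, 2]))
    stop("exon start greater than end")
  if (any(exons < 1L) || any(exons > n))
    stop("exon interval outside [1, length(sequence)]")
  if (nrow(exons) > 1L) {
    if (is.unsorted(exons[, 1], strictly = TRUE))
      stop("exons must be sorted by start")
    if (any(exons[-1L, 1] <= exons[-nrow(exons), 2]))
      stop("exons overlap or touch out of order")
  }
  sl <- sum(exons[, 2] - exons[, 1] + 1L)
  cds_start <- as.integer(cds_start); cds_end <- as.integer(cds_end)
  cds_len <- cds_end - cds_start + 1L
  if (cds_start < 1L || cds_end > sl)
    stop("CDS interval outside the spliced transcript")
  if (cds_len < 6L || cds_len %% 3L != 0L)
    stop("CDS length must be a multiple of 3 and at least 6")
  structure(list(name = name, sequence = sequence, exons = exons,
                 cds_start = cds_start, cds_end = cds_end),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s: %d nt genomic, %d exon(s), CDS %d..%d (%d nt) in %d nt spliced transcript\n",
              x$name, nchar(x$sequence), nrow(x$exons),
              x$cds_start, x$cds_end, x$cds_end - x$cds_start + 1L,
              spliced_length(x)))
  invisible(x)
}

#' Spliced transcript length of a gene model
#' @param model A `gene_model`.
#' @return Integer length of the exon-joined transcript.
#' @export
spliced_length <- function(model) {
  sum(model$exons[, 2] - model$exons[, 1] + 1L)
}

#' Extract the spliced transcript sequence
#' @param model A `gene_model`.
#' @return Nucleotide string of the exon-joined transcript.
#' @export
spliced_transcript <- function(model) {
  paste(substring(model$sequence, model$exons[, 1], model$exons[, 2]),
        collapse = "")
}

#' Extract the CDS sequence (stop codon included)
#' @param model A `gene_model`.
#' @return Nucleotide string of the reading frame.
#' @export
cds_sequence <- function(model) {
  substr(spliced_transcript(model), model$cds_start, model$cds_end)
}

n_introns <- function(model) nrow(model$exons) - 1L

# Map each spliced-transcript position to its genomic position.
transcript_to_genomic_map <- function(model) {
  unlist(lapply(seq_len(nrow(model$exons)), function(i)
    seq.int(model$exons[i, 1], model$exons[i, 2])), use.names = FALSE)
}

#' Read a gene model from FASTA plus a tab-separated annotation sidecar
#'
#' The sidecar holds one `exon<TAB>start<TAB>end` line per exon and single
#' `cds_start` / `cds_end` lines giving the reading-frame bounds in spliced
#' coordinates. GFF3 import is out of scope by design.
#'
#' @param fasta_path Path to a single-record FASTA file.
#' @param annot_path Path to the annotation sidecar.
#' @return A `gene_model`.
#' @export
read_gene_model <- function(fasta_path, annot_path) {
  seqs <- read_fasta(fasta_path)
  if (length(seqs) != 1L) stop("gene-model FASTA must hold exactly one record")
  lines <- readLines(annot_path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  key <- vapply(fields, `[`, "", 1L)
  ex <- fields[key == "exon"]
  if (!length(ex)) stop("annotation sidecar has no exon lines")
  exons <- t(vapply(ex, function(f) as.integer(f[2:3]), integer(2)))
  grab <- function(k) {
    i <- which(key == k)
    if (length(i) != 1L) stop("annotation sidecar needs exactly one '", k, "' line")
    as.integer(fields[[i]][2])
  }
  gene_model(names(seqs), unname(seqs), exons, grab("cds_start"), grab("cds_end"))
}
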