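#' Reverse complement of a nucleotide string
#' @param seq Nucleotide string (IUPAC codes allowed).
#' @return The reverse complement.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Read a FASTA file as a named character vector
#'
#' Sequences are upper-cased; wrapping and case differences in the input
#' are normalized away, so `write_fasta(read_fasta(p))` is the identity on
#' the sequence content.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("input error: no such file: ", path)
  x <- Biostrings::readBStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write sequences as FASTA, wrapped at 60 columns
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs))) stop("sequences must be named")
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- toupper(seqs[[i]])
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}

#' Read short reads from FASTA or FASTQ (qualities ignored)
#' @param path File path; format sniffed from the first character.
#' @return Named character vector of read sequences.
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) stop("input error: no such file: ", path)
  first <- substr(readLines(path, n = 1L), 1L, 1L)
  x <- if (first == "@") Biostrings::readBStringSet(path, format = "fastq")
       else Biostrings::readBStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Read / write generic TSV tables (lossless round-trip)
#' @param path File path.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("input error: no such file: ", path)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_tsv
#' @param df Data frame to write.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse a plain-text key = value configuration file
#'
#' Lines are `key = value`; `#` starts a comment. Dotted keys express
#' grouping (`rate.point = 1.25e-9`). Values that parse as numbers are
#' returned numeric; whitespace-separated values become vectors. Unknown
#' keys are rejected when `allowed` is given.
#'
#' @param path File path.
#' @param allowed Optional character vector of permitted keys.
#' @return Named list.
#' @export
read_config <- function(path, allowed = NULL) {
  if (!file.exists(path)) stop("input error: no such file: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (!length(m)) stop("malformed config line: '", ln, "'")
    key <- m[2]
    if (!is.null(allowed) && !key %in% allowed)
      stop("unknown config key: '", key, "'")
    vals <- strsplit(trimws(m[3]), "\\s+")[[1]]
    nums <- suppressWarnings(as.numeric(vals))
    out[[key]] <- if (!anyNA(nums)) nums else vals
  }
  out
}

#' Read a presence/absence table for phylogenetic bounds
#'
#' Config keys of the form `presence.<taxon> = <status> <div_low>
#' <div_high>` (status `present`/`absent`/`unknown`, divergences in
#' years).
#'
#' @param cfg Named list from [read_config()] (or a path).
#' @return Data frame suitable for [presence_bounds()].
#' @export
presence_table_from_config <- function(cfg) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  keys <- grep("^presence\\.", names(cfg), value = TRUE)
  if (!length(keys)) stop("no presence.<taxon> keys in config")
  rows <- lapply(keys, function(k) {
    v <- cfg[[k]]
    data.frame(taxon = sub("^presence\\.", "", k),
               status = as.character(v[1]),
               div_low = as.numeric(v[2]), div_high = as.numeric(v[3]))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Build a rate model from a config list
#' @param cfg Named list with `rate.point`, optional `rate.low`,
#'   `rate.high` (or a config file path).
#' @return A `rate_model`.
#' @export
rate_model_from_config <- function(cfg) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  p <- cfg[["rate.point"]]
  if (is.null(p)) stop("config lacks rate.point")
  rate_model(p,
             low = if (!is.null(cfg[["rate.low"]])) cfg[["rate.low"]] else p,
             high = if (!is.null(cfg[["rate.high"]])) cfg[["rate.high"]] else p)
}
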