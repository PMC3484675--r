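#' A set of pre-aligned near-identical paralogs
#'
#' Members are gap-padded to a common coordinate frame; one member is the
#' focal paralog whose diagnostic sites and reads are of interest.
#'
#' @param members Named character vector of aligned sequences (gap `-`),
#'   all the same length.
#' @param focal Name of the focal member.
#' @return An object of class `paralog_set`.
#' @export
paralog_set <- function(members, focal) {
  stopifnot(is.character(members), !is.null(names(members)))
  members <- toupper(members)
  if (length(unique(nchar(members))) != 1L)
    stop("all members must share the aligned length")
  if (!focal %in% names(members)) stop("focal member not in the set")
  structure(list(members = members, focal = focal), class = "paralog_set")
}

#' Find sites diagnostic for the focal paralog
#'
#' Returns exactly the aligned columns where the focal member's allele
#' differs from *every* other member's allele (gaps count as alleles). A
#' read covering such a column with the focal allele cannot have arisen
#' from any other member of the family.
#'
#' @param pset A `paralog_set` with at least two members.
#' @return Data frame: `column` (aligned coordinate), `allele` (focal).
#' @export
find_diagnostic_sites <- function(pset) {
  if (length(pset$members) < 2L)
    stop("input error: need at least two members")
  mat <- do.call(rbind, strsplit(unname(pset$members), ""))
  rownames(mat) <- names(pset$members)
  focal <- mat[pset$focal, ]
  others <- mat[setdiff(rownames(mat), pset$focal), , drop = FALSE]
  diff_all <- colSums(others == rep(focal, each = nrow(others))) == 0L
  data.frame(column = which(diff_all), allele = focal[diff_all])
}

hamming_profile <- function(readv, memv) {
  n <- length(memv); len <- length(readv)
  if (len > n) return(Inf)
  has_n <- any(readv == "N")
  if (!has_n) {
    d <- Biostrings::neditStartingAt(
      Biostrings::DNAString(paste(readv, collapse = "")),
      Biostrings::DNAString(paste(memv, collapse = "")),
      starting.at = seq_len(n - len + 1L), with.indels = FALSE)
    return(min(d))
  }
  # N in a read matches nothing (adds one mismatch everywhere)
  best <- Inf
  for (s in seq_len(n - len + 1L)) {
    win <- memv[s:(s + len - 1L)]
    d <- sum(win != readv | readv == "N")
    if (d < best) best <- d
  }
  best
}

edit_profile <- function(read, mem) {
  # best semi-global (read inside member) edit distance
  pa <- Biostrings::pairwiseAlignment(
    read, mem, type = "global-local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 0, mismatch = -1, baseOnly = FALSE),
    gapOpening = 0, gapExtension = 1)
  -Biostrings::score(pa)
}

#' Assign a short read among near-identical paralogs
#'
#' For each member the read is placed gaplessly at every offset in both
#' orientations and the minimum Hamming distance recorded. The verdict is
#' `unique` when a single member attains the minimum and the runner-up is
#' at least `margin` mismatches worse, `tied` when several members attain
#' it, and `unassigned` otherwise. An edit-distance mode
#' (`mode = "edit"`) allows indels in the placement.
#'
#' @param read Nucleotide string (length >= 20).
#' @param pset A `paralog_set` (members are degapped before placement).
#' @param margin Required distance margin for a conclusive call
#'   (default 1: the read must be strictly closer to one member).
#' @param mode `"hamming"` (default) or `"edit"`.
#' @param read_id Identifier carried into the result.
#' @return A list of class `read_assignment`: `read_id`,
#'   `per_member_mismatches`, `verdict` (`"unique"`, `"tied"`,
#'   `"unassigned"`), `best` (member name(s)).
#' @export
assign_read <- function(read, pset, margin = 1L,
                        mode = c("hamming", "edit"), read_id = "read") {
  mode <- match.arg(mode)
  read <- toupper(read)
  if (nchar(read) < 20L)
    stop("input error: read shorter than 20 nt")
  degapped <- gsub("-", "", pset$members, fixed = TRUE)
  if (nchar(read) > max(nchar(degapped)))
    stop("input error: read longer than the aligned members")
  rc <- revcomp(read)
  readv <- strsplit(read, "")[[1]]
  rcv <- strsplit(rc, "")[[1]]
  d <- vapply(degapped, function(mem) {
    if (mode == "hamming") {
      memv <- strsplit(mem, "")[[1]]
      min(hamming_profile(readv, memv), hamming_profile(rcv, memv))
    } else {
      min(edit_profile(read, mem), edit_profile(rc, mem))
    }
  }, numeric(1))
  best <- min(d)
  winners <- names(d)[d == best]
  second <- if (length(d) > 1L) sort(d)[2L] else Inf
  verdict <- if (length(winners) > 1L) "tied"
  else if (second - best >= margin) "unique"
  else "unassigned"
  structure(list(read_id = read_id, per_member_mismatches = d,
                 verdict = verdict, best = winners),
            class = "read_assignment")
}

#' @export
print.read_assignment <- function(x, ...) {
  cat(sprintf("<read_assignment> %s: %s (%s); distances: %s\n", x$read_id,
              x$verdict, paste(x$best, collapse = ","),
              paste(names(x$per_member_mismatches),
                    x$per_member_mismatches, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Assign a batch of reads and tabulate the verdicts
#'
#' @param reads Named character vector of reads.
#' @param pset A `paralog_set`.
#' @inheritParams assign_read
#' @return Data frame: `read_id`, `verdict`, `best`, `best_distance`,
#'   `second_distance`.
#' @export
assign_reads <- function(reads, pset, margin = 1L,
                         mode = c("hamming", "edit")) {
  mode <- match.arg(mode)
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  rows <- lapply(seq_along(reads), function(i) {
    a <- assign_read(reads[[i]], pset, margin = margin, mode = mode,
                     read_id = ids[i])
    d <- sort(a$per_member_mismatches)
    data.frame(read_id = a$read_id, verdict = a$verdict,
               best = paste(a$best, collapse = ","),
               best_distance = d[1L],
               second_distance = if (length(d) > 1L) d[2L] else NA_real_)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Does a read span a junction in a reference?
#'
#' The read is placed gaplessly on the reference (both orientations, best
#' Hamming placement); it spans the junction when the placement covers at
#' least `min_overhang` bases on each side of the cut.
#'
#' @param read Nucleotide string.
#' @param reference Nucleotide string containing the junction.
#' @param junction 0-based cut index (the junction lies between reference
#'   positions `junction` and `junction + 1`).
#' @param min_overhang Minimum covered bases on each side (default 10).
#' @return List: `spans` (logical), `start` (1-based placement start),
#'   `strand`, `mismatches`, `left_overhang`, `right_overhang`.
#' @export
spans_junction <- function(read, reference, junction, min_overhang = 10L) {
  read <- toupper(read); reference <- toupper(reference)
  if (junction < 0L || junction > nchar(reference))
    stop("junction outside the reference")
  refv <- strsplit(reference, "")[[1]]
  place <- function(rd) {
    rv <- strsplit(rd, "")[[1]]
    n <- length(refv); len <- length(rv)
    if (len > n) return(NULL)
    if (any(rv == "N")) {
      d <- vapply(seq_len(n - len + 1L), function(s)
        sum(refv[s:(s + len - 1L)] != rv | rv == "N"), numeric(1))
    } else {
      d <- Biostrings::neditStartingAt(
        Biostrings::DNAString(rd), Biostrings::DNAString(reference),
        starting.at = seq_len(n - len + 1L), with.indels = FALSE)
    }
    list(start = which.min(d), mism = min(d))
  }
  fwd <- place(read)
  rev <- place(revcomp(read))
  if (is.null(fwd)) stop("input error: read longer than reference")
  use_rev <- rev$mism < fwd$mism
  p <- if (use_rev) rev else fwd
  len <- nchar(read)
  left <- junction - (p$start - 1L)
  right <- (p$start + len - 1L) - junction
  list(spans = left >= min_overhang && right >= min_overhang,
       start = p$start, strand = if (use_rev) "-" else "+",
       mismatches = p$mism, left_overhang = left, right_overhang = right)
}
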