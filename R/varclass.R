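#' Build a site panel
#'
#' A site panel records, for one paralog, the alleles observed at coding
#' positions across a set of individuals or sources (reference assemblies
#' and panel sequences). Alleles are drawn from `A,C,G,T`, `del`, or
#' `repeat:n` for mononucleotide-run copy numbers; `N` observations are
#' ignored (missing data, never counted as an allele).
#'
#' @param paralog Paralog name.
#' @param position Coding-position labels (character).
#' @param individual Individual or source identifier.
#' @param allele Observed allele.
#' @param source `"reference_assembly"` or `"panel_sequence"`.
#' @return A data frame of class `site_panel`.
#' @export
site_panel <- function(paralog, position, individual, allele,
                       source = "panel_sequence") {
  position <- as.character(position)
  out <- data.frame(paralog = rep_len(paralog, length(position)),
                    position = position,
                    individual = individual, allele = toupper(allele),
                    source = rep_len(source, length(position)))
  bad <- !grepl("^([ACGTN]|DEL|REPEAT:[0-9]+)$", out$allele)
  if (any(bad)) stop("invalid allele(s): ", paste(unique(out$allele[bad]),
                                                  collapse = ", "))
  out$allele[out$allele == "DEL"] <- "del"
  out$allele <- sub("^REPEAT:", "repeat:", out$allele)
  class(out) <- c("site_panel", "data.frame")
  out
}

panel_alleles <- function(panel) {
  keep <- panel$allele != "N"
  split(panel$allele[keep], panel$position[keep])
}

#' Classify sites as polymorphic, fixed, or shared across two paralogs
#'
#' A site is polymorphic within a paralog iff at least two distinct alleles
#' are observed there; a fixed difference requires both paralogs monomorphic
#' with different alleles. Positions observed in only one paralog are
#' `unresolved`. Fixation is always relative to the observed panel, so the
#' panel size behind each call is reported alongside it ("evidently fixed"
#' stays evidence-qualified).
#'
#' @param parent_panel,retro_panel `site_panel` data frames (one paralog
#'   each).
#' @return Data frame of class `fixation_calls`: `position`, `status`,
#'   `parent_alleles`, `retro_alleles`, `n_parent`, `n_retro`,
#'   `is_substitution` (both alleles single nucleotides).
#' @export
classify_fixation <- function(parent_panel, retro_panel) {
  if (!nrow(parent_panel) || !nrow(retro_panel))
    stop("input error: empty panel")
  pa <- panel_alleles(parent_panel)
  ra <- panel_alleles(retro_panel)
  positions <- union(names(pa), names(ra))
  rows <- lapply(positions, function(pos) {
    p <- pa[[pos]]; r <- ra[[pos]]
    np <- length(p); nr <- length(r)
    pu <- unique(p); ru <- unique(r)
    status <-
      if (np == 0L || nr == 0L) "unresolved"
      else if (length(pu) > 1L && length(ru) > 1L) "polymorphic_in_both"
      else if (length(pu) > 1L) "polymorphic_in_parent"
      else if (length(ru) > 1L) "polymorphic_in_retrocopy"
      else if (pu == ru) "shared_invariant"
      else "fixed_difference"
    is_sub <- length(pu) == 1L && length(ru) == 1L &&
      all(nchar(c(pu, ru)) == 1L) && all(c(pu, ru) %in% c("A", "C", "G", "T"))
    data.frame(position = pos, status = status,
               parent_alleles = paste(sort(pu), collapse = "/"),
               retro_alleles = paste(sort(ru), collapse = "/"),
               n_parent = np, n_retro = nr, is_substitution = is_sub)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("fixation_calls", "data.frame")
  out
}

#' Assign the ancestral state of a site by outgroup unanimity
#'
#' The ancestral state is the unanimous state of all non-missing outgroups;
#' any disagreement yields `ambiguous` (unanimity, not majority: at this
#' scale a single conflicting outgroup makes the site unresolvable).
#' Mononucleotide repeat-length sites are always `ambiguous` because copy
#' numbers vary within and among species. All outgroups missing yields an
#' `unresolved` call rather than an error.
#'
#' @param position Coding-position label.
#' @param focal_states Character vector of alleles seen in the focal
#'   paralogs (carried into the call for reporting).
#' @param outgroups Named character vector, taxon -> allele (`NA` or `"N"`
#'   for missing).
#' @param is_repeat Logical: is this a repeat-length site?
#' @return A list of class `ancestral_call`: `position`, `state`
#'   (nucleotide, `"ambiguous"`, or `"unresolved"`), `basis`.
#' @export
assign_ancestral <- function(position, focal_states, outgroups,
                             is_repeat = FALSE) {
  og <- toupper(as.character(outgroups))
  names(og) <- names(outgroups)
  og[og == "N"] <- NA_character_
  obs <- og[!is.na(og)]
  state <-
    if (is_repeat || any(startsWith(obs, "REPEAT"))) "ambiguous"
    else if (!length(obs)) "unresolved"
    else if (length(unique(obs)) == 1L) unname(obs[1L])
    else "ambiguous"
  structure(list(position = as.character(position),
                 focal_states = focal_states,
                 state = state, basis = og),
            class = "ancestral_call")
}

#' @export
print.ancestral_call <- function(x, ...) {
  cat(sprintf("<ancestral_call> %s: %s (outgroups: %s)\n", x$position,
              x$state,
              paste(names(x$basis), x$basis, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Reconstruct the parent allele at retrotransposition time
#'
#' Merges two reference sequences of the parent gene by converting every
#' substitution difference between them to its ancestral form. Discordant
#' substitution positions lacking a resolvable ancestral state are emitted
#' as `N` and counted; indel discordances are flagged and their regions
#' recorded (the primary reference's allele is kept there).
#'
#' @param ref_primary,ref_alternate Nucleotide strings (transcript space).
#' @param ancestral_calls List of `ancestral_call` objects (or a data frame
#'   with `position` and `state`), keyed by coding-position label.
#' @param model A `gene_model` for coordinates.
#' @param transcript_offset As in [call_variants()].
#' @return List: `sequence`, `n_ambiguous`, `excluded_regions` (data frame
#'   of indel-discordant transcript intervals), `flagged`.
#' @export
reconstruct_parent <- function(ref_primary, ref_alternate, ancestral_calls,
                               model, transcript_offset = 0L) {
  aln <- global_align(ref_primary, ref_alternate,
                      seq_a_name = "primary", seq_b_name = "alternate")
  vars <- call_variants(aln, model, polarity = "a",
                        transcript_offset = transcript_offset)
  states <- ancestral_states_by_position(ancestral_calls)
  s <- strsplit(toupper(ref_primary), "")[[1]]
  n_ambiguous <- 0L
  excluded <- list()
  for (i in seq_len(nrow(vars))) {
    v <- vars[i, ]
    if (v$kind != "substitution") {
      excluded[[length(excluded) + 1L]] <-
        data.frame(tstart = v$tstart, tend = v$tend, label = v$label)
      next
    }
    st <- states[[v$position]]
    apos <- v$tstart - transcript_offset
    if (is.null(st))
      stop("no ancestral call for inter-reference substitution at ",
           v$position)
    if (st %in% c("ambiguous", "unresolved")) {
      s[apos] <- "N"
      n_ambiguous <- n_ambiguous + 1L
    } else {
      s[apos] <- st
    }
  }
  excluded <- if (length(excluded))
    do.call(rbind, c(excluded, list(make.row.names = FALSE)))
  else data.frame(tstart = integer(), tend = integer(), label = character())
  list(sequence = paste(s, collapse = ""), n_ambiguous = n_ambiguous,
       excluded_regions = excluded, flagged = nrow(excluded) > 0L)
}

ancestral_states_by_position <- function(calls) {
  if (is.data.frame(calls))
    return(stats::setNames(as.list(calls$state), calls$position))
  if (inherits(calls, "ancestral_call")) calls <- list(calls)
  stats::setNames(lapply(calls, `[[`, "state"),
                  vapply(calls, `[[`, "", "position"))
}

#' Count fixed differences over a comparison region
#'
#' `k` is the number of fixed-difference substitution calls whose position
#' falls inside the mask; `L` is the number of masked positions. Repeat
#' tracts and indel columns are excluded from `L` by constructing the mask
#' without them. When `polarize_to` is supplied (ancestral calls), only
#' fixed differences where the retrocopy carries the derived allele are
#' counted — the molecular clock counts substitutions accumulated on the
#' retrocopy lineage since the parent allele it arose from.
#'
#' @param calls A `fixation_calls` data frame.
#' @param region_mask Character vector of coding-position labels defining
#'   the compared region.
#' @param polarize_to Optional ancestral calls (list or data frame); when
#'   given, a fixed difference is counted only if the parent allele equals
#'   the ancestral state.
#' @return List `(k, L)`.
#' @export
count_fixed_differences <- function(calls, region_mask, polarize_to = NULL) {
  region_mask <- unique(as.character(region_mask))
  L <- length(region_mask)
  if (!L) return(list(k = 0L, L = 0L))
  fixed <- calls[calls$status == "fixed_difference" & calls$is_substitution &
                   calls$position %in% region_mask, , drop = FALSE]
  if (!is.null(polarize_to) && nrow(fixed)) {
    states <- ancestral_states_by_position(polarize_to)
    keep <- vapply(seq_len(nrow(fixed)), function(i) {
      st <- states[[fixed$position[i]]]
      if (is.null(st) || st %in% c("ambiguous", "unresolved")) return(FALSE)
      identical(fixed$parent_alleles[i], st)
    }, logical(1))
    fixed <- fixed[keep, , drop = FALSE]
  }
  list(k = nrow(fixed), L = L)
}

#' Read / write site panels as TSV
#'
#' Columns: paralog, position, individual, allele, source. Round-trips
#' losslessly.
#' @param path File path.
#' @export
read_site_panel <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  site_panel(df$paralog, df$position, df$individual, df$allele, df$source)
}

#' @rdname read_site_panel
#' @param panel A `site_panel`.
#' @export
write_site_panel <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a published-style variant ledger as a pair of site panels
#'
#' The ledger format is one row per variant position with the alleles
#' observed in each paralog; polymorphic sites carry both alleles
#' separated by a forward slash, ancestral first. Each allele listed
#' becomes one panel observation, so a slashed entry is polymorphic and a
#' plain entry monomorphic. The package ships the ledger of variants
#' between the human NANOG gene and its NANOGP8 retrocopy as
#' `system.file("extdata", "nanog_nanogp8_ledger.tsv", package =
#' "retrodate")`.
#'
#' @param path TSV with columns `position`, `parent`, `retro`.
#' @return List: `parent` and `retro` site panels, plus `positions` and
#'   `in_reading_frame` (positions without a 5'/3' UTR sigil).
#' @export
read_variant_ledger <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  expand <- function(paralog, col) {
    rows <- lapply(seq_len(nrow(df)), function(i) {
      alleles <- strsplit(df[[col]][i], "/", fixed = TRUE)[[1]]
      data.frame(position = df$position[i], allele = alleles,
                 individual = paste0(col, "_obs", seq_along(alleles)))
    })
    long <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    site_panel(paralog, long$position, long$individual, long$allele,
               source = "reference_assembly")
  }
  list(parent = expand("parent", "parent"),
       retro = expand("retro", "retro"),
       positions = df$position,
       in_reading_frame = !grepl("^[-*]", df$position))
}

#' Write fixation calls as TSV
#' @param calls A `fixation_calls` data frame.
#' @param path File path.
#' @export
write_fixation_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
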