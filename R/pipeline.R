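#' Run the full retrocopy-dating pipeline on a bundle
#'
#' Executes the analysis end to end: merge the two parent reference
#' haplotypes into the ancestral parent allele, align it against the
#' retrocopy mRNA and call/normalize variants, classify every panel site
#' for fixation, polarize with outgroup states, count retrocopy-derived
#' fixed substitutions over the comparison mask, date with the molecular
#' clock, reconcile against phylogenetic presence/absence bounds, and
#' annotate the insertion hallmarks. Intermediates are written as TSV when
#' `out_dir` is given.
#'
#' @param bundle A `truth_bundle` from [simulate_history()] or a list from
#'   [load_bundle()].
#' @param rate A `rate_model`.
#' @param presence Optional presence/absence data frame for
#'   [presence_bounds()].
#' @param L_target Optional number of mask positions (partial sequencing).
#' @param out_dir Optional output directory for intermediates.
#' @param reads Optional read table from [simulate_reads()]; junction
#'   spanning is tallied when present.
#' @return A list of class `pipeline_summary`.
#' @export
run_pipeline <- function(bundle, rate = rate_model(1.25e-9, 0.5e-9, 1.35e-9),
                         presence = NULL, L_target = NULL, out_dir = NULL,
                         reads = NULL) {
  s <- bundle$sequences
  model <- bundle$model
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  og <- bundle$outgroup_states
  taxa <- setdiff(names(og), "position")
  anc <- stage("ancestral", data.frame(
    position = og$position,
    state = vapply(seq_len(nrow(og)), function(i) {
      assign_ancestral(og$position[i], character(0),
                       unlist(og[i, taxa]))$state
    }, "")))
  recon <- stage("reconstruct_parent",
    reconstruct_parent(s$ref_alternate, s$ref_primary, anc, model))
  aln <- stage("align",
    global_align(recon$sequence, s$retro_mrna,
                 seq_a_name = "parent_ancestral", seq_b_name = "retrocopy"))
  vars <- stage("call_variants", {
    v <- call_variants(aln, model, polarity = "a")
    normalize_repeats(v, recon$sequence, model)
  })
  calls <- stage("classify_fixation",
    classify_fixation(bundle$panels$parent, bundle$panels$retro))
  mask <- bundle$mask
  if (!is.null(L_target)) mask <- mask[seq_len(min(L_target, length(mask)))]
  kl <- stage("count", count_fixed_differences(calls, mask,
                                               polarize_to = anc))
  clock <- stage("date", age_interval(kl$k, kl$L, rate))
  bounds <- if (!is.null(presence)) stage("bounds", presence_bounds(presence))
  consensus <- if (!is.null(bounds)) combine_evidence(clock, bounds)
  features <- stage("features",
    annotate_retrocopy(s$locus, bundle$element_interval, model))
  junction_reads <- NULL
  if (!is.null(reads)) {
    junction_reads <- stage("reads", {
      sp <- vapply(reads$sequence, function(r)
        spans_junction(r, s$locus, bundle$junction)$spans, logical(1))
      data.frame(read_id = reads$read_id, spans_junction = unname(sp))
    })
  }
  out <- structure(list(
    variants = vars, calls = calls, ancestral = anc,
    reconstruction = list(n_ambiguous = recon$n_ambiguous,
                          flagged = recon$flagged,
                          excluded_regions = recon$excluded_regions),
    k = kl$k, L = kl$L, clock = clock, bounds = bounds,
    consensus = consensus, features = features,
    junction_reads = junction_reads), class = "pipeline_summary")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_variants(vars, file.path(out_dir, "variants.tsv"))
    write_fixation_calls(calls, file.path(out_dir, "fixation_calls.tsv"))
    write_tsv(anc, file.path(out_dir, "ancestral_calls.tsv"))
    jsonlite::write_json(summary_list(out),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

summary_list <- function(x) {
  list(k = x$k, L = x$L,
       point_age_years = x$clock$point_age,
       point_age_my = format_age_my(x$clock$point_age),
       age_low_my = format_age_my(x$clock$age_low),
       age_high_my = format_age_my(x$clock$age_high),
       bounds_lower = if (!is.null(x$bounds)) x$bounds$lower,
       bounds_upper = if (!is.null(x$bounds)) x$bounds$upper,
       consistent = if (!is.null(x$consensus)) x$consensus$consistent,
       tsd_length = x$features$tsd$length,
       polya_length = x$features$polya_length,
       orientation = x$features$orientation,
       introns = paste(x$features$junctions$status, collapse = ","))
}

#' @export
print.pipeline_summary <- function(x, ...) {
  cat(sprintf("<pipeline_summary> k=%d over L=%d sites\n", x$k, x$L))
  cat(sprintf("  clock: %s My (interval %s-%s My)\n",
              format_age_my(x$clock$point_age),
              format_age_my(x$clock$age_low),
              format_age_my(x$clock$age_high)))
  if (!is.null(x$bounds))
    cat(sprintf("  bounds: %.2g-%.2g years%s\n", x$bounds$lower,
                x$bounds$upper,
                if (isTRUE(x$consensus$consistent)) " (consistent)" else ""))
  cat(sprintf("  features: TSD %d nt, poly(A) %d nt, orientation %s\n",
              x$features$tsd$length, x$features$polya_length,
              x$features$orientation))
  invisible(x)
}

#' Load a bundle directory written by [write_bundle()]
#'
#' Restores the pieces [run_pipeline()] needs (sequences, gene model,
#' panels, outgroup states, mask, element interval); the generator's truth
#' table is reloaded as well when present.
#'
#' @param dir Bundle directory.
#' @return A list shaped like a `truth_bundle`.
#' @export
load_bundle <- function(dir) {
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("input error: bundle lacks ", f)
    p
  }
  seqs <- read_fasta(need("sequences.fasta"))
  model <- read_gene_model(need("model.fasta"), need("model.tsv"))
  ts <- read_tsv(need("truth_summary.tsv"))
  val <- stats::setNames(ts$value, ts$key)
  taxa <- setdiff(names(seqs),
                  c("parent_genomic", "parent_transcript", "retro_mrna",
                    "retro_locus", "ref_primary", "ref_alternate"))
  list(
    sequences = list(parent_genomic = seqs[["parent_genomic"]],
                     parent_transcript = seqs[["parent_transcript"]],
                     retro_mrna = seqs[["retro_mrna"]],
                     locus = seqs[["retro_locus"]],
                     ref_primary = seqs[["ref_primary"]],
                     ref_alternate = seqs[["ref_alternate"]],
                     outgroups_genomic = seqs[taxa]),
    model = model,
    panels = list(parent = read_site_panel(need("parent_panel.tsv")),
                  retro = read_site_panel(need("retro_panel.tsv"))),
    outgroup_states = read_tsv(need("outgroup_states.tsv")),
    mask = readLines(need("mask.txt")),
    element_interval = as.integer(c(val[["element_start"]],
                                    val[["element_end"]])),
    junction = as.integer(val[["junction"]]),
    truth = if (file.exists(file.path(dir, "truth_variants.tsv")))
      read_tsv(file.path(dir, "truth_variants.tsv")))
}

#' Read a BED-style interval sidecar (0-based half-open) as 1-based closed
#' @param path BED file path (first record used).
#' @return Integer vector `c(start, end)`, 1-based closed.
#' @export
read_bed_interval <- function(path) {
  ln <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  if (length(ln) < 3L) stop("malformed BED line in ", path)
  c(as.integer(ln[2]) + 1L, as.integer(ln[3]))
}
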