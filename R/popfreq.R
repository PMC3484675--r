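#' Build a genotype count table
#'
#' One row per population with counts of individuals homozygous for the
#' ancestral allele, heterozygous, and homozygous for the derived allele.
#'
#' @param population Population names.
#' @param n_hom_ancestral,n_het,n_hom_derived Non-negative integer counts.
#' @return Data frame of class `genotype_table` with an `n` column.
#' @export
genotype_table <- function(population, n_hom_ancestral, n_het,
                           n_hom_derived) {
  counts <- cbind(n_hom_ancestral, n_het, n_hom_derived)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  out <- data.frame(population = population,
                    n_hom_ancestral = as.integer(n_hom_ancestral),
                    n_het = as.integer(n_het),
                    n_hom_derived = as.integer(n_hom_derived))
  out$n <- out$n_hom_ancestral + out$n_het + out$n_hom_derived
  class(out) <- c("genotype_table", "data.frame")
  out
}

#' Allele frequencies from genotype counts
#'
#' `freq_ancestral = (2 * hom_ancestral + het) / (2n)`; the derived
#' frequency is its complement. Display values are rounded half-up to four
#' decimals; raw fractions are retained.
#'
#' @param table A `genotype_table`.
#' @param scope `"total"` (pool all rows) or a population name.
#' @return List: `freq_ancestral`, `freq_derived` (raw),
#'   `display` (named character, 4 decimals), `n` individuals in scope.
#' @examples
#' tb <- genotype_table("Total", 43, 53, 23)
#' allele_freqs(tb)$display
#' @export
allele_freqs <- function(table, scope = "total") {
  rows <- if (identical(scope, "total")) table
          else table[table$population == scope, , drop = FALSE]
  if (!nrow(rows)) stop("unknown population: ", scope)
  n <- sum(rows$n)
  if (n == 0L) stop("input error: zero individuals in scope")
  fa <- (2 * sum(rows$n_hom_ancestral) + sum(rows$n_het)) / (2 * n)
  fd <- 1 - fa
  round4 <- function(x) sprintf("%.4f", floor(x * 1e4 + 0.5) / 1e4)
  list(freq_ancestral = fa, freq_derived = fd,
       display = c(ancestral = round4(fa), derived = round4(fd)), n = n)
}

#' Per-population frequency summary with a totals row
#'
#' @param table A `genotype_table`.
#' @return Data frame: one row per population plus a `Total` row whose
#'   counts are column sums, with raw and displayed frequencies.
#' @export
population_summary <- function(table) {
  rows <- lapply(seq_len(nrow(table)), function(i) {
    f <- allele_freqs(table[i, , drop = FALSE])
    cbind(table[i, c("population", "n", "n_hom_ancestral", "n_het",
                     "n_hom_derived")],
          data.frame(freq_ancestral = f$freq_ancestral,
                     freq_derived = f$freq_derived))
  })
  tot <- allele_freqs(table)
  rows[[length(rows) + 1L]] <- data.frame(
    population = "Total", n = tot$n,
    n_hom_ancestral = sum(table$n_hom_ancestral),
    n_het = sum(table$n_het), n_hom_derived = sum(table$n_hom_derived),
    freq_ancestral = tot$freq_ancestral, freq_derived = tot$freq_derived)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Read a genotype count table from CSV/TSV
#'
#' Expected columns: population, hom_ancestral (or n_hom_ancestral), het,
#' hom_derived; the separator is sniffed from the extension (.csv vs .tsv).
#'
#' @param path File path.
#' @return A `genotype_table`.
#' @export
read_genotype_table <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  names(df) <- sub("^n_", "", names(df))
  need <- c("population", "hom_ancestral", "het", "hom_derived")
  if (!all(need %in% names(df)))
    stop("genotype table needs columns: ", paste(need, collapse = ", "))
  genotype_table(df$population, df$hom_ancestral, df$het, df$hom_derived)
}
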