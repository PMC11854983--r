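#' AT and GC strand skew
#'
#' Strand-asymmetry statistics of nucleotide composition:
#' `AT skew = (A - T)/(A + T)` and `GC skew = (G - C)/(G + C)`. Both are
#' ratio statistics, so counts and percentages give identical results.
#' An undefined skew (zero denominator) is returned as `NA`, not 0.
#'
#' @param a,t,g,c counts or percentages of the four bases (vectorized).
#' @return Numeric vector of skews in `[-1, 1]`.
#' @examples
#' at_skew(37.64, 34.19)  # 0.048 after 3 d.p. rounding
#' gc_skew(9.88, 18.30)   # -0.299
#' @export
at_skew <- function(a, t) {
  ifelse(a + t == 0, NA_real_, (a - t) / (a + t))
}

#' @rdname at_skew
#' @export
gc_skew <- function(g, c) {
  ifelse(g + c == 0, NA_real_, (g - c) / (g + c))
}

#' Base composition of a nucleotide sequence
#'
#' Counts A/C/G/T (case-insensitive; IUPAC ambiguity codes are excluded
#' from all denominators), and derives percentages, A+T and G+C content and
#' the two strand skews. Values are kept at full precision; rounding is a
#' report-time concern.
#'
#' @param seq nucleotide string.
#' @return One-row tibble: `a_pct`, `c_pct`, `g_pct`, `t_pct`, `at_pct`,
#'   `gc_pct`, `at_skew`, `gc_skew`, `n_counted`.
#' @examples
#' base_composition("CCCG")$gc_skew   # (1 - 3)/(1 + 3) = -0.5
#' base_composition("ATAT")$gc_skew   # NA: no G or C
#' @export
base_composition <- function(seq) {
  s <- toupper(seq)
  counts <- vapply(c("A", "C", "G", "T"),
                   function(b) sum(stringr::str_count(s, stringr::fixed(b))),
                   numeric(1))
  n <- sum(counts)
  if (n == 0) {
    abort("sequence has no countable A/C/G/T bases.",
          class = "mitocub_empty_sequence")
  }
  pct <- 100 * counts / n
  tibble(
    a_pct = pct[["A"]], c_pct = pct[["C"]], g_pct = pct[["G"]], t_pct = pct[["T"]],
    at_pct = pct[["A"]] + pct[["T"]], gc_pct = pct[["G"]] + pct[["C"]],
    at_skew = at_skew(counts[["A"]], counts[["T"]]),
    gc_skew = gc_skew(counts[["G"]], counts[["C"]]),
    n_counted = as.integer(n)
  )
}

#' Per-gene composition table of a mitogenome
#'
#' The standard composition summary reported for mitogenomes: one row for the
#' whole genome (deposited strand) and one per protein-coding gene and rRNA
#' on its sense strand. PCG rows use the full annotated span, including any
#' incomplete stop remainder, so row lengths match the annotation table.
#'
#' @param genome a [mitogenome()].
#' @return Tibble with a `gene` column (`"whole genome"` first, then
#'   features in coordinate order) bound to [base_composition()] columns.
#' @examples
#' g <- generate_mitogenome(synthetic_spec(seed = 1))
#' composition_table(g)
#' @export
composition_table <- function(genome) {
  stopifnot(inherits(genome, "mitogenome"))
  feats <- genome$features[genome$features$kind %in% c("PCG", "rRNA"), ]
  rows <- dplyr::bind_cols(tibble(gene = "whole genome"),
                           base_composition(genome$sequence))
  for (i in seq_len(nrow(feats))) {
    f <- feats[i, ]
    rows <- dplyr::bind_rows(
      rows,
      dplyr::bind_cols(tibble(gene = f$gene),
                       base_composition(feature_sequence(genome, f))))
  }
  expected <- c("rrnL", "rrnS")
  missing <- setdiff(expected, feats$gene)
  if (length(missing)) {
    warn(paste0("no annotation for: ", paste(missing, collapse = ", "),
                "; row(s) emitted with missing values."))
    rows <- dplyr::bind_rows(rows, tibble(gene = missing))
  }
  rows
}
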