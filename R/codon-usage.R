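#' Count codons over a set of coding sequences
#'
#' Pools codon counts over one or more in-frame coding sequences. Stop
#' codons and codons containing non-ACGT symbols are excluded from the
#' counts (the convention of the classic codon-usage tools, which report
#' usage for sense codons only); start codons are counted as ordinary
#' codons unless `include_start = FALSE`.
#'
#' @param cds a tibble from [extract_pcgs()] / [generate_cds()] (columns
#'   `gene`, `nucleotides`), or a character vector of in-frame sequences.
#' @param code_id translation table (default 5).
#' @param include_start count the first codon of each sequence? Default
#'   `TRUE`.
#' @return Tibble with one row per codon of the code (64 rows): `codon`,
#'   `aa`, `degeneracy`, `count`. Stop-codon rows always have count 0.
#'   The attribute `gene_set` records the pooled gene names.
#' @examples
#' count_codons("ATGAAATAA")  # ATG 1, AAA 1; TAA excluded as stop
#' @export
count_codons <- function(cds, code_id = 5, include_start = TRUE) {
  if (is.character(cds)) cds <- tibble(gene = paste0("seq", seq_along(cds)),
                                       nucleotides = cds)
  cds <- as_tibble(cds)
  if (nrow(cds) == 0L) {
    abort("no coding sequences supplied.", class = "mitocub_empty_input")
  }
  code <- as_genetic_code(code_id)
  cod <- unlist(lapply(cds$nucleotides, function(s) {
    k <- split_codons(toupper(s))
    if (!include_start && length(k)) k <- k[-1L]
    k
  }))
  cod <- cod[is_acgt_codon(cod)]
  aa_of <- setNames(code$codons$aa, code$codons$codon)
  cod <- cod[aa_of[cod] != "*"]
  tab <- table(factor(cod, levels = code$codons$codon))
  out <- code$codons
  out$count <- as.integer(tab[out$codon])
  out$count[out$aa == "*"] <- 0L
  attr(out, "gene_set") <- cds$gene
  attr(out, "code_id") <- code$code_id
  out
}

#' Relative synonymous codon usage
#'
#' RSCU of a codon is its observed count divided by the mean count of its
#' synonymous family: `d * x_i / sum(x_family)` for a family of degeneracy
#' `d`. A value of 1 means no bias; within each observed family the RSCU
#' values sum exactly to `d`. Families of degeneracy 1 (none under the
#' invertebrate mitochondrial code, but Met/Trp under the standard code)
#' have no synonymous alternative and are excluded. A family with zero
#' total count yields `NA` (unobserved, not unbiased).
#'
#' @param counts codon-count tibble from [count_codons()], or anything
#'   [count_codons()] accepts.
#' @param code_id translation table; defaults to the code the counts were
#'   made with.
#' @return Tibble of sense codons in synonymous families of degeneracy
#'   >= 2: `aa`, `codon`, `codon_rna` (display alphabet), `degeneracy`,
#'   `count`, `rscu`.
#' @examples
#' cc <- count_codons(c("ATGAAAAAAAAGTAA"))  # Lys: AAA x2, AAG x1
#' rscu(cc)[rscu(cc)$aa == "K", ]
#' @export
rscu <- function(counts, code_id = NULL) {
  if (!is.data.frame(counts) || !"count" %in% names(counts)) {
    counts <- count_codons(counts, code_id %||% 5)
  }
  if (sum(counts$count) == 0) {
    abort("all codon counts are zero.", class = "mitocub_empty_input")
  }
  counts |>
    dplyr::filter(.data$aa != "*", .data$degeneracy >= 2L) |>
    dplyr::group_by(.data$aa) |>
    dplyr::mutate(rscu = if (sum(.data$count) == 0) NA_real_ else
                           .data$degeneracy * .data$count / sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::mutate(codon_rna = dna_to_rna(.data$codon)) |>
    dplyr::arrange(.data$aa, .data$codon) |>
    dplyr::select("aa", "codon", "codon_rna", "degeneracy", "count", "rscu")
}

#' Positional GC content of coding sequences
#'
#' G+C fractions at the three codon positions (GC1, GC2, GC3), their
#' neutrality-plot summary GC12 = (GC1 + GC2)/2, and GC3s — the
#' third-position G+C restricted to codons whose synonymous family has
#' degeneracy >= 2 under the code (the quantity the expected-ENC curve is
#' parameterized by). Stop codons and codons with non-ACGT symbols are
#' excluded, as in [count_codons()].
#'
#' @param cds tibble of coding sequences (`gene`, `nucleotides`) or a
#'   character vector.
#' @param code_id translation table (default 5).
#' @return Tibble, one row per input gene: `gene`, `gc1`, `gc2`, `gc3`,
#'   `gc12`, `gc3s`, `n_codons`.
#' @examples
#' positional_gc("ATGGGC")  # gc1 0.5, gc2 0.5, gc3 1
#' @export
positional_gc <- function(cds, code_id = 5) {
  if (is.character(cds)) cds <- tibble(gene = paste0("seq", seq_along(cds)),
                                       nucleotides = cds)
  cds <- as_tibble(cds)
  if (nrow(cds) == 0L) {
    abort("no coding sequences supplied.", class = "mitocub_empty_input")
  }
  code <- as_genetic_code(code_id)
  aa_of <- setNames(code$codons$aa, code$codons$codon)
  deg_of <- setNames(code$codons$degeneracy, code$codons$codon)
  gc <- function(b) b %in% c("G", "C")
  rows <- purrr::map(seq_len(nrow(cds)), function(i) {
    k <- split_codons(toupper(cds$nucleotides[i]))
    k <- k[is_acgt_codon(k)]
    k <- k[aa_of[k] != "*"]
    if (length(k) == 0L) {
      abort(sprintf("%s: no countable codons.", cds$gene[i]),
            class = "mitocub_empty_input")
    }
    b1 <- substr(k, 1, 1); b2 <- substr(k, 2, 2); b3 <- substr(k, 3, 3)
    syn <- deg_of[k] >= 2L
    gc1 <- mean(gc(b1)); gc2 <- mean(gc(b2))
    tibble(gene = cds$gene[i], gc1 = gc1, gc2 = gc2, gc3 = mean(gc(b3)),
           gc12 = (gc1 + gc2) / 2,
           gc3s = if (any(syn)) mean(gc(b3[syn])) else NA_real_,
           n_codons = length(k))
  })
  dplyr::bind_rows(rows)
}

#' Start and stop codon summary
#'
#' Per-gene table of the verbatim first codon and the recorded (possibly
#' incomplete) stop, as reported in mitogenome annotation tables.
#'
#' @param cds tibble from [extract_pcgs()].
#' @return Tibble `gene`, `start_codon`, `stop_codon`, `stop_complete`.
#' @export
start_stop_summary <- function(cds) {
  cds <- as_tibble(cds)
  if (nrow(cds) == 0L) {
    abort("no coding sequences supplied.", class = "mitocub_empty_input")
  }
  dplyr::select(cds, "gene", "start_codon", "stop_codon", "stop_complete")
}
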