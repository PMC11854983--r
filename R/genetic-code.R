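#' Genetic code tables with synonymous-family structure
#'
#' Wraps an NCBI translation table (via [Biostrings::getGeneticCode()]) and
#' derives the partition of sense codons into synonymous families, the
#' degeneracy of each family, and the start/stop codon sets. The default,
#' table 5, is the invertebrate mitochondrial code used for insect
#' mitogenomes: `TAA`/`TAG` are the only stops, `ATA` encodes Met, `TGA`
#' encodes Trp and `AGA`/`AGG` encode Ser, giving 62 sense codons in
#' families of degeneracy 2, 4, 6 (Leu) and 8 (Ser).
#'
#' @param code_id NCBI translation-table number (integer or string).
#'   Default `5`, invertebrate mitochondrial.
#'
#' @return An object of class `genetic_code`: a list with
#'   \describe{
#'     \item{code_id}{the table number, as given}
#'     \item{codons}{tibble with columns `codon`, `aa` (one-letter amino
#'       acid, `"*"` for stop), `degeneracy` (family size; `NA` for stops)}
#'     \item{start_codons}{character vector of initiation codons}
#'     \item{stop_codons}{character vector of stop codons}
#'     \item{n_sense}{number of sense codons}
#'   }
#' @examples
#' code <- genetic_code(5)
#' code$n_sense          # 62
#' code$stop_codons      # "TAA" "TAG"
#' @export
genetic_code <- function(code_id = 5) {
  map <- Biostrings::getGeneticCode(as.character(code_id), full.search = TRUE)
  tbl <- tibble(codon = names(map), aa = unname(map))
  deg <- table(tbl$aa[tbl$aa != "*"])
  tbl$degeneracy <- ifelse(tbl$aa == "*", NA_integer_,
                           as.integer(deg[tbl$aa]))
  starts <- sort(unique(c(names(map)[map == "M"],
                          attr(map, "alt_init_codons"))))
  structure(
    list(
      code_id = code_id,
      codons = tbl,
      start_codons = starts,
      stop_codons = tbl$codon[tbl$aa == "*"],
      n_sense = sum(tbl$aa != "*")
    ),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("<genetic_code> NCBI table", x$code_id, "-", x$n_sense, "sense codons,",
      length(x$stop_codons), "stops (", paste(x$stop_codons, collapse = ", "),
      ")\n")
  invisible(x)
}

as_genetic_code <- function(x) {
  if (inherits(x, "genetic_code")) x else genetic_code(x)
}

# Named list: amino acid -> character vector of its codons (sense only).
code_families <- function(code) {
  code <- as_genetic_code(code)
  sense <- code$codons[code$codons$aa != "*", ]
  split(sense$codon, sense$aa)
}
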