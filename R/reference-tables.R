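#' Published annotation of the Cyphochilus crataceus mitogenome
#'
#' The gene-by-gene annotation of the complete mitochondrial genome of the
#' scarab beetle *Cyphochilus crataceus* (GenBank accession OP963801.1;
#' 17,946 bp, circular): 13 protein-coding genes, 22 tRNAs, 2 rRNAs and the
#' A+T-rich control region (`OH`), with coding strand, 1-based inclusive
#' coordinates, published length, start/stop codons, tRNA anticodons and the
#' published intergenic spacing to the next gene. This table is the default
#' geometry template for [synthetic_spec()] and the reference input for the
#' desk-check examples in the package.
#'
#' `strand` is the orientation on the deposited sequence (`+`/`-`); `jn` is
#' the major/minor strand label used in mitogenome annotation tables
#' (N mapped to `+`, J to `-` for this record). `stop_codon` is kept as
#' published, including the `TA(A)` rendering of an incomplete stop.
#' `intergenic` is the published spacing (bp) between a gene and the next
#' one in coordinate order (negative = overlap); note the published trnP
#' value (10) disagrees with its coordinates, which give +1 — use
#' [intergenic_table()] for spacings recomputed from coordinates.
#'
#' @return A tibble with one row per feature and columns `gene`, `kind`
#'   (`PCG`/`tRNA`/`rRNA`/`control`), `strand`, `jn`, `start`, `end`,
#'   `length`, `start_codon`, `stop_codon`, `anticodon`, `intergenic`.
#' @examples
#' ann <- crataceus_annotation()
#' sum(ann$kind == "PCG")  # 13
#' @export
crataceus_annotation <- function() {
  tab <- tibble::tribble(
    ~gene,   ~jn, ~start,  ~end,   ~length, ~start_codon, ~stop_codon, ~anticodon, ~intergenic,
    "trnI",  "N",      1,     63,       63, NA,           NA,          "GAT",      -3,
    "trnQ",  "J",     61,    129,       69, NA,           NA,          "TTG",      -2,
    "trnM",  "N",    128,    196,       69, NA,           NA,          "CAT",       0,
    "nad2",  "N",    197,   1204,     1008, "ATT",        "TAG",       NA,         14,
    "trnW",  "N",   1219,   1284,       66, NA,           NA,          "TCA",      -8,
    "trnC",  "J",   1277,   1339,       63, NA,           NA,          "GCA",      15,
    "trnY",  "J",   1355,   1417,       63, NA,           NA,          "GTA",      -8,
    "cox1",  "N",   1410,   2951,     1542, "ATT",        "TAA",       NA,          6,
    "trnL2", "N",   2958,   3021,       64, NA,           NA,          "TAA",       0,
    "cox2",  "N",   3022,   3709,      688, "ATG",        "TAA",       NA,          0,
    "trnK",  "N",   3710,   3780,       71, NA,           NA,          "CTT",       0,
    "trnD",  "N",   3781,   3843,       63, NA,           NA,          "GTC",       0,
    "atp8",  "N",   3844,   3999,      156, "ATC",        "TAA",       NA,         -7,
    "atp6",  "N",   3993,   4665,      673, "ATG",        "TAG",       NA,          0,
    "cox3",  "N",   4666,   5452,      787, "ATG",        "TA(A)",     NA,          0,
    "trnG",  "N",   5453,   5517,       65, NA,           NA,          "TCC",       0,
    "nad3",  "N",   5518,   5871,      354, "ATA",        "TAG",       NA,         -2,
    "trnA",  "N",   5870,   5933,       64, NA,           NA,          "TGC",      -1,
    "trnR",  "N",   5933,   5997,       65, NA,           NA,          "TCG",       0,
    "trnN",  "N",   5998,   6060,       63, NA,           NA,          "GTT",       0,
    "trnS1", "N",   6061,   6127,       67, NA,           NA,          "TCT",       1,
    "trnE",  "N",   6129,   6190,       62, NA,           NA,          "TTC",      -2,
    "trnF",  "J",   6189,   6253,       65, NA,           NA,          "GAA",      -1,
    "nad5",  "J",   6253,   7971,     1719, "ATT",        "TAA",       NA,          0,
    "trnH",  "J",   7972,   8036,       65, NA,           NA,          "GTG",      -1,
    "nad4",  "J",   8036,   9370,     1335, "ATG",        "TAA",       NA,         -7,
    "nad4l", "J",   9364,   9654,      291, "ATG",        "TAA",       NA,          2,
    "trnT",  "N",   9657,   9720,       64, NA,           NA,          "TGT",       0,
    "trnP",  "J",   9721,   9782,       62, NA,           NA,          "TGG",      10,
    "nad6",  "N",   9784,  10287,      504, "ATA",        "TAA",       NA,         -1,
    "cob",   "N",  10287,  11429,     1143, "ATG",        "TAG",       NA,         -2,
    "trnS2", "N",  11428,  11490,       63, NA,           NA,          "TGA",      17,
    "nad1",  "J",  11508,  12458,      951, "ATG",        "TAA",       NA,          1,
    "trnL1", "J",  12460,  12522,       63, NA,           NA,          "TAG",      33,
    "rrnL",  "J",  12556,  13807,     1252, NA,           NA,          NA,         -3,
    "trnV",  "J",  13805,  13874,       70, NA,           NA,          "TAC",      -1,
    "rrnS",  "J",  13874,  14657,      784, NA,           NA,          NA,          0,
    "OH",    "N",  14658,  17946,     3289, NA,           NA,          NA,          0
  )
  tab$kind <- dplyr::case_when(
    grepl("^trn", tab$gene) ~ "tRNA",
    grepl("^rrn", tab$gene) ~ "rRNA",
    tab$gene == "OH"        ~ "control",
    TRUE                    ~ "PCG"
  )
  tab$strand <- ifelse(tab$jn == "N", "+", "-")
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  tab$length <- as.integer(tab$length)
  tab$intergenic <- as.integer(tab$intergenic)
  tab[, c("gene", "kind", "strand", "jn", "start", "end", "length",
          "start_codon", "stop_codon", "anticodon", "intergenic")]
}

#' Published base composition of the C. crataceus mitogenome
#'
#' Per-gene base composition and strand skews of the *Cyphochilus crataceus*
#' mitochondrial genome (GenBank OP963801.1) as published for the whole
#' genome, the 13 protein-coding genes and the two rRNAs. Percentages and
#' skews are the printed values (percentages to 2 d.p., skews to 3 d.p.,
#' except the cox2 AT-skew which was printed as `-0.0037`, inconsistent
#' with its own percentages — kept verbatim).
#'
#' Feeding the percentage columns through [at_skew()] / [gc_skew()]
#' reproduces the printed skew columns, a useful desk check of the skew
#' formulas.
#'
#' @return A tibble with columns `gene`, `a_pct`, `c_pct`, `g_pct`, `t_pct`,
#'   `at_pct`, `gc_pct`, `at_skew`, `gc_skew`.
#' @examples
#' comp <- crataceus_composition()
#' with(comp[comp$gene == "whole genome", ], at_skew(a_pct, t_pct))
#' @export
crataceus_composition <- function() {
  tibble::tribble(
    ~gene,          ~a_pct, ~c_pct, ~g_pct, ~t_pct, ~at_pct, ~gc_pct, ~at_skew, ~gc_skew,
    "whole genome",  37.64,  18.30,   9.88,  34.19,   71.82,   28.18,    0.048,   -0.299,
    "nad2",          34.72,  18.95,   7.94,  38.39,   73.12,   26.88,   -0.050,   -0.410,
    "cox1",          28.34,  19.71,  16.34,  35.60,   63.94,   36.06,   -0.114,   -0.094,
    "cox2",          32.12,  20.06,  13.23,  34.59,   66.71,   33.29,  -0.0037,   -0.205,
    "atp8",          37.82,  16.67,   7.69,  37.82,   75.64,   24.36,    0.000,   -0.368,
    "atp6",          32.10,  20.35,  10.55,  37.00,   69.10,   30.91,   -0.071,   -0.317,
    "cox3",          28.72,  19.44,  14.87,  36.97,   65.69,   34.31,   -0.126,   -0.133,
    "nad3",          33.05,  16.67,   9.89,  40.40,   73.45,   26.55,   -0.100,   -0.255,
    "nad5",          29.61,   9.25,  16.52,  44.62,   74.23,   25.77,   -0.202,    0.282,
    "nad4",          28.24,   9.29,  16.78,  45.69,   73.93,   26.07,   -0.236,    0.287,
    "nad4l",         24.74,   8.25,  16.15,  50.86,   75.60,   24.40,   -0.345,    0.324,
    "nad6",          36.31,  16.67,   6.94,  40.08,   76.39,   23.61,   -0.049,   -0.412,
    "cob",           31.06,  19.95,  12.51,  36.48,   67.54,   32.46,   -0.080,   -0.229,
    "nad1",          24.89,   9.63,  20.35,  45.13,   70.02,   29.98,   -0.289,    0.357,
    "rrnL",          35.70,   7.59,  16.37,  40.34,   76.04,   23.96,   -0.061,    0.367,
    "rrnS",          36.10,   8.93,  17.86,  37.12,   73.21,   26.79,   -0.014,    0.333
  )
}
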