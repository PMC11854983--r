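#' Construct an annotated mitogenome object
#'
#' The central container of the package: a (usually circular) nucleotide
#' sequence plus an ordered feature table. Coordinates are 1-based and
#' inclusive throughout the package (GenBank convention); a feature that
#' spans the circular origin carries `wraps_origin = TRUE` with `end` giving
#' its final position after the wrap (so `end < start`).
#'
#' @param sequence nucleotide string (IUPAC symbols, case-insensitive).
#' @param features data frame with columns `gene`, `kind` (one of `PCG`,
#'   `tRNA`, `rRNA`, `control`), `strand` (`+`/`-`, orientation on the
#'   deposited sequence), `start`, `end`; optional `wraps_origin` (logical),
#'   `anticodon`, `jn` (major/minor strand label, metadata only).
#' @param identifier short record name (used as LOCUS on write).
#' @param accession optional accession string.
#' @param topology `"circular"` or `"linear"`.
#'
#' @return An object of class `mitogenome`: a list with elements
#'   `identifier`, `accession`, `topology`, `sequence` (upper-case string)
#'   and `features` (tibble sorted by `start`).
#' @examples
#' g <- mitogenome("ATGAAATAAGCGCGC",
#'                 tibble::tibble(gene = "g1", kind = "PCG", strand = "+",
#'                                start = 1L, end = 9L),
#'                 identifier = "toy", topology = "linear")
#' g
#' @export
mitogenome <- function(sequence, features, identifier = "mitogenome",
                       accession = NA_character_, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  sequence <- toupper(gsub("\\s", "", sequence))
  iupac <- paste0("^[", paste(names(Biostrings::IUPAC_CODE_MAP), collapse = ""), "]*$")
  if (!grepl(iupac, sequence)) {
    abort("`sequence` contains non-IUPAC nucleotide symbols.",
          class = "mitocub_malformed_record")
  }
  features <- as_tibble(features)
  needed <- c("gene", "kind", "strand", "start", "end")
  if (!all(needed %in% names(features))) {
    abort(paste0("`features` must have columns: ", paste(needed, collapse = ", ")),
          class = "mitocub_malformed_record")
  }
  if (!"wraps_origin" %in% names(features)) features$wraps_origin <- FALSE
  if (!"anticodon" %in% names(features)) features$anticodon <- NA_character_
  if (!"jn" %in% names(features)) features$jn <- NA_character_
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  n <- nchar(sequence)
  bad <- features$start < 1L | features$end < 1L | features$start > n | features$end > n |
    (!features$wraps_origin & features$end < features$start)
  if (nrow(features) > 0 && any(bad)) {
    abort(paste0("feature(s) outside sequence bounds or malformed: ",
                 paste(features$gene[bad], collapse = ", ")),
          class = "mitocub_malformed_record")
  }
  if (any(features$wraps_origin) && topology != "circular") {
    abort("wrapping features require circular topology.",
          class = "mitocub_malformed_record")
  }
  features <- features[order(features$start, features$end), ]
  dup <- duplicated(features$gene) & features$kind != "control"
  if (any(dup)) {
    warn(paste0("duplicated feature name(s): ",
                paste(unique(features$gene[dup]), collapse = ", ")))
  }
  trna_len <- feature_length(features, n)[features$kind == "tRNA"]
  if (length(trna_len) && any(trna_len < 60 | trna_len > 75)) {
    warn("tRNA feature(s) outside the realistic 60-75 nt range.")
  }
  if (nrow(features) == 0L) warn("mitogenome has no annotated features.")
  structure(
    list(identifier = identifier, accession = accession, topology = topology,
         sequence = sequence,
         features = features[, c("gene", "kind", "strand", "start", "end",
                                 "wraps_origin", "anticodon", "jn")]),
    class = "mitogenome"
  )
}

#' @export
print.mitogenome <- function(x, ...) {
  cat("<mitogenome> ", x$identifier,
      if (!is.na(x$accession)) paste0(" (", x$accession, ")"), "\n",
      "  ", x$topology, ", ", nchar(x$sequence), " bp, ",
      nrow(x$features), " features (",
      sum(x$features$kind == "PCG"), " PCG, ",
      sum(x$features$kind == "tRNA"), " tRNA, ",
      sum(x$features$kind == "rRNA"), " rRNA)\n", sep = "")
  invisible(x)
}

#' @export
length.mitogenome <- function(x) nchar(x$sequence)

# Annotated span length, wrap-aware. `features` is the features tibble,
# `genome_len` the sequence length.
feature_length <- function(features, genome_len) {
  ifelse(features$wraps_origin,
         (genome_len - features$start + 1L) + features$end,
         features$end - features$start + 1L)
}

# Sense-strand sequence of one feature row (wrap-aware; reverse-complemented
# for "-" features).
feature_sequence <- function(genome, row) {
  s <- if (isTRUE(row$wraps_origin)) {
    paste0(substr(genome$sequence, row$start, nchar(genome$sequence)),
           substr(genome$sequence, 1L, row$end))
  } else {
    substr(genome$sequence, row$start, row$end)
  }
  if (row$strand == "-") revcomp(s) else s
}

#' Normalize mitochondrial gene names
#'
#' Maps the many synonyms found in GenBank mitogenome annotations onto one
#' canonical vocabulary: `nad1`..`nad6`, `nad4l`, `cox1`..`cox3`, `cob`,
#' `atp6`, `atp8`, `rrnS`, `rrnL`, `trnX` (with `S1`/`S2` and `L1`/`L2`
#' disambiguated by anticodon where available) and `OH` for the control
#' region. Unknown names pass through unchanged.
#'
#' @param x character vector of raw names (e.g. `"ND2"`, `"COI"`, `"CYTB"`,
#'   `"tRNA-Ser"`, `"D-loop"`, `"16S ribosomal RNA"`).
#' @param anticodon optional anticodon (DNA alphabet) used to resolve
#'   trnS1/trnS2 and trnL1/trnL2.
#' @return character vector of canonical names.
#' @examples
#' normalize_gene_name(c("ND2", "COI", "CYTB", "D-loop", "12S rRNA"))
#' @export
normalize_gene_name <- function(x, anticodon = NA_character_) {
  anticodon <- rep_len(toupper(ifelse(is.na(anticodon), "", anticodon)), length(x))
  raw <- x
  y <- toupper(trimws(x))
  out <- character(length(y))
  aa3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
           GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
           MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
           TYR = "Y", VAL = "V")
  for (i in seq_along(y)) {
    n <- gsub("[ _]", "-", y[i])
    out[i] <- if (grepl("^(NAD|ND|NADH)[- ]?([1-6])$", n)) {
      paste0("nad", sub("^(NAD|ND|NADH)[- ]?([1-6])$", "\\2", n))
    } else if (grepl("^(NAD|ND|NADH)[- ]?4L$", n)) {
      "nad4l"
    } else if (grepl("^(COX?|CO)[- ]?(1|I)$", n)) {
      "cox1"
    } else if (grepl("^(COX?|CO)[- ]?(2|II)$", n)) {
      "cox2"
    } else if (grepl("^(COX?|CO)[- ]?(3|III)$", n)) {
      "cox3"
    } else if (grepl("^(CYTB|COB|CYB|CYT-B)$", n)) {
      "cob"
    } else if (grepl("^ATP(ASE)?[- ]?6$", n)) {
      "atp6"
    } else if (grepl("^ATP(ASE)?[- ]?8$", n)) {
      "atp8"
    } else if (grepl("(^|-)12S|RRNS|S-RRNA|SMALL", n)) {
      "rrnS"
    } else if (grepl("(^|-)16S|RRNL|L-RRNA|LARGE", n)) {
      "rrnL"
    } else if (grepl("D-LOOP|CONTROL|A\\+T-RICH|^OH$", n)) {
      "OH"
    } else if (grepl("^TRN[A-Z][0-9]?$", n)) {
      paste0("trn", sub("^TRN", "", n), collapse = "")
    } else if (grepl("^TRNA-", n)) {
      aa <- sub("^TRNA-([A-Z]{3}).*", "\\1", n)
      one <- aa3[aa]
      if (is.na(one)) raw[i]
      else if (one == "S") paste0("trnS", trn_isoform(n, anticodon[i], "S"))
      else if (one == "L") paste0("trnL", trn_isoform(n, anticodon[i], "L"))
      else paste0("trn", one)
    } else {
      raw[i]
    }
  }
  # trnS/trnL given as one-letter without isoform: resolve by anticodon
  amb <- out %in% c("trnS", "trnL")
  if (any(amb)) {
    out[amb] <- vapply(which(amb), function(i) {
      paste0(out[i], trn_isoform("", anticodon[i], substr(out[i], 4, 4)))
    }, character(1))
  }
  out
}

# Ser/Leu isoform number from codon-family hints in the name or from the
# anticodon (DNA alphabet). trnS1 reads AGN codons (anticodon TCT/GCT),
# trnS2 reads TCN (anticodon TGA); trnL1 reads CTN (anticodon TAG),
# trnL2 reads TTR (anticodon TAA).
trn_isoform <- function(name, anticodon, aa) {
  if (aa == "S") {
    if (grepl("AGN|AGC|AGY|GCU|UCU|\\(S1\\)|SER1", name)) return("1")
    if (grepl("UCN|TCN|UGA|\\(S2\\)|SER2", name)) return("2")
    if (anticodon %in% c("TCT", "GCT")) return("1")
    if (anticodon == "TGA") return("2")
  } else {
    if (grepl("CUN|CTN|UAG|\\(L1\\)|LEU1", name)) return("1")
    if (grepl("UUR|TTR|UAA|\\(L2\\)|LEU2", name)) return("2")
    if (anticodon == "TAG") return("1")
    if (anticodon == "TAA") return("2")
  }
  ""  # undisambiguated: leave as trnS/trnL
}
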