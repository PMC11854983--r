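#' Extract in-frame protein-coding gene sequences
#'
#' Returns every annotated PCG as a sense-strand (5'→3') coding sequence
#' ready for codon statistics. Reverse-oriented genes are
#' reverse-complemented; an incomplete terminal stop (annotated span length
#' not a multiple of 3, the usual `T`/`TA` completed to `TAA` by
#' polyadenylation) is recorded in `stop_codon` and trimmed, so
#' `nucleotides` is always a whole number of codons and no invented bases
#' enter downstream counts. Internal stop codons under `code_id` trigger a
#' warning (annotations are sometimes imperfect), not an error.
#'
#' @param genome a [mitogenome()].
#' @param code_id NCBI translation table (default 5, invertebrate
#'   mitochondrial).
#' @return A tibble with one row per PCG, in coordinate order: `gene`,
#'   `nucleotides` (in-frame sense strand, stop codon included when
#'   complete), `length_annotated` (the annotated span), `start_codon`,
#'   `stop_codon` (3 letters when complete, the 1-2 leftover letters when
#'   incomplete), `stop_complete`, `code_id`.
#' @examples
#' g <- generate_mitogenome(synthetic_spec(seed = 1))
#' extract_pcgs(g)
#' @export
extract_pcgs <- function(genome, code_id = 5) {
  stopifnot(inherits(genome, "mitogenome"))
  pcgs <- genome$features[genome$features$kind == "PCG", ]
  if (nrow(pcgs) == 0L) {
    abort("genome has no protein-coding gene features.",
          class = "mitocub_no_pcgs")
  }
  code <- as_genetic_code(code_id)
  rows <- purrr::map(seq_len(nrow(pcgs)), function(i) {
    f <- pcgs[i, ]
    s <- feature_sequence(genome, f)
    L <- nchar(s)
    r <- L %% 3L
    if (r > 0L) {
      stop_codon <- substr(s, L - r + 1L, L)
      body <- substr(s, 1L, L - r)
      stop_complete <- FALSE
    } else {
      last <- substr(s, L - 2L, L)
      body <- s
      if (last %in% code$stop_codons) {
        stop_codon <- last
        stop_complete <- TRUE
      } else {
        stop_codon <- last
        stop_complete <- FALSE
        warn(sprintf("%s: annotated span ends without a stop codon under code %s.",
                     f$gene, code$code_id))
      }
    }
    if (nchar(body) < 6L) {
      abort(sprintf("%s: coding sequence too short (%d nt) after stop trimming.",
                    f$gene, nchar(body)),
            class = "mitocub_too_short")
    }
    cod <- split_codons(body)
    internal <- cod[-length(cod)] %in% code$stop_codons
    if (any(internal)) {
      warn(sprintf("%s: %d internal stop codon(s) under code %s.",
                   f$gene, sum(internal), code$code_id))
    }
    tibble(gene = f$gene, nucleotides = body,
           length_annotated = L, start_codon = substr(body, 1L, 3L),
           stop_codon = stop_codon, stop_complete = stop_complete,
           code_id = code$code_id)
  })
  dplyr::bind_rows(rows)
}

#' Intergenic spacing between adjacent features
#'
#' Walks the features in coordinate order and reports, for every adjacent
#' pair, the signed spacing `start(downstream) - end(upstream) - 1`
#' (negative = overlap, 0 = abutting, positive = gap). For a circular
#' genome a final record joins the last feature back to the first across
#' the origin.
#'
#' @param x a [mitogenome()], or a feature data frame with columns `gene`,
#'   `start`, `end` (already in coordinate order) for desk calculations on
#'   published annotation tables.
#' @param topology used when `x` is a plain data frame: `"circular"` adds
#'   the wrap record, for which `genome_length` must then be given.
#' @param genome_length sequence length, required for the circular wrap
#'   record when `x` is a data frame.
#' @return A tibble `upstream`, `downstream`, `spacing` (integer bp).
#' @examples
#' ann <- crataceus_annotation()
#' head(intergenic_table(ann, topology = "circular", genome_length = 17946))
#' @export
intergenic_table <- function(x, topology = NULL, genome_length = NULL) {
  if (inherits(x, "mitogenome")) {
    feats <- x$features
    topology <- x$topology
    genome_length <- nchar(x$sequence)
  } else {
    feats <- as_tibble(x)
    topology <- topology %||% "linear"
  }
  if (nrow(feats) < 2L) {
    abort("need at least two features for intergenic spacings.",
          class = "mitocub_too_few_features")
  }
  if (anyDuplicated(feats[, c("start", "end")])) {
    abort("duplicate feature coordinates.", class = "mitocub_duplicate_feature")
  }
  feats <- feats[order(feats$start, feats$end), ]
  up <- feats[-nrow(feats), ]
  dn <- feats[-1L, ]
  out <- tibble(upstream = up$gene, downstream = dn$gene,
                spacing = as.integer(dn$start - up$end - 1L))
  if (identical(topology, "circular")) {
    if (is.null(genome_length)) {
      abort("`genome_length` needed for the circular wrap record.")
    }
    last <- feats[nrow(feats), ]
    first <- feats[1L, ]
    wrap <- as.integer((first$start + genome_length) - last$end - 1L)
    out <- dplyr::bind_rows(out, tibble(upstream = last$gene,
                                        downstream = first$gene,
                                        spacing = wrap))
  }
  out
}

#' Annotation accounting table
#'
#' One row per feature in the layout of published mitogenome annotation
#' tables: strand label, position, length, start/stop codons for PCGs,
#' anticodon for tRNAs, and the intergenic spacing to the next feature
#' (recomputed from coordinates).
#'
#' @param genome a [mitogenome()].
#' @param code_id translation table forwarded to [extract_pcgs()].
#' @return A tibble `gene`, `strand`, `start`, `end`, `length`,
#'   `start_codon`, `stop_codon`, `anticodon`, `intergenic`.
#' @export
annotation_table <- function(genome, code_id = 5) {
  stopifnot(inherits(genome, "mitogenome"))
  feats <- genome$features
  len <- feature_length(feats, nchar(genome$sequence))
  strand <- ifelse(is.na(feats$jn), feats$strand, feats$jn)
  out <- tibble(gene = feats$gene, strand = strand,
                start = feats$start, end = feats$end, length = len,
                start_codon = NA_character_, stop_codon = NA_character_,
                anticodon = feats$anticodon)
  if (any(feats$kind == "PCG")) {
    cds <- extract_pcgs(genome, code_id)
    idx <- match(out$gene, cds$gene)
    out$start_codon <- cds$start_codon[idx]
    out$stop_codon <- ifelse(is.na(idx), NA_character_,
                             ifelse(cds$stop_complete[idx], cds$stop_codon[idx],
                                    paste0(cds$stop_codon[idx], "(incomplete)")))
  }
  ig <- if (nrow(feats) >= 2L) intergenic_table(genome) else NULL
  out$intergenic <- if (!is.null(ig)) {
    as.integer(ig$spacing[match(out$gene, ig$upstream)])
  } else NA_integer_
  out
}
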