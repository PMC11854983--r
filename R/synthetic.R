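#' Specification for a synthetic annotated mitogenome
#'
#' Parameter block driving [generate_mitogenome()]. The defaults emulate a
#' beetle mitogenome: the 37-feature gene order, strand assignment, feature
#' lengths and overlap/gap geometry of the *C. crataceus* record
#' ([crataceus_annotation()], with spacings recomputed from its
#' coordinates), whole-genome A+T content 71.82%, and moderately biased
#' synonymous codon usage under the invertebrate mitochondrial code.
#'
#' `bias_concentration` is a Dirichlet concentration over each synonymous
#' family: large values give near-uniform usage (RSCU near 1 everywhere,
#' high ENC), small values strongly skewed usage (low ENC). `gc3_target`
#' tilts third positions; its default `1 - at_content` keeps the coding
#' strand at the same A+T level as the rest of the genome.
#'
#' @param gene_order tibble with columns `gene`, `kind`, `strand` (`+`/`-`),
#'   `length`, optional `spacing` (signed bp to the *next* feature;
#'   negative = overlap), `anticodon`, `jn`. Default: the reference
#'   37-feature arrangement.
#' @param at_content whole-genome A+T target fraction (default 0.7182).
#' @param gc3_target third-position G+C target for PCGs; `NULL` (default)
#'   means `1 - at_content`.
#' @param bias_concentration positive real, may be `Inf` for exactly
#'   uniform within-family usage. Default 1.
#' @param code_id translation table (default 5).
#' @param topology `"circular"` (default) or `"linear"`.
#' @param seed integer seed; all randomness of the generator flows from a
#'   single stream seeded with it.
#' @return Object of class `synthetic_spec` (a list of the above).
#' @examples
#' spec <- synthetic_spec(seed = 42)
#' g <- generate_mitogenome(spec)
#' @export
synthetic_spec <- function(gene_order = NULL, at_content = 0.7182,
                           gc3_target = NULL, bias_concentration = 1,
                           code_id = 5, topology = "circular", seed = 1) {
  if (is.null(gene_order)) gene_order <- default_gene_order()
  gene_order <- as_tibble(gene_order)
  if (!"spacing" %in% names(gene_order)) gene_order$spacing <- 0L
  if (!"anticodon" %in% names(gene_order)) gene_order$anticodon <- NA_character_
  if (!"jn" %in% names(gene_order)) gene_order$jn <- NA_character_
  gene_order$spacing[is.na(gene_order$spacing)] <- 0L
  stopifnot(all(gene_order$length > 0), at_content > 0, at_content < 1,
            bias_concentration > 0)
  if (is.null(gc3_target)) gc3_target <- 1 - at_content
  structure(
    list(gene_order = gene_order, at_content = at_content,
         gc3_target = gc3_target, bias_concentration = bias_concentration,
         code_id = code_id, topology = topology, seed = seed),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec> ", nrow(x$gene_order), " features (",
      sum(x$gene_order$kind == "PCG"), " PCG), A+T ", x$at_content,
      ", GC3 ", signif(x$gc3_target, 3), ", concentration ",
      x$bias_concentration, ", code ", x$code_id, ", seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}

# Default 37-feature geometry: the reference record's order, strands,
# lengths and coordinate-derived spacings.
default_gene_order <- function() {
  ann <- crataceus_annotation()
  sp <- c(ann$start[-1] - ann$end[-nrow(ann)] - 1L, 0L)  # last wraps with gap 0
  tibble(gene = ann$gene, kind = ann$kind, strand = ann$strand,
         jn = ann$jn, length = ann$length, spacing = as.integer(sp),
         anticodon = ann$anticodon)
}

# --- composition machinery ---------------------------------------------------

# Base probabilities with A+T = at, keeping the A:T and G:C ratios of a
# typical AT-rich insect mitogenome (A/T 0.524/0.476 of the AT mass,
# G/C 0.351/0.649 of the GC mass).
base_probs <- function(at) {
  c(A = at * 0.524, T = at * 0.476,
    G = (1 - at) * 0.351, C = (1 - at) * 0.649)
}

# Amino-acid sampling weights implied by i.i.d. draws from `pi` restricted
# to sense codons.
aa_weights <- function(code, pi) {
  sense <- code$codons[code$codons$aa != "*", ]
  w <- pi[substr(sense$codon, 1, 1)] *
       pi[substr(sense$codon, 2, 2)] *
       pi[substr(sense$codon, 3, 3)]
  tapply(w, sense$aa, sum) / sum(w)
}

# Expected A+T fraction at codon positions 1-2 when amino acids are drawn
# with aa_weights(code, base_probs(theta)) and codons uniformly within
# family.
expected_at12 <- function(code, theta) {
  fams <- code_families(code)
  q <- aa_weights(code, base_probs(theta))
  at12 <- vapply(fams, function(cs) {
    mean((substr(cs, 1, 1) %in% c("A", "T")) + (substr(cs, 2, 2) %in% c("A", "T"))) / 2
  }, numeric(1))
  sum(q[names(fams)] * at12)
}

# Tilt parameter theta such that PCG positions 1-2 hit the A+T target in
# expectation. Deterministic (no randomness), cached per (code, target).
solve_at_tilt <- function(code, at_target) {
  f <- function(th) expected_at12(code, th) - at_target
  lo <- f(0.02); hi <- f(0.98)
  if (lo * hi > 0) {
    abort(sprintf("A+T target %.3f unreachable at codon positions 1-2.", at_target),
          class = "mitocub_infeasible_target")
  }
  uniroot(f, c(0.02, 0.98), tol = 1e-9)$root
}

# --- CDS generation ----------------------------------------------------------

# Pin the realized third-position G+C count of a sampled codon body to
# round(target * length) by synonymous swaps: excess W-ending (A/T) codons
# are re-drawn among their family's S-ending (G/C) alternatives with the
# family's conditional probabilities, or vice versa. Keeps amino-acid
# sequence fixed and within-family usage close to the sampled law, while
# removing the binomial noise in GC3 so composition targets are recovered
# tightly at realistic gene lengths.
calibrate_gc3 <- function(codons, target, fams, p, aas) {
  s3 <- substr(codons, 3, 3) %in% c("G", "C")
  want <- round(target * length(codons))
  delta <- want - sum(s3)
  if (delta == 0L) return(codons)
  to_s <- delta > 0L
  # positions currently on the wrong side whose family offers the other side
  fam_s3 <- lapply(fams, function(cs) substr(cs, 3, 3) %in% c("G", "C"))
  swappable <- vapply(aas, function(a) any(fam_s3[[a]] == to_s), logical(1))
  cand <- which((s3 != to_s) & swappable)
  if (length(cand) == 0L) return(codons)
  pick <- if (length(cand) <= abs(delta)) cand else
    cand[sample.int(length(cand), abs(delta))]
  for (i in pick) {
    cs <- fams[[aas[i]]]
    side <- fam_s3[[aas[i]]] == to_s
    w <- p[[aas[i]]][side]
    j <- if (sum(w) == 0) sample.int(sum(side), 1L) else
      sample.int(sum(side), 1L, prob = w)
    codons[i] <- cs[side][j]
  }
  codons
}

# Internal: draw one CDS in the *current* RNG stream.
# Returns list(sequence, codons) where codons are the body codons (start
# codon included, stop excluded).
gen_cds_stream <- function(n_codons, gc3_target, concentration, code, at_content,
                           aa_distribution = "background") {
  stopifnot(n_codons >= 2)
  fams <- code_families(code)
  q <- if (identical(aa_distribution, "uniform")) {
    setNames(rep(1 / length(fams), length(fams)), names(fams))
  } else {
    theta <- solve_at_tilt(code, at_content)
    aa_weights(code, base_probs(theta))[names(fams)]
  }

  # per-family codon probabilities: Dirichlet around uniform
  p0 <- lapply(fams, function(cs) setNames(rdirichlet1(length(cs), concentration), cs))

  # third-position tilt toward gc3_target
  if (!is.null(gc3_target)) {
    stopifnot(gc3_target >= 0, gc3_target <= 1)
    s3 <- lapply(fams, function(cs) substr(cs, 3, 3) %in% c("G", "C"))
    egc3 <- function(g) {
      sum(q * vapply(names(fams), function(a) {
        w <- p0[[a]] * ifelse(s3[[a]], g, 1 - g)
        if (sum(w) == 0) return(mean(s3[[a]]))
        sum(w[s3[[a]]]) / sum(w)
      }, numeric(1)))
    }
    eps <- 1e-9
    if (gc3_target < egc3(eps) - 1e-6 || gc3_target > egc3(1 - eps) + 1e-6) {
      abort(sprintf("gc3_target %.3f unreachable for this code/draw.", gc3_target),
            class = "mitocub_infeasible_target")
    }
    g <- uniroot(function(g) egc3(g) - gc3_target, c(eps, 1 - eps), tol = 1e-9)$root
    p <- lapply(names(fams), function(a) {
      w <- p0[[a]] * ifelse(s3[[a]], g, 1 - g)
      if (sum(w) == 0) p0[[a]] else w / sum(w)
    })
    names(p) <- names(fams)
  } else {
    p <- p0
  }

  n_body <- n_codons - 2L
  codons <- character(n_body)
  if (n_body > 0L) {
    aas <- sample(names(fams), n_body, replace = TRUE, prob = q)
    for (a in unique(aas)) {
      idx <- which(aas == a)
      cs <- fams[[a]]
      codons[idx] <- if (length(cs) == 1L) cs else
        sample(cs, length(idx), replace = TRUE, prob = p[[a]])
    }
    if (!is.null(gc3_target)) {
      codons <- calibrate_gc3(codons, gc3_target, fams, p, aas)
    }
  }
  start <- sample(intersect(c("ATT", "ATC", "ATA", "ATG"), code$start_codons), 1L)
  if (length(start) == 0L) start <- code$start_codons[1L]
  stop <- sample(code$stop_codons, 1L)
  list(sequence = paste0(start, paste(codons, collapse = ""), stop),
       codons = c(start, codons),
       stop = stop)
}

#' Generate a synthetic coding sequence
#'
#' Draws an in-frame CDS of `n_codons` codons (a start codon, a body of
#' synonymous-family draws, a stop codon). Within each synonymous family,
#' codon probabilities are one Dirichlet draw with the given concentration
#' (large = uniform usage, small = strong bias), then tilted at the third
#' position toward `gc3_target` and calibrated by synonymous swaps so the
#' realized third-position G+C count matches the target up to rounding
#' (plus the fixed start codon). Amino-acid frequencies
#' follow the AT-rich background implied by `at_content`, as in real
#' insect mitochondrial proteins. Deterministic given `seed`.
#'
#' @param n_codons total codons including start and stop (>= 2).
#' @param gc3_target target third-position G+C fraction, or `NULL` for no
#'   tilt.
#' @param bias_concentration positive Dirichlet concentration; `Inf` gives
#'   exactly uniform within-family usage.
#' @param code_id translation table (default 5).
#' @param at_content background A+T fraction shaping amino-acid usage
#'   (default 0.7182).
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @param gene name for the output row.
#' @param aa_distribution `"background"` (amino-acid frequencies implied by
#'   the AT-rich base composition, the default) or `"uniform"` (all
#'   families equally likely).
#' @return A one-row coding-sequence tibble (same shape as
#'   [extract_pcgs()] output) with the drawn codons in
#'   `attr(, "codons")`.
#' @examples
#' cds <- generate_cds(100, gc3_target = 0.25, seed = 7)
#' positional_gc(cds)$gc3
#' @export
generate_cds <- function(n_codons, gc3_target = NULL, bias_concentration = 1,
                         code_id = 5, at_content = 0.7182, seed = NULL,
                         gene = "synthetic", aa_distribution = "background") {
  code <- as_genetic_code(code_id)
  g <- with_seed(seed, gen_cds_stream(n_codons, gc3_target,
                                      bias_concentration, code, at_content,
                                      aa_distribution))
  out <- tibble(gene = gene, nucleotides = g$sequence,
                length_annotated = nchar(g$sequence),
                start_codon = substr(g$sequence, 1, 3),
                stop_codon = g$stop, stop_complete = TRUE,
                code_id = code$code_id)
  attr(out, "codons") <- g$codons
  out
}

#' Generate a synthetic annotated mitogenome
#'
#' Realizes a [synthetic_spec()] as a fully annotated [mitogenome()]:
#' features are laid out left to right with the requested signed spacings
#' (negative spacing = overlapping coordinates; overlapping sequence is
#' written once, with the downstream gene's bases taking precedence, as in
#' real atp8/atp6-style overlaps), PCGs are drawn with [generate_cds()] —
#' a PCG whose length is not a multiple of 3 gets a truncated (incomplete)
#' stop codon — and tRNA/rRNA/control features and intergenic gaps are
#' filled with composition-matched random sequence. Reverse-strand
#' features are written as the reverse complement of their sense sequence.
#'
#' The per-gene codon draws are attached as `attr(, "codon_tally")`, a
#' named list used to cross-check the counting pipeline (exact only for
#' genes not overwritten by a downstream overlap).
#'
#' @param spec a [synthetic_spec()].
#' @return A `mitogenome`.
#' @examples
#' g <- generate_mitogenome(synthetic_spec(seed = 1))
#' g
#' @export
generate_mitogenome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  go <- spec$gene_order
  n <- nrow(go)
  start <- integer(n); end <- integer(n)
  pos <- 0L
  for (i in seq_len(n)) {
    start[i] <- pos + 1L
    end[i] <- start[i] + go$length[i] - 1L
    if (start[i] < 1L) {
      abort(sprintf("spacing before %s pushes it beyond the origin.", go$gene[i]),
            class = "mitocub_geometry_error")
    }
    if (i > 1L && start[i] <= start[i - 1L]) {
      abort(sprintf("overlap at %s exceeds the upstream feature.", go$gene[i]),
            class = "mitocub_geometry_error")
    }
    pos <- end[i] + go$spacing[i]
  }
  genome_len <- max(end) + max(0L, go$spacing[n])
  code <- as_genetic_code(spec$code_id)
  pi_fill <- base_probs(spec$at_content)

  with_seed(spec$seed, {
    seq_vec <- character(genome_len)
    tally <- list()
    # Two passes: non-coding features first, then PCGs, so that coding
    # sequence is only ever overwritten in PCG-PCG overlaps (where the
    # downstream gene takes precedence, as documented).
    for (i in c(which(go$kind != "PCG"), which(go$kind == "PCG"))) {
      L <- go$length[i]
      if (go$kind[i] == "PCG") {
        r <- L %% 3L
        k <- (L - r) %/% 3L + (r > 0L)
        g <- gen_cds_stream(k, spec$gc3_target, spec$bias_concentration,
                            code, spec$at_content)
        s <- if (r > 0L) {
          paste0(substr(g$sequence, 1L, nchar(g$sequence) - 3L),
                 substr(g$stop, 1L, r))
        } else {
          g$sequence
        }
        tally[[go$gene[i]]] <- g$codons
      } else {
        s <- paste(sample(names(pi_fill), L, replace = TRUE, prob = pi_fill),
                   collapse = "")
      }
      if (go$strand[i] == "-") s <- revcomp(s)
      seq_vec[start[i]:end[i]] <- strsplit(s, "")[[1]]
    }
    holes <- which(seq_vec == "")
    if (length(holes)) {
      seq_vec[holes] <- sample(names(pi_fill), length(holes),
                               replace = TRUE, prob = pi_fill)
    }
    genome <- mitogenome(
      paste(seq_vec, collapse = ""),
      tibble(gene = go$gene, kind = go$kind, strand = go$strand,
             start = start, end = end, wraps_origin = FALSE,
             anticodon = go$anticodon, jn = go$jn),
      identifier = sprintf("synmt%d", spec$seed),
      topology = spec$topology)
    attr(genome, "codon_tally") <- tally
    attr(genome, "spec") <- spec
    genome
  })
}
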