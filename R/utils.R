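# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library code never perturbs the
# user's stream. `seed = NULL` runs in the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# One Dirichlet draw with common concentration `alpha` over `d` categories.
# alpha = Inf returns the uniform vector (no within-family bias).
rdirichlet1 <- function(d, alpha) {
  if (!is.finite(alpha)) return(rep(1 / d, d))
  g <- rgamma(d, shape = alpha)
  if (all(g == 0)) g <- rep(1, d)  # guard vanishing gamma draws at tiny alpha
  g / sum(g)
}

# Split a nucleotide string into consecutive codons; trailing remainder dropped.
split_codons <- function(x) {
  n <- nchar(x) %/% 3L
  if (n == 0L) return(character(0))
  substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

dna_to_rna <- function(x) chartr("Tt", "Uu", x)

is_acgt_codon <- function(codons) grepl("^[ACGT]{3}$", codons)

# Fixed-precision numeric formatting used by the report writers so that
# re-running an analysis yields byte-identical TSVs.
fmt_fixed <- function(x, digits) {
  out <- ifelse(is.na(x), "NA", formatC(x, format = "f", digits = digits))
  # normalise "-0.000" to "0.000"
  sub("^-(0\\.0+)$", "\\1", out)
}

`%!in%` <- function(x, y) !x %in% y
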