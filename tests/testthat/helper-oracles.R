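# Independent oracles and small fixture builders used across the suite.
# The oracles are written loop-by-loop from the definitions, independently
# of the package's vectorized paths.

# Brute-force Wright Nc from a named count vector over all 64 codons.
enc_brute <- function(counts, code_id) {
  map <- Biostrings::getGeneticCode(as.character(code_id), full.search = TRUE)
  sense <- names(map)[map != "*"]
  fam_rows <- list()
  for (a in unique(unname(map[sense]))) {
    cods <- sense[map[sense] == a]
    d <- length(cods)
    x <- as.numeric(counts[cods])
    n <- sum(x)
    if (n < 1) next  # unobserved amino acid
    if (d == 1) {
      Fh <- 1
    } else if (n > 1) {
      p <- x / n
      Fh <- (n * sum(p^2) - 1) / (n - 1)
    } else {
      Fh <- NA_real_
    }
    fam_rows[[length(fam_rows) + 1L]] <- data.frame(d = d, Fh = Fh)
  }
  fam <- do.call(rbind, fam_rows)
  ds <- sort(unique(fam$d))
  fbar <- nobs <- numeric(length(ds))
  for (i in seq_along(ds)) {
    sub <- fam[fam$d == ds[i], ]
    nobs[i] <- nrow(sub)
    vals <- sub$Fh[!is.na(sub$Fh)]
    fbar[i] <- if (length(vals) == 0 || mean(vals) <= 0) NA_real_ else mean(vals)
  }
  for (i in which(is.na(fbar))) {
    ok <- which(!is.na(fbar))
    dist <- abs(ds[ok] - ds[i])
    fbar[i] <- mean(fbar[ok[dist == min(dist)]])
  }
  min(sum(nobs / fbar), length(sense))
}

# GC3s by a per-codon filter loop, independent of positional_gc().
gc3s_brute <- function(nucleotides, code_id) {
  map <- Biostrings::getGeneticCode(as.character(code_id), full.search = TRUE)
  deg <- table(unname(map[map != "*"]))
  k <- substring(nucleotides, seq(1, nchar(nucleotides) - 2, 3),
                 seq(3, nchar(nucleotides), 3))
  hits <- 0; tot <- 0
  for (cod in k) {
    if (!grepl("^[ACGT]{3}$", cod)) next
    aa <- map[[cod]]
    if (aa == "*") next
    if (deg[[aa]] < 2) next
    tot <- tot + 1
    if (substr(cod, 3, 3) %in% c("G", "C")) hits <- hits + 1
  }
  if (tot == 0) NA_real_ else hits / tot
}

# A codon-count tibble (count_codons() shape) from a named vector.
make_counts <- function(x, code_id = 5) {
  out <- genetic_code(code_id)$codons
  out$count <- 0L
  out$count[match(names(x), out$codon)] <- as.integer(x)
  out$count[out$aa == "*"] <- 0L
  attr(out, "code_id") <- code_id
  out
}

# Random count table over the sense codons of a code.
random_counts <- function(code_id = 5, lambda = 5) {
  code <- genetic_code(code_id)
  sense <- code$codons$codon[code$codons$aa != "*"]
  make_counts(stats::setNames(stats::rpois(length(sense), lambda), sense),
              code_id)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Small three-feature mitogenome built by hand: a forward PCG, a reverse
# PCG and a tRNA, all with known sequence.
toy_genome <- function() {
  fwd <- "ATTAAACCTGGGTAA"                 # ATT AAA CCT GGG TAA
  rev <- "ATGTTTGAACATTAG"                 # ATG TTT GAA CAT TAG
  trna <- paste(rep("ACGT", 16), collapse = "")  # 64 nt filler
  seqs <- paste0(fwd, trna, revcomp_chr(rev))
  mitogenome(
    seqs,
    tibble::tibble(
      gene = c("nad2", "trnW", "cox1"),
      kind = c("PCG", "tRNA", "PCG"),
      strand = c("+", "+", "-"),
      start = c(1L, 16L, 80L),
      end = c(15L, 79L, 94L),
      anticodon = c(NA, "TCA", NA)),
    identifier = "toy", topology = "linear")
}

revcomp_chr <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}
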