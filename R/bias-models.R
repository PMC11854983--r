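#' Codon homozygosity of one synonymous family
#'
#' Wright's unbiased estimator of the probability that two randomly drawn
#' codons of an amino-acid family are identical:
#' `F = (n * sum(p_i^2) - 1) / (n - 1)` with `n` the family's total count
#' and `p_i` the within-family codon frequencies. Undefined (returned as
#' `NA`) when `n <= 1`.
#'
#' @param counts non-negative integer vector of codon counts for one
#'   amino acid.
#' @return A single numeric F-hat, or `NA`.
#' @examples
#' family_homozygosity(c(2, 2))  # 1/3
#' family_homozygosity(c(5, 0))  # 1
#' family_homozygosity(c(1, 0))  # NA
#' @export
family_homozygosity <- function(counts) {
  n <- sum(counts)
  if (n <= 1) return(NA_real_)
  p <- counts / n
  (n * sum(p^2) - 1) / (n - 1)
}

#' Observed effective number of codons (Wright's Nc)
#'
#' Wright's estimator of the effective number of codons, generalized to the
#' degeneracy-class structure of an arbitrary genetic code (the
#' invertebrate mitochondrial code has 2-, 4-, 6- and 8-fold families, so
#' the standard-code constants cannot be hard-coded). Amino-acid families
#' are grouped by degeneracy; each class contributes
#' `(number of observed amino acids in class) / mean F-hat of the class`,
#' where F-hat is [family_homozygosity()]. One-codon families always
#' contribute 1 each (F = 1 by construction). A class with no usable F-hat
#' (all families unobserved or single-count, or a zero mean) borrows the
#' mean of the nearest available classes by degeneracy distance — Wright's
#' repair rule for the missing 3-fold class, generalized. The result is
#' clipped at the code's sense-codon count, which small-sample noise can
#' otherwise exceed.
#'
#' Nc ranges from the number of amino-acid families in use (extreme bias:
#' one codon per family) up to the number of sense codons (62 under code 5;
#' no bias).
#'
#' @param counts codon-count tibble from [count_codons()] (or input
#'   accepted by it).
#' @param code_id translation table; defaults to the code attached to the
#'   counts, else 5.
#' @param warn_low warn when fewer than 30 codons are counted (the
#'   estimator is noisy there). Default `TRUE`.
#' @return A single numeric Nc.
#' @examples
#' cc <- count_codons("ATGAAAAAATTATTATAA")
#' enc_observed(cc, warn_low = FALSE)
#' @export
enc_observed <- function(counts, code_id = NULL, warn_low = TRUE) {
  if (!is.data.frame(counts) || !"count" %in% names(counts)) {
    counts <- count_codons(counts, code_id %||% 5)
  }
  code <- as_genetic_code(code_id %||% attr(counts, "code_id") %||% 5)
  total <- sum(counts$count)
  if (warn_low && total < 30) {
    warn(sprintf("only %d codons counted; Nc is noisy below ~30.", total))
  }
  fam <- counts |>
    dplyr::filter(.data$aa != "*") |>
    dplyr::group_by(.data$aa, .data$degeneracy) |>
    dplyr::summarise(n = sum(.data$count),
                     f_hat = family_homozygosity(.data$count),
                     .groups = "drop")
  fam$f_hat[fam$degeneracy == 1L & fam$n >= 1L] <- 1
  fam <- fam[fam$n >= 1L, ]  # unobserved amino acids do not enter Nc
  if (nrow(fam) == 0L) {
    abort("no observed amino-acid family.", class = "mitocub_insufficient_data")
  }
  cls <- fam |>
    dplyr::group_by(.data$degeneracy) |>
    dplyr::summarise(n_aa = dplyr::n(),
                     f_bar = if (all(is.na(.data$f_hat))) NA_real_
                             else mean(.data$f_hat, na.rm = TRUE),
                     .groups = "drop")
  cls$f_bar[!is.na(cls$f_bar) & cls$f_bar <= 0] <- NA_real_
  if (all(is.na(cls$f_bar))) {
    abort("no degeneracy class has a usable homozygosity estimate.",
          class = "mitocub_insufficient_data")
  }
  # repair rule: borrow the mean of the nearest available classes
  for (i in which(is.na(cls$f_bar))) {
    ok <- which(!is.na(cls$f_bar))
    d <- abs(cls$degeneracy[ok] - cls$degeneracy[i])
    cls$f_bar[i] <- mean(cls$f_bar[ok[d == min(d)]])
  }
  min(sum(cls$n_aa / cls$f_bar), code$n_sense)
}

#' Expected ENC under mutation pressure alone
#'
#' The null curve of the ENC-plot: the effective number of codons a gene
#' would show if codon usage were shaped only by its third-position
#' composition, `ENC = 2 + GC3s + 29 / (GC3s^2 + (1 - GC3s)^2)`.
#'
#' @param gc3s G+C fraction at synonymous third positions, in `[0, 1]`
#'   (vectorized).
#' @return Expected ENC values.
#' @examples
#' enc_expected(c(0, 0.5, 1))  # 31, 60.5, 32
#' @export
enc_expected <- function(gc3s) {
  if (any(!is.na(gc3s) & (gc3s < 0 | gc3s > 1))) {
    abort("`gc3s` must lie in [0, 1].", class = "mitocub_domain_error")
  }
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

#' ENC-plot points for the protein-coding genes of a genome
#'
#' Computes, per PCG, the synonymous third-position GC (GC3s), the observed
#' effective number of codons and the expected ENC at that GC3s. Genes
#' lying well below the expected curve (large positive `residual`) show
#' more codon bias than composition alone explains, the classic signature
#' of selection; genes on the curve are compatible with mutation pressure.
#'
#' @param x a [mitogenome()] or a coding-sequence tibble from
#'   [extract_pcgs()] / [generate_cds()].
#' @param code_id translation table (default 5).
#' @return A tibble of class `enc_table`: `gene`, `n_codons`, `gc3s`,
#'   `enc_obs`, `enc_exp`, `residual` (= `enc_exp - enc_obs`). Plot with
#'   [autoplot()].
#' @examples
#' g <- generate_mitogenome(synthetic_spec(seed = 1))
#' enc_table(g)
#' @export
enc_table <- function(x, code_id = 5) {
  cds <- if (inherits(x, "mitogenome")) extract_pcgs(x, code_id) else as_tibble(x)
  pos <- positional_gc(cds, code_id)
  obs <- vapply(seq_len(nrow(cds)), function(i) {
    enc_observed(count_codons(cds[i, ], code_id), code_id, warn_low = FALSE)
  }, numeric(1))
  out <- tibble(gene = cds$gene, n_codons = pos$n_codons, gc3s = pos$gc3s,
                enc_obs = obs, enc_exp = enc_expected(pos$gc3s),
                residual = enc_expected(pos$gc3s) - obs)
  class(out) <- c("enc_table", class(out))
  out
}

#' Neutrality-plot regression of GC12 on GC3
#'
#' Ordinary least-squares fit of per-gene GC12 (mean of the first- and
#' second-position G+C) on GC3, with the Pearson correlation and its
#' two-sided t-test p-value (n - 2 df). A slope near 1 says the three
#' codon positions drift together — composition is mutation-driven; a
#' slope near 0 says positions 1-2 are constrained while position 3 moves,
#' the signature of selection.
#'
#' @param points per-gene table with columns `gc12` and `gc3` (e.g. from
#'   [positional_gc()]), one row per gene.
#' @return Object of class `neutrality_fit` with fields `slope`,
#'   `intercept`, `r`, `p_value`, `n`, the underlying `lm` in `model`, and
#'   the input in `data`. Methods: `print()`, [tidy()], [glance()],
#'   [autoplot()].
#' @examples
#' pts <- tibble::tibble(gc3 = c(.2, .4, .6), gc12 = c(.2, .4, .6))
#' neutrality_fit(pts)$slope  # 1
#' @export
neutrality_fit <- function(points) {
  points <- as_tibble(points)
  stopifnot(all(c("gc12", "gc3") %in% names(points)))
  points <- points[stats::complete.cases(points[, c("gc12", "gc3")]), ]
  if (nrow(points) < 3L) {
    abort("need at least 3 genes for the neutrality fit.",
          class = "mitocub_degenerate_fit")
  }
  if (stats::var(points$gc3) == 0) {
    abort("GC3 has zero variance; fit is degenerate.",
          class = "mitocub_degenerate_fit")
  }
  fit <- lm(gc12 ~ gc3, data = points)
  ct <- suppressWarnings(cor.test(points$gc3, points$gc12))
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r = unname(ct$estimate), p_value = ct$p.value,
         n = nrow(points), model = fit, data = points),
    class = "neutrality_fit"
  )
}

#' @export
print.neutrality_fit <- function(x, ...) {
  cat(sprintf(
    "<neutrality_fit> n = %d genes\n  GC12 = %.4f + %.4f * GC3   (r = %.3f, p = %.3g)\n",
    x$n, x$intercept, x$slope, x$r, x$p_value))
  invisible(x)
}

#' @rdname neutrality_fit
#' @param x a `neutrality_fit`.
#' @param ... unused.
#' @export
tidy.neutrality_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble(term = rownames(s), estimate = unname(s[, 1]),
         std.error = unname(s[, 2]), statistic = unname(s[, 3]),
         p.value = unname(s[, 4]))
}

#' @rdname neutrality_fit
#' @export
glance.neutrality_fit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r = x$r,
         r.squared = x$r^2, p.value = x$p_value, n = x$n)
}
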