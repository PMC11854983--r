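# Report writers: deterministic TSV bundles for single-genome and
# multi-species comparative analyses. All tables are tab-separated, UTF-8,
# Unix newlines; numbers are written at fixed precision (percentages 2 d.p.,
# skews 3 d.p., GC fractions 4 d.p., ENC/RSCU 3 d.p.) so re-running an
# analysis on the same input yields byte-identical files.

default_rounding <- function() {
  list(percent = 2L, skew = 3L, gc = 4L, enc = 3L, rscu = 3L)
}

resolve_genome <- function(x, code_id) {
  if (inherits(x, "mitogenome")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    return(read_genbank(x, simplify = TRUE))
  }
  abort(paste0("cannot interpret input as a mitogenome: ",
               if (is.character(x)) x else class(x)[1]),
        class = "mitocub_bad_input")
}

write_tsv_det <- function(df, path) {
  readr::write_tsv(df, path, na = "NA", eol = "\n")
  path
}

# Analysis of one genome, in memory. Returns the list of result tables.
analyze_genome <- function(genome, code_id = 5) {
  cds <- extract_pcgs(genome, code_id)
  counts <- count_codons(cds, code_id)
  pos <- positional_gc(cds, code_id)
  nf <- if (nrow(pos) >= 3L && stats::var(pos$gc3) > 0) {
    neutrality_fit(pos)
  } else {
    warn(sprintf("%s: fewer than 3 usable PCGs (or no GC3 variance); no neutrality fit.",
                 genome$identifier))
    NULL
  }
  list(
    annotation = annotation_table(genome, code_id),
    composition = composition_table(genome),
    rscu = rscu(counts),
    enc = enc_table(cds, code_id),
    neutrality = dplyr::select(pos, "gene", "gc12", "gc3"),
    neutrality_fit = nf,
    cds = cds
  )
}

#' Single-genome analysis report
#'
#' Runs the full per-species pipeline on each input genome and writes the
#' report bundle: `annotation.tsv` (annotation-accounting layout),
#' `composition.tsv`, `rscu.tsv`, `enc.tsv`, `neutrality.tsv` (per-gene
#' GC12/GC3), `neutrality_fit.tsv` (the fit summary block) and a
#' `manifest.json` listing every output with its MD5 checksum. With more
#' than one input, each genome gets a subdirectory named by its identifier.
#'
#' @param inputs a `mitogenome`, a GenBank file path, or a list/vector of
#'   them.
#' @param output_dir directory to write into (created if needed).
#' @param code_id translation table (default 5).
#' @param plots also write `enc_plot.pdf` / `neutrality_plot.pdf`? Default
#'   `FALSE`; the TSVs are the contract, plots are presentational.
#' @param rounding named list of report digits (`percent`, `skew`, `gc`,
#'   `enc`, `rscu`).
#' @return Invisibly, a named list (one element per genome) of the result
#'   tables.
#' @seealso [mito_compare()]
#' @export
mito_analyze <- function(inputs, output_dir, code_id = 5, plots = FALSE,
                         rounding = default_rounding()) {
  if (inherits(inputs, "mitogenome") || is.character(inputs) && length(inputs) == 1L) {
    inputs <- list(inputs)
  }
  if (length(inputs) == 0L) {
    abort("no inputs given.", class = "mitocub_usage_error")
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  for (x in inputs) {
    genome <- resolve_genome(x, code_id)
    dir <- if (length(inputs) > 1L) {
      d <- file.path(output_dir, genome$identifier)
      dir.create(d, showWarnings = FALSE)
      d
    } else output_dir
    res <- analyze_genome(genome, code_id)
    files <- write_bundle(res, dir, rounding)
    if (plots) files <- c(files, write_plots(res, dir))
    write_manifest(dir, files,
                   config = list(identifier = genome$identifier,
                                 accession = genome$accession,
                                 code_id = code_id,
                                 rounding = rounding))
    results[[genome$identifier]] <- res
  }
  invisible(results)
}

write_bundle <- function(res, dir, rounding) {
  r <- rounding
  ann <- res$annotation
  files <- c(
    write_tsv_det(ann, file.path(dir, "annotation.tsv")),
    write_tsv_det(
      dplyr::mutate(res$composition,
                    dplyr::across(dplyr::ends_with("_pct"), ~fmt_fixed(.x, r$percent)),
                    dplyr::across(dplyr::ends_with("_skew"), ~fmt_fixed(.x, r$skew))),
      file.path(dir, "composition.tsv")),
    write_tsv_det(
      dplyr::mutate(res$rscu, rscu = fmt_fixed(.data$rscu, r$rscu)),
      file.path(dir, "rscu.tsv")),
    write_tsv_det(
      dplyr::mutate(res$enc,
                    dplyr::across(c("gc3s"), ~fmt_fixed(.x, r$gc)),
                    dplyr::across(c("enc_obs", "enc_exp", "residual"),
                                  ~fmt_fixed(.x, r$enc))),
      file.path(dir, "enc.tsv")),
    write_tsv_det(
      dplyr::mutate(res$neutrality,
                    dplyr::across(c("gc12", "gc3"), ~fmt_fixed(.x, r$gc))),
      file.path(dir, "neutrality.tsv"))
  )
  if (!is.null(res$neutrality_fit)) {
    files <- c(files, write_tsv_det(
      dplyr::mutate(glance(res$neutrality_fit),
                    dplyr::across(c("slope", "intercept", "r", "r.squared"),
                                  ~fmt_fixed(.x, 4L)),
                    p.value = formatC(.data$p.value, format = "g", digits = 4)),
      file.path(dir, "neutrality_fit.tsv")))
  }
  files
}

write_plots <- function(res, dir) {
  f1 <- file.path(dir, "enc_plot.pdf")
  ggplot2::ggsave(f1, autoplot(res$enc), width = 6, height = 4)
  f2 <- file.path(dir, "neutrality_plot.pdf")
  if (!is.null(res$neutrality_fit)) {
    ggplot2::ggsave(f2, autoplot(res$neutrality_fit), width = 6, height = 4)
    c(f1, f2)
  } else f1
}

write_manifest <- function(dir, files, config) {
  manifest <- list(
    package = "mitocub",
    version = as.character(packageVersion("mitocub")),
    config = config,
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) list(md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(file.path(dir, "manifest.json"))
}

#' Multi-species comparative report
#'
#' The comparative mode of the pipeline: pools each species' 13 PCGs into a
#' species-level RSCU (codon counts concatenated before RSCU, not per-gene
#' RSCU averaged), computes per-gene ENC-plot points per species, and
#' collects every species' neutrality regression into one summary of
#' slopes. Species with fewer than 3 usable PCGs are excluded from the
#' neutrality summary with a warning.
#'
#' Writes `rscu_long.tsv` (species x codon), `enc_by_species.tsv`,
#' `neutrality_summary.tsv` and `manifest.json` into `output_dir`.
#'
#' @param inputs list of >= 2 `mitogenome`s or GenBank file paths.
#' @param output_dir directory to write into.
#' @param code_id translation table (default 5).
#' @param rounding report precision, as in [mito_analyze()].
#' @return Invisibly, a list with tibbles `rscu_long`, `enc`,
#'   `neutrality_summary`.
#' @export
mito_compare <- function(inputs, output_dir, code_id = 5,
                         rounding = default_rounding()) {
  if (length(inputs) < 2L) {
    abort("comparative mode needs at least 2 inputs.",
          class = "mitocub_usage_error")
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  rscu_long <- list(); enc_all <- list(); fits <- list()
  for (x in inputs) {
    genome <- resolve_genome(x, code_id)
    id <- genome$identifier
    cds <- extract_pcgs(genome, code_id)
    rscu_long[[length(rscu_long) + 1L]] <-
      dplyr::mutate(rscu(count_codons(cds, code_id)), species = id, .before = 1)
    enc_all[[length(enc_all) + 1L]] <-
      dplyr::mutate(as_tibble(enc_table(cds, code_id)), species = id, .before = 1)
    pos <- positional_gc(cds, code_id)
    if (nrow(pos) >= 3L && stats::var(pos$gc3) > 0) {
      fits[[length(fits) + 1L]] <-
        dplyr::mutate(glance(neutrality_fit(pos)), species = id, .before = 1)
    } else {
      warn(sprintf("%s: <3 usable PCGs; excluded from neutrality summary.", id))
    }
  }
  out <- list(rscu_long = dplyr::bind_rows(rscu_long),
              enc = dplyr::bind_rows(enc_all),
              neutrality_summary = dplyr::bind_rows(fits))
  r <- rounding
  files <- c(
    write_tsv_det(dplyr::mutate(out$rscu_long, rscu = fmt_fixed(.data$rscu, r$rscu)),
                  file.path(output_dir, "rscu_long.tsv")),
    write_tsv_det(
      dplyr::mutate(out$enc,
                    gc3s = fmt_fixed(.data$gc3s, r$gc),
                    dplyr::across(c("enc_obs", "enc_exp", "residual"),
                                  ~fmt_fixed(.x, r$enc))),
      file.path(output_dir, "enc_by_species.tsv")),
    write_tsv_det(
      dplyr::mutate(out$neutrality_summary,
                    dplyr::across(c("slope", "intercept", "r", "r.squared"),
                                  ~fmt_fixed(.x, 4L)),
                    p.value = formatC(.data$p.value, format = "g", digits = 4)),
      file.path(output_dir, "neutrality_summary.tsv"))
  )
  write_manifest(output_dir, files,
                 config = list(n_species = length(inputs), code_id = code_id,
                               rounding = rounding))
  invisible(out)
}
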