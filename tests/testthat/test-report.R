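expected_files <- c("annotation.tsv", "composition.tsv", "rscu.tsv",
                    "enc.tsv", "neutrality.tsv", "neutrality_fit.tsv",
                    "manifest.json")

test_that("single-genome analysis writes the full, internally consistent bundle", {
  g <- generate_mitogenome(synthetic_spec(seed = 31))
  out <- withr::local_tempdir()
  res <- suppressWarnings(mito_analyze(g, out))
  expect_true(all(file.exists(file.path(out, expected_files))))
  ann <- readr::read_tsv(file.path(out, "annotation.tsv"),
                         show_col_types = FALSE)
  expect_equal(nrow(ann), 38)
  comp <- readr::read_tsv(file.path(out, "composition.tsv"),
                          show_col_types = FALSE)
  expect_equal(nrow(comp), 16)
  enc <- readr::read_tsv(file.path(out, "enc.tsv"), show_col_types = FALSE)
  expect_equal(nrow(enc), 13)
  neut <- readr::read_tsv(file.path(out, "neutrality.tsv"),
                          show_col_types = FALSE)
  expect_equal(nrow(neut), 13)
  # manifest lists every file with a correct checksum
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  listed <- names(man$files)
  expect_setequal(listed, setdiff(expected_files, "manifest.json"))
  for (f in listed) {
    expect_equal(man$files[[f]]$md5,
                 unname(tools::md5sum(file.path(out, f))))
  }
})

test_that("re-running the analysis yields byte-identical tables", {
  g <- generate_mitogenome(synthetic_spec(seed = 32))
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  suppressWarnings(mito_analyze(g, out1))
  suppressWarnings(mito_analyze(g, out2))
  for (f in setdiff(expected_files, "manifest.json")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)),
                     label = f)
  }
})

test_that("analysis accepts GenBank paths and rejects empty input", {
  g <- generate_mitogenome(synthetic_spec(seed = 33))
  gb <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, gb)
  out <- withr::local_tempdir()
  res <- suppressWarnings(mito_analyze(gb, out))
  expect_named(res, g$identifier)
  expect_error(mito_analyze(list(), withr::local_tempdir()),
               class = "mitocub_usage_error")
  expect_error(suppressWarnings(mito_analyze("/no/such/file.gb",
                                             withr::local_tempdir())),
               class = "mitocub_bad_input")
})

test_that("comparative mode separates species with different bias strengths", {
  specs <- list(
    synthetic_spec(bias_concentration = 0.1, seed = 41),
    synthetic_spec(bias_concentration = 1, seed = 42),
    synthetic_spec(bias_concentration = 100, seed = 43))
  genomes <- lapply(specs, generate_mitogenome)
  out <- withr::local_tempdir()
  res <- suppressWarnings(mito_compare(genomes, out))
  expect_true(all(file.exists(file.path(
    out, c("rscu_long.tsv", "enc_by_species.tsv",
           "neutrality_summary.tsv", "manifest.json")))))
  expect_equal(nrow(res$neutrality_summary), 3)
  mean_enc <- tapply(res$enc$enc_obs, res$enc$species, mean)
  ids <- vapply(genomes, function(g) g$identifier, character(1))
  expect_true(mean_enc[[ids[1]]] < mean_enc[[ids[2]]])
  expect_true(mean_enc[[ids[2]]] < mean_enc[[ids[3]]])
  # RSCU long table has one block per species over the same codon set
  expect_equal(nrow(res$rscu_long), 3 * 62)
})

test_that("comparative mode is idempotent and guards its preconditions", {
  g <- generate_mitogenome(synthetic_spec(seed = 44))
  out <- withr::local_tempdir()
  res <- suppressWarnings(mito_compare(list(g, g), out))
  half <- nrow(res$enc) / 2
  expect_equal(res$enc$enc_obs[seq_len(half)],
               res$enc$enc_obs[half + seq_len(half)])
  expect_error(mito_compare(list(g), withr::local_tempdir()),
               class = "mitocub_usage_error")
  # a species with < 3 PCGs is excluded from the neutrality summary
  go <- default_gene_order()
  go <- go[go$kind != "PCG" | go$gene %in% c("cox1", "nad2"), ]
  go$spacing <- 0L
  g2 <- generate_mitogenome(synthetic_spec(gene_order = go, seed = 45))
  ws <- testthat::capture_warnings(
    res2 <- mito_compare(list(g, g2), withr::local_tempdir()))
  expect_true(any(grepl("excluded", ws)))
  expect_equal(nrow(res2$neutrality_summary), 1)
})

test_that("autoplot and plot_rscu return ggplot objects", {
  g <- generate_mitogenome(synthetic_spec(seed = 46))
  cds <- suppressWarnings(extract_pcgs(g))
  expect_s3_class(autoplot(enc_table(cds)), "ggplot")
  expect_s3_class(autoplot(neutrality_fit(positional_gc(cds))), "ggplot")
  expect_s3_class(plot_rscu(rscu(count_codons(cds))), "ggplot")
})

test_that("the command-line wrapper runs synth and analyze with the exit-code contract", {
  cli <- system.file("cli", "mitocub.R", package = "mitocub")
  expect_true(nzchar(cli))
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- withr::local_tempdir()
  env <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  s1 <- system2(rscript, c(cli, "synth", "--out", out, "--seed", "2"),
                env = env, stdout = TRUE, stderr = TRUE)
  gb <- list.files(out, pattern = "\\.gb$", full.names = TRUE)
  expect_length(gb, 1)
  expect_true(file.exists(file.path(out, "synmt2_spec.json")))
  out2 <- withr::local_tempdir()
  status <- suppressWarnings(system2(
    rscript, c(cli, "analyze", "--out", out2, gb),
    env = env, stdout = NULL, stderr = NULL))
  expect_equal(status, 0)
  expect_true(file.exists(file.path(out2, "enc.tsv")))
  status_bad <- system2(rscript, c(cli, "analyze", "--out", out2),
                        env = env, stdout = NULL, stderr = NULL)
  expect_equal(status_bad, 2)
})
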