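test_that("GenBank records parse with normalized names, strands and kinds", {
  rec <- c(
    "LOCUS       testrec          200 bp    DNA     circular INV 01-JAN-2026",
    "ACCESSION   XX000001",
    "FEATURES             Location/Qualifiers",
    "     source          1..200",
    "     CDS             complement(10..54)",
    "                     /gene=\"ND2\"",
    "     tRNA            60..125",
    "                     /product=\"tRNA-Ser\"",
    "                     /note=\"anticodon:TGA\"",
    "     rRNA            130..150",
    "                     /product=\"16S ribosomal RNA\"",
    "     D-loop          151..190",
    "ORIGIN",
    paste0("        1 ", tolower(paste(substring(random_dna(60),
                                                 seq(1, 51, 10), seq(10, 60, 10)),
                                       collapse = " "))),
    "//")
  # three more origin lines to reach 200 bp
  set.seed(1)
  rec <- append(rec, values = c(
    paste0("       61 ", tolower(random_dna(60))),
    paste0("      121 ", tolower(random_dna(60))),
    paste0("      181 ", tolower(random_dna(20)))), after = length(rec) - 1)
  g <- read_genbank(rec)
  expect_s3_class(g, "mitogenome")
  expect_equal(g$accession, "XX000001")
  expect_equal(g$topology, "circular")
  expect_equal(nchar(g$sequence), 200)
  expect_equal(g$features$gene, c("nad2", "trnS2", "rrnL", "OH"))
  expect_equal(g$features$kind, c("PCG", "tRNA", "rRNA", "control"))
  expect_equal(g$features$strand, c("-", "+", "+", "+"))
  expect_equal(g$features$anticodon[2], "TGA")
})

test_that("degenerate and malformed records are handled as specified", {
  expect_error(read_genbank("no genbank here"), class = "mitocub_no_records")
  bare <- c("LOCUS       empty            12 bp    DNA     linear INV 01-JAN-2026",
            "ORIGIN", "        1 acgtacgtacgt", "//")
  expect_warning(g <- read_genbank(bare), "no annotated features")
  expect_equal(nrow(g$features), 0)
  bad <- c("LOCUS       bad              12 bp    DNA     linear INV 01-JAN-2026",
           "FEATURES             Location/Qualifiers",
           "     CDS             1..999",
           "                     /gene=\"cox1\"",
           "ORIGIN", "        1 acgtacgtacgt", "//")
  expect_error(read_genbank(bad), class = "mitocub_malformed_record")
})

test_that("write/parse round-trip reproduces synthetic genomes exactly", {
  for (seed in c(1, 7)) {
    g <- generate_mitogenome(synthetic_spec(seed = seed))
    path <- withr::local_tempfile(fileext = ".gb")
    write_genbank(g, path)
    g2 <- read_genbank(path)
    expect_identical(g2$sequence, g$sequence)
    expect_identical(g2$topology, g$topology)
    expect_equal(as.data.frame(g2$features), as.data.frame(g$features))
  }
})

test_that("features wrapping the circular origin round-trip and materialize", {
  body <- "ATTAAACCTGGGTAA"  # 15 nt CDS wrapping the origin: 91..100 + 1..5
  mid <- random_dna(85)
  seqs <- paste0(substr(body, 11, 15), mid, substr(body, 1, 10))
  g <- mitogenome(seqs, tibble::tibble(
    gene = "nad3", kind = "PCG", strand = "+", start = 91L, end = 5L,
    wraps_origin = TRUE), identifier = "wrap", topology = "circular")
  cds <- extract_pcgs(g)
  expect_equal(cds$nucleotides, body)
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, path)
  g2 <- read_genbank(path)
  expect_true(g2$features$wraps_origin[1])
  expect_equal(extract_pcgs(g2)$nucleotides, body)
})

test_that("PCG extraction is strand-aware and codon-exact", {
  g <- toy_genome()
  cds <- extract_pcgs(g)
  expect_equal(cds$gene, c("nad2", "cox1"))
  expect_equal(cds$nucleotides[1], "ATTAAACCTGGGTAA")
  expect_equal(cds$nucleotides[2], "ATGTTTGAACATTAG")  # reverse complement
  expect_equal(cds$start_codon, c("ATT", "ATG"))
  expect_equal(cds$stop_codon, c("TAA", "TAG"))
  expect_true(all(cds$stop_complete))
})

test_that("incomplete terminal stops are trimmed, recorded, and account for span length", {
  # 11 nt span: ATG AAA TTT + "TA" remainder
  s <- "ATGAAATTTTA"
  g <- mitogenome(paste0(s, random_dna(20)),
                  tibble::tibble(gene = "cox3", kind = "PCG", strand = "+",
                                 start = 1L, end = 11L),
                  topology = "linear")
  cds <- suppressWarnings(extract_pcgs(g))
  expect_equal(nchar(cds$nucleotides), 9)
  expect_equal(cds$stop_codon, "TA")
  expect_false(cds$stop_complete)
  # invariant: 3 * codon count + remainder length == annotated span
  expect_equal(3 * (nchar(cds$nucleotides) %/% 3) + nchar(cds$stop_codon),
               cds$length_annotated)

  # 1-nt remainder case
  g1 <- mitogenome(paste0("ATGAAATTTTAAC", random_dna(20)),
                   tibble::tibble(gene = "cox2", kind = "PCG", strand = "+",
                                  start = 1L, end = 13L),
                   topology = "linear")
  cds1 <- extract_pcgs(g1)
  expect_equal(cds1$stop_codon, "C")
  expect_equal(nchar(cds1$nucleotides), 12)
})

test_that("pathological coding sequences raise the specified conditions", {
  g <- mitogenome(paste0("ATGTA", random_dna(20)),
                  tibble::tibble(gene = "tiny", kind = "PCG", strand = "+",
                                 start = 1L, end = 5L),
                  topology = "linear")
  expect_error(extract_pcgs(g), class = "mitocub_too_short")
  g2 <- mitogenome(paste0("ATGTAAAAATAA", random_dna(10)),
                   tibble::tibble(gene = "istop", kind = "PCG", strand = "+",
                                  start = 1L, end = 12L),
                   topology = "linear")
  expect_warning(extract_pcgs(g2), "internal stop")
  bare <- suppressWarnings(mitogenome("ACGTACGT",
                                      tibble::tibble(gene = "t", kind = "tRNA",
                                                     strand = "+", start = 1L,
                                                     end = 8L)[0, ],
                                      topology = "linear"))
  expect_error(extract_pcgs(bare), class = "mitocub_no_pcgs")
})

test_that("intergenic spacings follow coordinate arithmetic, including the circular wrap", {
  ann <- crataceus_annotation()
  ig <- intergenic_table(ann, topology = "circular", genome_length = 17946)
  expect_equal(ig$spacing[ig$upstream == "trnI"], -3)
  expect_equal(ig$spacing[ig$upstream == "trnQ"], -2)
  expect_equal(ig$spacing[ig$upstream == "trnM"], 0)   # abuts nad2
  expect_equal(ig$spacing[ig$upstream == "OH"], 0)     # wraps to trnI
  expect_equal(nrow(ig), nrow(ann))                    # one record per junction
  # published intergenic column matches coordinates everywhere except the
  # typographical trnP row
  recomputed <- ig$spacing[match(ann$gene, ig$upstream)]
  agree <- recomputed == ann$intergenic
  expect_equal(ann$gene[!agree], "trnP")
  dup <- ann[c(1, 1, 2), ]
  expect_error(intergenic_table(dup), class = "mitocub_duplicate_feature")
})

test_that("a linear walk of lengths plus spacings reconstructs the genome length", {
  go <- default_gene_order()
  go$spacing <- 0L
  spec <- synthetic_spec(gene_order = go, topology = "linear", seed = 3)
  g <- generate_mitogenome(spec)
  expect_equal(nchar(g$sequence), sum(go$length))
  ig <- intergenic_table(g)
  expect_true(all(ig$spacing == 0))
})

test_that("FASTA plus feature-table input matches the GenBank route", {
  g <- generate_mitogenome(synthetic_spec(seed = 11))
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(paste0(">", g$identifier), g$sequence), fa)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(
    tibble::tibble(name = g$features$gene, kind = g$features$kind,
                   strand = g$features$jn, start = g$features$start,
                   end = g$features$end, anticodon = g$features$anticodon),
    tsv)
  g2 <- read_feature_table(fa, tsv)
  expect_identical(g2$sequence, g$sequence)
  expect_equal(g2$features$gene, g$features$gene)
  expect_equal(g2$features$strand, g$features$strand)  # J/N mapped back
  expect_equal(composition_table(g2), composition_table(g))
})

test_that("annotation accounting reproduces the synthetic geometry", {
  spec <- synthetic_spec(seed = 5)
  g <- generate_mitogenome(spec)
  ann <- suppressWarnings(annotation_table(g))
  expect_equal(ann$length, spec$gene_order$length)
  expect_equal(ann$gene, spec$gene_order$gene)
  # spacing to next feature equals the spec's requested spacing (wrap gap 0)
  expect_equal(ann$intergenic,
               c(spec$gene_order$spacing[-nrow(ann)], 0L))
})
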