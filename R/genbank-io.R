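#' Read annotated mitogenomes from a GenBank flat file
#'
#' Parses one or more GenBank records (LOCUS/FEATURES/ORIGIN) into
#' [mitogenome()] objects. Feature keys `CDS`, `tRNA`, `rRNA`, `D-loop`,
#' `rep_origin` and control-like `misc_feature`s are kept (`gene` and
#' `source` keys are skipped as duplicates); locations may be
#' `complement(...)` and a two-segment `join(a..b,1..c)` on a circular
#' record is read as a feature wrapping the origin. Gene names are
#' normalized with [normalize_gene_name()].
#'
#' @param path path to a GenBank flat file, or a character vector of its
#'   lines.
#' @param simplify if `TRUE` (default) a single-record file returns the
#'   `mitogenome` itself rather than a length-1 list.
#' @return A `mitogenome` or list of them.
#' @seealso [write_genbank()], [read_feature_table()]
#' @export
read_genbank <- function(path, simplify = TRUE) {
  lines <- if (length(path) == 1L && !grepl("\n", path) && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else {
    unlist(strsplit(path, "\n", fixed = TRUE))
  }
  starts <- grep("^LOCUS", lines)
  if (length(starts) == 0L) {
    abort("no GenBank records found in input.", class = "mitocub_no_records")
  }
  ends <- grep("^//", lines)
  genomes <- lapply(seq_along(starts), function(i) {
    to <- ends[ends >= starts[i]][1]
    if (is.na(to)) to <- length(lines)
    parse_genbank_record(lines[starts[i]:to])
  })
  if (simplify && length(genomes) == 1L) genomes[[1]] else genomes
}

parse_genbank_record <- function(rec) {
  locus <- strsplit(trimws(rec[1]), "\\s+")[[1]]
  identifier <- locus[2] %||% "record"
  topology <- if ("circular" %in% tolower(locus)) "circular" else "linear"
  acc_line <- grep("^ACCESSION", rec, value = TRUE)
  accession <- if (length(acc_line)) {
    a <- strsplit(trimws(acc_line[1]), "\\s+")[[1]][2]
    if (is.na(a)) NA_character_ else a
  } else NA_character_

  fstart <- grep("^FEATURES", rec)
  ostart <- grep("^ORIGIN", rec)
  if (length(ostart) == 0L) {
    abort("record has no ORIGIN sequence.", class = "mitocub_no_records")
  }
  seq_lines <- rec[(ostart[1] + 1L):length(rec)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  feats <- list()
  if (length(fstart)) {
    block <- rec[(fstart[1] + 1L):(ostart[1] - 1L)]
    cur <- NULL
    for (ln in block) {
      if (grepl("^ {1,10}\\S", ln) && !grepl("^\\s*/", ln)) {
        # new feature line: key + location
        if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
        parts <- strsplit(trimws(ln), "\\s+")[[1]]
        cur <- list(key = parts[1], loc = paste(parts[-1], collapse = ""),
                    quals = character(0), open_qual = FALSE)
      } else if (!is.null(cur) && grepl("^\\s*/", ln)) {
        cur$quals <- c(cur$quals, trimws(ln))
        cur$open_qual <- TRUE
      } else if (!is.null(cur)) {
        # continuation of location or of the last qualifier
        if (cur$open_qual && length(cur$quals)) {
          cur$quals[length(cur$quals)] <-
            paste(cur$quals[length(cur$quals)], trimws(ln))
        } else {
          cur$loc <- paste0(cur$loc, trimws(ln))
        }
      }
    }
    if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
  }

  rows <- purrr::map(feats, parse_one_feature, topology = topology)
  rows <- purrr::compact(rows)
  features <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble(gene = character(0), kind = character(0), strand = character(0),
           start = integer(0), end = integer(0), wraps_origin = logical(0),
           anticodon = character(0), jn = character(0))
  }
  mitogenome(sequence, features, identifier = identifier,
             accession = accession, topology = topology)
}

parse_one_feature <- function(f, topology) {
  key <- f$key
  if (key %in% c("source", "gene")) return(NULL)
  kind <- switch(key,
                 CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                 "D-loop" = "control", rep_origin = "control",
                 misc_feature = "control", NULL)
  if (is.null(kind)) return(NULL)

  loc <- gsub("[<>]", "", f$loc)
  strand <- if (grepl("complement", loc)) "-" else "+"
  nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
  if (length(nums) < 1L) return(NULL)
  wraps <- FALSE
  if (grepl("join|order", loc) && length(nums) >= 4L &&
      nums[3] == 1L && topology == "circular") {
    wraps <- TRUE
    start <- nums[1]; end <- nums[4]
  } else {
    start <- min(nums); end <- max(nums)
  }

  q <- function(name) {
    hit <- grep(paste0("^/", name, "="), f$quals, value = TRUE)
    if (!length(hit)) return(NA_character_)
    gsub(paste0("^/", name, "=\"?|\"$"), "", hit[1])
  }
  note <- q("note")
  anticodon <- NA_character_
  ac_q <- grep("^/anticodon=", f$quals, value = TRUE)
  if (length(ac_q) && grepl("seq:([a-zA-Z]{3})", ac_q[1])) {
    anticodon <- toupper(chartr("Uu", "Tt", sub(".*seq:([a-zA-Z]{3}).*", "\\1", ac_q[1])))
  } else if (!is.na(note) && grepl("anticodon[: ]([A-Za-z]{3})", note)) {
    anticodon <- toupper(sub(".*anticodon[: ]([A-Za-z]{3}).*", "\\1", note))
  }
  jn <- if (!is.na(note) && grepl("strand[: ]([JN])", note)) {
    sub(".*strand[: ]([JN]).*", "\\1", note)
  } else NA_character_

  raw_name <- q("gene")
  if (is.na(raw_name)) raw_name <- q("product")
  if (is.na(raw_name)) raw_name <- note
  if (is.na(raw_name)) raw_name <- key
  name <- normalize_gene_name(raw_name, anticodon)
  if (kind == "control" && !name %in% c("OH", "OL")) {
    if (grepl("control|D-loop|A\\+T", raw_name, ignore.case = TRUE)) name <- "OH"
  }
  tibble(gene = name, kind = kind, strand = strand,
         start = start, end = end, wraps_origin = wraps,
         anticodon = anticodon, jn = jn)
}

#' Write a mitogenome as a GenBank flat file
#'
#' Emits a minimal, deterministic GenBank record (fixed LOCUS date, so equal
#' genomes produce byte-identical files) that [read_genbank()] parses back
#' to an equal `mitogenome`: `CDS`/`tRNA`/`rRNA`/`D-loop` feature keys,
#' `complement()` locations for `-` strand features, a two-segment `join`
#' for origin-wrapping features, and `/note` qualifiers carrying the
#' anticodon and major/minor strand label.
#'
#' @param genome a `mitogenome`.
#' @param path output file path; `NULL` returns the lines invisibly instead.
#' @return Invisibly, the character vector of file lines.
#' @export
write_genbank <- function(genome, path = NULL) {
  stopifnot(inherits(genome, "mitogenome"))
  n <- nchar(genome$sequence)
  lines <- c(
    sprintf("LOCUS       %-16s %d bp    DNA     %-8s INV 01-JAN-2026",
            substr(genome$identifier, 1, 16), n, genome$topology),
    sprintf("DEFINITION  %s mitochondrion, complete genome.", genome$identifier),
    if (!is.na(genome$accession)) sprintf("ACCESSION   %s", genome$accession),
    "FEATURES             Location/Qualifiers",
    feature_line("source", sprintf("1..%d", n)),
    qual_line("/mol_type=\"genomic DNA\"")
  )
  for (i in seq_len(nrow(genome$features))) {
    f <- genome$features[i, ]
    key <- switch(f$kind, PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                  control = "D-loop", "misc_feature")
    loc <- if (f$wraps_origin) sprintf("join(%d..%d,1..%d)", f$start, n, f$end)
           else sprintf("%d..%d", f$start, f$end)
    if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
    lines <- c(lines, feature_line(key, loc),
               qual_line(sprintf("/gene=\"%s\"", f$gene)))
    notes <- c(if (!is.na(f$anticodon)) sprintf("anticodon:%s", f$anticodon),
               if (!is.na(f$jn)) sprintf("strand:%s", f$jn))
    if (length(notes)) {
      lines <- c(lines, qual_line(sprintf("/note=\"%s\"", paste(notes, collapse = "; "))))
    }
  }
  lines <- c(lines, "ORIGIN", origin_lines(genome$sequence), "//")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

feature_line <- function(key, loc) sprintf("     %-15s %s", key, loc)
qual_line <- function(q) paste0(strrep(" ", 21), q)

origin_lines <- function(seq) {
  n <- nchar(seq)
  starts <- seq(1L, n, by = 60L)
  vapply(starts, function(s) {
    chunk <- substr(seq, s, min(s + 59L, n))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    sprintf("%9d %s", s, tolower(paste(groups, collapse = " ")))
  }, character(1))
}

#' Read a mitogenome from FASTA plus a feature table
#'
#' Alternative input route for records that are not in GenBank format: a
#' single-sequence FASTA file and a tab-separated feature table with columns
#' `name`, `kind`, `strand`, `start`, `end`, `anticodon`. `strand` may be
#' `+`/`-` or the major/minor labels `J`/`N` (mapped N to `+`, J to `-`, and
#' kept as metadata).
#'
#' @param fasta path to the FASTA file (first record used).
#' @param features_tsv path to the 6-column TSV.
#' @param topology `"circular"` (default) or `"linear"`.
#' @return A `mitogenome`.
#' @export
read_feature_table <- function(fasta, features_tsv, topology = "circular") {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) == 0L) {
    abort("no sequences in FASTA input.", class = "mitocub_no_records")
  }
  tab <- readr::read_tsv(features_tsv, col_types = readr::cols(
    name = readr::col_character(), kind = readr::col_character(),
    strand = readr::col_character(), start = readr::col_integer(),
    end = readr::col_integer(), anticodon = readr::col_character()))
  jn <- ifelse(tab$strand %in% c("J", "N"), tab$strand, NA_character_)
  strand <- dplyr::case_when(tab$strand == "J" ~ "-",
                             tab$strand == "N" ~ "+",
                             TRUE ~ tab$strand)
  features <- tibble(
    gene = normalize_gene_name(tab$name, tab$anticodon),
    kind = tab$kind, strand = strand, start = tab$start, end = tab$end,
    wraps_origin = FALSE, anticodon = tab$anticodon, jn = jn)
  id <- strsplit(names(seqs)[1], "\\s+")[[1]][1]
  mitogenome(as.character(seqs[[1]]), features, identifier = id,
             topology = topology)
}
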