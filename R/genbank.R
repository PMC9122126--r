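# Minimal GenBank flat-file reader/writer covering the subset the pipeline
# needs: LOCUS records, CDS features with simple/join/complement locations,
# the locus_tag/product/translation/codon_start qualifiers, and an optional
# ORIGIN block. Coordinates are kept 1-based inclusive throughout.

#' Read an annotated genome from a GenBank flat file
#'
#' One `GeneFeature` is produced per CDS. The protein is taken from the
#' `/translation` qualifier when present, and otherwise translated from the
#' nucleotide span (genetic code 11, honouring `/codon_start` and
#' `complement()`/`join()` locations, exons concatenated in annotation
#' order). A CDS whose protein cannot be derived (no translation qualifier
#' and no ORIGIN sequence) is skipped with a warning; the number of skipped
#' CDS is attached as attribute `n_skipped`.
#'
#' @param path GenBank flat file (one or more LOCUS records = contigs).
#' @param genome_id Genome identifier; default is the file name without
#'   extension.
#' @return A [genome_annotation()].
#' @export
read_genbank <- function(path, genome_id = NULL) {
  if (is.null(genome_id)) {
    genome_id <- sub("\\.(gb|gbk|gbff|genbank)$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  rec_end <- grep("^//\\s*$", lines)
  rec_start <- c(1L, head(rec_end, -1) + 1L)
  if (length(rec_end) == 0) abort("malformed GenBank file: no record terminator '//'")
  contigs <- list()
  genes <- list()
  n_skipped <- 0L
  for (r in seq_along(rec_end)) {
    rec <- lines[rec_start[r]:rec_end[r]]
    locus_line <- grep("^LOCUS", rec, value = TRUE)
    if (length(locus_line) == 0) abort("malformed GenBank record: missing LOCUS line")
    toks <- strsplit(trimws(locus_line[1]), "\\s+")[[1]]
    contig_id <- toks[2]
    contig_len <- suppressWarnings(as.integer(toks[3]))
    if (is.na(contig_len)) {
      abort(paste0("malformed LOCUS line for contig ", contig_id))
    }
    sequence <- parse_origin(rec)
    feats <- parse_feature_table(rec, contig_id)
    gene_rows <- list()
    for (ft in feats) {
      if (ft$key != "CDS") next
      loc <- tryCatch(parse_location(ft$location),
                      error = function(e) {
                        abort(sprintf("malformed location for CDS '%s' on %s: %s",
                                      ft$qualifiers$locus_tag %||% ft$location,
                                      contig_id, conditionMessage(e)))
                      })
      q <- ft$qualifiers
      fid <- q$locus_tag %||% q$protein_id %||%
        sprintf("%s_cds%03d", contig_id, length(gene_rows) + 1L)
      protein <- q$translation
      if (is.null(protein) && !is.na(sequence)) {
        protein <- translate_cds(sequence, loc,
                                 codon_start = as.integer(q$codon_start %||% "1"))
      }
      if (is.null(protein) || is.na(protein) || nchar(protein) == 0) {
        warn(sprintf("skipping CDS '%s' on %s: no derivable protein", fid, contig_id))
        n_skipped <- n_skipped + 1L
        next
      }
      gene_rows[[length(gene_rows) + 1L]] <- tibble(
        feature_id = fid,
        contig_id = contig_id,
        start = min(loc$spans$start),
        end = max(loc$spans$end),
        strand = if (loc$complement) "-" else "+",
        protein = gsub("\\*$", "", protein),
        product = q$product %||% "")
    }
    contigs[[r]] <- tibble(contig_id = contig_id, length = contig_len,
                           sequence = sequence)
    genes[[r]] <- if (length(gene_rows) > 0) bind_rows(gene_rows) else NULL
  }
  gene_tbl <- bind_rows(genes[!vapply(genes, is.null, TRUE)])
  if (nrow(gene_tbl) == 0) gene_tbl <- empty_gene_table()
  out <- genome_annotation(genome_id, bind_rows(contigs), gene_tbl,
                           source = "genbank")
  attr(out, "n_skipped") <- n_skipped
  out
}

empty_gene_table <- function() {
  tibble(feature_id = character(), contig_id = character(),
         start = integer(), end = integer(), strand = character(),
         protein = character(), product = character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_origin <- function(rec) {
  i <- grep("^ORIGIN", rec)
  if (length(i) == 0) return(NA_character_)
  seq_lines <- rec[(i[1] + 1):length(rec)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  s <- gsub("[0-9 ]", "", paste(seq_lines, collapse = ""))
  toupper(s)
}

# Returns a list of features: list(key, location, qualifiers)
parse_feature_table <- function(rec, contig_id) {
  i <- grep("^FEATURES", rec)
  if (length(i) == 0) return(list())
  j <- grep("^(ORIGIN|CONTIG|BASE COUNT)", rec)
  j <- j[j > i[1]]
  end <- if (length(j) > 0) j[1] - 1L else length(rec)
  block <- rec[(i[1] + 1):end]
  block <- block[nzchar(trimws(block)) & !grepl("^//", block)]
  feats <- list()
  cur <- NULL
  cur_qual <- NULL
  flush_qual <- function(cur, cur_qual) {
    if (is.null(cur_qual) || is.na(cur_qual$name)) return(cur)
    val <- cur_qual$value
    if (!is.null(val)) {
      val <- gsub("^\"|\"$", "", val)
      if (cur_qual$name == "translation") val <- gsub("\\s", "", val)
    } else {
      val <- TRUE
    }
    cur$qualifiers[[cur_qual$name]] <- val
    cur
  }
  for (ln in block) {
    if (grepl("^ {5}\\S", ln)) {
      # new feature header: key at col 6, location at col 22
      cur <- flush_qual(cur, cur_qual); cur_qual <- NULL
      if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
      key <- trimws(substr(ln, 6, 20))
      loc <- trimws(substr(ln, 21, nchar(ln)))
      cur <- list(key = key, location = loc, qualifiers = list())
    } else {
      cont <- trimws(ln)
      if (is.null(cur)) next
      if (startsWith(cont, "/")) {
        cur <- flush_qual(cur, cur_qual)
        m <- regmatches(cont, regexec("^/([A-Za-z_0-9]+)(=(.*))?$", cont))[[1]]
        cur_qual <- list(name = m[2],
                         value = if (nzchar(m[3])) m[4] else NULL)
      } else if (!is.null(cur_qual)) {
        sep <- if (cur_qual$name == "translation") "" else " "
        cur_qual$value <- paste(cur_qual$value, cont, sep = sep)
      } else {
        cur$location <- paste0(cur$location, cont)
      }
    }
  }
  cur <- flush_qual(cur, cur_qual)
  if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
  feats
}

# Parse a (possibly complement/join) location string into exon spans.
parse_location <- function(loc) {
  loc <- gsub("\\s", "", loc)
  complement <- FALSE
  if (grepl("^complement\\(", loc)) {
    complement <- TRUE
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  joined <- FALSE
  if (grepl("^join\\(", loc)) {
    joined <- TRUE
    loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  }
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  spans <- purrr::map_dfr(parts, function(p) {
    p <- gsub("[<>]", "", p)
    if (grepl("^[0-9]+$", p)) return(tibble(start = as.integer(p), end = as.integer(p)))
    m <- regmatches(p, regexec("^([0-9]+)\\.\\.([0-9]+)$", p))[[1]]
    if (length(m) != 3) stop(sprintf("cannot parse span '%s'", p), call. = FALSE)
    tibble(start = as.integer(m[2]), end = as.integer(m[3]))
  })
  if (any(spans$start > spans$end)) stop("span with start > end", call. = FALSE)
  list(spans = spans, complement = complement, joined = joined)
}

# Translate a CDS from the contig nucleotide sequence (genetic code 11).
translate_cds <- function(sequence, loc, codon_start = 1L) {
  if (is.na(codon_start)) codon_start <- 1L
  exons <- purrr::map_chr(seq_len(nrow(loc$spans)), function(k) {
    substr(sequence, loc$spans$start[k], loc$spans$end[k])
  })
  nt <- paste(exons, collapse = "")
  dna <- Biostrings::DNAString(nt)
  if (loc$complement) dna <- Biostrings::reverseComplement(dna)
  if (codon_start > 1) dna <- Biostrings::subseq(dna, start = codon_start)
  usable <- 3L * (length(dna) %/% 3L)
  if (usable < 3L) return(NA_character_)
  dna <- Biostrings::subseq(dna, 1L, usable)
  aa <- as.character(Biostrings::translate(
    dna, genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "solve"))
  gsub("\\*$", "", aa)
}

#' Write a genome annotation as a GenBank flat file
#'
#' Emits one LOCUS record per contig with a CDS feature (and
#' `/locus_tag`, `/product`, `/translation` qualifiers) per gene, plus an
#' ORIGIN block when the contig carries a nucleotide sequence. The output
#' round-trips through [read_genbank()] with identical gene counts,
#' coordinates, strands and proteins. The LOCUS date is fixed so reruns are
#' byte-identical.
#'
#' @param genome A [genome_annotation()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(genome$contigs))) {
    cid <- genome$contigs$contig_id[i]
    clen <- genome$contigs$length[i]
    seqnt <- genome$contigs$sequence[i]
    writeLines(sprintf("LOCUS       %-16s %d bp    DNA     linear   PHG 01-JAN-1980",
                       cid, clen), con)
    writeLines(sprintf("DEFINITION  %s contig %s.", genome$genome_id, cid), con)
    writeLines(sprintf("ACCESSION   %s", cid), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", clen), con)
    g <- genome$genes[genome$genes$contig_id == cid, , drop = FALSE]
    if (nrow(g) > 0) {
      for (k in seq_len(nrow(g))) {
        span <- sprintf("%d..%d", g$start[k], g$end[k])
        if (g$strand[k] == "-") span <- sprintf("complement(%s)", span)
        writeLines(sprintf("     CDS             %s", span), con)
        writeLines(wrap_qualifier("locus_tag", g$feature_id[k]), con)
        writeLines(wrap_qualifier("product", g$product[k]), con)
        writeLines(wrap_qualifier("translation", g$protein[k]), con)
      }
    }
    if (!is.na(seqnt) && nzchar(seqnt)) {
      writeLines("ORIGIN", con)
      s <- tolower(seqnt)
      pos <- seq(1, nchar(s), by = 60)
      for (p in pos) {
        chunk <- substr(s, p, min(p + 59, nchar(s)))
        tens <- substring(chunk, seq(1, nchar(chunk), 10),
                          pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
        writeLines(sprintf("%9d %s", p, paste(tens, collapse = " ")), con)
      }
    }
    writeLines("//", con)
  }
  invisible(path)
}

wrap_qualifier <- function(name, value) {
  txt <- sprintf("/%s=\"%s\"", name, value)
  if (name != "translation") return(paste0(strrep(" ", 21), txt))
  # only the translation is wrapped: its continuation lines rejoin with no
  # separator, so splitting free text would corrupt round-trips
  width <- 58L
  pieces <- substring(txt, seq(1, nchar(txt), width),
                      pmin(seq(width, nchar(txt) + width - 1, width), nchar(txt)))
  paste0(strrep(" ", 21), pieces)
}

#' Write a corpus of genomes as GenBank files
#'
#' @param corpus List of [genome_annotation()] objects.
#' @param dir Output directory (created if needed); one `<genome_id>.gbk`
#'   per genome.
#' @return The directory, invisibly.
#' @export
write_corpus_genbank <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in corpus) write_genbank(g, file.path(dir, paste0(g$genome_id, ".gbk")))
  invisible(dir)
}

#' Read a directory of GenBank files as a corpus
#'
#' @param dir Directory containing `.gbk`/`.gb`/`.gbff` files.
#' @return Named list of [genome_annotation()] objects (sorted by file name).
#' @export
read_corpus_genbank <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(gb|gbk|gbff|genbank)$",
                           full.names = TRUE))
  if (length(files) == 0) abort(paste0("no GenBank files found in ", dir))
  corpus <- lapply(files, read_genbank)
  names(corpus) <- purrr::map_chr(corpus, "genome_id")
  corpus
}
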