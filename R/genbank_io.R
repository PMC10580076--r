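# GenBank flat-file and FASTA I/O.
#
# GenBank is written/parsed directly (LOCUS topology token, FEATURES table,
# ORIGIN block). Only the subset of the grammar this package emits is
# guaranteed to round-trip: simple spans, complement(), and two-span join()
# across the origin of circular records. FASTA goes through Biostrings.

KIND_TO_KEY <- c(promoter = "promoter", CDS = "CDS", utr3 = "3'UTR",
                 fluorophore = "misc_feature", linker = "misc_feature",
                 selection_marker = "misc_feature",
                 recombination_site = "misc_feature",
                 recognition_site = "misc_feature", misc = "misc_feature")
KEY_TO_KIND <- c(promoter = "promoter", CDS = "CDS", "3'UTR" = "utr3",
                 misc_feature = "misc")

#' Read DNA records from GenBank or FASTA
#'
#' @param path file path.
#' @param format \code{"genbank"}, \code{"fasta"}, or \code{NULL} to infer from
#'   the file extension (.gb/.gbk/.genbank vs .fa/.fasta).
#' @return \code{read_records()} returns a list of [dna_molecule];
#'   \code{read_record()} returns a single molecule and errors if the file
#'   holds more than one record.
#' @details Topology is taken from the LOCUS line when present ("circular" or
#'   "linear"); an unrecognized topology token triggers a warning and the
#'   record is treated as linear. FASTA records have no features and are
#'   always linear. GenBank 1-based inclusive coordinates are converted to the
#'   internal 0-based half-open convention.
#' @export
read_records <- function(path, format = NULL) {
  if (!file.exists(path))
    gk_stop("gatekit_io_error", sprintf("file '%s' does not exist", path))
  format <- format %||% guess_format(path)
  switch(format,
         genbank = read_genbank_file(path),
         fasta = read_fasta_file(path),
         gk_stop("gatekit_format_error", sprintf("unknown format '%s'", format)))
}

#' @rdname read_records
#' @export
read_record <- function(path, format = NULL) {
  recs <- read_records(path, format)
  if (length(recs) != 1)
    gk_stop("gatekit_format_error",
            sprintf("'%s' holds %d records where one was expected", path,
                    length(recs)))
  recs[[1]]
}

guess_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("gb", "gbk", "genbank")) "genbank"
  else if (ext %in% c("fa", "fasta", "fna")) "fasta"
  else gk_stop("gatekit_format_error",
               sprintf("cannot infer format from extension of '%s'", path))
}

read_fasta_file <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(set), function(i) {
    id <- strsplit(names(set)[i], "\\s+")[[1]][1]
    dna_molecule(id, as.character(set[[i]]), topology = "linear")
  })
}

read_genbank_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^LOCUS", lines)
  if (!length(starts))
    gk_stop("gatekit_format_error",
            sprintf("'%s': no LOCUS line found; not a GenBank flat file", path))
  ends <- grep("^//\\s*$", lines)
  if (length(ends) < length(starts))
    gk_stop("gatekit_format_error",
            sprintf("'%s': record %d has no terminating '//'", path, length(ends) + 1))
  lapply(seq_along(starts), function(i) {
    block <- lines[starts[i]:ends[ends >= starts[i]][1]]
    parse_genbank_record(block, path)
  })
}

parse_genbank_record <- function(block, path) {
  locus <- block[1]
  toks <- strsplit(trimws(locus), "\\s+")[[1]]
  id <- if (length(toks) >= 2) toks[2] else "unnamed"
  topology <- "linear"
  if (any(grepl("^circular$", toks, ignore.case = TRUE))) {
    topology <- "circular"
  } else if (!any(grepl("^linear$", toks, ignore.case = TRUE))) {
    # no topology token at all is common; only warn on an unknown token in the
    # topology column (after the 'bp'/molecule-type fields)
    bp_i <- which(toks == "bp")
    if (length(bp_i) && length(toks) >= bp_i + 2 &&
        !toks[bp_i + 2] %in% c("SYN", "PLN", "UNA") &&
        grepl("^[a-z]+$", toks[bp_i + 2])) {
      gk_warn("gatekit_format_warning",
              sprintf("unknown topology token '%s' in '%s'; treating as linear",
                      toks[bp_i + 2], id))
    }
  }

  feat_i <- grep("^FEATURES", block)
  orig_i <- grep("^ORIGIN", block)
  if (!length(orig_i))
    gk_stop("gatekit_format_error",
            sprintf("record '%s' in '%s' has no ORIGIN block", id, path))
  seq_lines <- block[(orig_i[1] + 1):length(block)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence))
    gk_stop("gatekit_format_error",
            sprintf("record '%s' in '%s' has an empty ORIGIN block", id, path))
  L <- nchar(sequence)

  features <- empty_features()
  if (length(feat_i)) {
    flines <- block[(feat_i[1] + 1):(orig_i[1] - 1)]
    features <- parse_feature_table(flines, L, id)
  }
  dna_molecule(id, sequence, topology = topology, features = features)
}

parse_feature_table <- function(flines, L, id) {
  # feature keys start at column 6; qualifier/continuation lines at column 22
  is_key <- grepl("^ {5}\\S", flines)
  idx <- which(is_key)
  out <- empty_features()
  for (j in seq_along(idx)) {
    from <- idx[j]
    to <- if (j < length(idx)) idx[j + 1] - 1 else length(flines)
    entry <- flines[from:to]
    key <- sub("^ {5}(\\S+).*", "\\1", entry[1])
    loc <- sub("^ {5}\\S+\\s+", "", entry[1])
    quals <- entry[-1]
    # location continuation lines (no leading '/')
    cont <- !grepl("^\\s*/", quals)
    if (any(cont)) {
      loc <- paste0(loc, paste(trimws(quals[cont]), collapse = ""))
      quals <- quals[!cont]
    }
    if (key == "source") next
    parsed <- parse_location(loc, L, id)
    label <- qualifier_value(quals, "label") %||%
      qualifier_value(quals, "gene") %||% key
    kind <- qualifier_value(quals, "gatekit_kind") %||%
      unname(KEY_TO_KIND[key]) %||% "misc"
    if (is.na(kind)) kind <- "misc"
    out <- rbind(out, data.frame(
      label = label, kind = kind, start = parsed$start, end = parsed$end,
      strand = parsed$strand, stringsAsFactors = FALSE))
  }
  out
}

qualifier_value <- function(quals, name) {
  pat <- paste0("^\\s*/", name, "=")
  hit <- grep(pat, quals, value = TRUE)
  if (!length(hit)) return(NULL)
  val <- sub(pat, "", hit[1])
  gsub('^"|"$', "", trimws(val))
}

parse_location <- function(loc, L, id) {
  loc <- gsub("\\s", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    body <- sub("^join\\((.*)\\)$", "\\1", loc)
    spans <- strsplit(body, ",", fixed = TRUE)[[1]]
    iv <- t(vapply(spans, parse_span_1based, numeric(2)))
    # two-span join across the origin: last span ends at L, next starts at 1
    if (nrow(iv) == 2 && iv[1, 2] == L && iv[2, 1] == 1) {
      return(list(start = as.integer(iv[1, 1] - 1),
                  end = as.integer(L + iv[2, 2]), strand = strand))
    }
    # contiguous joins collapse to one interval
    if (all(iv[-1, 1] == head(iv[, 2], -1) + 1)) {
      return(list(start = as.integer(iv[1, 1] - 1),
                  end = as.integer(iv[nrow(iv), 2]), strand = strand))
    }
    gk_stop("gatekit_format_error",
            sprintf("unsupported join() location '%s' in record '%s'", loc, id))
  }
  iv <- parse_span_1based(loc)
  list(start = as.integer(iv[1] - 1), end = as.integer(iv[2]), strand = strand)
}

parse_span_1based <- function(span) {
  span <- gsub("[<>]", "", span)
  if (grepl("\\.\\.", span)) {
    parts <- as.numeric(strsplit(span, "..", fixed = TRUE)[[1]])
    c(parts[1], parts[2])
  } else {
    p <- as.numeric(span)
    c(p, p)
  }
}

#' Write DNA records to GenBank or FASTA
#'
#' \code{write_record()} writes one molecule; \code{write_records()} writes a
#' list into a single file. GenBank output preserves topology and all features
#' (with \code{/label} and, for kinds without a native GenBank key, a
#' \code{/gatekit_kind} qualifier), so that \code{read_record(write_record(m))}
#' reproduces sequence, topology, and feature intervals exactly. FASTA output
#' is the plain, unannotated sequence.
#'
#' @param mol a [dna_molecule].
#' @param path output path.
#' @param format \code{"genbank"} or \code{"fasta"} (default inferred from the
#'   extension).
#' @return the path, invisibly.
#' @export
write_record <- function(mol, path, format = NULL) {
  write_records(list(mol), path, format)
}

#' @rdname write_record
#' @param mols list of [dna_molecule] objects.
#' @export
write_records <- function(mols, path, format = NULL) {
  format <- format %||% guess_format(path)
  lines <- switch(format,
                  genbank = unlist(lapply(mols, format_genbank_record)),
                  fasta = unlist(lapply(mols, function(m)
                    c(paste0(">", m$id), chunk_seq(m$sequence, 70)))),
                  gk_stop("gatekit_format_error",
                          sprintf("unknown format '%s'", format)))
  write_atomic(lines, path)
}

chunk_seq <- function(s, width) {
  n <- nchar(s)
  starts <- seq(1, n, by = width)
  substring(s, starts, pmin(starts + width - 1, n))
}

format_genbank_record <- function(mol) {
  L <- nchar(mol$sequence)
  locus <- sprintf("LOCUS       %-16s %d bp    DNA     %-8s SYN 01-JAN-2024",
                   mol$id, L, mol$topology)
  header <- c(locus,
              sprintf("DEFINITION  %s.", mol$id),
              sprintf("ACCESSION   %s", mol$id),
              "FEATURES             Location/Qualifiers",
              sprintf("     source          1..%d", L))
  feats <- character(0)
  f <- mol$features
  if (nrow(f)) {
    for (i in seq_len(nrow(f))) {
      key <- unname(KIND_TO_KEY[f$kind[i]])
      loc <- format_location(f$start[i], f$end[i], f$strand[i], L)
      feats <- c(feats, sprintf("     %-15s %s", key, loc),
                 sprintf('                     /label="%s"', f$label[i]))
      if (is.na(KEY_TO_KIND[key]) || KEY_TO_KIND[key] != f$kind[i])
        feats <- c(feats, sprintf('                     /gatekit_kind="%s"',
                                  f$kind[i]))
    }
  }
  seq_block <- character(0)
  s <- tolower(mol$sequence)
  for (off in seq(1, L, by = 60)) {
    line <- substr(s, off, min(off + 59, L))
    tens <- chunk_seq(line, 10)
    seq_block <- c(seq_block, sprintf("%9d %s", off, paste(tens, collapse = " ")))
  }
  c(header, feats, "ORIGIN", seq_block, "//")
}

format_location <- function(start, end, strand, L) {
  loc <- if (end <= L) {
    sprintf("%d..%d", start + 1, end)
  } else {
    sprintf("join(%d..%d,1..%d)", start + 1, L, end - L)
  }
  if (strand == "-") sprintf("complement(%s)", loc) else loc
}
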