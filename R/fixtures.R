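# Deterministic synthetic kits: destination vectors, entry clones, empty entry
# vectors and stress sets that emulate a physical Golden Gate kit so every
# module is testable without any downloaded sequence. All randomness is
# threaded through an explicit seed and the caller's RNG state is left
# untouched; the same seed always yields a byte-identical kit.
#
# Marker features are short symbolic placeholder ORFs labeled KanR (entry
# backbones) and AmpR (destination backbones): the marker logic in this
# package is annotation-driven, not sequence-homology-driven.

GK_MAX_STRESS_INSERTS <- 20L

#' Maximum insert count supported by the stress-set generator
#' @return integer, currently 20 (one backbone + up to 20 inserts, 21 labels).
#' @export
max_stress_inserts <- function() GK_MAX_STRESS_INSERTS

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# replace one base inside every forbidden-site occurrence until none remain;
# positions in `protect` (0-based) are never touched
scrub_sites <- function(s, enzymes, protect = integer(0)) {
  specs <- lapply(enzymes, get_enzyme)
  for (iter in 1:200) {
    mol <- dna_molecule("tmp", s, "linear")
    hit <- NULL
    for (spec in specs) {
      sites <- find_sites(mol, spec)
      if (nrow(sites)) {
        k <- nchar(spec$recognition)
        for (r in seq_len(nrow(sites))) {
          pos <- sites$recognition_start[r] + (k %/% 2)
          cand <- setdiff(sites$recognition_start[r] + 0:(k - 1), protect)
          if (length(cand)) {
            hit <- cand[ceiling(length(cand) / 2)]
            break
          }
        }
        if (!is.null(hit)) break
      }
    }
    if (is.null(hit)) return(s)
    old <- substr(s, hit + 1, hit + 1)
    substr(s, hit + 1, hit + 1) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
  }
  gk_stop("gatekit_parameter_error", "could not scrub forbidden sites")
}

#' Generate a random insert, optionally planting recognition sites
#'
#' @param length sequence length in nt.
#' @param seed integer seed; the same call is reproducible byte-for-byte.
#' @param forbid enzymes whose sites must not occur (default SapI and BsaI).
#' @param plant optional list of \code{list(enzyme=, pos=, strand=)} entries:
#'   the recognition sequence is written at the stated 0-based position on the
#'   stated strand, and survives scrubbing.
#' @param id molecule id.
#' @return linear [dna_molecule].
#' @export
make_random_insert <- function(length, seed, forbid = c("SapI", "BsaI"),
                               plant = NULL, id = NULL) {
  longest <- max(vapply(forbid, function(e) nchar(get_enzyme(e)$recognition),
                        integer(1)), 0L)
  if (length < longest)
    gk_stop("gatekit_parameter_error", sprintf(
      "length %d shorter than the longest forbidden recognition (%d nt)",
      length, longest))
  with_seed(seed, {
    s <- rand_dna(length)
    protect <- integer(0)
    if (!is.null(plant)) {
      for (p in plant) {
        rec <- get_enzyme(p$enzyme)$recognition
        if (identical(p$strand, "-")) rec <- revcomp_str(rec)
        if (p$pos + nchar(rec) > length)
          gk_stop("gatekit_parameter_error", "planted site beyond the sequence")
        substr(s, p$pos + 1, p$pos + nchar(rec)) <- rec
        protect <- c(protect, p$pos + 0:(nchar(rec) - 1))
      }
    }
    s <- scrub_sites(s, forbid, protect = protect)
    dna_molecule(id %||% sprintf("rand_%d_%d", length, seed), s, "linear")
  })
}

# n distinct labels of the given length: no N, not self-complementary, no
# label equal to another's reverse complement, none in `avoid`
gen_labels <- function(n, len, avoid = character(0)) {
  out <- character(0)
  taken <- c(avoid, revcomp_str(avoid))
  for (i in 1:5000) {
    lab <- rand_dna(len)
    if (lab %in% taken || is_self_complementary(lab)) next
    out <- c(out, lab)
    taken <- c(taken, lab, revcomp_str(lab))
    if (length(out) == n) return(out)
  }
  gk_stop("gatekit_parameter_error", sprintf(
    "label space exhausted: cannot draw %d distinct %d-nt overhangs", n, len))
}

# sequence chunks around markers and stuffers; scrubbed of both assembly enzymes
clean_chunk <- function(n) scrub_sites(rand_dna(n), c("SapI", "BsaI"))

marker_orf <- function(n_codons = 20) {
  aa_codons <- setdiff(names(Biostrings::GENETIC_CODE)[
    Biostrings::GENETIC_CODE != "*"], c("ATG"))
  body <- paste(sample(aa_codons, n_codons - 2, replace = TRUE), collapse = "")
  scrub_sites(paste0("ATG", body, "TAA"), c("SapI", "BsaI"))
}

#' Build a synthetic destination (targeting) vector
#'
#' Circular AmpR backbone whose stuffer carries two outward-facing sites of
#' the scheme enzyme, so that digestion releases a site-free backbone fragment
#' with the scheme's two vector junction labels.
#'
#' @param scheme a [slot_scheme].
#' @param seed integer seed.
#' @param id molecule id.
#' @param backbone_len approximate backbone length in nt.
#' @return circular [dna_molecule] with an AmpR \code{selection_marker}
#'   feature.
#' @export
make_destination_vector <- function(scheme, seed, id = "pDEST",
                                    backbone_len = 300) {
  enz <- get_enzyme(scheme$enzyme)
  rec <- enz$recognition
  j_left <- scheme$junction_labels[1]
  j_right <- scheme$junction_labels[length(scheme$junction_labels)]
  with_seed(seed, {
    for (attempt in 1:50) {
      marker <- marker_orf()
      spacer1 <- clean_chunk(backbone_len %/% 2)
      spacer2 <- clean_chunk(backbone_len %/% 2)
      stuffer_mid <- clean_chunk(40)
      # backbone ... [J_left PAD rc(rec) mid rec PAD J_right] ... backbone
      stuffer <- paste0(j_left, "A", revcomp_str(rec), stuffer_mid,
                        rec, "A", j_right)
      seqn <- paste0(spacer1, marker, spacer2, stuffer)
      mol <- dna_molecule(id, seqn, "circular")
      mol <- add_feature(mol, "AmpR", "selection_marker",
                         nchar(spacer1), nchar(spacer1) + nchar(marker), "+")
      sites <- find_sites(mol, enz)
      if (nrow(sites) == 2 && nrow(find_sites(mol, "BsaI")) ==
          (if (enz$name == "BsaI") 2 else 0))
        return(mol)
    }
    gk_stop("gatekit_parameter_error",
            "could not generate a clean destination vector")
  })
}

#' Build a synthetic entry clone
#'
#' Circular KanR plasmid carrying one insert flanked by inward-cutting sites
#' of the scheme enzyme, so that digestion releases the insert with the given
#' span's junction labels (and a backbone fragment that retains both
#' recognition sites).
#'
#' @param scheme a [slot_scheme].
#' @param span slot span key the clone occupies.
#' @param seed integer seed.
#' @param id molecule id.
#' @param kind feature kind for the insert body (promoter, CDS, linker, ...).
#' @param body_len insert body length in nt (between the two junction labels).
#' @param body optional explicit body sequence (overrides \code{body_len});
#'   must be free of scheme-enzyme and BsaI sites.
#' @return circular [dna_molecule].
#' @export
make_entry_clone <- function(scheme, span, seed, id = NULL, kind = "misc",
                             body_len = 120, body = NULL) {
  enz <- get_enzyme(scheme$enzyme)
  rec <- enz$recognition
  lab <- span_labels(scheme, span)
  id <- id %||% sprintf("p%s_%d", gsub("-", "", span), seed)
  with_seed(seed, {
    for (attempt in 1:50) {
      if (is.null(body)) {
        core <- if (kind == "CDS") make_cds_body(body_len) else clean_chunk(body_len)
      } else core <- body
      backbone <- paste0(clean_chunk(80), marker_orf(), clean_chunk(80))
      insert <- paste0(lab["left"], core, lab["right"])
      seqn <- paste0(backbone, rec, "A", insert, "T", revcomp_str(rec))
      mol <- dna_molecule(id, seqn, "circular")
      mol <- add_feature(mol, "KanR", "selection_marker", 80L,
                         80L + nchar(marker_orf_len_probe(backbone)), "+")
      ins_start <- nchar(backbone) + nchar(rec) + 1L
      mol <- add_feature(mol, id, kind,
                         ins_start + enz$overhang_len,
                         ins_start + enz$overhang_len + nchar(core), "+")
      sites <- find_sites(mol, enz)
      ok_extra <- if (enz$name == "BsaI") nrow(find_sites(mol, "SapI")) == 0
                  else nrow(find_sites(mol, "BsaI")) == 0
      if (nrow(sites) == 2 && ok_extra) {
        cls <- tryCatch(classify_part(mol, scheme, enz),
                        gatekit_error = function(e) NULL)
        if (!is.null(cls) && cls$span == span) return(mol)
      }
    }
    gk_stop("gatekit_parameter_error",
            sprintf("could not generate entry clone for span %s", span))
  })
}

# length of the marker ORF embedded at offset 80 of a generated backbone; the
# marker feature interval only needs to cover a representative ORF, so the
# fixed generator geometry (80 + ORF + 80) is reused
marker_orf_len_probe <- function(backbone) nchar(backbone) - 160L

make_cds_body <- function(body_len) {
  n_codons <- max(4L, body_len %/% 3L)
  marker <- marker_orf(n_codons)
  marker
}

#' Build the empty KanR entry vector for a span
#'
#' The BsaI-based vector used to create new entry clones: its stuffer carries
#' two outward-facing BsaI sites whose 4-nt overhangs embed the span's SapI
#' junction labels, and the backbone carries the inward SapI sites, so that
#' BsaI cloning of a tailed amplicon (see [design_entry_primers()]) yields an
#' entry clone classifiable to \code{span}.
#'
#' @inheritParams make_entry_clone
#' @return circular [dna_molecule] with a KanR marker.
#' @export
make_empty_entry_vector <- function(scheme, span, seed, id = NULL) {
  sap <- get_enzyme(scheme$enzyme)
  bsa <- get_enzyme("BsaI")
  vl <- entry_vector_labels(scheme, span)
  id <- id %||% sprintf("pENTRY_%s_%d", gsub("-", "", span), seed)
  with_seed(seed, {
    for (attempt in 1:50) {
      backbone <- paste0(clean_chunk(80), marker_orf(), clean_chunk(80))
      stuffer_mid <- clean_chunk(30)
      # backbone SapI> pad | vlL pad rc(BsaI) mid BsaI pad vlR | pad <SapI
      seqn <- paste0(backbone, sap$recognition, "A",
                     vl["left"], "A", revcomp_str(bsa$recognition),
                     stuffer_mid,
                     bsa$recognition, "A", vl["right"],
                     "T", revcomp_str(sap$recognition))
      mol <- dna_molecule(id, seqn, "circular")
      mol <- add_feature(mol, "KanR", "selection_marker", 80L,
                         80L + marker_orf_len_probe(backbone), "+")
      if (nrow(find_sites(mol, bsa)) == 2 && nrow(find_sites(mol, sap)) == 2)
        return(mol)
    }
    gk_stop("gatekit_parameter_error",
            sprintf("could not generate empty entry vector for span %s", span))
  })
}

#' Generate a complete synthetic kit
#'
#' A scheme with freshly drawn distinct junction labels, a destination vector,
#' at least one entry clone per slot (more via \code{parts_per_slot}) and, for
#' schemes of 4+ slots, parts for the two common combined spans (first two
#' slots, last two slots). The kit passes [validate_kit()] with zero findings
#' and is byte-identical under the same seed.
#'
#' @param scheme_size number of slots, 2..8; a 6-slot kit uses the canonical
#'   slot names (5arm, CT, FP, SEC, NT, 3arm), other sizes use slot1..slotN.
#' @param parts_per_slot scalar or named integer vector (by slot), 1..8
#'   alternative parts per slot.
#' @param seed integer seed.
#' @param enzyme assembly enzyme.
#' @return object of class \code{fixture_kit}: \code{scheme}, \code{vector},
#'   \code{registry} (in-memory \code{part_registry}), \code{seed}.
#' @export
make_kit <- function(scheme_size = 6, parts_per_slot = 1, seed = 1,
                     enzyme = "SapI") {
  if (scheme_size < 2 || scheme_size > 8)
    gk_stop("gatekit_parameter_error", "scheme_size must be in 2..8")
  if (any(parts_per_slot < 1) || any(parts_per_slot > 8))
    gk_stop("gatekit_parameter_error", "parts_per_slot must be in 1..8")
  enz <- get_enzyme(enzyme)
  slots <- if (scheme_size == 6) RMCE6_SLOTS
           else paste0("slot", seq_len(scheme_size))
  labels <- with_seed(seed * 13 + 1, gen_labels(scheme_size + 1, enz$overhang_len))
  scheme <- slot_scheme(sprintf("kit%d_seed%d", scheme_size, seed), slots,
                        labels, enzyme = enz)
  vector <- make_destination_vector(scheme, seed * 13 + 2)

  ppslot <- if (length(parts_per_slot) == 1)
    stats::setNames(rep(parts_per_slot, scheme_size), slots)
  else stats::setNames(as.integer(parts_per_slot[slots]), slots)
  kinds <- kit_slot_kinds(slots)

  molecules <- list()
  rows <- list()
  counter <- 0L
  add_part <- function(span, kind, pid) {
    counter <<- counter + 1L
    mol <- make_entry_clone(scheme, span, seed * 1000 + counter, id = pid,
                            kind = kind)
    molecules[[pid]] <<- mol
    ij <- parse_span(scheme, span)
    rows[[length(rows) + 1]] <<- data.frame(
      id = pid, slot_first = scheme$slots[ij["first"]],
      slot_last = scheme$slots[ij["last"]], kind = kind,
      path = paste0(pid, ".gb"), notes = "synthetic fixture",
      stringsAsFactors = FALSE)
  }
  for (sl in slots) {
    for (v in seq_len(ppslot[[sl]])) {
      pid <- if (ppslot[[sl]] == 1) paste0("p_", sl) else sprintf("p_%s_%d", sl, v)
      add_part(sl, kinds[[sl]], pid)
    }
  }
  if (scheme_size >= 4) {
    add_part(span_key(slots[1], slots[2]), kinds[[slots[1]]],
             paste0("p_", slots[1], "_", slots[2]))
    add_part(span_key(slots[scheme_size - 1], slots[scheme_size]),
             kinds[[slots[scheme_size]]],
             paste0("p_", slots[scheme_size - 1], "_", slots[scheme_size]))
  }
  registry <- registry_from_parts(do.call(rbind, rows), molecules)
  structure(list(scheme = scheme, vector = vector, registry = registry,
                 seed = seed), class = "fixture_kit")
}

kit_slot_kinds <- function(slots) {
  canonical <- c("5arm" = "promoter", CT = "linker", FP = "fluorophore",
                 SEC = "linker", NT = "CDS", "3arm" = "utr3")
  out <- lapply(slots, function(sl) {
    if (sl %in% names(canonical)) unname(canonical[sl]) else "misc"
  })
  stats::setNames(out, slots)
}

#' @export
print.fixture_kit <- function(x, ...) {
  cat(sprintf("<fixture_kit> seed %d\n", x$seed))
  print(x$scheme)
  cat(sprintf("  vector: %s (%d bp)\n", x$vector$id, nchar(x$vector$sequence)))
  cat(sprintf("  parts:  %s\n", paste(x$registry$table$id, collapse = ", ")))
  invisible(x)
}

#' Write a kit to disk
#'
#' One GenBank file per molecule plus the registry TSV.
#'
#' @param kit a \code{fixture_kit}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_kit <- function(kit, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_record(kit$vector, file.path(dir, "vector.gb"))
  for (pid in names(kit$registry$molecules))
    write_record(kit$registry$molecules[[pid]], file.path(dir, paste0(pid, ".gb")))
  tab <- kit$registry$table
  write_atomic(c(paste(names(tab), collapse = "\t"),
                 apply(tab, 1, paste, collapse = "\t")),
               file.path(dir, "registry.tsv"))
  scheme_tab <- c("name\tslots\tjunction_labels\tenzyme",
                  paste(kit$scheme$name, paste(kit$scheme$slots, collapse = ","),
                        paste(kit$scheme$junction_labels, collapse = ","),
                        kit$scheme$enzyme, sep = "\t"))
  write_atomic(scheme_tab, file.path(dir, "scheme.tsv"))
  invisible(dir)
}

#' Read a scheme definition written by [write_kit()]
#' @param path scheme TSV path.
#' @return a [slot_scheme].
#' @export
read_scheme <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  slot_scheme(tab$name[1], strsplit(tab$slots[1], ",")[[1]],
              strsplit(tab$junction_labels[1], ",")[[1]],
              enzyme = tab$enzyme[1])
}

#' Generate a stress set: one backbone plus up to 20 chained inserts
#'
#' n inserts and a destination vector wired through n + 1 distinct junction
#' labels, so that assembly yields exactly one circular product incorporating
#' every insert.
#'
#' @param n_inserts 1..[max_stress_inserts()].
#' @param seed integer seed.
#' @param enzyme assembly enzyme.
#' @return list: \code{vector}, \code{inserts} (list of entry clones),
#'   \code{labels}, \code{scheme} (the ad-hoc chain scheme).
#' @export
make_stress_set <- function(n_inserts = max_stress_inserts(), seed = 1,
                            enzyme = "SapI") {
  if (n_inserts < 1 || n_inserts > GK_MAX_STRESS_INSERTS)
    gk_stop("gatekit_parameter_error", sprintf(
      "n_inserts must be in 1..%d", GK_MAX_STRESS_INSERTS))
  enz <- get_enzyme(enzyme)
  labels <- with_seed(seed * 17 + 3, gen_labels(n_inserts + 1, enz$overhang_len))
  scheme <- slot_scheme(sprintf("stress%d_seed%d", n_inserts, seed),
                        paste0("s", seq_len(n_inserts)), labels, enzyme = enz)
  vector <- make_destination_vector(scheme, seed * 17 + 4, id = "pDEST_stress")
  inserts <- lapply(seq_len(n_inserts), function(i)
    make_entry_clone(scheme, paste0("s", i), seed * 17 + 10 + i,
                     id = sprintf("p_s%d", i), body_len = 60))
  list(vector = vector, inserts = inserts, labels = labels, scheme = scheme)
}
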