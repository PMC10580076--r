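# Slot architecture: an ordered list of named slots with a junction overhang
# label between each adjacent pair (plus the two vector junctions), and the
# registry-driven construct builder on top of it. A part may occupy one slot
# or a combined span of consecutive slots, in which case it uses the outer
# labels of its span (slot skipping).

RMCE6_SLOTS <- c("5arm", "CT", "FP", "SEC", "NT", "3arm")

#' Construct a slot scheme
#'
#' @param name scheme name.
#' @param slots ordered character vector of slot names.
#' @param junction_labels overhang labels, length \code{length(slots) + 1}:
#'   vector-left junction, one between each adjacent slot pair, vector-right.
#'   Must be pairwise distinct, of the enzyme's overhang length, free of N and
#'   not self-complementary.
#' @param enzyme assembly enzyme of the scheme.
#' @param role_notes optional named character vector of per-slot notes.
#' @return object of class \code{slot_scheme}.
#' @export
slot_scheme <- function(name, slots, junction_labels, enzyme = "SapI",
                        role_notes = NULL) {
  enzyme <- get_enzyme(enzyme)
  junction_labels <- toupper(junction_labels)
  if (length(junction_labels) != length(slots) + 1)
    gk_stop("gatekit_config_error", sprintf(
      "scheme '%s': %d slots require %d junction labels, got %d", name,
      length(slots), length(slots) + 1, length(junction_labels)))
  if (anyDuplicated(junction_labels))
    gk_stop("gatekit_config_error", sprintf(
      "scheme '%s': junction labels must be pairwise distinct", name))
  if (any(nchar(junction_labels) != enzyme$overhang_len))
    gk_stop("gatekit_config_error", sprintf(
      "scheme '%s': all junction labels must be %d nt (the %s overhang length)",
      name, enzyme$overhang_len, enzyme$name))
  if (any(grepl("N", junction_labels)))
    gk_stop("gatekit_config_error", "junction labels must not contain N")
  if (any(is_self_complementary(junction_labels)))
    gk_stop("gatekit_config_error", sprintf(
      "scheme '%s': self-complementary junction label(s) %s", name,
      paste(junction_labels[is_self_complementary(junction_labels)], collapse = ", ")))
  structure(list(name = name, slots = slots,
                 junction_labels = junction_labels, enzyme = enzyme$name,
                 role_notes = role_notes), class = "slot_scheme")
}

#' @export
print.slot_scheme <- function(x, ...) {
  chain <- paste0("[", x$junction_labels[1], "]")
  for (i in seq_along(x$slots))
    chain <- paste0(chain, " ", x$slots[i], " [", x$junction_labels[i + 1], "]")
  cat(sprintf("<slot_scheme> %s (%s): %s\n", x$name, x$enzyme, chain))
  invisible(x)
}

#' The default six-slot RMCE scheme
#'
#' Slots 5arm, CT, FP, SEC, NT, 3arm in order, joined by distinct 3-nt SapI
#' overhangs. The literature that defined this slot order does not fix the
#' seven overhang sequences as printed values, so the label table shipped here
#' is this package's own default, chosen to be pairwise distinct and
#' non-self-complementary; schemes with other labels are first-class via
#' [slot_scheme()], and fixture kits generate their own labels.
#'
#' @return a [slot_scheme].
#' @export
default_scheme <- function() {
  slot_scheme("rmce6", RMCE6_SLOTS,
              c("CAT", "GTT", "GGA", "ACG", "TCC", "AAC", "TGC"),
              enzyme = "SapI",
              role_notes = c(
                "5arm" = "promoter (or 5' homology arm in CRISPR schemes)",
                "CT" = "C-terminal tag or linker",
                "FP" = "fluorescent protein / protein tag",
                "SEC" = "linker (selection cassette slot in CRISPR schemes)",
                "NT" = "gene of interest (N-terminal fusion) or tag",
                "3arm" = "3' UTR (or 3' homology arm)"))
}

# span helpers -----------------------------------------------------------------

span_key <- function(first, last) {
  if (first == last) first else paste0(first, "-", last)
}

parse_span <- function(scheme, key) {
  parts <- strsplit(key, "-", fixed = TRUE)[[1]]
  if (length(parts) == 1) parts <- c(parts, parts)
  if (length(parts) != 2 || !all(parts %in% scheme$slots))
    gk_stop("gatekit_config_error", sprintf(
      "'%s' is not a slot span of scheme '%s' (slots: %s)", key, scheme$name,
      paste(scheme$slots, collapse = ", ")))
  i <- match(parts[1], scheme$slots)
  j <- match(parts[2], scheme$slots)
  if (j < i)
    gk_stop("gatekit_config_error", sprintf(
      "span '%s' runs against slot order", key))
  c(first = i, last = j)
}

#' Outer junction labels of a slot span
#'
#' @param scheme a [slot_scheme].
#' @param span span key: a slot name (\code{"FP"}) or a combined span
#'   (\code{"5arm-CT"}).
#' @return character vector \code{c(left, right)}.
#' @export
span_labels <- function(scheme, span) {
  ij <- parse_span(scheme, span)
  c(left = scheme$junction_labels[ij["first"]],
    right = scheme$junction_labels[ij["last"] + 1])
}

all_spans <- function(scheme) {
  n <- length(scheme$slots)
  out <- character(0)
  for (i in seq_len(n)) for (j in i:n)
    out <- c(out, span_key(scheme$slots[i], scheme$slots[j]))
  out
}

#' Classify a part molecule into its slot span
#'
#' Digests the part with the scheme enzyme and finds the unique slot span
#' whose outer junction labels match the released insert fragment (in either
#' orientation); the entry backbone, which retains the recognition sites, is
#' excluded automatically.
#'
#' @param mol part plasmid / PCR product ([dna_molecule]) or pre-cut
#'   [sticky_fragment].
#' @param scheme a [slot_scheme].
#' @param enzyme assembly enzyme; defaults to the scheme's.
#' @return list with \code{span} (key), \code{first}/\code{last} slot names,
#'   \code{fragment} (the insert), \code{orientation}.
#' @details Errors: \code{gatekit_unassignable_part} when no span matches;
#'   \code{gatekit_multi_insert_part} when several released fragments match
#'   spans.
#' @export
classify_part <- function(mol, scheme, enzyme = NULL) {
  enzyme <- get_enzyme(enzyme %||% scheme$enzyme)
  frags <- Filter(function(f) usable_fragment(f, enzyme),
                  input_fragments(mol, enzyme))
  spans <- all_spans(scheme)
  span_lab <- lapply(spans, function(sp) span_labels(scheme, sp))
  names(span_lab) <- spans
  hits <- list()
  for (f in frags) {
    for (ori in c("+", "-")) {
      g <- if (ori == "+") f else revcomp(f)
      pair <- c(g$left_end$label, g$right_end$label)
      for (sp in spans) {
        if (identical(unname(span_lab[[sp]]), pair)) {
          hits[[length(hits) + 1]] <- list(span = sp, fragment = g,
                                           orientation = ori)
        }
      }
    }
  }
  frag_ids <- unique(vapply(hits, function(h) h$fragment$id, character(1)))
  if (!length(hits))
    gk_stop("gatekit_unassignable_part", sprintf(
      "'%s' releases no fragment matching any span of scheme '%s'",
      input_id(mol), scheme$name))
  if (length(sub("_rc$", "", frag_ids)) > 1 &&
      length(unique(sub("_rc$", "", frag_ids))) > 1)
    gk_stop("gatekit_multi_insert_part", sprintf(
      "'%s' releases %d fragments matching spans of scheme '%s'",
      input_id(mol), length(unique(sub("_rc$", "", frag_ids))), scheme$name))
  h <- hits[[1]]
  ij <- parse_span(scheme, h$span)
  list(span = h$span, first = scheme$slots[ij["first"]],
       last = scheme$slots[ij["last"]], fragment = h$fragment,
       orientation = h$orientation)
}

# registry ----------------------------------------------------------------------

#' Parts registry
#'
#' The software twin of a kit's part sheet: one row per part (id, slot_first,
#' slot_last, kind, path, notes) plus the loaded molecules.
#'
#' \code{read_registry()} reads a tab-delimited table and loads each part's
#' record file (GenBank/FASTA, path relative to \code{base_dir});
#' \code{registry_from_parts()} builds a registry from in-memory molecules.
#'
#' @param path registry TSV path.
#' @param base_dir directory that part paths are relative to (default: the
#'   registry's directory).
#' @return object of class \code{part_registry}: \code{table} (data.frame) and
#'   \code{molecules} (named list).
#' @export
read_registry <- function(path, base_dir = dirname(path)) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "slot_first", "slot_last", "kind", "path")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    gk_stop("gatekit_format_error", sprintf(
      "registry '%s' lacks column(s): %s", path, paste(miss, collapse = ", ")))
  mols <- lapply(seq_len(nrow(tab)), function(i)
    read_record(file.path(base_dir, tab$path[i])))
  names(mols) <- tab$id
  structure(list(table = tab, molecules = mols), class = "part_registry")
}

#' @rdname read_registry
#' @param table registry data.frame (id, slot_first, slot_last, kind, notes).
#' @param molecules named list of [dna_molecule]/[sticky_fragment], names
#'   matching \code{table$id}.
#' @export
registry_from_parts <- function(table, molecules) {
  if (!all(table$id %in% names(molecules)))
    gk_stop("gatekit_config_error", "every registry id needs a molecule")
  structure(list(table = table, molecules = molecules[table$id]),
            class = "part_registry")
}

#' @export
print.part_registry <- function(x, ...) {
  cat(sprintf("<part_registry> %d part(s)\n", nrow(x$table)))
  print(x$table[, setdiff(names(x$table), "path"), drop = FALSE])
  invisible(x)
}

registry_part <- function(registry, id) {
  mol <- registry$molecules[[id]]
  if (is.null(mol))
    gk_stop("gatekit_config_error", sprintf("part '%s' not in registry", id))
  mol
}

#' Build a construct from a slot selection
#'
#' The in-silico construct builder: pick one part per slot span so that the
#' spans tile the scheme exactly, then assemble them into the destination
#' vector, yielding both an annotated and a plain sequence output.
#'
#' @param vector destination vector ([dna_molecule]).
#' @param selection named character vector: span key -> part id, e.g.
#'   \code{c("5arm-CT" = "Pprom1", FP = "BFP", "SEC-3arm" = "utr1")}. Spans
#'   must cover every slot exactly once (\code{gatekit_slot_coverage} error
#'   otherwise).
#' @param registry a \code{part_registry}.
#' @param scheme a [slot_scheme].
#' @param out_prefix if non-NULL, write \code{<prefix>.gb} (annotated),
#'   \code{<prefix>.fa} (plain sequence) and \code{<prefix>.json} (build
#'   record).
#' @param id product id (default derived from the selection).
#' @return an [assembly_product] with the selection recorded in
#'   \code{$selection}.
#' @export
build_construct <- function(vector, selection, registry, scheme,
                            out_prefix = NULL, id = NULL) {
  spans <- t(vapply(names(selection), function(k) parse_span(scheme, k),
                    numeric(2)))
  covered <- integer(0)
  for (r in seq_len(nrow(spans)))
    covered <- c(covered, spans[r, 1]:spans[r, 2])
  n <- length(scheme$slots)
  gaps <- setdiff(seq_len(n), covered)
  if (length(gaps) || anyDuplicated(covered))
    gk_stop("gatekit_slot_coverage", sprintf(
      "selection does not tile the scheme: %s",
      if (length(gaps)) paste0("uncovered slot(s) ",
                               paste(scheme$slots[gaps], collapse = ", "))
      else paste0("slot(s) covered twice: ",
                  paste(scheme$slots[unique(covered[duplicated(covered)])],
                        collapse = ", "))))
  ord <- order(spans[, 1])
  picks <- lapply(names(selection)[ord], function(k)
    registry_part(registry, selection[[k]]))
  product <- assemble(vector, picks, scheme$enzyme,
                      id = id %||% paste0(vector$id, "_",
                                          paste(selection[ord], collapse = "+")))
  product$selection <- selection[ord]
  if (!is.null(out_prefix)) {
    write_record(product$molecule, paste0(out_prefix, ".gb"), "genbank")
    write_record(product$molecule, paste0(out_prefix, ".fa"), "fasta")
    rec <- list(id = product$molecule$id, scheme = scheme$name,
                enzyme = scheme$enzyme, vector = vector$id,
                selection = as.list(selection[ord]),
                length_bp = nchar(product$molecule$sequence),
                diagnostics = product$diagnostics)
    write_atomic(jsonlite::toJSON(rec, auto_unbox = TRUE, pretty = TRUE),
                 paste0(out_prefix, ".json"))
  }
  product
}

#' Validate a kit against its scheme
#'
#' Report-only checker: per part, the insert must be released cleanly, its
#' labels must match the declared span, it must carry no internal site of the
#' scheme enzyme (nor of BsaI, which drives entry-clone construction), and
#' plasmid-borne parts must ride a KanR entry backbone; the destination vector
#' must release an AmpR backbone. Kit-wide, the scheme's label table must be
#' consistent and a pairwise ligation-compatibility matrix is reported.
#'
#' @param registry a \code{part_registry}.
#' @param scheme a [slot_scheme].
#' @param vector optional destination vector to check alongside the parts.
#' @param enzyme assembly enzyme; defaults to the scheme's.
#' @return object of class \code{kit_report}: \code{findings} data.frame
#'   (part_id, check, message) — zero rows means a clean kit — and
#'   \code{compatibility}, a logical matrix of which part's right end ligates
#'   to which part's left end.
#' @export
validate_kit <- function(registry, scheme, vector = NULL, enzyme = NULL) {
  enzyme <- get_enzyme(enzyme %||% scheme$enzyme)
  findings <- data.frame(part_id = character(), check = character(),
                         message = character(), stringsAsFactors = FALSE)
  note <- function(id, check, msg) {
    findings <<- rbind(findings, data.frame(
      part_id = id, check = check, message = msg, stringsAsFactors = FALSE))
  }
  ends <- list()
  for (i in seq_len(nrow(registry$table))) {
    row <- registry$table[i, ]
    mol <- registry$molecules[[row$id]]
    declared <- span_key(row$slot_first, row$slot_last)
    frags <- input_fragments(mol, enzyme)
    usable <- Filter(function(f) usable_fragment(f, enzyme), frags)
    if (length(usable) != 1) {
      note(row$id, "insert_release", sprintf(
        "releases %d usable insert fragment(s); expected exactly 1",
        length(usable)))
      next
    }
    ins <- usable[[1]]
    ends[[row$id]] <- c(ins$left_end$label, ins$right_end$label)
    want <- span_labels(scheme, declared)
    if (!identical(unname(want), c(ins$left_end$label, ins$right_end$label))) {
      got_span <- tryCatch(classify_part(mol, scheme, enzyme)$span,
                           gatekit_error = function(e) "none")
      note(row$id, "span_mismatch", sprintf(
        "declared span %s (labels %s/%s) but insert has labels %s/%s (matches: %s)",
        declared, want["left"], want["right"], ins$left_end$label,
        ins$right_end$label, got_span))
    }
    other <- setdiff(c("SapI", "BsaI"), enzyme$name)
    extra <- fragment_internal_sites(ins, other)
    if (extra > 0)
      note(row$id, "internal_site", sprintf(
        "insert carries %d internal %s site(s)", extra, other))
    if (inherits(mol, "dna_molecule") && mol$source_kind == "plasmid") {
      markers <- mol$features$label[mol$features$kind == "selection_marker"]
      if (!"KanR" %in% markers)
        note(row$id, "backbone_marker",
             "entry backbone lacks a KanR selection marker")
      if ("AmpR" %in% markers)
        note(row$id, "backbone_marker",
             "entry backbone carries AmpR (destination marker)")
    }
  }
  if (!is.null(vector)) {
    bb <- tryCatch(pick_backbone(input_fragments(vector, enzyme), enzyme,
                                 vector$id),
                   gatekit_error = function(e) NULL)
    if (is.null(bb)) {
      note(vector$id, "vector_backbone", "vector releases no usable backbone")
    } else if (!"AmpR" %in% bb$features$label[bb$features$kind == "selection_marker"]) {
      note(vector$id, "vector_backbone",
           "destination backbone lacks an AmpR selection marker")
    }
  }
  ids <- names(ends)
  compat <- matrix(FALSE, length(ids), length(ids),
                   dimnames = list(right_of = ids, left_of = ids))
  for (a in ids) for (b in ids) compat[a, b] <- ends[[a]][2] == ends[[b]][1]
  structure(list(findings = findings, compatibility = compat,
                 scheme = scheme$name), class = "kit_report")
}

#' @export
print.kit_report <- function(x, ...) {
  if (!nrow(x$findings)) {
    cat(sprintf("<kit_report> scheme %s: clean (0 findings)\n", x$scheme))
  } else {
    cat(sprintf("<kit_report> scheme %s: %d finding(s)\n", x$scheme,
                nrow(x$findings)))
    print(x$findings)
  }
  invisible(x)
}
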