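# Type IIS site finding and digestion into sticky-ended fragments.
#
# Cut arithmetic (0-based boundaries; a boundary b means "between positions
# b-1 and b" on the top strand):
#   + strand site starting at r, recognition length k:
#       cut_top    = r + k + cut_offset_top
#       cut_bottom = r + k + cut_offset_bottom
#   - strand site whose recognition reverse-complement starts at r (top coords):
#       cut_top    = r - cut_offset_bottom
#       cut_bottom = r - cut_offset_top
# The overhang duplex occupies [cut_top, cut_bottom) on the top strand; for
# positive offsets it is a 5' overhang. A sticky end's label is the top-strand
# 5'->3' sequence of the duplex it will form, so two ends are ligatable iff
# their labels are EQUAL (the reverse-complement pairing is absorbed by
# fragment orientation).

#' Find type IIS recognition sites on both strands
#'
#' @param mol a [dna_molecule].
#' @param enzyme an [enzyme_spec] or enzyme name.
#' @return data.frame with one row per site: enzyme, strand, recognition_start
#'   (0-based), cut_top, cut_bottom, cuttable. On circular molecules matches
#'   spanning the origin are found and positions are reported modulo length;
#'   on linear molecules a site whose cut would fall outside the sequence is
#'   reported with \code{cuttable = FALSE}.
#' @examples
#' m <- dna_molecule("x", "AAGCTCTTCAAAA", "linear")
#' find_sites(m, "SapI")
#' @export
find_sites <- function(mol, enzyme) {
  enzyme <- get_enzyme(enzyme)
  s <- mol$sequence
  L <- nchar(s)
  rec <- enzyme$recognition
  k <- nchar(rec)
  circular <- mol$topology == "circular"
  scan <- if (circular) paste0(s, subseq0(s, 0, min(k - 1, L))) else s
  fwd_hits <- str_find_all(scan, rec)
  rev_hits <- str_find_all(scan, revcomp_str(rec))
  hits <- data.frame(
    strand = c(rep("+", length(fwd_hits)), rep("-", length(rev_hits))),
    start = c(fwd_hits, rev_hits), stringsAsFactors = FALSE)
  hits <- hits[hits$start < L, , drop = FALSE]
  if (!nrow(hits)) {
    return(data.frame(enzyme = character(), strand = character(),
                      recognition_start = integer(), cut_top = integer(),
                      cut_bottom = integer(), cuttable = logical(),
                      stringsAsFactors = FALSE))
  }
  ct <- ifelse(hits$strand == "+",
               hits$start + k + enzyme$cut_offset_top,
               hits$start - enzyme$cut_offset_bottom)
  cb <- ifelse(hits$strand == "+",
               hits$start + k + enzyme$cut_offset_bottom,
               hits$start - enzyme$cut_offset_top)
  if (circular) {
    cuttable <- rep(TRUE, nrow(hits))
    ct <- ct %% L
    cb <- ct + enzyme$overhang_len  # stored unwrapped; cb may exceed L
  } else {
    cuttable <- ct >= 0 & cb <= L & ct <= cb
  }
  out <- data.frame(enzyme = enzyme$name, strand = hits$strand,
                    recognition_start = as.integer(hits$start),
                    cut_top = as.integer(ct), cut_bottom = as.integer(cb),
                    cuttable = cuttable, stringsAsFactors = FALSE)
  out <- out[order(out$recognition_start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count recognition sites per enzyme (domestication check)
#'
#' A part is "domesticated" for an enzyme set when it carries no recognition
#' site of any of them on either strand; such sites would be re-cut during
#' assembly.
#'
#' @param mol a [dna_molecule].
#' @param enzymes vector of enzyme names or list of specs.
#' @return named integer vector of site counts; the molecule is domesticated
#'   iff all counts are zero.
#' @export
is_domesticated <- function(mol, enzymes = c("SapI", "BsaI")) {
  counts <- vapply(enzymes, function(e) nrow(find_sites(mol, e)), integer(1))
  names(counts) <- vapply(enzymes, function(e) get_enzyme(e)$name, character(1))
  counts
}

# sticky fragments ------------------------------------------------------------

#' Construct a sticky-ended linear fragment
#'
#' A fragment is represented by its physical top strand plus explicit end
#' chemistry. The left end's overhang (when sticky) is the prefix of
#' \code{sequence}; the right end's overhang bases protrude on the bottom
#' strand and are stored only as the \code{right_end} label (in the assembled
#' product they are the first bases of the next fragment). Under this
#' bookkeeping ligation is plain concatenation of top strands and each
#' junction's overlap is counted exactly once.
#'
#' @param sequence top strand 5'->3'.
#' @param left_end,right_end lists \code{list(type = "sticky", label = ...)} or
#'   \code{list(type = "blunt")}.
#' @param features feature data.frame in full-span coordinates (the full span
#'   is \code{sequence} followed by the right-end overhang).
#' @param provenance data.frame(source_id, start, end) of source intervals.
#' @param id fragment identifier.
#' @param uncut TRUE for an undigested input passed through whole.
#' @param circular TRUE when the (uncut) source was circular.
#' @param source_kind source kind of the donor molecule.
#' @return object of class \code{sticky_fragment}.
#' @export
sticky_fragment <- function(sequence, left_end, right_end,
                            features = empty_features(),
                            provenance = NULL, id = "fragment",
                            uncut = FALSE, circular = FALSE,
                            source_kind = "plasmid") {
  for (e in list(left_end, right_end)) {
    if (!e$type %in% c("sticky", "blunt"))
      gk_stop("gatekit_config_error", "fragment end type must be sticky or blunt")
    if (e$type == "sticky") {
      if (grepl("N", e$label))
        gk_stop("gatekit_config_error", "overhang labels must not contain N")
      if (nchar(e$label) < 2 || nchar(e$label) > 4)
        gk_stop("gatekit_config_error",
                sprintf("overhang '%s' outside the 2-4 nt range", e$label))
    }
  }
  structure(list(id = id, sequence = sequence, left_end = left_end,
                 right_end = right_end, features = features,
                 provenance = provenance %||% data.frame(
                   source_id = character(), start = integer(), end = integer(),
                   stringsAsFactors = FALSE),
                 uncut = uncut, circular = circular, source_kind = source_kind),
            class = "sticky_fragment")
}

blunt_end <- function() list(type = "blunt")
sticky_end <- function(label) list(type = "sticky", label = label)

end_label <- function(e) if (e$type == "sticky") e$label else NA_character_

#' @export
print.sticky_fragment <- function(x, ...) {
  fmt <- function(e) if (e$type == "sticky") e$label else "blunt"
  cat(sprintf("<sticky_fragment> %s: %d nt top strand, ends [%s | %s]%s\n",
              x$id, nchar(x$sequence), fmt(x$left_end), fmt(x$right_end),
              if (x$uncut) " (uncut)" else ""))
  invisible(x)
}

# full span = top strand + right overhang bases (bottom-strand protrusion)
fragment_full_span <- function(f) {
  paste0(f$sequence, if (f$right_end$type == "sticky") f$right_end$label else "")
}

fragment_length <- function(f) nchar(f$sequence)

#' @export
revcomp.sticky_fragment <- function(x) {
  kl <- if (x$left_end$type == "sticky") nchar(x$left_end$label) else 0L
  kr <- if (x$right_end$type == "sticky") nchar(x$right_end$label) else 0L
  n <- nchar(x$sequence)
  N <- n + kr
  # new top strand = revcomp of the old bottom strand, which covers [kl, N)
  new_top <- revcomp_str(paste0(
    subseq0(x$sequence, kl, n),
    if (kr) x$right_end$label else ""))
  new_left <- if (kr) sticky_end(revcomp_str(x$right_end$label)) else blunt_end()
  new_right <- if (kl) sticky_end(revcomp_str(subseq0(x$sequence, 0, kl)))
               else blunt_end()
  f <- x$features
  if (nrow(f)) {
    len <- f$end - f$start
    new_start <- N - f$end
    f$start <- as.integer(new_start)
    f$end <- as.integer(new_start + len)
    f$strand <- ifelse(f$strand == "+", "-", "+")
    f <- f[order(f$start, f$end), , drop = FALSE]
    rownames(f) <- NULL
  }
  sticky_fragment(new_top, new_left, new_right, features = f,
                  provenance = x$provenance, id = paste0(x$id, "_rc"),
                  uncut = x$uncut, circular = x$circular,
                  source_kind = x$source_kind)
}

#' Digest a molecule with a type IIS enzyme
#'
#' Digestion is simulated to completion: every cuttable site is cut. Fragments
#' carry provenance and locally re-mapped features for annotation propagation.
#'
#' @param mol a [dna_molecule].
#' @param enzyme an [enzyme_spec] or enzyme name (must not be check-only).
#' @return list of [sticky_fragment]. A molecule with no cuttable site is
#'   returned whole as a single uncut fragment. A circular molecule with n
#'   sites yields n fragments; a linear one yields n + 1 (outermost ends
#'   blunt).
#' @examples
#' m <- dna_molecule("p", paste0(strrep("A", 20), "GCTCTTCA", strrep("T", 20)),
#'                   "circular")
#' digest(m, "SapI")
#' @export
digest <- function(mol, enzyme) {
  enzyme <- get_enzyme(enzyme)
  if (enzyme$check_only)
    gk_stop("gatekit_config_error",
            sprintf("%s is a check-only enzyme and cannot drive digestion",
                    enzyme$name))
  s <- mol$sequence
  L <- nchar(s)
  sites <- find_sites(mol, enzyme)
  sites <- sites[sites$cuttable, , drop = FALSE]
  if (nrow(sites)) {
    if (any(sites$cut_bottom - sites$cut_top != enzyme$overhang_len))
      gk_stop("gatekit_config_error",
              sprintf("malformed cut arithmetic for %s", enzyme$name))
  }
  cuts <- unique(sites[, c("cut_top", "cut_bottom")])
  cuts <- cuts[order(cuts$cut_top), , drop = FALSE]

  if (!nrow(cuts)) {
    ends <- blunt_end()
    frag <- sticky_fragment(
      s, ends, ends,
      features = mol$features,
      provenance = data.frame(source_id = mol$id, start = 0L, end = L,
                              stringsAsFactors = FALSE),
      id = mol$id, uncut = TRUE, circular = mol$topology == "circular",
      source_kind = mol$source_kind)
    return(list(frag))
  }

  oh <- enzyme$overhang_len
  feats <- unwrap_features(mol)
  frags <- list()
  if (mol$topology == "circular") {
    k <- nrow(cuts)
    for (i in seq_len(k)) {
      a <- cuts$cut_top[i]
      nxt <- cuts$cut_top[if (i == k) 1 else i + 1]
      top_len <- if (k == 1) L else ((nxt - a) %% L)
      if (top_len == 0) top_len <- L
      frags[[i]] <- make_cut_fragment(mol, s, L, a, top_len,
                                      left_label = substr_circ(s, a, oh),
                                      right_label = substr_circ(s, a + top_len, oh),
                                      feats = feats, idx = i, circular = TRUE)
    }
  } else {
    bounds <- c(0L, cuts$cut_top, L)
    k <- nrow(cuts)
    for (i in seq_len(k + 1)) {
      a <- bounds[i]
      b <- bounds[i + 1]
      left <- if (i == 1) blunt_end() else sticky_end(subseq0(s, a, a + oh))
      right <- if (i == k + 1) blunt_end()
               else sticky_end(subseq0(s, b, b + oh))
      frags[[i]] <- make_cut_fragment(mol, s, L, a, b - a,
                                      left_label = end_label(left),
                                      right_label = end_label(right),
                                      feats = feats, idx = i, circular = FALSE,
                                      left_blunt = i == 1,
                                      right_blunt = i == k + 1)
    }
  }
  frags
}

unwrap_features <- function(mol) mol$features

make_cut_fragment <- function(mol, s, L, a, top_len, left_label, right_label,
                              feats, idx, circular,
                              left_blunt = FALSE, right_blunt = FALSE) {
  kr <- if (right_blunt || is.na(right_label)) 0L else nchar(right_label)
  span_len <- top_len + kr
  top <- if (circular) substr_circ(s, a, top_len) else subseq0(s, a, a + top_len)
  local <- empty_features()
  if (nrow(feats)) {
    rel <- if (circular) (feats$start - a) %% L else feats$start - a
    keep <- rel >= 0 & rel + (feats$end - feats$start) <= span_len
    if (any(keep)) {
      local <- feats[keep, , drop = FALSE]
      local$start <- as.integer(rel[keep])
      local$end <- as.integer(rel[keep] + (feats$end - feats$start)[keep])
      rownames(local) <- NULL
    }
  }
  sticky_fragment(
    top,
    if (left_blunt) blunt_end() else sticky_end(left_label),
    if (right_blunt) blunt_end() else sticky_end(right_label),
    features = local,
    provenance = data.frame(source_id = mol$id, start = as.integer(a),
                            end = as.integer(a + span_len),
                            stringsAsFactors = FALSE),
    id = sprintf("%s.%d", mol$id, idx),
    source_kind = mol$source_kind)
}

# recognition-site count inside a fragment (full span, linear scan)
fragment_internal_sites <- function(frag, enzyme) {
  enzyme <- get_enzyme(enzyme)
  span <- fragment_full_span(frag)
  length(str_find_all(span, enzyme$recognition)) +
    length(str_find_all(span, revcomp_str(enzyme$recognition)))
}
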