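# Design of inputs that create new parts: enzyme-tailed primer pairs for new
# entry clones or direct PCR parts, annealed-oligo duplexes, and domestication
# plans that lesion internal recognition sites.
#
# Primer tail anatomy (5'->3'): 2-nt spacer ("AA", cutting-efficiency padding)
# + recognition + 1-nt offset base + junction label (4 nt for BsaI tails, 3 nt
# for SapI tails) + homology region. The homology region is extended until a
# simple Wallace-rule melting temperature (2(A+T) + 4(G+C) degC) reaches the
# configured threshold, clamped to [18, 35] nt — a deliberately crude, stated
# rule.

GK_SPACER <- "AA"
GK_PAD <- "A"
GK_TM_MIN <- 55
GK_HOM_RANGE <- c(18L, 35L)

#' Wallace-rule melting temperature
#'
#' @param s nucleotide string.
#' @return 2(A+T) + 4(G+C) in degrees C.
#' @export
primer_tm <- function(s) {
  b <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  2 * sum(b %in% c("A", "T")) + 4 * sum(b %in% c("G", "C"))
}

choose_homology <- function(template, from, reverse = FALSE,
                            min_len = GK_HOM_RANGE[1], tm_min = GK_TM_MIN,
                            avoid_mismatch_within = integer(0)) {
  L <- nchar(template)
  len <- min_len
  repeat {
    hom <- if (reverse) subseq0(template, max(0, from - len), from)
           else subseq0(template, from, min(L, from + len))
    ok_tm <- primer_tm(hom) >= tm_min
    # any template-mismatch position (lesion) must sit >= 12 nt from the 3' end
    ok_mm <- TRUE
    if (length(avoid_mismatch_within)) {
      d3 <- if (reverse) avoid_mismatch_within - (from - nchar(hom))
            else (from + nchar(hom)) - avoid_mismatch_within
      ok_mm <- all(d3 > 12)
    }
    if ((ok_tm && ok_mm) || len >= GK_HOM_RANGE[2]) return(hom)
    len <- len + 1
  }
}

new_primer_pair <- function(forward, reverse, hom_fwd, hom_rev, name = "primer") {
  structure(list(name = name, forward = forward, reverse = reverse,
                 homology_fwd = hom_fwd, homology_rev = hom_rev,
                 tm_fwd = primer_tm(hom_fwd), tm_rev = primer_tm(hom_rev)),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("<primer_pair> %s\n  F (%2d nt, Tm %2.0f): %s\n  R (%2d nt, Tm %2.0f): %s\n",
              x$name, nchar(x$forward), x$tm_fwd, x$forward,
              nchar(x$reverse), x$tm_rev, x$reverse))
  invisible(x)
}

tailed_primers <- function(target, left_label, right_label, enzyme, name,
                           lesions = integer(0)) {
  enzyme <- get_enzyme(enzyme)
  L <- nchar(target)
  hom_f <- choose_homology(target, nchar(left_label),
                           avoid_mismatch_within = lesions)
  hom_r_top <- choose_homology(target, L - nchar(right_label), reverse = TRUE,
                               avoid_mismatch_within = lesions)
  fwd <- paste0(GK_SPACER, enzyme$recognition, GK_PAD, left_label, hom_f)
  rev <- paste0(GK_SPACER, enzyme$recognition, GK_PAD,
                revcomp_str(paste0(hom_r_top, right_label)))
  new_primer_pair(fwd, rev, hom_f, hom_r_top, name = name)
}

#' Simulate a PCR amplification
#'
#' Primers anneal by their 3'-terminal \code{anchor} nucleotides, which must
#' match the template exactly and uniquely; the product carries the full
#' primer sequences (so primer-borne mutations upstream of the anchor are
#' incorporated, as in mutagenic PCR). Template features fully inside the
#' amplified core are propagated.
#'
#' @param template a [dna_molecule] or plain sequence string.
#' @param primers a [primer_pair], or the forward primer string (then supply
#'   \code{reverse}).
#' @param reverse reverse primer string when \code{primers} is a string.
#' @param anchor exact-match 3' anchor length in nt.
#' @param id product id.
#' @return linear [dna_molecule] with \code{source_kind = "pcr_product"}.
#' @export
simulate_pcr <- function(template, primers, reverse = NULL, anchor = 12L,
                         id = "amplicon") {
  if (inherits(primers, "primer_pair")) {
    fwd <- primers$forward
    rev <- primers$reverse
  } else {
    fwd <- primers
    rev <- reverse
  }
  mol <- if (inherits(template, "dna_molecule")) template
         else dna_molecule("template", template)
  s <- mol$sequence
  f3 <- substr(fwd, nchar(fwd) - anchor + 1, nchar(fwd))
  r3 <- substr(rev, nchar(rev) - anchor + 1, nchar(rev))
  fpos <- str_find_all(s, f3)
  rpos <- str_find_all(s, revcomp_str(r3))
  if (length(fpos) != 1 || length(rpos) != 1)
    gk_stop("gatekit_primer_error", sprintf(
      "primer 3' anchors must match the template exactly once (forward: %d hit(s), reverse: %d)",
      length(fpos), length(rpos)))
  core_from <- fpos + anchor
  core_to <- rpos
  if (core_to < core_from)
    gk_stop("gatekit_primer_error", "primers face away from each other on the template")
  product <- paste0(fwd, subseq0(s, core_from, core_to), revcomp_str(rev))
  feats <- mol$features
  out_feats <- empty_features()
  if (nrow(feats)) {
    keep <- feats$start >= core_from & feats$end <= core_to
    if (any(keep)) {
      out_feats <- feats[keep, , drop = FALSE]
      shift <- nchar(fwd) - core_from
      out_feats$start <- as.integer(out_feats$start + shift)
      out_feats$end <- as.integer(out_feats$end + shift)
      rownames(out_feats) <- NULL
    }
  }
  dna_molecule(id, product, topology = "linear", features = out_feats,
               source_kind = "pcr_product")
}

# BsaI cloning labels used by the empty entry vector of a span: the SapI slot
# label embedded so that, after BsaI cloning, the vector's inward SapI sites
# release the insert with exactly the span's 3-nt labels (left: label + pad,
# right: pad + label). Pads are chosen to avoid self-complementary 4-mers.
entry_vector_labels <- function(scheme, span) {
  lab <- span_labels(scheme, span)
  pick_pad <- function(make) {
    for (p in c("A", "C", "G", "T")) {
      cand <- make(p)
      if (!is_self_complementary(cand)) return(cand)
    }
    gk_stop("gatekit_config_error", "no usable pad base")  # unreachable
  }
  left <- pick_pad(function(p) paste0(lab["left"], p))
  right <- pick_pad(function(p) paste0(p, lab["right"]))
  if (left == right)
    right <- pick_pad(function(p) paste0(p, lab["right"]))  # distinct by pad order
  c(left = unname(left), right = unname(right))
}

#' Design BsaI-tailed primers for a new entry clone
#'
#' Produces the primer pair that amplifies \code{insert} with BsaI tails so
#' that a BsaI Golden Gate reaction into the matching empty KanR entry vector
#' (see [make_empty_entry_vector()]) yields an entry clone whose SapI-released
#' insert carries the span's junction labels — i.e. [classify_part()] assigns
#' it to \code{span}.
#'
#' @param insert linear [dna_molecule], domesticated for SapI and BsaI
#'   (\code{gatekit_domestication_required} error otherwise, pointing to
#'   [plan_domestication()]).
#' @param span slot span key of the target entry clone.
#' @param scheme a [slot_scheme].
#' @param tail_enzyme tail enzyme (default BsaI).
#' @return a [primer_pair].
#' @export
design_entry_primers <- function(insert, span, scheme, tail_enzyme = "BsaI") {
  counts <- is_domesticated(insert, c(scheme$enzyme, tail_enzyme))
  if (any(counts > 0))
    gk_stop("gatekit_domestication_required", sprintf(
      "insert '%s' carries internal site(s) (%s); run plan_domestication() first",
      insert$id,
      paste(sprintf("%s: %d", names(counts)[counts > 0], counts[counts > 0]),
            collapse = ", ")))
  vl <- entry_vector_labels(scheme, span)
  # the cloning-junction 4-mers flank the insert; homology starts at its ends
  target <- paste0(vl["left"], insert$sequence, vl["right"])
  tailed_primers(target, vl["left"], vl["right"], tail_enzyme,
                 name = sprintf("%s_%s_entry", insert$id, span))
}

#' Design SapI-tailed primers for a direct PCR part
#'
#' The purified PCR product can be fed straight into [assemble()] in place of
#' a plasmid part occupying \code{span}: its SapI tails release it with the
#' span's junction labels.
#'
#' @inheritParams design_entry_primers
#' @return a [primer_pair].
#' @export
design_direct_pcr_part <- function(insert, span, scheme) {
  enzyme <- get_enzyme(scheme$enzyme)
  counts <- is_domesticated(insert, list(enzyme))
  if (any(counts > 0))
    gk_stop("gatekit_domestication_required", sprintf(
      "insert '%s' carries %d internal %s site(s); run plan_domestication() first",
      insert$id, counts[[1]], enzyme$name))
  lab <- span_labels(scheme, span)
  # carry the entry vector's pad bases so that a part delivered as a PCR
  # product and the same part delivered as an entry clone yield
  # sequence-identical final constructs
  vl <- entry_vector_labels(scheme, span)
  target <- paste0(vl["left"], insert$sequence, vl["right"])
  tailed_primers(target, lab["left"], lab["right"], enzyme,
                 name = sprintf("%s_%s_pcr", insert$id, span))
}

#' Build a sticky fragment from an annealed oligo duplex
#'
#' Two 5'-phosphorylated strands annealed with perfect complementarity over
#' the duplex core and 5' extensions of \code{overhang_len} nt at both ends
#' form a pre-cut fragment that joins an assembly without digestion.
#'
#' @param top,bottom strand sequences, each 5'->3'.
#' @param overhang_len length of the 5' extensions (the scheme's overhang
#'   length); 0 for a blunt duplex.
#' @param id fragment id.
#' @return a [sticky_fragment] flagged \code{source_kind = "oligo_duplex"}.
#' @details An internal mismatch raises \code{gatekit_anneal_error} naming the
#'   first mismatched (top-strand, 0-based) position; strands whose lengths
#'   are inconsistent with the stated extension length raise a validation
#'   error.
#' @export
oligo_duplex <- function(top, bottom, overhang_len, id = "duplex") {
  top <- normalize_seq(top, "top strand")
  bottom <- normalize_seq(bottom, "bottom strand")
  k <- as.integer(overhang_len)
  n <- nchar(top)
  if (k < 0 || (k > 0 && (k < 2 || k > 4)))
    gk_stop("gatekit_config_error",
            sprintf("extension length %d outside the supported 2-4 nt range", k))
  if (nchar(bottom) != n)
    gk_stop("gatekit_config_error", sprintf(
      "strands of %d and %d nt cannot form a duplex with two %d-nt 5' extensions",
      n, nchar(bottom), k))
  if (n <= 2 * k)
    gk_stop("gatekit_config_error", "no duplex core between the extensions")
  bot_top_sense <- revcomp_str(bottom)  # covers top coords [k, n + k)
  core_top <- subseq0(top, k, n)
  core_bot <- subseq0(bot_top_sense, 0, n - k)
  if (core_top != core_bot) {
    mism <- which(strsplit(core_top, "")[[1]] != strsplit(core_bot, "")[[1]])[1]
    gk_stop("gatekit_anneal_error", sprintf(
      "strands mismatch within the duplex core at top-strand position %d",
      k + mism - 1))
  }
  if (k == 0) {
    return(sticky_fragment(top, blunt_end(), blunt_end(), id = id,
                           source_kind = "oligo_duplex"))
  }
  right_label <- subseq0(bot_top_sense, n - k, n)
  sticky_fragment(top, sticky_end(subseq0(top, 0, k)),
                  sticky_end(right_label), id = id,
                  source_kind = "oligo_duplex")
}

# domestication -----------------------------------------------------------------

#' Plan removal of internal recognition sites (domestication)
#'
#' Designs the fragment-wise mutagenic PCR + BsaI reassembly that lesions each
#' internal SapI/BsaI site of a linear insert: n internal sites yield n + 1
#' sub-amplicons and 2(n + 1) primers. Each lesion is a single substitution
#' inside the recognition occurrence that destroys it without creating a new
#' site of any assembly enzyme; when a reading frame is supplied the lesion is
#' required to be synonymous (chosen at a third codon position;
#' \code{gatekit_no_silent_lesion} error when none exists). Split-point
#' overhangs are the native 4-mers at each lesioned site's boundary, slid
#' downstream past collisions and self-complementary 4-mers.
#'
#' @param insert linear [dna_molecule].
#' @param enzymes enzymes whose sites must be removed (default SapI + BsaI).
#' @param frame optional reading frame offset (0, 1 or 2): position where the
#'   codon grid starts.
#' @param max_sites above this many internal sites the plan is refused with a
#'   recommendation to obtain a synthetic fragment instead.
#' @param allow_no_op with 0 internal sites, return a trivial plan instead of
#'   erroring.
#' @return object of class \code{domestication_plan}: \code{target} (the
#'   lesioned sequence), \code{lesions} (position, ref, alt, synonymous),
#'   \code{junctions} (split-point 4-mers), \code{fragments} (coordinate
#'   table) and \code{primers} (list of [primer_pair]).
#' @seealso [simulate_domestication()] to verify a plan end-to-end.
#' @export
plan_domestication <- function(insert, enzymes = c("SapI", "BsaI"),
                               frame = NULL, max_sites = 4L,
                               allow_no_op = FALSE) {
  if (insert$topology != "linear")
    gk_stop("gatekit_topology_error", "domestication plans require a linear insert")
  specs <- lapply(enzymes, get_enzyme)
  site_count <- sum(is_domesticated(insert, specs))
  if (site_count == 0) {
    if (allow_no_op) {
      return(structure(list(target = insert$sequence, insert_id = insert$id,
                            lesions = lesion_table(), junctions = character(0),
                            fragments = fragment_table(0, nchar(insert$sequence)),
                            primers = list(), frame = frame),
                       class = "domestication_plan"))
    }
    gk_stop("gatekit_parameter_error", sprintf(
      "insert '%s' carries no internal site; nothing to domesticate", insert$id))
  }
  if (site_count > max_sites)
    gk_stop("gatekit_too_many_sites", sprintf(
      "insert '%s' carries %d internal sites (max %d); synthesis of a synthetic fragment is the more expedient route",
      insert$id, site_count, max_sites))

  s <- insert$sequence
  lesions <- lesion_table()
  repeat {
    hit <- first_site(s, specs)
    if (is.null(hit)) break
    les <- choose_lesion(s, hit, specs, frame)
    if (is.null(les))
      gk_stop("gatekit_no_silent_lesion", sprintf(
        "no synonymous lesion removes the %s site at position %d of '%s'; user override (frame = NULL) required",
        hit$enzyme, hit$start, insert$id))
    substr(s, les$position + 1, les$position + 1) <- les$alt
    lesions <- rbind(lesions, data.frame(
      position = les$position, ref = les$ref, alt = les$alt,
      synonymous = les$synonymous, enzyme = hit$enzyme,
      site_start = hit$start, stringsAsFactors = FALSE))
  }
  if (!is.null(frame)) {
    if (translate_frame(insert$sequence, frame) != translate_frame(s, frame))
      gk_stop("gatekit_no_silent_lesion",
              "internal error: lesioned sequence changes the translation")
  }

  L <- nchar(s)
  junctions <- character(0)
  cuts <- integer(0)
  taken <- c(subseq0(s, 0, 4), subseq0(s, L - 4, L))  # outer cloning labels
  for (i in seq_len(nrow(lesions))) {
    j <- max(4L, lesions$position[i] - 1L)
    repeat {
      lab <- subseq0(s, j, j + 4)
      ok <- !lab %in% taken && !revcomp_str(lab) %in% taken &&
        !is_self_complementary(lab) && j + 4 <= L - 4
      if (ok) break
      j <- j + 1L
      if (j + 4 > L - 4)
        gk_stop("gatekit_parameter_error",
                "no usable split-point overhang downstream of a lesion")
    }
    taken <- c(taken, lab, revcomp_str(lab))
    junctions <- c(junctions, lab)
    cuts <- c(cuts, j)
  }
  ord <- order(cuts)
  cuts <- cuts[ord]
  junctions <- junctions[ord]

  bounds <- c(0L, cuts, L)
  frt <- fragment_table(bounds[-length(bounds)], bounds[-1])
  primers <- lapply(seq_len(nrow(frt)), function(i) {
    a <- frt$start[i]
    b <- frt$end[i]
    # full amplified region including the right split 4-mer (or native 3' end)
    region <- subseq0(s, a, min(L, b + 4))
    les_local <- lesions$position[lesions$position >= a &
                                    lesions$position < min(L, b + 4)] - a
    tailed_primers(region, subseq0(s, a, a + 4),
                   subseq0(s, min(L, b + 4) - 4, min(L, b + 4)),
                   "BsaI", name = sprintf("%s_dom_f%d", insert$id, i),
                   lesions = les_local)
  })
  structure(list(target = s, insert_id = insert$id, lesions = lesions,
                 junctions = junctions, fragments = frt, primers = primers,
                 frame = frame), class = "domestication_plan")
}

lesion_table <- function() {
  data.frame(position = integer(), ref = character(), alt = character(),
             synonymous = character(), enzyme = character(),
             site_start = integer(), stringsAsFactors = FALSE)
}

fragment_table <- function(start, end) {
  data.frame(fragment = seq_along(start), start = as.integer(start),
             end = as.integer(end), stringsAsFactors = FALSE)
}

#' @export
print.domestication_plan <- function(x, ...) {
  cat(sprintf("<domestication_plan> %s: %d lesion(s), %d fragment(s), %d primer(s)\n",
              x$insert_id, nrow(x$lesions), nrow(x$fragments),
              2 * length(x$primers)))
  if (nrow(x$lesions)) print(x$lesions)
  invisible(x)
}

first_site <- function(s, specs) {
  mol <- dna_molecule("tmp", s, "linear")
  best <- NULL
  for (spec in specs) {
    sites <- find_sites(mol, spec)
    if (nrow(sites)) {
      cand <- list(enzyme = spec$name, spec = spec,
                   start = sites$recognition_start[1],
                   strand = sites$strand[1], len = nchar(spec$recognition))
      if (is.null(best) || cand$start < best$start) best <- cand
    }
  }
  best
}

choose_lesion <- function(s, hit, specs, frame) {
  positions <- hit$start + seq_len(hit$len) - 1L
  if (!is.null(frame)) {
    positions <- positions[(positions - frame) %% 3 == 2]  # third codon positions
    positions <- positions[positions >= frame & positions < nchar(s)]
  }
  for (pos in positions) {
    ref <- subseq0(s, pos, pos + 1)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      cand <- s
      substr(cand, pos + 1, pos + 1) <- alt
      if (!is.null(frame)) {
        c0 <- frame + 3 * ((pos - frame) %/% 3)
        if (c0 + 3 > nchar(s)) next
        old_aa <- codon_aa(subseq0(s, c0, c0 + 3))
        new_aa <- codon_aa(subseq0(cand, c0, c0 + 3))
        if (old_aa != new_aa) next
      }
      # the lesion must kill this occurrence and create no net new site
      if (!site_at(cand, hit) &&
          site_count_all(cand, specs) < site_count_all(s, specs))
        return(list(position = pos, ref = ref, alt = alt,
                    synonymous = if (is.null(frame)) "unknown" else "yes"))
    }
  }
  NULL
}

site_count_all <- function(s, specs) {
  mol <- dna_molecule("tmp", s, "linear")
  sum(vapply(specs, function(spec) nrow(find_sites(mol, spec)), integer(1)))
}

site_at <- function(s, hit) {
  mol <- dna_molecule("tmp", s, "linear")
  sites <- find_sites(mol, hit$spec)
  any(sites$recognition_start == hit$start & sites$strand == hit$strand)
}

codon_aa <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

translate_frame <- function(s, frame) {
  coding <- subseq0(s, frame, frame + 3 * ((nchar(s) - frame) %/% 3))
  codons <- substring(coding, seq(1, nchar(coding), 3), seq(3, nchar(coding), 3))
  paste(Biostrings::GENETIC_CODE[codons], collapse = "")
}

#' Simulate a domestication plan end-to-end
#'
#' Runs each designed primer pair through [simulate_pcr()] on the original
#' insert, digests every sub-amplicon with BsaI, chains the released
#' fragments by their junction labels, and compares the reconstruction with
#' the plan's lesioned target.
#'
#' @param plan a \code{domestication_plan}.
#' @param insert the original insert the plan was designed for.
#' @return list: \code{reconstructed} (full-span sequence), \code{identical}
#'   (TRUE iff it equals the plan target), \code{site_counts} (per enzyme on
#'   the reconstruction), \code{translation_preserved} (NA without a frame).
#' @export
simulate_domestication <- function(plan, insert) {
  if (!length(plan$primers)) {
    return(list(reconstructed = plan$target, identical = TRUE,
                site_counts = is_domesticated(
                  dna_molecule("r", plan$target), c("SapI", "BsaI")),
                translation_preserved = NA))
  }
  amplicons <- lapply(seq_along(plan$primers), function(i)
    simulate_pcr(insert, plan$primers[[i]], id = sprintf("dom_f%d", i)))
  frags <- lapply(amplicons, function(a) {
    fr <- digest(a, "BsaI")
    usable <- Filter(function(f)
      f$left_end$type == "sticky" && f$right_end$type == "sticky" &&
        fragment_internal_sites(f, "BsaI") == 0, fr)
    if (length(usable) != 1)
      gk_stop("gatekit_parameter_error", sprintf(
        "sub-amplicon '%s' does not release exactly one clean fragment", a$id))
    usable[[1]]
  })
  # chain fragments left-to-right by matching labels
  chain <- frags[[1]]
  remaining <- frags[-1]
  ordered <- list(chain)
  while (length(remaining)) {
    right <- ordered[[length(ordered)]]$right_end$label
    nxt <- which(vapply(remaining, function(f) f$left_end$label == right,
                        logical(1)))
    if (length(nxt) != 1)
      gk_stop("gatekit_parameter_error", "sub-fragments do not chain uniquely")
    ordered[[length(ordered) + 1]] <- remaining[[nxt]]
    remaining <- remaining[-nxt]
  }
  tops <- vapply(ordered, `[[`, "", "sequence")
  last <- ordered[[length(ordered)]]
  recon <- paste0(paste(tops, collapse = ""),
                  if (last$right_end$type == "sticky") last$right_end$label else "")
  rmol <- dna_molecule("reconstructed", recon)
  tp <- NA
  if (!is.null(plan$frame))
    tp <- translate_frame(recon, plan$frame) ==
      translate_frame(insert$sequence, plan$frame)
  list(reconstructed = recon, identical = recon == plan$target,
       site_counts = is_domesticated(rmol, c("SapI", "BsaI")),
       translation_preserved = tp)
}

#' Check reading frame and stop codons across a fused CDS
#'
#' Inspects the fused coding region of an assembly product (all + strand CDS
#' features in order, or an explicit interval) and reports frame breaks and
#' internal stop codons, e.g. introduced at slot junctions.
#'
#' @param product an [assembly_product] or [dna_molecule].
#' @param cds_span optional \code{c(start, end)} 0-based half-open interval
#'   overriding the CDS features.
#' @return list: \code{in_frame} (length divisible by 3),
#'   \code{internal_stops} (0-based codon indices), \code{protein},
#'   \code{clean}.
#' @export
check_frame <- function(product, cds_span = NULL) {
  mol <- if (inherits(product, "assembly_product")) product$molecule else product
  if (is.null(cds_span)) {
    cds <- mol$features[mol$features$kind == "CDS" & mol$features$strand == "+",
                        , drop = FALSE]
    if (!nrow(cds))
      gk_stop("gatekit_parameter_error",
              "no + strand CDS features and no cds_span supplied")
    cds <- cds[order(cds$start), , drop = FALSE]
    seqs <- vapply(seq_len(nrow(cds)), function(i)
      substr_circ(mol$sequence, cds$start[i], cds$end[i] - cds$start[i]),
      character(1))
    coding <- paste(seqs, collapse = "")
  } else {
    coding <- substr_circ(mol$sequence, cds_span[1], cds_span[2] - cds_span[1])
  }
  in_frame <- nchar(coding) %% 3 == 0
  usable <- subseq0(coding, 0, 3 * (nchar(coding) %/% 3))
  codons <- substring(usable, seq(1, nchar(usable), 3), seq(3, nchar(usable), 3))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  stops <- which(aa == "*")
  internal <- stops[stops < length(aa)]
  list(in_frame = in_frame, internal_stops = internal - 1L,
       protein = paste(aa, collapse = ""),
       clean = in_frame && !length(internal))
}
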