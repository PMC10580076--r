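# Golden Gate product prediction.
#
# The repetitive digestion-ligation reaction is modeled at its fixed point:
# every input is digested to completion, and only fragments free of the
# assembly enzyme's recognition site can take part in a stable circular
# closure (anything still carrying a site would be re-cut). Closures are
# found over a label-matching graph: fragment A can precede fragment B iff
# A's right-end label equals B's left-end label. The destination backbone
# anchors the search in fixed orientation; every other fragment may enter in
# either orientation unless flagged directional.

#' Assemble a Golden Gate reaction in silico
#'
#' @param vector the destination vector, a circular [dna_molecule] whose
#'   stuffer carries the enzyme sites (so that its backbone fragment is
#'   released site-free), or an [assembly_product] for idempotent re-entry.
#' @param parts list of donor inputs: [dna_molecule] plasmids or PCR products
#'   (digested in place) and pre-cut [sticky_fragment] objects such as
#'   annealed oligo duplexes.
#' @param enzyme assembly enzyme ([enzyme_spec] or name).
#' @param allow_self_complementary allow 4-nt overhang labels that are their
#'   own reverse complement (these permit inverted ligation and break product
#'   uniqueness; rejected by default).
#' @param id identifier for the product molecule.
#' @return an [assembly_product]: the unique circular closure containing the
#'   vector backbone, with annotation propagated from every donor, the ordered
#'   parts list, and diagnostics (residual sites, unused inputs, duplicate
#'   labels, discarded non-backbone closures).
#' @details Errors: \code{gatekit_missing_junction} when no closure exists
#'   (names the unmatched labels); \code{gatekit_ambiguous_assembly} when more
#'   than one distinct circular product is possible or a closure skips a
#'   supplied part; a \code{gatekit_inert_input} warning when an input
#'   contributes no usable fragment.
#' @export
assemble <- function(vector, parts = list(), enzyme = "SapI",
                     allow_self_complementary = FALSE, id = NULL) {
  enzyme <- get_enzyme(enzyme)
  if (inherits(vector, "assembly_product")) vector <- vector$molecule
  if (inherits(parts, "dna_molecule") || inherits(parts, "sticky_fragment"))
    parts <- list(parts)

  # idempotence: a site-free circular vector with no parts is already the product
  vec_frags <- input_fragments(vector, enzyme)
  if (length(parts) == 0 && length(vec_frags) == 1 && vec_frags[[1]]$uncut &&
      vec_frags[[1]]$circular) {
    return(new_assembly_product(vector, parts_used = data.frame(
      part_id = vector$id, orientation = "+", stringsAsFactors = FALSE),
      diagnostics = empty_diagnostics(), enzyme = enzyme))
  }

  backbone <- pick_backbone(vec_frags, enzyme, vector_id = input_id(vector))
  pool <- list()
  inert <- character(0)
  part_ids <- character(0)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    pid <- input_id(p)
    part_ids <- c(part_ids, pid)
    frags <- input_fragments(p, enzyme)
    usable <- Filter(function(f) usable_fragment(f, enzyme), frags)
    if (!length(usable)) {
      inert <- c(inert, pid)
      gk_warn("gatekit_inert_input",
              sprintf("input '%s' contributes no ligatable, site-free fragment", pid))
      next
    }
    for (f in usable) {
      f$input_id <- pid
      pool[[length(pool) + 1]] <- f
    }
  }

  labels <- label_registry(c(list(backbone), pool))
  selfc <- labels$label[is_self_complementary(labels$label)]
  if (length(selfc) && !allow_self_complementary)
    gk_stop("gatekit_ambiguous_assembly", sprintf(
      "self-complementary overhang label(s) %s permit inverted ligation; pass allow_self_complementary = TRUE to override",
      paste(unique(selfc), collapse = ", ")))

  closures <- find_closures(backbone, pool)
  if (!length(closures)) {
    unmatched <- unmatched_labels(c(list(backbone), pool))
    gk_stop("gatekit_missing_junction", sprintf(
      "no circular closure found; unmatched junction label(s): %s",
      if (length(unmatched)) paste(unmatched, collapse = ", ") else "(none)"),
      unmatched = unmatched)
  }
  dup <- labels$label[duplicated(labels$label) & labels$side == "left"]
  if (length(closures) > 1)
    gk_stop("gatekit_ambiguous_assembly", sprintf(
      "%d distinct circular products are possible; colliding label(s): %s",
      length(closures),
      paste(unique(c(dup, duplicated_labels(labels))), collapse = ", ")))

  cyc <- closures[[1]]
  used_ids <- unique(vapply(cyc, function(f) f$input_id %||% "", character(1)))
  missing <- setdiff(setdiff(part_ids, inert), used_ids)
  if (length(missing))
    gk_stop("gatekit_ambiguous_assembly", sprintf(
      "the unique closure skips supplied part(s): %s (duplicate junction labels)",
      paste(missing, collapse = ", ")))

  product <- ligate_cycle(cyc, id = id %||% paste0(input_id(vector), "_product"))
  diag <- empty_diagnostics()
  diag$residual_sites <- nrow(find_sites(product, enzyme))
  diag$unused_inputs <- inert
  diag$duplicate_labels <- duplicated_labels(labels)
  new_assembly_product(product, parts_used = data.frame(
    part_id = vapply(cyc, function(f) f$input_id %||% f$id, character(1)),
    fragment_id = vapply(cyc, function(f) f$id, character(1)),
    orientation = vapply(cyc, function(f) f$orientation %||% "+", character(1)),
    stringsAsFactors = FALSE),
    diagnostics = diag, enzyme = enzyme)
}

input_id <- function(x) x$id
input_fragments <- function(x, enzyme) {
  if (inherits(x, "sticky_fragment")) return(list(x))
  if (inherits(x, "dna_molecule")) return(digest(x, enzyme))
  gk_stop("gatekit_config_error",
          "assembly inputs must be dna_molecule or sticky_fragment objects")
}

usable_fragment <- function(f, enzyme) {
  !f$uncut &&
    f$left_end$type == "sticky" && f$right_end$type == "sticky" &&
    fragment_internal_sites(f, enzyme) == 0
}

pick_backbone <- function(vec_frags, enzyme, vector_id) {
  cand <- Filter(function(f) usable_fragment(f, enzyme), vec_frags)
  if (length(cand) == 0)
    gk_stop("gatekit_config_error", sprintf(
      "vector '%s' releases no site-free backbone fragment (needs >= 2 %s sites in its stuffer)",
      vector_id, get_enzyme(enzyme)$name))
  if (length(cand) > 1) {
    markers <- vapply(cand, function(f)
      any(f$features$kind == "selection_marker"), logical(1))
    if (sum(markers) == 1) cand <- cand[markers]
    else gk_stop("gatekit_config_error", sprintf(
      "vector '%s' releases %d candidate backbone fragments; expected exactly one",
      vector_id, length(cand)))
  }
  bb <- cand[[1]]
  bb$input_id <- vector_id
  bb$orientation <- "+"
  bb
}

label_registry <- function(frags) {
  do.call(rbind, lapply(frags, function(f) data.frame(
    fragment = f$id,
    side = c("left", "right"),
    label = c(end_label(f$left_end), end_label(f$right_end)),
    stringsAsFactors = FALSE)))
}

duplicated_labels <- function(reg) {
  for_side <- function(side) {
    tab <- table(reg$label[reg$side == side])
    names(tab)[tab > 1]
  }
  unique(c(for_side("left"), for_side("right")))
}

unmatched_labels <- function(frags) {
  reg <- label_registry(frags)
  lefts <- reg$label[reg$side == "left"]
  rights <- reg$label[reg$side == "right"]
  unique(c(setdiff(rights, lefts), setdiff(lefts, rights)))
}

# enumerate all circular closures through `backbone` (fixed orientation).
# Each pool fragment may be used at most once, in either orientation unless
# directional. Cycles are deduplicated by canonical product sequence.
find_closures <- function(backbone, pool) {
  oriented <- list()
  for (i in seq_along(pool)) {
    f <- pool[[i]]
    f$orientation <- "+"
    f$pool_index <- i
    oriented[[length(oriented) + 1]] <- f
    if (!isTRUE(f$directional)) {
      r <- revcomp(f)
      r$orientation <- "-"
      r$input_id <- f$input_id
      r$pool_index <- i
      oriented[[length(oriented) + 1]] <- r
    }
  }
  closures <- list()
  seen <- character(0)
  target <- backbone$left_end$label
  recurse <- function(path, used, right_label) {
    if (right_label == target && length(path) >= 1) {
      key <- canonical_circular(paste(vapply(path, `[[`, "", "sequence"),
                                      collapse = ""))
      if (!key %in% seen) {
        seen <<- c(seen, key)
        closures[[length(closures) + 1]] <<- path
      }
      # fall through: longer closures through the same point are still explored
    }
    for (f in oriented) {
      if (used[f$pool_index]) next
      if (f$left_end$label != right_label) next
      used2 <- used
      used2[f$pool_index] <- TRUE
      recurse(c(path, list(f)), used2, f$right_end$label)
    }
  }
  recurse(list(backbone), logical(length(pool)), backbone$right_end$label)
  closures
}

canonical_circular <- function(s) {
  n <- nchar(s)
  if (n == 0) return(s)
  rots <- vapply(0:(n - 1), function(k) substr_circ(s, k, n), character(1))
  min(rots)
}

#' Ligate an ordered cycle of sticky fragments into a circular molecule
#'
#' Junction labels of adjacent fragments (and of the last/first pair) must be
#' equal. The product's top strand is the concatenation of the fragments' top
#' strands; each junction's overlap is counted once. Features are propagated
#' from every fragment and de-duplicated.
#'
#' @param frags list of [sticky_fragment] in assembly order.
#' @param id product identifier.
#' @return circular [dna_molecule].
#' @export
ligate_cycle <- function(frags, id = "product") {
  n <- length(frags)
  for (i in seq_len(n)) {
    a <- frags[[i]]
    b <- frags[[if (i == n) 1 else i + 1]]
    if (a$right_end$type != "sticky" || b$left_end$type != "sticky" ||
        a$right_end$label != b$left_end$label)
      gk_stop("gatekit_missing_junction", sprintf(
        "fragments '%s' and '%s' have incompatible ends", a$id, b$id))
  }
  seqs <- vapply(frags, `[[`, "", "sequence")
  product_seq <- paste(seqs, collapse = "")
  L <- nchar(product_seq)
  offsets <- cumsum(c(0, head(nchar(seqs), -1)))
  feats <- empty_features()
  for (i in seq_len(n)) {
    f <- frags[[i]]$features
    if (!nrow(f)) next
    len <- f$end - f$start
    f$start <- as.integer((f$start + offsets[i]) %% L)
    f$end <- as.integer(f$start + len)
    feats <- rbind(feats, f)
  }
  if (nrow(feats)) {
    feats <- feats[!duplicated(feats[, c("label", "kind", "start", "end", "strand")]),
                   , drop = FALSE]
    feats <- feats[order(feats$start, feats$end), , drop = FALSE]
    rownames(feats) <- NULL
  }
  dna_molecule(id, product_seq, topology = "circular", features = feats)
}

# assembly products ------------------------------------------------------------

empty_diagnostics <- function() {
  list(residual_sites = 0L, unused_inputs = character(0),
       duplicate_labels = character(0))
}

new_assembly_product <- function(molecule, parts_used, diagnostics, enzyme) {
  structure(list(molecule = molecule, parts_used = parts_used,
                 diagnostics = diagnostics, enzyme = enzyme$name),
            class = "assembly_product")
}

#' @export
print.assembly_product <- function(x, ...) {
  cat(sprintf("<assembly_product> %s: %d bp circular, %d fragment(s), enzyme %s\n",
              x$molecule$id, nchar(x$molecule$sequence), nrow(x$parts_used),
              x$enzyme))
  cat(sprintf("  parts: %s\n",
              paste(sprintf("%s(%s)", x$parts_used$part_id,
                            x$parts_used$orientation), collapse = " -> ")))
  d <- x$diagnostics
  clean <- d$residual_sites == 0 && !length(d$unused_inputs) &&
    !length(d$duplicate_labels)
  cat(sprintf("  diagnostics: %s\n", if (clean) "clean" else sprintf(
    "%d residual site(s); unused: %s; duplicate labels: %s", d$residual_sites,
    paste(d$unused_inputs, collapse = ","),
    paste(d$duplicate_labels, collapse = ","))))
  invisible(x)
}

#' Re-verify an assembly product
#'
#' Re-digests the product with the assembly enzyme (success means zero cuts:
#' the final product must not contain the enzyme cleavage site) and applies
#' the backbone marker logic: the product should carry the destination
#' marker (AmpR) and no entry-clone backbone marker (KanR).
#'
#' @param product an [assembly_product] or circular [dna_molecule].
#' @param enzyme assembly enzyme.
#' @return report list: \code{residual_sites}, \code{markers},
#'   \code{marker_ok}, \code{clean}.
#' @export
verify_product <- function(product, enzyme = "SapI") {
  mol <- if (inherits(product, "assembly_product")) product$molecule else product
  enzyme <- get_enzyme(enzyme)
  residual <- nrow(find_sites(mol, enzyme))
  markers <- mol$features$label[mol$features$kind == "selection_marker"]
  marker_ok <- !"KanR" %in% markers
  list(residual_sites = residual, markers = markers, marker_ok = marker_ok,
       clean = residual == 0 && marker_ok)
}

#' Multiplexed Golden Gate assembly
#'
#' Emulates a reaction fed with several alternative parts for one or more
#' slots: the full Cartesian set of products is returned, ordered by
#' slot-option index tuple (deterministic).
#'
#' @param vector destination vector.
#' @param slot_options named list: slot -> list of alternative parts. Every
#'   option within a slot must expose the same pair of end labels
#'   (\code{gatekit_slot_heterogeneity} error otherwise).
#' @param enzyme assembly enzyme.
#' @return list of [assembly_product], one per combination.
#' @export
multiplex_assemble <- function(vector, slot_options, enzyme = "SapI") {
  enzyme <- get_enzyme(enzyme)
  slot_names <- names(slot_options)
  for (sn in slot_names) {
    opts <- slot_options[[sn]]
    labs <- vapply(opts, function(p) {
      frags <- Filter(function(f) usable_fragment(f, enzyme),
                      input_fragments(p, enzyme))
      if (length(frags) != 1)
        gk_stop("gatekit_slot_heterogeneity", sprintf(
          "option '%s' in slot '%s' releases %d usable fragments; expected 1",
          input_id(p), sn, length(frags)))
      paste(frags[[1]]$left_end$label, frags[[1]]$right_end$label)
    }, character(1))
    if (length(unique(labs)) != 1)
      gk_stop("gatekit_slot_heterogeneity", sprintf(
        "options within slot '%s' expose differing end labels: %s", sn,
        paste(unique(labs), collapse = " | ")))
  }
  counts <- vapply(slot_options, length, integer(1))
  grid <- expand.grid(lapply(rev(counts), seq_len))  # last slot varies fastest
  grid <- grid[, rev(seq_along(counts)), drop = FALSE]
  names(grid) <- slot_names
  grid <- grid[do.call(order, as.list(grid)), , drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i) {
    picks <- lapply(slot_names, function(sn) slot_options[[sn]][[grid[i, sn]]])
    pid <- paste(vapply(picks, input_id, character(1)), collapse = "+")
    assemble(vector, picks, enzyme,
             id = sprintf("%s_%s", input_id(vector), pid))
  })
}
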