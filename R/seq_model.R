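FEATURE_KINDS <- c("promoter", "CDS", "fluorophore", "linker", "utr3",
                   "selection_marker", "recombination_site", "recognition_site",
                   "misc")

#' Empty feature table
#'
#' Features are stored as a data.frame with 0-based, half-open intervals on the
#' top strand. On circular molecules a feature may span the origin, in which
#' case it is kept "unwrapped": \code{end} exceeds the molecule length and the
#' feature occupies \code{[start, length) + [0, end - length)}.
#'
#' @return zero-row data.frame with columns label, kind, start, end, strand.
#' @export
empty_features <- function() {
  data.frame(label = character(), kind = character(),
             start = integer(), end = integer(), strand = character(),
             stringsAsFactors = FALSE)
}

#' Construct an annotated DNA molecule
#'
#' The core record type: a double-stranded DNA sequence given by its top strand
#' 5'->3', circular or linear, with typed features. All coordinates in the
#' package are 0-based and half-open; GenBank's 1-based inclusive convention is
#' converted at the I/O boundary only.
#'
#' @param id record identifier.
#' @param sequence top strand, characters A,C,G,T,N (case-insensitive input).
#' @param topology \code{"circular"} or \code{"linear"}.
#' @param features feature data.frame as returned by [empty_features()] /
#'   [add_feature()].
#' @param source_kind one of \code{"plasmid"}, \code{"pcr_product"},
#'   \code{"oligo_duplex"}.
#' @return an object of class \code{dna_molecule}.
#' @examples
#' m <- dna_molecule("demo", "ACGTACGT", "circular")
#' nchar(m$sequence)
#' @export
dna_molecule <- function(id, sequence, topology = c("linear", "circular"),
                         features = empty_features(),
                         source_kind = c("plasmid", "pcr_product", "oligo_duplex")) {
  topology <- match.arg(topology)
  source_kind <- match.arg(source_kind)
  sequence <- normalize_seq(sequence, sprintf("sequence of '%s'", id))
  mol <- structure(
    list(id = as.character(id), sequence = sequence, topology = topology,
         features = features, source_kind = source_kind),
    class = "dna_molecule")
  validate_molecule(mol)
  mol
}

validate_molecule <- function(mol) {
  L <- nchar(mol$sequence)
  f <- mol$features
  if (nrow(f)) {
    stopifnot(all(c("label", "kind", "start", "end", "strand") %in% names(f)))
    bad_kind <- setdiff(unique(f$kind), FEATURE_KINDS)
    if (length(bad_kind))
      gk_stop("gatekit_format_error",
              sprintf("unknown feature kind(s): %s", paste(bad_kind, collapse = ", ")))
    if (any(f$start < 0 | f$start >= L | f$end <= f$start))
      gk_stop("gatekit_format_error",
              sprintf("feature interval out of range on '%s'", mol$id))
    if (mol$topology == "linear" && any(f$end > L))
      gk_stop("gatekit_format_error",
              sprintf("feature beyond the end of linear molecule '%s'", mol$id))
    if (mol$topology == "circular" && any(f$end - f$start > L))
      gk_stop("gatekit_format_error",
              sprintf("feature longer than circular molecule '%s'", mol$id))
    if (any(f$kind == "CDS" & !(f$strand %in% c("+", "-"))))
      gk_stop("gatekit_format_error", "CDS features must carry a strand")
  }
  invisible(mol)
}

#' Add a feature to a molecule
#'
#' @param mol a [dna_molecule].
#' @param label free-text feature label.
#' @param kind one of the controlled vocabulary (see \code{gatekit:::FEATURE_KINDS}).
#' @param start,end 0-based half-open interval on the top strand; on circular
#'   molecules \code{end} may exceed the length for origin-spanning features.
#' @param strand \code{"+"} or \code{"-"}.
#' @return the molecule with the feature appended.
#' @export
add_feature <- function(mol, label, kind, start, end, strand = "+") {
  f <- data.frame(label = label, kind = kind, start = as.integer(start),
                  end = as.integer(end), strand = strand, stringsAsFactors = FALSE)
  mol$features <- rbind(mol$features, f)
  validate_molecule(mol)
  mol
}

#' @export
print.dna_molecule <- function(x, ...) {
  cat(sprintf("<dna_molecule> %s: %d bp, %s, %d feature(s) [%s]\n",
              x$id, nchar(x$sequence), x$topology, nrow(x$features),
              x$source_kind))
  if (nrow(x$features)) {
    for (i in seq_len(nrow(x$features)))
      cat(sprintf("  %-18s %-16s %6d..%-6d %s\n", x$features$label[i],
                  x$features$kind[i], x$features$start[i], x$features$end[i],
                  x$features$strand[i]))
  }
  invisible(x)
}

#' Reverse complement
#'
#' Generic over character strings, [dna_molecule] and [sticky_fragment]
#' objects. Feature intervals and strands are remapped; \code{revcomp(revcomp(m))}
#' is the identity.
#'
#' @param x object to reverse-complement.
#' @return object of the same class.
#' @export
revcomp <- function(x) UseMethod("revcomp")

#' @export
revcomp.character <- function(x) revcomp_str(x)

#' @export
revcomp.dna_molecule <- function(x) {
  L <- nchar(x$sequence)
  x$sequence <- revcomp_str(x$sequence)
  f <- x$features
  if (nrow(f)) {
    len <- f$end - f$start
    new_start <- (L - f$end) %% L
    f$start <- as.integer(new_start)
    f$end <- as.integer(new_start + len)
    f$strand <- ifelse(f$strand == "+", "-", "+")
    x$features <- f[order(f$start, f$end), , drop = FALSE]
    rownames(x$features) <- NULL
  }
  x
}

#' Rotate a circular molecule to a new origin
#'
#' @param mol a circular [dna_molecule].
#' @param new_origin 0-based index that becomes position 0.
#' @return rotated molecule; length and feature content are preserved. All
#'   site/fragment computations downstream are rotation-invariant.
#' @export
rotate <- function(mol, new_origin) {
  if (!inherits(mol, "dna_molecule"))
    gk_stop("gatekit_topology_error", "rotate() expects a dna_molecule")
  if (mol$topology != "circular")
    gk_stop("gatekit_topology_error",
            sprintf("cannot rotate linear molecule '%s'", mol$id))
  L <- nchar(mol$sequence)
  k <- ((new_origin %% L) + L) %% L
  if (k == 0) return(mol)
  mol$sequence <- paste0(subseq0(mol$sequence, k, L), subseq0(mol$sequence, 0, k))
  f <- mol$features
  if (nrow(f)) {
    len <- f$end - f$start
    f$start <- as.integer((f$start - k) %% L)
    f$end <- as.integer(f$start + len)
    mol$features <- f[order(f$start, f$end), , drop = FALSE]
    rownames(mol$features) <- NULL
  }
  mol
}
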