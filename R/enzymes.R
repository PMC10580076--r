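# Type IIS enzyme specifications.
#
# A spec names the recognition sequence (non-palindromic for type IIS cutters)
# and the cut offsets downstream of the recognition 3' end on each strand; the
# difference of the offsets is the length of the 5' overhang left by the cut.
# SapI (and its isoschizomer LguI) cut GCTCTTC(1/4) leaving 3-nt overhangs;
# BsaI cuts GGTCTC(1/5) leaving 4-nt overhangs. DpnI ships as a check-only
# entry: it may be used for site counting but not for digestion simulation.

#' Construct a type IIS enzyme specification
#'
#' @param name enzyme name.
#' @param recognition recognition sequence (top strand, no N).
#' @param cut_offset_top,cut_offset_bottom cut positions in nt downstream of
#'   the recognition 3' end on the recognition-bearing / opposite strand.
#' @param check_only if TRUE the enzyme is only available for site counting.
#' @return an object of class \code{enzyme_spec} with an \code{overhang_len}
#'   field (\code{cut_offset_bottom - cut_offset_top}; positive = 5' overhang).
#' @export
enzyme_spec <- function(name, recognition, cut_offset_top, cut_offset_bottom,
                        check_only = FALSE) {
  recognition <- normalize_seq(recognition, sprintf("recognition of %s", name))
  if (grepl("N", recognition))
    gk_stop("gatekit_config_error",
            sprintf("recognition of %s contains N; overhang identity must be unambiguous", name))
  overhang_len <- cut_offset_bottom - cut_offset_top
  if (!check_only) {
    if (recognition == revcomp_str(recognition))
      gk_stop("gatekit_config_error", sprintf(
        "%s: assembly enzymes must have a non-palindromic recognition sequence", name))
    if (overhang_len < 2 || overhang_len > 4)
      gk_stop("gatekit_config_error", sprintf(
        "%s: overhang length %d outside the supported 2-4 nt range", name,
        overhang_len))
  }
  structure(list(name = name, recognition = recognition,
                 cut_offset_top = as.integer(cut_offset_top),
                 cut_offset_bottom = as.integer(cut_offset_bottom),
                 overhang_len = as.integer(overhang_len),
                 check_only = isTRUE(check_only)),
            class = "enzyme_spec")
}

#' @export
print.enzyme_spec <- function(x, ...) {
  cat(sprintf("<enzyme_spec> %s %s(%d/%d), %d-nt 5' overhang%s\n", x$name,
              x$recognition, x$cut_offset_top, x$cut_offset_bottom,
              x$overhang_len, if (x$check_only) " [check-only]" else ""))
  invisible(x)
}

#' Load the enzyme table
#'
#' @param path a plain-text tab-delimited table (name, recognition,
#'   cut_offset_top, cut_offset_bottom, check_only); by default the table
#'   shipped with the package.
#' @return named list of [enzyme_spec] objects.
#' @export
load_enzymes <- function(path = NULL) {
  path <- path %||% system.file("extdata", "enzymes.tsv", package = "gatekit")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  specs <- lapply(seq_len(nrow(tab)), function(i)
    enzyme_spec(tab$name[i], tab$recognition[i], tab$cut_offset_top[i],
                tab$cut_offset_bottom[i], isTRUE(tab$check_only[i])))
  names(specs) <- tab$name
  specs
}

.gk_env <- new.env(parent = emptyenv())

#' Resolve an enzyme by name or pass a spec through
#'
#' @param enzyme an [enzyme_spec] or the name of a shipped enzyme
#'   (SapI, LguI, BsaI, DpnI).
#' @return an [enzyme_spec].
#' @export
get_enzyme <- function(enzyme) {
  if (inherits(enzyme, "enzyme_spec")) return(enzyme)
  if (is.null(.gk_env$enzymes)) .gk_env$enzymes <- load_enzymes()
  spec <- .gk_env$enzymes[[enzyme]]
  if (is.null(spec))
    gk_stop("gatekit_config_error", sprintf(
      "unknown enzyme '%s' (known: %s)", enzyme,
      paste(names(.gk_env$enzymes), collapse = ", ")))
  spec
}
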