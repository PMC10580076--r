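`%||%` <- function(x, y) if (is.null(x)) y else x

#' Reverse complement of a nucleotide string
#'
#' Operates on plain character vectors over the \code{A,C,G,T,N} alphabet.
#' An S3 method for [dna_molecule] objects is provided by [revcomp()].
#'
#' @param s character vector of nucleotide strings.
#' @return character vector of the same length.
#' @examples
#' revcomp_str("ACGT")   # palindrome: "ACGT"
#' revcomp_str("GCTCTTC")
#' @export
revcomp_str <- function(s) {
  vapply(s, function(x) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# 0-based, half-open substring: subseq0(s, a, b) == s[a, b)
subseq0 <- function(s, start, end) {
  if (end <= start) return("")
  substr(s, start + 1, end)
}

# circular substring: start taken modulo length, may wrap any number of times
substr_circ <- function(s, start, len) {
  L <- nchar(s)
  if (len == 0) return("")
  start <- ((start %% L) + L) %% L
  if (start + len <= L) return(substr(s, start + 1, start + len))
  paste0(substr(s, start + 1, L), substr_circ(s, 0, len - (L - start)))
}

# all 0-based start positions of fixed pattern `pat` in `s`, overlapping allowed
str_find_all <- function(s, pat) {
  if (nchar(pat) == 0 || nchar(pat) > nchar(s)) return(integer(0))
  m <- gregexpr(paste0("(?=", pat, ")"), s, perl = TRUE)[[1]]
  if (m[1] == -1) return(integer(0))
  as.integer(m) - 1L
}

is_self_complementary <- function(label) {
  nchar(label) %% 2 == 0 & label == revcomp_str(label)
}

normalize_seq <- function(s, what = "sequence") {
  s <- toupper(s)
  if (!nzchar(s)) gk_stop("gatekit_format_error", sprintf("%s is empty", what))
  if (grepl("[^ACGTN]", s)) {
    bad <- regmatches(s, regexpr("[^ACGTN]", s))
    gk_stop("gatekit_format_error", sprintf(
      "%s contains disallowed character '%s' (alphabet is A,C,G,T,N)", what, bad))
  }
  s
}

# condition helpers -----------------------------------------------------------

gk_stop <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "gatekit_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...))
  stop(cond)
}

gk_warn <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "gatekit_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1), ...))
  warning(cond)
}

# run `code` under `seed` without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# atomic file write: emit through a sibling temp file, then rename
write_atomic <- function(lines, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    gk_stop("gatekit_io_error", sprintf("cannot write to '%s'", path))
  }
  invisible(path)
}
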