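# Independent oracles, deliberately naive: quadratic scans, plain string
# slicing, and recursive enumeration. They share nothing with the package
# implementation beyond the published cut-arithmetic convention.

oracle_revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

# all 0-based match positions of `pat` by direct substring comparison
oracle_matches <- function(s, pat) {
  L <- nchar(s)
  k <- nchar(pat)
  if (k > L) return(integer(0))
  starts <- 0:(L - k)
  hits <- substring(s, starts + 1, starts + k) == pat
  starts[hits]
}

# fragments as full-span strings with explicit end overhang lengths:
# list(span=, kl=, kr=) ; kl/kr = 0 encodes a blunt end. The left label is the
# first kl characters of span, the right label the last kr.
oracle_digest <- function(seq, circular, rec, off_top, off_bottom) {
  L <- nchar(seq)
  oh <- off_bottom - off_top
  k <- nchar(rec)
  scan <- if (circular) paste0(seq, substr(seq, 1, k - 1)) else seq
  plus <- oracle_matches(scan, rec)
  minus <- oracle_matches(scan, oracle_revcomp(rec))
  plus <- plus[plus < L]
  minus <- minus[minus < L]
  ct <- c(plus + k + off_top, minus - off_bottom)
  if (circular) {
    ct <- sort(unique(ct %% L))
  } else {
    ct <- sort(unique(ct[ct >= 0 & ct + oh <= L]))
  }
  dbl <- paste0(seq, seq)
  if (!length(ct)) {
    return(list(list(span = seq, kl = 0L, kr = 0L)))
  }
  out <- list()
  if (circular) {
    n <- length(ct)
    for (i in seq_len(n)) {
      a <- ct[i]
      b <- if (i == n) ct[1] + L else ct[i + 1]
      out[[i]] <- list(span = substr(dbl, a + 1, b + oh), kl = oh, kr = oh)
    }
  } else {
    bounds <- c(0L, ct, L)
    for (i in seq_len(length(bounds) - 1)) {
      a <- bounds[i]
      b <- bounds[i + 1]
      kr <- if (i == length(bounds) - 1) 0L else oh
      out[[i]] <- list(span = substr(seq, a + 1, b + kr),
                       kl = if (i == 1) 0L else oh, kr = kr)
    }
  }
  out
}

oracle_frag_key <- function(f) sprintf("%s|%d|%d", f$span, f$kl, f$kr)

frag_multiset <- function(frags) sort(vapply(frags, oracle_frag_key, ""))

# package fragment -> oracle representation
pkg_frag_to_oracle <- function(f) {
  list(span = gatekit:::fragment_full_span(f),
       kl = if (f$left_end$type == "sticky") nchar(f$left_end$label) else 0L,
       kr = if (f$right_end$type == "sticky") nchar(f$right_end$label) else 0L)
}

pkg_frag_multiset <- function(frags) {
  frag_multiset(lapply(frags, pkg_frag_to_oracle))
}

oracle_frag_rc <- function(f) {
  list(span = oracle_revcomp(f$span), kl = f$kr, kr = f$kl)
}

oracle_left_label <- function(f) substr(f$span, 1, f$kl)
oracle_right_label <- function(f) substr(f$span, nchar(f$span) - f$kr + 1, nchar(f$span))

oracle_canonical_circular <- function(s) {
  n <- nchar(s)
  dbl <- paste0(s, s)
  min(substring(dbl, 1:n, n:(2 * n - 1)))
}

# Exhaustive enumeration of circular closures through `backbone` (fixed
# orientation): tries every remaining fragment in both orientations at every
# step and records a closure whenever the chain's right label returns to the
# backbone's left label. Exhaustive over all orderings/orientations that can
# ligate; distinct products keyed by canonical rotation of the sequence.
oracle_closures <- function(backbone, pool) {
  found <- character(0)
  target <- oracle_left_label(backbone)
  recurse <- function(chain_spans, used, right_lab) {
    if (right_lab == target) {
      oh <- nchar(target)
      prod <- paste(vapply(chain_spans, function(sp)
        substr(sp, 1, nchar(sp) - oh), ""), collapse = "")
      key <- oracle_canonical_circular(prod)
      if (!key %in% found) found <<- c(found, key)
    }
    for (i in seq_along(pool)) {
      if (used[i]) next
      for (f in list(pool[[i]], oracle_frag_rc(pool[[i]]))) {
        if (f$kl == 0 || f$kr == 0) next
        if (oracle_left_label(f) != right_lab) next
        used2 <- used
        used2[i] <- TRUE
        recurse(c(chain_spans, f$span), used2, oracle_right_label(f))
      }
    }
  }
  recurse(list(backbone$span), logical(length(pool)), oracle_right_label(backbone))
  sort(found)
}

# random molecule for property tests
random_molecule <- function(len, circular, seed) {
  withr::with_seed(seed, {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    dna_molecule(sprintf("rnd%d", seed), s,
                 if (circular) "circular" else "linear")
  })
}
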