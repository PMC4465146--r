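#' Nucleotide sequence with explicit topology
#'
#' Light container for a DNA sequence used throughout the package. Sequences
#' are stored as uppercase character strings over `{A,C,G,T,N}` together with
#' a topology flag, so that circular molecules (plasmid reporters) and linear
#' molecules (genomic loci, amplicons) flow through the same operations.
#'
#' All coordinates in this package are 0-based, half-open intervals; cut
#' positions are *gap* coordinates (gap `k` is the boundary immediately
#' before base index `k`). 1-based positions appear only in reports.
#'
#' @param seq Character scalar over `A,C,G,T,N` (case-insensitive).
#' @param topology `"linear"` or `"circular"`.
#' @param name Optional label.
#' @return An object of class `nuc_seq`.
#' @examples
#' x <- nuc_seq("gattaca", name = "toy")
#' reverse_complement(x)
#' @export
nuc_seq <- function(seq, topology = c("linear", "circular"), name = "") {
  topology <- match.arg(topology)
  if (length(seq) != 1L || is.na(seq)) stop("`seq` must be a single string")
  seq <- toupper(as.character(seq))
  bad <- regexpr("[^ACGTN]", seq)[1]
  if (bad > 0) {
    stop(sprintf("invalid symbol '%s' at position %d", substr(seq, bad, bad), bad))
  }
  structure(list(seq = seq, topology = topology, name = as.character(name)),
            class = "nuc_seq")
}

#' @export
as.character.nuc_seq <- function(x, ...) x$seq

#' Coerce to nuc_seq
#' @param x A `nuc_seq`, character scalar, or `Biostrings::DNAString`.
#' @param ... Passed to [nuc_seq()] for character input.
#' @return A `nuc_seq`.
#' @export
as_nuc_seq <- function(x, ...) {
  if (inherits(x, "nuc_seq")) return(x)
  nuc_seq(as.character(x), ...)
}

#' Sequence length in nucleotides
#' @param x A `nuc_seq` or character scalar.
#' @return Integer length.
#' @export
nuc_length <- function(x) nchar(as.character(as_nuc_seq(x)))

#' @export
print.nuc_seq <- function(x, ...) {
  s <- x$seq
  shown <- if (nchar(s) > 60) paste0(substr(s, 1, 57), "...") else s
  cat(sprintf("<nuc_seq %s: %d nt, %s> %s\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              nchar(s), x$topology, shown))
  invisible(x)
}

# reverse of a plain string
str_rev <- function(s) {
  vapply(s, function(z) intToUtf8(rev(utf8ToInt(z))), "", USE.NAMES = FALSE)
}

#' Reverse complement
#'
#' Watson-Crick complement, reversed; topology and name are preserved.
#' Invalid symbols are rejected with the offending symbol and position.
#'
#' @param x A `nuc_seq` or character scalar.
#' @return A `nuc_seq` (same topology); for character input the result is
#'   still a `nuc_seq` -- use `as.character()` if a string is needed.
#' @examples
#' as.character(reverse_complement("GATTACA"))  # "TGTAATC"
#' @export
reverse_complement <- function(x) {
  x <- as_nuc_seq(x)
  out <- str_rev(chartr("ACGTN", "TGCAN", x$seq))
  nuc_seq(out, topology = x$topology, name = x$name)
}

# revcomp on a bare string (internal fast path, assumes validated input)
rc_str <- function(s) str_rev(chartr("ACGTN", "TGCAN", s))

#' Extract a subsequence by 0-based half-open coordinates
#'
#' For circular sequences the window may wrap past the origin (`b` may exceed
#' the length, or `a` may be negative); for linear sequences out-of-range
#' windows are rejected.
#'
#' @param x A `nuc_seq`.
#' @param a,b 0-based half-open bounds, `a <= b`.
#' @return Character scalar (always linear sequence content).
#' @export
nuc_sub <- function(x, a, b) {
  x <- as_nuc_seq(x)
  L <- nchar(x$seq)
  if (b < a) stop("`b` must be >= `a`")
  w <- b - a
  if (x$topology == "circular") {
    if (w > L) stop("window longer than the circular sequence")
    a <- ((a %% L) + L) %% L
    s2 <- paste0(x$seq, x$seq)
    return(substr(s2, a + 1, a + w))
  }
  if (a < 0 || b > L) {
    stop(sprintf("window [%d,%d) outside linear sequence of length %d", a, b, L))
  }
  substr(x$seq, a + 1, b)
}
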