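# Independent oracles and shared toy data for the test suite.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

rc <- function(s) as.character(reverse_complement(s))

# Brute-force guide-site scan: slide a 23-nt window over every position of
# the + strand and of revcomp(ref), test protospacer equality and the PAM
# pattern directly, and map - strand hits back to + coordinates.
brute_guide_scan <- function(refstr, proto, classes) {
  L <- nchar(refstr)
  pam_ok <- function(p) {
    b2 <- substr(p, 2, 2); b3 <- substr(p, 3, 3)
    b3 == "G" && ((b2 == "G" && "NGG" %in% classes) ||
                  (b2 == "A" && "NAG" %in% classes))
  }
  hits <- list()
  for (s in 0:(L - 23)) {
    if (substr(refstr, s + 1, s + 20) == proto &&
        pam_ok(substr(refstr, s + 21, s + 23))) {
      hits[[length(hits) + 1L]] <- c("+", s)
    }
  }
  rstr <- rc(refstr)
  for (s in 0:(L - 23)) {
    if (substr(rstr, s + 1, s + 20) == proto &&
        pam_ok(substr(rstr, s + 21, s + 23))) {
      # + strand protospacer interval of this - strand hit
      hits[[length(hits) + 1L]] <- c("-", L - s - 20)
    }
  }
  if (!length(hits)) {
    return(data.frame(strand = character(), proto_start = integer()))
  }
  out <- data.frame(strand = vapply(hits, `[[`, "", 1),
                    proto_start = as.integer(vapply(hits, `[[`, "", 2)),
                    stringsAsFactors = FALSE)
  out[order(out$proto_start, out$strand), , drop = FALSE]
}

# Affine-gap glocal alignment score by dynamic programming (Gotoh): pattern
# global, subject local (both subject flanks free), gap of length L costs
# open + ext * L. Independent of the package's alignment path.
glocal_score <- function(pat, sub, match = 1, mismatch = -2,
                         open = 5, ext = 2) {
  p <- strsplit(pat, "")[[1]]; s <- strsplit(sub, "")[[1]]
  m <- length(p); n <- length(s)
  NEG <- -1e9
  H <- matrix(NEG, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)  # gap in pattern (deletion)
  F <- matrix(NEG, m + 1, n + 1)  # gap in subject (insertion)
  H[1, ] <- 0
  for (i in 2:(m + 1)) {
    F[i, 1] <- max(H[i - 1, 1] - (open + ext), F[i - 1, 1] - ext)
    H[i, 1] <- F[i, 1]
  }
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      sub_sc <- if (p[i - 1] == s[j - 1]) match else mismatch
      E[i, j] <- max(H[i, j - 1] - (open + ext), E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - (open + ext), F[i - 1, j] - ext)
      H[i, j] <- max(H[i - 1, j - 1] + sub_sc, E[i, j], F[i, j])
    }
  }
  max(H[m + 1, ])
}

# Brute-force in-silico PCR: enumerate all (forward-hit, reverse-hit) pairs
# on both orientations by direct substring scans.
brute_pcr <- function(tpl, fwd, rev, max_size) {
  find_all <- function(pat, s) {
    out <- integer(0); from <- 1
    repeat {
      i <- regexpr(pat, substr(s, from, nchar(s)), fixed = TRUE)[1]
      if (i < 0) break
      out <- c(out, from + i - 2L)  # 0-based
      from <- from + i
    }
    out
  }
  sizes <- integer(0)
  for (ori in 1:2) {
    a <- if (ori == 1) fwd else rev
    b <- if (ori == 1) rev else fwd
    fa <- find_all(a, tpl); rb <- find_all(rc(b), tpl)
    for (f in fa) for (r in rb) {
      size <- r + nchar(b) - f
      if (size >= nchar(a) + nchar(b) && size <= max_size) {
        sizes <- c(sizes, size)
      }
    }
  }
  sort(unique(sizes))
}

# Single shared two-cut locus fixture (construction is deterministic); cached
# so every test file does not rebuild it.
local_fixture_cache <- new.env(parent = emptyenv())
cached_locus_fixture <- function(scale = 3000L, seed = 7L) {
  key <- paste0("locus_", scale, "_", seed)
  if (is.null(local_fixture_cache[[key]])) {
    local_fixture_cache[[key]] <- make_fixture("two_cut_locus", scale, seed)
  }
  local_fixture_cache[[key]]
}

# A small two-site toy reference with known protospacers: site A on the +
# strand (PAM facing the segment), site B on the - strand (PAM facing the
# segment); cut gaps at 97 and 220.
toy_two_site_ref <- function() {
  protoA <- "ACGTACGTACGTACGGGGCA"
  protoB <- "TTGACCAGTACCAGTTGACC"
  set.seed(123)
  ref <- nuc_seq(paste0(rand_dna(80), protoA, "TGG", rand_dna(94), "CCA",
                        rc(protoB), rand_dna(80)))
  sa <- find_guide_sites(ref, guide_spec("a", protoA), "NGG")
  sb <- find_guide_sites(ref, guide_spec("b", protoB), "NGG")
  list(ref = ref, protoA = protoA, protoB = protoB,
       site_a = sa[1, ], site_b = sb[1, ])
}
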