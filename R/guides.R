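#' sgRNA guide specification
#'
#' A guide is identified by its 20-nt protospacer (the genomic sequence
#' matched by the sgRNA spacer, written 5'->3' on the protospacer/PAM-bearing
#' strand). The PAM is not part of the spec; PAM classes are chosen at scan
#' time.
#'
#' @param name Guide label.
#' @param protospacer 20-nt sequence over `A,C,G,T` (no `N`).
#' @return Object of class `guide_spec`.
#' @export
guide_spec <- function(name, protospacer) {
  protospacer <- toupper(as.character(protospacer))
  if (nchar(protospacer) != 20L) {
    stop(sprintf("protospacer of guide '%s' must be exactly 20 nt (got %d)",
                 name, nchar(protospacer)))
  }
  if (grepl("[^ACGT]", protospacer)) {
    stop(sprintf("protospacer of guide '%s' may only contain A,C,G,T", name))
  }
  structure(list(name = as.character(name), protospacer = protospacer),
            class = "guide_spec")
}

#' @export
print.guide_spec <- function(x, ...) {
  cat(sprintf("<guide_spec %s: %s>\n", x$name, x$protospacer))
  invisible(x)
}

# PAM test on the site's own strand: pam is a 3-nt string read 5'->3' on the
# strand carrying the protospacer. "N" in the class pattern matches any base.
pam_class_of <- function(pam, classes) {
  b2 <- substr(pam, 2, 2); b3 <- substr(pam, 3, 3)
  if (b3 != "G") return(NA_character_)
  cls <- if (b2 == "G") "NGG" else if (b2 == "A") "NAG" else NA_character_
  if (!is.na(cls) && cls %in% classes) cls else NA_character_
}

# all (possibly overlapping) 0-based start positions of `pat` in string `s`
match_starts <- function(pat, s) {
  if (nchar(s) < nchar(pat)) return(integer(0))
  m <- Biostrings::matchPattern(pat, Biostrings::DNAString(s))
  Biostrings::start(m) - 1L
}

#' Locate sgRNA target sites on both strands
#'
#' Scans a reference for exact protospacer matches immediately followed (on
#' the matching strand) by a PAM of one of the requested classes. Both
#' orientations are reported in + strand coordinates (0-based, half-open).
#' Circular references are scanned across the origin by doubling and
#' deduplicating hits modulo the length; coordinates of wrapping sites are
#' reported with `proto_start` in `[0, L)` and `proto_end` possibly `> L`.
#'
#' @param ref Reference sequence (`nuc_seq` or string).
#' @param guide A [guide_spec()].
#' @param pam_classes Non-empty subset of `c("NGG","NAG")`.
#' @return A `data.frame` with one row per site: `guide`, `strand` (`"+"` or
#'   `"-"`), `proto_start`, `proto_end`, `pam_start`, `pam_end`, `pam_class`,
#'   `pam_seq` (read on the site's strand), `protospacer`.
#' @export
find_guide_sites <- function(ref, guide, pam_classes = c("NGG", "NAG")) {
  ref <- as_nuc_seq(ref)
  if (length(pam_classes) == 0) stop("`pam_classes` must be non-empty")
  if (!all(pam_classes %in% c("NGG", "NAG"))) {
    stop("`pam_classes` must be a subset of c('NGG','NAG')")
  }
  stopifnot(inherits(guide, "guide_spec"))
  L <- nuc_length(ref)
  circular <- ref$topology == "circular"
  if (!circular && L < 23) stop("linear reference shorter than 23 nt")
  S <- if (circular) paste0(ref$seq, substr(ref$seq, 1, min(22L, L))) else ref$seq
  proto <- guide$protospacer
  rows <- list()

  # + strand: protospacer at [s, s+20), PAM at [s+20, s+23)
  for (s in match_starts(proto, S)) {
    if (s + 23 > nchar(S)) next
    pam <- substr(S, s + 21, s + 23)
    cls <- pam_class_of(pam, pam_classes)
    if (is.na(cls)) next
    if (circular && s >= L) next   # duplicate from doubling
    rows[[length(rows) + 1L]] <- data.frame(
      guide = guide$name, strand = "+",
      proto_start = s, proto_end = s + 20L,
      pam_start = s + 20L, pam_end = s + 23L,
      pam_class = cls, pam_seq = pam, protospacer = proto,
      stringsAsFactors = FALSE)
  }

  # - strand: revcomp(protospacer) at [s, s+20) on +, PAM at [s-3, s) on +
  # (read 5'->3' on the - strand, the PAM is the revcomp of those bases)
  rcp <- rc_str(proto)
  for (s in match_starts(rcp, S)) {
    if (s - 3 < 0) next                      # circular: same site seen at s+L
    pam <- rc_str(substr(S, s - 2, s))
    cls <- pam_class_of(pam, pam_classes)
    if (is.na(cls)) next
    s_norm <- if (circular) s %% L else s
    if (circular && s >= L && (s - 3) >= L) next  # fully in the doubled tail
    rows[[length(rows) + 1L]] <- data.frame(
      guide = guide$name, strand = "-",
      proto_start = s_norm, proto_end = s_norm + 20L,
      pam_start = s_norm - 3L, pam_end = s_norm,
      pam_class = cls, pam_seq = pam, protospacer = proto,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    guide = character(), strand = character(), proto_start = integer(),
    proto_end = integer(), pam_start = integer(), pam_end = integer(),
    pam_class = character(), pam_seq = character(), protospacer = character(),
    stringsAsFactors = FALSE)
  # deduplicate (circular doubling) and order by coordinate then strand
  key <- paste(out$strand, out$proto_start %% max(L, 1L))
  out <- out[!duplicated(key), , drop = FALSE]
  out <- out[order(out$proto_start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cas9 cleavage-offset model
#'
#' Cas9 cleaves the sgRNA-complementary (target) strand a fixed 3 nt upstream
#' of the PAM; the protospacer-bearing (non-complementary) strand may be cut
#' 3-8 nt upstream, so cuts are blunt (equal offsets) or leave a short 5'
#' overhang. 3' overhang geometries (protospacer offset smaller than the
#' target offset) are rejected.
#'
#' @param target_strand_offset Cut offset (nt upstream of PAM) on the
#'   target strand; default 3.
#' @param protospacer_strand_offset Cut offset on the protospacer strand,
#'   in `[3, 8]`; default 3 (blunt).
#' @return Object of class `cut_model`.
#' @export
cut_model <- function(target_strand_offset = 3L, protospacer_strand_offset = 3L) {
  t <- as.integer(target_strand_offset); p <- as.integer(protospacer_strand_offset)
  if (p < 3L || p > 8L) stop("protospacer_strand_offset must be in [3, 8]")
  if (p < t) stop("3' overhangs are not modeled (protospacer offset < target offset)")
  structure(list(target_strand_offset = t, protospacer_strand_offset = p,
                 overhang_length = p - t),
            class = "cut_model")
}

#' @export
print.cut_model <- function(x, ...) {
  cat(sprintf("<cut_model target %d nt / protospacer %d nt upstream of PAM (%s)>\n",
              x$target_strand_offset, x$protospacer_strand_offset,
              if (x$overhang_length == 0) "blunt"
              else sprintf("%d-nt 5' overhang", x$overhang_length)))
  invisible(x)
}

# one-row site accessor tolerant of data.frame rows and lists
site_row <- function(site) {
  if (is.data.frame(site)) {
    if (nrow(site) != 1L) stop("`site` must be a single guide site (one row)")
    return(as.list(site))
  }
  site
}

#' Physical cut coordinates for a guide site under a cut model
#'
#' Maps a [cut_model()] onto a located site. Coordinates are gap positions on
#' the + strand. `top_cut` is the cut on the + (top) strand, `bottom_cut` on
#' the - strand; under the 5'-overhang-only model `top_cut <= bottom_cut`
#' always holds, and the overhang (read on the PAM-bearing strand) is the
#' sequence between the two gaps.
#'
#' @param site One row of [find_guide_sites()] output.
#' @param model A [cut_model()].
#' @param ref The reference the site was found on.
#' @return Object of class `cut_site` with fields `top_cut`, `bottom_cut`,
#'   `overhang`, `blunt`, `site`, `model`.
#' @export
cut_site <- function(site, model = cut_model(), ref) {
  site <- site_row(site)
  stopifnot(inherits(model, "cut_model"))
  ref <- as_nuc_seq(ref)
  L <- nuc_length(ref)
  t <- model$target_strand_offset; p <- model$protospacer_strand_offset
  if (site$strand == "+") {
    e <- site$proto_end
    top <- e - p; bottom <- e - t
  } else {
    s <- site$proto_start
    top <- s + t; bottom <- s + p
  }
  if (ref$topology == "linear" && (top < 0 || bottom > L)) {
    stop(sprintf("cut gap outside [0, %d] on a linear reference", L))
  }
  ov_plus <- nuc_sub(ref, top, bottom)
  overhang <- if (site$strand == "+") ov_plus else rc_str(ov_plus)
  structure(list(top_cut = top, bottom_cut = bottom, overhang = overhang,
                 blunt = (top == bottom), site = site, model = model),
            class = "cut_site")
}

#' @export
print.cut_site <- function(x, ...) {
  cat(sprintf("<cut_site %s strand: top gap %d, bottom gap %d%s>\n",
              x$site$strand, x$top_cut, x$bottom_cut,
              if (x$blunt) " (blunt)" else sprintf(", 5' overhang '%s'", x$overhang)))
  invisible(x)
}

# the canonical blunt (3,3) fusion gap of a site, used as alignment reference
canonical_gap <- function(site) {
  site <- site_row(site)
  if (site$strand == "+") site$proto_end - 3L else site$proto_start + 3L
}

#' Exhaustive mismatch scan for off-target sites
#'
#' Enumerates every 20-nt window on either strand with at most
#' `max_mismatches` mismatches to the protospacer and a qualifying PAM. With
#' `max_mismatches = 0` this reduces exactly to [find_guide_sites()]. An `N`
#' in the reference counts as a mismatch.
#'
#' @inheritParams find_guide_sites
#' @param max_mismatches Integer in `[0, 20]`.
#' @return [find_guide_sites()]-shaped `data.frame` with extra column
#'   `mismatches`, sorted by mismatch count then coordinate. The
#'   `protospacer` column holds the matched reference window on the site's
#'   strand.
#' @export
enumerate_offtarget_sites <- function(guide, ref, max_mismatches,
                                      pam_classes = c("NGG", "NAG")) {
  ref <- as_nuc_seq(ref)
  if (length(pam_classes) == 0) stop("`pam_classes` must be non-empty")
  max_mismatches <- as.integer(max_mismatches)
  if (max_mismatches < 0 || max_mismatches > 20) {
    stop("`max_mismatches` must be in [0, 20]")
  }
  stopifnot(inherits(guide, "guide_spec"))
  L <- nuc_length(ref)
  circular <- ref$topology == "circular"
  S <- if (circular) paste0(ref$seq, substr(ref$seq, 1, min(22L, L))) else ref$seq
  ch <- strsplit(S, "")[[1]]
  g <- strsplit(guide$protospacer, "")[[1]]
  grc <- strsplit(rc_str(guide$protospacer), "")[[1]]
  nS <- length(ch)
  rows <- list()
  if (nS >= 23) {
    for (s in 0:(nS - 23)) {
      # + strand window
      if (!(circular && s >= L)) {
        win <- ch[(s + 1):(s + 20)]
        mm <- sum(win != g)
        if (mm <= max_mismatches) {
          pam <- paste0(ch[s + 21], ch[s + 22], ch[s + 23])
          cls <- pam_class_of(pam, pam_classes)
          if (!is.na(cls)) {
            rows[[length(rows) + 1L]] <- data.frame(
              guide = guide$name, strand = "+", proto_start = s,
              proto_end = s + 20L, pam_start = s + 20L, pam_end = s + 23L,
              pam_class = cls, pam_seq = pam,
              protospacer = paste(win, collapse = ""),
              mismatches = mm, stringsAsFactors = FALSE)
          }
        }
      }
      # - strand window: revcomp(protospacer)-like at [s+3, s+23), PAM [s, s+3)
      s2 <- s + 3L
      if (s2 + 20 <= nS && !(circular && s2 >= L && s >= L)) {
        win <- ch[(s2 + 1):(s2 + 20)]
        mm <- sum(win != grc)
        if (mm <= max_mismatches) {
          pam <- rc_str(paste0(ch[s + 1], ch[s + 2], ch[s + 3]))
          cls <- pam_class_of(pam, pam_classes)
          if (!is.na(cls)) {
            rows[[length(rows) + 1L]] <- data.frame(
              guide = guide$name, strand = "-",
              proto_start = if (circular) s2 %% L else s2,
              proto_end = (if (circular) s2 %% L else s2) + 20L,
              pam_start = (if (circular) s2 %% L else s2) - 3L,
              pam_end = if (circular) s2 %% L else s2,
              pam_class = cls, pam_seq = pam,
              protospacer = rc_str(paste(win, collapse = "")),
              mismatches = mm, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    guide = character(), strand = character(), proto_start = integer(),
    proto_end = integer(), pam_start = integer(), pam_end = integer(),
    pam_class = character(), pam_seq = character(), protospacer = character(),
    mismatches = integer(), stringsAsFactors = FALSE)
  key <- paste(out$strand, out$proto_start %% max(L, 1L))
  out <- out[!duplicated(key), , drop = FALSE]
  out <- out[order(out$mismatches, out$proto_start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
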