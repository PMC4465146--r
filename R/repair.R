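#' Indel token in Table-style notation
#'
#' Indels at a junction are reported as `+X` (insertion of `X`) or `-X`
#' (deletion of `X`) anchored at a 1-based base on the junction reference:
#' the anchor is the base immediately *before* the event (insertions fall
#' between `position` and `position + 1`; deletions remove bases starting at
#' `position + 1`). Tokens are left-normalized: shifted to the smallest
#' anchor that preserves the alternate sequence, so that e.g. an insertion
#' inside a homopolymer is always reported at its 5'-most placement.
#'
#' @param type `"+"` or `"-"`.
#' @param bases Inserted or deleted nucleotides (non-empty).
#' @param position 1-based anchor on the junction reference.
#' @param ref_seq Junction reference sequence used for normalization and the
#'   `ref_base` field (optional).
#' @return Object of class `indel_token` with fields `token` (e.g. `"+G"`),
#'   `type`, `bases`, `position`, `ref_base`.
#' @export
indel_token <- function(type, bases, position, ref_seq = NULL) {
  stopifnot(type %in% c("+", "-"), nzchar(bases))
  bases <- toupper(bases); position <- as.integer(position)
  ref_base <- NA_character_
  if (!is.null(ref_seq)) {
    ref_seq <- as.character(as_nuc_seq(ref_seq))
    nz <- normalize_indel(ref_seq, position, type, bases)
    position <- nz$position; bases <- nz$bases
    ref_base <- if (position >= 1) substr(ref_seq, position, position) else NA_character_
  }
  structure(list(token = paste0(type, bases), type = type, bases = bases,
                 position = position, ref_base = ref_base),
            class = "indel_token")
}

#' @export
print.indel_token <- function(x, ...) {
  cat(sprintf("<indel %s at %d (ref %s)>\n", x$token, x$position, x$ref_base))
  invisible(x)
}

#' Left-normalize an indel against a reference
#'
#' Shifts an insertion/deletion to the smallest 1-based anchor preserving the
#' alternate sequence: while the reference base at the anchor equals the last
#' base of the indel string, the event slides one base left.
#'
#' @param ref_seq Reference string.
#' @param position 1-based anchor (base before the event).
#' @param type `"+"` or `"-"`.
#' @param bases Indel sequence.
#' @return List with normalized `position` and `bases`.
#' @export
normalize_indel <- function(ref_seq, position, type, bases) {
  ref_seq <- as.character(as_nuc_seq(ref_seq))
  n <- nchar(bases)
  while (position >= 1 &&
         substr(ref_seq, position, position) == substr(bases, n, n)) {
    bases <- paste0(substr(ref_seq, position, position), substr(bases, 1, n - 1))
    position <- position - 1L
  }
  list(position = as.integer(position), bases = bases)
}

#' Templated insertion from fill-in of a staggered cut
#'
#' End filling of a 5' overhang followed by blunt ligation duplicates the
#' overhang, producing a templated insertion whose identity is read from the
#' PAM-bearing strand at positions `target_offset + 1 ... protospacer_offset`
#' upstream of the PAM. Blunt cuts yield no insertion.
#'
#' @param cut A [cut_site()].
#' @return Insertion token string (e.g. `"+G"`), or `NA_character_` for a
#'   blunt cut.
#' @export
fill_in_insertion <- function(cut) {
  stopifnot(inherits(cut, "cut_site"))
  if (cut$blunt) return(NA_character_)
  paste0("+", cut$overhang)
}

repair_mode_names <- c("blunt_ligation", "fill_in", "resection")

# How a cut end is resolved before ligation, as coordinates on the unedited
# molecule. Returns left_end (end of the fragment retained on the left of the
# cut) and right_start (start of the fragment retained on the right); NULL if
# the mode cannot resolve this cut (blunt ligation of a staggered end).
resolve_cut_ends <- function(cut, mode) {
  if (cut$blunt) {
    return(list(left_end = cut$top_cut, right_start = cut$top_cut))
  }
  switch(mode,
    blunt_ligation = NULL,
    fill_in   = list(left_end = cut$bottom_cut, right_start = cut$top_cut),
    resection = list(left_end = cut$top_cut,   right_start = cut$bottom_cut))
}

# Build one edited molecule under a (cut A, cut B, mode) mechanism, with the
# fusion gap(s) in edited coordinates.
build_repair_variant <- function(ref, cut_a, cut_b, kind, mode) {
  ra <- resolve_cut_ends(cut_a, mode); rb <- resolve_cut_ends(cut_b, mode)
  if (is.null(ra) || is.null(rb)) return(NULL)
  L <- nuc_length(ref)
  if (kind == "deletion") {
    seq <- paste0(nuc_sub(ref, 0, ra$left_end), nuc_sub(ref, rb$right_start, L))
    list(seq = nuc_seq(seq, as_nuc_seq(ref)$topology),
         fusion = ra$left_end)
  } else {
    seg <- rc_str(nuc_sub(ref, ra$right_start, rb$left_end))
    seq <- paste0(nuc_sub(ref, 0, ra$left_end), seg, nuc_sub(ref, rb$right_start, L))
    list(seq = nuc_seq(seq, as_nuc_seq(ref)$topology),
         fusion = c(ra$left_end, ra$left_end + nchar(seg)))
  }
}

# Compare a variant junction window to the canonical one; both share the
# fusion gap at `flank`. Returns NULL (identical), an indel_token, or NA for
# a difference that is not a single pure indel (does not occur in the
# mechanism space enumerated here).
diff_to_token <- function(canonical_win, variant_win, flank) {
  a <- canonical_win; b <- variant_win
  if (a == b) return(NULL)
  na <- nchar(a); nb <- nchar(b)
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  npref <- 0L
  while (npref < min(na, nb) && ca[npref + 1] == cb[npref + 1]) npref <- npref + 1L
  nsuf <- 0L
  while (nsuf < min(na, nb) - npref && ca[na - nsuf] == cb[nb - nsuf]) nsuf <- nsuf + 1L
  mid_a <- substr(a, npref + 1, na - nsuf)
  mid_b <- substr(b, npref + 1, nb - nsuf)
  if (nzchar(mid_a) && nzchar(mid_b)) return(NA)  # not a pure indel
  if (nzchar(mid_b)) {
    indel_token("+", mid_b, npref, ref_seq = a)
  } else {
    indel_token("-", mid_a, npref, ref_seq = a)
  }
}

#' Enumerate repair products over cut-offset and repair-mode combinations
#'
#' For every combination of protospacer-strand cut offsets at the two sites
#' (target-strand offset fixed at 3) and every repair mode, constructs the
#' resulting junction sequence variant and the indel it carries relative to
#' the canonical blunt (3,3) junction. Fill-in of a 5' overhang duplicates
#' the overhang (templated insertion); resection trims it (deletion); blunt
#' ligation is only defined when both cuts are blunt. The precise product
#' (blunt (3,3)+(3,3), blunt ligation) is always included. Products are
#' deduplicated by junction variant with all generating mechanisms retained
#' (`variant_key` groups rows describing the same molecule).
#'
#' @param ref Unedited molecule.
#' @param site_a,site_b Guide sites (rows of [find_guide_sites()] output);
#'   `site_a` must lie upstream of `site_b`.
#' @param kind `"deletion"` or `"inversion"`.
#' @param offsets_a,offsets_b Protospacer-strand offsets tried at each site
#'   (subset of 3:8).
#' @param modes Repair modes considered.
#' @param flank Junction window flank (default 30; large enough to contain
#'   any enumerated indel).
#' @return `data.frame` with one row per (mechanism, junction label):
#'   `label`, `offset_a`, `offset_b`, `mode`, `token` (`NA` = precise),
#'   `position` (1-based on the canonical junction window), `ref_base`,
#'   `variant` (junction window sequence), `variant_key`.
#' @export
enumerate_repair_products <- function(ref, site_a, site_b,
                                      kind = c("deletion", "inversion"),
                                      offsets_a = 3:8, offsets_b = 3:8,
                                      modes = repair_mode_names,
                                      flank = 30L) {
  kind <- match.arg(kind)
  ref <- as_nuc_seq(ref)
  stopifnot(all(modes %in% repair_mode_names))
  site_a <- site_row(site_a); site_b <- site_row(site_b)
  if (canonical_gap(site_a) >= canonical_gap(site_b)) {
    stop("site_a must lie strictly upstream of site_b")
  }
  # canonical junction(s)
  can_a <- cut_site(site_a, cut_model(3, 3), ref)
  can_b <- cut_site(site_b, cut_model(3, 3), ref)
  can <- build_repair_variant(ref, can_a, can_b, kind, "blunt_ligation")
  labels <- if (kind == "deletion") "deletion_junction" else
    c("inversion_5prime", "inversion_3prime")
  can_win <- vapply(seq_along(labels), function(i)
    nuc_sub(can$seq, can$fusion[i] - flank, can$fusion[i] + flank), "")

  modes_all <- unique(c("blunt_ligation", modes))
  rows <- list()
  for (pa in sort(unique(c(3L, as.integer(offsets_a))))) {
    for (pb in sort(unique(c(3L, as.integer(offsets_b))))) {
      cut_a <- cut_site(site_a, cut_model(3, pa), ref)
      cut_b <- cut_site(site_b, cut_model(3, pb), ref)
      if (max(cut_a$top_cut, cut_a$bottom_cut) >
          min(cut_b$top_cut, cut_b$bottom_cut)) {
        stop("cut windows of the two sites overlap")
      }
      for (mode in modes_all) {
        # blunt ligation is only defined for two blunt ends; fill-in and
        # resection act on staggered ends only (a fully blunt pair has
        # nothing to fill or trim and is just blunt ligation)
        if (mode == "blunt_ligation" && !(cut_a$blunt && cut_b$blunt)) next
        if (mode != "blunt_ligation" && cut_a$blunt && cut_b$blunt) next
        if (!(mode %in% modes) && !(pa == 3L && pb == 3L)) next
        v <- build_repair_variant(ref, cut_a, cut_b, kind, mode)
        if (is.null(v)) next
        delta <- nuc_length(v$seq) - nuc_length(can$seq)
        for (i in seq_along(labels)) {
          # per-junction signed deltas before/after the fusion gap, so the
          # variant window lines up base-for-base with the canonical one
          fus <- v$fusion[i]
          dj <- junction_delta(cut_a, cut_b, kind, mode, i)
          win <- nuc_sub(v$seq, fus - flank - dj[1], fus + flank + dj[2])
          tok <- diff_to_token(can_win[i], win, flank)
          if (is.null(tok)) {
            token <- NA_character_; pos <- NA_integer_; rb <- NA_character_
          } else if (!inherits(tok, "indel_token")) {
            next  # not a pure indel; outside the modeled space
          } else {
            token <- tok$token; pos <- tok$position; rb <- tok$ref_base
          }
          rows[[length(rows) + 1L]] <- data.frame(
            label = labels[i], offset_a = pa, offset_b = pb, mode = mode,
            token = token, position = pos, ref_base = rb, variant = win,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  # restrict to requested offsets plus the mandatory precise row
  keep <- (out$offset_a %in% offsets_a & out$offset_b %in% offsets_b &
             out$mode %in% modes) |
    (out$offset_a == 3L & out$offset_b == 3L & out$mode == "blunt_ligation")
  out <- out[keep, , drop = FALSE]
  out <- out[!duplicated(paste(out$label, out$offset_a, out$offset_b, out$mode)), ,
             drop = FALSE]
  out$variant_key <- paste(out$label, out$variant, sep = ":")
  out <- out[order(out$label, out$offset_a, out$offset_b, match(out$mode, repair_mode_names)), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("repair_products", class(out))
  out
}

# signed length changes a mechanism contributes to junction i (1 = 5' or the
# deletion junction, 2 = 3' inversion junction), split into the part landing
# immediately before the fusion gap and the part immediately after it
junction_delta <- function(cut_a, cut_b, kind, mode, i) {
  ga <- if (cut_a$blunt) cut_a$top_cut else canonical_gap(cut_a$site)
  gb <- if (cut_b$blunt) cut_b$top_cut else canonical_gap(cut_b$site)
  ra <- resolve_cut_ends(cut_a, mode); rb <- resolve_cut_ends(cut_b, mode)
  if (kind == "deletion") {
    c(ra$left_end - ga, gb - rb$right_start)
  } else if (i == 1L) {
    c(ra$left_end - ga, rb$left_end - gb)
  } else {
    c(ga - ra$right_start, gb - rb$right_start)
  }
}

#' Explain an observed junction indel mechanistically
#'
#' Inverts [enumerate_repair_products()]: returns every (offset A, offset B,
#' mode) mechanism whose product carries exactly the observed left-normalized
#' indel at the observed position. Because small junction indels can equally
#' arise from imprecise end joining, a generic `nhej` explanation is appended
#' whenever the token is a 1-2 nt event at the fusion point; the function
#' reports all consistent mechanisms and never picks one.
#'
#' @param token Observed token string (`"+G"`, `"-AC"`, ...), or `NA` for a
#'   precise junction.
#' @param position 1-based anchor on the canonical junction window used by
#'   `enumerate_repair_products` (i.e. with fusion gap at `flank`).
#' @param ref,site_a,site_b,kind,offsets_a,offsets_b,modes,flank As in
#'   [enumerate_repair_products()].
#' @param label Which junction the observation is from (defaults to the first
#'   junction of `kind`).
#' @param window Observations anchored further than this from the fusion gap
#'   are rejected (default 20 nt).
#' @param obs_fusion Fusion point (gap coordinate) of the junction window the
#'   observed `position` refers to, when that window was built with a
#'   different flank than `flank` (e.g. pileup positions on a flank-100
#'   junction); positions are translated accordingly. Defaults to `flank`.
#' @return `data.frame` of mechanisms: `offset_a`, `offset_b`, `mode`
#'   (possibly including `"nhej"`), ordered fill-in/resection first, smaller
#'   offsets first, generic NHEJ last.
#' @export
explain_indel <- function(token, position, ref, site_a, site_b,
                          kind = c("deletion", "inversion"),
                          label = NULL,
                          offsets_a = 3:8, offsets_b = 3:8,
                          modes = repair_mode_names,
                          flank = 30L, window = 20L, obs_fusion = flank) {
  kind <- match.arg(kind)
  if (!is.na(position)) position <- as.integer(position) - as.integer(obs_fusion) + as.integer(flank)
  prod <- enumerate_repair_products(ref, site_a, site_b, kind,
                                    offsets_a, offsets_b, modes, flank)
  if (is.null(label)) label <- prod$label[1]
  prod <- prod[prod$label == label, , drop = FALSE]
  if (is.na(token)) {
    # every mechanism that leaves this junction precise is consistent with a
    # precise observation; the canonical blunt (3,3) ligation is listed first
    hit <- prod[is.na(prod$token), c("offset_a", "offset_b", "mode")]
    hit <- hit[order(hit$mode != "blunt_ligation",
                     hit$offset_a + hit$offset_b, hit$offset_a), , drop = FALSE]
    rownames(hit) <- NULL
    return(hit)
  }
  if (!is.na(position) && abs(position - flank) > window) {
    stop("observed position lies outside the fusion window")
  }
  hit <- prod[!is.na(prod$token) & prod$token == token &
                (is.na(position) | prod$position == position),
              c("offset_a", "offset_b", "mode"), drop = FALSE]
  hit <- hit[order(hit$offset_a + hit$offset_b, hit$offset_a,
                   match(hit$mode, repair_mode_names)), , drop = FALSE]
  ev_len <- nchar(token) - 1L
  near_fusion <- is.na(position) || abs(position - flank) <= 2L + ev_len
  if (ev_len <= 2L && near_fusion) {
    hit <- rbind(hit, data.frame(offset_a = NA_integer_, offset_b = NA_integer_,
                                 mode = "nhej", stringsAsFactors = FALSE))
  }
  rownames(hit) <- NULL
  hit
}
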