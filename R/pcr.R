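#' Primer pair
#'
#' @param forward,reverse Primer sequences, each written 5'->3' on its own
#'   annealing strand; at least 15 nt.
#' @param name Pair label.
#' @return Object of class `primer_pair`.
#' @export
primer_pair <- function(forward, reverse, name = "") {
  forward <- toupper(as.character(forward)); reverse <- toupper(as.character(reverse))
  if (nchar(forward) < 15 || nchar(reverse) < 15) {
    stop("primers must be at least 15 nt")
  }
  if (grepl("[^ACGT]", forward) || grepl("[^ACGT]", reverse)) {
    stop("primers may only contain A,C,G,T")
  }
  structure(list(forward = forward, reverse = reverse, name = as.character(name)),
            class = "primer_pair")
}

#' In-silico PCR
#'
#' Enumerates every amplicon up to `max_size` where the forward primer
#' matches the template exactly and the reverse primer matches the opposite
#' strand downstream, in either template orientation. Detection logic only:
#' matches are exact, no thermodynamics or efficiency model. Circular
#' templates are scanned across the origin; an empty result is a valid
#' outcome.
#'
#' @param template Template molecule (`nuc_seq` or string).
#' @param primers A [primer_pair()].
#' @param max_size Largest amplicon reported (default 5000 nt).
#' @return `data.frame` with one row per amplicon: `start`, `end` (0-based
#'   half-open on the + strand, `end` may exceed the length for circular
#'   wrap), `size`, `orientation` (`"+"` if the forward primer sits on the +
#'   strand), `sequence` (5'->3' from the forward primer).
#' @export
insilico_pcr <- function(template, primers, max_size = 5000L) {
  template <- as_nuc_seq(template)
  stopifnot(inherits(primers, "primer_pair"))
  max_size <- as.integer(max_size)
  if (max_size <= max(nchar(primers$forward), nchar(primers$reverse))) {
    stop("`max_size` must exceed the primer lengths")
  }
  L <- nuc_length(template)
  circular <- template$topology == "circular"
  cap <- if (circular) min(max_size, L) else max_size
  S <- if (circular) paste0(template$seq, template$seq) else template$seq

  one_orientation <- function(fwd, rev, orient) {
    nf <- nchar(fwd); nr <- nchar(rev)
    f0 <- match_starts(fwd, S)
    r0 <- match_starts(rc_str(rev), S)
    rows <- list()
    for (f in f0) {
      if (circular && f >= L) next
      for (r in r0) {
        end <- r + nr
        size <- end - f
        if (size < nf + nr || size > cap) next
        seqc <- substr(S, f + 1, end)
        rows[[length(rows) + 1L]] <- data.frame(
          start = f, end = end, size = size, orientation = orient,
          sequence = if (orient == "+") seqc else rc_str(seqc),
          stringsAsFactors = FALSE)
      }
    }
    rows
  }

  rows <- c(one_orientation(primers$forward, primers$reverse, "+"),
            one_orientation(primers$reverse, primers$forward, "-"))
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    start = integer(), end = integer(), size = integer(),
    orientation = character(), sequence = character(), stringsAsFactors = FALSE)
  if (nrow(out)) {
    if (circular) {
      key <- paste(out$start %% L, out$end %% L, out$orientation)
      out <- out[!duplicated(key), , drop = FALSE]
    }
    # report each physical product once: a "-" orientation duplicate of a "+"
    # product (same interval) is the same molecule read from the other end
    key2 <- paste(out$start %% max(L, 1L), out$end %% max(L, 1L))
    out <- out[!duplicated(key2), , drop = FALSE]
    out <- out[order(out$start, out$size), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Predicted amplicon size table
#'
#' Runs [insilico_pcr()] for each primer pair over a set of templates and
#' tabulates the product sizes -- the dry-lab analogue of running the
#' detection PCRs on unedited, deleted and inverted molecules side by side.
#'
#' @param templates Named list of `nuc_seq`.
#' @param primer_pairs Named list of [primer_pair()].
#' @param max_size Passed to [insilico_pcr()].
#' @return `data.frame` with columns `template`, `primer_pair`, `n_products`,
#'   `sizes` (comma-separated) and one row per (template, pair).
#' @export
amplicon_table <- function(templates, primer_pairs, max_size = 5000L) {
  rows <- list()
  for (tn in names(templates)) {
    for (pn in names(primer_pairs)) {
      am <- insilico_pcr(templates[[tn]], primer_pairs[[pn]], max_size)
      rows[[length(rows) + 1L]] <- data.frame(
        template = tn, primer_pair = pn, n_products = nrow(am),
        sizes = paste(am$size, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
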