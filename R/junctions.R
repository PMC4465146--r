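#' Rearrangement event between two cut sites
#'
#' Pairs two cuts on the same molecule into a deletion or inversion event.
#' Cuts may be given as [cut_site()] objects or as bare gap coordinates
#' (interpreted as blunt cuts). The upstream cut (smaller canonical gap)
#' becomes `cut_a`.
#'
#' @param kind `"deletion"` or `"inversion"`.
#' @param cut_a,cut_b Cut sites or numeric gap coordinates.
#' @param topology Topology of the molecule the event acts on.
#' @return Object of class `rearrangement_event`.
#' @export
rearrangement_event <- function(kind = c("deletion", "inversion"),
                                cut_a, cut_b,
                                topology = c("linear", "circular")) {
  kind <- match.arg(kind)
  topology <- match.arg(topology)
  norm <- function(cut) {
    if (inherits(cut, "cut_site")) cut
    else structure(list(top_cut = as.integer(cut), bottom_cut = as.integer(cut),
                        overhang = "", blunt = TRUE, site = NULL, model = NULL),
                   class = "cut_site")
  }
  a <- norm(cut_a); b <- norm(cut_b)
  ga <- event_gap(a); gb <- event_gap(b)
  if (ga > gb) { tmp <- a; a <- b; b <- tmp; tmp <- ga; ga <- gb; gb <- tmp }
  if (ga == gb) stop("cuts coincide: no segment between them")
  if (max(a$top_cut, a$bottom_cut) > min(b$top_cut, b$bottom_cut)) {
    stop("cut windows overlap; cuts must be non-overlapping")
  }
  structure(list(kind = kind, cut_a = a, cut_b = b, topology = topology),
            class = "rearrangement_event")
}

# gap used to order/apply an event: blunt gap for blunt cuts, canonical (3,3)
# gap for staggered cuts (the canonical junction assumption)
event_gap <- function(cut) {
  if (cut$blunt) return(cut$top_cut)
  if (is.null(cut$site)) stop("staggered cut without a site cannot be anchored")
  canonical_gap(cut$site)
}

resolve_event <- function(ref, event, cut_a = NULL, cut_b = NULL, kind = NULL) {
  if (inherits(event, "rearrangement_event")) return(event)
  # allow apply_* to be called with bare gap coordinates
  rearrangement_event(kind, event, cut_a, topology = as_nuc_seq(ref)$topology)
}

#' Apply a deletion between two cuts
#'
#' Removes the segment strictly between the two cut gaps and re-ligates the
#' flanks (the canonical blunt-ligation product). For circular molecules the
#' arc `[gap_a, gap_b)` is removed by default; `arc = "outer"` removes the
#' complementary arc instead.
#'
#' @param ref Molecule to edit.
#' @param event A [rearrangement_event()], or a numeric gap (with the second
#'   gap in `gap_b`) for the common blunt toy case.
#' @param gap_b Optional second gap when `event` is numeric.
#' @param arc For circular molecules, which arc is deleted: `"inner"`
#'   (`[gap_a, gap_b)`) or `"outer"`.
#' @return Edited `nuc_seq`; linear length shrinks by the deleted span.
#' @export
apply_deletion <- function(ref, event, gap_b = NULL, arc = c("inner", "outer")) {
  ref <- as_nuc_seq(ref)
  arc <- match.arg(arc)
  event <- resolve_event(ref, event, gap_b, kind = "deletion")
  ga <- event_gap(event$cut_a); gb <- event_gap(event$cut_b)
  L <- nuc_length(ref)
  if (ref$topology == "linear") {
    out <- paste0(nuc_sub(ref, 0, ga), nuc_sub(ref, gb, L))
    return(nuc_seq(out, "linear", name = paste0(ref$name, "_del")))
  }
  # keep the fusion at gap `ga` in the result (rotation is free on a circle)
  kept <- if (arc == "inner") paste0(nuc_sub(ref, 0, ga), nuc_sub(ref, gb, L))
          else nuc_sub(ref, ga, gb)
  nuc_seq(kept, "circular", name = paste0(ref$name, "_del"))
}

#' Apply an inversion between two cuts
#'
#' Replaces the segment between the two cut gaps by its reverse complement;
#' length and topology are preserved. Applying the same inversion twice
#' restores the original molecule.
#'
#' @inheritParams apply_deletion
#' @return Edited `nuc_seq` of identical length.
#' @export
apply_inversion <- function(ref, event, gap_b = NULL) {
  ref <- as_nuc_seq(ref)
  event <- resolve_event(ref, event, gap_b, kind = "inversion")
  ga <- event_gap(event$cut_a); gb <- event_gap(event$cut_b)
  L <- nuc_length(ref)
  out <- paste0(nuc_sub(ref, 0, ga), rc_str(nuc_sub(ref, ga, gb)), nuc_sub(ref, gb, L))
  nuc_seq(out, ref$topology, name = paste0(ref$name, "_inv"))
}

#' Extract a fusion-junction reference window
#'
#' Cuts a window of `flank` nt on each side of a fusion gap out of an edited
#' molecule; the window is the reference that amplicon reads are aligned to,
#' with `fusion_point == flank` (a gap coordinate within the window).
#'
#' @param edited Edited molecule (`nuc_seq`).
#' @param fusion_gap Gap coordinate of the fusion in `edited`.
#' @param flank Nucleotides retained on each side.
#' @param label One of `"deletion_junction"`, `"inversion_5prime"`,
#'   `"inversion_3prime"` (free-form labels are allowed).
#' @param min_flank Smallest admissible flank (default 1; the pipeline uses
#'   flank 100).
#' @return Object of class `junction_ref` with fields `seq` (linear
#'   `nuc_seq`), `fusion_point`, `flank`, `label`.
#' @export
junction_reference <- function(edited, fusion_gap, flank = 100L,
                               label = "deletion_junction", min_flank = 1L) {
  edited <- as_nuc_seq(edited)
  flank <- as.integer(flank); fusion_gap <- as.integer(fusion_gap)
  if (flank < min_flank) stop(sprintf("flank must be >= %d", min_flank))
  L <- nuc_length(edited)
  if (edited$topology == "linear") {
    need_left <- flank - fusion_gap
    need_right <- fusion_gap + flank - L
    if (need_left > 0 || need_right > 0) {
      stop(sprintf(
        "junction window exceeds sequence ends; trim flank by %d nt",
        max(need_left, need_right)))
    }
  }
  win <- nuc_sub(edited, fusion_gap - flank, fusion_gap + flank)
  structure(list(
    seq = nuc_seq(win, "linear",
                  name = paste0(if (nzchar(edited$name)) edited$name else "junction",
                                "|", label)),
    fusion_point = flank, flank = flank, label = label),
    class = "junction_ref")
}

#' @export
print.junction_ref <- function(x, ...) {
  cat(sprintf("<junction_ref %s: %d nt, fusion gap at %d>\n",
              x$label, nuc_length(x$seq), x$fusion_point))
  invisible(x)
}

#' Predict canonical junction references for an event
#'
#' Builds the edited molecule under the canonical blunt (3,3) assumption and
#' returns its fusion-junction reference(s): one junction for a deletion, two
#' (5' and 3' fusion) for an inversion.
#'
#' @param ref Unedited molecule.
#' @param event A [rearrangement_event()].
#' @param flank Window flank per side (default 100).
#' @return List with `edited` (`nuc_seq`) and `junctions` (list of
#'   `junction_ref`).
#' @export
predict_junctions <- function(ref, event, flank = 100L) {
  ref <- as_nuc_seq(ref)
  ga <- event_gap(event$cut_a); gb <- event_gap(event$cut_b)
  if (event$kind == "deletion") {
    edited <- apply_deletion(ref, event)
    jx <- list(junction_reference(edited, ga, flank, "deletion_junction"))
  } else {
    edited <- apply_inversion(ref, event)
    jx <- list(junction_reference(edited, ga, flank, "inversion_5prime"),
               junction_reference(edited, gb, flank, "inversion_3prime"))
  }
  list(edited = edited, junctions = jx)
}
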