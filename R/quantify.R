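#' Alignment scoring parameters
#'
#' Affine scheme used for read-to-junction alignment: a gap of length `L`
#' costs `gap_open + gap_ext * L`. Defaults favour substitutions over gaps
#' (a 1-nt gap costs more than two mismatches), appropriate for amplicon
#' reads where the biological signal is an indel at the fusion and the noise
#' is substitution error.
#'
#' @param match Match score (> 0).
#' @param mismatch Mismatch score (< 0).
#' @param gap_open Gap opening penalty (> 0, subtracted).
#' @param gap_ext Per-base gap extension penalty (> 0, subtracted).
#' @return List of class `align_scoring`.
#' @export
align_scoring <- function(match = 1, mismatch = -2, gap_open = 5, gap_ext = 2) {
  stopifnot(match > 0, mismatch < 0, gap_open > 0, gap_ext > 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_ext = gap_ext),
            class = "align_scoring")
}

# Reconstruct run-length alignment operations (M/I/D, in order) for one read
# from the indel ranges reported in alignment-column coordinates.
# ref_pos: for M runs the 1-based ref position of the first base; for D the
# first deleted ref base; for I the 1-based ref base immediately before the
# inserted bases (the anchor).
ops_from_ranges <- function(read, refseq, ref_start, ins, del, read_len) {
  ev <- rbind(
    if (nrow(ins)) cbind(ins, op = "I") else NULL,
    if (nrow(del)) cbind(del, op = "D") else NULL)
  if (is.null(ev)) {
    return(data.frame(op = "M", ref_pos = ref_start, len = read_len,
                      bases = "", stringsAsFactors = FALSE))
  }
  ncol_tot <- read_len + if (nrow(del)) sum(del$width) else 0L
  ev <- ev[order(ev$start), , drop = FALSE]
  op <- character(0); ref_pos <- integer(0); len <- integer(0); bases <- character(0)
  cur <- 1L; ref_cur <- ref_start; pat_cur <- 1L
  emit <- function(o, rp, l, b) {
    op <<- c(op, o); ref_pos <<- c(ref_pos, rp); len <<- c(len, l); bases <<- c(bases, b)
  }
  add_m <- function(w) {
    if (w > 0) { emit("M", ref_cur, w, ""); ref_cur <<- ref_cur + w; pat_cur <<- pat_cur + w }
  }
  for (k in seq_len(nrow(ev))) {
    add_m(ev$start[k] - cur)
    w <- ev$width[k]
    if (ev$op[k] == "I") {
      emit("I", ref_cur - 1L, w, substr(read, pat_cur, pat_cur + w - 1L))
      pat_cur <- pat_cur + w
    } else {
      emit("D", ref_cur, w, substr(refseq, ref_cur, ref_cur + w - 1L))
      ref_cur <- ref_cur + w
    }
    cur <- ev$end[k] + 1L
  }
  add_m(ncol_tot - cur + 1L)
  data.frame(op = op, ref_pos = ref_pos, len = len, bases = bases,
             stringsAsFactors = FALSE)
}

#' Align reads to a junction reference
#'
#' Glocal alignment: each read is aligned end-to-end (globally) against a
#' local window of the junction reference, via
#' `Biostrings::pairwiseAlignment(type = "global-local")`. Reads that are
#' exact substrings of the reference take a fast path (leftmost placement).
#' A read is `mapped` when its identity (matches / read length) reaches
#' `min_identity`.
#'
#' @param reads Named character vector (or `DNAStringSet`) of reads, each at
#'   least `min_read_len` nt.
#' @param junction A [junction_reference()] object.
#' @param scoring An [align_scoring()].
#' @param min_identity Identity floor below which a read is unmapped
#'   (default 0.8).
#' @param min_read_len Reads shorter than this are rejected (default 30).
#' @param chunk_size Reads aligned per `pairwiseAlignment` call.
#' @return Object of class `junction_alignments`: list with `junction` and
#'   `reads`, a list holding per read `id`, `mapped`, `score`, `ref_start`,
#'   `ref_end` (1-based inclusive), `ops`.
#' @export
align_to_junction <- function(reads, junction, scoring = align_scoring(),
                              min_identity = 0.8, min_read_len = 30L,
                              chunk_size = 5000L) {
  stopifnot(inherits(junction, "junction_ref"), inherits(scoring, "align_scoring"))
  if (inherits(reads, "DNAStringSet")) {
    reads <- setNames(as.character(reads), names(reads))
  }
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  if (any(nchar(reads) < min_read_len)) {
    stop(sprintf("reads shorter than %d nt are rejected", min_read_len))
  }
  refseq <- as.character(junction$seq)
  reflen <- nchar(refseq)
  n <- length(reads)
  out <- vector("list", n)

  # fast path: exact substring placements per read width (leftmost)
  widths <- nchar(reads)
  exact_at <- rep(NA_integer_, n)
  for (w in unique(widths)) {
    if (w > reflen) next
    kmers <- substring(refseq, 1:(reflen - w + 1L), w:reflen)
    idx <- which(widths == w)
    exact_at[idx] <- match(unname(reads[idx]), kmers)
  }
  for (i in which(!is.na(exact_at))) {
    w <- unname(widths[i])
    out[[i]] <- list(id = names(reads)[i], mapped = TRUE,
                     score = w * scoring$match,
                     ref_start = exact_at[i], ref_end = exact_at[i] + w - 1L,
                     ops = data.frame(op = "M", ref_pos = exact_at[i],
                                      len = w, bases = "",
                                      stringsAsFactors = FALSE),
                     mism = integer(0))
  }

  todo <- which(is.na(exact_at))
  if (length(todo)) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(
      match = scoring$match, mismatch = scoring$mismatch)
    subj <- Biostrings::DNAString(refseq)
    for (chunk in split(todo, ceiling(seq_along(todo) / chunk_size))) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAStringSet(unname(reads[chunk])), subj,
        type = "global-local", substitutionMatrix = mat,
        gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext)
      rstarts <- Biostrings::start(Biostrings::subject(aln))
      rends <- Biostrings::end(Biostrings::subject(aln))
      scs <- Biostrings::score(aln)
      nmatches <- Biostrings::nmatch(aln)
      ins_df <- as.data.frame(Biostrings::insertion(aln))
      del_df <- as.data.frame(Biostrings::deletion(aln))
      mt <- Biostrings::mismatchTable(aln)
      ins_by <- split(ins_df[c("start", "end", "width")], ins_df$group)
      del_by <- split(del_df[c("start", "end", "width")], del_df$group)
      mism_by <- split(mt$SubjectStart, mt$PatternId)
      none <- data.frame(start = integer(), end = integer(), width = integer())
      for (j in seq_along(chunk)) {
        i <- chunk[j]
        mapped <- nmatches[j] / widths[i] >= min_identity
        ops <- if (mapped) {
          ops_from_ranges(unname(reads[i]), refseq, rstarts[j],
                          if (is.null(ins_by[[as.character(j)]])) none else ins_by[[as.character(j)]],
                          if (is.null(del_by[[as.character(j)]])) none else del_by[[as.character(j)]],
                          widths[i])
        } else data.frame(op = character(), ref_pos = integer(),
                          len = integer(), bases = character(),
                          stringsAsFactors = FALSE)
        mism <- mism_by[[as.character(j)]]
        out[[i]] <- list(id = names(reads)[i], mapped = mapped,
                         score = scs[j],
                         ref_start = rstarts[j], ref_end = rends[j],
                         ops = ops,
                         mism = if (is.null(mism) || !mapped) integer(0)
                                else as.integer(mism))
      }
    }
  }
  structure(list(junction = junction, reads = out),
            class = "junction_alignments")
}

#' @export
print.junction_alignments <- function(x, ...) {
  n <- length(x$reads)
  m <- sum(vapply(x$reads, `[[`, TRUE, "mapped"))
  cat(sprintf("<junction_alignments to %s: %d reads, %d mapped>\n",
              x$junction$label, n, m))
  invisible(x)
}

# does a mapped read span the fusion with >= min_flank anchored nt each side?
spans_fusion <- function(read, fusion, min_flank) {
  read$mapped && read$ref_start <= fusion - min_flank + 1L &&
    read$ref_end >= fusion + min_flank
}

#' Pile up indels around the fusion point
#'
#' Aggregates left-normalized indels observed within `window` nt of the
#' fusion gap over all fusion-spanning reads. A read spans the fusion when it
#' is mapped and anchored by at least `min_flank` nt on each side of the
#' fusion gap; non-spanning reads contribute to no count. For each
#' (position, token), `ref_reads` counts spanning reads covering the anchor
#' without that indel (reads carrying only mismatches count as reference at
#' indel anchors), and `var_freq = var_reads / (ref_reads + var_reads)`.
#'
#' @param alignments A [align_to_junction()] result.
#' @param window Indels anchored within `fusion_point +/- window` are
#'   reported (default 20).
#' @param min_flank Minimum anchored nt on each side of the fusion (default
#'   10).
#' @return `data.frame` with columns `position` (1-based), `ref_base`,
#'   `indel`, `ref_reads`, `var_reads`, `var_freq`, ordered by `var_freq`
#'   decreasing. Zero mapped reads yield the empty frame.
#' @export
pileup_indels <- function(alignments, window = 20L, min_flank = 10L) {
  stopifnot(inherits(alignments, "junction_alignments"), window >= 1)
  junction <- alignments$junction
  refseq <- as.character(junction$seq)
  fusion <- junction$fusion_point
  lo <- fusion - window + 1L; hi <- fusion + window
  span <- Filter(function(rd) spans_fusion(rd, fusion, min_flank),
                 alignments$reads)
  empty <- data.frame(position = integer(), ref_base = character(),
                      indel = character(), ref_reads = integer(),
                      var_reads = integer(), var_freq = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(span)) return(empty)

  # per-read normalized indel tokens within the window
  keys <- list(); read_of <- integer(0)
  for (ri in seq_along(span)) {
    ops <- span[[ri]]$ops
    idx <- which(ops$op %in% c("I", "D"))
    for (k in idx) {
      if (ops$op[k] == "I") {
        anchor <- ops$ref_pos[k]; bases <- ops$bases[k]; type <- "+"
      } else {
        anchor <- ops$ref_pos[k] - 1L; bases <- ops$bases[k]; type <- "-"
      }
      nz <- normalize_indel(refseq, anchor, type, bases)
      if (nz$position < lo || nz$position > hi) next
      keys[[length(keys) + 1L]] <- c(nz$position, paste0(type, nz$bases))
      read_of <- c(read_of, ri)
    }
  }
  if (!length(keys)) return(empty)
  kdf <- data.frame(position = as.integer(vapply(keys, `[[`, "", 1)),
                    indel = vapply(keys, `[[`, "", 2),
                    read = read_of, stringsAsFactors = FALSE)
  kdf <- kdf[!duplicated(kdf), , drop = FALSE]   # one vote per read per token
  grp <- paste(kdf$position, kdf$indel)
  starts <- vapply(span, `[[`, 1L, "ref_start")
  ends <- vapply(span, `[[`, 1L, "ref_end")
  rows <- lapply(split(seq_len(nrow(kdf)), grp), function(ii) {
    pos <- kdf$position[ii[1]]; tok <- kdf$indel[ii[1]]
    var <- length(unique(kdf$read[ii]))
    covering <- sum(starts <= pos & ends >= pos)
    refn <- covering - var
    data.frame(position = pos,
               ref_base = substr(refseq, pos, pos),
               indel = tok, ref_reads = refn, var_reads = var,
               var_freq = var / (refn + var), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$var_freq, out$position, out$indel), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Binomial significance of an indel observation against sequencing error
#'
#' One-sided binomial tail probability of observing at least `var_reads`
#' indel-supporting reads among `ref_reads + var_reads` trials if indels
#' arose only from a per-read error process of rate `error_rate`.
#'
#' @param var_reads,ref_reads Counts from [pileup_indels()].
#' @param error_rate Assumed error probability, in `(0, 0.5)` (default 0.01).
#' @return p-value in `[0, 1]`.
#' @export
indel_significance <- function(var_reads, ref_reads, error_rate = 0.01) {
  if (error_rate <= 0 || error_rate >= 0.5) stop("`error_rate` must be in (0, 0.5)")
  n <- var_reads + ref_reads
  if (any(n == 0)) stop("zero total reads: significance undefined")
  stats::pbinom(var_reads - 1, n, error_rate, lower.tail = FALSE)
}

#' Fraction of fusion-spanning reads matching the junction perfectly
#'
#' A spanning read is perfect when it has no mismatch and no indel anywhere
#' within `fusion_point +/- window` on the reference.
#'
#' @inheritParams pileup_indels
#' @return Fraction in `[0, 1]`; `NaN` when no read spans the fusion.
#' @export
classify_perfect_fusion <- function(alignments, window = 20L, min_flank = 10L) {
  stopifnot(inherits(alignments, "junction_alignments"))
  junction <- alignments$junction
  fusion <- junction$fusion_point
  lo <- fusion - window + 1L; hi <- fusion + window
  span <- Filter(function(rd) spans_fusion(rd, fusion, min_flank),
                 alignments$reads)
  if (!length(span)) return(NaN)
  perfect <- vapply(span, function(rd) {
    if (any(rd$mism >= lo & rd$mism <= hi)) return(FALSE)
    ops <- rd$ops
    # ref interval touched by each op (an insertion touches the two bases
    # flanking its gap)
    op_end <- ifelse(ops$op == "I", ops$ref_pos + 1L, ops$ref_pos + ops$len - 1L)
    !any(ops$op != "M" & op_end >= lo & ops$ref_pos <= hi)
  }, TRUE)
  mean(perfect)
}

#' Assemble a Table-style indel spectrum report
#'
#' Combines the pileup, per-indel significance, the precise-fusion fraction
#' and each indel's share of all indel-supporting reads (indel
#' representation) into one report.
#'
#' @inheritParams pileup_indels
#' @param sample,replicate Labels carried into the report.
#' @param error_rate Passed to [indel_significance()].
#' @return Object of class `spectrum_report`: list with `name`, `replicate`,
#'   `label`, `observations` (pileup plus `p_value` and `representation`
#'   columns), `perfect_fraction`, `mapped_fraction`, `n_reads`,
#'   `n_spanning`.
#' @export
spectrum_report <- function(alignments, sample = "sample", replicate = 1L,
                            window = 20L, min_flank = 10L, error_rate = 0.01) {
  obs <- pileup_indels(alignments, window, min_flank)
  if (nrow(obs)) {
    obs$p_value <- indel_significance(obs$var_reads, obs$ref_reads, error_rate)
    obs$representation <- obs$var_reads / sum(obs$var_reads)
  } else {
    obs$p_value <- numeric(0); obs$representation <- numeric(0)
  }
  n <- length(alignments$reads)
  mapped <- sum(vapply(alignments$reads, `[[`, TRUE, "mapped"))
  fusion <- alignments$junction$fusion_point
  nspan <- sum(vapply(alignments$reads, spans_fusion, TRUE,
                      fusion = fusion, min_flank = min_flank))
  structure(list(name = sample, replicate = replicate,
                 label = alignments$junction$label, observations = obs,
                 perfect_fraction = classify_perfect_fusion(alignments, window, min_flank),
                 mapped_fraction = if (n) mapped / n else 0,
                 n_reads = n, n_spanning = nspan),
            class = "spectrum_report")
}

#' @export
print.spectrum_report <- function(x, ...) {
  cat(sprintf("Spectrum report: %s (replicate %s), junction %s\n",
              x$name, x$replicate, x$label))
  cat(sprintf("  reads: %d (%.1f%% mapped), %d spanning the fusion\n",
              x$n_reads, 100 * x$mapped_fraction, x$n_spanning))
  cat(sprintf("  precise fusion: %.1f%%\n", 100 * x$perfect_fraction))
  if (nrow(x$observations)) {
    print(x$observations, digits = 3)
  } else cat("  no indel observations\n")
  invisible(x)
}

#' Filter an indel spectrum report
#'
#' Drops observations below a variant-frequency or supporting-read
#' threshold and recomputes the indel representation over the survivors.
#'
#' @param report A [spectrum_report()].
#' @param min_freq Minimum `var_freq` (default 0.01, the detection floor
#'   used for junction indels).
#' @param min_var_reads Minimum supporting reads (default 2).
#' @return Filtered `spectrum_report`.
#' @export
filter_observations <- function(report, min_freq = 0.01, min_var_reads = 2L) {
  stopifnot(inherits(report, "spectrum_report"), min_freq >= 0, min_var_reads >= 0)
  obs <- report$observations
  keep <- obs$var_freq >= min_freq & obs$var_reads >= min_var_reads
  obs <- obs[keep, , drop = FALSE]
  if (nrow(obs)) obs$representation <- obs$var_reads / sum(obs$var_reads)
  rownames(obs) <- NULL
  report$observations <- obs
  report
}

#' Write one or more spectrum reports as a Table-shaped TSV
#'
#' Fixed column order: `Name`, `Replicate`, `Junction`, `Position`, `Ref`,
#' `Indel`, `reads_ref`, `reads_var`, `VarFreq`, `p_value`,
#' `representation`.
#'
#' @param reports A `spectrum_report` or list of them.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_spectrum_tsv <- function(reports, path) {
  if (inherits(reports, "spectrum_report")) reports <- list(reports)
  rows <- lapply(reports, function(r) {
    o <- r$observations
    if (!nrow(o)) return(NULL)
    data.frame(Name = r$name, Replicate = r$replicate, Junction = r$label,
               Position = o$position, Ref = o$ref_base, Indel = o$indel,
               reads_ref = o$ref_reads, reads_var = o$var_reads,
               VarFreq = o$var_freq, p_value = signif(o$p_value, 4),
               representation = o$representation, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    Name = character(), Replicate = integer(), Junction = character(),
    Position = integer(), Ref = character(), Indel = character(),
    reads_ref = integer(), reads_var = integer(), VarFreq = numeric(),
    p_value = numeric(), representation = numeric(), stringsAsFactors = FALSE)
  write_tsv(out, path)
}

#' Write junction alignments as a minimal SAM file
#'
#' Plain-text single-reference SAM sufficient for IGV inspection: mapped
#' reads get CIGAR from the alignment operations (`M` covers matches and
#' mismatches), unmapped reads are emitted with flag 4.
#'
#' @param alignments A [align_to_junction()] result.
#' @param reads The read sequences that were aligned (named character).
#' @param path Output SAM.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, reads, path) {
  stopifnot(inherits(alignments, "junction_alignments"))
  junction <- alignments$junction
  rname <- junction$seq$name
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", rname, nuc_length(junction$seq))),
             con)
  for (rd in alignments$reads) {
    seqc <- unname(reads[[rd$id]])
    if (!isTRUE(rd$mapped)) {
      writeLines(sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t*", rd$id, seqc), con)
      next
    }
    ops <- rd$ops
    cig <- paste0(ops$len, chartr("X", "M", ops$op), collapse = "")
    writeLines(sprintf("%s\t0\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*",
                       rd$id, rname, rd$ref_start, cig, seqc), con)
  }
  invisible(path)
}
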