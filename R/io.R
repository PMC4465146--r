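#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @param topology Topology to assign to every record (FASTA itself does not
#'   encode it); records whose description contains the token
#'   `topology=circular` override this.
#' @return Named list of `nuc_seq`.
#' @export
read_fasta <- function(path, topology = "linear") {
  ss <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(ss), function(i) {
    nm <- names(ss)[i]
    topo <- if (grepl("topology=circular", nm, fixed = TRUE)) "circular" else topology
    nuc_seq(as.character(ss[[i]]), topology = topo,
            name = sub("\\s.*$", "", nm))
  })
  names(out) <- vapply(out, function(x) x$name, "")
  out
}

#' Write sequences to a FASTA file
#'
#' Circular sequences are tagged with `topology=circular` in the description
#' so that a round-trip through [read_fasta()] preserves topology.
#'
#' @param seqs A `nuc_seq` or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "nuc_seq")) seqs <- list(seqs)
  nm <- vapply(seq_along(seqs), function(i) {
    x <- seqs[[i]]
    base <- if (nzchar(x$name)) x$name else paste0("seq", i)
    if (x$topology == "circular") paste(base, "topology=circular") else base
  }, "")
  ss <- Biostrings::DNAStringSet(vapply(seqs, as.character, ""))
  names(ss) <- nm
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read single-end reads from a FASTQ file
#'
#' Base qualities are not used by the alignment or pileup stages and are
#' discarded; paired-end data should be supplied as two files and the mates
#' are processed as independent reads.
#'
#' @param path FASTQ file.
#' @return Named character vector of read sequences (names = read ids).
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write reads to a FASTQ file with constant base quality
#'
#' @param reads Named character vector of read sequences.
#' @param path Output file.
#' @param quality Single quality character applied to every base.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality = "I") {
  ss <- Biostrings::DNAStringSet(unname(reads))
  names(ss) <- names(reads)
  quals <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    strrep(quality, n), "", USE.NAMES = FALSE))
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = quals)
  invisible(path)
}

# small TSV writer with fixed column order
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
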