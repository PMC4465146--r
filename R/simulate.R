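# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# random 20-mer protospacer
random_protospacer <- function() random_dna(20)

# a LoxP-like 34-nt site: 13-nt arm, asymmetric 8-nt spacer, inverted-repeat
# arm; the second arm starts with an NAG PAM so the internal 20-nt
# protospacer (site positions 2-21) is cuttable. Not the true LoxP sequence.
random_loxp_like <- function() {
  arm <- strsplit(random_dna(13), "")[[1]]
  arm[11] <- "C"; arm[12] <- "T"   # gives ...NAG at arm2 positions 2-3
  arm <- paste(arm, collapse = "")
  spacer <- random_dna(8)
  paste0(arm, spacer, rc_str(arm))
}

count_sites <- function(fixture, guide, pam_classes) {
  nrow(find_guide_sites(fixture$seq, fixture$guides[[guide]], pam_classes))
}

new_fixture <- function(kind, seq, features, guides, primers, seed) {
  structure(list(kind = kind, seq = seq, features = features,
                 guides = guides, primers = primers, seed = seed),
            class = "construct_fixture")
}

#' @export
print.construct_fixture <- function(x, ...) {
  cat(sprintf("<construct_fixture %s: %d nt %s, %d guides, %d primer pairs>\n",
              x$kind, nuc_length(x$seq), x$seq$topology,
              length(x$guides), length(x$primers)))
  print(x$features, row.names = FALSE)
  invisible(x)
}

# pick a unique 20-mer window as a primer from region [a,b) (0-based) of seq;
# direction "fwd" uses the + strand, "rev" returns the revcomp (primer on -)
pick_primer <- function(seqstr, a, direction = "fwd") {
  w <- substr(seqstr, a + 1, a + 20)
  if (direction == "fwd") w else rc_str(w)
}

# count occurrences of a pattern on either strand of a (possibly circular)
# sequence
occurrences <- function(pat, x) {
  x <- as_nuc_seq(x)
  S <- if (x$topology == "circular") paste0(x$seq, substr(x$seq, 1, nchar(pat) - 1)) else x$seq
  length(match_starts(pat, S)) + length(match_starts(rc_str(pat), S))
}

#' Generate a reporter-construct fixture
#'
#' Builds synthetic constructs with the architecture of the three study
#' designs, on random background sequence (deterministic for a fixed seed):
#'
#' * `igfp_like` -- a circular plasmid carrying a promoter and a reporter
#'   cassette cloned in inverted orientation, flanked by two NGG-PAM guide
#'   sites (one per flank) and by two inverted LoxP-like 34-nt sites, each
#'   offering the same internal protospacer with a weak NAG PAM so that a
#'   single guide cuts at both. Inversion between the flanking cuts
#'   reorients the cassette behind the promoter.
#' * `lsl_like` -- a circular plasmid with promoter, a STOP cassette between
#'   two direct-repeat LoxP-like sites (one NAG guide cutting twice), and a
#'   downstream reporter; deletion between the cuts removes the STOP.
#' * `two_cut_locus` -- a linear molecule with two NGG guide sites roughly
#'   `scale/2` apart, a desk-scale stand-in for a multi-kilobase genomic
#'   region targeted for deletion or inversion.
#'
#' Every fixture carries primer pairs: `inversion` (amplifies only the
#' inverted molecule), `deletion` (product shortens by the excised length).
#' Construction is validated: the declared guides must hit the declared
#' number of sites and primers must be unique; a failing draw is retried
#' deterministically.
#'
#' @param kind `"igfp_like"`, `"lsl_like"` or `"two_cut_locus"`.
#' @param scale Total construct length in nt (>= 500).
#' @param seed Integer seed; same (kind, scale, seed) gives an identical
#'   fixture.
#' @return Object of class `construct_fixture` with fields `seq` (`nuc_seq`),
#'   `features` (BED-like `data.frame`), `guides` (named list of
#'   [guide_spec()]), `primers` (named list of [primer_pair()]), `seed`.
#' @export
make_fixture <- function(kind = c("igfp_like", "lsl_like", "two_cut_locus"),
                         scale = 3000L, seed = 1L) {
  kind <- match.arg(kind)
  scale <- as.integer(scale)
  if (scale < 500L) stop("`scale` must be at least 500 nt")
  build <- switch(kind, igfp_like = build_igfp, lsl_like = build_lsl,
                  two_cut_locus = build_locus)
  for (attempt in 0:24) {
    fx <- with_seed(seed * 1000L + attempt, build(scale, seed))
    if (validate_fixture(fx)) return(fx)
  }
  stop("could not construct a valid fixture; try another seed or scale")
}

validate_fixture <- function(fx) {
  ok <- TRUE
  for (gname in names(fx$guides)) {
    expected <- attr(fx$guides, "expected_sites")[[gname]]
    classes <- attr(fx$guides, "pam_classes")[[gname]]
    n <- nrow(find_guide_sites(fx$seq, fx$guides[[gname]], classes))
    if (n != expected) ok <- FALSE
  }
  for (pp in fx$primers) {
    if (occurrences(pp$forward, fx$seq) > 1 || occurrences(pp$reverse, fx$seq) > 1) ok <- FALSE
  }
  ok
}

feature_row <- function(name, start, end, strand = "+") {
  data.frame(name = name, start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

build_igfp <- function(scale, seed) {
  cass_len <- max(200L, round(scale * 0.3))
  fixed <- 60 + 30 + 23 + 20 + 34 + 20 + cass_len + 20 + 34 + 20 + 23 + 30
  if (fixed + 60 > scale) stop("`scale` too small to fit the igfp_like features")
  protoA <- random_protospacer(); protoB <- random_protospacer()
  lox <- random_loxp_like()
  cassette_sense <- random_dna(cass_len)   # reporter in sense orientation
  promoter <- random_dna(60)
  parts <- list(
    promoter = promoter,
    sp1 = random_dna(30),
    guideA = paste0(protoA, "TGG"),                 # + strand NGG site
    sp2 = random_dna(20),
    loxp1 = lox,                                    # + orientation
    sp3 = random_dna(20),
    cassette = rc_str(cassette_sense),              # inverted reporter
    sp4 = random_dna(20),
    loxp2 = rc_str(lox),                            # inverted LoxP-like
    sp5 = random_dna(20),
    guideB = paste0("CCA", rc_str(protoB)),         # - strand NGG site
    sp6 = random_dna(30))
  filler <- random_dna(scale - sum(nchar(unlist(parts))))
  parts$filler <- filler
  seqstr <- paste(unlist(parts), collapse = "")
  offs <- cumsum(c(0, nchar(unlist(parts))))
  names(offs) <- c(names(parts), "end")
  seq <- nuc_seq(seqstr, "circular", name = sprintf("igfp_like_s%d", seed))

  guides <- list(igfp_a = guide_spec("igfp_a", protoA),
                 igfp_b = guide_spec("igfp_b", protoB),
                 loxp = guide_spec("loxp", substr(lox, 2, 21)))
  attr(guides, "expected_sites") <- list(igfp_a = 1L, igfp_b = 1L, loxp = 2L)
  attr(guides, "pam_classes") <- list(igfp_a = "NGG", igfp_b = "NGG",
                                      loxp = c("NGG", "NAG"))

  # canonical cut gaps of the flanking guides
  gapA <- offs[["guideA"]] + 20L - 3L
  gapB <- offs[["guideB"]] + 3L + 3L      # - site: proto starts after "CCA"
  inverted <- apply_inversion(seq, gapA, gapB)
  p_fwd <- pick_primer(seqstr, offs[["promoter"]] + 5L)
  # reverse primer annealing inside the cassette in its *inverted* (sense)
  # orientation: matches only the edited molecule
  w_sense <- substr(cassette_sense, 51, 70)
  p_inv_rev <- rc_str(w_sense)
  # deletion primer downstream of the guide B cut
  p_del_rev <- pick_primer(seqstr, offs[["sp6"]] + 5L, "rev")
  primers <- list(
    inversion = primer_pair(p_fwd, p_inv_rev, "inversion"),
    deletion = primer_pair(p_fwd, p_del_rev, "deletion"))

  features <- rbind(
    feature_row("promoter", offs[["promoter"]], offs[["sp1"]]),
    feature_row("guideA_site", offs[["guideA"]], offs[["sp2"]], "+"),
    feature_row("loxp1", offs[["loxp1"]], offs[["sp3"]], "+"),
    feature_row("cassette", offs[["cassette"]], offs[["sp4"]], "-"),
    feature_row("loxp2", offs[["loxp2"]], offs[["sp5"]], "-"),
    feature_row("guideB_site", offs[["guideB"]], offs[["sp6"]], "-"))
  new_fixture("igfp_like", seq, features, guides, primers, seed)
}

build_lsl <- function(scale, seed) {
  stop_len <- max(150L, round(scale * 0.35))
  rep_len <- max(100L, round(scale * 0.15))
  fixed <- 60 + 20 + 34 + stop_len + 34 + 20 + rep_len + 30
  if (fixed + 40 > scale) stop("`scale` too small to fit the lsl_like features")
  lox <- random_loxp_like()
  parts <- list(
    promoter = random_dna(60),
    sp1 = random_dna(20),
    loxp1 = lox,
    stop_cassette = random_dna(stop_len),
    loxp2 = lox,                      # direct repeat: same orientation
    sp2 = random_dna(20),
    reporter = random_dna(rep_len),
    sp3 = random_dna(30))
  parts$filler <- random_dna(scale - sum(nchar(unlist(parts))))
  seqstr <- paste(unlist(parts), collapse = "")
  offs <- cumsum(c(0, nchar(unlist(parts))))
  names(offs) <- c(names(parts), "end")
  seq <- nuc_seq(seqstr, "circular", name = sprintf("lsl_like_s%d", seed))

  guides <- list(loxp = guide_spec("loxp", substr(lox, 2, 21)))
  attr(guides, "expected_sites") <- list(loxp = 2L)
  attr(guides, "pam_classes") <- list(loxp = c("NGG", "NAG"))

  p_fwd <- pick_primer(seqstr, offs[["promoter"]] + 5L)
  p_rev <- pick_primer(seqstr, offs[["reporter"]] + 20L, "rev")
  primers <- list(deletion = primer_pair(p_fwd, p_rev, "deletion"))

  features <- rbind(
    feature_row("promoter", offs[["promoter"]], offs[["sp1"]]),
    feature_row("loxp1", offs[["loxp1"]], offs[["stop_cassette"]], "+"),
    feature_row("stop_cassette", offs[["stop_cassette"]], offs[["loxp2"]], "+"),
    feature_row("loxp2", offs[["loxp2"]], offs[["sp2"]], "+"),
    feature_row("reporter", offs[["reporter"]], offs[["sp3"]], "+"))
  new_fixture("lsl_like", seq, features, guides, primers, seed)
}

build_locus <- function(scale, seed) {
  if (scale < 700L) stop("`scale` too small for a two_cut_locus fixture")
  flankL <- round(scale * 0.2); mid <- round(scale * 0.45)
  protoA <- random_protospacer(); protoB <- random_protospacer()
  parts <- list(
    flank_left = random_dna(flankL),
    guideA = paste0(protoA, "TGG"),
    middle = random_dna(mid),
    guideB = paste0("CCA", rc_str(protoB)))
  parts$flank_right <- random_dna(scale - sum(nchar(unlist(parts))))
  seqstr <- paste(unlist(parts), collapse = "")
  offs <- cumsum(c(0, nchar(unlist(parts))))
  names(offs) <- c(names(parts), "end")
  seq <- nuc_seq(seqstr, "linear", name = sprintf("two_cut_locus_s%d", seed))

  guides <- list(locus_a = guide_spec("locus_a", protoA),
                 locus_b = guide_spec("locus_b", protoB))
  attr(guides, "expected_sites") <- list(locus_a = 1L, locus_b = 1L)
  attr(guides, "pam_classes") <- list(locus_a = "NGG", locus_b = "NGG")

  gapA <- offs[["guideA"]] + 20L - 3L
  gapB <- offs[["guideB"]] + 3L + 3L
  p_fwd <- pick_primer(seqstr, offs[["guideA"]] - 60L)
  p_del_rev <- pick_primer(seqstr, offs[["end"]] - 60L, "rev")
  # inversion-detection reverse primer: anneals to the middle segment only
  # in its inverted orientation
  m_plus <- substr(seqstr, offs[["middle"]] + 101L, offs[["middle"]] + 120L)
  p_inv_rev <- m_plus   # = rc of the segment after inversion flips it
  primers <- list(
    deletion = primer_pair(p_fwd, p_del_rev, "deletion"),
    inversion = primer_pair(p_fwd, p_inv_rev, "inversion"))

  features <- rbind(
    feature_row("guideA_site", offs[["guideA"]], offs[["middle"]], "+"),
    feature_row("segment", gapA, gapB, "+"),
    feature_row("guideB_site", offs[["guideB"]], offs[["flank_right"]], "-"))
  new_fixture("two_cut_locus", seq, features, guides, primers, seed)
}

# resolve the two flanking cut sites of a fixture (canonical 3,3 models)
fixture_sites <- function(fixture) {
  gn <- switch(fixture$kind,
               igfp_like = c("igfp_a", "igfp_b"),
               two_cut_locus = c("locus_a", "locus_b"),
               lsl_like = c("loxp", "loxp"))
  classes <- attr(fixture$guides, "pam_classes")
  if (fixture$kind == "lsl_like") {
    sites <- find_guide_sites(fixture$seq, fixture$guides$loxp, classes$loxp)
    list(a = sites[1, ], b = sites[2, ])
  } else {
    list(a = find_guide_sites(fixture$seq, fixture$guides[[gn[1]]], classes[[gn[1]]])[1, ],
         b = find_guide_sites(fixture$seq, fixture$guides[[gn[2]]], classes[[gn[2]]])[1, ])
  }
}

#' Simulate a pool of edited molecules
#'
#' Draws `n` molecules independently: each is unedited, deleted, or inverted
#' according to `rates`, and edited molecules are built under a repair
#' mechanism sampled from `mechanism_mixture` (default: canonical blunt
#' (3,3) ligation only). Truth labels are retained per molecule.
#'
#' @param fixture A [make_fixture()] result.
#' @param rates Named numeric, `c(deletion=, inversion=, unedited=)`, summing
#'   to 1.
#' @param mechanism_mixture `data.frame` with columns `offset_a`, `offset_b`,
#'   `mode`, `prob` (probabilities sum to 1), drawn from the repair
#'   enumeration space.
#' @param n Pool size.
#' @param seed RNG seed; pools are reproducible bit-for-bit given
#'   (fixture, rates, mixture, n, seed).
#' @return Object of class `edited_pool`: list with `molecules` (character),
#'   `truth` (`data.frame` with `label`, `offset_a`, `offset_b`, `mode`),
#'   `rates`, `seed`.
#' @export
simulate_editing_pool <- function(fixture,
                                  rates = c(deletion = 0.3, inversion = 0.3,
                                            unedited = 0.4),
                                  mechanism_mixture = NULL,
                                  n = 1000L, seed = 1L) {
  stopifnot(inherits(fixture, "construct_fixture"))
  if (abs(sum(rates) - 1) > 1e-8) stop("`rates` must sum to 1")
  if (!all(names(rates) %in% c("deletion", "inversion", "unedited"))) {
    stop("`rates` names must be deletion/inversion/unedited")
  }
  if (is.null(mechanism_mixture)) {
    mechanism_mixture <- data.frame(offset_a = 3L, offset_b = 3L,
                                    mode = "blunt_ligation", prob = 1)
  }
  if (abs(sum(mechanism_mixture$prob) - 1) > 1e-8) {
    stop("mechanism mixture probabilities must sum to 1")
  }
  bad <- mechanism_mixture$mode == "blunt_ligation" &
    (mechanism_mixture$offset_a != 3L | mechanism_mixture$offset_b != 3L)
  if (any(bad)) stop("blunt ligation is only defined for (3,3) cuts")
  sites <- fixture_sites(fixture)
  ref <- fixture$seq
  with_seed(seed, {
    labels <- sample(names(rates), n, replace = TRUE, prob = rates)
    mech_i <- sample.int(nrow(mechanism_mixture), n, replace = TRUE,
                         prob = mechanism_mixture$prob)
    mols <- character(n)
    truth <- data.frame(label = labels,
                        offset_a = mechanism_mixture$offset_a[mech_i],
                        offset_b = mechanism_mixture$offset_b[mech_i],
                        mode = mechanism_mixture$mode[mech_i],
                        stringsAsFactors = FALSE)
    truth$offset_a[labels == "unedited"] <- NA_integer_
    truth$offset_b[labels == "unedited"] <- NA_integer_
    truth$mode[labels == "unedited"] <- NA_character_
    # cache variants per (label, mechanism): construction is deterministic
    cache <- new.env(parent = emptyenv())
    for (i in seq_len(n)) {
      if (labels[i] == "unedited") { mols[i] <- ref$seq; next }
      key <- paste(labels[i], truth$offset_a[i], truth$offset_b[i], truth$mode[i])
      if (is.null(cache[[key]])) {
        ca <- cut_site(sites$a, cut_model(3, truth$offset_a[i]), ref)
        cb <- cut_site(sites$b, cut_model(3, truth$offset_b[i]), ref)
        v <- build_repair_variant(ref, ca, cb, labels[i], truth$mode[i])
        if (is.null(v)) stop(sprintf("mechanism %s incompatible with %s",
                                     key, labels[i]))
        cache[[key]] <- as.character(v$seq)
      }
      mols[i] <- cache[[key]]
    }
    structure(list(molecules = mols, truth = truth, rates = rates,
                   fixture_kind = fixture$kind, seed = seed),
              class = "edited_pool")
  })
}

#' @export
print.edited_pool <- function(x, ...) {
  cat(sprintf("<edited_pool: %d molecules from a %s fixture>\n",
              length(x$molecules), x$fixture_kind))
  print(table(x$truth$label))
  invisible(x)
}

#' Simulate amplicon reads from a junction with a known outcome spectrum
#'
#' Each read first receives an outcome sampled from `spectrum` -- `"none"`
#' for the precise junction, or an indel token such as `"+G"` or `"-A"`
#' applied at the fusion gap (`+X` inserts `X` at the gap; `-X` requires the
#' bases after the gap to equal `X` and deletes them) -- and is then drawn as
#' a window of `read_length` nt across the fusion point, with independent
#' per-base substitution errors at `error_rate`. Deterministic for a fixed
#' seed.
#'
#' @param junction A [junction_reference()] object.
#' @param spectrum Named probabilities over outcomes, summing to 1.
#' @param n_reads Number of reads (>= 1).
#' @param read_length Read length; must not exceed the shortest outcome
#'   template.
#' @param error_rate Per-base substitution probability.
#' @param seed RNG seed.
#' @return Object of class `read_sim`: list with `reads` (named character),
#'   `truth` (`data.frame` with `id`, `outcome`, `start`), `junction`,
#'   `params`.
#' @export
simulate_reads <- function(junction, spectrum = c(none = 1), n_reads = 1000L,
                           read_length = 150L, error_rate = 0.001, seed = 1L) {
  stopifnot(inherits(junction, "junction_ref"), n_reads >= 1)
  if (abs(sum(spectrum) - 1) > 1e-8) stop("`spectrum` must sum to 1")
  if (is.null(names(spectrum)) || any(!nzchar(names(spectrum)))) {
    stop("`spectrum` must be a named vector (use name 'none' for precise)")
  }
  templates <- vapply(names(spectrum), function(tok)
    apply_junction_outcome(junction, tok), "")
  if (any(nchar(templates) < read_length)) {
    stop("`read_length` exceeds an outcome template length")
  }
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    outcome <- sample(names(spectrum), n_reads, replace = TRUE, prob = spectrum)
    reads <- character(n_reads); startv <- integer(n_reads)
    for (tok in unique(outcome)) {
      idx <- which(outcome == tok)
      tpl <- templates[[tok]]
      smax <- nchar(tpl) - read_length
      st <- if (smax > 0) sample.int(smax + 1L, length(idx), replace = TRUE) - 1L
            else rep(0L, length(idx))
      reads[idx] <- substring(tpl, st + 1L, st + read_length)
      startv[idx] <- st
    }
    # substitution errors: only a small fraction of reads carries any
    nerr <- rbinom(n_reads, read_length, error_rate)
    for (i in which(nerr > 0)) {
      pos <- sample.int(read_length, nerr[i])
      ch <- strsplit(reads[i], "")[[1]]
      for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1)
      reads[i] <- paste(ch, collapse = "")
    }
    ids <- sprintf("read%06d", seq_len(n_reads))
    names(reads) <- ids
    structure(list(reads = reads,
                   truth = data.frame(id = ids, outcome = outcome,
                                      start = startv, stringsAsFactors = FALSE),
                   junction = junction,
                   params = list(n_reads = n_reads, read_length = read_length,
                                 error_rate = error_rate, seed = seed)),
              class = "read_sim")
  })
}

#' @export
print.read_sim <- function(x, ...) {
  cat(sprintf("<read_sim: %d reads of %d nt from %s, error %.2g>\n",
              x$params$n_reads, x$params$read_length, x$junction$label,
              x$params$error_rate))
  print(table(x$truth$outcome))
  invisible(x)
}

#' Apply an outcome token to a junction sequence
#'
#' @param junction A [junction_reference()] object.
#' @param token `"none"`, or `"+X"`/`"-X"` applied at the fusion gap.
#' @return The outcome template sequence (character).
#' @export
apply_junction_outcome <- function(junction, token) {
  s <- as.character(junction$seq)
  f <- junction$fusion_point
  if (identical(token, "none") || is.na(token)) return(s)
  type <- substr(token, 1, 1); bases <- substr(token, 2, nchar(token))
  if (!type %in% c("+", "-") || !nzchar(bases) || grepl("[^ACGT]", bases)) {
    stop(sprintf("invalid outcome token '%s'", token))
  }
  if (type == "+") {
    paste0(substr(s, 1, f), bases, substr(s, f + 1, nchar(s)))
  } else {
    have <- substr(s, f + 1, f + nchar(bases))
    if (have != bases) {
      stop(sprintf("token '%s' invalid for this junction: bases after the fusion are '%s'",
                   token, have))
    }
    paste0(substr(s, 1, f), substr(s, f + nchar(bases) + 1, nchar(s)))
  }
}
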