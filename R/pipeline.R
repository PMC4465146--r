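#' Pipeline configuration
#'
#' Collects every tunable of the predict/quantify pipeline into one
#' validated object. `config` may be a YAML file path or a named list; any
#' entry supplied in `...` overrides it. Required entries: either
#' `reference` (FASTA path) plus `guides` (named list of 20-nt protospacer
#' strings), or `fixture` (a [make_fixture()] result).
#'
#' @param config YAML path or named list.
#' @param ... Individual overrides.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list(), ...) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop(sprintf("config file '%s' does not exist", config))
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  over <- list(...)
  config[names(over)] <- over
  defaults <- list(
    pam_classes = c("NGG", "NAG"),
    kind = "deletion",
    topology = "linear",
    offsets = 3:8,
    flank = 100L,
    window = 20L,
    min_flank = 10L,
    scoring = list(match = 1, mismatch = -2, gap_open = 5, gap_ext = 2),
    min_identity = 0.8,
    min_freq = 0.01,
    min_var_reads = 2L,
    error_rate = 0.01,
    max_size = 5000L,
    seed = 1L,
    sample = "sample", replicate = 1L,
    write_sam = FALSE,
    outdir = ".")
  miss <- setdiff(names(defaults), names(config))
  config[miss] <- defaults[miss]

  if (!is.null(config$fixture)) {
    stopifnot(inherits(config$fixture, "construct_fixture"))
  } else {
    if (is.null(config$reference) || is.null(config$guides)) {
      stop("config needs either `fixture`, or `reference` + `guides`")
    }
    if (!file.exists(config$reference)) {
      stop(sprintf("reference file '%s' does not exist", config$reference))
    }
    if (length(config$guides) < 1 || is.null(names(config$guides))) {
      stop("`guides` must be a named list of protospacers")
    }
  }
  if (!all(config$kind %in% c("deletion", "inversion"))) {
    stop("`kind` must be 'deletion' and/or 'inversion'")
  }
  if (!all(config$offsets %in% 3:8)) stop("`offsets` must lie in 3:8")
  if (config$min_freq < 0 || config$min_freq > 1) stop("`min_freq` must be in [0,1]")
  if (config$error_rate <= 0 || config$error_rate >= 0.5) {
    stop("`error_rate` must be in (0, 0.5)")
  }
  config$scoring <- do.call(align_scoring, config$scoring[
    c("match", "mismatch", "gap_open", "gap_ext")])
  structure(config, class = c("pipeline_config", "list"))
}

# resolve (reference, site_a, site_b, primer pairs) from a config
config_targets <- function(config) {
  if (!is.null(config$fixture)) {
    fx <- config$fixture
    return(list(ref = fx$seq, sites = fixture_sites(fx), primers = fx$primers))
  }
  seqs <- read_fasta(config$reference, topology = config$topology)
  ref <- seqs[[1]]
  gnames <- names(config$guides)
  hits <- lapply(gnames, function(g) {
    s <- find_guide_sites(ref, guide_spec(g, config$guides[[g]]),
                          config$pam_classes)
    if (nrow(s) == 0) stop(sprintf("no target site found for guide '%s'", g))
    s
  })
  all_sites <- do.call(rbind, hits)
  if (nrow(all_sites) < 2) stop("need two cut sites to define a rearrangement")
  all_sites <- all_sites[order(vapply(seq_len(nrow(all_sites)), function(i)
    canonical_gap(all_sites[i, ]), 0)), , drop = FALSE]
  primers <- list()
  if (!is.null(config$primers)) {
    primers <- lapply(config$primers, function(p)
      primer_pair(p$forward, p$reverse, if (is.null(p$name)) "" else p$name))
  }
  list(ref = ref, sites = list(a = all_sites[1, ], b = all_sites[nrow(all_sites), ]),
       primers = primers)
}

run_log <- function(config, path, extra = character()) {
  lines <- c(
    sprintf("crisprJunctions %s", as.character(packageVersion("crisprJunctions"))),
    sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("seed: %s", config$seed),
    sprintf("kind: %s", paste(config$kind, collapse = ",")),
    sprintf("flank: %d  window: %d  min_flank: %d", config$flank,
            config$window, config$min_flank),
    sprintf("min_freq: %g  min_var_reads: %d  error_rate: %g",
            config$min_freq, config$min_var_reads, config$error_rate),
    extra)
  writeLines(lines, path)
  invisible(path)
}

#' Predict junctions and amplicon sizes for a configured event
#'
#' Emits the canonical (blunt 3,3) junction reference(s) for each configured
#' event kind, plus an in-silico PCR size table for every primer pair over
#' the unedited, deleted and inverted templates.
#'
#' @param config A [pipeline_config()] (or arguments for one).
#' @return List with `junctions` (named list of `junction_ref`), `edited`
#'   (named list of `nuc_seq`), `amplicons` (`data.frame`), and the output
#'   paths written: `<outdir>/junctions.fasta`, `<outdir>/edited.fasta`,
#'   `<outdir>/amplicons.tsv`, `<outdir>/run_predict.log`.
#' @export
run_predict <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  tg <- config_targets(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  ca <- cut_site(tg$sites$a, cut_model(3, 3), tg$ref)
  cb <- cut_site(tg$sites$b, cut_model(3, 3), tg$ref)
  junctions <- list(); edited <- list(unedited = tg$ref)
  for (kind in config$kind) {
    ev <- rearrangement_event(kind, ca, cb, topology = tg$ref$topology)
    pj <- predict_junctions(tg$ref, ev, flank = config$flank)
    edited[[kind]] <- pj$edited
    for (j in pj$junctions) junctions[[j$label]] <- j
  }
  jpath <- file.path(config$outdir, "junctions.fasta")
  write_fasta(lapply(junctions, `[[`, "seq"), jpath)
  epath <- file.path(config$outdir, "edited.fasta")
  write_fasta(edited, epath)
  amp <- NULL
  apath <- file.path(config$outdir, "amplicons.tsv")
  if (length(tg$primers)) {
    amp <- amplicon_table(edited, tg$primers, config$max_size)
    write_tsv(amp, apath)
  }
  run_log(config, file.path(config$outdir, "run_predict.log"),
          sprintf("junctions: %s", paste(names(junctions), collapse = ", ")))
  invisible(list(junctions = junctions, edited = edited, amplicons = amp,
                 paths = c(junctions = jpath, edited = epath,
                           amplicons = if (length(tg$primers)) apath else NA)))
}

#' Quantify junction repair outcomes from amplicon reads
#'
#' Runs the full analysis chain on a FASTQ of amplicon reads: predict the
#' canonical junction(s), align every read to each junction (a read is
#' assigned to the junction where it scores highest), pile up and filter
#' indels around the fusion, attach binomial significance, classify the
#' precise-fusion fraction, and explain every reported indel token
#' mechanistically. Writes `junctions.fasta`, `spectrum.tsv`,
#' `mechanisms.tsv`, optionally per-junction SAM, and a run log.
#'
#' @param config A [pipeline_config()].
#' @param reads FASTQ path, or a named character vector of reads.
#' @return List of filtered [spectrum_report()] objects (one per junction),
#'   invisibly, with the mechanism table as attribute `mechanisms`.
#' @export
run_quantify <- function(config, reads) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_fastq(reads)
  }
  pred <- run_predict(config)
  junctions <- pred$junctions
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  alns <- lapply(junctions, function(j)
    align_to_junction(reads, j, config$scoring,
                      min_identity = config$min_identity))
  # assign each read to its best-scoring junction
  if (length(alns) > 1) {
    scores <- vapply(alns, function(a)
      vapply(a$reads, `[[`, 0, "score"), numeric(length(reads)))
    best <- max.col(scores, ties.method = "first")
    for (k in seq_along(alns)) {
      drop <- which(best != k)
      for (i in drop) alns[[k]]$reads[[i]]$mapped <- FALSE
    }
  }
  reports <- list(); mech_rows <- list()
  tg <- config_targets(config)
  for (k in seq_along(alns)) {
    rep_k <- spectrum_report(alns[[k]], sample = config$sample,
                             replicate = config$replicate,
                             window = config$window,
                             min_flank = config$min_flank,
                             error_rate = config$error_rate)
    if (rep_k$n_spanning == 0) {
      warning(sprintf("no reads mapped to junction %s; empty report",
                      names(alns)[k]))
    }
    rep_k <- filter_observations(rep_k, config$min_freq, config$min_var_reads)
    reports[[names(alns)[k]]] <- rep_k
    obs <- rep_k$observations
    kind_k <- if (grepl("^deletion", names(alns)[k])) "deletion" else "inversion"
    for (i in seq_len(nrow(obs))) {
      mech <- explain_indel(obs$indel[i], obs$position[i], tg$ref,
                            tg$sites$a, tg$sites$b, kind = kind_k,
                            label = names(alns)[k],
                            offsets_a = config$offsets,
                            offsets_b = config$offsets,
                            window = config$window,
                            obs_fusion = junctions[[k]]$fusion_point)
      if (nrow(mech)) {
        mech_rows[[length(mech_rows) + 1L]] <- data.frame(
          Junction = names(alns)[k], Position = obs$position[i],
          Indel = obs$indel[i], offset_a = mech$offset_a,
          offset_b = mech$offset_b, mode = mech$mode,
          stringsAsFactors = FALSE)
      }
    }
    if (isTRUE(config$write_sam)) {
      write_sam(alns[[k]], reads,
                file.path(config$outdir, paste0(names(alns)[k], ".sam")))
    }
  }
  write_spectrum_tsv(reports, file.path(config$outdir, "spectrum.tsv"))
  mechs <- if (length(mech_rows)) do.call(rbind, mech_rows) else data.frame(
    Junction = character(), Position = integer(), Indel = character(),
    offset_a = integer(), offset_b = integer(), mode = character(),
    stringsAsFactors = FALSE)
  write_tsv(mechs, file.path(config$outdir, "mechanisms.tsv"))
  run_log(config, file.path(config$outdir, "run_quantify.log"),
          c(sprintf("reads: %d", length(reads)),
            sprintf("junction %s: perfect %.4f, mapped %.4f",
                    names(reports),
                    vapply(reports, `[[`, 0, "perfect_fraction"),
                    vapply(reports, `[[`, 0, "mapped_fraction"))))
  attr(reports, "mechanisms") <- mechs
  invisible(reports)
}
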