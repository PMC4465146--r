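test_that("the inverted-reporter fixture presents its declared guide sites", {
  fx <- make_fixture("igfp_like", 2500, 1)
  expect_equal(fx$seq$topology, "circular")
  expect_equal(nrow(find_guide_sites(fx$seq, fx$guides$igfp_a, "NGG")), 1L)
  expect_equal(nrow(find_guide_sites(fx$seq, fx$guides$igfp_b, "NGG")), 1L)
  lox_sites <- find_guide_sites(fx$seq, fx$guides$loxp, c("NGG", "NAG"))
  expect_equal(nrow(lox_sites), 2L)
  # the LoxP-like sites are targeted through a weak NAG PAM
  expect_equal(unique(lox_sites$pam_class), "NAG")
  # one site per orientation: the LoxP-like pair is inverted
  expect_setequal(lox_sites$strand, c("+", "-"))
})

test_that("the iGFP-like reporter inverts into a PCR-detectable orientation", {
  fx <- make_fixture("igfp_like", 2500, 2)
  sites <- crisprJunctions:::fixture_sites(fx)
  ca <- cut_site(sites$a, cut_model(3, 3), fx$seq)
  cb <- cut_site(sites$b, cut_model(3, 3), fx$seq)
  inv <- apply_inversion(fx$seq, rearrangement_event("inversion", ca, cb))
  expect_equal(nrow(insilico_pcr(fx$seq, fx$primers$inversion)), 0L)
  expect_equal(nrow(insilico_pcr(inv, fx$primers$inversion)), 1L)
})

test_that("the Lox-STOP-Lox fixture deletes the STOP between its two cut sites", {
  fx <- make_fixture("lsl_like", 2000, 1)
  sites <- find_guide_sites(fx$seq, fx$guides$loxp, c("NGG", "NAG"))
  expect_equal(nrow(sites), 2L)
  expect_equal(unique(sites$strand), "+")  # direct repeats: one strand
  full <- insilico_pcr(fx$seq, fx$primers$deletion)
  expect_equal(nrow(full), 1L)
  ca <- cut_site(sites[1, ], cut_model(3, 3), fx$seq)
  cb <- cut_site(sites[2, ], cut_model(3, 3), fx$seq)
  del <- apply_deletion(fx$seq, rearrangement_event("deletion", ca, cb,
                                                    topology = "circular"))
  short <- insilico_pcr(del, fx$primers$deletion)
  expect_equal(nrow(short), 1L)
  expect_equal(full$size - short$size, cb$top_cut - ca$top_cut)
})

test_that("fixtures are deterministic in (kind, scale, seed) and FASTA round-trips", {
  f1 <- make_fixture("two_cut_locus", 3000, 7)
  f2 <- make_fixture("two_cut_locus", 3000, 7)
  expect_identical(as.character(f1$seq), as.character(f2$seq))
  expect_identical(f1$features, f2$features)
  f3 <- make_fixture("two_cut_locus", 3000, 8)
  expect_false(identical(as.character(f1$seq), as.character(f3$seq)))
  expect_error(make_fixture("igfp_like", 400), "at least 500")

  path <- tempfile(fileext = ".fasta")
  write_fasta(list(f1$seq, make_fixture("igfp_like", 2500, 1)$seq), path)
  back <- read_fasta(path)
  expect_equal(as.character(back[[1]]), as.character(f1$seq))
  expect_equal(back[[2]]$topology, "circular")
})

test_that("edited pools converge to the configured event rates", {
  fx <- cached_locus_fixture()
  pool0 <- simulate_editing_pool(fx, c(deletion = 0, inversion = 0, unedited = 1),
                                 n = 50, seed = 1)
  expect_true(all(pool0$molecules == as.character(fx$seq)))

  rates <- c(deletion = 0.3, inversion = 0.3, unedited = 0.4)
  pool <- simulate_editing_pool(fx, rates, n = 10000, seed = 2)
  frac <- table(pool$truth$label) / 10000
  for (lab in names(rates)) {
    tol <- 3 * sqrt(rates[[lab]] * (1 - rates[[lab]]) / 10000)
    expect_lt(abs(frac[[lab]] - rates[[lab]]), tol)
  }
  # bit-for-bit reproducibility
  pool2 <- simulate_editing_pool(fx, rates, n = 10000, seed = 2)
  expect_identical(pool$molecules, pool2$molecules)
  expect_identical(pool$truth, pool2$truth)
})

test_that("a ligation-deficient setting removes inversion products downstream", {
  fx <- cached_locus_fixture()
  pool <- simulate_editing_pool(fx, c(deletion = 0.5, inversion = 0,
                                      unedited = 0.5), n = 300, seed = 3)
  expect_equal(sum(pool$truth$label == "inversion"), 0L)
  inv_hits <- vapply(unique(pool$molecules), function(m)
    nrow(insilico_pcr(nuc_seq(m), fx$primers$inversion)), 0L)
  expect_true(all(inv_hits == 0L))
})

test_that("pool molecules reflect their sampled repair mechanisms", {
  fx <- cached_locus_fixture()
  mix <- data.frame(offset_a = c(3L, 4L), offset_b = c(3L, 3L),
                    mode = c("blunt_ligation", "resection"),
                    prob = c(0.5, 0.5))
  pool <- simulate_editing_pool(fx, c(deletion = 1, inversion = 0, unedited = 0),
                                mechanism_mixture = mix, n = 100, seed = 4)
  lens <- nchar(pool$molecules)
  blunt <- pool$truth$mode == "blunt_ligation"
  expect_true(all(lens[!blunt] == lens[blunt][1] - 1L))
  expect_error(simulate_editing_pool(fx, c(deletion = 1, inversion = 0, unedited = 0),
                                     data.frame(offset_a = 4L, offset_b = 3L,
                                                mode = "blunt_ligation", prob = 1),
                                     n = 10, seed = 1),
               "only defined for \\(3,3\\)")
})

test_that("simulated reads honor spectrum, error rate and seed", {
  fx <- cached_locus_fixture()
  sites <- crisprJunctions:::fixture_sites(fx)
  ev <- rearrangement_event("deletion",
                            cut_site(sites$a, cut_model(), fx$seq),
                            cut_site(sites$b, cut_model(), fx$seq))
  j <- predict_junctions(fx$seq, ev)$junctions[[1]]

  clean <- simulate_reads(j, c(none = 1), n_reads = 300, read_length = 120,
                          error_rate = 0, seed = 9)
  aln <- align_to_junction(clean$reads, j)
  expect_equal(classify_perfect_fusion(aln), 1.0)

  # degenerate control: error 0.5 destroys mappability
  noisy <- simulate_reads(j, c(none = 1), n_reads = 100, read_length = 120,
                          error_rate = 0.5, seed = 9)
  alnN <- align_to_junction(noisy$reads, j)
  mapped <- mean(vapply(alnN$reads, `[[`, TRUE, "mapped"))
  expect_lt(mapped, 0.05)

  again <- simulate_reads(j, c(none = 1), n_reads = 300, read_length = 120,
                          error_rate = 0, seed = 9)
  expect_identical(clean$reads, again$reads)

  expect_error(simulate_reads(j, c(none = 0.5, "-Q" = 0.5), 10, 100, 0, 1),
               "invalid outcome token")
  expect_error(simulate_reads(j, c(none = 1), 10, 10000, 0, 1),
               "read_length")

  # FASTQ round trip preserves sequences and ids
  path <- tempfile(fileext = ".fastq")
  write_fastq(clean$reads, path)
  back <- read_fastq(path)
  expect_identical(back, clean$reads)
})

test_that("deletion tokens must match the bases after the fusion gap", {
  fx <- cached_locus_fixture()
  sites <- crisprJunctions:::fixture_sites(fx)
  ev <- rearrangement_event("deletion",
                            cut_site(sites$a, cut_model(), fx$seq),
                            cut_site(sites$b, cut_model(), fx$seq))
  j <- predict_junctions(fx$seq, ev)$junctions[[1]]
  first2 <- substr(as.character(j$seq), j$fusion_point + 1, j$fusion_point + 2)
  ok <- apply_junction_outcome(j, paste0("-", first2))
  expect_equal(nchar(ok), nuc_length(j$seq) - 2L)
  wrong <- setdiff(c("A", "C", "G", "T"), substr(first2, 1, 1))[1]
  expect_error(apply_junction_outcome(j, paste0("-", wrong)), "invalid for this junction")
})
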