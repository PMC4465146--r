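# shared deletion junction for this file, with known fusion context
quant_junction <- local({
  set.seed(77)
  left <- paste0(rand_dna(79), "T")             # last left-flank base: T
  right <- paste0("ACG", rand_dna(77))          # first right-flank bases: ACG
  junction_reference(nuc_seq(paste0(left, right)), 80, flank = 80)
})

test_that("exact reads align all-match at their true position", {
  j <- quant_junction
  read <- nuc_sub(j$seq, 20, 80)
  aln <- align_to_junction(c(r1 = read), j)
  rd <- aln$reads[[1]]
  expect_true(rd$mapped)
  expect_equal(rd$ref_start, 21)
  expect_equal(rd$ops$op, "M")
  expect_length(rd$mism, 0)
})

test_that("a single fusion-gap deletion is recovered as one 1-nt deletion op", {
  j <- quant_junction
  tpl <- apply_junction_outcome(j, "-A")
  read <- substr(tpl, 41, 120)
  aln <- align_to_junction(c(r1 = read), j)
  ops <- aln$reads[[1]]$ops
  expect_equal(ops$op[ops$op != "M"], "D")
  expect_equal(ops$len[ops$op == "D"], 1L)
  po <- pileup_indels(aln)
  expect_equal(po$indel, "-A")
  expect_equal(po$position, 80L)
})

test_that("low-identity reads are flagged unmapped", {
  set.seed(88)
  j <- quant_junction
  junk <- rand_dna(60)  # ~25% expected identity
  aln <- align_to_junction(c(r1 = junk), j)
  expect_false(aln$reads[[1]]$mapped)
  expect_equal(nrow(aln$reads[[1]]$ops), 0L)
  expect_error(align_to_junction(c(r1 = "ACGTACGT"), j), "shorter than")
})

test_that("alignment scores equal the brute-force affine-gap oracle", {
  set.seed(90)
  for (k in 1:50) {
    n <- sample(40:60, 1)
    refseq <- rand_dna(n)
    j <- junction_reference(nuc_seq(refseq), n %/% 2,
                            flank = min(n %/% 2, n - n %/% 2))
    m <- sample(15:30, 1)
    if (runif(1) < 0.7) {
      s0 <- sample(1:(nchar(as.character(j$seq)) - m + 1), 1)
      ch <- strsplit(substr(as.character(j$seq), s0, s0 + m - 1), "")[[1]]
      nmut <- sample(0:2, 1)
      if (nmut) for (p in sample(m, nmut)) ch[p] <- sample(c("A","C","G","T"), 1)
      if (runif(1) < 0.4) ch <- ch[-sample(length(ch) - 2, 1)]
      if (runif(1) < 0.4) ch <- append(ch, sample(c("A","C","G","T"), 1),
                                       sample(length(ch) - 1, 1))
      pat <- paste(ch, collapse = "")
    } else pat <- rand_dna(m)
    got <- align_to_junction(c(r = pat), j, min_read_len = 10)$reads[[1]]$score
    expect_equal(got, glocal_score(pat, as.character(j$seq)))
  }
})

test_that("pileup counts reference and variant reads per anchored token", {
  j <- quant_junction
  perfect <- nuc_sub(j$seq, 20, 140)
  with_g <- substr(apply_junction_outcome(j, "+G"), 21, 141)
  reads <- c(setNames(rep(perfect, 80), sprintf("p%02d", 1:80)),
             setNames(rep(with_g, 20), sprintf("v%02d", 1:20)))
  aln <- align_to_junction(reads, j)
  po <- pileup_indels(aln)
  expect_equal(nrow(po), 1L)
  expect_equal(po$indel, "+G")
  expect_equal(po$var_reads, 20L)
  expect_equal(po$ref_reads, 80L)
  expect_equal(po$var_freq, 0.2)
  # reads that do not span the fusion contribute to neither count
  far <- nuc_sub(j$seq, 0, 70)  # ends 10 nt before the fusion gap at 80
  aln2 <- align_to_junction(c(reads, far1 = far, far2 = far), j)
  expect_equal(pileup_indels(aln2)$ref_reads, 80L)
})

test_that("ambiguous homopolymer insertions aggregate at the leftmost anchor", {
  # reference with A5 homopolymer straddling the fusion; insertions of A
  # placed anywhere in the run must normalize to one row
  set.seed(91)
  left <- paste0(rand_dna(37), "C", "AAA")
  right <- paste0("AA", "G", rand_dna(37))
  j <- junction_reference(nuc_seq(paste0(left, right)), 41, flank = 40)
  base <- as.character(j$seq)
  reads <- character(0)
  for (p in 37:42) {  # insert an extra A at each placement across the run
    reads <- c(reads, paste0(substr(base, 11, p), "A", substr(base, p + 1, 70)))
  }
  names(reads) <- sprintf("i%d", seq_along(reads))
  aln <- align_to_junction(reads, j)
  po <- pileup_indels(aln)
  expect_equal(nrow(po), 1L)
  expect_equal(po$indel, "+A")
  # leftmost placement: anchored at the C before the homopolymer run
  expect_equal(po$position, 37L)
  expect_equal(po$ref_base, "C")
  expect_equal(po$var_reads, length(reads))
})

test_that("binomial significance matches exact tail sums", {
  expect_equal(indel_significance(0, 100), 1.0)
  expect_equal(indel_significance(10, 0), 0.01^10)
  oracle <- sum(vapply(5:50, function(k)
    choose(50, k) * 0.01^k * 0.99^(50 - k), 0))
  expect_equal(indel_significance(5, 45), oracle, tolerance = 1e-12)
  expect_error(indel_significance(0, 0), "zero total reads")
  expect_error(indel_significance(1, 9, error_rate = 0.6), "error_rate")
})

test_that("perfect-fusion classification counts clean windows only", {
  j <- quant_junction
  sim <- simulate_reads(j, c(none = 1), n_reads = 200, read_length = 80,
                        error_rate = 0, seed = 3)
  aln <- align_to_junction(sim$reads, j)
  expect_equal(classify_perfect_fusion(aln), 1.0)
  sim2 <- simulate_reads(j, c("+G" = 1), n_reads = 100, read_length = 80,
                         error_rate = 0, seed = 4)
  aln2 <- align_to_junction(sim2$reads, j)
  expect_equal(classify_perfect_fusion(aln2), 0.0)
  expect_equal(classify_perfect_fusion(
    align_to_junction(c(a = nuc_sub(j$seq, 0, 40)), j)), NaN)
})

test_that("perfect fraction is non-increasing in substitution error rate", {
  j <- quant_junction
  fracs <- vapply(c(0, 0.002, 0.01, 0.05), function(e) {
    sim <- simulate_reads(j, c(none = 1), n_reads = 400, read_length = 100,
                          error_rate = e, seed = 5)
    classify_perfect_fusion(align_to_junction(sim$reads, j))
  }, 0)
  expect_true(all(diff(fracs) <= 0))
})

test_that("filtering drops weak observations and renormalizes representation", {
  j <- quant_junction
  mk_reads <- function(tok, n, offset = 0) {
    tpl <- apply_junction_outcome(j, tok)
    setNames(rep(substr(tpl, 21 + offset, 140 + offset), n),
             sprintf("%s_%d_%d", gsub("[+-]", "", tok), offset, 1:n))
  }
  reads <- c(mk_reads("none", 100), mk_reads("+G", 60), mk_reads("-A", 30),
             mk_reads("+GG", 1))
  rep0 <- spectrum_report(align_to_junction(reads, j))
  expect_equal(sum(rep0$observations$representation), 1)
  filt <- filter_observations(rep0, min_freq = 0.01, min_var_reads = 2)
  expect_setequal(filt$observations$indel, c("-A", "+G"))
  expect_equal(sort(filt$observations$representation), c(1/3, 2/3))
  # identity filter
  same <- filter_observations(rep0, 0, 0)
  expect_equal(same$observations$indel, rep0$observations$indel)
})

test_that("reports are invariant to read input order", {
  j <- quant_junction
  sim <- simulate_reads(j, c(none = 0.7, "+G" = 0.3), n_reads = 500,
                        read_length = 100, error_rate = 0.002, seed = 6)
  r1 <- spectrum_report(align_to_junction(sim$reads, j))
  set.seed(10)
  shuffled <- sim$reads[sample(length(sim$reads))]
  r2 <- spectrum_report(align_to_junction(shuffled, j))
  expect_equal(r1$observations, r2$observations)
  expect_equal(r1$perfect_fraction, r2$perfect_fraction)
})

test_that("SAM output round-trips through samtools-free parsing", {
  j <- quant_junction
  reads <- c(a = nuc_sub(j$seq, 10, 90),
             b = substr(apply_junction_outcome(j, "-A"), 31, 110))
  aln <- align_to_junction(reads, j)
  path <- tempfile(fileext = ".sam")
  write_sam(aln, reads, path)
  lines <- readLines(path)
  expect_match(lines[2], "^@SQ\tSN:")
  body <- strsplit(lines[3:4], "\t")
  expect_equal(body[[1]][6], "80M")
  expect_match(body[[2]][6], "^[0-9]+M1D[0-9]+M$")
})
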