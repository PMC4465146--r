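test_that("fill-in insertion tokens duplicate the overhang; blunt cuts give none", {
  proto <- "ACGTACGTACGTACGGGGCA"
  ref <- nuc_seq(paste0(proto, "TGG", strrep("C", 10)))
  site <- find_guide_sites(ref, guide_spec("t", proto), "NGG")[1, ]
  expect_equal(fill_in_insertion(cut_site(site, cut_model(3, 4), ref)), "+G")
  expect_equal(fill_in_insertion(cut_site(site, cut_model(3, 5), ref)), "+GG")
  expect_true(is.na(fill_in_insertion(cut_site(site, cut_model(3, 3), ref))))
})

test_that("blunt-only enumeration yields exactly the precise product", {
  toy <- toy_two_site_ref()
  pr <- enumerate_repair_products(toy$ref, toy$site_a, toy$site_b, "deletion",
                                  offsets_a = 3, offsets_b = 3)
  expect_equal(nrow(pr), 1L)
  expect_true(is.na(pr$token))
  expect_equal(pr$mode, "blunt_ligation")
})

test_that("staggered cutting at one site produces the fill-in insertion and resection deletion", {
  toy <- toy_two_site_ref()
  # inversion: both fragments of each cut are retained, so a staggered cut at
  # site A shows up at one of the two junctions
  pr <- enumerate_repair_products(toy$ref, toy$site_a, toy$site_b, "inversion",
                                  offsets_a = c(3, 4), offsets_b = 3,
                                  modes = c("blunt_ligation", "fill_in"))
  ins <- pr[!is.na(pr$token), ]
  expect_true(any(pr$mode == "blunt_ligation" & is.na(pr$token)))
  expect_equal(unique(ins$mode), "fill_in")
  # A's overhang is "G" on the + strand; at the 3' junction the duplicated
  # base enters through the inverted segment as its complement
  cs4 <- cut_site(toy$site_a, cut_model(3, 4), toy$ref)
  expect_equal(fill_in_insertion(cs4), "+G")
  expect_setequal(ins$token[ins$offset_a == 4], "+C")
  expect_equal(unique(ins$label[ins$offset_a == 4]), "inversion_3prime")

  # deletion with the PAM of site B facing the segment: resection of a 1-nt
  # overhang at B deletes the 4th nt upstream of B's PAM
  prd <- enumerate_repair_products(toy$ref, toy$site_a, toy$site_b, "deletion",
                                   offsets_a = 3, offsets_b = c(3, 4),
                                   modes = c("blunt_ligation", "resection"))
  del <- prd[!is.na(prd$token), ]
  expect_equal(nrow(del), 1L)
  cs_b4 <- cut_site(toy$site_b, cut_model(3, 4), toy$ref)
  # B is a - strand site: the deleted + strand base is the complement of the
  # overhang read on B's PAM-bearing strand
  expect_equal(del$token, paste0("-", rc(cs_b4$overhang)))
})

test_that("a deletion with a PAM-in-flank guide shows the literal fill-in token", {
  # site B on the + strand places its PAM inside the retained right flank, so
  # fill-in of B's overhang inserts the overhang bases verbatim
  protoA <- "GGATCCTTAAGGCCTTAAGG"
  protoB <- "ACGTACGTACGTACGGGGCA"
  set.seed(31)
  ref <- nuc_seq(paste0(rand_dna(60), "CCT", rc(protoA), rand_dna(80),
                        protoB, "TGG", rand_dna(60)))
  sa <- find_guide_sites(ref, guide_spec("a", protoA), "NGG")[1, ]
  sb <- find_guide_sites(ref, guide_spec("b", protoB), "NGG")[1, ]
  pr <- enumerate_repair_products(ref, sa, sb, "deletion",
                                  offsets_a = 3, offsets_b = c(3, 4),
                                  modes = c("blunt_ligation", "fill_in"))
  ins <- pr[!is.na(pr$token), ]
  expect_equal(nrow(ins), 1L)
  expect_equal(ins$token,
               fill_in_insertion(cut_site(sb, cut_model(3, 4), ref)))
  expect_equal(ins$token, "+G")
})

test_that("product count is bounded by the mechanism space", {
  toy <- toy_two_site_ref()
  for (kind in c("deletion", "inversion")) {
    pr <- enumerate_repair_products(toy$ref, toy$site_a, toy$site_b, kind,
                                    offsets_a = 3:6, offsets_b = 3:6)
    njunc <- if (kind == "deletion") 1L else 2L
    expect_lte(nrow(pr), 4 * 4 * 3 * njunc)
    # duplicated variants keep all generating mechanisms
    expect_true(all(table(pr$variant_key) >= 1))
  }
})

test_that("explain_indel inverts the enumeration and appends a generic NHEJ call", {
  toy <- toy_two_site_ref()
  pr <- enumerate_repair_products(toy$ref, toy$site_a, toy$site_b, "inversion",
                                  offsets_a = 3:5, offsets_b = 3:5)
  tok_rows <- pr[!is.na(pr$token), ]
  for (i in seq_len(nrow(tok_rows))) {
    got <- explain_indel(tok_rows$token[i], tok_rows$position[i], toy$ref,
                         toy$site_a, toy$site_b, "inversion",
                         label = tok_rows$label[i],
                         offsets_a = 3:5, offsets_b = 3:5)
    expect_true(any(got$offset_a == tok_rows$offset_a[i] &
                      got$offset_b == tok_rows$offset_b[i] &
                      got$mode == tok_rows$mode[i]),
                info = paste("mechanism lost for", tok_rows$token[i]))
  }

  # an insertion no offset model can produce: only the generic call remains
  none <- explain_indel("+TTTT", 30, toy$ref, toy$site_a, toy$site_b,
                        "deletion")
  expect_equal(nrow(none[none$mode != "nhej", ]), 0L)
  short <- explain_indel("+TT", 30, toy$ref, toy$site_a, toy$site_b,
                         "deletion")
  expect_true("nhej" %in% short$mode)

  # a precise junction: canonical blunt (3,3) ligation heads the list
  prec <- explain_indel(NA, NA, toy$ref, toy$site_a, toy$site_b, "deletion")
  expect_equal(prec$mode[1], "blunt_ligation")
  expect_equal(c(prec$offset_a[1], prec$offset_b[1]), c(3L, 3L))

  expect_error(explain_indel("+G", 300, toy$ref, toy$site_a, toy$site_b,
                             "deletion"),
               "outside the fusion window")
})

test_that("mechanism lists are deterministically ordered", {
  toy <- toy_two_site_ref()
  got <- explain_indel("-C", 29, toy$ref, toy$site_a, toy$site_b, "deletion",
                       offsets_a = 3:8, offsets_b = 3:8)
  mech <- got[got$mode != "nhej", ]
  if (nrow(mech) > 1) {
    expect_true(all(diff(mech$offset_a + mech$offset_b) >= 0))
  }
  expect_equal(got$mode[nrow(got)], "nhej")
})
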