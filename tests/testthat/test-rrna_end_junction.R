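test_that("junction location finds the 5' anchor and handles edge cases", {
  expect_identical(locate_junction("GGCCUCCAAUCCGG"), 7L)
  expect_identical(locate_junction("AAUCCGGUU"), 0L)
  expect_error(locate_junction("GGGGGGGGGG"), "not found")

  # two anchor occurrences: the one agreeing with the 5' reference wins
  ref <- "AAUCCGGUUGAUCC"
  read <- paste0("CCAAUCCTTTTT", "CCUCC", "AAUCCGGUUGA")
  # first AAUCC (pos 3) is followed by junk, second (pos 18) by the reference
  expect_identical(locate_junction(read, reference_5prime = ref), 17L)
  # without a disambiguating reference the leftmost occurrence is taken
  expect_identical(locate_junction(read), 2L)
})

test_that("end variants are called by longest exact suffix match", {
  ref <- "AAUCCGGUUG"
  for (v in end_variant_catalog) {
    read <- paste0("GAGAGAGAGA", v, ref)
    j <- locate_junction(read, reference_5prime = ref)
    expect_identical(j, 10L + nchar(v))
    call <- classify_end_variant(read, j)
    expect_identical(call$variant, v)
    expect_identical(call$matched_suffix, v)
  }
  read <- paste0("GAGAGGGGG", ref)
  call <- classify_end_variant(read, locate_junction(read, reference_5prime = ref))
  expect_identical(call$variant, "other")
  expect_identical(call$matched_suffix, "")
  # degenerate: junction at read start leaves no 3' side
  expect_identical(classify_end_variant("AAUCCGG", 0L)$variant, "other")
})

test_that("longest-match precedence never demotes CCUCC to CCUC or CCU", {
  # every catalog entry whose suffix contains a shorter entry must win
  for (v in end_variant_catalog) {
    read <- paste0("AGAGAGAGAG", v, "AAUCCGG")
    j <- 10L + nchar(v)
    shorter <- end_variant_catalog[nchar(end_variant_catalog) < nchar(v)]
    got <- classify_end_variant(read, j)$variant
    expect_identical(got, v)
    expect_false(got %in% shorter)
  }
})

test_that("classification matches a brute-force suffix oracle on random reads", {
  set.seed(88)
  ref <- "AAUCCGGUUGAUCCUGCC"
  for (i in 1:300) {
    read <- paste0(rand_dna(sample(6:20, 1), alphabet = c("C", "C", "U", "A", "G")),
                   ref)
    j <- locate_junction(read, reference_5prime = ref)
    got <- classify_end_variant(read, j)$variant
    expect_identical(got, oracle_end_variant(read, j, end_variant_catalog))
  }
})

test_that("variant tallies are complete, ordered and permutation invariant", {
  calls <- data.frame(variant = rep(c("CCUCC", "CCUCA", "CCUC", "CCU"),
                                    c(27, 1, 3, 1)))
  t1 <- tally_variants(calls)
  expect_identical(t1$variant, c(end_variant_catalog, "other"))
  expect_identical(t1$n, c(27L, 1L, 3L, 1L, 0L))
  expect_identical(sum(t1$n), nrow(calls))

  set.seed(3)
  t2 <- tally_variants(calls[sample.int(nrow(calls)), , drop = FALSE])
  expect_identical(t2, t1)

  expect_identical(tally_variants(data.frame(variant = rep("CCU", 4)))$n,
                   c(0L, 0L, 0L, 4L, 0L))
  expect_error(tally_variants(calls[0, , drop = FALSE]), "no calls")
  expect_error(tally_variants(data.frame(variant = "XXXXX")), "absent from")
})
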