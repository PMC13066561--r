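test_that("generate_bdna produces a 3-bead-per-nucleotide duplex", {
  d <- generate_bdna("ACGTACGT")
  expect_s3_class(d$watson, "cg_chain")
  # 3 beads per nucleotide, minus the missing 5'-terminal phosphate
  expect_equal(nrow(d$watson$beads), 3 * 8 - 1)
  expect_equal(nrow(d$crick$beads), 3 * 8 - 1)
  expect_setequal(unique(d$watson$beads$bead_kind),
                  c("phosphate", "sugar", "base"))
  expect_equal(sum(d$watson$beads$bead_kind == "phosphate"), 7)
  ph <- d$watson$beads[d$watson$beads$bead_kind == "phosphate", ]
  ph <- ph[order(ph$residue_index), ]
  expect_equal(diff(ph$z), rep(3.38, 6), tolerance = 1e-10)
})

test_that("generate_bdna rejects invalid sequences", {
  expect_error(generate_bdna("ACGU"), "invalid sequence")
  expect_error(generate_bdna(""), "length")
})

test_that("reverse_complement is correct and involutive", {
  expect_equal(reverse_complement("AAGC"), "GCTT")
  expect_equal(reverse_complement("ACGT"), "ACGT")
  s <- "GATTACAGGA"
  expect_equal(reverse_complement(reverse_complement(s)), s)
})

test_that("duplex terms pair every base at the pairing distance", {
  topo <- small_duplex("ATCGGACCCT")
  expect_equal(nrow(topo$base_pairs), 10)
  pos <- bead_positions(topo)
  dbp <- sqrt(rowSums((pos[topo$base_pairs$i, ] -
                         pos[topo$base_pairs$j, ])^2))
  expect_equal(dbp, rep(bdna_pairing_distance(), 10), tolerance = 1e-6)
  expect_gt(nrow(topo$stacking), 0)
  expect_equal(bdna_pairing_distance(), 2 * 3.5 * sin(52 * pi / 180))
})

test_that("bundled positioning-sequence strands are complementary", {
  f1 <- system.file("extdata", "positioning_sequence_193bp_strand1.txt",
                    package = "chromacg", mustWork = TRUE)
  f2 <- system.file("extdata", "positioning_sequence_193bp_strand2.txt",
                    package = "chromacg", mustWork = TRUE)
  s1 <- paste(readLines(f1), collapse = "")
  s2 <- paste(readLines(f2), collapse = "")
  expect_equal(nchar(s1), 193)
  expect_equal(nchar(s2), 193)
  expect_equal(reverse_complement(s1), s2)
})
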