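test_that("hps_parameters covers the 20 amino acids plus acetyl-lysine", {
  tab <- hps_parameters()
  expect_equal(nrow(tab), 21)
  expect_true(all(tab$hps_lambda >= 0 & tab$hps_lambda <= 1))
  expect_equal(tab$charge[tab$code == "K"], 1)
  expect_equal(tab$charge[tab$code == "R"], 1)
  expect_equal(tab$charge[tab$code == "D"], -1)
  expect_equal(tab$charge[tab$code == "E"], -1)
  expect_equal(tab$charge[tab$code == "k"], 0)
  expect_equal(tab$residue_name[tab$code == "k"], "ALY")
})

test_that("sequence_net_charge applies the unit-charge rule", {
  expect_equal(sequence_net_charge("KKRDE"), 1)
  expect_equal(sequence_net_charge("GGGG"), 0)
  expect_equal(sequence_net_charge("KKKK"), 4)
  expect_equal(sequence_net_charge("kkkk"), 0)
  expect_equal(sequence_net_charge("SGRGKGGKGLGKGGAKRHRK"), 8)
})

test_that("build_protein_chain grows a deterministic self-avoiding walk", {
  a <- build_protein_chain("KAERKDGSLM", chain_id = "A", seed = 11)
  b <- build_protein_chain("KAERKDGSLM", chain_id = "A", seed = 11)
  expect_identical(a$beads, b$beads)
  c2 <- build_protein_chain("KAERKDGSLM", chain_id = "A", seed = 12)
  expect_false(isTRUE(all.equal(a$beads$x, c2$beads$x)))
  expect_equal(nrow(a$beads), 10)
  expect_true(all(a$beads$disordered))
  xyz <- as.matrix(a$beads[, c("x", "y", "z")])
  steps <- sqrt(rowSums(diff(xyz)^2))
  expect_equal(steps, rep(3.8, 9), tolerance = 1e-9)
  dmat <- as.matrix(dist(xyz))
  diag(dmat) <- Inf
  expect_gt(min(dmat), 0.9 * 3.5 - 1e-9)
})

test_that("build_protein_chain respects avoid coordinates", {
  block <- matrix(c(0, 0, -4), nrow = 1)
  ch <- build_protein_chain("GGGGG", avoid = block, seed = 2)
  xyz <- as.matrix(ch$beads[, c("x", "y", "z")])
  d <- sqrt(rowSums(sweep(xyz, 2, block[1, ])^2))
  expect_true(all(d >= 0.9 * 3.5 - 1e-9))
})

test_that("build_protein_chain keeps reference coordinates and flags", {
  ref <- data.frame(residue_index = 1:3, x = c(0, 3.8, 7.6),
                    y = 0, z = c(0, 1, 0))
  ch <- build_protein_chain("KAERK", reference_coords = ref, seed = 3)
  expect_equal(ch$beads$x[1:3], ref$x)
  expect_equal(ch$beads$disordered, c(FALSE, FALSE, FALSE, TRUE, TRUE))
})

test_that("build_protein_chain validates input", {
  expect_error(build_protein_chain(""), "empty")
  expect_error(build_protein_chain("KXZ"), "unknown amino-acid code")
})
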