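test_that("toy system build is deterministic and well-formed", {
  toy1 <- make_toy_chromatosome(toy_system_spec(seed = 42))
  toy2 <- make_toy_chromatosome(toy_system_spec(seed = 42))
  expect_identical(toy1$topology$beads, toy2$topology$beads)
  topo <- toy1$topology
  pos <- bead_positions(topo)
  expect_true(all(is.finite(pos)))

  # region map: 16 proximal, 40 core, 16 distal
  cls <- topo$region_map$bp$class
  expect_equal(sum(cls == "core"), 40)
  expect_equal(sum(cls == "linker_proximal"), 16)
  expect_equal(sum(cls == "linker_distal"), 16)

  # all seven labelled disordered chains present
  expect_setequal(topo$region_map$tails$label,
                  c("H3_A", "H3_B", "H4_A", "H4_B",
                    "H1_N", "H1_GD", "H1_C"))

  # no severe steric clash of grown (disordered) beads at build time
  ch <- topo$beads$chain_id
  dis <- topo$beads$disordered
  d <- as.matrix(dist(pos))
  diag(d) <- Inf
  sel <- outer(ch, ch, "!=") & outer(dis, dis, "|")
  expect_gt(min(d[sel]), 3)

  # the starting configuration has finite, moderate forces
  ef <- total_energy_forces(pos, topo)
  expect_true(all(is.finite(ef$forces)))
  expect_lt(max(abs(ef$forces)), 200)
})

test_that("toy tails carry the expected charges", {
  toy <- make_toy_chromatosome(toy_system_spec(seed = 42))
  b <- toy$topology$beads
  tails <- toy$topology$region_map$tails
  tail_q <- function(label) {
    tl <- tails[tails$label == label, ]
    sum(b$base_charge[b$chain_id == tl$chain_id &
                        b$residue_index >= tl$from &
                        b$residue_index <= tl$to])
  }
  expect_equal(tail_q("H4_A"), 8)   # basic tail
  expect_equal(tail_q("H4_B"), 8)
  expect_gt(tail_q("H1_C"), 20)     # long basic tail
  topo_ac <- apply_acetylation(toy$topology, "H4_A", c(5, 8, 12, 16))
  bb <- topo_ac$beads
  expect_equal(sum(bb$base_charge[bb$chain_id == "H4_A"]), 4)
  expect_equal(sum(bb$residue_name[bb$chain_id == "H4_A"] == "ALY"), 4)
})

test_that("toy spec validates its arguments", {
  expect_error(toy_system_spec(core_bp = 0))
  expect_error(toy_system_spec(wrap_turns = 0))
  expect_error(toy_system_spec(junction_depth_bp = 0))
})
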