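test_that("cg_topology merges chains with contiguous bead ids", {
  topo <- composite_system()
  expect_s3_class(topo, "cg_topology")
  expect_equal(topo$beads$bead_id, seq_len(nrow(topo$beads)))
  # 2 strands x (3 beads x 3 nt - 1 terminal phosphate) + 8 residues
  expect_equal(nrow(topo$beads), 24)
  expect_setequal(unique(topo$beads$chain_id), c("DNA_W", "DNA_C", "P"))
})

test_that("assign_charges follows the unit-charge and phosphate rules", {
  topo <- composite_system()
  b <- topo$beads
  expect_true(all(b$base_charge[b$bead_kind == "phosphate"] < 0))
  expect_equal(unique(b$base_charge[b$bead_kind %in% c("sugar", "base")]), 0)
  expect_equal(b$base_charge[b$residue_name == "LYS"],
               rep(1, sum(b$residue_name == "LYS")))
  expect_equal(b$base_charge[b$residue_name == "GLU"],
               rep(-1, sum(b$residue_name == "GLU")))
})

test_that("native contact and hydrogen-bond detection fill sane tables", {
  topo <- composite_system()
  nc <- topo$native_contacts
  expect_gt(nrow(nc), 0)
  expect_true(all(nc$i < nc$j))
  expect_true(all(nc$r0 > 0 & nc$r0 < 9))
  isp <- topo$beads$bead_kind == "amino_acid"
  expect_true(all(isp[nc$i] | isp[nc$j]))
  same <- topo$beads$chain_id[nc$i] == topo$beads$chain_id[nc$j]
  sep <- abs(topo$beads$residue_index[nc$i] -
               topo$beads$residue_index[nc$j])
  expect_true(all(!same | sep >= 3))
  hb <- topo$hbond_pairs
  expect_gt(nrow(hb), 0)
  expect_true(all(topo$beads$bead_kind[hb$j] == "phosphate"))
  expect_true(all(!topo$beads$disordered[hb$i]))
  expect_true(all(hb$r0 < 8))
})

test_that("apply_acetylation neutralises lysines and validates targets", {
  ch <- build_protein_chain("GKGKG", chain_id = "T", seed = 1)
  topo <- assign_charges(cg_topology(list(ch)))
  q0 <- topo$beads$base_charge
  expect_equal(sum(q0), 2)
  topo2 <- apply_acetylation(topo, "T", c(2, 4))
  expect_equal(topo2$beads$residue_name[c(2, 4)], c("ALY", "ALY"))
  expect_equal(sum(topo2$beads$base_charge), 0)
  expect_error(apply_acetylation(topo, "T", 3), "not lysine")
  expect_error(apply_acetylation(topo, "T", 9), "not found")
  expect_error(apply_acetylation(topo, "NOPE", 2), "not found")
})

test_that("classify_dna_regions defaults to a central 147-bp core", {
  seq197 <- paste(rep(c("A", "C", "G", "T"), length.out = 197),
                  collapse = "")
  d <- generate_bdna(seq197)
  topo <- add_duplex_terms(cg_topology(list(d$watson, d$crick)))
  topo <- classify_dna_regions(topo, h1_proximal_side = "left")
  cls <- topo$region_map$bp$class
  expect_equal(sum(cls == "core"), 147)
  expect_equal(sum(cls == "linker_proximal"), 25)
  expect_equal(sum(cls == "linker_distal"), 25)
  expect_equal(cls[1], "linker_proximal")
  expect_equal(cls[197], "linker_distal")
  topoR <- classify_dna_regions(topo, h1_proximal_side = "right")
  expect_equal(topoR$region_map$bp$class[1], "linker_distal")
})

test_that("classify_dna_regions validates input", {
  topo <- small_duplex()
  expect_error(classify_dna_regions(topo, core_bp = 8:12),
               "exceeds duplex length")
  ch <- build_protein_chain("GGG")
  expect_error(classify_dna_regions(cg_topology(list(ch))),
               "no duplex")
})

test_that("define_tails stores labels and rejects overlaps", {
  topo <- small_duplex()
  tails <- tibble::tibble(label = c("a", "b"), chain_id = "X",
                          from = c(1L, 3L), to = c(4L, 6L))
  expect_error(define_tails(topo, tails), "overlap")
  tails$to[1] <- 2L
  topo <- define_tails(topo, tails)
  expect_equal(topo$region_map$tails$label, c("a", "b"))
})

test_that("bp_bead_ids returns six beads per base pair", {
  topo <- small_duplex("ATCGGACCCT")
  ids <- bp_bead_ids(topo)
  expect_length(ids, 10)
  len <- vapply(ids, length, 1L)
  expect_true(all(len %in% c(5L, 6L)))   # terminal bps lack a phosphate
  expect_equal(len[2:9], rep(6L, 8))
  expect_setequal(unlist(ids), topo$beads$bead_id)
})
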