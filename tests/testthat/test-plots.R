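test_that("autoplot methods return ggplot objects", {
  d <- generate_bdna("ATCGGACCCTGG")
  t1 <- build_protein_chain("KKKKK", chain_id = "T1",
                            origin = c(60, 0, 0), seed = 9)
  topo <- cg_topology(list(d$watson, d$crick, t1))
  topo <- add_duplex_terms(topo)
  topo <- assign_charges(topo)
  topo <- classify_dna_regions(topo, core_bp = 4:9)
  topo <- define_tails(topo, tibble::tibble(label = "T1", chain_id = "T1",
                                            from = 1L, to = 5L))
  trA <- make_scripted_trajectory(
    topo, tibble::tibble(tail = "T1", region = "core", occupancy = 0.6))
  trB <- make_scripted_trajectory(
    topo, tibble::tibble(tail = "T1", region = "core", occupancy = 0.2))
  mA <- contact_heatmap(trA, "T1")
  mB <- contact_heatmap(trB, "T1")
  expect_s3_class(ggplot2::autoplot(mA), "ggplot")
  expect_s3_class(ggplot2::autoplot(difference_map(mA, mB)), "ggplot")
  s <- region_percentages(trA)
  expect_s3_class(ggplot2::autoplot(s), "ggplot")
  fit <- fit_exponential(make_decay_series(2e-5, noise_sd = 0.01), n_mc = 10)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
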