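# host with a 12-bp duplex, two labelled 5-residue tails and a region map
scripted_host <- function() {
  d <- generate_bdna("ATCGGACCCTGG")
  t1 <- build_protein_chain("KKKKK", chain_id = "T1",
                            origin = c(60, 0, 0), seed = 9)
  t2 <- build_protein_chain("RRRRR", chain_id = "T2",
                            origin = c(-60, 0, 0), seed = 10)
  topo <- cg_topology(list(d$watson, d$crick, t1, t2))
  topo <- add_duplex_terms(topo)
  topo <- assign_charges(topo)
  topo <- classify_dna_regions(topo, core_bp = 4:9,
                               h1_proximal_side = "left")
  define_tails(topo, tibble::tibble(label = c("T1", "T2"),
                                    chain_id = c("T1", "T2"),
                                    from = 1L, to = 5L))
}

test_that("frame_contact detects any-residue proximity", {
  frame <- rbind(c(0, 0, 0), c(20, 0, 0), c(9, 0, 0))
  expect_true(frame_contact(frame, residue_beads = 3, bp_beads = 1,
                            cutoff = 10))
  expect_false(frame_contact(frame, residue_beads = 2, bp_beads = 1,
                             cutoff = 10))
  expect_error(frame_contact(frame, integer(), 1), "non-empty")
})

test_that("scripted occupancies are recovered exactly", {
  topo <- scripted_host()
  sched <- tibble::tibble(
    tail = c("T1", "T1", "T2"),
    region = c("core", "linker_proximal", "linker_distal"),
    occupancy = c(0.4, 0.2, 0.5))
  tr <- make_scripted_trajectory(topo, sched, n_frames = 100, cutoff = 10)
  s <- region_percentages(tr, cutoff = 10)
  get <- function(tl, rg) s$mean[s$tail == tl & s$region == rg]
  expect_equal(get("T1", "core"), 40)
  expect_equal(get("T1", "linker_proximal"), 20)
  expect_equal(get("T1", "linker_distal"), 0)
  expect_equal(get("T1", "linker_any"), 20)
  expect_equal(get("T2", "linker_distal"), 50)
  expect_equal(get("T2", "core"), 0)
  expect_true(all(is.na(s$sd)))  # single replica: no spread estimate
  expect_equal(unique(s$n_replicas), 1L)
})

test_that("replica means and standard deviations follow the sample formulas", {
  topo <- scripted_host()
  mk <- function(q) make_scripted_trajectory(
    topo, tibble::tibble(tail = "T1", region = "core", occupancy = q),
    n_frames = 100)
  reps <- structure(list(trajectories = list(mk(0.4), mk(0.5), mk(0.6)),
                         seeds = 1:3, n_replicas = 3),
                    class = "cg_replica_set")
  s <- region_percentages(reps, tails = "T1")
  expect_equal(s$mean[s$region == "core"], 50)
  expect_equal(s$sd[s$region == "core"], 10)
  expect_equal(unique(s$n_replicas), 3L)
  pr <- attr(s, "per_replica")
  expect_equal(sort(pr$percent[pr$region == "core"]), c(40, 50, 60))
})

test_that("infeasible schedules are rejected", {
  topo <- scripted_host()
  bad <- tibble::tibble(tail = c("T1", "T1"),
                        region = c("core", "linker_proximal"),
                        occupancy = c(0.7, 0.6))
  expect_error(make_scripted_trajectory(topo, bad), "infeasible")
  expect_error(make_scripted_trajectory(
    topo, tibble::tibble(tail = "T1", region = "core", occupancy = 1.2)),
    "\\[0, 1\\]")
  expect_error(make_scripted_trajectory(
    topo, tibble::tibble(tail = "NO", region = "core", occupancy = 0.5)),
    "unknown tail")
})

test_that("contact heatmaps and difference maps are consistent", {
  topo <- scripted_host()
  trA <- make_scripted_trajectory(
    topo, tibble::tibble(tail = "T1", region = "core", occupancy = 0.6))
  trB <- make_scripted_trajectory(
    topo, tibble::tibble(tail = "T1", region = "core", occupancy = 0.2))
  mA <- contact_heatmap(trA, "T1")
  mB <- contact_heatmap(trB, "T1")
  expect_s3_class(mA, "contact_map")
  expect_equal(nrow(mA), 5 * 12)  # residues x bp
  expect_true(all(mA$occupancy >= 0 & mA$occupancy <= 100))  # percent
  dm <- difference_map(mA, mB)
  expect_s3_class(dm, "difference_map")
  expect_gt(max(dm$delta), 0)
  mC <- contact_heatmap(trA, "T1", cutoff = 8)
  expect_error(difference_map(mA, mC), "different cutoffs")
  expect_error(contact_heatmap(trA, "NOPE"), "unknown tail")
})

test_that("contact maps round-trip through TSV", {
  topo <- scripted_host()
  tr <- make_scripted_trajectory(
    topo, tibble::tibble(tail = "T1", region = "core", occupancy = 0.3))
  m <- contact_heatmap(tr, "T1")
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f), add = TRUE)
  write_contact_map(m, f)
  back <- utils::read.delim(f)
  expect_equal(nrow(back), nrow(m))
  expect_equal(back$occupancy, m$occupancy)
})
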