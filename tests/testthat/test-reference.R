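test_that("reference rate-constant targets are machine-readable", {
  rc <- reference_rate_constants()
  expect_s3_class(rc, "tbl_df")
  expect_equal(nrow(rc), 4)
  expect_true(all(c("system", "k_app_per_s", "uncertainty_per_s",
                    "desk_scale") %in% names(rc)))
  expect_true(all(rc$k_app_per_s > 0))
  expect_true(all(rc$uncertainty_per_s > 0))
  expect_true("chromatosome" %in% rc$system)
  # slower exchange in the chromatosome than the nucleosome, and slower
  # still after H4 tetra-acetylation
  k <- function(s) rc$k_app_per_s[rc$system == s]
  expect_lt(k("chromatosome"), k("nucleosome"))
  expect_lt(k("h4_tetra_acetylated_chromatosome"), k("chromatosome"))
})

test_that("reference contact-percentage targets are machine-readable", {
  cp <- reference_contact_percentages()
  expect_equal(nrow(cp), 6)
  expect_true(all(c("tail", "region", "condition", "percent",
                    "desk_scale") %in% names(cp)))
  expect_true(all(cp$percent >= 0 & cp$percent <= 100))
  get <- function(tl, rg, cd)
    cp$percent[cp$tail == tl & cp$region == rg & cp$condition == cd]
  # acetylation weakens every recorded contact class
  expect_lt(get("H3_distal", "core", "h4_tetra_acetylated"),
            get("H3_distal", "core", "unmodified"))
  expect_lt(get("H3_proximal", "linker", "h4_tetra_acetylated"),
            get("H3_proximal", "linker", "unmodified"))
})

test_that("reference targets are flagged as beyond desk scale", {
  expect_true(all(reference_rate_constants()$desk_scale == FALSE))
  expect_true(all(reference_contact_percentages()$desk_scale == FALSE))
})
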