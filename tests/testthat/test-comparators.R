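normal_tertiles <- function() {
  data.frame(tertile = 1:3,
             villous_number = "normal", villous_extent = "none",
             villous_descriptor = "none", ulcer_number = "none",
             ulcer_extent = "none", ulcer_size = "none")
}
no_stenosis <- function() {
  data.frame(stenosis_number = "none", stenosis_ulcerated = "none",
             stenosis_traversed = "none")
}

test_that("Lewis Score multiplies descriptor points and takes the worst tertile", {
  expect_identical(lewis_score(normal_tertiles(), no_stenosis())$lewis, 0L)

  # no inflammation, one ulcerated traversed stenosis: stenosis product alone
  st <- data.frame(stenosis_number = "single",
                   stenosis_ulcerated = "ulcerated",
                   stenosis_traversed = "traversed")
  expect_identical(lewis_score(normal_tertiles(), st)$lewis,
                   14L * 24L * 7L)  # hand product from the published table

  # single small ulcer, short segment, in tertile 1
  t1 <- normal_tertiles()
  t1[1, c("ulcer_number", "ulcer_extent", "ulcer_size")] <-
    c("single", "short_segment", "lt_quarter")
  expect_identical(lewis_score(t1, no_stenosis())$lewis, 3L * 5L * 9L)

  # dominated tertile: zeroing it leaves the max unchanged
  t2 <- t1
  t2[2, c("ulcer_number", "ulcer_extent", "ulcer_size")] <-
    c("single", "short_segment", "lt_quarter")
  t2[1, c("ulcer_number", "ulcer_extent", "ulcer_size")] <-
    c("multiple", "whole_tertile", "gt_half")
  with_dominated <- lewis_score(t2, no_stenosis())$lewis
  t2z <- t2
  t2z[2, c("ulcer_number", "ulcer_extent", "ulcer_size")] <-
    c("none", "none", "none")
  expect_identical(lewis_score(t2z, no_stenosis())$lewis, with_dominated)
  expect_identical(with_dominated, 10L * 15L * 18L)

  # invariant to tertile row order
  expect_identical(lewis_score(t2[c(3, 1, 2), ], no_stenosis())$lewis,
                   with_dominated)

  expect_error(lewis_score(t1[1:2, ], no_stenosis()), "exactly 3")
  t_bad <- t1; t_bad$ulcer_size[1] <- "huge"
  expect_error(lewis_score(t_bad, no_stenosis()), "unknown Lewis")
})

test_that("Lewis Score is monotone in each descriptor class upgrade", {
  t1 <- normal_tertiles()
  t1[1, c("ulcer_number", "ulcer_extent", "ulcer_size")] <-
    c("single", "short_segment", "lt_quarter")
  base <- lewis_score(t1, no_stenosis())$lewis
  upgrades <- list(
    c("ulcer_number", "few"), c("ulcer_number", "multiple"),
    c("ulcer_extent", "long_segment"), c("ulcer_extent", "whole_tertile"),
    c("ulcer_size", "quarter_to_half"), c("ulcer_size", "gt_half"))
  for (u in upgrades) {
    t_up <- t1; t_up[1, u[1]] <- u[2]
    expect_gte(lewis_score(t_up, no_stenosis())$lewis, base)
  }
})

test_that("CECDAI is A*B + C summed over segments, checked by enumeration", {
  zero <- data.frame(segment = c("proximal", "distal"),
                     inflammation = 0, extent = 0, stricture = 0)
  expect_identical(cecdai_score(zero)$cecdai, 0L)

  # full enumeration of one segment grid against the closed form, with the
  # other segment fixed; additivity gives the two-segment total
  grid <- expand.grid(a = 0:5, b = 0:3, c = 0:3)
  for (i in seq_len(nrow(grid))) {
    seg <- data.frame(segment = c("proximal", "distal"),
                      inflammation = c(grid$a[i], 5),
                      extent = c(grid$b[i], 3),
                      stricture = c(grid$c[i], 3))
    expect_identical(cecdai_score(seg)$cecdai,
                     as.integer(grid$a[i] * grid$b[i] + grid$c[i] + 18L))
  }

  maxi <- data.frame(segment = c("proximal", "distal"),
                     inflammation = 5, extent = 3, stricture = 3)
  expect_identical(cecdai_score(maxi)$cecdai, 36L)

  prox_only <- data.frame(segment = c("proximal", "distal"),
                          inflammation = c(2, 0), extent = c(1, 0),
                          stricture = 0)
  expect_identical(cecdai_score(prox_only)$cecdai, 2L)

  bad <- zero; bad$inflammation[1] <- 6
  expect_error(cecdai_score(bad), "0..5")
  expect_error(cecdai_score(zero[1, ]), "proximal and one distal")
})

test_that("annotation adapters produce valid findings that score sensibly", {
  # lesion-free, stenosis-free study maps to zero on both comparators
  clean <- make_study("clean", c(0, 0, 0, 0))
  lf <- as_lewis_findings(clean)
  expect_identical(lewis_score(lf$tertiles, lf$stenosis)$lewis, 0L)
  expect_identical(cecdai_score(as_cecdai_findings(clean))$cecdai, 0L)

  # worse annotations never decrease either comparator
  mild <- make_study("a", c(2, 0, 0, 0))
  severe <- make_study("a", c(4, 4, 2, 0), traversed = FALSE)
  lw_mild <- as_lewis_findings(mild)
  lw_sev <- as_lewis_findings(severe)
  expect_gte(lewis_score(lw_sev$tertiles, lw_sev$stenosis)$lewis,
             lewis_score(lw_mild$tertiles, lw_mild$stenosis)$lewis)
  expect_gte(cecdai_score(as_cecdai_findings(severe))$cecdai,
             cecdai_score(as_cecdai_findings(mild))$cecdai)

  # adapters keep every study of a simulated cohort scoreable
  ann <- simulate_cohort(cohort_spec(n_studies = 25, seed = 5))
  lf2 <- as_lewis_findings(ann)
  lw <- lewis_score(lf2$tertiles, lf2$stenosis)
  ce <- cecdai_score(as_cecdai_findings(ann))
  expect_identical(nrow(lw), 25L)
  expect_identical(nrow(ce), 25L)
  expect_true(all(lw$lewis >= 0))
  expect_true(all(ce$cecdai >= 0 & ce$cecdai <= 36))
})
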