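test_that("delta response is mean unblocked minus mean blocked, sign kept", {
  w <- make_wells(no_ab = c(100, 100), pd1 = c(40, 40))
  unb <- w[w$condition == "NO_AB", ]
  blk <- w[w$condition == "BLOCK_PD1", ]
  expect_equal(compute_delta_response(unb, blk)$delta, 60)

  w2 <- make_wells(no_ab = 50, pd1 = 50)
  r2 <- compute_delta_response(w2[w2$condition == "NO_AB", ],
                               w2[w2$condition == "BLOCK_PD1", ])
  expect_equal(r2$delta, 0)
  expect_length(r2$qc, 0)

  w3 <- make_wells(no_ab = 40, pd1 = 60)
  r3 <- compute_delta_response(w3[w3$condition == "NO_AB", ],
                               w3[w3$condition == "BLOCK_PD1", ])
  expect_equal(r3$delta, -20)
  expect_identical(r3$qc, "negative_delta")
})

test_that("delta response rejects mismatched or missing wells", {
  a <- make_wells(sample_id = "S1")
  b <- make_wells(sample_id = "S2")
  expect_error(compute_delta_response(a[a$condition == "NO_AB", ],
                                      b[b$condition == "BLOCK_PD1", ]),
               "sample_mismatch")
  expect_error(compute_delta_response(a[a$condition == "NO_AB", ],
                                      a[0, ]), "missing_condition")
  expect_error(compute_delta_response(a[a$condition == "BLOCK_PD1", ],
                                      a[a$condition == "BLOCK_PD1", ]),
               "missing_condition")
})

test_that("the score formula evaluates delta / log2(coverage) * pc_ratio", {
  expect_equal(compute_icar_score(0, 4, 1), 0)
  expect_equal(compute_icar_score(10, 2, 1), 10)
  expect_equal(compute_icar_score(6, 4, 0.5), 1.5)
  expect_error(compute_icar_score(10, 1, 1), "coverage_too_small")
  expect_error(compute_icar_score(10, 0.5, 1), "coverage_too_small")
})

test_that("the score is linear in delta and pc_ratio, decreasing in coverage", {
  set.seed(7)
  for (i in 1:20) {
    delta <- runif(1, -50, 150)
    cov <- runif(1, 1.5, 20)
    pcr <- runif(1, 0.3, 3)
    s <- compute_icar_score(delta, cov, pcr)
    expect_equal(compute_icar_score(2 * delta, cov, pcr), 2 * s)
    expect_equal(compute_icar_score(delta, cov, 2 * pcr), 2 * s)
  }
  covs <- seq(2.5, 20, length.out = 10)
  scores <- compute_icar_score(10, covs, 1)
  expect_true(all(diff(scores) < 0))
})

test_that("a toy plate scores each ligand by its own blocking delta", {
  w <- make_wells(no_ab = 100, pd1 = 40, pdl1 = 70, pdl2 = 90, coverage = 4)
  s <- score_patient(w, 1)
  expect_equal(s$pd1_score, 30)
  expect_equal(s$pdl1_score, 15)
  expect_equal(s$pdl2_score, 5)
  expect_identical(s$qc_flags, "")

  s2 <- score_patient(w, 2)  # PC ratio scales every score linearly
  expect_equal(c(s2$pd1_score, s2$pdl1_score, s2$pdl2_score), c(60, 30, 10))
})

test_that("missing conditions flag and NA rather than fail; no NO_AB fails", {
  w <- make_wells(pdl2 = NULL)
  s <- score_patient(w, 1)
  expect_true(is.na(s$pdl2_score))
  expect_match(s$qc_flags, "missing_BLOCK_PDL2")
  expect_false(is.na(s$pd1_score))

  w2 <- make_wells()
  expect_error(score_patient(w2[w2$condition != "NO_AB", ], 1),
               "missing_condition")
})

test_that("scores are invariant to replicate ordering", {
  w <- make_wells(no_ab = c(90, 110, 100), pd1 = c(35, 45, 40),
                  pdl1 = c(60, 80, 70), pdl2 = c(85, 95, 90))
  s1 <- score_patient(w, 1.3)
  set.seed(11)
  s2 <- score_patient(w[sample.int(nrow(w)), ], 1.3)
  expect_equal(s1, s2, ignore_attr = TRUE)
})

test_that("plate normalization is reference over per-plate PC mean", {
  wells <- rbind(make_wells(plate_id = "P1"), make_wells(plate_id = "P2",
                                                         sample_id = "S2"),
                 pc_wells("P1", 800), pc_wells("P2", 1250))
  norm <- plate_normalization(wells, pc_reference = 1000)
  expect_equal(norm$pc_ratio[norm$plate_id == "P1"], 1000 / 800)
  expect_equal(norm$pc_ratio[norm$plate_id == "P2"], 1000 / 1250)
  # default reference: grand mean of PC wells
  norm2 <- plate_normalization(wells)
  expect_equal(unique(norm2$pc_reference), mean(c(800, 800, 1250, 1250)))
  expect_error(plate_normalization(make_wells()), "missing_condition")
})

test_that("blank subtraction precedes scoring and clamps at zero", {
  blanks <- data.frame(plate_id = "PLATE01", sample_id = "BLK",
                       condition = "BLANK", signal = c(10, 10),
                       coverage_mm2 = NA_real_, replicate_index = 1:2)
  wells <- rbind(make_wells(no_ab = 110, pd1 = 50, pdl1 = 80, pdl2 = 100),
                 pc_wells(signal = 1000), blanks)
  # blanks are subtracted from every measured well, PC included, so the
  # default (grand-mean) reference gives a unit PC ratio here and the
  # signals match the canonical toy plate
  s <- score_plates(wells)
  expect_equal(c(s$pd1_score, s$pdl1_score, s$pdl2_score), c(30, 15, 5))
})
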