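table4 <- tibble::tribble(
  ~genotype, ~ggt, ~auc, ~cmax, ~cmin,
  "A&AG", 10,  79.746, 0.859, 0.176,
  "A&AG", 30, 134.529, 1.165, 0.460,
  "A&AG", 50, 171.561, 1.377, 0.666,
  "A&AG", 100, 238.620, 1.767, 1.051,
  "GG",   10,  97.977, 0.959, 0.266,
  "GG",   30, 196.080, 1.519, 0.806,
  "GG",   50, 286.080, 2.046, 1.328,
  "GG",   100, 538.383, 3.538, 2.815
)

test_that("the exposure grid reproduces every published cell within 0.5%", {
  got <- simulate_exposure_grid()
  for (i in seq_len(nrow(table4))) {
    row <- got[got$genotype == table4$genotype[i] & got$ggt == table4$ggt[i], ]
    expect_equal(row$auc_weekly_ss, table4$auc[i], tolerance = 5e-3)
    expect_equal(row$cmax_ss, table4$cmax[i], tolerance = 5e-3)
    expect_equal(row$cmin_ss, table4$cmin[i], tolerance = 5e-3)
  }
  expect_true(all(got$valid))
})

test_that("exposure metrics are monotone in GGT and higher for GG", {
  got <- simulate_exposure_grid()
  for (gt in c("A&AG", "GG")) {
    sub <- dplyr::arrange(got[got$genotype == gt, ], ggt)
    expect_true(all(diff(sub$auc_weekly_ss) > 0))
    expect_true(all(diff(sub$cmax_ss) > 0))
    expect_true(all(diff(sub$cmin_ss) > 0))
  }
  aag <- dplyr::arrange(got[got$genotype == "A&AG", ], ggt)
  gg <- dplyr::arrange(got[got$genotype == "GG", ], ggt)
  expect_true(all(gg$auc_weekly_ss > aag$auc_weekly_ss))
  expect_true(all(gg$cmax_ss > aag$cmax_ss))
  expect_true(all(gg$cmin_ss > aag$cmin_ss))
})

test_that("fold changes reproduce the published ratio statements", {
  fc <- fold_changes(simulate_exposure_grid())
  pick <- function(cmp, metric, geno = NA, ggt = NA) {
    r <- fc[fc$comparison == cmp & fc$metric == metric, ]
    if (!is.na(geno)) r <- r[!is.na(r$genotype) & r$genotype == geno, ]
    if (!is.na(ggt)) r <- r[!is.na(r$ggt) & r$ggt == ggt, ]
    r$ratio
  }
  # GG vs A&AG at GGT 30, after rounding to the printed precision
  expect_equal(round(pick("GG vs A&AG", "cmin", ggt = 30), 2), 1.75)
  expect_equal(round(pick("GG vs A&AG", "cmax", ggt = 30), 1), 1.3)
  expect_equal(round(pick("GG vs A&AG", "auc", ggt = 30), 2), 1.46)
  # GGT 100 vs 10 within A&AG
  expect_equal(round(pick("GGT 100 vs 10", "cmin", geno = "A&AG"), 2), 5.97)
  expect_equal(round(pick("GGT 100 vs 10", "cmax", geno = "A&AG"), 2), 2.06)
  expect_equal(round(pick("GGT 100 vs 10", "auc", geno = "A&AG"), 2), 2.99)
  # any stratum against itself is exactly 1
  one <- simulate_exposure_grid(tibble::tibble(genotype = "A&AG",
                                               ggt = c(30, 30)))
  fc1 <- fold_changes(one)
  expect_equal(fc1$ratio[fc1$comparison == "GGT 30 vs 30"], rep(1, 3))
})

test_that("peak concentration relative to the target ceiling is reported", {
  fc <- fold_changes(simulate_exposure_grid())
  r <- fc[fc$comparison == "Cmax vs target ceiling" &
            !is.na(fc$genotype) & fc$genotype == "GG" &
            !is.na(fc$ggt) & fc$ggt == 100, ]
  expect_equal(r$ratio, 1.68, tolerance = 5e-3)
})

test_that("typical curves are consistent with the exposure metrics", {
  grid <- tibble::tibble(genotype = "A&AG", ggt = 30)
  cur <- typical_curves(grid, resolution = 1 / 60, span = 56)
  em <- simulate_exposure_grid(grid)
  expect_equal(max(cur$conc), em$cmax_ss, tolerance = 1e-3)
  # pointwise dominance of higher GGT within a genotype
  cur2 <- typical_curves(tibble::tibble(genotype = "A&AG", ggt = c(30, 100)),
                         resolution = 0.5)
  c30 <- cur2$conc[cur2$ggt == 30]; c100 <- cur2$conc[cur2$ggt == 100]
  expect_true(all(c100 > c30))
  # degenerate time vector
  empty <- typical_curves(grid, resolution = 1, span = -1)
  expect_identical(nrow(empty), 0L)
  expect_s3_class(ggplot2::autoplot(cur2), "ggplot")
})

test_that("strata with non-positive clearance are flagged, not dropped", {
  cm <- covariate_model(genotype_shift = -5)
  got <- simulate_exposure_grid(tibble::tibble(genotype = c("A&AG", "GG"),
                                               ggt = c(100, 100)), cm = cm)
  expect_identical(nrow(got), 2L)
  expect_false(got$valid[got$genotype == "GG"])
  expect_true(is.na(got$cmax_ss[got$genotype == "GG"]))
  expect_error(fold_changes(got), "invalid")
})
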