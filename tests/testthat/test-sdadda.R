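test_that("closed-form class frequencies match their anchors", {
  hex0 <- expected_class_freqs(0, "hexasomic")
  expect_equal(as.numeric(hex0[1, -1]), c(1 / 2, 0, 3 / 10, 1 / 5))
  tet0 <- expected_class_freqs(0, "tetrasomic")
  expect_equal(as.numeric(tet0[1, -1]), c(1 / 2, 0, 1 / 3, 1 / 6))
  # r = 0.5 factorises into the product of the marginals
  tet5 <- as.numeric(expected_class_freqs(0.5, "tetrasomic")[1, -1])
  expect_equal(tet5, c(1 / 2 * 5 / 6, 1 / 2 * 1 / 6, 1 / 2 * 5 / 6,
                       1 / 2 * 1 / 6))
  hex5 <- as.numeric(expected_class_freqs(0.5, "hexasomic")[1, -1])
  expect_equal(hex5, c(1 / 2 * 4 / 5, 1 / 2 * 1 / 5, 1 / 2 * 4 / 5,
                       1 / 2 * 1 / 5))
  expect_error(expected_class_freqs(0.6), "0, 0.5")
  expect_error(expected_class_freqs(-0.1), "0, 0.5")
})

test_that("enumeration oracle equals the closed forms on a 51-point grid", {
  grid <- seq(0, 0.5, length.out = 51)
  for (model in c("hexasomic", "tetrasomic")) {
    closed <- as.matrix(expected_class_freqs(grid, model)[, -1])
    enum <- as.matrix(enumerate_class_freqs(grid, model)[, -1])
    expect_lt(max(abs(closed - enum)), 1e-12)
  }
})

test_that("class frequencies are proper and monotone with conserved marginals", {
  grid <- seq(0, 0.5, length.out = 101)
  for (model in c("hexasomic", "tetrasomic")) {
    f <- expected_class_freqs(grid, model)
    probs <- as.matrix(f[, -1])
    expect_true(all(probs >= 0 & probs <= 1))
    expect_equal(rowSums(probs), rep(1, length(grid)))
    expect_true(all(diff(f$p_ab) < 0))        # AB decreasing in r
    expect_true(all(diff(f$p_a) > 0))         # A increasing in r
    expect_equal(f$p_ab + f$p_a, rep(1 / 2, length(grid))) # SDA marginal
    pb <- if (model == "tetrasomic") 5 / 6 else 4 / 5
    expect_equal(f$p_ab + f$p_b, rep(pb, length(grid)))    # DDA marginal
  }
})

test_that("independence test recovers the worked chi-square values", {
  # counts at exactly the null expectation
  null_counts <- 100 * as.numeric(expected_class_freqs(0.5, "hexasomic")[1, -1])
  res0 <- independence_test(null_counts, "hexasomic")
  expect_equal(res0$chisq, 0)
  expect_equal(res0$p_value, 1)
  expect_false(res0$linked)
  # counts at the r = 0 pattern: (50, 0, 30, 20) vs expected (40, 10, 40, 10)
  res <- independence_test(c(50, 0, 30, 20), "hexasomic")
  expect_equal(res$chisq, 100 / 40 + 100 / 10 + 100 / 40 + 100 / 10) # 25
  expect_lt(res$p_value, 1e-4)
  expect_true(res$linked)
  expect_identical(res$df, 3L)
  expect_error(independence_test(c(0, 0, 0, 0)), "no observations")
  expect_warning(independence_test(c(3, 1, 2, 1), "hexasomic"),
                 "below 1")
})

test_that("excess in the AB class is required for a linkage call", {
  # strong deviation but with AB *deficit* must not be called coupling-linked
  res <- independence_test(c(10, 40, 60, 10), "hexasomic")
  expect_lt(res$p_value, 0.05)
  expect_false(res$linked)
})

test_that("ML recombination estimation is self-consistent and bounded", {
  probs <- as.numeric(expected_class_freqs(0.2, "hexasomic")[1, -1])
  res <- estimate_r_ml(1000 * probs, "hexasomic")
  expect_lt(abs(res$r_hat - 0.2), 1e-3)
  expect_false(res$boundary)
  # r = 0 pattern pushes the estimate to the lower boundary
  res0 <- estimate_r_ml(c(50, 0, 30, 20), "hexasomic")
  expect_true(res0$boundary)
  expect_lt(res0$r_hat, 1e-4)
  # degenerate single-class counts sit on a boundary too
  resd <- estimate_r_ml(c(102, 0, 0, 0), "hexasomic")
  expect_true(resd$boundary)
  expect_error(estimate_r_ml(c(0, 0, 0, 0)), "no observations")
})

test_that("optimised r-hat agrees with a fine grid search", {
  set.seed(401)
  grid <- seq(1e-6, 0.5, by = 1e-4)
  for (model in c("hexasomic", "tetrasomic")) {
    lp <- log(t(as.matrix(expected_class_freqs(grid, model)[, -1])))
    for (i in 1:20) {
      r_true <- runif(1, 0, 0.5)
      counts <- as.numeric(rmultinom(
        1, 102, as.numeric(expected_class_freqs(r_true, model)[1, -1])))
      ll_grid <- as.numeric(counts %*% lp)
      r_grid <- grid[which.max(ll_grid)]
      r_opt <- estimate_r_ml(counts, model)$r_hat
      expect_lt(abs(r_opt - r_grid), 1e-3)
    }
  }
})

test_that("DDA markers are assigned to their true homolog-group pair", {
  set.seed(402)
  mother <- minimal_mother()
  hits <- 0; reps <- 60
  for (i in seq_len(reps)) {
    father <- sim_parent(n_chrom = 1, n_sda_per_homolog = 12,
                         n_dda_per_pair = 0, length_cM = 20,
                         spacing = "even", prefix = "F")
    # one duplex on homologs {2, 5} mid-block: the median-chi-square rule
    # needs the carrier group's median SDA within ~5 cM (r ~ 0.05) of the
    # DDA for reliable power at n = 102
    dda <- tibble::tibble(marker_id = "DD", chrom = "1", pos_cM = 10,
                          carriers = list(c(2L, 5L)))
    father <- parental_genome(dplyr::bind_rows(father$markers, dda),
                              copy_number = father$copy_number)
    cross <- sim_cross(mother, father, n_hybrids = 102, n_selfs = 0,
                       undetermined_rate = 0)
    pm <- presence_of(cross, "paternal", 1)
    groups <- two_point_grouping(pm)
    if (length(unique(groups$group)) != 6) next
    hom_of <- group_homologs(groups, father)
    res <- assign_dda(presence_of(cross, "paternal", 2)[, "DD"],
                      pm, groups)
    if (!res$ambiguous &&
        setequal(hom_of[c(res$group1, res$group2)], c(2L, 5L)))
      hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})

test_that("an unlinked DDA stays unassigned", {
  set.seed(403)
  mother <- minimal_mother(n_chrom = 2)
  father <- sim_parent(n_chrom = 2, n_sda_per_homolog = 8,
                       n_dda_per_pair = 0, spacing = "even", prefix = "F")
  dda <- tibble::tibble(marker_id = "DD", chrom = "2", pos_cM = 50,
                        carriers = list(c(1L, 2L)))
  father <- parental_genome(dplyr::bind_rows(father$markers, dda),
                            copy_number = father$copy_number)
  cross <- sim_cross(mother, father, n_hybrids = 102, n_selfs = 0,
                     undetermined_rate = 0)
  # scan the DDA (on chromosome 2) against chromosome 1 groups only
  chr1 <- cross$markers$marker_id[cross$markers$parent == "paternal" &
                                    cross$markers$chrom == "1" &
                                    cross$markers$dose == 1]
  pm <- true_presence(cross)[, chr1, drop = FALSE]
  groups <- two_point_grouping(pm)
  res <- assign_dda(true_presence(cross)[, "DD"], pm, groups)
  expect_true(res$ambiguous)
  expect_lte(res$n_passing, 1)
})

test_that("subgenome uniformity test matches hand-computed chi-squares", {
  flat <- subgenome_uniformity_test(rep(2L, 15))
  expect_equal(flat$chisq, 0)
  expect_equal(flat$p_value, 1)
  expect_identical(flat$df, 14L)
  # 30 DDAs uniform over the 6 pairs of a 4-homolog subset of 6 homologs
  conc <- subgenome_uniformity_test(c(rep(5L, 6), rep(0L, 9)))
  expect_equal(conc$chisq, 6 * (5 - 2)^2 / 2 + 9 * (0 - 2)^2 / 2) # 45
  expect_identical(conc$df, 14L)
  expect_lt(conc$p_value, 1e-4)
  expect_warning(subgenome_uniformity_test(c(1L, rep(0L, 14))),
                 "below the number")
  ex <- suppressWarnings(
    subgenome_uniformity_test(c(5L, rep(0L, 9)), exact = TRUE))
  expect_lt(ex$p_value, 0.05)
})
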