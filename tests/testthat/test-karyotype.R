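test_that("internal exact p equals fisher.test across random 2x2 tables", {
  set.seed(501)
  for (i in 1:200) {
    tab <- matrix(rpois(4, sample(c(0.5, 3, 20), 1)), 2)
    if (sum(tab) == 0) next
    ours <- polykaryo:::fisher_p2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    ref <- stats::fisher.test(tab)$p.value
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("pairwise association finds coupling, repulsion and independence", {
  a <- c(rep(1L, 50), rep(0L, 52))
  ident <- pairwise_association(a, a)
  expect_lt(ident$p_value, 1e-20)
  expect_identical(ident$direction, "coupling")
  comp <- pairwise_association(a, 1L - a)
  expect_lt(comp$p_value, 1e-20)
  expect_identical(comp$direction, "repulsion")
  # near-independent table (25, 25, 25, 27)
  b <- c(rep(1L, 25), rep(0L, 25), rep(1L, 25), rep(0L, 27))
  c2 <- c(rep(1L, 25), rep(0L, 25), rep(0L, 25), rep(1L, 27))
  near <- pairwise_association(b, c2)
  expect_gt(near$p_value, 0.9)
  # p is symmetric in marker order
  expect_equal(pairwise_association(c2, b)$p_value, near$p_value)
})

test_that("pairs with too few complete cases are skipped", {
  a <- c(1L, 0L, 1L, rep(NA_integer_, 20))
  b <- c(1L, 0L, 0L, rep(NA_integer_, 20))
  res <- pairwise_association(a, b)
  expect_true(res$skipped)
  expect_true(is.na(res$p_value))
})

test_that("two-point LOD matches the closed formula", {
  # perfectly cosegregating pair at n = 102
  a <- c(rep(1L, 51), rep(0L, 51))
  m <- cbind(x = a, y = a)
  grp <- two_point_grouping(m)
  pairs <- attr(grp, "pairs")
  expect_equal(pairs$r_hat, 1e-6)
  expect_equal(pairs$lod, 102 * log10(2 * (1 - 1e-6)), tolerance = 1e-6)
  expect_identical(length(unique(grp$group)), 1L)
  # an independent pair with r-hat exactly 0.5 has LOD 0
  b <- c(rep(1L, 25), rep(0L, 26), rep(1L, 26), rep(0L, 25))
  c2 <- c(rep(1L, 51), rep(0L, 51))
  m2 <- cbind(x = b, y = c2)
  p2 <- attr(two_point_grouping(m2), "pairs")
  expect_equal(p2$r_hat, 0.5)
  expect_equal(p2$lod, 0)
})

test_that("grouping recovers the six homologs of a simulated chromosome", {
  set.seed(502)
  mother <- minimal_mother()
  good <- 0
  for (i in 1:10) {
    father <- sim_parent(n_chrom = 1, n_sda_per_homolog = 10,
                         n_dda_per_pair = 0, spacing = "even", prefix = "F")
    cross <- sim_cross(mother, father, n_hybrids = 102, n_selfs = 0,
                       undetermined_rate = 0)
    pm <- presence_of(cross, "paternal", 1)
    groups <- two_point_grouping(pm)
    hom_of <- group_homologs(groups, father)
    if (length(unique(groups$group)) == 6 &&
        setequal(hom_of, 1:6)) good <- good + 1
  }
  expect_gte(good, 9)
})

test_that("karyotype aggregation calls coupled, repulsed and neutral tiers", {
  set.seed(503)
  mother <- minimal_mother(n_chrom = 2)
  # chromosome 1 with an affinity-1 pair {5,6}; chromosome 2 random
  father <- sim_parent(n_chrom = 2, n_sda_per_homolog = 6,
                       n_dda_per_pair = 0, spacing = "even",
                       pairing = data.frame(chrom = "1", h1 = 5, h2 = 6,
                                            affinity = 1),
                       prefix = "F")
  cross <- sim_cross(mother, father, n_hybrids = 102, n_selfs = 0,
                     undetermined_rate = 0)
  pm <- presence_of(cross, "paternal", 1)
  groups <- two_point_grouping(pm)
  kt <- aggregate_karyotype(pairwise_association(pm), groups)
  hom_of <- group_homologs(groups, father)
  chrom_of <- vapply(split(groups$marker_id, groups$group), function(ids) {
    ch <- cross$markers$chrom[match(ids, cross$markers$marker_id)]
    names(sort(table(ch), decreasing = TRUE))[1]
  }, character(1))
  gp <- tidy(kt)
  # a group against itself is coupled
  self_rows <- gp[gp$group_a == gp$group_b, ]
  expect_true(all(self_rows$call == "coupled"))
  # the forced pair {5,6} on chromosome 1 is repulsed at the darkest tier
  g5 <- names(hom_of)[hom_of == 5 & chrom_of == "1"]
  g6 <- names(hom_of)[hom_of == 6 & chrom_of == "1"]
  row56 <- gp[gp$group_a == min(g5, g6) & gp$group_b == max(g5, g6), ]
  expect_identical(row56$call, "repulsed")
  expect_gt(row56$frac_repulsed_t3, 0.5)
  # cross-chromosome group pairs are neutral
  cross_rows <- gp[chrom_of[gp$group_a] != chrom_of[gp$group_b], ]
  expect_true(all(cross_rows$call == "neutral"))
})

test_that("homolog clustering separates chromosomes and flags singletons", {
  # synthetic group-pair structure via a hand-built karyotype: 3 groups on one
  # chromosome (mutually repulsed), 2 on another, one isolated group
  set.seed(504)
  # presence built so that groups A,B repel (complementary), C independent
  a <- c(rep(1L, 30), rep(0L, 30))
  m <- cbind(a1 = a, a2 = a, b1 = 1L - a, b2 = 1L - a,
             c1 = c(rep(1L, 15), rep(0L, 15), rep(1L, 15), rep(0L, 15)),
             c2 = c(rep(1L, 15), rep(0L, 15), rep(1L, 15), rep(0L, 15)))
  groups <- tibble::tibble(marker_id = colnames(m),
                           group = c("GA", "GA", "GB", "GB", "GC", "GC"))
  kt <- aggregate_karyotype(pairwise_association(m), groups)
  comp <- cluster_homologs(kt)
  byg <- stats::setNames(comp$chromosome, comp$group)
  expect_identical(byg[["GA"]], byg[["GB"]])
  expect_false(byg[["GC"]] == byg[["GA"]])
  expect_true(comp$singleton[comp$group == "GC"])
  # DDA bridge edges join otherwise unlinked groups
  dda <- tibble::tibble(marker_id = c("d1", "d2"), group1 = "GA",
                        group2 = "GC", n_passing = 2L, ambiguous = FALSE)
  comp2 <- cluster_homologs(kt, dda = dda, min_shared_dda = 2)
  byg2 <- stats::setNames(comp2$chromosome, comp2$group)
  expect_identical(byg2[["GA"]], byg2[["GC"]])
})

test_that("pairing classification separates preferential from random", {
  set.seed(505)
  mother <- minimal_mother()
  father <- sim_parent(n_chrom = 1, n_sda_per_homolog = 8,
                       n_dda_per_pair = 0, spacing = "even",
                       pairing = data.frame(chrom = "1", h1 = 5, h2 = 6,
                                            affinity = 1),
                       prefix = "F")
  cross <- sim_cross(mother, father, n_hybrids = 102, n_selfs = 0,
                     undetermined_rate = 0)
  pm <- presence_of(cross, "paternal", 1)
  groups <- two_point_grouping(pm)
  kt <- aggregate_karyotype(pairwise_association(pm), groups)
  comp <- cluster_homologs(kt)
  calls <- classify_pairing(kt, comp)
  hom_of <- group_homologs(groups, father)
  pref <- calls[calls$call == "preferential", ]
  expect_gte(nrow(pref), 1L)
  # the forced pair {5,6} is among the preferential calls
  pref_homs <- lapply(seq_len(nrow(pref)), function(i)
    sort(hom_of[c(pref$group_a[i], pref$group_b[i])]))
  expect_true(any(vapply(pref_homs, function(h) all(h == c(5L, 6L)),
                         logical(1))))
  # a two-group component with one marker each is untestable
  a <- c(rep(1L, 51), rep(0L, 51))
  m1 <- cbind(x = a, y = 1L - a)
  g1 <- tibble::tibble(marker_id = c("x", "y"), group = c("GX", "GY"))
  kt1 <- aggregate_karyotype(pairwise_association(m1), g1)
  c1 <- cluster_homologs(kt1)
  expect_identical(classify_pairing(kt1, c1)$call, "untestable")
})
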