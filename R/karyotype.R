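# Two-sided Fisher exact p for 2x2 tables, vectorised over table cells.
# Same definition as stats::fisher.test (sum of hypergeometric probabilities
# not exceeding that of the observed table, with the conventional relative
# tolerance); equivalence is asserted in the test suite.
fisher_p2x2 <- function(n11, n10, n01, n00) {
  mapply(function(a, b, c, d) {
    n <- a + b + c + d
    if (n == 0) return(NA_real_)
    r1 <- a + b; c1 <- a + c
    lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
    x <- lo:hi
    pr <- dhyper(x, c1, n - c1, r1)
    pobs <- dhyper(a, c1, n - c1, r1)
    min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
  }, n11, n10, n01, n00)
}

# pairwise-complete 2x2 counts for all column pairs of a 0/1/NA matrix
pair_counts_all <- function(presence) {
  stopifnot(is.matrix(presence), !is.null(colnames(presence)))
  A <- (presence == 1); A[is.na(A)] <- FALSE; storage.mode(A) <- "double"
  O <- (presence == 0); O[is.na(O)] <- FALSE; storage.mode(O) <- "double"
  n11 <- crossprod(A); n10 <- crossprod(A, O)
  n01 <- crossprod(O, A); n00 <- crossprod(O)
  idx <- which(upper.tri(n11), arr.ind = TRUE)
  ids <- colnames(presence)
  tibble(
    marker_a = ids[idx[, 1]], marker_b = ids[idx[, 2]],
    n11 = n11[idx], n10 = n10[idx], n01 = n01[idx], n00 = n00[idx]
  ) %>%
    mutate(n = .data$n11 + .data$n10 + .data$n01 + .data$n00)
}

#' Pairwise Fisher exact association of marker alleles
#'
#' For each marker pair, the progeny are cross-tabulated by joint allele
#' presence/absence (pairwise-complete individuals only) and the 2x2 table is
#' tested with Fisher's exact test (two-sided). The association direction is
#' taken from the sample odds ratio with Haldane-Anscombe correction (+0.5 to
#' every cell) so zero cells still yield a direction: `coupling` (odds ratio
#' > 1, alleles co-occur, same homolog) or `repulsion` (< 1, alleles avoid
#' each other, different homologs of one chromosome).
#'
#' @param x Either a 0/1/NA presence matrix (individuals x markers, column
#'   names = marker ids) for all-pairs testing, or a single presence vector.
#' @param y Second presence vector when `x` is a vector.
#' @param min_n Minimum pairwise-complete individuals; pairs below it are
#'   returned with `skipped = TRUE` and no p-value.
#' @return Tibble with one row per pair: counts `n11, n10, n01, n00`, `n`,
#'   `p_value`, `odds_ratio` (corrected), `direction`, `skipped`.
#' @export
pairwise_association <- function(x, y = NULL, min_n = 10) {
  if (!is.null(y)) {
    stopifnot(length(x) == length(y))
    x <- cbind(a = x, b = y)
  }
  cnt <- pair_counts_all(as.matrix(x))
  orr <- (cnt$n11 + 0.5) * (cnt$n00 + 0.5) /
    ((cnt$n10 + 0.5) * (cnt$n01 + 0.5))
  skipped <- cnt$n < min_n
  p <- rep(NA_real_, nrow(cnt))
  if (any(!skipped))
    p[!skipped] <- fisher_p2x2(cnt$n11[!skipped], cnt$n10[!skipped],
                               cnt$n01[!skipped], cnt$n00[!skipped])
  cnt %>%
    mutate(p_value = p, odds_ratio = orr,
           direction = dplyr::case_when(
             orr > 1 ~ "coupling", orr < 1 ~ "repulsion", TRUE ~ "none"),
           skipped = skipped)
}

#' Two-point coupling-phase linkage grouping
#'
#' Groups single-dose markers of one parent into homologous linkage groups.
#' For each pair, the recombination fraction is estimated as
#' `r = (n10 + n01) / n` (clipped to `[1e-6, 0.5]`) and the two-point LOD is
#' `(n11 + n00) log10(2 (1 - r)) + (n10 + n01) log10(2 r)`. Markers are
#' clustered by single linkage over edges with `LOD >= lod_threshold` in
#' coupling phase only (repulsion-phase linkage is ignored, as its
#' expectation depends on the inheritance model).
#'
#' @param presence 0/1/NA presence matrix (individuals x SDA markers).
#' @param lod_threshold Grouping threshold (default 7).
#' @return Tibble `marker_id`, `group` (labels `G01`, `G02`, ... by
#'   decreasing group size); the pair table with `r_hat` and `lod` is
#'   attached as attribute `"pairs"`.
#' @export
two_point_grouping <- function(presence, lod_threshold = 7) {
  cnt <- pair_counts_all(as.matrix(presence))
  nrec <- cnt$n10 + cnt$n01
  r_hat <- pmin(pmax(nrec / pmax(cnt$n, 1), 1e-6), 0.5)
  lod <- (cnt$n11 + cnt$n00) * log10(2 * (1 - r_hat)) +
    nrec * log10(2 * r_hat)
  coupling <- (cnt$n11 + 0.5) * (cnt$n00 + 0.5) >
    (cnt$n10 + 0.5) * (cnt$n01 + 0.5)
  pairs <- mutate(cnt, r_hat = r_hat, lod = lod, coupling = coupling)
  edges <- filter(pairs, .data$lod >= lod_threshold, .data$coupling)
  g <- igraph::graph_from_data_frame(
    select(edges, "marker_a", "marker_b"), directed = FALSE,
    vertices = colnames(presence))
  comp <- igraph::components(g)$membership
  sizes <- sort(table(comp), decreasing = TRUE)
  relabel <- setNames(sprintf("G%02d", seq_along(sizes)), names(sizes))
  out <- tibble(marker_id = names(comp),
                group = unname(relabel[as.character(comp)])) %>%
    arrange(.data$group, .data$marker_id)
  attr(out, "pairs") <- pairs
  out
}

#' Aggregate pairwise associations into a molecular karyotype
#'
#' Summarises all inter-group marker-pair Fisher tests into a linkage-group
#' by linkage-group report. Each marker pair is assigned a significance tier
#' per direction (default tiers 0.05, 0.001, 1e-5 — the familiar
#' yellow/orange/red for coupling and light/medium/dark blue for repulsion);
#' a group pair is called `coupled` or `repulsed` when more than `majority`
#' of its marker pairs are significant at the outer tier in that direction,
#' else `neutral`.
#'
#' @param assoc Pair table from [pairwise_association()].
#' @param groups Tibble `marker_id`, `group` (from [two_point_grouping()] or
#'   a user-supplied map).
#' @param tiers Strictly decreasing significance thresholds (length 3).
#' @param majority Fraction of significant marker pairs required for a
#'   directional group-pair call (default 0.5).
#' @return A `polyk_karyotype` object; `tidy()` returns the group-pair
#'   table, `autoplot()` draws the marker-pair heat matrix.
#' @export
aggregate_karyotype <- function(assoc, groups, tiers = c(0.05, 1e-3, 1e-5),
                                majority = 0.5) {
  stopifnot(length(tiers) == 3, all(diff(tiers) < 0), majority > 0,
            majority < 1)
  lut <- setNames(groups$group, groups$marker_id)
  pairs <- assoc %>%
    filter(!.data$skipped) %>%
    mutate(group_a = unname(lut[.data$marker_a]),
           group_b = unname(lut[.data$marker_b])) %>%
    filter(!is.na(.data$group_a), !is.na(.data$group_b)) %>%
    mutate(
      ga = pmin(.data$group_a, .data$group_b),
      gb = pmax(.data$group_a, .data$group_b),
      tier = dplyr::case_when(
        .data$p_value < tiers[3] ~ 3L,
        .data$p_value < tiers[2] ~ 2L,
        .data$p_value < tiers[1] ~ 1L,
        TRUE ~ 0L)
    )
  gp <- pairs %>%
    group_by(.data$ga, .data$gb) %>%
    summarise(
      n_pairs = dplyr::n(),
      frac_coupled_t1 = mean(.data$tier >= 1 & .data$direction == "coupling"),
      frac_coupled_t2 = mean(.data$tier >= 2 & .data$direction == "coupling"),
      frac_coupled_t3 = mean(.data$tier >= 3 & .data$direction == "coupling"),
      frac_repulsed_t1 = mean(.data$tier >= 1 & .data$direction == "repulsion"),
      frac_repulsed_t2 = mean(.data$tier >= 2 & .data$direction == "repulsion"),
      frac_repulsed_t3 = mean(.data$tier >= 3 & .data$direction == "repulsion"),
      median_p = median(.data$p_value),
      .groups = "drop"
    ) %>%
    mutate(call = dplyr::case_when(
      .data$frac_repulsed_t1 > majority ~ "repulsed",
      .data$frac_coupled_t1 > majority ~ "coupled",
      TRUE ~ "neutral"
    )) %>%
    rename(group_a = "ga", group_b = "gb")
  structure(
    list(group_pairs = gp, pairs = pairs, groups = as_tibble(groups),
         tiers = tiers, majority = majority),
    class = "polyk_karyotype"
  )
}

#' @export
print.polyk_karyotype <- function(x, ...) {
  cat("<polyk_karyotype> ", nrow(x$groups), " markers in ",
      length(unique(x$groups$group)), " groups; ", nrow(x$group_pairs),
      " group pairs (", sum(x$group_pairs$call == "repulsed"), " repulsed, ",
      sum(x$group_pairs$call == "coupled"), " coupled)\n", sep = "")
  invisible(x)
}

#' @export
tidy.polyk_karyotype <- function(x, ...) x$group_pairs

#' @export
glance.polyk_karyotype <- function(x, ...) {
  tibble(
    n_markers = nrow(x$groups),
    n_groups = length(unique(x$groups$group)),
    n_group_pairs = nrow(x$group_pairs),
    n_repulsed = sum(x$group_pairs$call == "repulsed"),
    n_coupled = sum(x$group_pairs$call == "coupled"),
    n_neutral = sum(x$group_pairs$call == "neutral")
  )
}

#' Cluster homologous linkage groups into chromosomes
#'
#' Homologous linkage groups of one chromosome repel one another (their
#' alleles avoid co-occurrence), and a duplex (DDA) marker bridges exactly
#' two of them. Chromosomes are therefore recovered as connected components
#' of the graph whose edges are (i) group pairs with a majority of marker
#' pairs repulsed at the `edge_tier` significance level and (ii) group pairs
#' sharing at least `min_shared_dda` assigned DDA markers. The component
#' size is the homolog count; a component whose size differs from the
#' expected copy number indicates (compensated) aneuploidy.
#'
#' With `G` recovered groups there are of order `G^2 / 2` candidate group
#' pairs, so the clustering edge uses the middle significance tier (default
#' `p < 0.001`) rather than the outer reporting tier: a 5% per-pair false
#' repulsion rate would otherwise merge unrelated chromosomes in a sizeable
#' fraction of analyses.
#'
#' @param karyotype A `polyk_karyotype`.
#' @param dda Optional [assign_dda()] table contributing bridge edges.
#' @param min_shared_dda Minimum shared DDA markers for a bridge edge
#'   (default 2).
#' @param expected_copies Optional expected homolog count used to flag
#'   aneuploid components.
#' @param edge_tier Which significance tier (1, 2 or 3, outermost to
#'   innermost) a majority of a group pair's marker pairs must reach, in the
#'   repulsion direction, to form a clustering edge. Default 2.
#' @return Tibble `group`, `chromosome`, `n_groups`, `singleton` (flagged
#'   when a group has no edges), `aneuploid` (when `expected_copies` given).
#' @export
cluster_homologs <- function(karyotype, dda = NULL, min_shared_dda = 2,
                             expected_copies = NULL, edge_tier = 2) {
  stopifnot(inherits(karyotype, "polyk_karyotype"),
            edge_tier %in% 1:3)
  gp <- karyotype$group_pairs
  frac <- gp[[paste0("frac_repulsed_t", edge_tier)]]
  edges <- gp %>%
    filter(frac > karyotype$majority, .data$group_a != .data$group_b) %>%
    select("group_a", "group_b")
  if (!is.null(dda)) {
    dd <- dda %>%
      filter(!.data$ambiguous) %>%
      count(.data$group1, .data$group2, name = "n_shared") %>%
      filter(.data$n_shared >= min_shared_dda) %>%
      select(group_a = "group1", group_b = "group2")
    edges <- bind_rows(edges, dd)
  }
  verts <- sort(unique(karyotype$groups$group))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = verts)
  comp <- igraph::components(g)$membership
  sizes <- table(comp)
  relabel <- setNames(sprintf("chr%02d", seq_along(sizes)), names(sizes))
  out <- tibble(group = names(comp),
                chromosome = unname(relabel[as.character(comp)])) %>%
    group_by(.data$chromosome) %>%
    mutate(n_groups = dplyr::n()) %>%
    ungroup() %>%
    mutate(singleton = .data$n_groups == 1L) %>%
    arrange(.data$chromosome, .data$group)
  if (!is.null(expected_copies))
    out <- mutate(out, aneuploid = .data$n_groups != expected_copies)
  out
}

#' Classify homolog pairing as random or preferential
#'
#' Within a chromosome component, a homolog pair is called `preferential`
#' when its group pair is repulsed at the middle significance tier (more
#' than `strong_majority` of marker pairs at `p < tiers[2]`) while each
#' member is neutral-or-weaker (no such repulsion majority) against every
#' other member of the component — the signature of two homologs that form a
#' bivalent with each other nearly always, i.e. subgenome differentiation.
#' Pairs where either group has fewer than `min_markers` markers are
#' `untestable`.
#'
#' A chromosome component carries on the order of 15 candidate pairs, so the
#' strong call is held to a stricter majority (default 0.75) than the
#' reporting call: under fully random hexasomic pairing the group-level
#' repulsion already has noncentrality ~ n/25, and a bare 50% majority at
#' the middle tier would flag a chance pair in well over 10% of analyses,
#' while a truly preferential (affinity ~ 1) pair drives essentially every
#' marker pair past the tier.
#'
#' @param karyotype A `polyk_karyotype`.
#' @param components Output of [cluster_homologs()].
#' @param min_markers Minimum markers per group for a testable pair
#'   (default 2).
#' @param strong_majority Fraction of a group pair's marker pairs that must
#'   be repulsed at the middle tier for the strong call (default 0.75).
#' @return Tibble `chromosome`, `group_a`, `group_b`, `call` in
#'   `{random, preferential, untestable}`.
#' @export
classify_pairing <- function(karyotype, components, min_markers = 2,
                             strong_majority = 0.75) {
  stopifnot(inherits(karyotype, "polyk_karyotype"),
            strong_majority > 0, strong_majority < 1)
  gp <- karyotype$group_pairs
  nmark <- count(karyotype$groups, .data$group, name = "n_markers")
  strong <- gp %>%
    filter(.data$group_a != .data$group_b) %>%
    mutate(strong = .data$frac_repulsed_t2 > strong_majority) %>%
    select("group_a", "group_b", "strong")
  is_strong <- function(g1, g2) {
    a <- pmin(g1, g2); b <- pmax(g1, g2)
    hit <- strong$strong[strong$group_a == a & strong$group_b == b]
    length(hit) == 1 && hit
  }
  out <- list()
  for (ch in unique(components$chromosome)) {
    members <- components$group[components$chromosome == ch]
    if (length(members) < 2) next
    prs <- combn(sort(members), 2)
    for (j in seq_len(ncol(prs))) {
      a <- prs[1, j]; b <- prs[2, j]
      na <- nmark$n_markers[nmark$group == a]
      nb <- nmark$n_markers[nmark$group == b]
      if (length(na) == 0 || length(nb) == 0 || min(na, nb) < min_markers) {
        call <- "untestable"
      } else if (is_strong(a, b)) {
        others_a <- setdiff(members, c(a, b))
        clean <- !any(vapply(others_a, function(o) is_strong(a, o),
                             logical(1))) &&
          !any(vapply(others_a, function(o) is_strong(b, o), logical(1)))
        call <- if (clean) "preferential" else "random"
      } else {
        call <- "random"
      }
      out[[length(out) + 1]] <- tibble(chromosome = ch, group_a = a,
                                       group_b = b, call = call)
    }
  }
  if (length(out) == 0)
    return(tibble(chromosome = character(), group_a = character(),
                  group_b = character(), call = character()))
  bind_rows(out)
}
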