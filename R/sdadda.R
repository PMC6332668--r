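#' Expected SDA-DDA coupling class frequencies
#'
#' Closed-form expected frequencies of the four progeny classes (`AB`: both
#' alleles present, `A`: simplex allele only, `B`: duplex allele only, `0`:
#' neither) for a simplex (SDA, `A000...`) and a duplex (DDA, `BB00...`)
#' marker linked in coupling on the same parental chromosome, as a function
#' of the recombination fraction `r`:
#'
#' * tetrasomic (4 homologs): `(1/2 - r/6, r/6, 1/3 + r/6, 1/6 - r/6)`
#' * hexasomic (6 homologs): `(1/2 - r/5, r/5, 3/10 + r/5, 1/5 - r/5)`
#'
#' At `r = 0.5` each class probability factorises into the product of the
#' marginals (`P(A) = 1/2`; `P(B) = 5/6` tetrasomic, `4/5` hexasomic).
#'
#' @param r Recombination fraction(s) in `[0, 0.5]`.
#' @param model `"hexasomic"` (default) or `"tetrasomic"`.
#' @return Tibble with columns `r`, `p_ab`, `p_a`, `p_b`, `p_0` (one row per
#'   value of `r`).
#' @seealso [enumerate_class_freqs()] for the brute-force meiotic oracle.
#' @examples
#' expected_class_freqs(0, "hexasomic")   # 1/2, 0, 3/10, 1/5
#' expected_class_freqs(0, "tetrasomic")  # 1/2, 0, 1/3, 1/6
#' @export
expected_class_freqs <- function(r, model = c("hexasomic", "tetrasomic")) {
  model <- match.arg(model)
  p <- class_probs(r, model)
  tibble(r = r, p_ab = p[, 1], p_a = p[, 2], p_b = p[, 3], p_0 = p[, 4])
}

# bare-matrix version of expected_class_freqs (rows = r values, columns
# AB/A/B/0); hot path for the likelihood optimiser
class_probs <- function(r, model) {
  if (any(!is.finite(r)) || any(r < 0) || any(r > 0.5))
    stop("r must lie in [0, 0.5]")
  if (model == "tetrasomic")
    cbind(1 / 2 - r / 6, r / 6, 1 / 3 + r / 6, 1 / 6 - r / 6)
  else
    cbind(1 / 2 - r / 5, r / 5, 3 / 10 + r / 5, 1 / 5 - r / 5)
}

#' Enumerate SDA-DDA class frequencies from the meiosis model
#'
#' Independent oracle for [expected_class_freqs()]: places the simplex allele
#' A on homolog 1 and the duplex allele B on homologs 1 and 2 (coupling
#' phase), enumerates every perfect matching of the homologs into bivalents
#' (uniform over matchings) and every per-bivalent transmission outcome
#' (either member at the A locus with probability 1/2, switching to the other
#' member at the B locus with probability `r`), and accumulates the exact
#' class probabilities.
#'
#' @inheritParams expected_class_freqs
#' @return Tibble with columns `r`, `p_ab`, `p_a`, `p_b`, `p_0`.
#' @export
enumerate_class_freqs <- function(r, model = c("hexasomic", "tetrasomic")) {
  model <- match.arg(model)
  if (any(!is.finite(r)) || any(r < 0) || any(r > 0.5))
    stop("r must lie in [0, 0.5]")
  k <- if (model == "hexasomic") 6L else 4L
  matchings <- all_matchings(seq_len(k))
  one_r <- function(rr) {
    acc <- c(p_ab = 0, p_a = 0, p_b = 0, p_0 = 0)
    for (m in matchings) {
      # state distribution over (A present, B present) so far
      st <- matrix(0, 2, 2, dimnames = list(A = c("no", "yes"),
                                            B = c("no", "yes")))
      st["no", "no"] <- 1
      for (j in seq_len(ncol(m))) {
        pair <- m[, j]
        new <- matrix(0, 2, 2, dimnames = dimnames(st))
        for (s in 1:2) for (sw in 0:1) {
          p <- 0.5 * (if (sw == 1) rr else 1 - rr)
          start <- pair[s]
          end <- if (sw == 1) pair[3 - s] else pair[s]
          a <- (start == 1) + 1L
          b <- (end %in% c(1L, 2L)) + 1L
          # OR the bivalent's contribution into the running presence state
          for (ia in 1:2) for (ib in 1:2) {
            na <- max(ia, a); nb <- max(ib, b)
            new[na, nb] <- new[na, nb] + st[ia, ib] * p
          }
        }
        st <- new
      }
      acc <- acc + c(st["yes", "yes"], st["yes", "no"],
                     st["no", "yes"], st["no", "no"])
    }
    acc / length(matchings)
  }
  res <- t(vapply(r, one_r, numeric(4)))
  tibble(r = r, p_ab = res[, 1], p_a = res[, 2], p_b = res[, 3],
         p_0 = res[, 4])
}

#' Chi-square independence test for an SDA-DDA contingency
#'
#' Tests observed four-class counts `(AB, A, B, 0)` against the expected
#' frequencies of independently segregating SDA and DDA markers, i.e.
#' [expected_class_freqs()] at `r = 0.5` (Pearson chi-square, df 3, no
#' continuity correction). Coupling linkage is declared only when the test is
#' significant *and* the `AB` class exceeds its expectation (the coupling
#' direction).
#'
#' @param counts Numeric vector of 4 counts `(n_AB, n_A, n_B, n_0)`.
#' @inheritParams expected_class_freqs
#' @param alpha Significance level for the linkage call (default 0.05).
#' @return One-row tibble: `chisq`, `df`, `p_value`, `linked`, `n`.
#' @examples
#' independence_test(c(50, 0, 30, 20), "hexasomic") # chisq 25, linked
#' @export
independence_test <- function(counts, model = c("hexasomic", "tetrasomic"),
                              alpha = 0.05) {
  model <- match.arg(model)
  stopifnot(length(counts) == 4, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("contingency has no observations")
  expected <- n * as.numeric(class_probs(0.5, model))
  if (any(expected < 1))
    warning("expected cell count below 1; chi-square approximation is poor")
  chisq <- sum((counts - expected)^2 / expected)
  p <- pchisq(chisq, df = 3, lower.tail = FALSE)
  tibble(chisq = chisq, df = 3L, p_value = p,
         linked = p < alpha && counts[1] > expected[1], n = n)
}

#' Maximum-likelihood recombination fraction for an SDA-DDA pair
#'
#' Maximises the multinomial log-likelihood of the observed four-class counts
#' under the coupling model of [expected_class_freqs()] over
#' `r` in `[1e-6, 0.5]` (1-D bounded optimisation, with the interval
#' endpoints checked explicitly so boundary optima are not missed).
#'
#' @inheritParams independence_test
#' @return One-row tibble: `r_hat`, `loglik`, `boundary` (`TRUE` when the
#'   estimate sits at an interval end, e.g. for degenerate counts).
#' @export
estimate_r_ml <- function(counts, model = c("hexasomic", "tetrasomic")) {
  model <- match.arg(model)
  stopifnot(length(counts) == 4, all(counts >= 0))
  if (sum(counts) == 0) stop("contingency has no observations")
  ll <- function(r) {
    p <- as.numeric(class_probs(r, model))
    sum(ifelse(counts > 0, counts * log(p), 0))
  }
  lo <- 1e-6; hi <- 0.5
  opt <- optimize(ll, c(lo, hi), maximum = TRUE, tol = 1e-8)
  cand_r <- c(opt$maximum, lo, hi)
  cand_ll <- c(opt$objective, ll(lo), ll(hi))
  best <- which.max(cand_ll)
  r_hat <- cand_r[best]
  tibble(r_hat = r_hat, loglik = cand_ll[best],
         boundary = r_hat <= lo + 1e-5 || r_hat >= hi - 1e-5)
}

# vectorised 4-class counts for one DDA presence vector against columns of an
# SDA presence matrix (0/1 with NA), pairwise-complete
sdadda_counts <- function(dda, sda_mat) {
  ok <- !is.na(dda)
  d <- dda == 1
  res <- matrix(0L, ncol(sda_mat), 4,
                dimnames = list(colnames(sda_mat), c("ab", "a", "b", "o")))
  for (j in seq_len(ncol(sda_mat))) {
    s <- sda_mat[, j]
    use <- ok & !is.na(s)
    sv <- s[use] == 1; dv <- d[use]
    res[j, ] <- c(sum(sv & dv), sum(sv & !dv), sum(!sv & dv), sum(!sv & !dv))
  }
  res
}

#' Assign a DDA marker to a homolog-group pair
#'
#' A duplex allele sits on two homologs, so it should be linked in coupling
#' with the SDA markers of exactly two homologous linkage groups. For each
#' group, the coupling score is the median signed Pearson chi-square
#' (positive when the `AB` class exceeds the product of the observed
#' marginals) of the 2x2 presence/absence table of the DDA against each of
#' the group's SDA markers; a group passes when its median chi-square is in
#' the coupling direction and significant at `alpha` (df 1). The DDA is
#' assigned to the two passing groups, or flagged ambiguous when the number
#' of passing groups is not exactly two.
#'
#' Conditioning on the observed marginals (rather than the theoretical
#' `r = 0.5` class frequencies of [independence_test()]) makes the score
#' insensitive to sampling drift in a group's allele-presence fraction,
#' which would otherwise let one lucky group pass against every DDA.
#'
#' @param dda_presence 0/1/NA matrix (individuals x DDA markers), or a single
#'   vector for one DDA.
#' @param sda_presence 0/1/NA matrix (individuals x SDA markers) over the
#'   same individuals.
#' @param groups Tibble `marker_id`, `group` assigning each SDA column to a
#'   homolog group (as from [two_point_grouping()]).
#' @param alpha Significance level a group's median chi-square must reach.
#' @return Tibble with one row per DDA: `marker_id`, `group1`, `group2`
#'   (NA when ambiguous), `n_passing`, `ambiguous`, and a list-column
#'   `scores` of per-group statistics.
#' @export
assign_dda <- function(dda_presence, sda_presence, groups, alpha = 0.05) {
  if (is.null(dim(dda_presence)))
    dda_presence <- matrix(dda_presence, ncol = 1,
                           dimnames = list(NULL, "dda"))
  stopifnot(nrow(dda_presence) == nrow(sda_presence))
  sda_ids <- colnames(sda_presence)
  stopifnot(all(sda_ids %in% groups$marker_id))
  grp <- setNames(groups$group, groups$marker_id)[sda_ids]
  out <- purrr::map(seq_len(ncol(dda_presence)), function(j) {
    cnt <- sdadda_counts(dda_presence[, j], sda_presence)
    n <- rowSums(cnt)
    # margin-conditional 2x2 association: rows = SDA presence, cols = DDA
    r1 <- cnt[, "ab"] + cnt[, "a"]; r0 <- n - r1
    c1 <- cnt[, "ab"] + cnt[, "b"]; c0 <- n - c1
    den <- r1 * r0 * c1 * c0
    chisq <- ifelse(den > 0,
                    n * (cnt[, "ab"] * cnt[, "o"] -
                           cnt[, "a"] * cnt[, "b"])^2 / den, 0)
    signed <- ifelse(cnt[, "ab"] * n > r1 * c1, chisq, -chisq)
    sc <- tibble(group = grp, signed_chisq = signed) %>%
      group_by(.data$group) %>%
      summarise(median_chisq = median(.data$signed_chisq),
                n_sda = dplyr::n(), .groups = "drop") %>%
      mutate(p_value = ifelse(.data$median_chisq > 0,
                              pchisq(.data$median_chisq, 1,
                                     lower.tail = FALSE), 1),
             pass = .data$median_chisq > 0 & .data$p_value < alpha)
    passing <- arrange(filter(sc, .data$pass),
                       dplyr::desc(.data$median_chisq))
    np <- nrow(passing)
    tibble(
      marker_id = colnames(dda_presence)[j],
      group1 = if (np == 2) sort(passing$group)[1] else NA_character_,
      group2 = if (np == 2) sort(passing$group)[2] else NA_character_,
      n_passing = np,
      ambiguous = np != 2,
      scores = list(sc)
    )
  })
  bind_rows(out)
}

#' Subgenome uniformity test for DDA linkages
#'
#' Under fully polysomic (undifferentiated) inheritance a duplex allele is
#' equally likely to sit on any of the `choose(k, 2)` homolog pairs of its
#' chromosome, so the tally of DDA assignments per pair should be uniform.
#' Concentration on the pairs within a homolog subset is the signature of
#' subgenome differentiation (allopolyploidy). Pearson chi-square against the
#' uniform expectation, df = number of pairs - 1.
#'
#' @param tally Integer vector of DDA counts per homolog pair. Supply all
#'   pairs, including zero counts (length `choose(k, 2)`: 15 for 6 homologs,
#'   10 for 5, 21 for 7).
#' @param exact Use a simulated (Monte Carlo multinomial) p-value instead of
#'   the asymptotic one; advisable when the total count is below the number
#'   of pairs.
#' @return One-row tibble: `chisq`, `df`, `p_value`, `n_pairs`, `total`.
#' @examples
#' subgenome_uniformity_test(rep(2, 15)) # chisq 0, P 1
#' @export
subgenome_uniformity_test <- function(tally, exact = FALSE) {
  stopifnot(length(tally) >= 2, all(tally >= 0), sum(tally) >= 1)
  k <- length(tally)
  total <- sum(tally)
  if (total < k && !exact)
    warning("total DDA count below the number of homolog pairs; ",
            "consider `exact = TRUE` (simulated multinomial p-value)")
  if (exact) {
    ct <- suppressWarnings(chisq.test(tally, simulate.p.value = TRUE, B = 1e4))
    tibble(chisq = unname(ct$statistic), df = k - 1L,
           p_value = ct$p.value, n_pairs = k, total = total)
  } else {
    e <- total / k
    chisq <- sum((tally - e)^2 / e)
    tibble(chisq = chisq, df = k - 1L,
           p_value = pchisq(chisq, k - 1, lower.tail = FALSE),
           n_pairs = k, total = total)
  }
}
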