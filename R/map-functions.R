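#' Haldane map function
#'
#' Convert a genetic map distance in centimorgans to a recombination fraction
#' under the Haldane (no-interference) model, `r = (1 - exp(-2 d / 100)) / 2`,
#' or back via [haldane_inverse()].
#'
#' @param d Map distance in cM (numeric, >= 0).
#' @return Recombination fraction in `[0, 0.5)`.
#' @examples
#' haldane(0)
#' haldane(50)
#' haldane_inverse(haldane(10))
#' @export
haldane <- function(d) {
  stopifnot(is.numeric(d), all(d >= 0))
  (1 - exp(-2 * d / 100)) / 2
}

#' @param r Recombination fraction in `[0, 0.5)`.
#' @rdname haldane
#' @export
haldane_inverse <- function(r) {
  stopifnot(is.numeric(r), all(r >= 0), all(r < 0.5))
  -50 * log(1 - 2 * r)
}

#' Expected presence:absence segregation ratio by gamete enumeration
#'
#' Exhaustively enumerates every way a gamete can sample `n_homologs / 2`
#' chromosomes out of the `n_homologs` homologs of one parental chromosome,
#' and counts gametes that carry at least one copy of an allele present on
#' `n_carriers` homologs. In an F1 pseudo-testcross where the other parent is
#' null, the progeny presence:absence (heterozygote:homozygote) ratio equals
#' the gamete carrier:non-carrier ratio. A simplex (single-dose) allele gives
#' 1:1 regardless of ploidy; a duplex (double-dose) allele gives 4:1 under
#' hexasomic (6-homolog) and 5:1 under tetrasomic (4-homolog) assortment.
#'
#' @param n_homologs Even number of homologs assorting at meiosis (4 or 6
#'   for tetrasomic/hexasomic inheritance).
#' @param n_carriers Number of homologs carrying the allele (1 = simplex,
#'   2 = duplex).
#' @return A one-row tibble with columns `n_subsets`, `n_present`, `n_absent`
#'   and `ratio` (= `n_present / n_absent`, the "ratio-to-one" figure).
#' @examples
#' gamete_presence_ratio(6, 2) # duplex, hexasomic: 4:1
#' gamete_presence_ratio(4, 2) # duplex, tetrasomic: 5:1
#' gamete_presence_ratio(6, 1) # simplex: 1:1
#' @export
gamete_presence_ratio <- function(n_homologs, n_carriers) {
  stopifnot(n_homologs %% 2 == 0, n_homologs >= 2,
            n_carriers >= 1, n_carriers < n_homologs)
  subsets <- combn(n_homologs, n_homologs / 2)
  present <- apply(subsets, 2, function(s) any(s <= n_carriers))
  tibble(
    n_subsets = ncol(subsets),
    n_present = sum(present),
    n_absent  = sum(!present),
    ratio     = sum(present) / sum(!present)
  )
}

# all perfect matchings of an even-length vector, as a list of 2 x m matrices
all_matchings <- function(v) {
  k <- length(v)
  if (k == 0) return(list(matrix(integer(0), nrow = 2)))
  stopifnot(k %% 2 == 0)
  out <- list()
  for (j in 2:k) {
    rest <- all_matchings(v[-c(1, j)])
    out <- c(out, lapply(rest, function(m) cbind(c(v[1], v[j]), m)))
  }
  out
}
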