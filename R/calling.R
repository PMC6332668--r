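#' Call presence/absence genotypes from read counts
#'
#' Applies fixed read-count thresholds to biallelic GBS read counts. A
#' heterozygote requires at least `t_het` reads of each allele and a minor
#' allele read fraction strictly greater than `maf_min`. Otherwise a
#' homozygote for the majority allele is called when that allele has at least
#' `t_hom` reads. Anything else is missing.
#'
#' Codes: `0` = homozygous reference, `1` = heterozygous, `2` = homozygous
#' alternate, `NA` = missing.
#'
#' @param reads Data frame with columns `marker_id`, `individual`,
#'   `ref_reads`, `alt_reads` (as from [sim_reads()] or [read_read_counts()]).
#' @param t_hom Minimum reads of a single allele for a homozygote call
#'   (default 11; use 17 for the strict mode).
#' @param t_het Minimum reads of each allele for a heterozygote (default 2).
#' @param maf_min Minimum minor-allele read fraction for a heterozygote
#'   (default 0.10, strict inequality).
#' @return The input tibble with a `call` column (integer, `NA` = missing).
#' @examples
#' reads <- tibble::tibble(marker_id = "m", individual = c("a", "b", "c", "d"),
#'                         ref_reads = c(11L, 2L, 10L, 20L),
#'                         alt_reads = c(0L, 2L, 0L, 1L))
#' call_genotypes(reads)$call # 0, 1, NA, 0
#' @export
call_genotypes <- function(reads, t_hom = 11, t_het = 2, maf_min = 0.10) {
  reads <- as_tibble(reads)
  stopifnot(all(c("marker_id", "individual", "ref_reads", "alt_reads") %in%
                  names(reads)),
            t_hom >= t_het, t_het >= 1, maf_min > 0, maf_min < 0.5,
            all(reads$ref_reads >= 0), all(reads$alt_reads >= 0))
  ref <- reads$ref_reads; alt <- reads$alt_reads
  tot <- ref + alt
  minor <- pmin(ref, alt)
  het <- ref >= t_het & alt >= t_het & tot > 0 & minor / pmax(tot, 1) > maf_min
  hom_ref <- !het & ref >= t_hom & ref >= alt
  hom_alt <- !het & alt >= t_hom & alt > ref
  call <- rep(NA_integer_, length(ref))
  call[het] <- 1L
  call[hom_ref] <- 0L
  call[hom_alt] <- 2L
  mutate(reads, call = call)
}

#' Exclude markers with excess missing data
#'
#' Markers with a missing-call fraction strictly greater than `max_missing`
#' are removed (a marker missing in exactly 20% of individuals is retained
#' under the default).
#'
#' @param geno Long genotype tibble with columns `marker_id`, `individual`,
#'   `call`.
#' @param max_missing Maximum tolerated missing fraction (default 0.20).
#' @return The filtered genotype tibble; the per-marker missingness table of
#'   the removed markers is attached as attribute `"removed"`.
#' @export
filter_markers <- function(geno, max_missing = 0.20) {
  stopifnot(max_missing > 0, max_missing < 1)
  miss <- marker_missingness(geno)
  drop <- miss$marker_id[miss$missing_fraction > max_missing]
  out <- filter(geno, !.data$marker_id %in% drop)
  attr(out, "removed") <- filter(miss, .data$marker_id %in% drop)
  out
}

#' Per-marker missing-call fractions
#'
#' @inheritParams filter_markers
#' @return Tibble with `marker_id`, `n`, `n_missing`, `missing_fraction`.
#' @export
marker_missingness <- function(geno) {
  geno %>%
    group_by(.data$marker_id) %>%
    summarise(n = dplyr::n(), n_missing = sum(is.na(.data$call)),
              .groups = "drop") %>%
    mutate(missing_fraction = .data$n_missing / .data$n)
}

#' Impute a parental genotype from selfed progeny
#'
#' When a parent itself was not sequenced, its genotype per marker is
#' recovered from accidental selfed progeny: homozygous (in that state) when
#' all non-missing selfs are homozygous for the same allele; heterozygous
#' when the selfs are all heterozygous or segregate (mixed states); missing
#' when every self is missing.
#'
#' @param geno Long genotype tibble (`marker_id`, `individual`, `call`).
#' @param self_ids Character vector of selfed-progeny individual ids.
#' @return Tibble with `marker_id`, `parent_call` (0/1/2/NA) and `n_selfs`
#'   (non-missing selfs used).
#' @export
impute_parent_from_selfs <- function(geno, self_ids) {
  stopifnot(length(self_ids) >= 1)
  sub <- filter(geno, .data$individual %in% self_ids)
  if (nrow(sub) == 0) stop("no genotype rows for the given self ids")
  sub %>%
    group_by(.data$marker_id) %>%
    summarise(parent_call = impute_one(.data$call),
              n_selfs = sum(!is.na(.data$call)), .groups = "drop")
}

impute_one <- function(calls) {
  obs <- calls[!is.na(calls)]
  if (length(obs) == 0) return(NA_integer_)
  states <- unique(obs)
  if (length(states) == 1 && states %in% c(0L, 2L)) return(states)
  1L # all het, or segregating mixed states
}

#' Screen progeny for excess heterozygosity
#'
#' Individuals whose heterozygote fraction across single-dose (SDA) markers
#' deviates from the expected 1/2 are tested with a two-sided exact binomial
#' test; an individual is excluded only when the test is significant at
#' `alpha` *and* the excess is in the heterozygote direction (the signature
#' of pollen contamination / sample mixing). Individuals with fewer than
#' `min_informative` non-missing SDA calls are flagged untestable and
#' retained.
#'
#' @param geno Long genotype tibble (`marker_id`, `individual`, `call`).
#' @param sda_markers Character vector of SDA marker ids to base the screen
#'   on.
#' @param alpha Exclusion threshold on the exact p-value (default 1e-10).
#' @param min_informative Minimum non-missing SDA calls (default 30).
#' @return Tibble with `individual`, `n_het`, `n`, `het_fraction`, `p_value`,
#'   `testable`, `excluded`.
#' @export
screen_outlier_progeny <- function(geno, sda_markers, alpha = 1e-10,
                                   min_informative = 30) {
  stopifnot(alpha > 0, alpha < 1)
  out <- geno %>%
    filter(.data$marker_id %in% sda_markers, !is.na(.data$call)) %>%
    group_by(.data$individual) %>%
    summarise(n_het = sum(.data$call == 1L), n = dplyr::n(),
              .groups = "drop") %>%
    mutate(
      het_fraction = .data$n_het / .data$n,
      p_value = purrr::map2_dbl(.data$n_het, .data$n,
                                ~ binom.test(.x, .y, 0.5)$p.value),
      testable = .data$n >= min_informative,
      excluded = .data$testable & .data$p_value < alpha &
        .data$het_fraction > 0.5
    )
  out
}
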