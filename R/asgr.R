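#' Classify reproductive mode from pistil observations
#'
#' An individual is scored from cleared-pistil embryo-sac counts: Polygonum
#' type sacs are the sexual (meiotic) pathway; Panicum type sacs (including
#' pistils with enlarged vacuolated nucellar cells, folded into the
#' `panicum` count as aposporous evidence) indicate apomixis. Individuals
#' with fewer than `min_normal` normally developed (Polygonum + Panicum)
#' pistils are `undetermined`; any aposporous pistil makes an individual
#' `apomictic`; otherwise it is `sexual`.
#'
#' @param pistils Data frame with columns `individual`, `polygonum`,
#'   `panicum`; optional `multiple_sac` and `abnormal` counts are carried
#'   into the fractions.
#' @param min_normal Minimum normally developed pistils for a call
#'   (default 10).
#' @return The input tibble with `n_normal`, `panicum_fraction`,
#'   `abnormal_fraction` and `mode` columns.
#' @examples
#' classify_mode(tibble::tibble(individual = c("a", "b", "c"),
#'                              polygonum = c(12, 10, 8),
#'                              panicum = c(0, 1, 0),
#'                              abnormal = c(0, 0, 20)))
#' @export
classify_mode <- function(pistils, min_normal = 10) {
  pistils <- as_tibble(pistils)
  stopifnot(all(c("individual", "polygonum", "panicum") %in% names(pistils)))
  if (!"multiple_sac" %in% names(pistils)) pistils$multiple_sac <- 0
  if (!"abnormal" %in% names(pistils)) pistils$abnormal <- 0
  stopifnot(all(pistils$polygonum >= 0), all(pistils$panicum >= 0),
            all(pistils$multiple_sac >= 0), all(pistils$abnormal >= 0))
  pistils %>%
    mutate(
      n_normal = .data$polygonum + .data$panicum,
      total = .data$n_normal + .data$multiple_sac + .data$abnormal,
      panicum_fraction = ifelse(.data$n_normal > 0,
                                .data$panicum / .data$n_normal, NA_real_),
      abnormal_fraction = ifelse(.data$total > 0,
                                 .data$abnormal / .data$total, NA_real_),
      mode = dplyr::case_when(
        .data$n_normal < min_normal ~ "undetermined",
        .data$panicum >= 1 ~ "apomictic",
        TRUE ~ "sexual"
      )
    ) %>%
    select(-"total")
}

#' Test 1:1 segregation of reproductive mode
#'
#' Pearson goodness-of-fit chi-square (df 1, no continuity correction) of
#' sexual:apomictic counts against the 1:1 ratio expected for a single
#' dominant apomixis factor in a pseudo-testcross.
#'
#' @param n_sexual,n_apomictic Progeny counts by mode.
#' @return One-row tibble: `chisq`, `df`, `p_value`, `n`.
#' @examples
#' test_monogenic_segregation(37, 40) # chisq 0.117, P 0.73
#' @export
test_monogenic_segregation <- function(n_sexual, n_apomictic) {
  stopifnot(n_sexual >= 0, n_apomictic >= 0, n_sexual + n_apomictic > 0)
  n <- n_sexual + n_apomictic
  e <- n / 2
  chisq <- (n_sexual - e)^2 / e + (n_apomictic - e)^2 / e
  tibble(chisq = chisq, df = 1L,
         p_value = pchisq(chisq, 1, lower.tail = FALSE), n = n)
}

#' Marker-phenotype cosegregation scan for the ASGR
#'
#' Scores every paternal single-dose marker against the reproductive-mode
#' phenotype: with a dominant apospory locus, allele presence should coincide
#' with the apomictic state in every informative individual.
#' `recombinant_count` is the number of mismatches (allele present in a
#' sexual individual, or absent in an apomictic one) among phenotyped,
#' non-missing individuals; `undetermined` individuals are excluded. The
#' perfect-linkage set collects markers with zero recombinants observed in at
#' least `min_informative` individuals. When a marker map is supplied, the
#' nearest flanking markers on either side of the perfect block (in map
#' order, minimal recombinant count) are reported.
#'
#' @param modes Data frame `individual`, `mode` (`sexual` / `apomictic` /
#'   `undetermined`), or a named character vector.
#' @param presence 0/1/NA presence matrix (individuals x markers) of
#'   paternal SDA markers; rownames are individual ids.
#' @param min_informative Minimum informative individuals for membership in
#'   the perfect-linkage set (default 50).
#' @param map Optional tibble `marker_id`, `chrom`, `pos_cM` for the
#'   flanking-marker report.
#' @return A `polyk_coseg` object: list with `markers` (per-marker tibble),
#'   `perfect` (marker ids) and `flanking` (tibble or `NULL`); `tidy()`
#'   returns the per-marker table.
#' @export
cosegregation_scan <- function(modes, presence, min_informative = 50,
                               map = NULL) {
  if (is.data.frame(modes)) {
    stopifnot(all(c("individual", "mode") %in% names(modes)))
    modes <- setNames(modes$mode, modes$individual)
  }
  keep <- names(modes)[modes %in% c("sexual", "apomictic")]
  keep <- intersect(keep, rownames(presence))
  if (length(keep) == 0) stop("no phenotyped individuals overlap the matrix")
  ph <- modes[keep] == "apomictic"
  pm <- presence[keep, , drop = FALSE]
  informative <- colSums(!is.na(pm))
  mismatch <- colSums((pm == 1) != ph, na.rm = TRUE)
  markers <- tibble(
    marker_id = colnames(pm),
    recombinant_count = as.integer(mismatch),
    informative_n = as.integer(informative)
  ) %>%
    mutate(perfect = .data$recombinant_count == 0L &
             .data$informative_n >= min_informative)
  flanking <- NULL
  if (!is.null(map) && any(markers$perfect)) {
    m <- left_join(markers, as_tibble(map), by = "marker_id") %>%
      filter(!is.na(.data$pos_cM))
    pf <- filter(m, .data$perfect)
    ch <- names(sort(table(pf$chrom), decreasing = TRUE))[1]
    onch <- filter(m, .data$chrom == ch) %>% arrange(.data$pos_cM)
    lo <- min(pf$pos_cM[pf$chrom == ch]); hi <- max(pf$pos_cM[pf$chrom == ch])
    below <- filter(onch, .data$pos_cM < lo, !.data$perfect)
    above <- filter(onch, .data$pos_cM > hi, !.data$perfect)
    flanking <- bind_rows(
      if (nrow(below)) mutate(dplyr::slice_tail(below, n = 1), side = "below"),
      if (nrow(above)) mutate(dplyr::slice_head(above, n = 1), side = "above")
    )
  }
  structure(list(markers = markers,
                 perfect = markers$marker_id[markers$perfect],
                 flanking = flanking,
                 n_phenotyped = length(keep)),
            class = "polyk_coseg")
}

#' @export
print.polyk_coseg <- function(x, ...) {
  cat("<polyk_coseg> ", nrow(x$markers), " markers scanned over ",
      x$n_phenotyped, " phenotyped individuals; ", length(x$perfect),
      " in perfect linkage\n", sep = "")
  invisible(x)
}

#' @export
tidy.polyk_coseg <- function(x, ...) x$markers

#' @export
glance.polyk_coseg <- function(x, ...) {
  tibble(n_markers = nrow(x$markers), n_phenotyped = x$n_phenotyped,
         n_perfect = length(x$perfect),
         min_recombinants = min(x$markers$recombinant_count))
}
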