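#' Classify marker dosage from F1 segregation
#'
#' In a pseudo-testcross, a single-dose allele (SDA, simplex) segregates 1:1
#' heterozygote:homozygote; a double-dose allele (DDA, duplex) segregates 5:1
#' under tetrasomic (4-homolog) or 4:1 under hexasomic (6-homolog)
#' inheritance. A marker is classified SDA when its het:hom ratio is inside
#' the symmetric band `(1/2, 2)` (strictly less than 2:1 in either
#' direction); otherwise the 5:1 and 4:1 ratios are tested by Pearson
#' goodness-of-fit chi-square (df 1, no continuity correction) and the marker
#' is a DDA of the inheritance class that fits (`P > alpha`), preferring the
#' larger p-value and flagging ambiguity when both fit. Markers fitting
#' nothing are `unclassified`.
#'
#' @param geno Long genotype tibble with `marker_id`, `individual`, `call`
#'   (0/1/2/NA); heterozygotes are `call == 1`, homozygotes 0 or 2.
#' @param alpha Significance level for the DDA ratio tests (default 0.05).
#' @param informative Optional tibble `marker_id`, `informative` (one of
#'   `maternal`, `paternal`, `both`, `neither`) carried through to the
#'   output; markers informative in both or neither parent are always
#'   `unclassified` (pseudo-testcross convention).
#' @return Tibble with one row per marker: counts, per-ratio chi-square
#'   statistics and p-values, `class` in `{SDA, DDA_tetrasomic,
#'   DDA_hexasomic, unclassified}` and `ambiguous`.
#' @seealso [classify_dosage_counts()] for the scalar rule,
#'   [summarize_dosage()].
#' @export
classify_dosage <- function(geno, alpha = 0.05, informative = NULL) {
  counts <- geno %>%
    filter(!is.na(.data$call)) %>%
    group_by(.data$marker_id) %>%
    summarise(n_het = sum(.data$call == 1L),
              n_hom = sum(.data$call != 1L), .groups = "drop")
  out <- classify_dosage_counts(counts$n_het, counts$n_hom, alpha = alpha)
  out <- bind_rows(out)
  out <- mutate(out, marker_id = counts$marker_id, .before = 1)
  if (!is.null(informative)) {
    out <- left_join(out, informative, by = "marker_id")
    out <- mutate(out,
                  class = if_else(.data$informative %in% c("both", "neither"),
                                  "unclassified", .data$class))
  }
  out
}

#' @param n_het,n_hom Heterozygote and homozygote counts (vectors).
#' @rdname classify_dosage
#' @examples
#' classify_dosage_counts(51, 51)  # SDA
#' classify_dosage_counts(85, 17)  # DDA_tetrasomic (exact 5:1)
#' classify_dosage_counts(80, 20)  # DDA_hexasomic (exact 4:1)
#' classify_dosage_counts(70, 30)  # unclassified
#' @export
classify_dosage_counts <- function(n_het, n_hom, alpha = 0.05) {
  stopifnot(length(n_het) == length(n_hom), all(n_het + n_hom > 0),
            alpha > 0, alpha < 1)
  n <- n_het + n_hom
  gof <- function(p_het) {
    e_het <- n * p_het; e_hom <- n * (1 - p_het)
    (n_het - e_het)^2 / e_het + (n_hom - e_hom)^2 / e_hom
  }
  chisq_5to1 <- gof(5 / 6)
  chisq_4to1 <- gof(4 / 5)
  p_5to1 <- pchisq(chisq_5to1, df = 1, lower.tail = FALSE)
  p_4to1 <- pchisq(chisq_4to1, df = 1, lower.tail = FALSE)
  sda <- n_het < 2 * n_hom & n_hom < 2 * n_het
  fit5 <- p_5to1 > alpha; fit4 <- p_4to1 > alpha
  class <- dplyr::case_when(
    sda ~ "SDA",
    fit5 & (!fit4 | p_5to1 >= p_4to1) ~ "DDA_tetrasomic",
    fit4 ~ "DDA_hexasomic",
    TRUE ~ "unclassified"
  )
  tibble(n_het = as.integer(n_het), n_hom = as.integer(n_hom),
         chisq_5to1 = chisq_5to1, p_5to1 = p_5to1,
         chisq_4to1 = chisq_4to1, p_4to1 = p_4to1,
         class = class, ambiguous = !sda & fit5 & fit4)
}

#' Tabulate dosage classes
#'
#' @param classification Output of [classify_dosage()]; may carry an
#'   `informative` column for per-parent tabulation.
#' @return Tibble of class counts and fractions (per parent when available).
#' @export
summarize_dosage <- function(classification) {
  if (nrow(classification) == 0)
    return(tibble(class = character(), n = integer(), fraction = numeric()))
  grp <- if ("informative" %in% names(classification))
    c("informative", "class") else "class"
  classification %>%
    count(across(dplyr::all_of(grp)), name = "n") %>%
    group_by(across(dplyr::all_of(setdiff(grp, "class")))) %>%
    mutate(fraction = .data$n / sum(.data$n)) %>%
    ungroup()
}
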