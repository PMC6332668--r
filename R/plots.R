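#' Heat-matrix plot of a molecular karyotype
#'
#' Marker-by-marker heat matrix in the style of a molecular-karyotype
#' figure: markers ordered by linkage group, each cell coloured by the
#' significance tier of its Fisher test — warm colours (yellow/orange/red)
#' for coupling, blues for repulsion, grey for non-significant.
#'
#' @param object A `polyk_karyotype`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.polyk_karyotype <- function(object, ...) {
  ord <- arrange(object$groups, .data$group, .data$marker_id)$marker_id
  pr <- object$pairs %>%
    mutate(
      level = dplyr::case_when(
        .data$tier == 0L ~ "ns",
        .data$direction == "coupling" ~ paste0("coupling_t", .data$tier),
        .data$direction == "repulsion" ~ paste0("repulsion_t", .data$tier),
        TRUE ~ "ns")
    )
  both <- bind_rows(
    select(pr, x = "marker_a", y = "marker_b", "level"),
    select(pr, x = "marker_b", y = "marker_a", "level")
  ) %>%
    mutate(x = factor(.data$x, levels = ord),
           y = factor(.data$y, levels = rev(ord)))
  pal <- c(ns = "grey92",
           coupling_t1 = "#ffe066", coupling_t2 = "#ff9933",
           coupling_t3 = "#cc0000",
           repulsion_t1 = "#9ecae1", repulsion_t2 = "#4292c6",
           repulsion_t3 = "#08306b")
  ggplot2::ggplot(both, ggplot2::aes(x = .data$x, y = .data$y,
                                     fill = .data$level)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = pal, name = "association") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Bar chart of dosage classification
#'
#' @param classification Output of [classify_dosage()].
#' @return A ggplot object.
#' @export
plot_dosage_summary <- function(classification) {
  s <- summarize_dosage(classification)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$class, y = .data$n)) +
    ggplot2::geom_col(fill = "#4292c6") +
    ggplot2::labs(x = "dosage class", y = "markers") +
    ggplot2::theme_minimal()
}

#' Recombinant counts along the ASGR cosegregation scan
#'
#' @param object A `polyk_coseg`.
#' @param map Optional tibble `marker_id`, `chrom`, `pos_cM`; when given,
#'   markers are placed at their map position.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.polyk_coseg <- function(object, map = NULL, ...) {
  d <- object$markers
  if (!is.null(map)) {
    d <- left_join(d, as_tibble(map), by = "marker_id")
    ggplot2::ggplot(d, ggplot2::aes(x = .data$pos_cM,
                                    y = .data$recombinant_count,
                                    colour = .data$perfect)) +
      ggplot2::geom_point() +
      ggplot2::facet_wrap(~chrom, scales = "free_x") +
      ggplot2::labs(x = "position (cM)", y = "recombinants vs ASGR") +
      ggplot2::theme_minimal()
  } else {
    d <- mutate(d, marker_id = factor(.data$marker_id,
                                      levels = d$marker_id))
    ggplot2::ggplot(d, ggplot2::aes(x = .data$marker_id,
                                    y = .data$recombinant_count,
                                    fill = .data$perfect)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = NULL, y = "recombinants vs ASGR") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                         size = 6))
  }
}
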