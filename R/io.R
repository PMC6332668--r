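#' Read and write genotype matrices
#'
#' The canonical interchange format is a comma-delimited text file with `#`
#' comment header lines documenting the coding, then columns `marker_id`,
#' `chrom`, `pos_cM` and one column per individual holding calls coded
#' `0` (homozygous reference), `1` (heterozygous), `2` (homozygous
#' alternate) or `NA` (missing). Positions are cM coordinates.
#'
#' @param geno Long genotype tibble (`marker_id`, `individual`, `call`).
#' @param map Tibble `marker_id`, `chrom`, `pos_cM` (one row per marker).
#' @param path File path.
#' @return `read_genotype_matrix()` returns a list with `geno` (long tibble)
#'   and `map`; `write_genotype_matrix()` returns `path` invisibly.
#' @export
write_genotype_matrix <- function(geno, map, path) {
  stopifnot(all(c("marker_id", "individual", "call") %in% names(geno)),
            all(c("marker_id", "chrom", "pos_cM") %in% names(map)))
  if (anyDuplicated(map$marker_id)) stop("duplicate marker ids in `map`")
  wide <- geno %>%
    select("marker_id", "individual", "call") %>%
    tidyr::pivot_wider(names_from = "individual", values_from = "call")
  out <- map %>%
    select("marker_id", "chrom", "pos_cM") %>%
    dplyr::inner_join(wide, by = "marker_id")
  writeLines(c(
    "# polykaryo genotype matrix",
    "# calls: 0 = hom ref, 1 = het, 2 = hom alt, NA = missing",
    "# pos_cM: genetic position in centimorgans"
  ), path)
  readr::write_csv(out, path, append = TRUE, col_names = TRUE, na = "NA")
  invisible(path)
}

#' @rdname write_genotype_matrix
#' @export
read_genotype_matrix <- function(path) {
  wide <- readr::read_csv(path, comment = "#", na = "NA",
                          show_col_types = FALSE)
  need <- c("marker_id", "chrom", "pos_cM")
  if (!all(need %in% names(wide)))
    stop("malformed genotype matrix: missing column(s) ",
         paste(setdiff(need, names(wide)), collapse = ", "))
  if (anyDuplicated(wide$marker_id))
    stop("duplicate marker ids in ", path)
  map <- select(wide, "marker_id", "chrom", "pos_cM") %>%
    mutate(chrom = as.character(.data$chrom))
  geno <- wide %>%
    select(-"chrom", -"pos_cM") %>%
    tidyr::pivot_longer(-"marker_id", names_to = "individual",
                        values_to = "call") %>%
    mutate(call = as.integer(.data$call))
  list(geno = geno, map = map)
}

#' Read and write read-count tables
#'
#' Long comma-delimited table with `#` comment header and columns
#' `marker_id`, `individual`, `ref_reads`, `alt_reads`.
#'
#' @param reads Read-count tibble (as from [sim_reads()]).
#' @param path File path.
#' @return `read_read_counts()` returns the tibble;
#'   `write_read_counts()` returns `path` invisibly.
#' @export
write_read_counts <- function(reads, path) {
  stopifnot(all(c("marker_id", "individual", "ref_reads", "alt_reads") %in%
                  names(reads)))
  writeLines(c("# polykaryo read counts",
               "# one row per marker x individual; biallelic ref/alt depths"),
             path)
  readr::write_csv(select(reads, "marker_id", "individual", "ref_reads",
                          "alt_reads"),
                   path, append = TRUE, col_names = TRUE, na = "NA")
  invisible(path)
}

#' @rdname write_read_counts
#' @export
read_read_counts <- function(path) {
  out <- readr::read_csv(path, comment = "#", na = "NA",
                         show_col_types = FALSE)
  need <- c("marker_id", "individual", "ref_reads", "alt_reads")
  if (!all(need %in% names(out)))
    stop("malformed read-count table: missing column(s) ",
         paste(setdiff(need, names(out)), collapse = ", "))
  mutate(out, ref_reads = as.integer(.data$ref_reads),
         alt_reads = as.integer(.data$alt_reads))
}

#' Import biallelic VCF allele depths as a read-count table
#'
#' Convenience adapter: reads a VCF with per-genotype `AD` (allele depth)
#' fields and converts the biallelic records to the same long read-count
#' tibble produced by [sim_reads()], so the downstream pipeline is format
#' agnostic. Requires the `vcfR` package.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @return Tibble `marker_id`, `individual`, `ref_reads`, `alt_reads`.
#' @export
read_vcf_counts <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the `vcfR` package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  biallelic <- !grepl(",", vcfR::getALT(v))
  v <- v[biallelic, ]
  ad <- vcfR::extract.gt(v, element = "AD")
  ids <- vcfR::getID(v)
  if (anyDuplicated(ids)) stop("duplicate marker ids in VCF")
  rownames(ad) <- ids
  ref <- apply(ad, 2, function(x) as.integer(sub(",.*", "", x)))
  alt <- apply(ad, 2, function(x) as.integer(sub(".*,", "", x)))
  tibble(
    marker_id = rep(ids, times = ncol(ad)),
    individual = rep(colnames(ad), each = nrow(ad)),
    ref_reads = as.integer(ref),
    alt_reads = as.integer(alt)
  )
}

pipeline_defaults <- function() {
  list(
    seed = NULL,
    n_chrom = 6, copy_number = 6,
    n_sda_per_homolog = 6, n_dda_per_pair = 1, length_cM = 100,
    spacing = "uniform",
    n_hybrids = 102, n_selfs = 12, undetermined_rate = 25 / 102,
    asgr = list(chrom = "1", pos_cM = 50, carrier = 1),
    mean_depth = 60, dispersion = NULL,
    t_hom = 11, t_het = 2, maf_min = 0.10,
    max_missing = 0.20, outlier_alpha = 1e-10,
    dosage_alpha = 0.05,
    lod_threshold = 7, tiers = c(0.05, 1e-3, 1e-5), majority = 0.5,
    min_shared_dda = 2, min_informative = 50
  )
}

#' Read a pipeline configuration file
#'
#' YAML file whose keys mirror the arguments of [run_pipeline()]; unknown
#' keys are rejected, and a `seed` is mandatory because every simulation
#' stage is stochastic.
#'
#' @param path Path to a YAML config.
#' @return A named list merging the file over the defaults.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$seed)) stop("config must set a `seed`")
  modifyList(defaults, cfg)
}

#' Run the full simulate-to-ASGR pipeline
#'
#' Simulates a hexaploid F1 pseudo-testcross (sexual mother x apomictic
#' father carrying a dominant ASGR), generates GBS-like read counts, calls
#' genotypes, filters markers and screens outlier progeny, classifies marker
#' dosage, builds the paternal molecular karyotype (grouping, Fisher
#' aggregation, homolog clustering, pairing classification), assigns DDA
#' markers and tests subgenome uniformity, and scans for ASGR
#' cosegregation. One mandatory seed makes the whole run reproducible.
#'
#' @param seed Integer seed (mandatory).
#' @param config Optional named list (or [read_run_config()] output)
#'   overriding the defaults listed in the vignette.
#' @return A `polyk_run` object (list of stage results with timings);
#'   `glance()` gives a one-row summary, [write_run_report()] a JSON report.
#' @export
run_pipeline <- function(seed, config = list()) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  cfg <- modifyList(pipeline_defaults(), config)
  cfg$seed <- as.integer(seed)
  set.seed(cfg$seed)
  timings <- list()
  tic <- function() Sys.time()
  lap <- function(t0) as.numeric(difftime(Sys.time(), t0, units = "secs"))

  t0 <- tic()
  mother <- sim_parent(n_chrom = cfg$n_chrom, copy_number = cfg$copy_number,
                       n_sda_per_homolog = cfg$n_sda_per_homolog,
                       n_dda_per_pair = cfg$n_dda_per_pair,
                       length_cM = cfg$length_cM, spacing = cfg$spacing,
                       prefix = "M")
  father <- sim_parent(n_chrom = cfg$n_chrom, copy_number = cfg$copy_number,
                       n_sda_per_homolog = cfg$n_sda_per_homolog,
                       n_dda_per_pair = cfg$n_dda_per_pair,
                       length_cM = cfg$length_cM, spacing = cfg$spacing,
                       asgr = cfg$asgr, prefix = "F")
  cross <- sim_cross(mother, father, n_hybrids = cfg$n_hybrids,
                     n_selfs = cfg$n_selfs,
                     undetermined_rate = cfg$undetermined_rate)
  reads <- sim_reads(cross, mean_depth = cfg$mean_depth,
                     dispersion = cfg$dispersion)
  timings$simulate <- lap(t0)

  t0 <- tic()
  geno <- call_genotypes(reads, t_hom = cfg$t_hom, t_het = cfg$t_het,
                         maf_min = cfg$maf_min)
  geno <- filter_markers(geno, max_missing = cfg$max_missing)
  self_ids <- cross$individuals$individual[
    cross$individuals$origin == "maternal_self"]
  maternal_imputed <- impute_parent_from_selfs(geno, self_ids)
  timings$call <- lap(t0)

  t0 <- tic()
  hybrid_ids <- cross$individuals$individual[
    cross$individuals$origin == "hybrid"]
  geno_h <- filter(geno, .data$individual %in% hybrid_ids)
  dosage_cls <- classify_dosage(geno_h, alpha = cfg$dosage_alpha)
  sda_ids <- dosage_cls$marker_id[dosage_cls$class == "SDA"]
  screen <- screen_outlier_progeny(geno_h, sda_ids,
                                   alpha = cfg$outlier_alpha)
  timings$classify <- lap(t0)

  t0 <- tic()
  pat <- cross$markers$marker_id[cross$markers$parent == "paternal"]
  pat_sda <- intersect(sda_ids, pat)
  presence <- geno_h %>%
    filter(.data$marker_id %in% pat_sda) %>%
    mutate(present = if_else(is.na(.data$call), NA_integer_,
                             as.integer(.data$call > 0))) %>%
    select("marker_id", "individual", "present") %>%
    tidyr::pivot_wider(names_from = "marker_id", values_from = "present")
  pm <- as.matrix(presence[, -1, drop = FALSE])
  rownames(pm) <- presence$individual
  groups <- two_point_grouping(pm, lod_threshold = cfg$lod_threshold)
  assoc <- pairwise_association(pm)
  karyotype <- aggregate_karyotype(assoc, groups, tiers = cfg$tiers,
                                   majority = cfg$majority)
  timings$karyotype <- lap(t0)

  t0 <- tic()
  pat_dda <- intersect(
    dosage_cls$marker_id[grepl("^DDA", dosage_cls$class)], pat)
  dda_res <- NULL; uniformity <- NULL
  if (length(pat_dda)) {
    dda_presence <- geno_h %>%
      filter(.data$marker_id %in% pat_dda) %>%
      mutate(present = if_else(is.na(.data$call), NA_integer_,
                               as.integer(.data$call > 0))) %>%
      select("marker_id", "individual", "present") %>%
      tidyr::pivot_wider(names_from = "marker_id", values_from = "present")
    dm <- as.matrix(dda_presence[, -1, drop = FALSE])
    rownames(dm) <- dda_presence$individual
    dm <- dm[rownames(pm), , drop = FALSE]
    dda_res <- assign_dda(dm, pm, groups)
  }
  components <- cluster_homologs(karyotype, dda = dda_res,
                                 min_shared_dda = cfg$min_shared_dda,
                                 expected_copies = NULL)
  if (!is.null(dda_res))
    uniformity <- uniformity_by_component(dda_res, components)
  pairing <- classify_pairing(karyotype, components)
  timings$linkdda <- lap(t0)

  t0 <- tic()
  modes <- cross$individuals %>%
    filter(.data$origin == "hybrid") %>%
    select("individual", mode = "phenotype")
  coseg <- cosegregation_scan(modes, pm,
                              min_informative = cfg$min_informative)
  timings$asgr <- lap(t0)

  structure(
    list(config = cfg, cross = cross, reads_summary = nrow(reads),
         geno = geno, maternal_imputed = maternal_imputed,
         dosage = dosage_cls, screen = screen,
         groups = groups, karyotype = karyotype, components = components,
         pairing = pairing, dda = dda_res, uniformity = uniformity,
         coseg = coseg, timings = timings),
    class = "polyk_run"
  )
}

#' Per-chromosome subgenome uniformity tests from DDA assignments
#'
#' Tallies unambiguous [assign_dda()] assignments over the homolog-group
#' pairs of each chromosome component (zero-padded to all `choose(k, 2)`
#' pairs of a k-homolog chromosome) and applies
#' [subgenome_uniformity_test()] per chromosome.
#'
#' @param dda [assign_dda()] output.
#' @param components [cluster_homologs()] output.
#' @return Tibble with one row per chromosome that received at least one
#'   assignment: `chromosome`, `chisq`, `df`, `p_value`, `n_pairs`, `total`.
#' @export
uniformity_by_component <- function(dda, components) {
  tal <- dda %>%
    filter(!.data$ambiguous) %>%
    count(.data$group1, .data$group2, name = "n_dda") %>%
    left_join(select(components, group1 = "group", "chromosome"),
              by = "group1")
  out <- list()
  for (ch in unique(components$chromosome)) {
    members <- components$group[components$chromosome == ch]
    if (length(members) < 2) next
    sub <- filter(tal, .data$chromosome == ch, .data$group2 %in% members)
    if (nrow(sub) == 0 || sum(sub$n_dda) == 0) next
    k <- choose(length(members), 2)
    if (k < 2) next
    tally <- c(sub$n_dda, rep(0L, k - nrow(sub)))
    res <- suppressWarnings(subgenome_uniformity_test(tally))
    out[[length(out) + 1]] <- mutate(res, chromosome = ch, .before = 1)
  }
  if (length(out) == 0)
    return(tibble(chromosome = character(), chisq = numeric(),
                  df = integer(), p_value = numeric(), n_pairs = integer(),
                  total = integer()))
  bind_rows(out)
}

#' @export
print.polyk_run <- function(x, ...) {
  g <- glance(x)
  cat("<polyk_run> seed ", x$config$seed, ": ", g$n_markers_called,
      " markers called, ", g$n_sda, " SDA / ", g$n_dda, " DDA; ",
      g$n_groups, " linkage groups in ", g$n_chromosomes,
      " chromosome components; ", g$n_perfect_coseg,
      " markers in perfect ASGR linkage\n", sep = "")
  invisible(x)
}

#' @export
glance.polyk_run <- function(x, ...) {
  tibble(
    seed = x$config$seed,
    n_markers_called = length(unique(x$geno$marker_id)),
    n_sda = sum(x$dosage$class == "SDA"),
    n_dda = sum(grepl("^DDA", x$dosage$class)),
    n_excluded_progeny = sum(x$screen$excluded),
    n_groups = length(unique(x$groups$group)),
    n_chromosomes = length(unique(x$components$chromosome)),
    n_preferential_pairs = sum(x$pairing$call == "preferential"),
    min_uniformity_p = if (!is.null(x$uniformity) && nrow(x$uniformity))
      min(x$uniformity$p_value) else NA_real_,
    n_perfect_coseg = length(x$coseg$perfect)
  )
}

#' Write a JSON run report
#'
#' Serialises the stage summaries, counts and timings of a [run_pipeline()]
#' result so that no result exists only inside an R session.
#'
#' @param run A `polyk_run`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(run, path) {
  stopifnot(inherits(run, "polyk_run"))
  report <- list(
    config = run$config[setdiff(names(run$config), "asgr")],
    asgr_config = run$config$asgr,
    summary = as.list(glance(run)),
    dosage_summary = summarize_dosage(run$dosage),
    group_sizes = count(run$groups, .data$group),
    components = run$components,
    pairing = run$pairing,
    uniformity = run$uniformity,
    coseg = tidy(run$coseg),
    timings = run$timings
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
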