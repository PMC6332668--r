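#' Construct a parental genome for meiosis simulation
#'
#' A parental genome describes one hexaploid (or aneuploid) parent: how many
#' homologous copies of each base chromosome it carries, where its segregating
#' marker alleles sit (which homologs carry them, at which cM positions), how
#' its homologs pair at meiosis, and optionally a dominant apospory locus
#' (ASGR) on one homolog.
#'
#' @param markers Data frame with columns `marker_id` (unique), `chrom`,
#'   `pos_cM` (>= 0) and `carriers`, a list-column of integer vectors giving
#'   the homolog indices (1..copy number) that carry the segregating allele.
#'   One carrier = simplex/SDA, two = duplex/DDA. May have zero rows for a
#'   marker-free parent.
#' @param copy_number Integer copy number per chromosome: either a single
#'   value recycled over all chromosomes, or a named vector keyed by
#'   chromosome. Default 6 (hexasomic); 5 or 7 model compensated aneuploidy.
#' @param pairing Optional data frame of preferential bivalents with columns
#'   `chrom`, `h1`, `h2`, `affinity` (probability in `[0, 1]` that the pair is
#'   formed before the remaining homologs are matched uniformly at random).
#'   Pairs must be disjoint within a chromosome. `NULL` means fully random
#'   (polysomic) pairing.
#' @param asgr Optional `list(chrom =, pos_cM =, carrier =)` placing a
#'   dominant apospory locus on one homolog.
#' @param univalent_p Probability that an unpaired homolog (odd copy number)
#'   enters the gamete. Default 1/2 (unbiased transmission).
#' @return An object of class `polyk_parent`.
#' @seealso [sim_parent()] for a randomised builder, [sim_cross()].
#' @export
parental_genome <- function(markers, copy_number = 6, pairing = NULL,
                            asgr = NULL, univalent_p = 0.5) {
  markers <- as_tibble(markers)
  if (nrow(markers) == 0 && !"marker_id" %in% names(markers)) {
    markers <- tibble(marker_id = character(), chrom = character(),
                      pos_cM = numeric(), carriers = list())
  }
  stopifnot(all(c("marker_id", "chrom", "pos_cM", "carriers") %in% names(markers)),
            is.numeric(univalent_p), univalent_p >= 0, univalent_p <= 1)
  if (anyDuplicated(markers$marker_id)) stop("duplicate marker_id in `markers`")
  if (nrow(markers) && (any(!is.finite(markers$pos_cM)) || any(markers$pos_cM < 0)))
    stop("marker positions must be finite and nonnegative")
  markers$chrom <- as.character(markers$chrom)
  if (!"is_asgr" %in% names(markers)) markers$is_asgr <- FALSE
  markers$is_asgr[is.na(markers$is_asgr)] <- FALSE

  chroms <- unique(c(markers$chrom,
                     if (!is.null(names(copy_number))) names(copy_number)))
  if (length(chroms) == 0) stop("genome has no chromosomes")
  if (is.null(names(copy_number))) {
    copy_number <- setNames(rep(as.integer(copy_number), length.out = length(chroms)),
                            chroms)
  } else {
    copy_number <- setNames(as.integer(copy_number), names(copy_number))
    missing_ch <- setdiff(chroms, names(copy_number))
    if (length(missing_ch)) stop("no copy number for chromosome(s): ",
                                 paste(missing_ch, collapse = ", "))
  }
  stopifnot(all(copy_number >= 1))

  bad <- purrr::map2_lgl(markers$carriers, markers$chrom, function(cc, ch) {
    length(cc) < 1 || any(cc < 1) || any(cc > copy_number[[ch]]) || anyDuplicated(cc) > 0
  })
  if (any(bad)) stop("carriers must be distinct homolog indices within the ",
                     "chromosome's copy number (markers: ",
                     paste(head(markers$marker_id[bad]), collapse = ", "), ")")

  if (!is.null(asgr)) {
    stopifnot(all(c("chrom", "pos_cM", "carrier") %in% names(asgr)))
    asgr$chrom <- as.character(asgr$chrom)
    if (!asgr$chrom %in% names(copy_number))
      stop("ASGR chromosome '", asgr$chrom, "' absent from the genome")
    if (asgr$carrier < 1 || asgr$carrier > copy_number[[asgr$chrom]])
      stop("ASGR carrier homolog does not exist on chromosome ", asgr$chrom)
    markers <- bind_rows(markers,
                         tibble(marker_id = ".ASGR", chrom = asgr$chrom,
                                pos_cM = asgr$pos_cM,
                                carriers = list(as.integer(asgr$carrier)),
                                is_asgr = TRUE))
  }

  if (!is.null(pairing)) {
    pairing <- as_tibble(pairing)
    stopifnot(all(c("chrom", "h1", "h2", "affinity") %in% names(pairing)),
              all(pairing$affinity >= 0), all(pairing$affinity <= 1))
    pairing$chrom <- as.character(pairing$chrom)
    for (ch in unique(pairing$chrom)) {
      pp <- pairing[pairing$chrom == ch, ]
      hs <- c(pp$h1, pp$h2)
      if (!ch %in% names(copy_number) || any(hs < 1) || any(hs > copy_number[[ch]]))
        stop("preferential pair references an unknown homolog on chromosome ", ch)
      if (anyDuplicated(hs)) stop("preferential pairs overlap on chromosome ", ch)
    }
  }

  markers <- arrange(markers, .data$chrom, .data$pos_cM, .data$marker_id)
  structure(
    list(markers = markers, copy_number = copy_number, pairing = pairing,
         asgr = asgr, univalent_p = univalent_p),
    class = "polyk_parent"
  )
}

#' @export
print.polyk_parent <- function(x, ...) {
  nm <- sum(!x$markers$is_asgr)
  cat("<polyk_parent> ", length(x$copy_number), " chromosome(s), 2n = ",
      sum(x$copy_number), ", ", nm, " marker(s)",
      if (!is.null(x$asgr)) " + ASGR", "\n", sep = "")
  invisible(x)
}

#' Randomised parental genome builder
#'
#' Builds a [parental_genome()] with markers placed at random positions:
#' `n_sda_per_homolog` simplex markers on every homolog, and
#' `n_dda_per_pair` duplex markers on each eligible homolog pair. Duplex
#' placement can be restricted to pairs within a homolog subset
#' (`dda_pool`), emulating an allopolyploid parent whose double-dose alleles
#' are shared within, not across, subgenomes.
#'
#' @inheritParams parental_genome
#' @param n_chrom Number of base chromosomes (default 6, as for a genome with
#'   base number x = 6).
#' @param copy_number Copy number per chromosome (scalar or vector of length
#'   `n_chrom`).
#' @param n_sda_per_homolog Simplex markers per homolog.
#' @param n_dda_per_pair Duplex markers per eligible homolog pair.
#' @param length_cM Chromosome length in cM.
#' @param dda_pool Optional list (by chromosome index) of homolog index
#'   vectors; duplex markers are drawn only from pairs inside the pool.
#' @param prefix Marker-id prefix, so two parents' marker sets stay disjoint.
#' @param spacing `"uniform"` draws marker positions uniformly at random
#'   (GBS-like); `"even"` places them on a regular grid
#'   (`length_cM * (i - 0.5) / n`), convenient for guaranteed two-point
#'   connectivity in simulation studies.
#' @return A `polyk_parent`.
#' @export
sim_parent <- function(n_chrom = 6, copy_number = 6, n_sda_per_homolog = 6,
                       n_dda_per_pair = 1, length_cM = 100, pairing = NULL,
                       dda_pool = NULL, asgr = NULL, prefix = "M",
                       spacing = c("uniform", "even"), univalent_p = 0.5) {
  spacing <- match.arg(spacing)
  place <- function(n) {
    if (spacing == "even") length_cM * (seq_len(n) - 0.5) / n
    else sort(runif(n, 0, length_cM))
  }
  copy_number <- rep(as.integer(copy_number), length.out = n_chrom)
  names(copy_number) <- as.character(seq_len(n_chrom))
  rows <- list()
  for (ci in seq_len(n_chrom)) {
    ch <- as.character(ci)
    k <- copy_number[[ci]]
    for (h in seq_len(k)) {
      if (n_sda_per_homolog > 0) {
        pos <- place(n_sda_per_homolog)
        rows[[length(rows) + 1]] <- tibble(
          marker_id = sprintf("%s%s_h%d_s%d", prefix, ch, h, seq_along(pos)),
          chrom = ch, pos_cM = pos, carriers = lapply(pos, function(.) h))
      }
    }
    pool <- if (!is.null(dda_pool)) dda_pool[[ci]] else seq_len(k)
    if (n_dda_per_pair > 0 && length(pool) >= 2) {
      prs <- combn(sort(pool), 2)
      for (j in seq_len(ncol(prs))) {
        pos <- place(n_dda_per_pair)
        rows[[length(rows) + 1]] <- tibble(
          marker_id = sprintf("%s%s_d%d.%d_%d", prefix, ch, prs[1, j], prs[2, j],
                              seq_along(pos)),
          chrom = ch, pos_cM = pos,
          carriers = lapply(pos, function(.) as.integer(prs[, j])))
      }
    }
  }
  markers <- if (length(rows)) bind_rows(rows) else
    tibble(marker_id = character(), chrom = character(),
           pos_cM = numeric(), carriers = list())
  parental_genome(markers, copy_number = copy_number, pairing = pairing,
                  asgr = asgr, univalent_p = univalent_p)
}

#' Pair homologs into bivalents
#'
#' Partitions a chromosome's homolog set into bivalents (plus one univalent
#' when the copy number is odd). Preferential pairs are resolved first, in
#' listed order: each forms with probability `affinity` if both members are
#' still free. The remaining homologs are then matched uniformly at random
#' over all perfect matchings (each matching of 6 free homologs has
#' probability 1/15).
#'
#' @param homologs Integer vector of homolog indices (or a single integer k,
#'   meaning `1:k`).
#' @param preferential Optional data frame with columns `h1`, `h2`,
#'   `affinity`.
#' @return A list with `bivalents` (list of length-2 integer vectors) and
#'   `univalent` (length-0 or length-1 integer vector).
#' @export
pair_homologs <- function(homologs, preferential = NULL) {
  if (length(homologs) == 1 && homologs > 1) homologs <- seq_len(homologs)
  homologs <- as.integer(homologs)
  stopifnot(length(homologs) >= 1, anyDuplicated(homologs) == 0)
  bivalents <- list()
  avail <- homologs
  if (!is.null(preferential) && nrow(preferential)) {
    hs <- c(preferential$h1, preferential$h2)
    if (!all(hs %in% homologs))
      stop("preferential pair references a homolog not in the copy set")
    if (anyDuplicated(hs)) stop("preferential pairs must be disjoint")
    for (i in seq_len(nrow(preferential))) {
      h1 <- preferential$h1[i]; h2 <- preferential$h2[i]
      if (h1 %in% avail && h2 %in% avail &&
          runif(1) < preferential$affinity[i]) {
        bivalents[[length(bivalents) + 1]] <- as.integer(c(h1, h2))
        avail <- setdiff(avail, c(h1, h2))
      }
    }
  }
  perm <- avail[sample.int(length(avail))]
  while (length(perm) >= 2) {
    bivalents[[length(bivalents) + 1]] <- perm[1:2]
    perm <- perm[-(1:2)]
  }
  list(bivalents = bivalents,
       univalent = if (length(perm)) perm else integer(0))
}

# transmit one chromosome from a bivalent: start from either member with
# probability 1/2, switch member between adjacent markers with Haldane r.
# pos must be sorted; carriers a list of integer vectors. Returns logical
# presence at each marker.
transmit_bivalent <- function(pair, pos, carriers) {
  nm <- length(pos)
  if (nm == 0) return(logical(0))
  start <- sample.int(2L, 1L)
  sw <- if (nm > 1) runif(nm - 1) < haldane(diff(pos)) else logical(0)
  idx <- (c(0L, cumsum(sw)) + start - 1L) %% 2L + 1L
  member <- pair[idx]
  purrr::map2_lgl(carriers, member, function(cc, m) m %in% cc)
}

#' Generate one gamete from a parental genome
#'
#' Runs one meiosis: homologs of each chromosome are paired with
#' [pair_homologs()]; each bivalent transmits a (possibly recombinant)
#' chromosome built by switching between its two members with Haldane
#' recombination fractions between adjacent markers; a univalent is
#' transmitted whole with probability `univalent_p`.
#'
#' @param parent A `polyk_parent`.
#' @return A list with `dosage` (named integer vector over the parent's
#'   markers, counting transmitted allele copies), `n_copies` (chromosomes
#'   transmitted per base chromosome) and `asgr` (logical; `NA` when no ASGR
#'   is configured).
#' @export
generate_gamete <- function(parent) {
  stopifnot(inherits(parent, "polyk_parent"))
  mk <- parent$markers
  dosage <- setNames(integer(nrow(mk)), mk$marker_id)
  n_copies <- setNames(integer(length(parent$copy_number)),
                       names(parent$copy_number))
  for (ch in names(parent$copy_number)) {
    k <- parent$copy_number[[ch]]
    rows <- which(mk$chrom == ch)
    pos <- mk$pos_cM[rows]
    carriers <- mk$carriers[rows]
    pref <- if (!is.null(parent$pairing))
      parent$pairing[parent$pairing$chrom == ch, ] else NULL
    part <- pair_homologs(seq_len(k), pref)
    got <- integer(length(rows))
    for (bv in part$bivalents)
      got <- got + transmit_bivalent(bv, pos, carriers)
    nt <- length(part$bivalents)
    if (length(part$univalent) && runif(1) < parent$univalent_p) {
      got <- got + purrr::map_lgl(carriers, function(cc) part$univalent %in% cc)
      nt <- nt + 1L
    }
    dosage[rows] <- got
    n_copies[[ch]] <- nt
  }
  asgr <- NA
  if (!is.null(parent$asgr)) asgr <- unname(dosage[".ASGR"] > 0)
  list(dosage = dosage, n_copies = n_copies, asgr = asgr)
}

#' Simulate an F1 pseudo-testcross population
#'
#' Crosses two parental genomes: each hybrid receives one maternal and one
#' paternal gamete; selfed contaminants receive two independent maternal
#' gametes (and therefore carry no paternal-unique alleles). When the
#' paternal genome carries an ASGR locus, the reproductive mode is apomictic
#' exactly when the paternal gamete transmits the ASGR haplotype (dominant,
#' monogenic); a fraction of individuals is independently relabelled
#' `undetermined`, emulating progeny whose embryo sacs could not be scored.
#'
#' @param mother,father `polyk_parent` objects with disjoint marker ids.
#' @param n_hybrids Number of true hybrids (default 102, a typical analysed
#'   population size for this design).
#' @param n_selfs Number of accidental maternal selfs appended to the
#'   population (default 12).
#' @param undetermined_rate Probability an individual's reproductive mode is
#'   relabelled `undetermined` (default 25/102, the rate at which pistil
#'   phenotyping fails in a population of this size).
#' @return A `polyk_cross` object: list with `markers` (truth table of both
#'   parents' markers, with `parent` and `dose` columns), `individuals`
#'   (tibble of `individual`, `origin`, `phenotype`), `dosage`
#'   (markers x individuals integer matrix of true allele dosages) and
#'   `copy_number` (chromosomes x individuals matrix).
#' @export
sim_cross <- function(mother, father, n_hybrids = 102, n_selfs = 12,
                      undetermined_rate = 25 / 102) {
  stopifnot(inherits(mother, "polyk_parent"), inherits(father, "polyk_parent"),
            n_hybrids >= 0, n_selfs >= 0, n_hybrids + n_selfs > 0,
            undetermined_rate >= 0, undetermined_rate <= 1)
  if (!is.null(mother$asgr))
    stop("the ASGR is modelled on the paternal (apomictic) genome only")
  mm <- mother$markers[!mother$markers$is_asgr, ]
  fm <- father$markers[!father$markers$is_asgr, ]
  if (length(intersect(mm$marker_id, fm$marker_id)))
    stop("maternal and paternal marker ids overlap; use distinct prefixes")

  markers <- bind_rows(
    mutate(mm, parent = "maternal"),
    mutate(fm, parent = "paternal")
  ) %>%
    mutate(dose = lengths(.data$carriers)) %>%
    select("marker_id", "parent", "chrom", "pos_cM", "dose", "carriers")

  n <- n_hybrids + n_selfs
  ids <- sprintf("P%03d", seq_len(n))
  origin <- c(rep("hybrid", n_hybrids), rep("maternal_self", n_selfs))
  chroms <- union(names(mother$copy_number), names(father$copy_number))

  dosage <- matrix(0L, nrow = nrow(markers), ncol = n,
                   dimnames = list(markers$marker_id, ids))
  cpn <- matrix(0L, nrow = length(chroms), ncol = n,
                dimnames = list(chroms, ids))
  pheno <- rep(NA_character_, n)
  has_asgr <- !is.null(father$asgr)

  for (i in seq_len(n)) {
    gm <- generate_gamete(mother)
    g2 <- if (origin[i] == "hybrid") generate_gamete(father)
          else generate_gamete(mother)
    dmat <- setNames(integer(nrow(markers)), markers$marker_id)
    dmat[names(gm$dosage)] <- dmat[names(gm$dosage)] + gm$dosage
    if (origin[i] == "hybrid") {
      keep <- names(g2$dosage)[!names(g2$dosage) %in% ".ASGR"]
      dmat[keep] <- dmat[keep] + g2$dosage[keep]
    } else {
      keep <- names(g2$dosage)
      dmat[keep] <- dmat[keep] + g2$dosage[keep]
    }
    dosage[, i] <- dmat
    for (ch in chroms) {
      cpn[ch, i] <- (if (ch %in% names(gm$n_copies)) gm$n_copies[[ch]] else 0L) +
        (if (origin[i] == "hybrid" && ch %in% names(g2$n_copies))
           g2$n_copies[[ch]]
         else if (origin[i] != "hybrid" && ch %in% names(g2$n_copies))
           g2$n_copies[[ch]] else 0L)
    }
    if (has_asgr) {
      pheno[i] <- if (origin[i] == "hybrid" && isTRUE(g2$asgr)) "apomictic"
                  else "sexual"
    }
  }
  if (has_asgr && undetermined_rate > 0) {
    und <- runif(n) < undetermined_rate
    pheno[und] <- "undetermined"
  }
  # drop the maternal ".ASGR" guard: mothers cannot carry one (checked above)
  structure(
    list(mother = mother, father = father,
         markers = markers,
         individuals = tibble(individual = ids, origin = origin,
                              phenotype = pheno),
         dosage = dosage, copy_number = cpn),
    class = "polyk_cross"
  )
}

#' @export
print.polyk_cross <- function(x, ...) {
  cat("<polyk_cross> ", nrow(x$markers), " markers x ", ncol(x$dosage),
      " individuals (", sum(x$individuals$origin == "hybrid"), " hybrids, ",
      sum(x$individuals$origin == "maternal_self"), " selfs)\n", sep = "")
  invisible(x)
}

#' True allele-presence matrix of a simulated cross
#'
#' @param cross A `polyk_cross`.
#' @param parent Restrict to markers segregating from one parent
#'   (`"maternal"`, `"paternal"`, or `"both"` for all).
#' @return Integer matrix (individuals x markers) of 0/1 allele presence.
#' @export
true_presence <- function(cross, parent = c("both", "maternal", "paternal")) {
  stopifnot(inherits(cross, "polyk_cross"))
  parent <- match.arg(parent)
  keep <- if (parent == "both") cross$markers$marker_id
          else cross$markers$marker_id[cross$markers$parent == parent]
  t(cross$dosage[keep, , drop = FALSE] > 0) * 1L
}

#' Simulate GBS-like read counts for a cross
#'
#' Per marker and individual, a sequencing depth is drawn (Poisson with mean
#' `mean_depth` times the marker's depth multiplier, or negative binomial
#' when `dispersion` is given); alternate-allele reads are
#' `Binomial(depth, dosage / copy_number)` and reference reads make up the
#' rest.
#'
#' @param cross A `polyk_cross`.
#' @param mean_depth Mean depth lambda (> 0, default 60).
#' @param dispersion Optional negative-binomial size parameter (> 0); `NULL`
#'   uses Poisson depths.
#' @param depth_multiplier Optional named vector of per-marker depth
#'   multipliers (> 0).
#' @return A tibble with columns `marker_id`, `individual`, `ref_reads`,
#'   `alt_reads`.
#' @export
sim_reads <- function(cross, mean_depth = 60, dispersion = NULL,
                      depth_multiplier = NULL) {
  stopifnot(inherits(cross, "polyk_cross"), mean_depth > 0,
            is.null(dispersion) || dispersion > 0)
  mk <- cross$markers
  ids <- colnames(cross$dosage)
  mult <- setNames(rep(1, nrow(mk)), mk$marker_id)
  if (!is.null(depth_multiplier)) {
    stopifnot(all(depth_multiplier > 0),
              all(names(depth_multiplier) %in% mk$marker_id))
    mult[names(depth_multiplier)] <- depth_multiplier
  }
  nmk <- nrow(mk); nid <- length(ids)
  lam <- rep(mean_depth * mult[mk$marker_id], times = nid)
  depth <- if (is.null(dispersion)) rpois(nmk * nid, lam)
           else rnbinom(nmk * nid, size = dispersion, mu = lam)
  dsg <- as.vector(cross$dosage)
  cpn <- cross$copy_number[mk$chrom, ids, drop = FALSE]
  frac <- ifelse(as.vector(cpn) > 0, dsg / as.vector(cpn), 0)
  alt <- rbinom(nmk * nid, depth, frac)
  tibble(
    marker_id = rep(mk$marker_id, times = nid),
    individual = rep(ids, each = nmk),
    ref_reads = as.integer(depth - alt),
    alt_reads = as.integer(alt)
  )
}

#' @export
tidy.polyk_cross <- function(x, ...) {
  mk <- x$markers
  ids <- colnames(x$dosage)
  tibble(
    marker_id = rep(mk$marker_id, times = length(ids)),
    individual = rep(ids, each = nrow(mk)),
    dosage = as.integer(as.vector(x$dosage))
  ) %>%
    left_join(select(mk, "marker_id", "parent", "chrom", "pos_cM", "dose"),
              by = "marker_id") %>%
    left_join(x$individuals, by = "individual")
}

#' @export
glance.polyk_cross <- function(x, ...) {
  tibble(
    n_markers = nrow(x$markers),
    n_individuals = ncol(x$dosage),
    n_hybrids = sum(x$individuals$origin == "hybrid"),
    n_selfs = sum(x$individuals$origin == "maternal_self"),
    n_apomictic = sum(x$individuals$phenotype == "apomictic", na.rm = TRUE),
    n_sexual = sum(x$individuals$phenotype == "sexual", na.rm = TRUE),
    n_undetermined = sum(x$individuals$phenotype == "undetermined", na.rm = TRUE)
  )
}
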