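# shared builders for simulated fixtures; everything is generated in code

# a marker-free (or single-marker) sexual mother, so crosses can focus on
# paternal segregation
minimal_mother <- function(n_chrom = 1, copy_number = 6) {
  parental_genome(
    tibble::tibble(marker_id = paste0("Mstub", seq_len(n_chrom)),
                   chrom = as.character(seq_len(n_chrom)),
                   pos_cM = 0, carriers = lapply(seq_len(n_chrom), function(.) 1L)),
    copy_number = stats::setNames(rep(copy_number, length.out = n_chrom),
                                  as.character(seq_len(n_chrom)))
  )
}

# individuals x markers true-presence matrix for one parent's markers,
# optionally restricted by dose (1 = SDA, 2 = DDA)
presence_of <- function(cross, parent = "paternal", dose = 1) {
  ids <- cross$markers$marker_id[cross$markers$parent == parent &
                                   cross$markers$dose %in% dose]
  true_presence(cross)[, ids, drop = FALSE]
}

# majority true homolog per recovered linkage group (SDA markers only)
group_homologs <- function(groups, parent_obj) {
  truth <- parent_obj$markers
  truth <- truth[!truth$is_asgr & lengths(truth$carriers) == 1, ]
  hom <- stats::setNames(vapply(truth$carriers, `[`, integer(1), 1),
                         truth$marker_id)
  out <- vapply(split(groups$marker_id, groups$group), function(ids) {
    as.integer(names(sort(table(hom[ids]), decreasing = TRUE))[1])
  }, integer(1))
  out
}

# long genotype tibble from explicit call vectors (markers x individuals)
geno_from_matrix <- function(m) {
  tibble::tibble(
    marker_id = rep(rownames(m), times = ncol(m)),
    individual = rep(colnames(m), each = nrow(m)),
    call = as.integer(as.vector(m))
  )
}
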