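# Shared fixtures built in code.

# A small two-population panel with clear structure.
quick_sim <- function(seed = 1, n_snps = 300, n_ref = 25, fst = 0.15,
                      q = c(0.5, 0.5), ...) {
  cfg <- sim_config(
    n_pops = 2, fst_per_pop = c(fst, fst), n_snps = n_snps,
    n_ref_per_pop = n_ref, admixture_truth = q, ...
  )
  c(simulate_panel(cfg, seed), list(cfg = cfg))
}

# Hand-built fragment rows. `quals` is a single phred score applied to all
# bases unless a quality string is given.
make_fragment <- function(sequence, ref_bases, pos = 1L, chrom = "1",
                          strand = "+", mapq = 37L, qual = 40L,
                          sample_id = "s1", base_quals = NULL) {
  if (is.null(base_quals)) {
    base_quals <- strrep(intToUtf8(qual + 33L), nchar(sequence))
  }
  tibble::tibble(
    sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
    strand = strand, mapq = as.integer(mapq), sequence = sequence,
    base_quals = base_quals, ref_bases = ref_bases
  )
}

# Pseudo-haploid call set built directly from a dosage vector (0/2/NA)
# against a panel's site table.
calls_from_vector <- function(sites, dose, sample_id = "anc") {
  out <- tibble::tibble(
    sample_id = sample_id, chrom = sites$chrom, pos = sites$pos,
    id = sites$id, ref = sites$ref, alt = sites$alt,
    call = as.integer(dose), depth = ifelse(is.na(dose), 0L, 1L)
  )
  class(out) <- c("pseudo_haploid_calls", class(out))
  attr(out, "n_called") <- sum(!is.na(dose))
  out
}

# Best-permutation mean absolute error between an estimated Q and a truth
# matrix (labels are arbitrary).
aligned_q_mae <- function(q, truth) {
  k <- ncol(q)
  perms <- adnakit:::all_permutations(k)
  min(apply(perms, 1, function(p) mean(abs(q[, p, drop = FALSE] - truth))))
}
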