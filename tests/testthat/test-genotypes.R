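test_that("pseudo-haploid calling follows single-read sampling rules", {
  sites <- tibble::tibble(
    chrom = "1", pos = c(100L, 200L, 300L), id = c("s1", "s2", "s3"),
    ref = c("A", "C", "G"), alt = c("C", "A", "T")
  )
  frags <- dplyr::bind_rows(
    make_fragment("CAAAA", "AAAAA", pos = 100), # alt at s1
    # s3 uncovered; s2 covered by a read whose base is neither allele
    make_fragment("GGGGG", "CGGGG", pos = 200)
  )
  calls <- call_pseudohaploid(frags, sites, seed = 1)
  expect_identical(calls$call, c(2L, NA_integer_, NA_integer_))
  expect_identical(attr(calls, "n_called"), 1L)
  expect_identical(calls$depth, c(1L, 1L, 0L))
})

test_that("random base choice at covered sites is uniform", {
  # 10,000 independent sites, each piled up with 3 ref reads and 1 alt read:
  # each site's pick is an independent uniform choice among 4 bases
  m <- 10000L
  sites <- tibble::tibble(
    chrom = "1", pos = seq_len(m) * 10L, id = sprintf("s%d", seq_len(m)),
    ref = "A", alt = "C"
  )
  # reads start at distinct offsets so none is removed as a duplicate
  one <- function(seqs, refs, offset) {
    tibble::tibble(
      sample_id = "s1", chrom = "1", pos = sites$pos - offset,
      strand = "+", mapq = 37L, sequence = seqs,
      base_quals = strrep("I", nchar(seqs)), ref_bases = refs
    )
  }
  frags <- dplyr::bind_rows(
    one("AAAAA", "AAAAA", 1L), # site base A (ref)
    one("AAAAA", "AAAAA", 2L),
    one("AAAAA", "AAAAA", 3L),
    one("CAAAA", "AAAAA", 0L) # site base C (alt)
  )
  calls <- call_pseudohaploid(frags, sites, seed = 7)
  expect_true(all(!is.na(calls$call)))
  expect_lt(abs(mean(calls$call == 2L) - 0.25), 0.013)
})

test_that("duplicates are collapsed and quality gates applied before calling", {
  sites <- tibble::tibble(chrom = "1", pos = 100L, id = "s1", ref = "A", alt = "C")
  frags <- dplyr::bind_rows(
    make_fragment("C", "A", pos = 100),
    make_fragment("C", "A", pos = 100), # exact duplicate (chrom,pos,strand,len)
    make_fragment("A", "A", pos = 100, mapq = 10, strand = "-") # mapq-gated
  )
  calls <- call_pseudohaploid(frags, sites, seed = 1)
  expect_identical(calls$depth, 1L)
  expect_identical(calls$call, 2L)
  expect_identical(attr(calls, "qc")$duplicates_removed, 1L)
  # low base quality is gated too
  fbq <- make_fragment("C", "A", pos = 100, qual = 5)
  expect_identical(call_pseudohaploid(fbq, sites, seed = 1)$call, NA_integer_)
})

test_that("sites contradicting the fragment reference are skipped and reported", {
  sites <- tibble::tibble(chrom = "1", pos = 100L, id = "s1", ref = "A", alt = "C")
  frags <- make_fragment("G", "G", pos = 100) # aligned reference base is G, not A
  calls <- call_pseudohaploid(frags, sites, seed = 1)
  expect_identical(calls$call, NA_integer_)
  expect_identical(attr(calls, "qc")$sites_skipped_ref_mismatch, "s1")
})

test_that("pseudo-haploid dosage is unbiased for the true alt fraction", {
  cfg <- sim_config(n_snps = 1200, mean_depth = 3, admixture_truth = c(0.5, 0.5))
  sim <- simulate_panel(cfg, 8)
  frags <- simulate_fragments(sim$truth, cfg, 9)
  calls <- call_pseudohaploid(frags, sim$truth$sites, seed = 10)
  ok <- !is.na(calls$call)
  expect_lt(
    abs(mean(calls$call[ok]) / 2 - mean(sim$truth$ancient_genotypes[1, ok]) / 2),
    0.02
  )
})

test_that("homozygization resolves hets fairly and deterministically", {
  sites <- tibble::tibble(
    chrom = "1", pos = 1:2 * 100L, id = c("s1", "s2"), ref = "A", alt = "C"
  )
  ind <- tibble::tibble(id = sprintf("i%d", 1:10000), population = "p")
  g <- cbind(rep(1L, 10000), rep(c(0L, 2L, NA), length.out = 10000))
  panel <- genotype_panel(ind, sites, g)
  hom <- homozygize_panel(panel, seed = 3)
  expect_true(all(hom$genotypes[, 1] %in% c(0L, 2L)))
  expect_lt(abs(mean(hom$genotypes[, 1]) - 1), 0.04)
  expect_identical(hom$genotypes[, 2], panel$genotypes[, 2]) # non-hets untouched
  expect_identical(homozygize_panel(panel, seed = 3), hom)
  # a het-free panel is unchanged
  expect_identical(homozygize_panel(hom, seed = 99), hom)
})

test_that("transition masking removes exactly the deamination-mimicking SNPs", {
  s <- tibble::tibble(
    chrom = "1", pos = 1:5 * 10L, id = sprintf("s%d", 1:5),
    ref = c("A", "C", "A", "G", "T"), alt = c("G", "T", "C", "A", "G")
  )
  kept <- mask_transitions(s)
  expect_identical(kept$id, c("s3", "s5"))
  expect_identical(mask_transitions(kept), kept) # idempotent
  expect_identical(nrow(mask_transitions(s[0, ])), 0L)
  allt <- s[s$id %in% c("s3", "s5"), ]
  expect_identical(mask_transitions(allt), allt)
})

test_that("merging harmonizes alleles and respects the mode", {
  sim <- quick_sim(2, n_snps = 60, n_ref = 10)
  panel <- homozygize_panel(sim$panel, 1)
  full <- calls_from_vector(panel$sites, panel$genotypes[1, ])
  # allele-swapped duplicate merges losslessly
  swapped <- full
  swapped$ref <- panel$sites$alt
  swapped$alt <- panel$sites$ref
  swapped$call <- 2L - swapped$call
  m <- merge_calls(panel, swapped, mode = "union")
  expect_identical(
    unname(m$genotypes[nrow(m$genotypes), ]),
    unname(panel$genotypes[1, ])
  )
  # strand-complemented calls harmonize too
  comp <- full
  comp$ref <- unname(c(A = "T", C = "G", G = "C", T = "A")[panel$sites$ref])
  comp$alt <- unname(c(A = "T", C = "G", G = "C", T = "A")[panel$sites$alt])
  ambig <- paste(panel$sites$ref, panel$sites$alt) %in%
    c("A T", "T A", "C G", "G C")
  comp <- comp[!ambig, ]
  m2 <- merge_calls(panel, comp, mode = "union")
  got <- m2$genotypes[nrow(m2$genotypes), !ambig]
  expect_identical(unname(got), unname(panel$genotypes[1, !ambig]))
  # intersection keeps only covered sites
  part <- full
  part$call[11:60] <- NA_integer_
  mi <- merge_calls(panel, part, mode = "intersection")
  expect_identical(nrow(mi$sites), 10L)
  expect_identical(
    mi$individuals$population[nrow(mi$individuals)], "ancient"
  )
  # zero overlap errors
  none <- full
  none$call <- NA_integer_
  expect_error(
    merge_calls(panel, none, mode = "intersection"),
    "no shared sites"
  )
  # irreconcilable alleles error (A/G against a panel A/C site)
  bad <- full
  bad$ref <- "A"
  bad$alt <- "G"
  badsite <- panel$sites$ref == "A" & panel$sites$alt == "C"
  expect_gt(sum(badsite), 0)
  bad <- bad[badsite, ]
  bad$call <- 0L
  expect_error(merge_calls(panel, bad, mode = "union"), "irreconcilable")
})

test_that("LD pruning drops linked duplicates and spares unlinked sites", {
  # a single unstructured population: sites are truly unlinked (population
  # structure would itself induce r^2 between unlinked SNPs)
  cfg <- sim_config(
    n_pops = 1, fst_per_pop = 0.1, n_snps = 200, n_ref_per_pop = 200,
    admixture_truth = matrix(1, 1, 1)
  )
  panel <- simulate_panel(cfg, 4)$panel
  # unlinked panel: nearly everything survives
  kept <- ld_prune(panel, r2_max = 0.2)
  expect_gte(nrow(kept), 0.95 * 200)
  # a duplicated SNP column (r^2 = 1) loses exactly one copy
  sites2 <- panel$sites
  sites2$pos[2] <- sites2$pos[1] + 1L
  sites2$id[2] <- "dup_of_1"
  g2 <- panel$genotypes
  g2[, 2] <- g2[, 1]
  dup <- genotype_panel(panel$individuals, sites2, g2)
  kept2 <- ld_prune(dup, r2_max = 0.2)
  expect_identical(sum(kept2$id %in% c(panel$sites$id[1], "dup_of_1")), 1L)
  # r2_max = 1 is the identity
  expect_equal(ld_prune(dup, r2_max = 1), dup$sites)
})
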