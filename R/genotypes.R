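#' Pseudo-haploid genotype calls at panel SNPs
#'
#' Pile up passing bases over the site table and, at every covered site,
#' choose one base uniformly at random: the call is 0 when it equals the
#' site's reference allele, 2 when it equals the alternate, and missing
#' otherwise. Duplicate fragments (same chrom, pos, strand, length) are
#' collapsed before piling up. Sites where an overlapping fragment's
#' aligned reference base disagrees with the site's reference allele are
#' skipped and reported.
#'
#' @param frags Fragment tibble.
#' @param sites Site tibble (chrom, pos, id, ref, alt).
#' @param min_bq,min_mq Base- and mapping-quality gates (defaults 15 / 30).
#' @param seed Integer seed for the random base choice.
#' @param sample_id Label for the call set; defaults to the fragment
#'   table's (single) sample id.
#' @return A tibble of class `pseudo_haploid_calls` with one row per site:
#'   `sample_id`, `chrom`, `pos`, `id`, `ref`, `alt`, `call` (0, 2 or NA),
#'   `depth`.
#'   Attributes: `n_called`, `qc` (list with `sites_skipped_ref_mismatch`,
#'   `duplicates_removed`).
#' @examples
#' cfg <- sim_config(n_snps = 30, mean_depth = 2)
#' sim <- simulate_panel(cfg, 1)
#' frags <- simulate_fragments(sim$truth, cfg, 1)
#' calls <- call_pseudohaploid(frags, sim$truth$sites, seed = 1)
#' attr(calls, "n_called")
#' @export
call_pseudohaploid <- function(frags, sites, min_bq = 15L, min_mq = 30L,
                               seed = 1L, sample_id = NULL) {
  sites <- validate_sites(sites)
  if (is.null(sample_id)) {
    sample_id <- if (nrow(frags)) frags$sample_id[1] else "sample"
  }
  dup_key <- paste(frags$chrom, frags$pos, frags$strand, nchar(frags$sequence))
  n_dup <- sum(duplicated(dup_key))
  frags <- frags[!duplicated(dup_key) & frags$mapq >= min_mq, , drop = FALSE]

  skipped <- character(0)
  calls <- rep(NA_integer_, nrow(sites))
  depth <- rep(0L, nrow(sites))

  if (nrow(frags) > 0) {
    bt <- fragment_base_table(frags)
    bt$chrom <- frags$chrom[bt$frag]
    key <- paste(bt$chrom, bt$gpos)
    site_key <- paste(sites$chrom, sites$pos)
    bt$site <- match(key, site_key)
    bt <- bt[!is.na(bt$site), , drop = FALSE]

    # flag sites whose aligned reference bases contradict the site table
    bad <- unique(bt$site[bt$ref != sites$ref[bt$site] & bt$ref != "N"])
    skipped <- sites$id[bad]

    bt <- bt[!(bt$site %in% bad) & bt$qual >= min_bq & bt$obs != "N", ,
      drop = FALSE
    ]
    if (nrow(bt) > 0) {
      picked <- with_seed(seed, {
        bt %>%
          group_by(.data$site) %>%
          slice(sample.int(n(), 1)) %>%
          ungroup()
      })
      dp <- bt %>% count(.data$site)
      depth[dp$site] <- dp$n
      base <- picked$obs
      s <- picked$site
      calls[s] <- ifelse(base == sites$ref[s], 0L,
        ifelse(base == sites$alt[s], 2L, NA_integer_)
      )
    }
  }

  out <- tibble(
    sample_id = sample_id,
    chrom = sites$chrom, pos = sites$pos, id = sites$id,
    ref = sites$ref, alt = sites$alt,
    call = calls, depth = depth
  )
  class(out) <- c("pseudo_haploid_calls", class(out))
  attr(out, "n_called") <- sum(!is.na(calls))
  attr(out, "qc") <- list(
    sites_skipped_ref_mismatch = skipped,
    duplicates_removed = n_dup
  )
  out
}

#' Homozygize a diploid panel
#'
#' Replaces every heterozygous genotype by 0 or 2 with probability one half
#' each, independently, leaving homozygous and missing entries untouched.
#' This removes the diploid/pseudo-haploid asymmetry before joint analysis
#' with single-read-sampled ancient calls.
#'
#' @param panel A [genotype_panel()].
#' @param seed Integer seed.
#' @return A `genotype_panel` with entries in `{0, 2, NA}`.
#' @export
homozygize_panel <- function(panel, seed = 1L) {
  g <- panel$genotypes
  het <- which(!is.na(g) & g == 1L)
  if (length(het)) {
    g[het] <- with_seed(seed, 2L * rbinom(length(het), 1, 0.5))
  }
  genotype_panel(panel$individuals, panel$sites, g)
}

#' Remove transition SNPs
#'
#' Drops SNPs whose allele pair is C/T or G/A (in either order). These are
#' the mutation classes mimicked by post-mortem cytosine deamination and
#' are conventionally excluded from ancient-sample genotype analyses.
#'
#' @param sites Site tibble.
#' @return The site tibble restricted to transversion SNPs.
#' @examples
#' s <- tibble::tibble(
#'   chrom = "1", pos = 1:3, id = paste0("s", 1:3),
#'   ref = c("A", "C", "A"), alt = c("G", "T", "C")
#' )
#' mask_transitions(s) # keeps only the A/C SNP
#' @export
mask_transitions <- function(sites) {
  sites <- validate_sites(sites)
  pair <- paste(pmin(sites$ref, sites$alt), pmax(sites$ref, sites$alt))
  sites[!pair %in% c("C T", "A G"), , drop = FALSE]
}

#' Merge pseudo-haploid call sets into a reference panel
#'
#' Harmonizes each call set's alleles with the panel (exact match; ref/alt
#' swap with dosage flip; strand complement; complemented swap) and appends
#' the samples with population label `"ancient"`. Strand-ambiguous SNPs
#' (A/T, C/G) are reported in the QC attribute. In `"intersection"` mode
#' the merged panel is restricted to sites the calls cover (union across
#' samples of non-missing calls); in `"union"` mode all panel sites are
#' kept with missing entries.
#'
#' @param panel A [genotype_panel()].
#' @param calls A `pseudo_haploid_calls` tibble or list of them.
#' @param mode `"intersection"` or `"union"`.
#' @return A `genotype_panel` with appended individuals; attribute `qc`
#'   lists flipped, complemented and ambiguous site ids.
#' @export
merge_calls <- function(panel, calls, mode = c("intersection", "union")) {
  mode <- match.arg(mode)
  if (inherits(calls, "pseudo_haploid_calls")) calls <- list(calls)

  site_key <- paste(panel$sites$chrom, panel$sites$pos)
  flipped <- character(0)
  complemented <- character(0)
  ambiguous <- panel$sites$id[
    paste(panel$sites$ref, panel$sites$alt) %in% c("A T", "T A", "C G", "G C")
  ]

  rows <- list()
  ids <- character(0)
  covered <- rep(FALSE, nrow(panel$sites))
  for (cs in calls) {
    idx <- match(paste(cs$chrom, cs$pos), site_key)
    known <- !is.na(idx) & !is.na(cs$call)
    row <- rep(NA_integer_, nrow(panel$sites))
    if (any(known)) {
      pref <- panel$sites$ref[idx[known]]
      palt <- panel$sites$alt[idx[known]]
      # calls were made against their own site table; map through its alleles
      csref <- cs_ref_alleles(cs)[known, , drop = FALSE]
      dos <- integer(sum(known))
      # precedence matters: for strand-ambiguous SNPs (A/T, C/G) the
      # complemented interpretations coincide with the direct ones, so an
      # exact allele match must win over a complement/flip
      same <- csref$ref == pref & csref$alt == palt
      swap <- !same & csref$ref == palt & csref$alt == pref
      comp <- !same & !swap &
        COMPLEMENT[csref$ref] == pref & COMPLEMENT[csref$alt] == palt
      compswap <- !same & !swap & !comp &
        COMPLEMENT[csref$ref] == palt & COMPLEMENT[csref$alt] == pref
      dos[same] <- cs$call[known][same]
      dos[swap] <- 2L - cs$call[known][swap]
      dos[comp] <- cs$call[known][comp]
      dos[compswap] <- 2L - cs$call[known][compswap]
      ok <- same | swap | comp | compswap
      if (any(!ok)) {
        abort(
          paste0(
            "irreconcilable alleles at site(s): ",
            paste(head(panel$sites$id[idx[known]][!ok], 5), collapse = ", ")
          ),
          class = "adnakit_format_error"
        )
      }
      flipped <- c(flipped, panel$sites$id[idx[known]][swap | compswap])
      complemented <- c(complemented, panel$sites$id[idx[known]][comp | compswap])
      row[idx[known]] <- dos
      covered[idx[known]] <- TRUE
    }
    rows[[length(rows) + 1]] <- row
    ids <- c(ids, cs$sample_id[1])
  }

  if (mode == "intersection" && !any(covered)) {
    abort("no shared sites between calls and panel",
      class = "adnakit_format_error"
    )
  }
  keep <- if (mode == "intersection") covered else rep(TRUE, nrow(panel$sites))

  g <- rbind(
    panel$genotypes[, keep, drop = FALSE],
    do.call(rbind, rows)[, keep, drop = FALSE]
  )
  ind <- bind_rows(
    panel$individuals,
    tibble(id = ids, population = "ancient")
  )
  out <- genotype_panel(ind, panel$sites[keep, , drop = FALSE], g)
  attr(out, "qc") <- list(
    flipped = unique(flipped),
    complemented = unique(complemented),
    strand_ambiguous = ambiguous
  )
  out
}

# ref/alt alleles the calls were made against. call_pseudohaploid carries
# them as columns when available; otherwise they must be supplied by
# attaching `ref`/`alt` columns before merging.
cs_ref_alleles <- function(cs) {
  if (all(c("ref", "alt") %in% names(cs))) {
    tibble(ref = cs$ref, alt = cs$alt)
  } else {
    abort("call set lacks ref/alt columns needed for allele harmonization",
      class = "adnakit_format_error"
    )
  }
}

#' LD pruning by sliding-window r-squared
#'
#' Slides a window of `window` SNPs advancing by `step`; while any pair of
#' retained SNPs inside the window has squared Pearson dosage correlation
#' above `r2_max`, the later SNP of the worst (highest r-squared) pair is
#' dropped. Returns the retained site table.
#'
#' @param panel A [genotype_panel()].
#' @param r2_max Maximum tolerated r-squared (default 0.2).
#' @param window Window size in SNPs.
#' @param step Window advance in SNPs.
#' @return The retained subset of `panel$sites`.
#' @export
ld_prune <- function(panel, r2_max = 0.2, window = 50L, step = 5L) {
  m <- nrow(panel$sites)
  ord <- order(panel$sites$chrom, panel$sites$pos)
  g <- panel$genotypes[, ord, drop = FALSE]
  keep <- rep(TRUE, m)
  if (m >= 2) {
    starts <- unique(c(seq(1L, max(m - window + 1L, 1L), by = step)))
    for (s in starts) {
      w <- s:min(s + window - 1L, m)
      w <- w[keep[w]]
      if (length(w) < 2) next
      r2 <- suppressWarnings(cor(g[, w, drop = FALSE],
        use = "pairwise.complete.obs"
      ))^2
      r2[is.na(r2)] <- 0
      diag(r2) <- 0
      while (max(r2) > r2_max) {
        worst <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
        drop_local <- max(worst) # the later SNP of the pair
        keep[w[drop_local]] <- FALSE
        r2[drop_local, ] <- 0
        r2[, drop_local] <- 0
      }
    }
  }
  panel$sites[sort(ord[keep]), , drop = FALSE]
}
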