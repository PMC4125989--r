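#' Simulate a structured reference genotype panel
#'
#' Draws a reference panel under the Balding-Nichols model: an ancestral
#' allele frequency per SNP, per-population frequencies Beta-distributed
#' around it with divergence `FST`, reference genotypes binomial in the
#' population frequency, and ancient-sample genotypes binomial in the
#' admixture-weighted frequency. A single diploid "contaminant" individual
#' is drawn from the configured contaminant population; its genotype feeds
#' the modern-contamination arm of [simulate_fragments()].
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return A list with elements `panel` (a [genotype_panel()]) and `truth`
#'   (a `sim_truth` list: `sites`, `ancestral_freq`, `pop_freqs` (pops x
#'   SNPs), `ref_genotypes`, `ancient_genotypes`, `admixture_truth`,
#'   `contaminant_genotype`, damage parameters, `karyotype`).
#' @examples
#' sim <- simulate_panel(sim_config(n_snps = 50, n_ref_per_pop = 10), seed = 1)
#' sim$panel
#' @export
simulate_panel <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    m <- config$n_snps
    k <- config$n_pops
    p_anc <- runif(m, config$ancestral_freq_range[1], config$ancestral_freq_range[2])

    # Balding-Nichols: f ~ Beta(p(1-F)/F, (1-p)(1-F)/F); F = 0 degenerates
    # to the ancestral frequency itself.
    pop_freqs <- matrix(0, nrow = k, ncol = m)
    for (kk in seq_len(k)) {
      fst <- config$fst_per_pop[kk]
      if (fst == 0) {
        pop_freqs[kk, ] <- p_anc
      } else {
        a <- p_anc * (1 - fst) / fst
        b <- (1 - p_anc) * (1 - fst) / fst
        pop_freqs[kk, ] <- rbeta(m, a, b)
      }
    }

    n_ref <- config$n_ref_per_pop * k
    ref_geno <- matrix(0L, nrow = n_ref, ncol = m)
    pops <- rep(seq_len(k), each = config$n_ref_per_pop)
    for (i in seq_len(n_ref)) {
      ref_geno[i, ] <- rbinom(m, 2, pop_freqs[pops[i], ])
    }

    q <- config$admixture_truth
    anc_geno <- matrix(0L, nrow = nrow(q), ncol = m)
    for (s in seq_len(nrow(q))) {
      dose <- as.vector(q[s, , drop = FALSE] %*% pop_freqs)
      anc_geno[s, ] <- rbinom(m, 2, dose)
    }

    contaminant <- rbinom(m, 2, pop_freqs[config$contaminant_pop, ])

    # SNP alleles: uniform over ordered distinct base pairs, so the site
    # table carries a realistic mix of transitions and transversions.
    ref_allele <- sample(BASES, m, replace = TRUE)
    alt_allele <- vapply(ref_allele, function(r) sample(setdiff(BASES, r), 1),
      character(1)
    )
    sites <- tibble(
      chrom = "1",
      pos = seq_len(m) * 1000L,
      id = sprintf("snp%d", seq_len(m)),
      ref = unname(ref_allele),
      alt = unname(alt_allele)
    )

    individuals <- tibble(
      id = sprintf("pop%d_ind%d", pops, sequence(rep(config$n_ref_per_pop, k))),
      population = sprintf("pop%d", pops)
    )
    panel <- genotype_panel(individuals, sites, ref_geno)

    truth <- structure(
      list(
        sites = sites,
        ancestral_freq = p_anc,
        pop_freqs = pop_freqs,
        ref_genotypes = ref_geno,
        ancient_genotypes = anc_geno,
        admixture_truth = q,
        contaminant_genotype = contaminant,
        damage = list(
          dmax = config$damage_dmax, decay = config$damage_decay,
          bg = config$damage_bg
        ),
        karyotype = config$karyotype,
        mt_haplogroup = NA_character_
      ),
      class = "sim_truth"
    )
    list(panel = panel, truth = truth)
  })
}

# Shifted-geometric fragment lengths: min + Geom(1 / (mean - min + 1)).
draw_fragment_lengths <- function(n, config) {
  p <- 1 / (config$fragment_mean - config$fragment_min + 1)
  config$fragment_min + rgeom(n, p)
}

# Core fragment factory. Builds n fragments in genomic orientation around
# anchor positions. Deamination is applied symmetrically (C->T from the
# left end, G->A from the right end of the *genomic* strand); because the
# two terminal curves are identical this equals read-space 5' C->T /
# 3' G->A damage for either strand.
synth_fragments <- function(chrom, anchor_pos, anchor_ref, anchor_read,
                            damaged, config, sample_id) {
  n <- length(anchor_pos)
  if (n == 0) {
    return(empty_fragments())
  }
  lens <- draw_fragment_lengths(n, config)
  offs <- 1L + as.integer(floor(runif(n) * lens)) # anchor offset in fragment
  starts <- pmax(anchor_pos - offs + 1L, 1L)

  total <- sum(lens)
  fid <- rep.int(seq_len(n), lens)
  bpos <- sequence(lens) # 1..L within fragment
  ref <- sample(BASES, total, replace = TRUE)

  anchor_idx <- cumsum(c(0L, lens[-n])) + (anchor_pos - starts) + 1L
  keep_anchor <- !is.na(anchor_ref)
  obs <- ref
  obs[anchor_idx[keep_anchor]] <- anchor_read[keep_anchor]
  # known polymorphic sites are masked (N) in the aligned-reference string,
  # as damage profiling conventionally excludes known SNPs so that true
  # variants are never counted as deamination
  ref[anchor_idx[keep_anchor]] <- "N"

  # terminal deamination on damaged molecules
  z5 <- bpos
  z3 <- rep.int(lens, lens) - bpos + 1L
  dmg <- rep.int(damaged, lens)
  u <- runif(total)
  d5 <- damage_curve(z5, config$damage_dmax, config$damage_decay, config$damage_bg)
  d3 <- damage_curve(z3, config$damage_dmax, config$damage_decay, config$damage_bg)
  obs[dmg & obs == "C" & u < d5] <- "T"
  obs[dmg & obs == "G" & u < d3] <- "A"

  # independent per-base sequencing error to a uniform different base
  err <- runif(total) < config$base_error
  if (any(err)) {
    cur <- match(obs[err], BASES)
    shift <- sample.int(3L, sum(err), replace = TRUE)
    obs[err] <- BASES[((cur - 1L + shift) %% 4L) + 1L]
  }

  q <- as.integer(round(-10 * log10(max(config$base_error, 1e-4))))
  ends <- cumsum(lens)
  starts_chr <- ends - lens + 1L
  seq_all <- paste(obs, collapse = "")
  ref_all <- paste(ref, collapse = "")
  qual_char <- substr(int_to_phred(q), 1, 1)

  tibble(
    sample_id = sample_id,
    chrom = chrom,
    pos = as.integer(starts),
    strand = sample(c("+", "-"), n, replace = TRUE),
    mapq = 37L,
    sequence = substring(seq_all, starts_chr, ends),
    base_quals = strrep(qual_char, lens),
    ref_bases = substring(ref_all, starts_chr, ends),
    origin = ifelse(damaged, "endogenous", "contaminant")
  )
}

empty_fragments <- function() {
  tibble(
    sample_id = character(), chrom = character(), pos = integer(),
    strand = character(), mapq = integer(), sequence = character(),
    base_quals = character(), ref_bases = character(), origin = character()
  )
}

#' Simulate low-coverage damaged fragments over panel SNPs
#'
#' For every ancient sample in the truth object, draws a Poisson number of
#' reads per SNP site, assigns each read to the endogenous genotype with
#' probability `1 - contamination` (otherwise to the modern contaminant
#' individual), samples one allele from the chosen diploid genotype, embeds
#' it in random flanking reference sequence, and applies geometric-decay
#' terminal cytosine deamination (endogenous molecules only) plus uniform
#' base error. The `origin` column records the simulation ground truth and
#' is ignored by all analysis functions.
#'
#' @param truth `sim_truth` from [simulate_panel()].
#' @param config The matching [sim_config()].
#' @param seed Integer seed.
#' @param samples Which ancient samples (rows of `admixture_truth`) to
#'   simulate; default all.
#' @return Fragment tibble (one row per read) with columns `sample_id`,
#'   `chrom`, `pos`, `strand`, `mapq`, `sequence`, `base_quals`,
#'   `ref_bases` (the SNP position itself is masked as `N`, mirroring the
#'   convention that known polymorphic sites are excluded from damage
#'   profiling), `origin`.
#' @examples
#' sim <- simulate_panel(sim_config(n_snps = 20, n_ref_per_pop = 5), 1)
#' frags <- simulate_fragments(sim$truth, sim_config(n_snps = 20, n_ref_per_pop = 5), 1)
#' head(frags)
#' @export
simulate_fragments <- function(truth, config, seed = config$seed,
                               samples = seq_len(nrow(truth$admixture_truth))) {
  stopifnot(inherits(truth, "sim_truth"))
  if (nrow(truth$sites) == 0) {
    abort("truth contains no sites", class = "adnakit_parameter_error")
  }
  with_seed(seed, {
    out <- vector("list", length(samples))
    for (si in seq_along(samples)) {
      s <- samples[si]
      m <- nrow(truth$sites)
      depth <- rpois(m, config$mean_depth)
      site_idx <- rep.int(seq_len(m), depth)
      n <- length(site_idx)
      if (n == 0) {
        out[[si]] <- empty_fragments()
        next
      }
      endo <- runif(n) >= config$contamination
      g <- ifelse(endo,
        truth$ancient_genotypes[s, site_idx],
        truth$contaminant_genotype[site_idx]
      )
      carries_alt <- runif(n) < g / 2
      allele <- ifelse(carries_alt,
        truth$sites$alt[site_idx],
        truth$sites$ref[site_idx]
      )
      out[[si]] <- synth_fragments(
        chrom = truth$sites$chrom[site_idx],
        anchor_pos = truth$sites$pos[site_idx],
        anchor_ref = truth$sites$ref[site_idx],
        anchor_read = allele,
        damaged = endo,
        config = config,
        sample_id = sprintf("ancient%d", s)
      )
    }
    bind_rows(out)
  })
}

#' Simulate X/Y-aligned read counts for a karyotype
#'
#' An XY individual yields Y reads at rate `xy_ry` (before mismapping);
#' an XX individual yields Y reads only through `mismap_rate`. Counts sum
#' to `n_total`.
#'
#' @param karyotype `"XX"` or `"XY"`.
#' @param n_total Total sex-chromosome reads (>= 0).
#' @param config A [sim_config()] (supplies `xy_ry` and `mismap_rate`).
#' @param seed Integer seed.
#' @return Named integer vector `c(nX = ..., nY = ...)`.
#' @examples
#' simulate_sex_counts("XY", 2000, sim_config(), seed = 1)
#' @export
simulate_sex_counts <- function(karyotype, n_total, config = sim_config(),
                                seed = config$seed) {
  stopifnot(karyotype %in% c("XX", "XY"), n_total >= 0)
  if (n_total == 0) {
    return(c(nX = 0L, nY = 0L))
  }
  with_seed(seed, {
    m <- config$mismap_rate
    p_y <- if (karyotype == "XY") {
      config$xy_ry * (1 - m) + (1 - config$xy_ry) * m
    } else {
      m
    }
    ny <- rbinom(1, n_total, p_y)
    c(nX = as.integer(n_total - ny), nY = as.integer(ny))
  })
}

#' Simulate sex-chromosome fragments
#'
#' Fragment-table counterpart of [simulate_sex_counts()]: emits fragments
#' whose `chrom` label is `"X"` or `"Y"`, with the same damage and error
#' model as autosomal fragments, so PMD-restricted sex estimation can be
#' exercised end to end. Contaminant fragments (undamaged) are drawn with
#' female chromosome proportions.
#'
#' @param config A [sim_config()] (karyotype, contamination, damage).
#' @param n_total Total sex-chromosome reads.
#' @param seed Integer seed.
#' @param sample_id Sample label for the output rows.
#' @return Fragment tibble as in [simulate_fragments()].
#' @export
simulate_sex_fragments <- function(config, n_total, seed = config$seed,
                                   sample_id = "ancient1") {
  if (n_total == 0) {
    return(empty_fragments())
  }
  with_seed(seed, {
    endo <- runif(n_total) >= config$contamination
    kary <- ifelse(endo, config$karyotype, "XX")
    m <- config$mismap_rate
    p_y <- ifelse(
      kary == "XY", config$xy_ry * (1 - m) + (1 - config$xy_ry) * m, m
    )
    is_y <- runif(n_total) < p_y
    synth_fragments(
      chrom = ifelse(is_y, "Y", "X"),
      anchor_pos = as.integer(sample.int(1e6L, n_total, replace = TRUE)) + 200L,
      anchor_ref = rep(NA_character_, n_total),
      anchor_read = rep(NA_character_, n_total),
      damaged = endo,
      config = config,
      sample_id = sample_id
    )
  })
}
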