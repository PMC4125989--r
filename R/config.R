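#' Simulation configuration for the synthetic ancient-DNA generator
#'
#' Bundles every knob of the synthetic-data module: Balding-Nichols panel
#' structure, low-coverage fragment generation with terminal cytosine
#' deamination, modern contamination, sex-chromosome read behaviour and
#' fragment-length geometry. Defaults describe a typical poorly-preserved
#' historical bone sample sequenced at shallow shotgun depth.
#'
#' @param n_pops Number of reference populations.
#' @param fst_per_pop Per-population divergence (FST) from the shared
#'   ancestral allele frequency; each in `[0, 1)`. `0` collapses the
#'   Balding-Nichols Beta to a point mass at the ancestral frequency.
#' @param n_snps Number of unlinked SNPs.
#' @param ancestral_freq_range Interval within (0, 1) from which ancestral
#'   allele frequencies are drawn uniformly.
#' @param n_ref_per_pop Reference individuals simulated per population.
#' @param admixture_truth Matrix (or single vector) of ancestry proportions
#'   for the simulated ancient samples, one row per sample, rows summing
#'   to 1; columns are populations.
#' @param mean_depth Expected reads per SNP site (Poisson rate).
#' @param base_error Per-base substitution error probability in `[0, 0.25]`.
#' @param damage_dmax 5' terminal deamination probability (amplitude of the
#'   geometric decay), in `[0, 1)`.
#' @param damage_decay Geometric decay rate per base from the fragment end,
#'   in `(0, 1]`.
#' @param damage_bg Background (interior) deamination probability in
#'   `[0, 0.1]`.
#' @param contamination Fraction of fragments drawn from the modern
#'   contaminant individual instead of the endogenous genotype, in `[0, 1]`.
#' @param fragment_mean,fragment_min Mean and minimum of the shifted
#'   geometric fragment-length distribution (bases).
#' @param karyotype `"XX"` or `"XY"`; used by [simulate_sex_counts()].
#' @param mismap_rate Fraction of sex-chromosome reads assigned to the wrong
#'   sex chromosome (drives the small Y count of female samples).
#' @param xy_ry Expected Ry, nY / (nX + nY), for an XY individual before
#'   mismapping. Default 0.11 sits above the 0.075 male band and makes
#'   strict confidence-interval sex assignment reliable from roughly 2,000
#'   sex-chromosome reads upward.
#' @param contaminant_pop Index of the population the contaminant individual
#'   is drawn from.
#' @param seed Default master seed recorded in the config (operations also
#'   take explicit seeds).
#' @return A `sim_config` list with validated fields.
#' @examples
#' cfg <- sim_config(n_pops = 2, fst_per_pop = c(0.1, 0.1), n_snps = 100)
#' cfg$damage_dmax
#' @export
sim_config <- function(n_pops = 2,
                       fst_per_pop = rep(0.1, n_pops),
                       n_snps = 1000,
                       ancestral_freq_range = c(0.05, 0.95),
                       n_ref_per_pop = 50,
                       admixture_truth = NULL,
                       mean_depth = 1,
                       base_error = 0.002,
                       damage_dmax = 0.3,
                       damage_decay = 0.3,
                       damage_bg = 0.01,
                       contamination = 0,
                       fragment_mean = 60,
                       fragment_min = 30,
                       karyotype = c("XX", "XY"),
                       mismap_rate = 0.002,
                       xy_ry = 0.11,
                       contaminant_pop = 1,
                       seed = 1) {
  karyotype <- match.arg(karyotype)
  if (n_pops < 1 || n_snps < 1 || n_ref_per_pop < 1) {
    abort("n_pops, n_snps and n_ref_per_pop must all be >= 1",
      class = "adnakit_parameter_error"
    )
  }
  if (length(fst_per_pop) != n_pops) {
    abort("fst_per_pop must have one entry per population",
      class = "adnakit_parameter_error"
    )
  }
  if (any(fst_per_pop < 0 | fst_per_pop >= 1)) {
    abort("fst_per_pop entries must lie in [0, 1)",
      class = "adnakit_parameter_error"
    )
  }
  if (length(ancestral_freq_range) != 2 ||
    ancestral_freq_range[1] <= 0 || ancestral_freq_range[2] >= 1 ||
    diff(ancestral_freq_range) < 0) {
    abort("ancestral_freq_range must be an interval within (0, 1)",
      class = "adnakit_parameter_error"
    )
  }
  if (is.null(admixture_truth)) {
    admixture_truth <- matrix(1 / n_pops, nrow = 1, ncol = n_pops)
  }
  if (is.vector(admixture_truth) && !is.matrix(admixture_truth)) {
    admixture_truth <- matrix(admixture_truth, nrow = 1)
  }
  if (ncol(admixture_truth) != n_pops) {
    abort("admixture_truth needs one column per population",
      class = "adnakit_parameter_error"
    )
  }
  if (any(admixture_truth < 0) ||
    any(abs(rowSums(admixture_truth) - 1) > 1e-9)) {
    abort("admixture_truth rows must be nonnegative and sum to 1 (+/- 1e-9)",
      class = "adnakit_parameter_error"
    )
  }
  check01 <- function(x, lo, hi, what) {
    if (x < lo || x > hi) {
      abort(sprintf("%s must lie in [%g, %g]", what, lo, hi),
        class = "adnakit_parameter_error"
      )
    }
  }
  check01(base_error, 0, 0.25, "base_error")
  if (damage_dmax < 0 || damage_dmax >= 1) {
    abort("damage_dmax must lie in [0, 1)", class = "adnakit_parameter_error")
  }
  if (damage_decay <= 0 || damage_decay > 1) {
    abort("damage_decay must lie in (0, 1]", class = "adnakit_parameter_error")
  }
  check01(damage_bg, 0, 0.1, "damage_bg")
  check01(contamination, 0, 1, "contamination")
  check01(mismap_rate, 0, 1, "mismap_rate")
  check01(xy_ry, 0, 1, "xy_ry")
  if (mean_depth < 0) {
    abort("mean_depth must be >= 0", class = "adnakit_parameter_error")
  }
  if (fragment_min < 1 || fragment_mean < fragment_min) {
    abort("need fragment_mean >= fragment_min >= 1",
      class = "adnakit_parameter_error"
    )
  }
  structure(
    list(
      n_pops = as.integer(n_pops),
      fst_per_pop = as.numeric(fst_per_pop),
      n_snps = as.integer(n_snps),
      ancestral_freq_range = as.numeric(ancestral_freq_range),
      n_ref_per_pop = as.integer(n_ref_per_pop),
      admixture_truth = admixture_truth,
      mean_depth = mean_depth,
      base_error = base_error,
      damage_dmax = damage_dmax,
      damage_decay = damage_decay,
      damage_bg = damage_bg,
      contamination = contamination,
      fragment_mean = fragment_mean,
      fragment_min = fragment_min,
      karyotype = karyotype,
      mismap_rate = mismap_rate,
      xy_ry = xy_ry,
      contaminant_pop = as.integer(contaminant_pop),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf(
    "  panel: %d pops (FST %s), %d SNPs, %d ref/pop\n",
    x$n_pops, paste(signif(x$fst_per_pop, 3), collapse = "/"),
    x$n_snps, x$n_ref_per_pop
  ))
  cat(sprintf(
    "  fragments: depth %g, error %g, damage dmax %g decay %g bg %g, contamination %g\n",
    x$mean_depth, x$base_error, x$damage_dmax, x$damage_decay,
    x$damage_bg, x$contamination
  ))
  cat(sprintf(
    "  lengths: min %d mean %d; karyotype %s (mismap %g)\n",
    x$fragment_min, x$fragment_mean, x$karyotype, x$mismap_rate
  ))
  invisible(x)
}

# Expected deamination probability at 1-based terminal offset z.
damage_curve <- function(z, dmax, decay, bg) {
  bg + dmax * (1 - decay)^(z - 1)
}
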