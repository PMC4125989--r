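#' Post-mortem damage model
#'
#' Parameters of the geometric-decay deamination curve
#' `D(z) = bg + dmax * (1 - decay)^(z - 1)` used both to score reads
#' (PMD) and to describe simulated damage. `epsilon_floor` bounds the
#' per-base error probability away from zero so log-likelihood ratios stay
#' finite at very high base qualities.
#'
#' @param dmax Terminal deamination probability, `[0, 1)`.
#' @param decay Geometric decay per base, `(0, 1]`.
#' @param bg Background (interior) deamination probability, `[0, 0.1]`.
#' @param epsilon_floor Minimum per-base error probability.
#' @param window Number of terminal bases scored at each end.
#' @return A `pmd_model` list.
#' @examples
#' pmd_model()
#' @export
pmd_model <- function(dmax = 0.3, decay = 0.3, bg = 0.01,
                      epsilon_floor = 1e-4, window = 25L) {
  stopifnot(
    dmax >= 0, dmax < 1, decay > 0, decay <= 1, bg >= 0, bg <= 0.1,
    epsilon_floor > 0, epsilon_floor < 0.25, window >= 1
  )
  structure(
    list(
      dmax = dmax, decay = decay, bg = bg,
      epsilon_floor = epsilon_floor, window = as.integer(window)
    ),
    class = "pmd_model"
  )
}

#' @export
print.pmd_model <- function(x, ...) {
  cat(sprintf(
    "<pmd_model> D(z) = %.3g + %.3g * (1 - %.3g)^(z-1); window %d, eps floor %g\n",
    x$bg, x$dmax, x$decay, x$window, x$epsilon_floor
  ))
  invisible(x)
}

# Base table augmented with read-orientation terminal offsets and the
# read-space damage categories. Fragments are stored in genomic
# orientation; on the reverse strand the read's 5' C->T appears as a
# genomic G->A counted from the genomic right end, and vice versa.
damage_base_table <- function(frags) {
  bt <- fragment_base_table(frags)
  lens <- nchar(frags$sequence)
  minus <- frags$strand[bt$frag] == "-"
  len_b <- lens[bt$frag]
  left <- bt$offset
  right <- len_b - bt$offset + 1L
  bt$z5 <- ifelse(minus, right, left) # offset from the read 5' end
  bt$z3 <- ifelse(minus, left, right) # offset from the read 3' end
  # read-space identity of the aligned reference base
  bt$ref5C <- ifelse(minus, bt$ref == "G", bt$ref == "C")
  bt$ref3G <- ifelse(minus, bt$ref == "C", bt$ref == "G")
  bt$obs_deam5 <- ifelse(minus, bt$obs == "A", bt$obs == "T")
  bt$obs_deam3 <- ifelse(minus, bt$obs == "T", bt$obs == "A")
  bt$obs_match <- bt$obs == bt$ref
  bt
}

#' Terminal mismatch (deamination) profile
#'
#' Computes the C->T mismatch frequency by 5' offset and the G->A frequency
#' by 3' offset, always in read orientation (reverse-strand fragments are
#' complement-oriented first), plus the fraction of fragments carrying at
#' least one terminal deamination-type mismatch.
#'
#' @param frags Fragment tibble.
#' @param max_offset Number of terminal offsets profiled at each end.
#' @param min_mapq Fragments below this mapping quality are excluded.
#' @return A `damage_profile` tibble with columns `offset`, `f5`, `n5`,
#'   `f3`, `n3`; attribute `deaminated_fraction` (share of fragments with a
#'   terminal, offset <= 5, C->T/G->A mismatch).
#' @examples
#' cfg <- sim_config(n_snps = 50, mean_depth = 3)
#' sim <- simulate_panel(cfg, 1)
#' prof <- mismatch_profile(simulate_fragments(sim$truth, cfg, 1))
#' head(prof)
#' @export
mismatch_profile <- function(frags, max_offset = 25L, min_mapq = 30L) {
  frags <- filter(frags, .data$mapq >= min_mapq)
  if (nrow(frags) == 0) {
    abort("no fragments to profile", class = "adnakit_empty_error")
  }
  bt <- damage_base_table(frags)

  tab <- function(z, opp, hit) {
    keep <- opp & z <= max_offset
    n <- tabulate(z[keep], nbins = max_offset)
    x <- tabulate(z[keep & hit], nbins = max_offset)
    list(f = ifelse(n > 0, x / n, 0), n = n)
  }
  t5 <- tab(bt$z5, bt$ref5C, bt$obs_deam5)
  t3 <- tab(bt$z3, bt$ref3G, bt$obs_deam3)

  term <- (bt$ref5C & bt$obs_deam5 & bt$z5 <= 5L) |
    (bt$ref3G & bt$obs_deam3 & bt$z3 <= 5L)
  deam_frac <- length(unique(bt$frag[term])) / nrow(frags)

  out <- tibble(
    offset = seq_len(max_offset),
    f5 = t5$f, n5 = t5$n, f3 = t3$f, n3 = t3$n
  )
  class(out) <- c("damage_profile", class(out))
  attr(out, "deaminated_fraction") <- deam_frac
  out
}

#' Fit the geometric damage curve to an observed profile
#'
#' Weighted least squares fit of `D(z) = bg + dmax * (1 - decay)^(z - 1)`
#' to the pooled 5' C->T and 3' G->A frequencies, weights proportional to
#' the opportunity counts.
#'
#' @param profile A [mismatch_profile()] result.
#' @return List with `dmax`, `decay`, `bg` and the residual sum of squares.
#' @export
fit_damage_model <- function(profile) {
  z <- rep(profile$offset, 2)
  f <- c(profile$f5, profile$f3)
  w <- c(profile$n5, profile$n3)
  keep <- w > 0
  if (sum(keep) < 3) {
    abort("profile has fewer than 3 informative offsets",
      class = "adnakit_parameter_error"
    )
  }
  z <- z[keep]
  f <- f[keep]
  w <- w[keep] / mean(w[keep])
  obj <- function(par) {
    d <- damage_curve(z, par[1], par[2], par[3])
    sum(w * (f - d)^2)
  }
  bg0 <- max(mean(f[z > 15]), 1e-4)
  start <- c(
    dmax = max(max(f) - bg0, 0.01),
    decay = 0.3,
    bg = bg0
  )
  fit <- optim(start, obj,
    method = "L-BFGS-B",
    lower = c(1e-6, 1e-3, 0), upper = c(0.999, 1, 0.1)
  )
  list(
    dmax = unname(fit$par[1]), decay = unname(fit$par[2]),
    bg = unname(fit$par[3]), rss = fit$value
  )
}

#' Per-fragment PMD score
#'
#' Log-likelihood ratio of a post-mortem damage model against a pure
#' sequencing-error null, accumulated over terminal positions whose
#' strand-oriented reference base is C (5' end) or G (3' end) within the
#' model window. Observed deaminated bases (T over C / A over G) contribute
#' `log((D(z) + (1 - D(z)) * eps) / eps)`; observed matches contribute
#' `log(1 - D(z))`; all other positions contribute 0. The per-base error
#' probability is `eps = max(10^(-q/10) / 3, epsilon_floor)`.
#'
#' @param frags Fragment tibble.
#' @param model A [pmd_model()].
#' @return Numeric vector of scores, one per fragment (in input order).
#' @examples
#' cfg <- sim_config(n_snps = 20, mean_depth = 2)
#' sim <- simulate_panel(cfg, 1)
#' frags <- simulate_fragments(sim$truth, cfg, 1)
#' summary(pmd_score(frags, pmd_model()))
#' @export
pmd_score <- function(frags, model = pmd_model()) {
  if (nrow(frags) == 0) {
    return(numeric(0))
  }
  if (any(nchar(frags$sequence) != nchar(frags$ref_bases)) ||
    any(nchar(frags$sequence) != nchar(frags$base_quals))) {
    abort("malformed fragment: sequence, ref_bases and base_quals lengths differ",
      class = "adnakit_format_error"
    )
  }
  bt <- damage_base_table(frags)
  eps <- pmax(10^(-bt$qual / 10) / 3, model$epsilon_floor)

  contrib <- numeric(nrow(bt))
  in5 <- bt$ref5C & bt$z5 <= model$window
  in3 <- bt$ref3G & bt$z3 <= model$window
  d <- numeric(nrow(bt))
  d[in5] <- damage_curve(bt$z5[in5], model$dmax, model$decay, model$bg)
  d[in3] <- damage_curve(bt$z3[in3], model$dmax, model$decay, model$bg)

  deam <- (in5 & bt$obs_deam5) | (in3 & bt$obs_deam3)
  match_ <- (in5 | in3) & bt$obs_match
  contrib[deam] <- log((d[deam] + (1 - d[deam]) * eps[deam]) / eps[deam])
  contrib[match_] <- log(1 - d[match_])

  out <- numeric(nrow(frags))
  agg <- tapply(contrib, bt$frag, sum)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}

#' Filter fragments by PMD score
#'
#' Retains fragments whose PMD score is at least `threshold`, preserving
#' input order. The conventional threshold 3 keeps reads with clear
#' deamination evidence; -2 approximates "unfiltered".
#'
#' @param frags Fragment tibble.
#' @param threshold Minimum score retained.
#' @param model A [pmd_model()].
#' @return The retained fragment tibble.
#' @export
filter_by_pmd <- function(frags, threshold = 3, model = pmd_model()) {
  if (nrow(frags) == 0) {
    return(frags)
  }
  frags[pmd_score(frags, model) >= threshold, , drop = FALSE]
}

#' Endogenous DNA percentage
#'
#' Percentage of reads surviving alignment and filtering, the standard
#' screening estimate of endogenous DNA content: `100 * mapped / total`,
#' rounded to 2 decimal places.
#'
#' @param total_reads Total reads sequenced for the sample (> 0).
#' @param mapped_filtered Reads mapped and passing quality/duplicate
#'   filters (0 <= mapped <= total).
#' @return Numeric percentage rounded to 2 decimals. Use
#'   [format_percent()] for the display form with trailing zeros stripped.
#' @examples
#' summarize_alignment(1076124, 107507) # 9.99
#' summarize_alignment(597681, 45414) # 7.6
#' @export
summarize_alignment <- function(total_reads, mapped_filtered) {
  if (any(total_reads <= 0)) {
    abort("total_reads must be > 0", class = "adnakit_parameter_error")
  }
  if (any(mapped_filtered < 0) || any(mapped_filtered > total_reads)) {
    abort("need 0 <= mapped_filtered <= total_reads",
      class = "adnakit_parameter_error"
    )
  }
  round(100 * mapped_filtered / total_reads, 2)
}

#' Format a percentage with trailing zeros stripped
#'
#' @param x Numeric percentage (already rounded as desired).
#' @return Character, e.g. `7.6`, `9.99`, `0.1`.
#' @export
format_percent <- function(x) {
  sub("\\.?0+$", "", sprintf("%.2f", x))
}
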