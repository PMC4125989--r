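#' Genetic sex from X/Y read counts (Ry statistic)
#'
#' Computes `Ry = nY / (nX + nY)` with its normal-approximation standard
#' error and 95% confidence interval, and assigns karyotype conservatively:
#' XX only when the whole interval lies below the female band, XY only when
#' it lies entirely above the male band, `insufficient` below a read floor,
#' `indeterminate` otherwise. Some published descriptions print the band
#' sentence with the directions swapped ("female if Ry > 0.016, male if
#' Ry < 0.075"); this function follows the method's actual orientation:
#' females have few Y reads, so low Ry means XX.
#'
#' @param nX,nY Reads aligned to X and to Y (vectors recycle together).
#' @param t_female Upper Ry band for an XX call (default 0.016).
#' @param t_male Lower Ry band for an XY call (default 0.075).
#' @param min_reads Below this many sex-chromosome reads the sample is
#'   flagged `insufficient`.
#' @param conf_z Normal quantile for the interval (1.96 for 95%).
#' @param exact Use an exact binomial (Clopper-Pearson) interval instead of
#'   the normal approximation.
#' @return Tibble with one row per input: `nX`, `nY`, `Ry`, `SE`,
#'   `ci_low`, `ci_high`, `call`.
#' @examples
#' estimate_sex(900, 100) # XY
#' estimate_sex(950, 50) # indeterminate
#' @export
estimate_sex <- function(nX, nY, t_female = 0.016, t_male = 0.075,
                         min_reads = 100, conf_z = 1.96, exact = FALSE) {
  stopifnot(all(nX >= 0), all(nY >= 0))
  n <- nX + nY
  ry <- ifelse(n > 0, nY / n, NA_real_)
  se <- ifelse(n > 0, sqrt(ry * (1 - ry) / n), NA_real_)
  if (exact) {
    lo <- mapply(function(y, tot) {
      if (tot == 0) NA_real_ else stats::binom.test(y, tot)$conf.int[1]
    }, nY, n)
    hi <- mapply(function(y, tot) {
      if (tot == 0) NA_real_ else stats::binom.test(y, tot)$conf.int[2]
    }, nY, n)
  } else {
    lo <- pmax(ry - conf_z * se, 0)
    hi <- pmin(ry + conf_z * se, 1)
  }
  call <- dplyr::case_when(
    n < min_reads ~ "insufficient",
    hi < t_female ~ "XX",
    lo > t_male ~ "XY",
    TRUE ~ "indeterminate"
  )
  tibble(
    nX = as.integer(nX), nY = as.integer(nY),
    Ry = ry, SE = se, ci_low = lo, ci_high = hi, call = call
  )
}

#' Sex-chromosome read counts from a fragment table
#'
#' Counts fragments whose `chrom` label is X or Y per sample, after a
#' mapping-quality gate and optional exclusion of masked intervals (e.g.
#' pseudoautosomal regions).
#'
#' @param frags Fragment tibble.
#' @param min_mapq Mapping-quality gate.
#' @param mask Optional tibble of intervals `chrom`, `start`, `end`
#'   (1-based, inclusive); fragments whose leftmost position falls inside a
#'   masked interval are dropped.
#' @return Tibble `sample_id`, `nX`, `nY`.
#' @export
count_sex_reads <- function(frags, min_mapq = 30L, mask = NULL) {
  frags <- filter(frags, .data$mapq >= min_mapq, .data$chrom %in% c("X", "Y"))
  if (!is.null(mask) && nrow(frags) > 0) {
    hit <- rep(FALSE, nrow(frags))
    for (i in seq_len(nrow(mask))) {
      hit <- hit | (frags$chrom == mask$chrom[i] &
        frags$pos >= mask$start[i] & frags$pos <= mask$end[i])
    }
    frags <- frags[!hit, , drop = FALSE]
  }
  out <- frags %>%
    count(.data$sample_id, .data$chrom) %>%
    tidyr::pivot_wider(
      names_from = "chrom", values_from = "n", values_fill = 0L
    )
  if (!"X" %in% names(out)) out$X <- 0L
  if (!"Y" %in% names(out)) out$Y <- 0L
  tibble(
    sample_id = out$sample_id,
    nX = as.integer(out$X), nY = as.integer(out$Y)
  )
}

#' Plot sex estimates against the assignment bands
#'
#' One point per sample at its Ry with 95% error bars; shaded bands mark
#' the XX and XY assignment regions.
#'
#' @param est Tibble from [estimate_sex()] (optionally with a `sample_id`
#'   column).
#' @param t_female,t_male Band edges drawn.
#' @return A ggplot object.
#' @export
plot_sex_estimate <- function(est, t_female = 0.016, t_male = 0.075) {
  est <- as_tibble(est)
  if (!"sample_id" %in% names(est)) {
    est$sample_id <- sprintf("sample%d", seq_len(nrow(est)))
  }
  ggplot2::ggplot(est, ggplot2::aes(x = .data$sample_id, y = .data$Ry)) +
    ggplot2::annotate("rect",
      xmin = -Inf, xmax = Inf, ymin = 0, ymax = t_female,
      alpha = 0.15, fill = "grey30"
    ) +
    ggplot2::annotate("rect",
      xmin = -Inf, xmax = Inf, ymin = t_male, ymax = 1,
      alpha = 0.15, fill = "grey30"
    ) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high)
    ) +
    ggplot2::coord_cartesian(
      ylim = c(0, max(0.2, max(est$ci_high, na.rm = TRUE)))
    ) +
    ggplot2::labs(
      x = NULL, y = "Ry = nY / (nX + nY)",
      title = "Sex assignment from sex-chromosome read counts"
    ) +
    ggplot2::theme_minimal()
}
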