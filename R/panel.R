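#' Construct a genotype panel
#'
#' A `genotype_panel` holds reference individuals by SNP dosages: a tibble
#' of individuals (id, population), a site table (chrom, pos, id, ref, alt)
#' and an individuals x sites integer matrix counting alternate alleles
#' (0/1/2, `NA` missing).
#'
#' @param individuals Tibble with columns `id` and `population`.
#' @param sites Site tibble as produced by [validate_sites()].
#' @param genotypes Integer matrix, `nrow(individuals)` x `nrow(sites)`,
#'   entries in `{0, 1, 2, NA}`.
#' @return A `genotype_panel` object.
#' @export
genotype_panel <- function(individuals, sites, genotypes) {
  individuals <- as_tibble(individuals)
  sites <- validate_sites(sites)
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (nrow(genotypes) != nrow(individuals) ||
    ncol(genotypes) != nrow(sites)) {
    abort("genotype matrix dimensions must match individuals x sites",
      class = "adnakit_parameter_error"
    )
  }
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    abort("genotype entries must be 0, 1, 2 or NA",
      class = "adnakit_parameter_error"
    )
  }
  rownames(genotypes) <- individuals$id
  colnames(genotypes) <- sites$id
  structure(
    list(individuals = individuals, sites = sites, genotypes = genotypes),
    class = "genotype_panel"
  )
}

#' Validate a SNP site table
#'
#' Checks the invariants of the site table: unique `(chrom, pos)` keys,
#' `ref != alt`, alleles among A/C/G/T.
#'
#' @param sites Data frame with columns `chrom`, `pos`, `id`, `ref`, `alt`.
#' @return The site table as a tibble, with `pos` as integer.
#' @export
validate_sites <- function(sites) {
  sites <- as_tibble(sites)
  need <- c("chrom", "pos", "id", "ref", "alt")
  miss <- setdiff(need, names(sites))
  if (length(miss)) {
    abort(paste0("site table lacks column(s): ", paste(miss, collapse = ", ")),
      class = "adnakit_format_error"
    )
  }
  sites$pos <- as.integer(sites$pos)
  key <- paste(sites$chrom, sites$pos)
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    abort(
      paste0(
        "duplicate (chrom, pos) in site table: ",
        paste(head(dups, 5), collapse = "; ")
      ),
      class = "adnakit_format_error"
    )
  }
  if (any(!sites$ref %in% BASES) || any(!sites$alt %in% BASES)) {
    abort("site alleles must be A, C, G or T", class = "adnakit_format_error")
  }
  if (any(sites$ref == sites$alt)) {
    abort("site ref and alt alleles must differ",
      class = "adnakit_format_error"
    )
  }
  sites
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf(
    "<genotype_panel> %d individuals x %d SNPs (%d populations)\n",
    nrow(x$individuals), nrow(x$sites),
    length(unique(x$individuals$population))
  ))
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  missingness: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Tidy a genotype panel into a long tibble
#'
#' @param x A `genotype_panel`.
#' @param ... Unused.
#' @return Tibble with one row per individual x site: `id`, `population`,
#'   `site_id`, `dosage`.
#' @export
tidy.genotype_panel <- function(x, ...) {
  tibble(
    id = rep(x$individuals$id, times = nrow(x$sites)),
    population = rep(x$individuals$population, times = nrow(x$sites)),
    site_id = rep(x$sites$id, each = nrow(x$individuals)),
    dosage = as.vector(x$genotypes)
  )
}

# Restrict a panel to a subset of site indices (logical or integer).
subset_panel_sites <- function(panel, idx) {
  genotype_panel(
    panel$individuals,
    panel$sites[idx, , drop = FALSE],
    panel$genotypes[, idx, drop = FALSE]
  )
}

#' Dosage matrix of a panel
#'
#' @param panel A `genotype_panel`.
#' @return The individuals x sites integer dosage matrix.
#' @export
panel_dosages <- function(panel) {
  panel$genotypes
}
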