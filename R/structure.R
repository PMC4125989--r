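#' Reference principal component analysis of a genotype panel
#'
#' Standardizes each SNP dosage column by the posterior-mean allele
#' frequency, `p = (1 + sum g) / (2 + 2n)`: center by `2p`, scale by
#' `sqrt(p (1 - p))`; missing entries are mean-imputed (zero after
#' centering); monomorphic columns are dropped with a warning count. The
#' coordinates come from the singular value decomposition of the
#' standardized matrix.
#'
#' @param panel A [genotype_panel()], normally transition-masked and
#'   LD-pruned first.
#' @param n_components Number of PCs returned.
#' @return An `adna_pca` object: `coordinates` tibble (`id`, `population`,
#'   `PC1..`), `eigenvalues`, `snp_means`, `snp_scales`, `sites`,
#'   `n_monomorphic_dropped`.
#' @examples
#' sim <- simulate_panel(sim_config(n_snps = 100, n_ref_per_pop = 20), 1)
#' pca <- reference_pca(sim$panel, 2)
#' head(tidy(pca))
#' @export
reference_pca <- function(panel, n_components = 10L) {
  g <- panel$genotypes
  n <- colSums(!is.na(g))
  p_hat <- (1 + colSums(g, na.rm = TRUE)) / (2 + 2 * n)
  scale_ <- sqrt(p_hat * (1 - p_hat))
  obs_var <- apply(g, 2, function(col) {
    v <- stats::var(col[!is.na(col)])
    if (is.na(v)) 0 else v
  })
  mono <- obs_var == 0 | scale_ == 0
  if (any(mono)) {
    warn(sprintf("dropping %d monomorphic SNP(s) before PCA", sum(mono)))
  }
  keep <- which(!mono)
  if (length(keep) < 1) {
    abort("no polymorphic SNPs left for PCA", class = "adnakit_parameter_error")
  }
  x <- sweep(g[, keep, drop = FALSE], 2, 2 * p_hat[keep], "-")
  x <- sweep(x, 2, scale_[keep], "/")
  x[is.na(x)] <- 0
  k <- min(n_components, nrow(x) - 1L, ncol(x))
  sv <- svd(x, nu = k, nv = 0)
  coords <- sv$u %*% diag(sv$d[seq_len(k)], nrow = k)
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(
    list(
      coordinates = bind_cols(panel$individuals, as_tibble(coords)),
      eigenvalues = sv$d[seq_len(k)]^2 / max(nrow(x) - 1, 1),
      snp_means = 2 * p_hat[keep],
      snp_scales = scale_[keep],
      sites = panel$sites[keep, , drop = FALSE],
      n_monomorphic_dropped = sum(mono)
    ),
    class = "adna_pca"
  )
}

#' @export
print.adna_pca <- function(x, ...) {
  cat(sprintf(
    "<adna_pca> %d individuals, %d SNPs, %d components\n",
    nrow(x$coordinates), nrow(x$sites), length(x$eigenvalues)
  ))
  invisible(x)
}

#' @export
tidy.adna_pca <- function(x, ...) {
  x$coordinates
}

#' @export
glance.adna_pca <- function(x, ...) {
  tibble(
    n_individuals = nrow(x$coordinates),
    n_snps = nrow(x$sites),
    n_components = length(x$eigenvalues),
    var_pc1 = x$eigenvalues[1] / sum(x$eigenvalues)
  )
}

pca_matrix <- function(pca) {
  as.matrix(pca$coordinates[, grep("^PC", names(pca$coordinates)),
    drop = FALSE
  ])
}

#' Least-squares Procrustes superimposition
#'
#' Finds the translation, positive scale and orthogonal rotation
#' (reflections permitted) minimizing `sum || s * X R + t - Y ||^2` over
#' paired configurations, in closed form via the SVD of the centered
#' cross-covariance. The similarity statistic is
#' `rho = sqrt(1 - residual / total centered variance of Y)`.
#'
#' @param source Numeric matrix X (rows are paired points).
#' @param target Numeric matrix Y, same dimensions.
#' @return A `procrustes_fit`: `rotation`, `scale`, `translation`,
#'   `similarity`, `residual`.
#' @examples
#' x <- matrix(rnorm(20), 10, 2)
#' fit <- procrustes_fit(x, x)
#' fit$similarity # 1
#' @export
procrustes_fit <- function(source, target) {
  x <- as.matrix(source)
  y <- as.matrix(target)
  if (nrow(x) != nrow(y) || ncol(x) != ncol(y)) {
    abort("source and target must have identical dimensions",
      class = "adnakit_parameter_error"
    )
  }
  if (nrow(x) < 3) {
    abort("procrustes needs at least 3 paired anchor points",
      class = "adnakit_parameter_error"
    )
  }
  xm <- colMeans(x)
  ym <- colMeans(y)
  xc <- sweep(x, 2, xm)
  yc <- sweep(y, 2, ym)
  ssx <- sum(xc^2)
  ssy <- sum(yc^2)
  if (ssx == 0) {
    abort("source configuration has zero variance",
      class = "adnakit_parameter_error"
    )
  }
  sv <- svd(crossprod(xc, yc))
  rotation <- sv$u %*% t(sv$v)
  s <- sum(sv$d) / ssx
  translation <- ym - s * as.vector(xm %*% rotation)
  residual <- max(ssy - sum(sv$d)^2 / ssx, 0)
  rho <- if (ssy > 0) sqrt(max(1 - residual / ssy, 0)) else 1
  structure(
    list(
      rotation = rotation, scale = s, translation = translation,
      similarity = rho, residual = residual
    ),
    class = "procrustes_fit"
  )
}

#' Apply a fitted Procrustes transform to new coordinates
#'
#' @param fit A [procrustes_fit()].
#' @param x Matrix of coordinates in the source frame.
#' @return Matrix in the target frame: `scale * x %*% rotation + translation`.
#' @export
procrustes_apply <- function(fit, x) {
  x <- rbind(x) # keep matrix shape for a single point
  sweep(fit$scale * x %*% fit$rotation, 2, fit$translation, "+")
}

#' @export
print.procrustes_fit <- function(x, ...) {
  cat(sprintf(
    "<procrustes_fit> scale %.4g, residual %.4g, similarity %.4f\n",
    x$scale, x$residual, x$similarity
  ))
  invisible(x)
}

#' @export
glance.procrustes_fit <- function(x, ...) {
  tibble(
    scale = x$scale, residual = x$residual, similarity = x$similarity,
    reflected = det(x$rotation) < 0
  )
}

#' Project a sparse ancient sample into a reference PC space
#'
#' For each sample: restrict the reference panel to the sample's
#' non-missing call sites; rebuild the principal components on that site
#' subset (reusing the reference standardization, so the reference
#' configuration is an exact function of the panel); place the ancient
#' pseudo-haploid row into this per-sample PC space by projection — the
#' sparse, variance-inflated 0/2 row never tilts the axes; fit a Procrustes
#' transform from the per-sample reference coordinates onto the reference
#' PCA coordinates (anchors are reference individuals only); and map the
#' ancient point through it. A full-coverage exact copy of a panel
#' individual therefore lands exactly on its twin. Samples sharing fewer
#' than `min_sites` covered SNPs with the panel are skipped with an
#' "insufficient SNPs" report.
#'
#' @param panel The reference [genotype_panel()] used for `ref_pca`.
#' @param calls A `pseudo_haploid_calls` tibble or list of them.
#' @param ref_pca The [reference_pca()] of `panel`.
#' @param min_sites Minimum shared non-missing sites (default 50).
#' @return Tibble: `sample_id`, `n_sites`, `projected` (logical), `note`,
#'   and one column per PC (NA when skipped).
#' @export
project_ancient <- function(panel, calls, ref_pca, min_sites = 50L) {
  if (inherits(calls, "pseudo_haploid_calls")) calls <- list(calls)
  npc <- length(ref_pca$eigenvalues)
  ref_coords <- pca_matrix(ref_pca)
  site_key <- paste(ref_pca$sites$chrom, ref_pca$sites$pos)
  panel_key <- paste(panel$sites$chrom, panel$sites$pos)

  out <- purrr::map(calls, function(cs) {
    idx <- match(paste(cs$chrom, cs$pos), site_key)
    use <- !is.na(idx) & !is.na(cs$call)
    n_sites <- sum(use)
    blank <- setNames(
      as.list(rep(NA_real_, npc)), paste0("PC", seq_len(npc))
    )
    if (n_sites < min_sites) {
      return(tibble(
        sample_id = cs$sample_id[1], n_sites = n_sites,
        projected = FALSE, note = "insufficient SNPs", !!!blank
      ))
    }
    ridx <- idx[use] # positions within ref_pca's site set
    pidx <- match(paste(cs$chrom, cs$pos)[use], panel_key)
    g <- panel$genotypes[, pidx, drop = FALSE]
    x <- sweep(g, 2, ref_pca$snp_means[ridx], "-")
    x <- sweep(x, 2, ref_pca$snp_scales[ridx], "/")
    x[is.na(x)] <- 0
    k <- min(npc, nrow(x) - 1L, ncol(x))
    sv <- svd(x, nu = k, nv = k)
    anchors <- sv$u %*% diag(sv$d[seq_len(k)], nrow = k)
    xa <- (cs$call[use] - ref_pca$snp_means[ridx]) / ref_pca$snp_scales[ridx]
    anc <- rbind(as.vector(xa %*% sv$v))
    fit <- procrustes_fit(anchors, ref_coords[, seq_len(k), drop = FALSE])
    proj <- procrustes_apply(fit, anc)
    vals <- setNames(
      as.list(c(proj[1, ], rep(NA_real_, npc - k))),
      paste0("PC", seq_len(npc))
    )
    tibble(
      sample_id = cs$sample_id[1], n_sites = n_sites,
      projected = TRUE, note = NA_character_, !!!vals
    )
  })
  bind_rows(out)
}

#' Admixture proportions by binomial-mixture EM
#'
#' Maximizes the binomial log-likelihood
#' `L = sum g log p + (2 - g) log(1 - p)`, `p_ij = sum_k q_ik f_kj`, by
#' expectation-maximization from a seeded random start (Q rows Dirichlet(1),
#' F uniform on (0.05, 0.95)). The update never decreases the likelihood;
#' iteration stops when the gain drops below `tol` or at `max_iter`.
#' Cluster frequencies are clipped to `[1e-6, 1 - 1e-6]`.
#'
#' @param dosages Individuals x SNPs matrix with entries 0/1/2 and NA, or a
#'   [genotype_panel()].
#' @param k Number of ancestral clusters (>= 1).
#' @param seed Integer seed for the initialization.
#' @param tol Log-likelihood convergence tolerance.
#' @param max_iter Iteration cap.
#' @return An `admixture_fit`: `k`, `Q`, `F`, `loglik`, `loglik_trace`,
#'   `n_iter`, `converged`.
#' @examples
#' sim <- simulate_panel(sim_config(
#'   n_pops = 2, fst_per_pop = c(0.2, 0.2),
#'   n_snps = 200, n_ref_per_pop = 15
#' ), 1)
#' fit <- admixture_em(sim$panel, k = 2, seed = 1)
#' fit$converged
#' @export
admixture_em <- function(dosages, k, seed = 1L, tol = 1e-4, max_iter = 2000L) {
  ids <- NULL
  if (inherits(dosages, "genotype_panel")) {
    ids <- dosages$individuals$id
    dosages <- dosages$genotypes
  }
  g <- as.matrix(dosages)
  storage.mode(g) <- "double"
  if (k < 1) abort("k must be >= 1", class = "adnakit_parameter_error")
  if (k > nrow(g)) {
    abort("k cannot exceed the number of individuals",
      class = "adnakit_parameter_error"
    )
  }
  g[is.na(g)] <- -1
  init <- with_seed(seed, {
    q0 <- matrix(stats::rexp(nrow(g) * k), ncol = k)
    q0 <- q0 / rowSums(q0) # Dirichlet(1,...,1)
    f0 <- matrix(runif(k * ncol(g), 0.05, 0.95), nrow = k)
    list(q0 = q0, f0 = f0)
  })
  res <- .admixture_em_cpp(g, init$q0, init$f0, tol, as.integer(max_iter))
  if (!is.null(ids)) rownames(res$Q) <- ids
  structure(
    list(
      k = as.integer(k), Q = res$Q, F = res$F, loglik = res$loglik,
      loglik_trace = as.numeric(res$loglik_trace),
      n_iter = res$n_iter, converged = res$converged
    ),
    class = "admixture_fit"
  )
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf(
    "<admixture_fit> k = %d, %d individuals, loglik %.2f (%d iterations%s)\n",
    x$k, nrow(x$Q), x$loglik, x$n_iter,
    if (x$converged) ", converged" else ""
  ))
  invisible(x)
}

#' @export
tidy.admixture_fit <- function(x, ...) {
  q <- x$Q
  ids <- rownames(q) %||% sprintf("ind%d", seq_len(nrow(q)))
  tibble(
    id = rep(ids, times = ncol(q)),
    cluster = rep(seq_len(ncol(q)), each = nrow(q)),
    proportion = as.vector(q)
  )
}

#' @export
glance.admixture_fit <- function(x, ...) {
  tibble(
    k = x$k, loglik = x$loglik, n_iter = x$n_iter, converged = x$converged
  )
}

#' Cross-validation error of an admixture model
#'
#' Masks a random fold of the observed genotype cells, refits the model on
#' the remainder, and scores the masked cells by mean binomial deviance
#' between the held-out dosage and its prediction `2 * p_hat`; the result
#' is averaged over folds. Used to choose the number of clusters k.
#'
#' @param dosages Dosage matrix or [genotype_panel()].
#' @param k Number of clusters.
#' @param folds Number of folds (>= 2, default 5).
#' @param seed Integer seed (drives both fold assignment and EM starts).
#' @param tol,max_iter Passed to [admixture_em()]. The defaults are looser
#'   than the estimation defaults: model choice needs the deviance ranking
#'   across k, which stabilizes long before the parameters converge.
#' @return Mean held-out deviance (a single number; lower is better).
#' @export
cv_error <- function(dosages, k, folds = 5L, seed = 1L, tol = 1e-2,
                     max_iter = 150L) {
  if (inherits(dosages, "genotype_panel")) dosages <- dosages$genotypes
  g <- as.matrix(dosages)
  storage.mode(g) <- "double"
  if (folds < 2) abort("folds must be >= 2", class = "adnakit_parameter_error")
  obs <- which(!is.na(g))
  fold_of <- with_seed(seed, sample(rep_len(seq_len(folds), length(obs))))
  dev <- numeric(folds)
  for (f in seq_len(folds)) {
    masked <- obs[fold_of == f]
    gtrain <- g
    gtrain[masked] <- NA
    fit <- admixture_em(gtrain, k,
      seed = derive_seed(seed, paste0("cvfold", f)),
      tol = tol, max_iter = max_iter
    )
    p <- fit$Q %*% fit$F
    p <- pmin(pmax(p[masked], 1e-6), 1 - 1e-6)
    gm <- g[masked]
    # binomial deviance, with 0*log(0) = 0
    t1 <- ifelse(gm > 0, gm * log(gm / (2 * p)), 0)
    t2 <- ifelse(gm < 2, (2 - gm) * log((2 - gm) / (2 * (1 - p))), 0)
    dev[f] <- mean(2 * (t1 + t2))
  }
  mean(dev)
}

#' Align repeated admixture runs by cluster-label permutation
#'
#' CLUMPP-style alignment: the first run is the reference; every other
#' run's cluster labels are permuted to maximize the pairwise similarity
#' `G = 1 - ||Q_ref - Q_perm||_F / sqrt(2 n)`. For `k <= 8` the search is
#' exhaustive over all k! permutations (the fullSearch strategy); beyond
#' that a greedy column matching is used.
#'
#' @param runs List of Q matrices with identical dimensions.
#' @param reference Index of the reference run (default 1).
#' @return A `cluster_alignment`: `permutations` (list), `similarity`
#'   (mean pairwise G to the reference), `Q_mean` (element-wise mean of
#'   aligned runs), `runs_aligned`.
#' @export
align_runs <- function(runs, reference = 1L) {
  if (!length(runs)) abort("no runs supplied", class = "adnakit_parameter_error")
  dims <- vapply(runs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("all runs must share dimensions", class = "adnakit_parameter_error")
  }
  k <- ncol(runs[[1]])
  n <- nrow(runs[[1]])
  qref <- runs[[reference]]
  gsim <- function(a, b) 1 - norm(a - b, "F") / sqrt(2 * n)

  perms <- if (k <= 8) all_permutations(k) else NULL
  aligned <- vector("list", length(runs))
  permutation <- vector("list", length(runs))
  sims <- numeric(length(runs))
  for (r in seq_along(runs)) {
    if (r == reference) {
      permutation[[r]] <- seq_len(k)
      aligned[[r]] <- runs[[r]]
      sims[r] <- 1
      next
    }
    if (!is.null(perms)) {
      best <- -Inf
      bp <- seq_len(k)
      for (pi in seq_len(nrow(perms))) {
        p <- perms[pi, ]
        s <- gsim(qref, runs[[r]][, p, drop = FALSE])
        if (s > best) {
          best <- s
          bp <- p
        }
      }
    } else {
      # greedy: repeatedly match the most correlated remaining column pair
      bp <- integer(k)
      cors <- suppressWarnings(cor(qref, runs[[r]]))
      cors[is.na(cors)] <- 0
      free_ref <- rep(TRUE, k)
      free_run <- rep(TRUE, k)
      for (step in seq_len(k)) {
        sub <- cors
        sub[!free_ref, ] <- -Inf
        sub[, !free_run] <- -Inf
        ij <- which(sub == max(sub), arr.ind = TRUE)[1, ]
        bp[ij[1]] <- ij[2]
        free_ref[ij[1]] <- FALSE
        free_run[ij[2]] <- FALSE
      }
      best <- gsim(qref, runs[[r]][, bp, drop = FALSE])
    }
    permutation[[r]] <- bp
    aligned[[r]] <- runs[[r]][, bp, drop = FALSE]
    sims[r] <- best
  }
  structure(
    list(
      reference = as.integer(reference),
      permutations = permutation,
      similarity = mean(sims[-reference]),
      Q_mean = Reduce(`+`, aligned) / length(aligned),
      runs_aligned = aligned
    ),
    class = "cluster_alignment"
  )
}

all_permutations <- function(k) {
  if (k == 1) {
    return(matrix(1L, 1, 1))
  }
  sub <- all_permutations(k - 1L)
  out <- matrix(0L, nrow(sub) * k, k)
  row <- 1L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(k)) {
      out[row, ] <- as.integer(append(sub[i, ], k, after = pos - 1L))
      row <- row + 1L
    }
  }
  out
}

#' @export
print.cluster_alignment <- function(x, ...) {
  cat(sprintf(
    "<cluster_alignment> %d runs, k = %d, mean similarity %.4f\n",
    length(x$runs_aligned), ncol(x$Q_mean), x$similarity
  ))
  invisible(x)
}
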