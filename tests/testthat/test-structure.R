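test_that("PCA separates maximally distinct populations on PC1", {
  m <- 120
  sites <- tibble::tibble(
    chrom = "1", pos = seq_len(m) * 10L, id = sprintf("s%d", seq_len(m)),
    ref = "A", alt = "C"
  )
  ind <- tibble::tibble(
    id = sprintf("i%d", 1:40),
    population = rep(c("p1", "p2"), each = 20)
  )
  g <- rbind(
    matrix(0L, 20, m), # p1 fixed ref
    matrix(2L, 20, m) # p2 fixed alt
  )
  # a little noise so columns are not perfectly degenerate
  set.seed(1)
  flip <- cbind(sample(1:40, 30, replace = TRUE), sample(1:m, 30, replace = TRUE))
  g[flip] <- 1L
  pca <- suppressWarnings(reference_pca(genotype_panel(ind, sites, g), 2))
  pc1 <- pca$coordinates$PC1
  within <- stats::var(pc1[1:20]) + stats::var(pc1[21:40])
  between <- (mean(pc1[1:20]) - mean(pc1[21:40]))^2
  expect_lt(within / between, 0.01)
  # coordinates are centered (up to the pseudocount in the frequency prior)
  expect_lt(abs(mean(pc1)), 0.01 * stats::sd(pc1))
  # components ordered by decreasing eigenvalue
  expect_true(all(diff(pca$eigenvalues) <= 1e-8))
})

test_that("duplicated individuals receive identical coordinates", {
  sim <- quick_sim(3, n_snps = 150, n_ref = 15)
  panel <- sim$panel
  ind <- dplyr::bind_rows(
    panel$individuals,
    tibble::tibble(id = "dup_of_1", population = panel$individuals$population[1])
  )
  g <- rbind(panel$genotypes, panel$genotypes[1, ])
  pca <- suppressWarnings(reference_pca(genotype_panel(ind, panel$sites, g), 3))
  cm <- adnakit:::pca_matrix(pca)
  expect_equal(cm[nrow(cm), ], cm[1, ], tolerance = 1e-10)
})

test_that("eigenvalue count is bounded by the matrix rank", {
  sim <- quick_sim(5, n_snps = 60, n_ref = 15)
  sub <- genotype_panel(
    sim$panel$individuals[1:3, ], sim$panel$sites,
    sim$panel$genotypes[1:3, , drop = FALSE]
  )
  pca <- suppressWarnings(reference_pca(sub, 2))
  expect_lte(length(pca$eigenvalues), 2)
  expect_lte(sum(pca$eigenvalues > 1e-12), 2)
})

test_that("procrustes recovers constructed similarity transforms exactly", {
  set.seed(4)
  x <- matrix(rnorm(20), 10, 2)
  idfit <- procrustes_fit(x, x)
  expect_equal(idfit$scale, 1, tolerance = 1e-12)
  expect_equal(idfit$rotation, diag(2), tolerance = 1e-12)
  expect_equal(unname(idfit$translation), c(0, 0), tolerance = 1e-12)
  expect_equal(idfit$similarity, 1)

  th <- 30 * pi / 180
  rot <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  y <- 2 * x %*% rot + matrix(c(1, 3), 10, 2, byrow = TRUE)
  fit <- procrustes_fit(x, y)
  expect_equal(fit$scale, 2, tolerance = 1e-10)
  expect_lt(fit$residual, 1e-10)
  expect_equal(fit$similarity, 1, tolerance = 1e-10)
  expect_equal(procrustes_apply(fit, x), y, tolerance = 1e-10)
  # rotation stays orthogonal
  expect_equal(crossprod(fit$rotation), diag(2), tolerance = 1e-8)

  expect_error(procrustes_fit(x[1:2, ], x[1:2, ]), class = "adnakit_parameter_error")
  expect_error(
    procrustes_fit(matrix(1, 5, 2), x[1:5, ]),
    class = "adnakit_parameter_error"
  )
})

test_that("closed-form procrustes matches direct numerical minimization", {
  set.seed(9)
  x <- matrix(rnorm(20), 10, 2)
  y <- matrix(rnorm(20), 10, 2)
  fit <- procrustes_fit(x, y)
  # independent 1-D oracle: profile out translation (centering) and scale
  # (closed form given the rotation), minimize numerically over the angle
  # for both reflection classes
  xc <- scale(x, scale = FALSE)
  yc <- scale(y, scale = FALSE)
  ssx <- sum(xc^2)
  ssy <- sum(yc^2)
  resid_at <- function(th, refl) {
    r <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2) %*%
      diag(c(1, refl))
    tr <- sum(diag(crossprod(xc %*% r, yc)))
    s <- max(tr, 0) / ssx
    ssy + s^2 * ssx - 2 * s * tr
  }
  best <- Inf
  for (refl in c(1, -1)) {
    grid <- seq(-pi, pi, length.out = 721)
    vals <- vapply(grid, resid_at, numeric(1), refl = refl)
    th0 <- grid[which.min(vals)]
    best <- min(
      best,
      stats::optimize(resid_at, c(th0 - 0.02, th0 + 0.02),
        refl = refl, tol = 1e-12
      )$objective
    )
  }
  expect_lt(abs(fit$residual - best), 1e-6)
})

test_that("procrustes is exact for random transforms including reflections", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(4:30, 1)
    d <- sample(2:3, 1)
    x <- matrix(rnorm(n * d), n, d)
    q <- qr.Q(qr(matrix(rnorm(d * d), d)))
    if (i %% 2 == 0) q[, 1] <- -q[, 1] # force a reflection half the time
    s <- runif(1, 0.1, 5)
    t <- rnorm(d)
    y <- s * x %*% q + matrix(t, n, d, byrow = TRUE)
    fit <- procrustes_fit(x, y)
    expect_lt(fit$residual, 1e-8)
    expect_equal(fit$similarity, 1, tolerance = 1e-8)
  }
})

test_that("closed-form procrustes agrees with the vegan implementation", {
  set.seed(13)
  x <- matrix(rnorm(24), 12, 2)
  y <- matrix(rnorm(24), 12, 2)
  fit <- procrustes_fit(x, y)
  vfit <- vegan::procrustes(y, x, symmetric = FALSE) # rotates x onto y
  expect_equal(fit$residual, sum(stats::residuals(vfit)^2), tolerance = 1e-8)
  expect_equal(abs(det(fit$rotation)), 1, tolerance = 1e-8)
})

test_that("an exact-copy sample projects onto its panel twin", {
  sim <- quick_sim(6, n_snps = 250, n_ref = 30)
  hom <- homozygize_panel(sim$panel, 2)
  pca <- suppressWarnings(reference_pca(hom, 2))
  calls <- calls_from_vector(hom$sites, hom$genotypes[7, ], "copy")
  pr <- project_ancient(hom, calls, pca)
  twin <- unlist(pca$coordinates[7, c("PC1", "PC2")])
  expect_lt(max(abs(c(pr$PC1, pr$PC2) - twin)), 1e-6)
})

test_that("projection is invariant to reference-axis sign flips", {
  sim <- quick_sim(7, n_snps = 250, n_ref = 30)
  hom <- homozygize_panel(sim$panel, 2)
  pca <- suppressWarnings(reference_pca(hom, 2))
  calls <- calls_from_vector(hom$sites, hom$genotypes[3, ], "copy")
  pr <- project_ancient(hom, calls, pca)
  flipped <- pca
  flipped$coordinates$PC1 <- -flipped$coordinates$PC1
  pr2 <- project_ancient(hom, calls, flipped)
  expect_equal(pr2$PC1, -pr$PC1, tolerance = 1e-8)
  expect_equal(pr2$PC2, pr$PC2, tolerance = 1e-8)
})

test_that("sparse admixed samples project between the population centroids", {
  cfg <- sim_config(
    n_pops = 2, fst_per_pop = c(0.15, 0.15), n_snps = 400,
    n_ref_per_pop = 40, mean_depth = 3, admixture_truth = c(0.5, 0.5)
  )
  between <- 0
  for (s in 1:10) {
    sim <- simulate_panel(cfg, 300 + s)
    tv <- mask_transitions(sim$panel$sites)
    keep <- sim$panel$sites$id %in% tv$id
    hom <- homozygize_panel(adnakit:::subset_panel_sites(sim$panel, keep), s)
    pca <- suppressWarnings(reference_pca(hom, 2))
    frags <- simulate_fragments(sim$truth, cfg, 400 + s)
    calls <- call_pseudohaploid(frags, tv, seed = 500 + s)
    pr <- project_ancient(hom, calls, pca)
    cent <- tapply(pca$coordinates$PC1, pca$coordinates$population, mean)
    between <- between + (pr$PC1 > min(cent) && pr$PC1 < max(cent))
  }
  expect_gte(between, 9)
})

test_that("insufficient shared sites are reported, not projected", {
  sim <- quick_sim(8, n_snps = 100, n_ref = 10)
  hom <- homozygize_panel(sim$panel, 1)
  pca <- suppressWarnings(reference_pca(hom, 2))
  sparse <- calls_from_vector(
    hom$sites,
    c(hom$genotypes[1, 1:20], rep(NA_integer_, 80)), "thin"
  )
  pr <- project_ancient(hom, sparse, pca, min_sites = 50)
  expect_false(pr$projected)
  expect_identical(pr$note, "insufficient SNPs")
  expect_true(is.na(pr$PC1))
})

test_that("k = 1 admixture reduces to the closed-form allele frequencies", {
  sim <- quick_sim(9, n_snps = 120, n_ref = 12)
  fit <- admixture_em(sim$panel, 1, seed = 1)
  expect_equal(unname(fit$Q[, 1]), rep(1, 24))
  expect_equal(
    as.vector(fit$F),
    unname(colMeans(sim$panel$genotypes) / 2),
    tolerance = 1e-6
  )
  expect_error(admixture_em(sim$panel, 25, seed = 1), class = "adnakit_parameter_error")
})

test_that("an all-het individual between fixed clusters gets q = (1/2, 1/2)", {
  m <- 400
  sites <- tibble::tibble(
    chrom = "1", pos = seq_len(m) * 10L, id = sprintf("s%d", seq_len(m)),
    ref = "A", alt = "C"
  )
  n_side <- 30
  ind <- tibble::tibble(
    id = sprintf("i%d", seq_len(2 * n_side + 1)),
    population = c(rep(c("a", "b"), each = n_side), "anc")
  )
  g <- rbind(
    matrix(0L, n_side, m), matrix(2L, n_side, m),
    matrix(1L, 1, m)
  )
  fit <- admixture_em(genotype_panel(ind, sites, g), 2, seed = 3, tol = 1e-8)
  expect_equal(unname(fit$Q[2 * n_side + 1, ]), c(0.5, 0.5), tolerance = 1e-3)
})

test_that("EM log-likelihood is monotone and label-permutation invariant", {
  sim <- quick_sim(10, n_snps = 200, n_ref = 20)
  for (s in 1:3) {
    fit <- admixture_em(sim$panel, 2, seed = s)
    expect_true(all(diff(fit$loglik_trace) >= 0))
    expect_true(all(abs(rowSums(fit$Q) - 1) < 1e-6))
    expect_true(all(fit$Q >= 0 & fit$Q <= 1))
  }
  fit <- admixture_em(sim$panel, 2, seed = 1)
  ll <- function(q, f) {
    g <- panel_dosages(sim$panel)
    p <- pmin(pmax(q %*% f, 1e-6), 1 - 1e-6)
    sum(g * log(p) + (2 - g) * log(1 - p), na.rm = TRUE)
  }
  expect_equal(ll(fit$Q, fit$F), ll(fit$Q[, 2:1], fit$F[2:1, ]))
  expect_equal(ll(fit$Q, fit$F), fit$loglik, tolerance = 1e-6)
})

test_that("admixture recovery and missing data handling are sound", {
  cfg <- sim_config(
    n_pops = 2, fst_per_pop = c(0.2, 0.2), n_snps = 500,
    n_ref_per_pop = 40
  )
  sim <- simulate_panel(cfg, 12)
  g <- panel_dosages(sim$panel)
  set.seed(1)
  g[sample(length(g), length(g) %/% 10)] <- NA # 10% missing
  pan <- genotype_panel(sim$panel$individuals, sim$panel$sites, g)
  fit <- admixture_em(pan, 2, seed = 2)
  truth <- cbind(
    rep(c(1, 0), each = 40),
    rep(c(0, 1), each = 40)
  )
  expect_lt(aligned_q_mae(fit$Q, truth), 0.05)
})

test_that("cross-validation prefers the true cluster count", {
  cfg <- sim_config(
    n_pops = 2, fst_per_pop = c(0.2, 0.2), n_snps = 400,
    n_ref_per_pop = 30
  )
  sim <- simulate_panel(cfg, 14)
  cv1 <- cv_error(sim$panel, 1, seed = 5)
  cv2 <- cv_error(sim$panel, 2, seed = 5)
  expect_gt(cv1, cv2)
  expect_error(cv_error(sim$panel, 2, folds = 1), class = "adnakit_parameter_error")
  # unstructured data: extra clusters do not help
  cfg0 <- sim_config(
    n_pops = 1, fst_per_pop = 0.1, n_snps = 400, n_ref_per_pop = 60,
    admixture_truth = matrix(1, 1, 1)
  )
  worse <- 0
  for (s in 1:5) {
    sim0 <- simulate_panel(cfg0, 20 + s)
    worse <- worse +
      (cv_error(sim0$panel, 2, seed = s) >= cv_error(sim0$panel, 1, seed = s))
  }
  expect_gte(worse, 3)
})

test_that("run alignment recovers label permutations and averages runs", {
  set.seed(2)
  q <- matrix(stats::rexp(60), 20, 3)
  q <- q / rowSums(q)
  runs <- list(q, q[, c(3, 1, 2)], q[, c(2, 3, 1)])
  al <- align_runs(runs)
  expect_equal(al$similarity, 1, tolerance = 1e-12)
  expect_equal(al$Q_mean, q, tolerance = 1e-12)
  # the stored permutation, applied to the run's columns, restores the
  # reference labelling
  expect_equal(runs[[2]][, al$permutations[[2]]], q)
  # single run: identity
  one <- align_runs(list(q))
  expect_identical(one$permutations[[1]], 1:3)
  expect_equal(one$Q_mean, q)
  expect_error(
    align_runs(list(q, q[1:10, ])),
    class = "adnakit_parameter_error"
  )
})

test_that("repeated seeded runs on structured data align almost perfectly", {
  sim <- quick_sim(15, n_snps = 300, n_ref = 25, fst = 0.2)
  runs <- lapply(1:5, function(s) admixture_em(sim$panel, 2, seed = s)$Q)
  al <- align_runs(runs)
  expect_gt(al$similarity, 0.95)
})
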