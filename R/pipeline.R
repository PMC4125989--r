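#' Default analysis settings for the screening pipeline
#'
#' Thresholds mirror the conventional low-coverage screening workflow:
#' base quality >= 15, mapping quality >= 30, LD pruning at r-squared 0.2,
#' PMD thresholds 3 (damage-restricted) / -2 (effectively unfiltered), Ry
#' bands 0.016 / 0.075, admixture at k = 3 with 10 aligned replicate runs.
#'
#' @param ... Overrides for any default field.
#' @return Named list of settings.
#' @export
pipeline_defaults <- function(...) {
  defaults <- list(
    min_bq = 15, min_mq = 30,
    r2_max = 0.2, ld_window = 50, ld_step = 5,
    pmd_threshold = 3, pmd_unfiltered = -2,
    t_female = 0.016, t_male = 0.075, min_sex_reads = 100,
    min_proj_sites = 50,
    admix_k = 3, admix_replicates = 10,
    select_k = FALSE, k_range = 2:10, cv_folds = 5,
    pmd_replicate = TRUE, pmd_floor = 100,
    mt_min_len = 25, mt_trim = 3,
    n_components = 2,
    seed = 1,
    total_reads = NULL, genome_size = NULL,
    quiet = FALSE
  )
  over <- list(...)
  defaults[names(over)] <- over
  defaults
}

stage_log <- function(settings, fmt, ...) {
  if (!isTRUE(settings$quiet)) message(sprintf(fmt, ...))
}

#' Run the full low-coverage screening pipeline
#'
#' Executes, per sample: damage profiling; sex estimation from X/Y read
#' counts; pseudo-haploid calling at panel SNPs; Procrustes projection into
#' the reference PC space; admixture-proportion estimation (aligned over
#' seeded replicate runs); mitochondrial haplogroup scoring; and, when
#' enough reads survive, a PMD-restricted replicate of the sex estimate and
#' the projection as a contamination check. A failing sample is reported
#' with a note and skipped, never aborting the batch.
#'
#' The reference panel is prepared once: transitions masked, heterozygotes
#' randomly homozygized, LD pruned, then a reference PCA fitted.
#'
#' @param frags Fragment tibble for all samples (autosomes + X/Y + MT).
#' @param panel Reference [genotype_panel()].
#' @param settings [pipeline_defaults()] list (or a path to a key-value
#'   config file parsed by [read_config()]).
#' @param tree Haplogroup tree for the mt stage.
#' @param mt_ref Circular mt reference bases.
#' @param out_dir Optional directory; per-stage outputs and the report are
#'   written there with a manifest.
#' @return A list of class `pipeline_result`: `report` (one tibble row per
#'   sample), `ref_pca`, `admixture`, and per-sample stage objects.
#' @export
run_pipeline <- function(frags, panel, settings = pipeline_defaults(),
                         tree = mt_toy_tree(), mt_ref = mt_reference(),
                         out_dir = NULL) {
  if (is.character(settings)) {
    settings <- do.call(pipeline_defaults, read_config(settings))
  }
  s <- settings
  seed <- as.integer(s$seed)

  # ---- panel preparation (shared across samples) ----
  stage_log(s, "panel: %d individuals, %d SNPs", nrow(panel$individuals), nrow(panel$sites))
  sites_tv <- mask_transitions(panel$sites)
  keep <- panel$sites$id %in% sites_tv$id
  stage_log(s, "panel: %d transition SNPs masked", sum(!keep))
  panel_tv <- subset_panel_sites(panel, keep)
  panel_hom <- homozygize_panel(panel_tv, seed = derive_seed(seed, "homozygize"))
  pruned <- ld_prune(panel_hom, r2_max = s$r2_max, window = s$ld_window, step = s$ld_step)
  stage_log(s, "panel: %d SNPs pruned by LD", nrow(panel_tv$sites) - nrow(pruned))
  panel_pca <- subset_panel_sites(panel_hom, panel_hom$sites$id %in% pruned$id)
  ref_pca <- suppressWarnings(reference_pca(panel_pca, s$n_components))
  centroids <- ref_pca$coordinates %>%
    group_by(.data$population) %>%
    summarise(dplyr::across(dplyr::starts_with("PC"), mean))

  samples <- unique(frags$sample_id)
  model <- pmd_model()
  per_sample <- list()
  report_rows <- list()
  all_calls <- list()

  for (sid in samples) {
    row <- tryCatch(
      {
        f <- frags[frags$sample_id == sid, , drop = FALSE]
        res <- list()

        # damage
        auto <- f[!f$chrom %in% c("X", "Y"), , drop = FALSE]
        prof <- tryCatch(mismatch_profile(f, min_mapq = s$min_mq),
          error = function(e) NULL
        )
        res$damage <- prof
        dfit <- if (!is.null(prof)) tryCatch(fit_damage_model(prof), error = function(e) NULL)

        # sex, unfiltered
        cnt <- count_sex_reads(f, min_mapq = s$min_mq)
        sex <- if (nrow(cnt)) {
          estimate_sex(cnt$nX, cnt$nY,
            t_female = s$t_female,
            t_male = s$t_male, min_reads = s$min_sex_reads
          )
        } else {
          estimate_sex(0, 0, min_reads = s$min_sex_reads)
        }
        res$sex <- sex

        # pseudo-haploid calls at pruned transversion sites
        calls <- call_pseudohaploid(
          auto[auto$chrom %in% panel_pca$sites$chrom, , drop = FALSE],
          panel_pca$sites,
          min_bq = s$min_bq, min_mq = s$min_mq,
          seed = derive_seed(seed, paste0("call_", sid)), sample_id = sid
        )
        res$calls <- calls
        all_calls[[sid]] <- calls

        # projection
        proj <- project_ancient(panel_pca, calls, ref_pca,
          min_sites = s$min_proj_sites
        )
        res$projection <- proj

        # mt haplogroup
        mt <- f[f$chrom == "MT", , drop = FALSE]
        mt_call <- NULL
        if (nrow(mt)) {
          mtp <- mt_prepare(mt,
            min_len = s$mt_min_len, trim = s$mt_trim,
            ref_length = length(mt_ref)
          )
          vars <- suppressWarnings(call_mt_variants(mtp, mt_ref, min_bq = s$min_bq))
          mt_call <- assign_haplogroup(vars, tree)
          res$mt <- mt_call
        }

        # PMD-restricted replicate
        sex_pmd_call <- NA_character_
        proj_pmd <- NULL
        if (isTRUE(s$pmd_replicate)) {
          fp <- filter_by_pmd(f, s$pmd_threshold, model)
          if (nrow(fp) >= s$pmd_floor) {
            cntp <- count_sex_reads(fp, min_mapq = s$min_mq)
            if (nrow(cntp)) {
              sex_pmd_call <- estimate_sex(cntp$nX, cntp$nY,
                t_female = s$t_female, t_male = s$t_male,
                min_reads = s$min_sex_reads
              )$call
            }
            callsp <- call_pseudohaploid(
              fp[!fp$chrom %in% c("X", "Y", "MT"), , drop = FALSE],
              panel_pca$sites,
              min_bq = s$min_bq, min_mq = s$min_mq,
              seed = derive_seed(seed, paste0("callpmd_", sid)), sample_id = sid
            )
            proj_pmd <- project_ancient(panel_pca, callsp, ref_pca,
              min_sites = s$min_proj_sites
            )
            res$projection_pmd <- proj_pmd
          }
        }

        per_sample[[sid]] <- res
        stage_log(
          s, "%s: %d fragments, sex %s, %d SNPs called, mt %s",
          sid, nrow(f), sex$call[1], attr(calls, "n_called"),
          if (is.null(mt_call)) "-" else mt_call$best
        )

        total <- if (is.null(s$total_reads)) {
          NA_real_
        } else {
          s$total_reads[[sid]] %||% NA_real_
        }
        tibble(
          sample_id = sid,
          total_reads = total,
          mapped_filtered = nrow(f),
          endogenous_percent = if (is.na(total)) {
            NA_real_
          } else {
            summarize_alignment(total, nrow(f))
          },
          genome_coverage_x = if (is.null(s$genome_size)) {
            NA_real_
          } else {
            nrow(f) * mean(nchar(f$sequence)) / s$genome_size
          },
          deaminated_fraction = if (is.null(prof)) {
            NA_real_
          } else {
            attr(prof, "deaminated_fraction")
          },
          damage_dmax_hat = if (is.null(dfit)) NA_real_ else dfit$dmax,
          sex_call = sex$call[1],
          Ry = sex$Ry[1],
          n_snps_called = attr(calls, "n_called"),
          projected = isTRUE(proj$projected[1]),
          PC1 = proj$PC1[1],
          PC2 = if ("PC2" %in% names(proj)) proj$PC2[1] else NA_real_,
          mt_haplogroup = if (is.null(mt_call)) NA_character_ else mt_call$best,
          mt_score = if (is.null(mt_call)) NA_real_ else mt_call$score,
          sex_call_pmd = sex_pmd_call,
          PC1_pmd = if (is.null(proj_pmd)) NA_real_ else proj_pmd$PC1[1],
          PC2_pmd = if (!is.null(proj_pmd) && "PC2" %in% names(proj_pmd)) {
            proj_pmd$PC2[1]
          } else {
            NA_real_
          },
          note = NA_character_
        )
      },
      error = function(e) {
        warn(sprintf("sample %s failed: %s", sid, conditionMessage(e)))
        tibble(
          sample_id = sid, total_reads = NA_real_, mapped_filtered = NA_integer_,
          endogenous_percent = NA_real_, genome_coverage_x = NA_real_,
          deaminated_fraction = NA_real_, damage_dmax_hat = NA_real_,
          sex_call = "insufficient", Ry = NA_real_, n_snps_called = 0L,
          projected = FALSE, PC1 = NA_real_, PC2 = NA_real_,
          mt_haplogroup = NA_character_, mt_score = NA_real_,
          sex_call_pmd = NA_character_, PC1_pmd = NA_real_, PC2_pmd = NA_real_,
          note = conditionMessage(e)
        )
      }
    )
    report_rows[[sid]] <- row
  }

  # admixture on the merged panel (reference + all callable samples)
  admix <- NULL
  callable <- purrr::keep(all_calls, ~ attr(.x, "n_called") >= s$min_proj_sites)
  if (length(callable)) {
    merged <- merge_calls(panel_pca, unname(callable), mode = "union")
    k <- s$admix_k
    if (isTRUE(s$select_k)) {
      cvs <- vapply(
        s$k_range,
        function(kk) {
          cv_error(merged, kk,
            folds = s$cv_folds,
            seed = derive_seed(seed, paste0("cv_k", kk))
          )
        },
        numeric(1)
      )
      k <- s$k_range[which.min(cvs)]
      stage_log(s, "admixture: cross-validation selected k = %d", k)
    }
    runs <- lapply(seq_len(s$admix_replicates), function(r) {
      admixture_em(merged, k, seed = derive_seed(seed, paste0("admix", r)))$Q
    })
    admix <- align_runs(runs)
    admix$individuals <- merged$individuals
    qm <- admix$Q_mean
    for (sid in names(callable)) {
      i <- match(sid, merged$individuals$id)
      qv <- paste(sprintf("%.3f", qm[i, ]), collapse = ",")
      report_rows[[sid]]$admixture <- qv
    }
  }
  report <- bind_rows(report_rows)
  if (!"admixture" %in% names(report)) report$admixture <- NA_character_

  out <- structure(
    list(
      report = report, ref_pca = ref_pca, centroids = centroids,
      admixture = admix, samples = per_sample, settings = s
    ),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d sample(s)\n", nrow(x$report)))
  print(x$report[, c(
    "sample_id", "sex_call", "n_snps_called", "projected",
    "mt_haplogroup", "admixture"
  )])
  invisible(x)
}

#' @export
tidy.pipeline_result <- function(x, ...) {
  x$report
}

#' Write pipeline outputs with a manifest
#'
#' Writes the per-sample report as TSV and JSON, the reference PCA
#' coordinates and averaged admixture matrix as TSV, and a `manifest.json`
#' naming every file with the settings used.
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  p <- file.path(out_dir, "report.tsv")
  write.table(result$report, p, sep = "\t", quote = FALSE, row.names = FALSE)
  files$report_tsv <- p
  p <- file.path(out_dir, "report.json")
  jsonlite::write_json(result$report, p, auto_unbox = TRUE, digits = NA, na = "null")
  files$report_json <- p
  p <- file.path(out_dir, "reference_pca.tsv")
  write.table(result$ref_pca$coordinates, p,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  files$reference_pca <- p
  if (!is.null(result$admixture)) {
    p <- file.path(out_dir, "admixture_Q.tsv")
    qm <- as.data.frame(result$admixture$Q_mean)
    names(qm) <- paste0("cluster", seq_along(qm))
    qm <- cbind(result$admixture$individuals, qm)
    write.table(qm, p, sep = "\t", quote = FALSE, row.names = FALSE)
    files$admixture_q <- p
  }
  settings <- result$settings
  settings$total_reads <- NULL
  jsonlite::write_json(
    list(files = files, settings = settings),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(out_dir)
}
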