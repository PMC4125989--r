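MT_LENGTH <- 16569L

#' Synthetic circular mitochondrial reference
#'
#' A deterministic, seeded 16,569-base random sequence standing in for the
#' human mitochondrial reference coordinate system (same length and
#' circular topology; the bases themselves are synthetic, not the real
#' reference, which is not bundled). All mitochondrial coordinates in the
#' package are 1-based positions on this circle.
#'
#' @param length Reference length (default 16,569).
#' @param seed Seed fixing the synthetic sequence.
#' @return Character vector of single bases.
#' @export
mt_reference <- function(length = MT_LENGTH, seed = 16569L) {
  with_seed(seed, sample(BASES, length, replace = TRUE))
}

#' Built-in toy mitochondrial haplogroup tree
#'
#' A small fabricated defining-mutation tree covering the African L0-L3
#' macrohaplogroup topology (including L1b1, L2b1 and L3'4'6). Positions
#' and bases are synthetic stand-ins chosen on the [mt_reference()]
#' coordinate system; they are documented test fixtures, not phylotree
#' content. Mutations are written `<pos><base>`, e.g. `"1048T"`.
#'
#' @param reference The reference the mutations are placed on (used to
#'   ensure each defining base differs from the reference base).
#' @return A `haplogroup_tree` tibble: `node`, `parent` (`NA` for the
#'   root), `mutations` (comma-separated, possibly empty).
#' @export
mt_toy_tree <- function(reference = mt_reference()) {
  spine <- tibble(
    node = c(
      "mt-root",
      "L0", "L0a", "L0a1", "L0d",
      "L1", "L1b", "L1b1", "L1c",
      "L2", "L2a", "L2a1", "L2b", "L2b1",
      "L3'4'6", "L3", "L3b", "L3b1", "L3e", "L3f",
      "L4", "L6",
      "L5", "L5a", "L5b"
    ),
    parent = c(
      NA,
      "mt-root", "L0", "L0a", "L0",
      "mt-root", "L1", "L1b", "L1",
      "mt-root", "L2", "L2a", "L2", "L2b",
      "mt-root", "L3'4'6", "L3", "L3b", "L3", "L3",
      "L3'4'6", "L3'4'6",
      "mt-root", "L5", "L5"
    ),
    n_mut = c(
      0L,
      3L, 2L, 2L, 3L,
      3L, 2L, 2L, 2L,
      3L, 2L, 2L, 2L, 2L,
      2L, 2L, 2L, 2L, 2L, 2L,
      3L, 3L,
      3L, 2L, 2L
    )
  )
  # deterministic, non-overlapping defining positions
  total <- sum(spine$n_mut)
  pos <- with_seed(20140808L, sort(sample.int(MT_LENGTH, total)))
  stopifnot(!anyDuplicated(pos))
  idx <- 1L
  muts <- character(nrow(spine))
  for (i in seq_len(nrow(spine))) {
    if (spine$n_mut[i] == 0L) {
      muts[i] <- ""
      next
    }
    p <- pos[idx:(idx + spine$n_mut[i] - 1L)]
    idx <- idx + spine$n_mut[i]
    # first non-reference base in fixed order: differs per position,
    # mixes damage-like and damage-unlike substitutions
    b <- vapply(p, function(pp) {
      setdiff(BASES, reference[pp])[1 + (pp %% 3)]
    }, character(1))
    muts[i] <- paste0(p, b, collapse = ",")
  }
  out <- tibble(node = spine$node, parent = spine$parent, mutations = muts)
  class(out) <- c("haplogroup_tree", class(out))
  validate_tree(out)
}

#' Validate a haplogroup tree table
#'
#' Checks for a single root, known parents and acyclicity.
#'
#' @param tree Tibble with columns `node`, `parent`, `mutations`.
#' @return The tree, invisibly classed as `haplogroup_tree`.
#' @export
validate_tree <- function(tree) {
  tree <- as_tibble(tree)
  if (!all(c("node", "parent", "mutations") %in% names(tree))) {
    abort("tree needs columns node, parent, mutations",
      class = "adnakit_format_error"
    )
  }
  if (nrow(tree) == 0) {
    abort("empty haplogroup tree", class = "adnakit_format_error")
  }
  roots <- tree$node[is.na(tree$parent) | tree$parent == ""]
  if (length(roots) != 1) {
    abort("tree must have exactly one root", class = "adnakit_format_error")
  }
  known <- tree$parent %in% tree$node | is.na(tree$parent) | tree$parent == ""
  if (!all(known)) {
    abort("tree has unknown parent node(s)", class = "adnakit_format_error")
  }
  # acyclicity: walking up from every node must reach the root
  for (nd in tree$node) {
    seen <- character(0)
    cur <- nd
    while (!is.na(cur) && cur != "") {
      if (cur %in% seen) {
        abort("tree contains a cycle", class = "adnakit_format_error")
      }
      seen <- c(seen, cur)
      cur <- tree$parent[match(cur, tree$node)]
    }
  }
  if (!inherits(tree, "haplogroup_tree")) {
    class(tree) <- c("haplogroup_tree", class(tree))
  }
  tree
}

parse_mutations <- function(s) {
  if (is.na(s) || s == "") {
    return(tibble(pos = integer(0), base = character(0)))
  }
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([0-9]+)([ACGT])$", parts))
  bad <- vapply(m, length, integer(1)) != 3
  if (any(bad)) {
    abort(paste0("malformed mutation token(s): ", paste(parts[bad], collapse = ", ")),
      class = "adnakit_format_error"
    )
  }
  tibble(
    pos = as.integer(vapply(m, `[`, character(1), 2)),
    base = vapply(m, `[`, character(1), 3)
  )
}

# All defining mutations on the path root -> node (union of ancestors' and own).
node_path_mutations <- function(tree, node) {
  out <- list()
  cur <- node
  while (!is.na(cur) && cur != "") {
    i <- match(cur, tree$node)
    out[[length(out) + 1]] <- parse_mutations(tree$mutations[i])
    cur <- tree$parent[i]
  }
  distinct(bind_rows(out))
}

node_depth <- function(tree, node) {
  d <- 0L
  cur <- tree$parent[match(node, tree$node)]
  while (!is.na(cur) && cur != "") {
    d <- d + 1L
    cur <- tree$parent[match(cur, tree$node)]
  }
  d
}

#' Simulate mitochondrial fragments from a haplogroup
#'
#' Builds the haplotype by applying the node's path-defining mutations to
#' the circular reference, then draws fragments with uniform starts
#' (wrapping the origin), shifted-geometric lengths, terminal deamination
#' and base error as configured.
#'
#' @param haplogroup Node name in `tree`.
#' @param tree A [mt_toy_tree()]-style tree.
#' @param reference Circular reference as a character base vector.
#' @param mean_depth Expected coverage per position.
#' @param config A [sim_config()] (damage, error, fragment lengths).
#' @param seed Integer seed.
#' @param sample_id Sample label.
#' @return Fragment tibble with `chrom = "MT"`; positions 1-based on the
#'   circle (fragments may wrap past the origin).
#' @export
simulate_mt_fragments <- function(haplogroup, tree = mt_toy_tree(),
                                  reference = mt_reference(),
                                  mean_depth = 2, config = sim_config(),
                                  seed = 1L, sample_id = "ancient1") {
  stopifnot(haplogroup %in% tree$node)
  lref <- length(reference)
  hap <- reference
  pm <- node_path_mutations(tree, haplogroup)
  hap[pm$pos] <- pm$base

  with_seed(seed, {
    n <- rpois(1, mean_depth * lref / config$fragment_mean)
    if (n == 0) {
      return(empty_fragments())
    }
    lens <- draw_fragment_lengths(n, config)
    starts <- sample.int(lref, n, replace = TRUE)

    total <- sum(lens)
    fid <- rep.int(seq_len(n), lens)
    gpos <- ((rep.int(starts, lens) + sequence(lens) - 2L) %% lref) + 1L
    ref <- reference[gpos]
    obs <- hap[gpos]

    z5 <- sequence(lens)
    z3 <- rep.int(lens, lens) - z5 + 1L
    u <- runif(total)
    d5 <- damage_curve(z5, config$damage_dmax, config$damage_decay, config$damage_bg)
    d3 <- damage_curve(z3, config$damage_dmax, config$damage_decay, config$damage_bg)
    obs[obs == "C" & u < d5] <- "T"
    obs[obs == "G" & u < d3] <- "A"
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
    tibble(
      sample_id = sample_id,
      chrom = "MT",
      pos = as.integer(starts),
      strand = sample(c("+", "-"), n, replace = TRUE),
      mapq = 37L,
      sequence = substring(seq_all, starts_chr, ends),
      base_quals = strrep(substr(int_to_phred(q), 1, 1), lens),
      ref_bases = substring(ref_all, starts_chr, ends),
      origin = "endogenous"
    )
  })
}

#' Length-filter and end-trim mitochondrial fragments
#'
#' Drops fragments shorter than `min_len` (before trimming), then removes
#' `trim` bases and their qualities from each end, advancing the start
#' coordinate accordingly (with circular wrap-around). Trimming the ends
#' discards the positions where deamination is concentrated.
#'
#' @param frags Fragment tibble.
#' @param min_len Minimum pre-trim fragment length (default 25).
#' @param trim Bases removed from each end (default 3).
#' @param ref_length Circle length for coordinate wrap-around.
#' @return The filtered, trimmed fragment tibble.
#' @export
mt_prepare <- function(frags, min_len = 25L, trim = 3L,
                       ref_length = MT_LENGTH) {
  stopifnot(min_len > 2L * trim)
  frags <- frags[nchar(frags$sequence) >= min_len, , drop = FALSE]
  if (nrow(frags) == 0 || trim == 0L) {
    return(frags)
  }
  lens <- nchar(frags$sequence)
  frags$sequence <- substring(frags$sequence, trim + 1L, lens - trim)
  frags$ref_bases <- substring(frags$ref_bases, trim + 1L, lens - trim)
  frags$base_quals <- substring(frags$base_quals, trim + 1L, lens - trim)
  frags$pos <- as.integer(((frags$pos + trim - 1L) %% ref_length) + 1L)
  frags
}

#' Consensus mitochondrial variants against a circular reference
#'
#' At every covered position (coordinates wrap the circle), takes the
#' majority base among reads passing the base-quality gate and emits a
#' variant wherever it differs from the reference, with supporting depth
#' and the fraction of reads in agreement. Ties are broken toward the
#' reference, then alphabetically.
#'
#' @param frags Fragment tibble (chrom label is not interpreted).
#' @param reference Circular reference as a character base vector.
#' @param min_bq Base-quality gate (default 15).
#' @return An `mt_variants` tibble: `pos`, `ref`, `obs`, `depth`,
#'   `agreement`; attribute `n_covered` gives the number of covered
#'   positions.
#' @export
call_mt_variants <- function(frags, reference = mt_reference(), min_bq = 15L) {
  lref <- length(reference)
  empty <- tibble(
    pos = integer(0), ref = character(0), obs = character(0),
    depth = integer(0), agreement = numeric(0)
  )
  if (nrow(frags) == 0) {
    warn("no covered positions")
    attr(empty, "n_covered") <- 0L
    return(empty)
  }
  bt <- fragment_base_table(frags)
  bt$gpos <- (((bt$gpos - 1L) %% lref)) + 1L
  bt <- bt[bt$qual >= min_bq & bt$obs %in% BASES, , drop = FALSE]
  if (nrow(bt) == 0) {
    warn("no covered positions")
    attr(empty, "n_covered") <- 0L
    return(empty)
  }
  # per-base coverage counts via tabulate: rows A, C, G, T
  cnt <- vapply(
    BASES,
    function(b) tabulate(bt$gpos[bt$obs == b], nbins = lref),
    integer(lref)
  )
  depth <- rowSums(cnt)
  covered <- which(depth > 0L)
  n_cov <- length(covered)
  sub <- cnt[covered, , drop = FALSE]
  is_ref <- outer(reference[covered], BASES, "==")
  # majority base; ties break toward the reference, then alphabetically
  score <- sub * 8L + is_ref * 4L +
    matrix(3:0, n_cov, 4L, byrow = TRUE) / 4
  maj <- max.col(score, ties.method = "first")
  majbase <- BASES[maj]
  majn <- sub[cbind(seq_len(n_cov), maj)]
  isvar <- majbase != reference[covered]
  depth_var <- as.integer(depth[covered][isvar])
  out <- tibble(
    pos = covered[isvar],
    ref = reference[covered][isvar],
    obs = majbase[isvar],
    depth = depth_var,
    agreement = majn[isvar] / depth_var
  )
  class(out) <- c("mt_variants", class(out))
  attr(out, "n_covered") <- n_cov
  attr(out, "covered_pos") <- covered
  out
}

#' Score haplogroups against an observed variant set
#'
#' Every tree node is scored by the Kulczynski measure over its
#' path-defining mutations restricted to covered positions:
#' `(found / expected_on_path + found / observed_total) / 2`, where
#' `found` counts path mutations present in the variant set,
#' `expected_on_path` counts path mutations at covered positions, and
#' `observed_total` counts observed variants. Ties break toward the deeper
#' node, then lexicographically. With no covered positions the root is
#' returned with score 0 and an `uninformative` flag.
#'
#' @param variants An [call_mt_variants()] result (needs its
#'   `covered_pos` attribute, or supply `covered_pos`).
#' @param tree A [validate_tree()]-valid haplogroup tree.
#' @param covered_pos Optional integer vector of covered positions,
#'   overriding the attribute.
#' @return A `haplogroup_call`: `best`, `score`, `found`, `expected`,
#'   `conflicting` (covered path positions carrying a different observed
#'   base), `uninformative`, and `ranking` (tibble over all nodes).
#' @export
assign_haplogroup <- function(variants, tree = mt_toy_tree(),
                              covered_pos = NULL) {
  tree <- validate_tree(tree)
  covered <- covered_pos %||% attr(variants, "covered_pos") %||% variants$pos
  observed_total <- nrow(variants)
  root <- tree$node[is.na(tree$parent) | tree$parent == ""]

  if (length(covered) == 0) {
    return(structure(
      list(
        best = root, score = 0, found = 0L, expected = 0L,
        conflicting = 0L, uninformative = TRUE,
        ranking = tibble(
          node = root, score = 0, found = 0L, expected = 0L,
          conflicting = 0L, depth = 0L
        )
      ),
      class = "haplogroup_call"
    ))
  }

  vkey <- paste0(variants$pos, variants$obs)
  rows <- purrr::map(tree$node, function(nd) {
    pm <- node_path_mutations(tree, nd)
    pm <- pm[pm$pos %in% covered, , drop = FALSE]
    expected <- nrow(pm)
    found <- sum(paste0(pm$pos, pm$base) %in% vkey)
    conflicting <- sum(pm$pos %in% variants$pos) - found
    s1 <- if (expected > 0) found / expected else 0
    s2 <- if (observed_total > 0) found / observed_total else 0
    tibble(
      node = nd,
      score = (s1 + s2) / 2,
      found = found, expected = expected,
      conflicting = as.integer(conflicting),
      depth = node_depth(tree, nd)
    )
  })
  ranking <- bind_rows(rows) %>%
    arrange(
      dplyr::desc(.data$score), dplyr::desc(.data$depth), .data$node
    )
  best <- ranking[1, ]
  structure(
    list(
      best = best$node, score = best$score, found = best$found,
      expected = best$expected, conflicting = best$conflicting,
      uninformative = FALSE, ranking = ranking
    ),
    class = "haplogroup_call"
  )
}

#' @export
print.haplogroup_call <- function(x, ...) {
  if (x$uninformative) {
    cat("<haplogroup_call> uninformative (no covered positions)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<haplogroup_call> %s (score %.3f; %d/%d path mutations found, %d conflicting)\n",
    x$best, x$score, x$found, x$expected, x$conflicting
  ))
  invisible(x)
}

#' @export
tidy.haplogroup_call <- function(x, ...) {
  x$ranking
}
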