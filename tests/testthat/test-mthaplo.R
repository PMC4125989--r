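test_that("mt preparation length-filters then trims both ends", {
  ref <- mt_reference()
  f30 <- make_fragment(strrep("A", 30), strrep("A", 30), pos = 101, chrom = "MT")
  f24 <- make_fragment(strrep("A", 24), strrep("A", 24), pos = 500, chrom = "MT")
  out <- mt_prepare(dplyr::bind_rows(f30, f24), min_len = 25, trim = 3)
  expect_identical(nrow(out), 1L) # the 24-base fragment is dropped
  expect_identical(nchar(out$sequence), 24L)
  expect_identical(nchar(out$base_quals), 24L)
  expect_identical(out$pos, 104L)
  # trim = 0 is the identity apart from the length filter
  both <- dplyr::bind_rows(f30, f24)
  expect_identical(mt_prepare(both, min_len = 25, trim = 0), both[1, ])
  # start coordinates wrap the circle
  fwrap <- make_fragment(strrep("A", 30), strrep("A", 30), pos = 16568, chrom = "MT")
  expect_identical(mt_prepare(fwrap)$pos, 2L)
  expect_error(mt_prepare(both, min_len = 5, trim = 3))
})

test_that("consensus variant calling reports substitutions with support", {
  ref <- mt_reference()
  seq10 <- paste(ref[101:110], collapse = "")
  f_match <- make_fragment(seq10, seq10, pos = 101, chrom = "MT")
  v0 <- call_mt_variants(f_match, ref)
  expect_identical(nrow(v0), 0L)
  expect_identical(attr(v0, "n_covered"), 10L)

  # a single substitution at position 105, depth 1
  mut <- unlist(strsplit(seq10, ""))
  mut[5] <- setdiff(c("A", "C", "G", "T"), mut[5])[1]
  f_mut <- make_fragment(paste(mut, collapse = ""), seq10, pos = 101, chrom = "MT")
  v1 <- call_mt_variants(f_mut, ref)
  expect_identical(v1$pos, 105L)
  expect_identical(v1$depth, 1L)
  expect_equal(v1$agreement, 1)
  expect_identical(v1$ref, ref[105])

  # ties break toward the reference
  v2 <- call_mt_variants(dplyr::bind_rows(f_match, f_mut), ref)
  expect_identical(nrow(v2), 0L)

  # empty input warns and returns an empty set
  expect_warning(ve <- call_mt_variants(f_match[0, ], ref), "no covered")
  expect_identical(nrow(ve), 0L)
})

test_that("a clean simulated 12-variant haplotype is recovered almost completely", {
  ref <- mt_reference()
  pos <- seq(800L, 16000L, length.out = 12)
  pos <- as.integer(round(pos))
  base <- vapply(pos, function(p) setdiff(c("A", "C", "G", "T"), ref[p])[1], character(1))
  tree12 <- validate_tree(tibble::tibble(
    node = c("root", "H12"),
    parent = c(NA, "root"),
    mutations = c("", paste0(pos, base, collapse = ","))
  ))
  cfg <- sim_config(base_error = 0, damage_dmax = 0, damage_bg = 0)
  frags <- simulate_mt_fragments("H12", tree12, ref,
    mean_depth = 3,
    config = cfg, seed = 5
  )
  v <- call_mt_variants(mt_prepare(frags), ref)
  found <- sum(paste0(pos, base) %in% paste0(v$pos, v$obs))
  expect_gte(found, 10) # a position can escape coverage, not be miscalled
  # zero false positives among well-supported variants
  strong <- v[v$agreement >= 0.8, ]
  expect_identical(
    nrow(strong),
    sum(paste0(strong$pos, strong$obs) %in% paste0(pos, base))
  )
})

test_that("haplogroup scoring follows the Kulczynski measure", {
  tree <- mt_toy_tree()
  all_pos <- 1:16569
  pm <- adnakit:::node_path_mutations(tree, "L2b1")
  v <- tibble::tibble(
    pos = pm$pos, ref = "N", obs = pm$base, depth = 2L, agreement = 1
  )
  hc <- assign_haplogroup(v, tree, covered_pos = all_pos)
  expect_identical(hc$best, "L2b1")
  expect_equal(hc$score, 1)
  expect_identical(hc$conflicting, 0L)
  # ranking never increases down the list
  expect_true(all(diff(hc$ranking$score) <= 1e-12))

  # a private extra mutation lowers the score but not the call
  pm3 <- adnakit:::node_path_mutations(tree, "L3")
  private_pos <- setdiff(all_pos, unlist(lapply(
    tree$node,
    function(n) adnakit:::node_path_mutations(tree, n)$pos
  )))[1]
  v3 <- tibble::tibble(
    pos = c(pm3$pos, private_pos), ref = "N",
    obs = c(pm3$base, "A"), depth = 1L, agreement = 1
  )
  hc3 <- assign_haplogroup(v3, tree, covered_pos = all_pos)
  expect_identical(hc3$best, "L3")
  expect_lt(hc3$score, 1)
  expect_identical(hc3$conflicting, 0L)

  # no coverage at all: root with score 0, flagged uninformative
  v_none <- tibble::tibble(
    pos = integer(0), ref = character(0), obs = character(0),
    depth = integer(0), agreement = numeric(0)
  )
  hc0 <- assign_haplogroup(v_none, tree, covered_pos = integer(0))
  expect_identical(hc0$best, "mt-root")
  expect_equal(hc0$score, 0)
  expect_true(hc0$uninformative)

  expect_error(
    assign_haplogroup(v, tibble::tibble(
      node = character(0),
      parent = character(0), mutations = character(0)
    )),
    class = "adnakit_format_error"
  )
})

test_that("restricting coverage never raises a node's expected count", {
  tree <- mt_toy_tree()
  set.seed(6)
  full <- 1:16569
  sub <- sort(sample(full, 8000))
  for (nd in sample(tree$node, 8)) {
    pm <- adnakit:::node_path_mutations(tree, nd)
    expect_lte(sum(pm$pos %in% sub), sum(pm$pos %in% full))
  }
})

test_that("damaged low-coverage haplotypes still rank the true node first", {
  tree <- mt_toy_tree()
  ref <- mt_reference()
  nodes <- c("L1b1", "L2b1", "L3'4'6", "L0a1", "L3b", "L5a")
  hits <- 0
  for (s in seq_along(nodes)) {
    frags <- simulate_mt_fragments(nodes[s], tree, ref,
      mean_depth = 2, seed = 60 + s
    )
    v <- call_mt_variants(mt_prepare(frags), ref)
    hits <- hits + (assign_haplogroup(v, tree)$best == nodes[s])
  }
  expect_gte(hits, 5)
})

test_that("tree validation catches malformed trees", {
  expect_error(
    validate_tree(tibble::tibble(
      node = c("r", "a"), parent = c(NA, "zz"), mutations = c("", "")
    )),
    "unknown parent"
  )
  expect_error(
    validate_tree(tibble::tibble(
      node = c("a", "b"), parent = c("b", "a"), mutations = c("", "")
    )),
    "root"
  )
  expect_error(
    adnakit:::parse_mutations("1048X"),
    class = "adnakit_format_error"
  )
  tree <- mt_toy_tree()
  expect_identical(sum(is.na(tree$parent)), 1L)
})
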