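#' Read and write fragment tables
#'
#' The fragment table is a TSV with one aligned fragment per row and
#' columns `sample_id`, `chrom`, `pos` (1-based leftmost), `strand`,
#' `mapq`, `sequence`, `base_quals` (phred+33 string), `ref_bases`, plus
#' any extra columns (round-tripped verbatim). Parsing is strict: length
#' mismatches between sequence, qualities and reference bases are reported
#' with the offending line.
#'
#' @param path File path.
#' @param frags Fragment tibble.
#' @return `read_fragments()` returns the fragment tibble;
#'   `write_fragments()` returns `path` invisibly.
#' @export
read_fragments <- function(path) {
  df <- read.table(path,
    header = TRUE, sep = "\t", quote = "",
    colClasses = "character", comment.char = ""
  )
  need <- c(
    "sample_id", "chrom", "pos", "strand", "mapq", "sequence",
    "base_quals", "ref_bases"
  )
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(
      sprintf(
        "%s: missing column(s) %s", path, paste(miss, collapse = ", ")
      ),
      class = "adnakit_format_error"
    )
  }
  df$pos <- as.integer(df$pos)
  df$mapq <- as.integer(df$mapq)
  bad <- which(
    nchar(df$sequence) != nchar(df$ref_bases) |
      nchar(df$sequence) != nchar(df$base_quals)
  )
  if (length(bad)) {
    abort(
      sprintf(
        "%s: line %d: sequence/base_quals/ref_bases lengths differ",
        path, bad[1] + 1L
      ),
      class = "adnakit_format_error"
    )
  }
  if (any(is.na(df$pos)) || any(is.na(df$mapq))) {
    abort(sprintf("%s: non-numeric pos or mapq", path),
      class = "adnakit_format_error"
    )
  }
  as_tibble(df)
}

#' @rdname read_fragments
#' @export
write_fragments <- function(frags, path) {
  write.table(frags, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read and write SNP site tables
#'
#' TSV with columns `chrom`, `pos`, `id`, `ref`, `alt`; duplicate
#' `(chrom, pos)` keys are an error listing the duplicates.
#'
#' @param path File path.
#' @param sites Site tibble.
#' @return The site tibble / the path invisibly.
#' @export
read_sites <- function(path) {
  df <- read.table(path,
    header = TRUE, sep = "\t", quote = "",
    colClasses = "character", comment.char = ""
  )
  df$pos <- suppressWarnings(as.integer(df$pos))
  if (any(is.na(df$pos))) {
    abort(sprintf("%s: non-integer pos at line %d", path, which(is.na(df$pos))[1] + 1L),
      class = "adnakit_format_error"
    )
  }
  validate_sites(df)
}

#' @rdname read_sites
#' @export
write_sites <- function(sites, path) {
  write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write and read genotype panels in PLINK-text ped/map dialect
#'
#' `write_panel_ped()` writes `<prefix>.ped` (whitespace-delimited: family
#' id, individual id, paternal/maternal ids, sex, phenotype, then two
#' allele letters per SNP, `0` for missing) and `<prefix>.map` (chrom, SNP
#' id, genetic distance, position). The family id column carries the
#' population label. `read_panel_ped()` needs the ref/alt alleles, which
#' ped/map does not store; supply the site table (or its path).
#'
#' @param panel A [genotype_panel()].
#' @param prefix Output path prefix.
#' @param sites Site table giving ref/alt per SNP (same order as the map).
#' @return The path prefix / the panel.
#' @export
write_panel_ped <- function(panel, prefix) {
  map <- data.frame(
    chrom = panel$sites$chrom, id = panel$sites$id,
    cm = 0, pos = panel$sites$pos
  )
  write.table(map, paste0(prefix, ".map"),
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  g <- panel$genotypes
  n <- nrow(g)
  m <- ncol(g)
  a1 <- matrix("0", n, m)
  a2 <- matrix("0", n, m)
  ref <- matrix(panel$sites$ref, n, m, byrow = TRUE)
  alt <- matrix(panel$sites$alt, n, m, byrow = TRUE)
  a1[!is.na(g) & g == 0L] <- ref[!is.na(g) & g == 0L]
  a2[!is.na(g) & g == 0L] <- ref[!is.na(g) & g == 0L]
  a1[!is.na(g) & g == 1L] <- ref[!is.na(g) & g == 1L]
  a2[!is.na(g) & g == 1L] <- alt[!is.na(g) & g == 1L]
  a1[!is.na(g) & g == 2L] <- alt[!is.na(g) & g == 2L]
  a2[!is.na(g) & g == 2L] <- alt[!is.na(g) & g == 2L]
  inter <- matrix("", n, 2L * m)
  inter[, seq(1, 2 * m, 2)] <- a1
  inter[, seq(2, 2 * m, 2)] <- a2
  ped <- cbind(
    panel$individuals$population, panel$individuals$id,
    "0", "0", "0", "-9", inter
  )
  write.table(ped, paste0(prefix, ".ped"),
    sep = " ", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(prefix)
}

#' @rdname write_panel_ped
#' @export
read_panel_ped <- function(prefix, sites) {
  if (is.character(sites) && length(sites) == 1 && file.exists(sites)) {
    sites <- read_sites(sites)
  }
  sites <- validate_sites(sites)
  map <- read.table(paste0(prefix, ".map"),
    sep = "\t", header = FALSE,
    colClasses = c("character", "character", "numeric", "integer")
  )
  names(map) <- c("chrom", "id", "cm", "pos")
  key <- paste(map$chrom, map$pos)
  skey <- paste(sites$chrom, sites$pos)
  if (!all(key %in% skey)) {
    abort("map file contains SNPs absent from the site table",
      class = "adnakit_format_error"
    )
  }
  sites <- sites[match(key, skey), , drop = FALSE]
  ped <- read.table(paste0(prefix, ".ped"),
    header = FALSE,
    colClasses = "character"
  )
  m <- nrow(map)
  if (ncol(ped) != 6 + 2 * m) {
    abort(
      sprintf(
        "%s.ped: expected %d columns, found %d",
        prefix, 6 + 2 * m, ncol(ped)
      ),
      class = "adnakit_format_error"
    )
  }
  a1 <- as.matrix(ped[, 6 + seq(1, 2 * m, 2), drop = FALSE])
  a2 <- as.matrix(ped[, 6 + seq(2, 2 * m, 2), drop = FALSE])
  ref <- matrix(sites$ref, nrow(ped), m, byrow = TRUE)
  alt <- matrix(sites$alt, nrow(ped), m, byrow = TRUE)
  dose <- function(a) {
    ifelse(a == "0", NA_integer_, ifelse(a == alt, 1L, ifelse(a == ref, 0L, NA_integer_)))
  }
  bad <- (a1 != "0" & a1 != ref & a1 != alt) |
    (a2 != "0" & a2 != ref & a2 != alt)
  if (any(bad)) {
    abort(
      sprintf(
        "%s.ped: allele not matching site table at SNP %s",
        prefix, sites$id[which(colSums(bad) > 0)[1]]
      ),
      class = "adnakit_format_error"
    )
  }
  g <- dose(a1) + dose(a2)
  genotype_panel(
    tibble(id = ped[[2]], population = ped[[1]]),
    sites, g
  )
}

#' Write and read genotype panels in the transposed-TSV dialect
#'
#' One row per SNP: `chrom`, `pos`, `id`, `ref`, `alt`, then one dosage
#' column per individual (0/1/2, `NA` missing). A leading header line
#' `#populations:` records each individual's population label.
#'
#' @param panel A [genotype_panel()].
#' @param path File path.
#' @return The path / the panel.
#' @export
write_panel_tsv <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(
    "#populations:\t",
    paste(panel$individuals$population, collapse = "\t")
  ), con)
  df <- bind_cols(
    panel$sites,
    as_tibble(setNames(
      as.data.frame(t(panel$genotypes)),
      panel$individuals$id
    ))
  )
  suppressWarnings(write.table(df, con,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  ))
  invisible(path)
}

#' @rdname write_panel_tsv
#' @export
read_panel_tsv <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#populations:")) {
    abort(sprintf("%s: line 1: missing #populations: header", path),
      class = "adnakit_format_error"
    )
  }
  pops <- strsplit(first, "\t", fixed = TRUE)[[1]][-1]
  df <- read.table(path,
    header = TRUE, sep = "\t", skip = 1, quote = "",
    comment.char = "", check.names = FALSE,
    colClasses = c(
      chrom = "character", id = "character",
      ref = "character", alt = "character"
    )
  )
  sites <- validate_sites(df[, c("chrom", "pos", "id", "ref", "alt")])
  gcols <- setdiff(names(df), c("chrom", "pos", "id", "ref", "alt"))
  if (length(gcols) != length(pops)) {
    abort(sprintf(
      "%s: %d genotype columns but %d population labels",
      path, length(gcols), length(pops)
    ), class = "adnakit_format_error")
  }
  g <- t(as.matrix(df[, gcols, drop = FALSE]))
  genotype_panel(tibble(id = gcols, population = pops), sites, g)
}

#' Read and write haplogroup trees
#'
#' TSV with columns `node`, `parent` (empty for the root) and `mutations`
#' (comma-separated `<pos><base>` tokens, possibly empty).
#'
#' @param path File path.
#' @param tree A `haplogroup_tree` tibble.
#' @return The tree / the path.
#' @export
read_tree <- function(path) {
  df <- read.table(path,
    header = TRUE, sep = "\t", quote = "",
    colClasses = "character", comment.char = "", na.strings = NULL
  )
  df$parent[df$parent == ""] <- NA_character_
  validate_tree(as_tibble(df))
}

#' @rdname read_tree
#' @export
write_tree <- function(tree, path) {
  out <- tree
  out$parent[is.na(out$parent)] <- ""
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write a mitochondrial reference as FASTA
#'
#' @param path FASTA path (first record used).
#' @param reference Character base vector.
#' @param name Sequence name for writing.
#' @return Character base vector / the path.
#' @export
read_mt_fasta <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "DNA", forceDNAtolower = FALSE)
  if (!length(seqs)) {
    abort(sprintf("%s: no FASTA records", path), class = "adnakit_format_error")
  }
  toupper(as.character(seqs[[1]]))
}

#' @rdname read_mt_fasta
#' @export
write_mt_fasta <- function(reference, path, name = "MT-synthetic") {
  seqinr::write.fasta(list(reference), names = name, file.out = path)
  invisible(path)
}

#' Write a damage profile as TSV
#'
#' @param profile A [mismatch_profile()] result.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_profile <- function(profile, path) {
  write.table(as.data.frame(profile), path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}

#' Parse a plain key-value pipeline configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a
#' comment. Values are parsed as numbers where possible; comma-separated
#' values become vectors.
#'
#' @param path File path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    m <- regmatches(lines[i], regexec("^([^=:]+)[=:](.*)$", lines[i]))[[1]]
    if (length(m) != 3) {
      abort(sprintf("%s: line %d: expected key = value", path, i),
        class = "adnakit_format_error"
      )
    }
    key <- trimws(m[2])
    val <- trimws(strsplit(m[3], ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!any(is.na(num))) num else val
  }
  out
}

#' Convert simple SAM records to a fragment table
#'
#' Minimal text-SAM adapter: keeps records whose CIGAR is a single
#' `<len>M` match block and which carry an `MD:Z:` tag, reconstructs the
#' aligned reference bases from the read and the MD tag, and maps flag bit
#' 16 to the `-` strand. Records with indels, clipping or no MD tag are
#' skipped (counted in the `skipped` attribute). Sequences in SAM are
#' already stored in genomic orientation, matching the fragment-table
#' convention.
#'
#' @param path SAM file path.
#' @param sample_id Sample label for all records.
#' @return Fragment tibble; attribute `skipped` counts unconvertible
#'   records.
#' @export
read_fragments_sam <- function(path, sample_id = "sample") {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  skipped <- 0L
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) {
      abort(sprintf("%s: line %d: fewer than 11 SAM fields", path, i),
        class = "adnakit_format_error"
      )
    }
    cigar <- f[6]
    md <- sub("^MD:Z:", "", grep("^MD:Z:", f[-(1:11)], value = TRUE)[1])
    if (!grepl("^[0-9]+M$", cigar) || is.na(md)) {
      skipped <- skipped + 1L
      next
    }
    seqb <- strsplit(f[10], "", fixed = TRUE)[[1]]
    refb <- seqb
    # walk the MD tag: numbers are matches, letters are reference bases at
    # mismatches (no deletions possible for an all-M CIGAR)
    toks <- regmatches(md, gregexpr("[0-9]+|[A-Z]", md))[[1]]
    at <- 1L
    ok <- TRUE
    for (tk in toks) {
      if (grepl("^[0-9]+$", tk)) {
        at <- at + as.integer(tk)
      } else {
        if (at > length(refb)) {
          ok <- FALSE
          break
        }
        refb[at] <- tk
        at <- at + 1L
      }
    }
    if (!ok || at != length(refb) + 1L) {
      skipped <- skipped + 1L
      next
    }
    flag <- as.integer(f[2])
    rows[[i]] <- tibble(
      sample_id = sample_id, chrom = f[3], pos = as.integer(f[4]),
      strand = if (bitwAnd(flag, 16L) > 0) "-" else "+",
      mapq = as.integer(f[5]), sequence = f[10], base_quals = f[11],
      ref_bases = paste(refb, collapse = "")
    )
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) out <- empty_fragments()[, 1:8]
  attr(out, "skipped") <- skipped
  out
}
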