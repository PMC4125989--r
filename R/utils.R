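#' Derive per-stage seeds from a single pipeline seed
#'
#' A single user-facing seed fans out into independent per-stage seeds so
#' that every pipeline stage is reproducible in isolation. The derivation
#' is a splitmix-style integer hash of the master seed and the stage name,
#' folded into the 31-bit range R accepts in [set.seed()].
#'
#' @param seed Master integer seed.
#' @param stage Character stage label (e.g. `"panel"`, `"fragments"`).
#' @return A single integer in `[0, 2^31 - 1)`.
#' @examples
#' derive_seed(1, "panel")
#' derive_seed(1, "fragments")
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  # 31-bit modular mix; doubles hold integers exactly below 2^53 so the
  # intermediate products must stay below that: work modulo 2^31 - 1.
  m <- 2147483647
  h <- as.numeric(seed) %% m
  h <- (h * 48271) %% m
  for (ch in utf8ToInt(stage)) {
    h <- (h * 69621 + ch) %% m
  }
  as.integer(h)
}

# Evaluate `code` under a local RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Positions of each base of every fragment, as parallel vectors. Fragments
# are stored in genomic orientation, so base i of a fragment sits at
# pos + i - 1 irrespective of strand.
fragment_base_table <- function(frags) {
  lens <- nchar(frags$sequence)
  idx <- rep.int(seq_len(nrow(frags)), lens)
  offset <- sequence(lens)
  tibble(
    frag = idx,
    offset = offset,
    gpos = frags$pos[idx] + offset - 1L,
    obs = unlist(strsplit(frags$sequence, "", fixed = TRUE), use.names = FALSE),
    ref = unlist(strsplit(frags$ref_bases, "", fixed = TRUE), use.names = FALSE),
    qual = unlist(lapply(frags$base_quals, phred_to_int), use.names = FALSE)
  )
}

BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp_chr <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE), function(b) {
    paste(rev(unname(COMPLEMENT[b])), collapse = "")
  }, character(1))
}

# Phred+33 encoding of per-base qualities, as in FASTQ/SAM: integer vector
# in, single quality string out.
int_to_phred <- function(q) {
  intToUtf8(pmin(pmax(as.integer(q), 0L), 93L) + 33L)
}

phred_to_int <- function(s) {
  utf8ToInt(s) - 33L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
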