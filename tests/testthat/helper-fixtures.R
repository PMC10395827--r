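# shared fixtures, built in code; the MSH2-like gene is cached per session
msh_gene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- mshlike_gene()
    cache
  }
})

# a small, fast toy-gene spec for property loops
small_spec <- function(seed, cryptic = 20L, trunc_stop = 5L, ret_stop = 3L) {
  toy_gene_spec(exon_lengths = c(45L, 150L, 120L),
                intron_lengths = c(120L, 100L),
                target_exon = 2L, cds_prefix_codons = 15L,
                cryptic_ag_offsets = cryptic,
                truncation_stop = trunc_stop, retention_stop = ret_stop,
                seed = seed)
}

# sample one integer from [lo, hi] without the scalar-range sample() gotcha
pick <- function(lo, hi) if (lo >= hi) lo else sample(seq(lo, hi), 1)

# a randomized feasible spec (three exons, studied intron 1)
random_toy_spec <- function(seed) {
  set.seed(seed)
  P <- pick(8, 40)
  target_len <- pick(45, 150)
  last_len <- pick(60, 150)
  L1 <- pick(90, 200)
  L2 <- pick(60, 150)
  d <- pick(16, min(98L, L1 - 12L))
  ts <- pick(3, min(12L, (target_len - 2L) %/% 3L))
  rs <- pick(2, max(2L, (d - 10L) %/% 3L))
  toy_gene_spec(exon_lengths = c(3L * P, target_len, last_len),
                intron_lengths = c(L1, L2),
                target_exon = 2L, cds_prefix_codons = P,
                cryptic_ag_offsets = d,
                truncation_stop = ts, retention_stop = rs,
                seed = seed)
}

# brute-force AG enumeration: the scanner's independent oracle
brute_force_ag <- function(seq, from, to) {
  seq <- toupper(seq)
  hits <- integer(0)
  for (i in from:(to - 1)) {
    if (substr(seq, i, i + 1) == "AG") hits <- c(hits, i)
  }
  hits
}

# literal translation walk: residue count before the first stop, read straight
# off an mRNA string (independent of the package's bookkeeping formula)
walk_protein_length <- function(mrna, cds_start = 0) {
  s <- substr(mrna, cds_start + 1, nchar(mrna))
  stops <- c("TAA", "TAG", "TGA")
  n <- 0L
  for (i in seq(1, nchar(s) - 2, by = 3)) {
    if (substr(s, i, i + 2) %in% stops) return(n)
    n <- n + 1L
  }
  NA_integer_
}

# the variant string for a toy gene built from a given spec
toy_variant <- function(spec) sprintf("c.%d-1G>A", 3L * spec$cds_prefix_codons + 1L)
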