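#' The shipped 3' acceptor position-weight matrix
#'
#' A 16-position nucleotide frequency table describing the metazoan 3' splice
#' acceptor: positions 1-8 cover the polypyrimidine tract (T/C rich, with the
#' -3 position strongly C), positions 9-10 the essentially invariant AG, and
#' positions 11-16 the first exonic bases (G favoured at +1). Scores from
#' [score_acceptor()] are consensus-value style on a 0-100 scale: a window
#' matching the per-position modal nucleotides scores exactly 100.
#'
#' The table is self-consistent rather than a reproduction of any external
#' tool's matrix; published tool scores (HSF, MaxEnt, SpliceAI, NetGene2) are
#' treated as inputs to the delta arithmetic, never recomputed.
#'
#' @return An object of class `acceptor_pwm`: a list with `window_length`
#'   (16), `ag_offset` (9: the A of the invariant AG), `exon_start` (11),
#'   `weights` (16 x 4 matrix, columns A/C/G/T, rows summing to 1) and
#'   `scale`.
#' @examples
#' pwm <- acceptor_pwm()
#' score_acceptor(pwm, "TTAATTTTAGGTTGCA")
#' @export
acceptor_pwm <- function() {
  ppt  <- c(A = 0.07, C = 0.31, G = 0.07, T = 0.55)
  m3   <- c(A = 0.05, C = 0.64, G = 0.01, T = 0.30)
  invA <- c(A = 0.994, C = 0.002, G = 0.002, T = 0.002)
  invG <- c(A = 0.002, C = 0.002, G = 0.994, T = 0.002)
  ex1  <- c(A = 0.25, C = 0.14, G = 0.50, T = 0.11)
  exn  <- c(A = 0.30, C = 0.22, G = 0.26, T = 0.22)
  w <- rbind(ppt, ppt, ppt, ppt, ppt, ppt, ppt, m3, invA, invG,
             ex1, exn, exn, exn, exn, exn)
  dimnames(w) <- list(NULL, c("A", "C", "G", "T"))
  stopifnot(all(abs(rowSums(w) - 1) < 1e-9))
  structure(list(window_length = 16L, ag_offset = 9L, exon_start = 11L,
                 weights = w, scale = "cv-0-100"),
            class = "acceptor_pwm")
}

#' Score acceptor windows against a position-weight matrix
#'
#' The raw score is the summed log frequency of the window's bases; it is
#' rescaled so that the per-position modal window scores 100 and the
#' anti-modal window 0. Rescaling is monotone, so mutating any position away
#' from its modal nucleotide never increases the score.
#'
#' @param pwm An [acceptor_pwm()] (or compatible list).
#' @param window Character vector of windows, each `pwm$window_length` long,
#'   A/C/G/T only (case-insensitive). Ambiguity codes are rejected.
#' @return Numeric vector of scores on the 0-100 scale.
#' @export
score_acceptor <- function(pwm, window) {
  window <- str_to_upper(window)
  if (any(nchar(window) != pwm$window_length)) {
    abort(sprintf("windows must be exactly %d nt long", pwm$window_length))
  }
  if (any(grepl("[^ACGT]", window))) {
    abort("unsupported alphabet: windows must contain only A/C/G/T")
  }
  lw <- log(pwm$weights)
  smax <- sum(apply(lw, 1, max))
  smin <- sum(apply(lw, 1, min))
  vapply(window, function(x) {
    bases <- strsplit(x, "")[[1]]
    s <- sum(lw[cbind(seq_along(bases), match(bases, colnames(lw)))])
    100 * (s - smin) / (smax - smin)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Percent change between wild-type and mutant splice-site scores
#'
#' The delta-consensus-value convention: `100 * (mut - wt) / abs(wt)`. The
#' absolute value in the denominator keeps the sign interpretable for negative
#' baselines (a free-range log-odds score of -2.15 rising to 5.8 is +369.77%,
#' a gain). Values are returned unrounded; round only at presentation.
#'
#' @param wt_score,mut_score Numeric vectors (recycled), wild-type and mutant
#'   scores. `wt_score` must be non-zero.
#' @return Numeric vector of percent changes.
#' @examples
#' percent_change(86.74, 58.87) # -32.13
#' percent_change(10.35, 1.6)   # -84.54
#' percent_change(-2.15, 5.8)   # +369.77
#' @export
percent_change <- function(wt_score, mut_score) {
  if (any(wt_score == 0)) {
    abort("undefined baseline: wt_score must be non-zero")
  }
  100 * (mut_score - wt_score) / abs(wt_score)
}

#' Call site loss / maintenance / gain from a score delta
#'
#' @param percent_change Numeric vector from [percent_change()].
#' @param loss_threshold Negative percent at or below which a canonical site
#'   is called lost (default -10).
#' @param gain_threshold Positive percent at or above which a non-canonical
#'   site is called gained (default +10).
#' @param canonical Logical (recycled): is the scored position the canonical
#'   acceptor? Gains are only called at non-canonical positions.
#' @return Character vector: "site_loss", "site_maintained" or
#'   "new_site_gain".
#' @export
call_site <- function(percent_change, loss_threshold = -10, gain_threshold = 10,
                      canonical = TRUE) {
  stopifnot(loss_threshold < 0, gain_threshold > 0)
  n <- length(percent_change)
  canonical <- rep_len(canonical, n)
  dplyr::case_when(
    percent_change <= loss_threshold ~ "site_loss",
    percent_change >= gain_threshold & !canonical ~ "new_site_gain",
    .default = "site_maintained"
  )
}

#' Build a splice-delta record (scores, percent change, call)
#'
#' The container for wild-type/mutant score pairs, whether the scores come
#' from the shipped PWM or from an external prediction tool's printed output.
#'
#' @inheritParams call_site
#' @param wt_score,mut_score Scores before and after the variant.
#' @return Tibble with `wt_score`, `mut_score`, `percent_change`, `call`.
#' @examples
#' splice_delta(86.74, 58.87)                    # canonical site lost
#' splice_delta(-2.15, 5.8, canonical = FALSE)   # new site gained
#' @export
splice_delta <- function(wt_score, mut_score, canonical = TRUE,
                         loss_threshold = -10, gain_threshold = 10) {
  pc <- percent_change(wt_score, mut_score)
  tibble(wt_score = wt_score, mut_score = mut_score, percent_change = pc,
         call = call_site(pc, loss_threshold, gain_threshold, canonical))
}

#' Enumerate and score AG dinucleotides in a sequence window
#'
#' Finds every AG whose A falls inside `[from, to - 1]` of `seq`, scores each
#' with the 16-nt context placing the AG at the matrix's invariant positions,
#' and sorts by score (descending), breaking ties by proximity to
#' `canonical_g` (nearest first). Contexts truncated by the sequence ends get
#' `NA` scores and sort last.
#'
#' @param seq A single nucleotide string.
#' @param from,to 1-based inclusive bounds of the search window within `seq`.
#'   An empty window returns an empty tibble.
#' @param pwm An [acceptor_pwm()].
#' @param canonical_g Position used for tie-breaking distance (defaults to
#'   `to`).
#' @return Tibble: `a_pos`, `g_pos`, `context`, `score`.
#' @export
scan_cryptic_acceptors <- function(seq, from, to, pwm = acceptor_pwm(),
                                   canonical_g = to) {
  stopifnot(length(seq) == 1)
  seq <- str_to_upper(seq)
  n <- nchar(seq)
  if (from < 1 || to > n) abort("search window outside sequence bounds")
  if (from > to - 1) {
    return(tibble(a_pos = integer(0), g_pos = integer(0),
                  context = character(0), score = numeric(0)))
  }
  chars <- strsplit(seq, "")[[1]]
  a_pos <- which(chars[from:(to - 1)] == "A" & chars[(from + 1):to] == "G") + from - 1L
  if (!length(a_pos)) {
    return(tibble(a_pos = integer(0), g_pos = integer(0),
                  context = character(0), score = numeric(0)))
  }
  g_pos <- a_pos + 1L
  lead <- pwm$ag_offset - 1L                 # bases of context before the A
  trail <- pwm$window_length - pwm$ag_offset - 1L  # bases after the G
  ctx_from <- g_pos - lead - 1L
  ctx_to <- g_pos + trail
  ok <- ctx_from >= 1 & ctx_to <= n
  context <- rep(NA_character_, length(a_pos))
  if (any(ok)) context[ok] <- substring(seq, ctx_from[ok], ctx_to[ok])
  score <- rep(NA_real_, length(a_pos))
  if (any(ok)) score[ok] <- score_acceptor(pwm, context[ok])
  out <- tibble(a_pos = a_pos, g_pos = g_pos, context = context, score = score)
  out[order(-ifelse(is.na(out$score), -Inf, out$score),
            abs(out$g_pos - canonical_g)), ]
}

#' Scan a gene's mutated acceptor region for candidate splice sites
#'
#' Builds the sequence around the disrupted 3' acceptor (the full upstream
#' intron, with the variant applied in mutant context, followed by the
#' downstream exon), scans the configured window (`intron_window` nt into the
#' intron plus `exon_window` nt into the exon) for AG dinucleotides, and
#' annotates each site with its relation to the canonical junction:
#' `retained` intronic bases for intronic AGs, `exon_g_index` for AGs whose G
#' lies in the exon (including the junction-spanning AG a substitution can
#' create from the mutated intron-terminal base plus an exon-initial G).
#'
#' In wild-type context, AGs overlapping the canonical AG dinucleotide are
#' reported (provenance "canonical") but flagged as non-candidates for
#' new-site calls; in mutant context every AG is a candidate.
#'
#' @param gene A `gene_model`.
#' @param variant HGVS c. string or parsed variant; must be an acceptor-region
#'   substitution (intron offset -1 or -2) for mutant context.
#' @param context "mutant" (default) or "wt".
#' @param intron_window,exon_window Scan extents in nt (defaults 100 and 25).
#' @param pwm An [acceptor_pwm()].
#' @return Tibble of class `acceptor_sites`: `location` ("intron"/"exon"),
#'   `retained`, `exon_g_index`, `context`, `score`, `provenance`,
#'   `candidate`, ordered by score then proximity to the canonical junction.
#' @examples
#' g <- mshlike_gene()
#' scan_acceptors(g, "c.793-1G>A")
#' @export
scan_acceptors <- function(gene, variant, context = c("mutant", "wt"),
                           intron_window = 100L, exon_window = 25L,
                           pwm = acceptor_pwm()) {
  context <- match.arg(context)
  if (is.character(variant)) variant <- parse_hgvs_c(variant)
  coord <- resolve_variant(gene, variant)
  if (coord$region != "intron") {
    abort("variant does not disrupt a 3' acceptor (expected intron offset -1 or -2)",
          class = "splicetriage_not_acceptor")
  }
  i <- coord$region_index
  L <- gene$length[gene$role == "intron"][i]
  if ((L - 1L - coord$offset) > 1L) {  # offset is 0-based; last base has offset L-1
    abort("variant does not disrupt a 3' acceptor (expected intron offset -1 or -2)",
          class = "splicetriage_not_acceptor")
  }
  intron <- intron_seqs(gene)[i]
  exon <- exon_seqs(gene)[i + 1L]
  if (context == "mutant") {
    if (variant$kind != "substitution") abort("only substitutions supported in mutant context")
    substr(intron, coord$offset + 1L, coord$offset + 1L) <- variant$alt
  }
  full <- paste0(intron, exon)
  w_i <- min(intron_window, L)
  w_e <- min(exon_window, nchar(exon))
  sites <- scan_cryptic_acceptors(full, from = L - w_i + 1L, to = L + w_e,
                                  pwm = pwm, canonical_g = L)
  sites$location <- ifelse(sites$g_pos <= L, "intron", "exon")
  sites$retained <- ifelse(sites$location == "intron", L - sites$g_pos, NA_integer_)
  sites$exon_g_index <- ifelse(sites$location == "exon", sites$g_pos - L, NA_integer_)
  sites$provenance <- ifelse(!is.na(sites$retained) & sites$retained == 0,
                             "canonical", "cryptic")
  sites$candidate <- if (context == "wt") {
    !(sites$a_pos %in% c(L - 1L, L) | sites$g_pos %in% c(L - 1L, L))
  } else rep(TRUE, nrow(sites))
  structure(
    select(sites, "location", "retained", "exon_g_index", "a_pos", "g_pos",
           "context", "score", "provenance", "candidate"),
    class = c("acceptor_sites", class(tibble())),
    intron_index = i, intron_length = L, variant = variant$hgvs,
    scan_context = context
  )
}
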