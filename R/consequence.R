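#' Reconstruct aberrant transcripts implied by acceptor loss
#'
#' Given a disrupted 3' acceptor and the candidate cryptic sites found by
#' [scan_acceptors()], builds one aberrant isoform per site: an AG whose G
#' lies inside the downstream exon yields an exon truncation (the exon loses
#' its first bases up to and including the G's position); an AG inside the
#' intron yields an intron retention (all intronic bases 3' of the AG stay in
#' the mRNA, carrying the variant base where applicable). Optionally an exon
#' skip of the downstream exon is appended. Isoforms keep the sites' score
#' ranking.
#'
#' @param gene A `gene_model`.
#' @param variant HGVS c. string or parsed variant; must be an acceptor
#'   disruption (intron offset -1 or -2).
#' @param sites Tibble from [scan_acceptors()] (mutant context). Non-candidate
#'   and canonical-position rows are ignored.
#' @param include_skip Append an exon-skip isoform (default `FALSE`).
#' @return Tibble of class `aberrant_transcripts`: `kind`, `nt_delta`,
#'   `cdna_hgvs`, `junction_desc`, `score`, `mrna`, and a `junctions`
#'   list-column holding each isoform's exon-exon junction positions
#'   (1-based transcript coordinates).
#' @examples
#' g <- mshlike_gene()
#' enumerate_outcomes(g, "c.793-1G>A", scan_acceptors(g, "c.793-1G>A"))
#' @export
enumerate_outcomes <- function(gene, variant, sites, include_skip = FALSE) {
  if (is.character(variant)) variant <- parse_hgvs_c(variant)
  coord <- resolve_variant(gene, variant)
  i <- coord$region_index
  L <- gene$length[gene$role == "intron"][i]
  if (coord$region != "intron" || (L - 1L - coord$offset) > 1L) {
    abort("variant is not an acceptor disruption (intron offset -1 or -2)",
          class = "splicetriage_not_acceptor")
  }
  t_ex <- i + 1L                      # downstream exon index
  exons <- exon_seqs(gene)
  elens <- nchar(exons)
  cds_first <- variant$cds_base       # first CDS base of the downstream exon
  mut_intron <- intron_seqs(gene)[i]
  if (variant$kind == "substitution") {
    substr(mut_intron, coord$offset + 1L, coord$offset + 1L) <- variant$alt
  }

  use <- sites[sites$candidate & sites$provenance != "canonical", , drop = FALSE]
  rows <- pmap(use, function(location, retained, exon_g_index, score, ...) {
    if (location == "exon") {
      k <- exon_g_index
      if (k >= elens[t_ex]) return(NULL)
      new_exons <- exons
      new_exons[t_ex] <- substr(exons[t_ex], k + 1L, elens[t_ex])
      hgvs <- if (k == 1L) sprintf("c.%ddel", cds_first) else
        sprintf("c.%d_%ddel", cds_first, cds_first + k - 1L)
      tibble(kind = "exon_truncation", nt_delta = -k, cdna_hgvs = hgvs,
             score = score,
             mrna = paste(new_exons, collapse = ""),
             blocks = list(new_exons))
    } else {
      d <- retained
      if (d <= 0L) return(NULL)
      insert <- substr(mut_intron, L - d + 1L, L)
      new_exons <- exons
      new_exons[t_ex] <- paste0(insert, exons[t_ex])
      hgvs <- sprintf("c.%d_%dins%d", cds_first - 1L, cds_first, d)
      tibble(kind = "intron_retention", nt_delta = d, cdna_hgvs = hgvs,
             score = score,
             mrna = paste(new_exons, collapse = ""),
             blocks = list(new_exons))
    }
  })
  out <- bind_rows(rows)
  if (include_skip) {
    new_exons <- exons[-t_ex]
    hgvs <- sprintf("c.%d_%ddel", cds_first, cds_first + elens[t_ex] - 1L)
    out <- bind_rows(out, tibble(
      kind = "exon_skip", nt_delta = -elens[t_ex], cdna_hgvs = hgvs,
      score = NA_real_,
      mrna = paste(new_exons, collapse = ""),
      blocks = list(new_exons)))
  }
  if (!nrow(out)) {
    out <- tibble(kind = character(0), nt_delta = integer(0),
                  cdna_hgvs = character(0), score = numeric(0),
                  mrna = character(0), blocks = list())
  }
  out$nt_delta <- as.integer(out$nt_delta)
  out$junctions <- map(out$blocks, function(b) {
    len <- nchar(b)
    if (length(len) < 2) integer(0) else as.integer(cumsum(len)[-length(len)])
  })
  out$junction_desc <- map_chr(out$blocks, function(b) {
    if (length(b) < 2) return("single-exon")
    k <- 8L
    j <- max(2L, min(length(b), t_ex))  # junction 5' of the altered block
    paste0("...", str_sub(b[j - 1L], -k), "|", str_sub(b[j], 1L, k), "...")
  })
  out$blocks <- NULL
  structure(out[, c("kind", "nt_delta", "cdna_hgvs", "junction_desc",
                    "score", "mrna", "junctions")],
            class = c("aberrant_transcripts", class(tibble())),
            variant = variant$hgvs, target_exon = t_ex,
            normal_mrna = spliced_mrna(gene))
}

#' Truncated-protein length from HGVS frameshift bookkeeping
#'
#' Under the fs*N convention the first changed residue counts as position 1
#' and the new-frame stop sits at position N, so the truncated protein is
#' `first_codon + N - 2` residues long (the stop itself is not counted):
#' Val265...fs*9 gives 272 aa, Val265...fs*15 gives 278 aa.
#'
#' @param first_codon 1-based codon index of the first changed residue.
#' @param stop_offset_n The N of fs*N (>= 2; N = 1 is a plain nonsense
#'   substitution, handled separately).
#' @return Integer amino-acid count.
#' @examples
#' truncated_length(265, 9)   # 272
#' truncated_length(265, 15)  # 278
#' @export
truncated_length <- function(first_codon, stop_offset_n) {
  if (any(first_codon < 1) || any(stop_offset_n < 1)) {
    abort("first_codon and stop_offset_n must be positive")
  }
  as.integer(first_codon + stop_offset_n - 2L)
}

#' Predict nonsense-mediated decay for a premature termination codon
#'
#' The classic boundary rule: an mRNA is an NMD substrate when its PTC lies
#' more than `boundary` nucleotides (default 50) upstream of the final
#' exon-exon junction. Single-exon transcripts are never substrates.
#'
#' @param ptc_codon 1-based codon index of the stop in the aberrant reading.
#' @param junctions Integer vector of exon-exon junction positions (1-based
#'   transcript coordinates of the last base of each non-terminal exon).
#' @param cds_start 0-based CDS offset within the transcript.
#' @param boundary Distance rule in nt (default 50).
#' @return Logical.
#' @export
predict_nmd <- function(ptc_codon, junctions, cds_start = 0L, boundary = 50L) {
  if (length(junctions) < 1) return(FALSE)
  ptc_start <- cds_start + 3L * (ptc_codon - 1L) + 1L
  (max(junctions) - ptc_start) > boundary
}

#' Translate aberrant transcripts to their premature termination codons
#'
#' Translates each isoform from c.1 in the standard genetic code, locates the
#' first residue differing from the normal protein, and walks the new reading
#' to its first stop. Frameshifts (and stop-containing insertions) are
#' rendered as `p.<Ref><pos><Alt>fs*<N>`; an alternate codon that is itself a
#' stop gives nonsense `p.<Ref><pos>*`; an unchanged protein gives `p.(=)`.
#' If no stop occurs before the transcript end the isoform is flagged
#' `no_ptc` (an extension), not an error.
#'
#' @param gene The `gene_model` the transcripts came from.
#' @param transcripts Tibble from [enumerate_outcomes()].
#' @param nmd_boundary Passed to [predict_nmd()].
#' @return `transcripts` with appended columns `first_codon`, `ref_aa`,
#'   `alt_aa`, `stop_offset_n`, `truncated_length`, `hgvs_p`, `frameshift`,
#'   `no_ptc`, `nmd_predicted`.
#' @examples
#' g <- mshlike_gene()
#' s <- scan_acceptors(g, "c.793-1G>A")
#' translate_to_ptc(g, enumerate_outcomes(g, "c.793-1G>A", s))
#' @export
translate_to_ptc <- function(gene, transcripts, nmd_boundary = 50L) {
  cds_start <- attr(gene, "cds_start")
  normal <- translate_nt(substr(spliced_mrna(gene), cds_start + 1L, nchar(spliced_mrna(gene))))
  n_stop <- which(normal == "Ter")[1]

  res <- pmap(transcripts[, c("mrna", "nt_delta", "junctions")],
              function(mrna, nt_delta, junctions) {
    if (substr(mrna, cds_start + 1L, cds_start + 3L) != "ATG") {
      abort("aberrant transcript CDS does not begin with the model's start codon")
    }
    aa <- translate_nt(substr(mrna, cds_start + 1L, nchar(mrna)))
    shared <- min(length(aa), length(normal))
    diff <- which(aa[seq_len(shared)] != normal[seq_len(shared)])
    f <- if (length(diff)) diff[1] else NA_integer_
    if (is.na(f) && nt_delta == 0L) {
      return(tibble(first_codon = NA_integer_, ref_aa = NA_character_,
                    alt_aa = NA_character_, stop_offset_n = NA_integer_,
                    truncated_length = as.integer(n_stop - 1L),
                    hgvs_p = "p.(=)", frameshift = FALSE, no_ptc = FALSE,
                    nmd_predicted = FALSE))
    }
    if (is.na(f)) f <- shared + 1L   # divergence past the shared prefix
    ref_aa <- if (f <= length(normal)) normal[f] else NA_character_
    alt_aa <- if (f <= length(aa)) aa[f] else NA_character_
    if (identical(alt_aa, "Ter")) {
      return(tibble(first_codon = f, ref_aa = ref_aa, alt_aa = "Ter",
                    stop_offset_n = 1L, truncated_length = f - 1L,
                    hgvs_p = sprintf("p.%s%d*", ref_aa, f),
                    frameshift = FALSE, no_ptc = FALSE,
                    nmd_predicted = predict_nmd(f, junctions, cds_start, nmd_boundary)))
    }
    # clean in-frame events realign downstream and carry no fs*N; an in-frame
    # insertion whose inserted block contains a stop falls through to the
    # PTC path below (that is how a 51-nt retention truncates the protein)
    if (nt_delta != 0L && nt_delta %% 3L == 0L) {
      k <- abs(nt_delta) %/% 3L
      if (nt_delta > 0L && f > 1L &&
          !"Ter" %in% aa[f:(f + k - 1L)] &&
          identical(aa[(f + k):(n_stop + k)], normal[f:n_stop])) {
        return(tibble(first_codon = f, ref_aa = ref_aa, alt_aa = alt_aa,
                      stop_offset_n = NA_integer_, truncated_length = NA_integer_,
                      hgvs_p = sprintf("p.%s%d_%s%dins%d",
                                       normal[f - 1L], f - 1L, normal[f], f, k),
                      frameshift = FALSE, no_ptc = FALSE, nmd_predicted = FALSE))
      }
      if (nt_delta < 0L && n_stop - k >= f &&
          identical(aa[f:(n_stop - k)], normal[(f + k):n_stop])) {
        return(tibble(first_codon = f, ref_aa = ref_aa, alt_aa = alt_aa,
                      stop_offset_n = NA_integer_, truncated_length = NA_integer_,
                      hgvs_p = sprintf("p.%s%d_%s%ddel",
                                       normal[f], f, normal[f + k - 1L], f + k - 1L),
                      frameshift = FALSE, no_ptc = FALSE, nmd_predicted = FALSE))
      }
    }
    stop_at <- which(aa == "Ter")
    stop_at <- stop_at[stop_at >= f][1]
    fs <- (nt_delta %% 3L) != 0L
    if (is.na(stop_at)) {
      return(tibble(first_codon = f, ref_aa = ref_aa, alt_aa = alt_aa,
                    stop_offset_n = NA_integer_,
                    truncated_length = NA_integer_,
                    hgvs_p = sprintf("p.%s%d%sfs*?", ref_aa, f, alt_aa),
                    frameshift = fs, no_ptc = TRUE, nmd_predicted = FALSE))
    }
    n_off <- stop_at - f + 1L
    tibble(first_codon = f, ref_aa = ref_aa, alt_aa = alt_aa,
           stop_offset_n = as.integer(n_off),
           truncated_length = truncated_length(f, n_off),
           hgvs_p = sprintf("p.%s%d%sfs*%d", ref_aa, f, alt_aa, n_off),
           frameshift = fs, no_ptc = FALSE,
           nmd_predicted = predict_nmd(stop_at, junctions, cds_start, nmd_boundary))
  })
  dplyr::bind_cols(transcripts, bind_rows(res))
}
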