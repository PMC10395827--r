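#' Pipeline configuration
#'
#' Collects every tunable threshold in one place. Defaults: cryptic scan 100
#' nt into the intron and 25 nt into the exon; loss/gain calls at -10%/+10%;
#' the 50-nt NMD boundary; MSI-H at 40% unstable markers; a 160-nt transcribed
#' minigene flank.
#'
#' @param intron_window,exon_window Cryptic-acceptor scan extents (nt).
#' @param loss_threshold,gain_threshold Percent-change call cutoffs.
#' @param nmd_boundary NMD distance rule (nt).
#' @param msi_h_threshold MSI-H fraction.
#' @param flank_total Transcribed vector flank for minigene bands (nt).
#' @param include_skip Include an exon-skip isoform.
#' @param spectrum Lynch-spectrum cancer labels for Amsterdam II.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(intron_window = 100L, exon_window = 25L,
                            loss_threshold = -10, gain_threshold = 10,
                            nmd_boundary = 50L, msi_h_threshold = 0.40,
                            flank_total = 160L, include_skip = FALSE,
                            spectrum = c("colorectal", "endometrial",
                                         "small bowel", "ureter", "renal pelvis")) {
  stopifnot(intron_window > 0, exon_window >= 0,
            loss_threshold < 0, gain_threshold > 0,
            nmd_boundary >= 0, msi_h_threshold > 0, msi_h_threshold <= 1,
            flank_total >= 0)
  structure(list(intron_window = as.integer(intron_window),
                 exon_window = as.integer(exon_window),
                 loss_threshold = loss_threshold,
                 gain_threshold = gain_threshold,
                 nmd_boundary = as.integer(nmd_boundary),
                 msi_h_threshold = msi_h_threshold,
                 flank_total = as.integer(flank_total),
                 include_skip = isTRUE(include_skip),
                 spectrum = spectrum),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration (lossless JSON round-trip)
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `read_config()` returns a `pipeline_config`.
#' @name config-io
NULL

#' @rdname config-io
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname config-io
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x)
}

#' Run the full splice-consequence pipeline on one variant
#'
#' The end-to-end flow: resolve the variant against the gene model (with
#' reference check), score the canonical acceptor window before and after the
#' variant and call loss/maintenance, scan the mutant context for cryptic
#' acceptors, reconstruct the implied aberrant transcripts, translate each to
#' its PTC with an NMD call, and predict the minigene RT-PCR band table. If
#' the variant does not disrupt an acceptor the report stops after scoring
#' with a note. Clinical inputs (MSI marker calls, IHC patterns, a pedigree)
#' are evaluated when supplied. Deterministic given its inputs.
#'
#' @param gene A `gene_model`.
#' @param variant HGVS c. string or parsed variant.
#' @param config A [pipeline_config()].
#' @param pwm An [acceptor_pwm()].
#' @param msi,ihc,pedigree Optional clinical inputs (see [classify_msi()],
#'   [infer_mmr_gene()], [amsterdam_ii()]).
#' @return A list of class `splice_report`: `variant`, `delta`, `sites`,
#'   `transcripts`, `bands`, `clinical`, `note`, `config`.
#' @examples
#' rep <- run_pipeline(mshlike_gene(), "c.793-1G>A")
#' tidy(rep)
#' @export
run_pipeline <- function(gene, variant, config = pipeline_config(),
                         pwm = acceptor_pwm(), msi = NULL, ihc = NULL,
                         pedigree = NULL) {
  if (is.character(variant)) variant <- parse_hgvs_c(variant)
  coord <- resolve_variant(gene, variant)   # ref check happens here

  clinical <- list()
  if (!is.null(msi)) {
    clinical$msi <- classify_msi(msi, h_threshold = config$msi_h_threshold)
  }
  if (!is.null(ihc)) clinical$mmr_gene <- infer_mmr_gene(ihc)
  if (!is.null(pedigree)) {
    clinical$amsterdam <- amsterdam_ii(pedigree, spectrum = config$spectrum)
  }

  acceptor <- coord$region == "intron" &&
    coord$offset >= gene$length[gene$role == "intron"][coord$region_index] - 2L
  if (!acceptor) {
    return(structure(list(
      variant = variant, delta = NULL, sites = NULL, transcripts = NULL,
      bands = NULL, clinical = clinical,
      note = "not an acceptor variant; stopped after coordinate resolution",
      config = config), class = "splice_report"))
  }

  i <- coord$region_index
  L <- gene$length[gene$role == "intron"][i]
  intron <- intron_seqs(gene)[i]
  exon <- exon_seqs(gene)[i + 1L]
  lead <- pwm$ag_offset + 1L   # intronic bases in the canonical window
  wt_window <- paste0(str_sub(intron, -(pwm$ag_offset + 1L)),
                      str_sub(exon, 1L, pwm$window_length - pwm$ag_offset - 1L))
  mut_intron <- intron
  substr(mut_intron, coord$offset + 1L, coord$offset + 1L) <- variant$alt
  mut_window <- paste0(str_sub(mut_intron, -(pwm$ag_offset + 1L)),
                       str_sub(exon, 1L, pwm$window_length - pwm$ag_offset - 1L))
  delta <- splice_delta(score_acceptor(pwm, wt_window),
                        score_acceptor(pwm, mut_window),
                        canonical = TRUE,
                        loss_threshold = config$loss_threshold,
                        gain_threshold = config$gain_threshold)
  delta$wt_window <- wt_window
  delta$mut_window <- mut_window

  sites <- scan_acceptors(gene, variant, context = "mutant",
                          intron_window = config$intron_window,
                          exon_window = config$exon_window, pwm = pwm)
  transcripts <- enumerate_outcomes(gene, variant, sites,
                                    include_skip = config$include_skip)
  transcripts <- translate_to_ptc(gene, transcripts,
                                  nmd_boundary = config$nmd_boundary)
  construct <- construct_from_gene(gene, i, flank_total = config$flank_total)
  bands <- rtpcr_size(construct, transcripts)

  structure(list(variant = variant, delta = delta, sites = sites,
                 transcripts = transcripts, bands = bands,
                 clinical = clinical, note = NULL, config = config),
            class = "splice_report")
}

#' @export
print.splice_report <- function(x, ...) {
  cat(sprintf("<splice_report> %s\n", x$variant$hgvs))
  if (!is.null(x$note)) {
    cat("  note:", x$note, "\n")
  }
  if (!is.null(x$delta)) {
    cat(sprintf("  canonical acceptor: %.2f -> %.2f (%+.2f%%), %s\n",
                x$delta$wt_score, x$delta$mut_score,
                x$delta$percent_change, x$delta$call))
  }
  if (!is.null(x$transcripts) && nrow(x$transcripts)) {
    cat(sprintf("  %d aberrant isoform(s):\n", nrow(x$transcripts)))
    for (j in seq_len(nrow(x$transcripts))) {
      t <- x$transcripts[j, ]
      cat(sprintf("    %-16s %+4d nt  %-18s %-22s %s aa%s\n",
                  t$kind, t$nt_delta, t$cdna_hgvs, t$hgvs_p,
                  ifelse(is.na(t$truncated_length), "?", t$truncated_length),
                  ifelse(isTRUE(t$nmd_predicted), "  [NMD]", "")))
    }
  }
  if (!is.null(x$bands)) {
    cat("  predicted RT-PCR bands:",
        paste(sprintf("%s=%d bp", x$bands$band_label, x$bands$size_bp),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy an end-to-end splice report
#'
#' One row per reconstructed isoform with its cDNA and protein nomenclature,
#' consequence bookkeeping and predicted band size.
#'
#' @param x A `splice_report`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy splice_report
#' @export
tidy.splice_report <- function(x, ...) {
  if (is.null(x$transcripts) || !nrow(x$transcripts)) {
    return(tibble(kind = character(0)))
  }
  out <- select(x$transcripts, "kind", "nt_delta", "cdna_hgvs", "hgvs_p",
                "first_codon", "ref_aa", "alt_aa", "stop_offset_n",
                "truncated_length", "frameshift", "no_ptc", "nmd_predicted",
                "score")
  if (!is.null(x$bands)) {
    out <- left_join(out,
                     select(x$bands, "isoform_kind", "nt_delta", "size_bp",
                            "band_label"),
                     by = c(kind = "isoform_kind", nt_delta = "nt_delta"))
  }
  as_tibble(out)
}

#' Summarise a splice report in one row
#'
#' @param x A `splice_report`.
#' @param ... Unused.
#' @return One-row tibble: variant, canonical-site call and percent change,
#'   isoform count, and whether any isoform is an NMD substrate.
#' @method glance splice_report
#' @export
glance.splice_report <- function(x, ...) {
  tibble(variant = x$variant$hgvs,
         acceptor_call = if (is.null(x$delta)) NA_character_ else x$delta$call,
         percent_change = if (is.null(x$delta)) NA_real_ else x$delta$percent_change,
         n_isoforms = if (is.null(x$transcripts)) 0L else nrow(x$transcripts),
         any_nmd = if (is.null(x$transcripts)) FALSE else
           any(x$transcripts$nmd_predicted, na.rm = TRUE),
         note = x$note %||% NA_character_)
}
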