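#' Assemble a minigene construct from a segment table
#'
#' Minigene splicing assays clone selected exons and intron fragments between
#' vector flanks; RT-PCR products then read out the splice pattern as band
#' sizes. This builds the construct bookkeeping: the insert length is the sum
#' of the non-vector segments, and `flank_total` is the transcribed
#' vector-derived length that every RT-PCR product carries (the motivating
#' construct: exon 147 + intron part 1708 + exon 150 = 2005 bp insert, 160 bp
#' of flank, 457 bp wild-type product).
#'
#' @param segments Data frame with columns `label`, `role` (one of "exon",
#'   "intron_part", "vector_flank"), `length` (nt, > 0) and optionally `seq`.
#' @param flank_total Transcribed vector length contributing to RT-PCR
#'   products, in nt. Defaults to all-5' (`flank_split = c(flank_total, 0)`);
#'   only the total affects band sizes.
#' @param flank_split Optional 5'/3' split of `flank_total` (length-2).
#' @param cloning_sites Pair of restriction-site labels, carried as metadata.
#' @return The segment tibble with class `minigene_construct` and attributes
#'   `insert_length`, `flank_total`, `flank_split`, `cloning_sites`.
#' @examples
#' minigene_assemble(tibble::tibble(
#'   label = c("exon4", "intron4_part", "exon5"),
#'   role = c("exon", "intron_part", "exon"),
#'   length = c(147, 1708, 150)), flank_total = 160)
#' @export
minigene_assemble <- function(segments, flank_total = 0L,
                              flank_split = c(flank_total, 0L),
                              cloning_sites = c("XhoI", "EcoRI")) {
  segments <- as_tibble(segments)
  if (!nrow(segments)) abort("a construct needs at least one segment")
  if (!all(c("label", "role", "length") %in% names(segments))) {
    abort("`segments` needs columns label, role, length")
  }
  if (!all(segments$role %in% c("exon", "intron_part", "vector_flank"))) {
    abort("segment roles must be exon, intron_part or vector_flank")
  }
  if (any(segments$length <= 0)) abort("segment lengths must be positive")
  if (!"seq" %in% names(segments)) segments$seq <- NA_character_
  has_seq <- !is.na(segments$seq)
  segments$seq[has_seq] <- str_to_upper(segments$seq[has_seq])
  if (any(has_seq & nchar(segments$seq) != segments$length, na.rm = TRUE)) {
    abort("segment `length` disagrees with its stored sequence")
  }
  if (sum(flank_split) != flank_total) abort("flank_split must sum to flank_total")
  structure(segments,
            class = c("minigene_construct", class(tibble())),
            insert_length = as.integer(sum(segments$length[segments$role != "vector_flank"])),
            flank_total = as.integer(flank_total),
            flank_split = as.integer(flank_split),
            cloning_sites = cloning_sites)
}

#' Insert length of a minigene construct
#' @param construct A [minigene_assemble()] result.
#' @return Integer nt.
#' @export
insert_length <- function(construct) attr(construct, "insert_length")

#' Predict RT-PCR band sizes for minigene isoforms
#'
#' The wild-type product is `flank_total` plus the construct's exonic
#' nucleotides; each aberrant isoform's product differs from wild type by
#' exactly its `nt_delta`. Bands are labelled a, b, c, ... in row order,
#' wild type first.
#'
#' @param construct A [minigene_assemble()] result.
#' @param transcripts Optional tibble from [enumerate_outcomes()] (needs
#'   `kind` and `nt_delta`); `NULL` gives the wild-type band alone.
#' @return Tibble of class `rtpcr_bands`: `band_label`, `isoform_kind`,
#'   `nt_delta`, `size_bp`; attribute `target_bp` holds the exonic (insert
#'   target) portion of the wild-type product.
#' @examples
#' cons <- minigene_assemble(tibble::tibble(
#'   label = c("exon4", "intron4_part", "exon5"),
#'   role = c("exon", "intron_part", "exon"),
#'   length = c(147, 1708, 150)), flank_total = 160)
#' rtpcr_size(cons)  # 457 bp
#' @export
rtpcr_size <- function(construct, transcripts = NULL) {
  exonic <- sum(construct$length[construct$role == "exon"])
  wt <- attr(construct, "flank_total") + exonic
  out <- tibble(band_label = "a", isoform_kind = "normal",
                nt_delta = 0L, size_bp = as.integer(wt))
  if (!is.null(transcripts) && nrow(transcripts)) {
    if (any(abs(transcripts$nt_delta) > insert_length(construct))) {
      abort("isoform does not fit this construct (|nt_delta| exceeds the insert)",
            class = "splicetriage_model_mismatch")
    }
    out <- bind_rows(out, tibble(
      band_label = letters[1L + seq_len(nrow(transcripts))],
      isoform_kind = transcripts$kind,
      nt_delta = transcripts$nt_delta,
      size_bp = as.integer(wt + transcripts$nt_delta)))
  }
  structure(out, class = c("rtpcr_bands", class(tibble())),
            target_bp = as.integer(exonic))
}

#' Junction k-mers for Sanger verification of minigene products
#'
#' Returns the sequence spanning each splice junction of an isoform (k nt
#' each side), for primer design and Sanger read checking. Supports
#' constructs with a single intron part: the wild-type isoform splices it
#' out; a truncation trims the first `|nt_delta|` bases of the downstream
#' exon; a retention keeps the last `nt_delta` intronic bases attached to it;
#' a skip drops the downstream exon. `k` longer than a block is trimmed with
#' a warning.
#'
#' @param construct A [minigene_assemble()] result with sequences for all
#'   non-vector segments.
#' @param isoform `NULL` (wild type) or a one-row tibble with `kind` and
#'   `nt_delta`.
#' @param k Nucleotides per side (default 8).
#' @return Tibble: `junction`, `left_label`, `right_label`, `kmer`.
#' @export
junction_strings <- function(construct, isoform = NULL, k = 8L) {
  ins <- construct[construct$role != "vector_flank", , drop = FALSE]
  if (any(is.na(ins$seq))) abort("junction_strings needs sequences for all insert segments")
  n_int <- sum(ins$role == "intron_part")
  if (n_int > 1) abort("junction_strings supports single-intron constructs")

  labels <- ins$label[ins$role == "exon"]
  blocks <- ins$seq[ins$role == "exon"]
  if (!is.null(isoform)) {
    stopifnot(nrow(isoform) == 1)
    i_int <- which(ins$role == "intron_part")
    down <- sum(ins$role[seq_len(i_int)] == "exon") + 1L  # exon after the intron
    kind <- isoform$kind
    if (kind == "exon_truncation") {
      blocks[down] <- substr(blocks[down], abs(isoform$nt_delta) + 1L, nchar(blocks[down]))
    } else if (kind == "intron_retention") {
      intr <- ins$seq[i_int]
      blocks[down] <- paste0(str_sub(intr, -isoform$nt_delta), blocks[down])
      labels[down] <- paste0("retained+", labels[down])
    } else if (kind == "exon_skip") {
      blocks <- blocks[-down]
      labels <- labels[-down]
    } else if (kind != "normal") {
      abort(sprintf("unsupported isoform kind: %s", kind))
    }
  }
  if (length(blocks) < 2) {
    return(tibble(junction = integer(0), left_label = character(0),
                  right_label = character(0), kmer = character(0)))
  }
  kk <- pmin(k, nchar(blocks))
  if (any(kk < k)) warn("k exceeds a block length; junction strings trimmed")
  n <- length(blocks) - 1L
  tibble(junction = seq_len(n),
         left_label = labels[seq_len(n)],
         right_label = labels[seq_len(n) + 1L],
         kmer = paste0(str_sub(blocks[seq_len(n)], -kk[seq_len(n)]),
                       str_sub(blocks[seq_len(n) + 1L], 1L, kk[seq_len(n) + 1L])))
}

#' Build the minigene construct implied by a gene model's studied junction
#'
#' Convenience wrapper: takes the exon, intron and exon around a disrupted
#' acceptor and assembles them into a construct (the exon-trapping design of
#' a splicing minigene), with the given transcribed flank.
#'
#' @param gene A `gene_model`.
#' @param intron_index Intron whose acceptor is under study.
#' @param flank_total Transcribed vector flank (default 160 nt).
#' @return A `minigene_construct`.
#' @export
construct_from_gene <- function(gene, intron_index, flank_total = 160L) {
  ex <- exon_seqs(gene); intr <- intron_seqs(gene)
  i <- intron_index
  minigene_assemble(tibble(
    label = c(paste0("exon", i), paste0("intron", i, "_part"), paste0("exon", i + 1L)),
    role = c("exon", "intron_part", "exon"),
    length = nchar(c(ex[i], intr[i], ex[i + 1L])),
    seq = unname(c(ex[i], intr[i], ex[i + 1L]))),
    flank_total = flank_total)
}
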