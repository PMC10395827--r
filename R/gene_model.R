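#' Build a coding gene model from a segment table
#'
#' A gene model is the coordinate authority for the whole pipeline: an ordered
#' run of exon and intron segments with their sequences, plus the offset of the
#' CDS start (c.1) within the spliced transcript. All internal coordinates are
#' 0-based half-open; HGVS-facing functions convert at the surface, and only in
#' this file.
#'
#' @param segments Data frame with columns `role` ("exon"/"intron"), `index`
#'   (1-based within its role) and `seq` (A/C/G/T, any case). Rows must
#'   alternate exon, intron, exon, ... beginning and ending with an exon, in
#'   transcript (5'->3') order. An optional `length` column is checked against
#'   `nchar(seq)`.
#' @param name,chrom Gene / chromosome labels.
#' @param strand Strand; only `"+"` is supported. Minus-strand models are
#'   rejected rather than silently reverse-complemented.
#' @param cds_start 0-based offset of c.1 within the spliced transcript.
#' @param validate_orf If `TRUE`, require the CDS to begin with ATG and to
#'   contain an in-frame stop codon.
#' @return A tibble of segments with class `gene_model` and attributes
#'   `gene_name`, `chrom`, `strand`, `cds_start`.
#' @examples
#' g <- gene_model(
#'   tibble::tibble(
#'     role = c("exon", "intron", "exon"),
#'     index = c(1L, 1L, 2L),
#'     seq = c("ATGGTT", "GTTTTTTTTTTTTAG", "CCTTAA")
#'   ),
#'   name = "toy"
#' )
#' spliced_mrna(g)
#' @export
gene_model <- function(segments, name = "gene", chrom = "chrN", strand = "+",
                       cds_start = 0L, validate_orf = TRUE) {
  segments <- as_tibble(segments)
  if (!all(c("role", "index", "seq") %in% names(segments))) {
    abort("`segments` needs columns role, index, seq")
  }
  if (!identical(strand, "+")) {
    abort("only plus-strand gene models are supported; reverse-complement the input explicitly")
  }
  segments$seq <- str_to_upper(segments$seq)
  bad <- grepl("[^ACGT]", segments$seq)
  if (any(bad)) {
    abort(paste0("non-ACGT characters in segment ", which(bad)[1]))
  }
  if ("length" %in% names(segments)) {
    if (!all(segments$length == nchar(segments$seq))) {
      abort("segment `length` disagrees with its stored sequence")
    }
  }
  segments$length <- nchar(segments$seq)
  n <- nrow(segments)
  expected_roles <- rep(c("exon", "intron"), length.out = n)
  if (n %% 2 == 0 || !all(segments$role == expected_roles)) {
    abort("segments must alternate exon/intron and begin and end with an exon")
  }
  expected_index <- ifelse(segments$role == "exon",
                           cumsum(segments$role == "exon"),
                           cumsum(segments$role == "intron"))
  if (!all(segments$index == expected_index)) {
    abort("segment `index` must count 1,2,... within each role, in transcript order")
  }
  segments <- segments[, c("role", "index", "length", "seq")]

  mrna <- paste(segments$seq[segments$role == "exon"], collapse = "")
  cds_start <- as.integer(cds_start)
  if (cds_start < 0 || nchar(mrna) - cds_start < 3) {
    abort("CDS must be at least 3 nt long within the spliced transcript")
  }
  if (validate_orf) {
    cds <- substr(mrna, cds_start + 1L, nchar(mrna))
    if (substr(cds, 1, 3) != "ATG") {
      abort("CDS does not begin with a start codon (ATG); set validate_orf = FALSE to override")
    }
    prot <- translate_nt(cds)
    if (!any(prot == "Ter")) {
      abort("CDS has no in-frame stop codon; set validate_orf = FALSE to override")
    }
  }
  structure(segments,
            class = c("gene_model", class(tibble())),
            gene_name = name, chrom = chrom, strand = strand,
            cds_start = cds_start)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s, %s strand), %d exons, CDS offset %d\n",
              attr(x, "gene_name"), attr(x, "chrom"), attr(x, "strand"),
              sum(x$role == "exon"), attr(x, "cds_start")))
  NextMethod()
}

#' Gene model accessors
#'
#' Small helpers around a [gene_model()]: per-role sequences, the spliced
#' mRNA, and the transcript coordinates of exon boundaries.
#'
#' @param gene A `gene_model`.
#' @return `exon_seqs()`/`intron_seqs()` return named character vectors;
#'   `spliced_mrna()` a single string; `exon_junctions()` the 1-based
#'   transcript positions of the last nucleotide of each exon except the last
#'   (i.e. the exon-exon junction positions of the mature mRNA).
#' @name gene-accessors
NULL

#' @rdname gene-accessors
#' @export
exon_seqs <- function(gene) {
  stats::setNames(gene$seq[gene$role == "exon"],
                  paste0("exon", gene$index[gene$role == "exon"]))
}

#' @rdname gene-accessors
#' @export
intron_seqs <- function(gene) {
  stats::setNames(gene$seq[gene$role == "intron"],
                  paste0("intron", gene$index[gene$role == "intron"]))
}

#' @rdname gene-accessors
#' @export
spliced_mrna <- function(gene) {
  paste(gene$seq[gene$role == "exon"], collapse = "")
}

#' @rdname gene-accessors
#' @export
exon_junctions <- function(gene) {
  len <- gene$length[gene$role == "exon"]
  if (length(len) < 2) return(integer(0))
  cumsum(len)[-length(len)]
}

# 1-based transcript position -> (exon index, 1-based offset within exon)
transcript_to_exon <- function(gene, tpos) {
  len <- gene$length[gene$role == "exon"]
  ends <- cumsum(len)
  if (tpos < 1 || tpos > ends[length(ends)]) {
    abort(sprintf("transcript position %d outside transcript (1..%d)", tpos, ends[length(ends)]))
  }
  e <- which(tpos <= ends)[1]
  list(exon = e, offset = tpos - c(0L, ends)[e])
}

#' Convert a CDS position to codon index and phase
#'
#' Standard 1-based codon numbering from c.1: `codon_index = ceiling(base/3)`,
#' `phase = ((base - 1) %% 3) + 1`. c.793 lies in codon 265, phase 1.
#'
#' @param cds_base Positive integer vector of CDS nucleotide positions.
#' @return Tibble with `cds_base`, `codon_index`, `phase`.
#' @examples
#' cds_to_codon(c(793, 1, 792))
#' @export
cds_to_codon <- function(cds_base) {
  if (!length(cds_base) || any(!is.finite(cds_base)) || any(cds_base < 1) ||
      any(cds_base != floor(cds_base))) {
    abort("cds_base must be positive integers")
  }
  cds_base <- as.integer(cds_base)
  tibble(cds_base = cds_base,
         codon_index = as.integer(ceiling(cds_base / 3)),
         phase = as.integer((cds_base - 1L) %% 3L + 1L))
}

#' Resolve an HGVS c. variant against a gene model
#'
#' Maps a parsed variant (see [parse_hgvs_c()]) to a concrete segment
#' coordinate. Intronic offsets are anchored at the adjacent exon boundary:
#' `c.793-1` resolves to the final base of the intron preceding the exon whose
#' first CDS base is 793. The reference base is checked here against the model.
#'
#' @param gene A `gene_model`.
#' @param variant One-row tibble from [parse_hgvs_c()], or an HGVS c. string.
#' @return One-row tibble: `region` ("exon"/"intron"), `region_index`,
#'   `offset` (0-based within the segment), `codon_index` and `phase` (NA for
#'   intronic positions), `tpos` (1-based transcript position of the anchor
#'   exonic base).
#' @examples
#' g <- mshlike_gene()
#' resolve_variant(g, "c.793-1G>A")
#' @export
resolve_variant <- function(gene, variant) {
  if (is.character(variant)) variant <- parse_hgvs_c(variant)
  stopifnot(nrow(variant) == 1)
  cds_start <- attr(gene, "cds_start")
  tpos <- cds_start + variant$cds_base
  loc <- transcript_to_exon(gene, tpos)
  e <- loc$exon
  elen <- gene$length[gene$role == "exon"][e]
  off <- variant$intron_offset
  ilens <- gene$length[gene$role == "intron"]

  if (off == 0) {
    base <- substr(exon_seqs(gene)[e], loc$offset, loc$offset)
    if (!is.na(variant$ref) && base != variant$ref) {
      abort(sprintf("reference mismatch at c.%d: model has %s, variant says %s",
                    variant$cds_base, base, variant$ref),
            class = "splicetriage_ref_mismatch")
    }
    cod <- cds_to_codon(variant$cds_base)
    return(tibble(region = "exon", region_index = e, offset = loc$offset - 1L,
                  codon_index = cod$codon_index, phase = cod$phase, tpos = tpos))
  }

  if (off < 0) {
    if (loc$offset != 1 || e < 2) {
      abort(sprintf("c.%d%+d: negative offsets require the first CDS base of an exon with an upstream intron",
                    variant$cds_base, off), class = "splicetriage_coord_error")
    }
    i <- e - 1L
    L <- ilens[i]
    pos <- L + off + 1L  # -1 -> last intron base
    if (pos < 1) {
      abort(sprintf("c.%d%+d walks past the 5' end of intron %d (length %d)",
                    variant$cds_base, off, i, L), class = "splicetriage_coord_error")
    }
  } else {
    if (loc$offset != elen || e > sum(gene$role == "intron")) {
      abort(sprintf("c.%d%+d: positive offsets require the last CDS base of an exon with a downstream intron",
                    variant$cds_base, off), class = "splicetriage_coord_error")
    }
    i <- e
    L <- ilens[i]
    pos <- off
    if (pos > L) {
      abort(sprintf("c.%d%+d walks past the 3' end of intron %d (length %d)",
                    variant$cds_base, off, i, L), class = "splicetriage_coord_error")
    }
  }
  base <- substr(intron_seqs(gene)[i], pos, pos)
  if (!is.na(variant$ref) && base != variant$ref) {
    abort(sprintf("reference mismatch at c.%d%+d: model has %s, variant says %s",
                  variant$cds_base, off, base, variant$ref),
          class = "splicetriage_ref_mismatch")
  }
  tibble(region = "intron", region_index = i, offset = pos - 1L,
         codon_index = NA_integer_, phase = NA_integer_, tpos = tpos)
}

#' Convert a resolved coordinate back to HGVS c. anchors
#'
#' Inverse of [resolve_variant()] for positions at or near exon boundaries.
#' Intronic positions in the 5' half of an intron are reported as `+` offsets
#' from the upstream exon's last CDS base; positions in the 3' half as `-`
#' offsets from the downstream exon's first CDS base.
#'
#' @param gene A `gene_model`.
#' @param region "exon" or "intron".
#' @param region_index 1-based segment index within its role.
#' @param offset 0-based offset within the segment.
#' @return One-row tibble with `cds_base` and `intron_offset`.
#' @export
coordinate_to_hgvs <- function(gene, region, region_index, offset) {
  cds_start <- attr(gene, "cds_start")
  elens <- gene$length[gene$role == "exon"]
  ends <- cumsum(elens)
  if (region == "exon") {
    tpos <- c(0L, ends)[region_index] + offset + 1L
    return(tibble(cds_base = as.integer(tpos - cds_start), intron_offset = 0L))
  }
  L <- gene$length[gene$role == "intron"][region_index]
  pos1 <- offset + 1L
  if (pos1 <= ceiling(L / 2)) {
    cds_base <- ends[region_index] - cds_start           # last base of upstream exon
    tibble(cds_base = as.integer(cds_base), intron_offset = as.integer(pos1))
  } else {
    cds_base <- ends[region_index] + 1L - cds_start      # first base of downstream exon
    tibble(cds_base = as.integer(cds_base), intron_offset = as.integer(pos1 - L - 1L))
  }
}

# translate an uppercase nt string into 3-letter residues, through the end of
# the last complete codon; does NOT stop at Ter (callers walk the result)
translate_nt <- function(seq) {
  n <- nchar(seq) %/% 3
  if (n == 0) return(character(0))
  codons <- substring(seq, 3 * seq_len(n) - 2, 3 * seq_len(n))
  unname(GENETIC_CODE_3[codons])
}
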