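#' Read and write FASTA sequence files
#'
#' Thin wrappers over Biostrings with the package's conventions: sequences
#' are uppercase-normalised on read and strictly A/C/G/T (a record containing
#' anything else is rejected with the offending record and position); writes
#' wrap at 60 columns. An empty file reads as an empty set with a warning.
#'
#' @param path File path.
#' @param x Named character vector of sequences.
#' @return `read_fasta()` returns a named character vector.
#' @name fasta-io
NULL

#' @rdname fasta-io
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  if (file.size(path) == 0) {
    warn(sprintf("empty FASTA file: %s", path))
    return(stats::setNames(character(0), character(0)))
  }
  ss <- Biostrings::readBStringSet(path)
  seqs <- stats::setNames(toupper(as.character(ss)), names(ss))
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGT]", seqs[i])
    if (bad > 0) {
      abort(sprintf("non-ACGT character in record '%s' at position %d",
                    names(seqs)[i], bad))
    }
  }
  seqs
}

#' @rdname fasta-io
#' @export
write_fasta <- function(x, path) {
  stopifnot(is.character(x), !is.null(names(x)))
  ss <- Biostrings::DNAStringSet(toupper(x))
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Read and write the gene-model segment format
#'
#' A plain TSV dialect: `#key=value` header lines carry the model metadata
#' (`name`, `chrom`, `strand`, `cds_start`), followed by a header row and one
#' row per segment with columns `role`, `index`, `length`, `seq`.
#'
#' @param gene A `gene_model`.
#' @param path File path.
#' @return `read_gene_model()` returns a `gene_model`.
#' @name gene-model-io
NULL

#' @rdname gene-model-io
#' @export
write_gene_model <- function(gene, path) {
  hdr <- sprintf("#%s=%s",
                 c("name", "chrom", "strand", "cds_start"),
                 c(attr(gene, "gene_name"), attr(gene, "chrom"),
                   attr(gene, "strand"), attr(gene, "cds_start")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(gene)[, c("role", "index", "length", "seq")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname gene-model-io
#' @export
read_gene_model <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- str_match(hdr, "^#([a-z_]+)=(.*)$")
  meta <- stats::setNames(kv[, 3], kv[, 2])
  body <- utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  gene_model(body, name = meta[["name"]], chrom = meta[["chrom"]],
             strand = meta[["strand"]],
             cds_start = as.integer(meta[["cds_start"]]))
}

#' Map a minimal VCF record to an HGVS c. variant through a gene model
#'
#' Reads CHROM/POS/REF/ALT from a VCF (via vcfR) and converts plus-strand
#' SNVs to HGVS c. notation using the gene model's genomic anchor: `tx_start`
#' is the 1-based genomic position of the model's first transcribed base, and
#' segments are assumed contiguous from there. Only single-nucleotide
#' substitutions are accepted.
#'
#' @param gene A `gene_model`.
#' @param vcf_path Path to an (uncompressed) VCF file.
#' @param tx_start Genomic position of the model's first base.
#' @return Tibble of parsed variants (one row per record) as from
#'   [parse_hgvs_c()], with a `genomic_pos` column.
#' @export
variant_from_vcf <- function(gene, vcf_path, tx_start = 1L) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("VCF input requires the vcfR package")
  }
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) {   # single-record files come back as a named vector
    fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  }
  fx <- as_tibble(as.data.frame(fx, stringsAsFactors = FALSE))
  if (any(nchar(fx$REF) != 1 | nchar(fx$ALT) != 1)) {
    abort("only single-nucleotide substitutions are supported from VCF")
  }
  # genomic offset within the unspliced gene body
  seg_ends <- cumsum(gene$length)
  cds_start <- attr(gene, "cds_start")
  elens <- gene$length[gene$role == "exon"]
  e_t_ends <- cumsum(elens)
  out <- map(seq_len(nrow(fx)), function(j) {
    gpos <- as.integer(fx$POS[j]) - tx_start + 1L
    if (gpos < 1 || gpos > seg_ends[length(seg_ends)]) {
      abort(sprintf("VCF position %s outside the gene model", fx$POS[j]))
    }
    k <- which(gpos <= seg_ends)[1]
    off0 <- gpos - c(0L, seg_ends)[k] - 1L
    anchor <- coordinate_to_hgvs(gene, gene$role[k], gene$index[k], off0)
    hgvs <- if (anchor$intron_offset == 0) {
      sprintf("c.%d%s>%s", anchor$cds_base, fx$REF[j], fx$ALT[j])
    } else {
      sprintf("c.%d%+d%s>%s", anchor$cds_base, anchor$intron_offset,
              fx$REF[j], fx$ALT[j])
    }
    mutate(parse_hgvs_c(hgvs), genomic_pos = as.integer(fx$POS[j]))
  })
  bind_rows(out)
}
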