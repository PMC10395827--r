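#' Parse the HGVS c. subset used for splice-variant work
#'
#' Supports substitutions with optional intronic offsets (`c.793-1G>A`,
#' `c.1A>G`), single-base and range deletions (`c.793del`, `c.793_942del`),
#' and insertions given either as an explicit sequence or as a length
#' (`c.792_793insACGT`, `c.792_793ins51`, and the looser `ins51bp` dialect).
#' Anything outside this subset (duplications, inversions, delins, genomic
#' `g.` notation, UTR positions) raises an "unsupported nomenclature" error
#' rather than a silent misparse.
#'
#' @param text A single HGVS c. string.
#' @return One-row tibble: `hgvs`, `kind` ("substitution"/"deletion"/
#'   "insertion"), `cds_base`, `intron_offset`, `cds_end` (range deletions),
#'   `ref`, `alt`, `ins_len`, `ins_seq`.
#' @examples
#' parse_hgvs_c("c.793-1G>A")
#' parse_hgvs_c("c.792_793ins51bp")
#' @export
parse_hgvs_c <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  txt <- trimws(text)
  unsupported <- function() {
    abort(sprintf("unsupported nomenclature: %s", txt),
          class = "splicetriage_unsupported_hgvs")
  }
  if (!startsWith(txt, "c.")) unsupported()
  if (grepl("dup|inv|delins|con|ext|\\[|c\\.[-*]", txt)) unsupported()

  m <- str_match(txt, "^c\\.(\\d+)([+-]\\d+)?([ACGT])>([ACGT])$")
  if (!is.na(m[1, 1])) {
    return(tibble(hgvs = txt, kind = "substitution",
                  cds_base = as.integer(m[1, 2]),
                  intron_offset = ifelse(is.na(m[1, 3]), 0L, as.integer(m[1, 3])),
                  cds_end = NA_integer_,
                  ref = m[1, 4], alt = m[1, 5],
                  ins_len = NA_integer_, ins_seq = NA_character_))
  }
  m <- str_match(txt, "^c\\.(\\d+)(?:_(\\d+))?del$")
  if (!is.na(m[1, 1])) {
    from <- as.integer(m[1, 2])
    to <- ifelse(is.na(m[1, 3]), from, as.integer(m[1, 3]))
    if (to < from) unsupported()
    return(tibble(hgvs = txt, kind = "deletion", cds_base = from,
                  intron_offset = 0L, cds_end = as.integer(to),
                  ref = NA_character_, alt = NA_character_,
                  ins_len = NA_integer_, ins_seq = NA_character_))
  }
  m <- str_match(txt, "^c\\.(\\d+)_(\\d+)ins([ACGT]+|\\d+(?:bp)?)$")
  if (!is.na(m[1, 1])) {
    from <- as.integer(m[1, 2]); to <- as.integer(m[1, 3])
    if (to != from + 1L) unsupported()
    payload <- m[1, 4]
    if (grepl("^\\d", payload)) {
      len <- as.integer(sub("bp$", "", payload))
      seq <- NA_character_
    } else {
      len <- nchar(payload)
      seq <- payload
    }
    return(tibble(hgvs = txt, kind = "insertion", cds_base = from,
                  intron_offset = 0L, cds_end = to,
                  ref = NA_character_, alt = NA_character_,
                  ins_len = len, ins_seq = seq))
  }
  unsupported()
}

#' Parse HGVS p. frameshift / nonsense / silent descriptions
#'
#' Accepts `p.Val265Leufs*9` (frameshift: first changed residue plus the
#' new-frame stop offset N), `p.Val265*` (nonsense), and `p.(=)` (silent), in
#' either plain or parenthesised predicted form.
#'
#' @param text A single HGVS p. string.
#' @return One-row tibble: `hgvs`, `kind` ("frameshift"/"nonsense"/"silent"),
#'   `first_codon`, `ref_aa`, `alt_aa`, `fs_n`.
#' @examples
#' parse_hgvs_p("p.Val265Leufs*9")
#' @export
parse_hgvs_p <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  txt <- trimws(text)
  if (txt %in% c("p.(=)", "p.=")) {
    return(tibble(hgvs = txt, kind = "silent", first_codon = NA_integer_,
                  ref_aa = NA_character_, alt_aa = NA_character_,
                  fs_n = NA_integer_))
  }
  m <- str_match(txt, "^p\\.\\(?([A-Z][a-z]{2})(\\d+)([A-Z][a-z]{2})fs\\*(\\d+)\\)?$")
  if (!is.na(m[1, 1])) {
    return(tibble(hgvs = txt, kind = "frameshift",
                  first_codon = as.integer(m[1, 3]),
                  ref_aa = m[1, 2], alt_aa = m[1, 4],
                  fs_n = as.integer(m[1, 5])))
  }
  m <- str_match(txt, "^p\\.\\(?([A-Z][a-z]{2})(\\d+)\\*\\)?$")
  if (!is.na(m[1, 1])) {
    return(tibble(hgvs = txt, kind = "nonsense",
                  first_codon = as.integer(m[1, 3]),
                  ref_aa = m[1, 2], alt_aa = "Ter", fs_n = 1L))
  }
  abort(sprintf("unsupported nomenclature: %s", txt),
        class = "splicetriage_unsupported_hgvs")
}
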