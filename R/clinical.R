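#' Classify microsatellite instability from a marker panel
#'
#' The NCI reference panel is two mononucleotide repeats (BAT25, BAT26) and
#' three dinucleotide repeats (D2S123, D5S346, D17S250). A tumour is MSI-H
#' when at least `h_threshold` (default 40%) of markers are unstable; any
#' instability below that is MSI-L (the Bethesda convention; the source study
#' only defines the MSI-H cutoff) and none is MSS.
#'
#' @param calls Data frame with columns `marker` and `status`
#'   ("stable"/"unstable"). Markers outside the NCI panel are counted but
#'   flagged with a warning.
#' @param h_threshold Unstable fraction at or above which the class is MSI-H.
#' @param l_threshold Fraction above which (exclusive) the class is at least
#'   MSI-L; default 0.
#' @return One-row tibble: `n_markers`, `n_unstable`, `fraction_unstable`,
#'   `msi_class`.
#' @examples
#' classify_msi(tibble::tibble(
#'   marker = c("BAT25", "BAT26", "D2S123", "D5S346", "D17S250"),
#'   status = c("unstable", "unstable", "stable", "stable", "stable")))
#' @export
classify_msi <- function(calls, h_threshold = 0.40, l_threshold = 0) {
  calls <- as_tibble(calls)
  if (!nrow(calls)) abort("at least one marker call is required")
  if (!all(c("marker", "status") %in% names(calls))) {
    abort("`calls` needs columns marker and status")
  }
  if (!all(calls$status %in% c("stable", "unstable"))) {
    abort("marker status must be 'stable' or 'unstable'")
  }
  panel <- c("BAT25", "BAT26", "D2S123", "D5S346", "D17S250")
  unknown <- setdiff(unique(calls$marker), panel)
  if (length(unknown)) {
    warn(sprintf("markers outside the NCI panel (still counted): %s",
                 paste(unknown, collapse = ", ")))
  }
  n <- nrow(calls)
  u <- sum(calls$status == "unstable")
  frac <- u / n
  cls <- if (frac >= h_threshold) "MSI-H" else if (frac > l_threshold) "MSI-L" else "MSS"
  tibble(n_markers = n, n_unstable = u, fraction_unstable = frac,
         msi_class = cls)
}

#' Infer the mutated mismatch-repair gene from an IHC loss pattern
#'
#' MSH2 dimerises with MSH6 and MLH1 with PMS2, and each heterodimer is
#' stabilised by its obligate partner (MSH2, MLH1). Loss patterns therefore
#' implicate: MSH2 lost (with or without MSH6) -> MSH2; MSH6 lost alone ->
#' MSH6; MLH1 lost (with or without PMS2) -> MLH1; PMS2 lost alone -> PMS2.
#' When both dimer axes show loss, candidates are ranked by the number of
#' lost proteins in each axis (ties: axis with its obligate partner lost
#' first, then alphabetical). All four retained returns zero rows.
#'
#' @param pattern Data frame with columns `protein` (MLH1, MSH2, MSH6, PMS2 -
#'   all four required) and `status` ("retained"/"lost"), or a named character
#'   vector.
#' @return Tibble: `gene`, `rank` (possibly zero rows).
#' @examples
#' infer_mmr_gene(c(MLH1 = "retained", MSH2 = "lost",
#'                  MSH6 = "lost", PMS2 = "retained"))  # MSH2
#' @export
infer_mmr_gene <- function(pattern) {
  if (is.character(pattern) && !is.null(names(pattern))) {
    pattern <- tibble(protein = names(pattern), status = unname(pattern))
  }
  pattern <- as_tibble(pattern)
  req <- c("MLH1", "MSH2", "MSH6", "PMS2")
  if (!all(req %in% pattern$protein) || !all(pattern$protein %in% req)) {
    abort("pattern must cover exactly MLH1, MSH2, MSH6, PMS2")
  }
  if (!all(pattern$status %in% c("retained", "lost"))) {
    abort("protein status must be 'retained' or 'lost'")
  }
  lost <- pattern$protein[pattern$status == "lost"]
  cand <- list()
  if ("MSH2" %in% lost) {
    cand <- c(cand, list(c(gene = "MSH2", n = sum(c("MSH2", "MSH6") %in% lost), obligate = 1)))
  } else if ("MSH6" %in% lost) {
    cand <- c(cand, list(c(gene = "MSH6", n = 1, obligate = 0)))
  }
  if ("MLH1" %in% lost) {
    cand <- c(cand, list(c(gene = "MLH1", n = sum(c("MLH1", "PMS2") %in% lost), obligate = 1)))
  } else if ("PMS2" %in% lost) {
    cand <- c(cand, list(c(gene = "PMS2", n = 1, obligate = 0)))
  }
  if (!length(cand)) return(tibble(gene = character(0), rank = integer(0)))
  d <- tibble(gene = map_chr(cand, ~ .x[["gene"]]),
              n = as.integer(map_chr(cand, ~ .x[["n"]])),
              obligate = as.integer(map_chr(cand, ~ .x[["obligate"]])))
  d <- d[order(-d$n, -d$obligate, d$gene), ]
  tibble(gene = d$gene, rank = seq_len(nrow(d)))
}

#' Evaluate the Amsterdam II criteria on a pedigree
#'
#' Amsterdam II requires: at least three relatives with a Lynch-spectrum
#' cancer, one of them a first-degree relative of the other two; disease in
#' at least two successive generations; at least one diagnosis before age 50;
#' familial adenomatous polyposis excluded; and pathological verification of
#' tumours. The last two are attestations supplied by the caller, not
#' computed. First-degree relationships (parent-child, siblings sharing a
#' parent) and generation depth are derived from the parent links; if the
#' relative-trio test fails while some affected members lack parent
#' information, the criterion is marked indeterminate and the pedigree "not
#' evaluable" rather than failed.
#'
#' @param pedigree Data frame, one row per diagnosis (unaffected members may
#'   appear with `cancer = NA`): columns `id`, `father`, `mother` (NA
#'   allowed), `cancer`, `age_dx`.
#' @param spectrum Lynch-spectrum cancer labels (default colorectal,
#'   endometrial, small bowel, ureter, renal pelvis).
#' @param age_cutoff Age threshold for the early-onset criterion (default 50).
#' @param fap_excluded,pathology_verified Attestations (default `TRUE`).
#' @return One-row tibble: the five sub-criteria, `evaluable`, and `met`.
#' @examples
#' amsterdam_ii(make_clinical_fixtures(1)$pedigree)
#' @export
amsterdam_ii <- function(pedigree,
                         spectrum = c("colorectal", "endometrial",
                                      "small bowel", "ureter", "renal pelvis"),
                         age_cutoff = 50,
                         fap_excluded = TRUE, pathology_verified = TRUE) {
  ped <- as_tibble(pedigree)
  need <- c("id", "father", "mother", "cancer", "age_dx")
  if (!all(need %in% names(ped))) {
    abort(paste("pedigree needs columns", paste(need, collapse = ", ")))
  }
  if (any(!is.na(ped$age_dx) & ped$age_dx <= 0)) abort("ages must be positive")
  people <- dplyr::distinct(ped, .data$id, .data$father, .data$mother)
  if (anyDuplicated(people$id)) {
    abort("conflicting parent links: each id must have one father/mother pair")
  }
  affected <- unique(ped$id[!is.na(ped$cancer) & ped$cancer %in% spectrum])

  parent_of <- function(a, b) {  # is a a parent of b?
    pb <- people[people$id == b, ]
    isTRUE(a %in% c(pb$father, pb$mother))
  }
  first_degree <- function(a, b) {
    if (a == b) return(FALSE)
    if (parent_of(a, b) || parent_of(b, a)) return(TRUE)
    pa <- people[people$id == a, ]; pb <- people[people$id == b, ]
    shared <- intersect(stats::na.omit(c(pa$father, pa$mother)),
                        stats::na.omit(c(pb$father, pb$mother)))
    length(shared) > 0
  }

  trio <- FALSE
  if (length(affected) >= 3) {
    for (a in affected) {
      fd <- vapply(setdiff(affected, a), function(b) first_degree(a, b), logical(1))
      if (sum(fd) >= 2) { trio <- TRUE; break }
    }
  }
  missing_links <- any(vapply(affected, function(a) {
    p <- people[people$id == a, ]
    is.na(p$father) && is.na(p$mother) && !any(people$father %in% a | people$mother %in% a)
  }, logical(1)))
  trio_state <- if (trio) "met" else if (missing_links) "indeterminate" else "unmet"

  # generation depth from founders via parent links
  depth <- stats::setNames(rep(NA_integer_, nrow(people)), people$id)
  changed <- TRUE; iter <- 0L
  depth[is.na(people$father) & is.na(people$mother)] <- 0L
  while (changed && iter < nrow(people) + 1L) {
    changed <- FALSE; iter <- iter + 1L
    for (j in seq_len(nrow(people))) {
      if (!is.na(depth[people$id[j]])) next
      pd <- depth[stats::na.omit(c(people$father[j], people$mother[j]))]
      if (length(pd) && all(!is.na(pd))) {
        depth[people$id[j]] <- max(pd) + 1L; changed <- TRUE
      }
    }
  }
  if (any(is.na(depth))) abort("parent links are cyclic or dangling")
  gens <- sort(unique(depth[affected]))
  two_gen <- length(gens) >= 2 && any(diff(gens) == 1)

  under_50 <- any(!is.na(ped$cancer) & ped$cancer %in% spectrum &
                    !is.na(ped$age_dx) & ped$age_dx < age_cutoff)

  evaluable <- trio_state != "indeterminate"
  met <- evaluable && trio_state == "met" && two_gen && under_50 &&
    isTRUE(fap_excluded) && isTRUE(pathology_verified)
  tibble(three_affected_first_degree = trio_state,
         two_successive_generations = two_gen,
         diagnosis_before_50 = under_50,
         fap_excluded = isTRUE(fap_excluded),
         pathology_verified = isTRUE(pathology_verified),
         evaluable = evaluable, met = met)
}
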