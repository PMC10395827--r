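#' Specify a toy gene for the splice-consequence pipeline
#'
#' A toy gene emulates the structure the pipeline assumes around a studied 3'
#' acceptor: a CDS prefix of `cds_prefix_codons` full codons upstream of the
#' target exon (so the variant position c.(3*prefix+1)-1 is the disrupted
#' acceptor), a target exon beginning GTTGCA (a Val codon at the junction, so
#' the junction-spanning AG created by the G>A substitution yields a 1-bp
#' truncation with a Val->Leu first changed residue), a cryptic AG planted in
#' the upstream intron at each `cryptic_ag_offsets` distance (retained
#' nucleotides when used), and stop codons engineered so the truncation and
#' retention readings terminate at prescribed new-frame codons. The defaults
#' reproduce the MSH2-like case: 264-codon prefix, exon lengths
#' 210/210/225/147/150/300, a 1,708-nt studied intron, a cryptic AG at 51 nt,
#' and new-frame stops at 9 (truncation) and 15 (retention).
#'
#' @param exon_lengths,intron_lengths Segment lengths, 5'->3'.
#' @param target_exon Index of the exon whose acceptor is studied.
#' @param cds_prefix_codons Complete codons upstream of the target exon; the
#'   exon lengths before `target_exon` must sum to three times this.
#' @param cryptic_ag_offsets Retained-length offsets (nt from the intron 3'
#'   end) at which cryptic AGs are planted; each must sit inside the scan
#'   window and clear of the 10-nt acceptor context.
#' @param truncation_stop,retention_stop New-frame codon indices where the
#'   first stop is engineered for the 1-bp truncation and each retention
#'   scenario (`retention_stop` recycled over `cryptic_ag_offsets`).
#' @param intron_window,exon_window Scan extents the gene is audited against.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return A list of class `toy_gene_spec`.
#' @export
toy_gene_spec <- function(exon_lengths = c(210L, 210L, 225L, 147L, 150L, 300L),
                          intron_lengths = c(200L, 200L, 200L, 1708L, 200L),
                          target_exon = 5L,
                          cds_prefix_codons = 264L,
                          cryptic_ag_offsets = 51L,
                          truncation_stop = 9L,
                          retention_stop = 15L,
                          intron_window = 100L, exon_window = 25L,
                          seed = 17L) {
  stopifnot(length(intron_lengths) == length(exon_lengths) - 1L,
            all(exon_lengths > 0), all(intron_lengths > 0),
            target_exon >= 2L, target_exon <= length(exon_lengths))
  if (sum(exon_lengths[seq_len(target_exon - 1L)]) != 3L * cds_prefix_codons) {
    abort("exon lengths upstream of target_exon must sum to 3 * cds_prefix_codons")
  }
  L <- intron_lengths[target_exon - 1L]
  if (any(cryptic_ag_offsets < 12L) ||
      any(cryptic_ag_offsets > min(intron_window - 2L, L - 12L))) {
    abort("cryptic AG offsets must lie within the scan window and clear of the acceptor context")
  }
  if (exon_lengths[target_exon] < 3L * truncation_stop + 2L) {
    abort("target exon too short for the requested truncation stop")
  }
  if (truncation_stop < 3L) {
    abort("truncation stops below new-frame codon 3 overlap the fixed GTTGCA junction motif")
  }
  if (any(retention_stop < 2L)) {
    abort("retention stop must be >= 2 (codon 1 is the fixed AAT)")
  }
  rs <- rep_len(retention_stop, length(cryptic_ag_offsets))
  d <- cryptic_ag_offsets
  # a retention stop is plantable in the intron background (clear of the
  # 10-nt acceptor context), or it can be one of the stops the ttaattttag
  # context itself supplies when the retained length is a codon multiple
  # (TAA at codon (d-6)/3, TAG at codon d/3)
  natural <- d %% 3L == 0L & (3L * rs == d - 6L | 3L * rs == d)
  if (any(!(3L * rs <= d - 10L | natural))) {
    abort("retention stop not plantable: need 3*stop <= offset-10, or a codon-multiple offset with the stop the acceptor context provides")
  }
  structure(list(exon_lengths = as.integer(exon_lengths),
                 intron_lengths = as.integer(intron_lengths),
                 target_exon = as.integer(target_exon),
                 cds_prefix_codons = as.integer(cds_prefix_codons),
                 cryptic_ag_offsets = as.integer(cryptic_ag_offsets),
                 truncation_stop = as.integer(truncation_stop),
                 retention_stop = as.integer(rs),
                 intron_window = as.integer(intron_window),
                 exon_window = as.integer(exon_window),
                 seed = as.integer(seed)),
            class = "toy_gene_spec")
}

# sample a random ACGT string
random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

#' Generate a toy gene from a spec
#'
#' Sequences are sampled uniformly over A/C/G/T, required motifs are planted
#' (start codon, GTTGCA target-exon start, the ttaattttag acceptor context,
#' cryptic AGs, an AAT first retained codon, the normal stop, and the
#' scenario stops), and collisions are repaired by flipping offending bases
#' to C (which can never create an AG or a stop). Repairs never touch planted
#' positions; if a constraint can only be met by altering a planted base the
#' draw is discarded and re-sampled, up to 100 times before a generation
#' error. Every accepted gene passes [audit_toy_gene()].
#'
#' @param spec A [toy_gene_spec()].
#' @return A `gene_model` with attribute `toy_spec`.
#' @examples
#' g <- make_toy_gene(toy_gene_spec())
#' substr(exon_seqs(g)[5], 1, 6)  # "GTTGCA"
#' @export
make_toy_gene <- function(spec) {
  stopifnot(inherits(spec, "toy_gene_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  for (try in seq_len(100L)) {
    g <- try_toy_gene(spec)
    if (!is.null(g)) {
      audit <- audit_toy_gene(g, spec)
      if (isTRUE(audit)) return(g)
    }
  }
  abort("infeasible toy-gene spec: no draw satisfied all constraints in 100 attempts",
        class = "splicetriage_generation_error")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# one sampling + planting + repair attempt; NULL if a protected position
# would have to change
try_toy_gene <- function(spec) {
  t_ex <- spec$target_exon
  P <- spec$cds_prefix_codons
  el <- spec$exon_lengths; il <- spec$intron_lengths
  n_ex <- length(el)
  i_st <- t_ex - 1L                 # studied intron
  L <- il[i_st]

  exons <- lapply(el, function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE))
  introns <- lapply(il, function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE))
  prot_e <- lapply(el, function(n) logical(n))
  prot_i <- lapply(il, function(n) logical(n))

  plant <- function(vec, prot, at, motif) {
    m <- strsplit(motif, "")[[1]]
    idx <- at + seq_along(m) - 1L
    clash <- prot[idx] & vec[idx] != m
    if (any(clash)) return(NULL)
    vec[idx] <- m
    prot[idx] <- TRUE
    list(vec = vec, prot = prot)
  }
  # --- plants ---
  p <- plant(exons[[1]], prot_e[[1]], 1L, "ATG"); if (is.null(p)) return(NULL)
  exons[[1]] <- p$vec; prot_e[[1]] <- p$prot
  p <- plant(exons[[t_ex]], prot_e[[t_ex]], 1L, "GTTGCA"); if (is.null(p)) return(NULL)
  exons[[t_ex]] <- p$vec; prot_e[[t_ex]] <- p$prot
  p <- plant(introns[[i_st]], prot_i[[i_st]], L - 9L, "TTAATTTTAG"); if (is.null(p)) return(NULL)
  introns[[i_st]] <- p$vec; prot_i[[i_st]] <- p$prot
  for (d in spec$cryptic_ag_offsets) {
    p <- plant(introns[[i_st]], prot_i[[i_st]], L - d - 1L, "AG"); if (is.null(p)) return(NULL)
    introns[[i_st]] <- p$vec; prot_i[[i_st]] <- p$prot
    p <- plant(introns[[i_st]], prot_i[[i_st]], L - d + 1L, "AAT"); if (is.null(p)) return(NULL)
    introns[[i_st]] <- p$vec; prot_i[[i_st]] <- p$prot
  }
  # non-studied introns get a plain acceptor context so they splice "normally"
  for (j in setdiff(seq_len(n_ex - 1L), i_st)) {
    p <- plant(introns[[j]], prot_i[[j]], il[j] - 1L, "AG"); if (is.null(p)) return(NULL)
    introns[[j]] <- p$vec; prot_i[[j]] <- p$prot
  }
  # normal stop: last codon before a short 3' UTR, fully inside the last exon
  T_len <- sum(el)
  K <- (T_len - 15L) %/% 3L
  stop_start <- 3L * K + 1L                  # transcript coords, cds_start = 0
  last_start <- sum(el[-n_ex]) + 1L
  if (stop_start <= last_start + 2L) abort("last exon too short for the normal stop")
  le_pos <- stop_start - last_start + 1L
  p <- plant(exons[[n_ex]], prot_e[[n_ex]], le_pos, "TAA"); if (is.null(p)) return(NULL)
  exons[[n_ex]] <- p$vec; prot_e[[n_ex]] <- p$prot

  # --- scenario stop plants (on source coordinates via block maps) ---
  # truncation: exons with target exon minus its first base
  trunc_blocks <- make_blocks(seq_len(n_ex), t_ex, drop_first = 1L)
  pos3 <- function(codon) 3L * (P + codon - 1L) + c(1L, 2L, 3L)
  src <- map_blocks(trunc_blocks, el, il, pos3(spec$truncation_stop))
  r <- plant_src(exons, introns, prot_e, prot_i, src, "TAA"); if (is.null(r)) return(NULL)
  exons <- r$exons; introns <- r$introns; prot_e <- r$prot_e; prot_i <- r$prot_i

  for (s in seq_along(spec$cryptic_ag_offsets)) {
    d <- spec$cryptic_ag_offsets[s]
    ret_blocks <- make_blocks(seq_len(n_ex), t_ex, retain = c(i_st, d))
    src <- map_blocks(ret_blocks, el, il, pos3(spec$retention_stop[s]))
    r <- plant_src(exons, introns, prot_e, prot_i, src, "TAA"); if (is.null(r)) return(NULL)
    exons <- r$exons; introns <- r$introns; prot_e <- r$prot_e; prot_i <- r$prot_i
  }

  # --- repair passes (flip to C; C never creates an AG or a stop) ---
  for (pass in 1:10) {
    changed <- FALSE
    # AG suppression in the scan window of the studied intron + target exon
    w_i <- min(spec$intron_window, L); w_e <- min(spec$exon_window, el[t_ex])
    win <- c(introns[[i_st]][(L - w_i + 1L):L], exons[[t_ex]][seq_len(w_e)])
    winp <- c(prot_i[[i_st]][(L - w_i + 1L):L], prot_e[[t_ex]][seq_len(w_e)])
    ag <- which(win[-length(win)] == "A" & win[-1] == "G")
    for (a in ag) {
      gpos <- a + 1L
      if (winp[a] && winp[gpos]) next   # planted / canonical AG, intentional
      tgt <- if (!winp[gpos]) gpos else a
      if (tgt <= w_i) introns[[i_st]][L - w_i + tgt] <- "C" else exons[[t_ex]][tgt - w_i] <- "C"
      changed <- TRUE
    }
    # stop-free frames: normal codons 1..K, truncation codons P+1..P+N-1,
    # retention codons P+1..P+N-1
    fix <- function(blocks, first, last) {
      for (codon in first:last) {
        src <- map_blocks(blocks, el, il, 3L * (codon - 1L) + c(1L, 2L, 3L))
        tri <- paste(get_src(exons, introns, src), collapse = "")
        if (tri %in% STOP_CODONS) {
          flipped <- FALSE
          for (b in 3:1) {   # prefer the wobble position
            ty <- src$type[b]; ix <- src$idx[b]; po <- src$pos[b]
            protd <- if (ty == "exon") prot_e[[ix]][po] else prot_i[[ix]][po]
            cur <- if (ty == "exon") exons[[ix]][po] else introns[[ix]][po]
            if (!protd && cur != "C") {
              if (ty == "exon") exons[[ix]][po] <<- "C" else introns[[ix]][po] <<- "C"
              flipped <- TRUE; break
            }
          }
          if (!flipped) return(FALSE)
          changed <<- TRUE
        }
      }
      TRUE
    }
    norm_blocks <- make_blocks(seq_len(n_ex), t_ex)
    if (!fix(norm_blocks, 1L, K)) return(NULL)
    if (!fix(trunc_blocks, P + 1L, P + spec$truncation_stop - 1L)) return(NULL)
    for (s in seq_along(spec$cryptic_ag_offsets)) {
      d <- spec$cryptic_ag_offsets[s]
      ret_blocks <- make_blocks(seq_len(n_ex), t_ex, retain = c(i_st, d))
      if (!fix(ret_blocks, P + 1L, P + spec$retention_stop[s] - 1L)) return(NULL)
    }
    if (!changed) break
  }

  seg <- tibble(
    role = rep(c("exon", "intron"), length.out = 2L * n_ex - 1L),
    index = as.integer(ceiling(seq_len(2L * n_ex - 1L) / 2)),
    seq = unlist(lapply(seq_len(2L * n_ex - 1L), function(j) {
      if (j %% 2 == 1) paste(exons[[(j + 1) %/% 2]], collapse = "")
      else paste(introns[[j %/% 2]], collapse = "")
    }))
  )
  g <- gene_model(seg, name = "toy", chrom = "chrT", cds_start = 0L)
  attr(g, "toy_spec") <- spec
  g
}

# block descriptors for a (possibly aberrant) isoform: rows (type, idx, from, to)
# in transcript order; `drop_first` trims the target exon's 5' end, `retain`
# (intron_idx, d) keeps that intron's last d bases before the target exon
make_blocks <- function(exon_idx, t_ex, drop_first = 0L, retain = NULL) {
  rows <- list()
  for (e in exon_idx) {
    if (!is.null(retain) && e == t_ex) {
      rows[[length(rows) + 1L]] <- list(type = "intron", idx = retain[1],
                                        from_end = retain[2])
    }
    from <- if (e == t_ex) drop_first + 1L else 1L
    rows[[length(rows) + 1L]] <- list(type = "exon", idx = e, from = from)
  }
  rows
}

# map aberrant-transcript positions to source coordinates; plain vectors for
# speed (this runs once per codon inspected during repair)
map_blocks <- function(blocks, el, il, positions) {
  type_b <- vapply(blocks, function(b) b$type, character(1))
  idx_b <- vapply(blocks, function(b) as.integer(b$idx), integer(1))
  from_b <- vapply(blocks, function(b) as.integer(b$from %||% NA_integer_), integer(1))
  fend_b <- vapply(blocks, function(b) as.integer(b$from_end %||% NA_integer_), integer(1))
  lens <- ifelse(type_b == "intron", fend_b, el[idx_b] - from_b + 1L)
  ends <- cumsum(lens)
  if (any(positions > ends[length(ends)])) abort("position beyond transcript in block map")
  k <- findInterval(positions - 1L, ends) + 1L
  off <- positions - c(0L, ends)[k]
  pos <- ifelse(type_b[k] == "intron",
                il[idx_b[k]] - fend_b[k] + off,
                from_b[k] + off - 1L)
  list(type = type_b[k], idx = idx_b[k], pos = as.integer(pos))
}

get_src <- function(exons, introns, src) {
  vapply(seq_along(src$type), function(j) {
    if (src$type[j] == "exon") exons[[src$idx[j]]][src$pos[j]]
    else introns[[src$idx[j]]][src$pos[j]]
  }, character(1))
}

plant_src <- function(exons, introns, prot_e, prot_i, src, motif) {
  m <- strsplit(motif, "")[[1]]
  for (j in seq_along(src$type)) {
    idx <- src$idx[j]; pos <- src$pos[j]
    if (src$type[j] == "exon") {
      if (prot_e[[idx]][pos] && exons[[idx]][pos] != m[j]) return(NULL)
      exons[[idx]][pos] <- m[j]; prot_e[[idx]][pos] <- TRUE
    } else {
      if (prot_i[[idx]][pos] && introns[[idx]][pos] != m[j]) return(NULL)
      introns[[idx]][pos] <- m[j]; prot_i[[idx]][pos] <- TRUE
    }
  }
  list(exons = exons, introns = introns, prot_e = prot_e, prot_i = prot_i)
}

#' Audit a generated toy gene against its spec
#'
#' Re-derives every promised property from the sequences alone: the scan
#' window contains exactly the canonical plus planted AGs (wild type) and the
#' planted plus junction AGs (mutant); the target exon starts GTTGCA; the
#' studied intron ends in the ttaattttag context; normal translation runs
#' stop-free to the designated terminator; and the truncation and retention
#' readings hit their first stops exactly at the engineered new-frame codons.
#'
#' @param gene A `gene_model` from [make_toy_gene()].
#' @param spec The [toy_gene_spec()] it was generated from (defaults to the
#'   attached one).
#' @return `TRUE`, or a character vector of failed checks.
#' @export
audit_toy_gene <- function(gene, spec = attr(gene, "toy_spec")) {
  fails <- character(0)
  t_ex <- spec$target_exon; P <- spec$cds_prefix_codons
  i_st <- t_ex - 1L
  intr <- intron_seqs(gene)[i_st]; L <- nchar(intr)
  ex <- exon_seqs(gene)
  variant <- sprintf("c.%d-1G>A", 3L * P + 1L)

  if (substr(ex[t_ex], 1, 6) != "GTTGCA") fails <- c(fails, "target exon start")
  if (str_sub(intr, -10L) != "TTAATTTTAG") fails <- c(fails, "acceptor context")

  wt <- scan_acceptors(gene, variant, context = "wt",
                       intron_window = spec$intron_window,
                       exon_window = spec$exon_window)
  want_wt <- sort(c(0L, spec$cryptic_ag_offsets))
  if (!identical(sort(wt$retained[wt$location == "intron"]), want_wt) ||
      any(wt$location == "exon")) {
    fails <- c(fails, "wild-type AG census")
  }
  mut <- scan_acceptors(gene, variant, context = "mutant",
                        intron_window = spec$intron_window,
                        exon_window = spec$exon_window)
  ok_mut <- identical(sort(mut$retained[mut$location == "intron"]),
                      sort(spec$cryptic_ag_offsets)) &&
    identical(mut$exon_g_index[mut$location == "exon"], 1L)
  if (!ok_mut) fails <- c(fails, "mutant AG census")

  mrna <- spliced_mrna(gene)
  aa <- translate_nt(mrna)
  K <- (nchar(mrna) - 15L) %/% 3L
  if (!identical(which(aa == "Ter")[1], K + 1L)) fails <- c(fails, "normal stop position")

  sites <- mut
  tr <- enumerate_outcomes(gene, variant, sites)
  cons <- translate_to_ptc(gene, tr)
  tcase <- cons[cons$kind == "exon_truncation" & cons$nt_delta == -1L, ]
  if (nrow(tcase) != 1 || tcase$stop_offset_n != spec$truncation_stop ||
      tcase$first_codon != P + 1L) {
    fails <- c(fails, "truncation stop")
  }
  for (s in seq_along(spec$cryptic_ag_offsets)) {
    rcase <- cons[cons$kind == "intron_retention" &
                    cons$nt_delta == spec$cryptic_ag_offsets[s], ]
    if (nrow(rcase) != 1 || rcase$stop_offset_n != spec$retention_stop[s] ||
        rcase$first_codon != P + 1L) {
      fails <- c(fails, sprintf("retention stop (offset %d)", spec$cryptic_ag_offsets[s]))
    }
  }
  if (length(fails)) fails else TRUE
}

#' The MSH2-like preset toy gene
#'
#' [make_toy_gene()] under the default [toy_gene_spec()]: 264-codon CDS
#' prefix, exon 4 of 147 nt, a 1,708-nt studied intron ending ttaattttag with
#' a cryptic AG 51 nt from its end, exon 5 of 150 nt starting GTTGCA, and
#' engineered stops reproducing p.Val265Leufs*9 / p.Val265Asnfs*15.
#'
#' @param seed Integer seed (default 17).
#' @return A `gene_model`.
#' @export
mshlike_gene <- function(seed = 17L) {
  make_toy_gene(toy_gene_spec(seed = seed))
}

#' Generate clinical fixtures shaped like a Lynch-syndrome work-up
#'
#' Builds an internally consistent bundle: a four-generation pedigree with
#' nine Lynch-spectrum diagnoses across two successive generations and
#' several before age 50 (so Amsterdam II is met), a five-marker MSI record
#' with 2-5 unstable markers (so the panel classifies MSI-H at the 40%
#' threshold), and the two observed IHC loss patterns (MSH2-/MSH6- and
#' MSH2- alone, both implicating MSH2).
#'
#' @param seed Integer seed controlling which markers are unstable.
#' @return List with elements `pedigree`, `msi`, `ihc` (tibbles).
#' @export
make_clinical_fixtures <- function(seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  ped <- tibble::tribble(
    ~id,      ~father, ~mother,  ~sex, ~cancer,       ~age_dx,
    "I-1",    NA,      NA,       "M",  NA,            NA,
    "I-2",    NA,      NA,       "F",  NA,            NA,
    "II-3",   NA,      NA,       "M",  NA,            NA,   # married in
    "II-4",   "I-1",   "I-2",    "F",  "colorectal",  48,
    "II-6",   "I-1",   "I-2",    "F",  "colorectal",  53,
    "II-8",   "I-1",   "I-2",    "F",  "colorectal",  57,
    "II-9",   NA,      NA,       "M",  NA,            NA,   # married in
    "II-10",  "I-1",   "I-2",    "F",  "colorectal",  49,
    "III-11", "II-9",  "II-10",  "M",  "colorectal",  46,
    "III-14", "II-9",  "II-10",  "F",  "colorectal",  37,
    "III-14", "II-9",  "II-10",  "F",  "endometrial", 47,
    "III-15", "II-9",  "II-10",  "M",  "colorectal",  43,
    "III-18", "II-9",  "II-10",  "F",  "colorectal",  39,
    "III-18", "II-9",  "II-10",  "F",  "endometrial", 31,
    "III-20", "II-9",  "II-10",  "F",  NA,            NA,
    "III-21", "II-9",  "II-10",  "M",  NA,            NA,
    "III-40", "II-3",  "II-4",   "F",  "colorectal",  44,
    "IV-11",  NA,      "III-14", "F",  NA,            NA,
    "IV-12",  NA,      "III-14", "M",  NA,            NA
  )

  markers <- c("BAT25", "BAT26", "D2S123", "D5S346", "D17S250")
  n_unstable <- sample(2:5, 1)
  unstable <- sample(markers, n_unstable)
  msi <- tibble(marker = markers,
                status = ifelse(markers %in% unstable, "unstable", "stable"))

  ihc <- tibble(
    case = c(rep("III-14", 4), rep("III-15", 4)),
    protein = rep(c("MLH1", "MSH2", "MSH6", "PMS2"), 2),
    status = c("retained", "lost", "lost", "retained",
               "retained", "lost", "retained", "retained"))

  list(pedigree = ped, msi = msi, ihc = ihc)
}
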