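test_that("truncated-length bookkeeping matches the fs*N convention", {
  expect_equal(truncated_length(265, 9), 272L)
  expect_equal(truncated_length(265, 15), 278L)
  expect_equal(truncated_length(1, 2), 1L)
  expect_error(truncated_length(0, 5), "positive")
  expect_error(truncated_length(265, 0), "positive")
})

test_that("acceptor loss enumerates the truncation and retention isoforms", {
  g <- msh_gene()
  sites <- scan_acceptors(g, "c.793-1G>A")
  tr <- enumerate_outcomes(g, "c.793-1G>A", sites)
  expect_equal(nrow(tr), 2L)
  expect_setequal(tr$kind, c("exon_truncation", "intron_retention"))

  tcase <- tr[tr$kind == "exon_truncation", ]
  expect_equal(tcase$nt_delta, -1L)
  expect_equal(tcase$cdna_hgvs, "c.793del")
  rcase <- tr[tr$kind == "intron_retention", ]
  expect_equal(rcase$nt_delta, 51L)
  expect_equal(rcase$cdna_hgvs, "c.792_793ins51")

  # length bookkeeping: |mrna delta| equals |nt_delta| for every isoform
  normal_len <- nchar(spliced_mrna(g))
  expect_equal(nchar(tr$mrna) - normal_len, tr$nt_delta)

  # an exonic variant is not an acceptor disruption
  expect_error(enumerate_outcomes(g, "c.793G>A", sites),
               class = "splicetriage_not_acceptor")
})

test_that("exon skip is forced when no candidate site exists", {
  g <- msh_gene()
  sites <- scan_acceptors(g, "c.793-1G>A")
  none <- sites[0, ]
  tr <- enumerate_outcomes(g, "c.793-1G>A", none, include_skip = TRUE)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$kind, "exon_skip")
  expect_equal(tr$nt_delta, -150L)
  expect_equal(tr$cdna_hgvs, "c.793_942del")
})

test_that("translation to the PTC reproduces the published consequences", {
  g <- msh_gene()
  tr <- translate_to_ptc(g, enumerate_outcomes(g, "c.793-1G>A",
                                               scan_acceptors(g, "c.793-1G>A")))
  tcase <- tr[tr$kind == "exon_truncation", ]
  expect_equal(tcase$first_codon, 265L)
  expect_equal(tcase$ref_aa, "Val")
  expect_equal(tcase$alt_aa, "Leu")
  expect_equal(tcase$stop_offset_n, 9L)
  expect_equal(tcase$truncated_length, 272L)
  expect_equal(tcase$hgvs_p, "p.Val265Leufs*9")
  expect_true(tcase$frameshift)
  expect_true(tcase$nmd_predicted)

  rcase <- tr[tr$kind == "intron_retention", ]
  expect_equal(rcase$hgvs_p, "p.Val265Asnfs*15")
  expect_equal(rcase$truncated_length, 278L)
  expect_false(rcase$frameshift)  # +51 is a codon multiple; the stop sits inside the insert
  expect_true(rcase$nmd_predicted)

  # hgvs_p round-trips through the parser
  for (j in seq_len(nrow(tr))) {
    p <- parse_hgvs_p(tr$hgvs_p[j])
    expect_equal(p$first_codon, tr$first_codon[j])
    expect_equal(p$ref_aa, tr$ref_aa[j])
    expect_equal(p$alt_aa, tr$alt_aa[j])
    expect_equal(p$fs_n, tr$stop_offset_n[j])
  }
})

test_that("an unchanged transcript reports p.(=)", {
  g <- msh_gene()
  idt <- tibble::tibble(kind = "normal", nt_delta = 0L, cdna_hgvs = "c.=",
                        junction_desc = "", score = NA_real_,
                        mrna = spliced_mrna(g),
                        junctions = list(exon_junctions(g)))
  out <- translate_to_ptc(g, idt)
  expect_equal(out$hgvs_p, "p.(=)")
  expect_false(out$no_ptc)
  expect_false(out$nmd_predicted)
})

test_that("clean in-frame events carry in-frame nomenclature, not fs*N", {
  g <- msh_gene()
  # in-frame insertion of three alanines at the junction: realigns downstream
  ex <- exon_seqs(g)
  ex[5] <- paste0("GCTGCAGCC", ex[5])
  ins <- tibble::tibble(kind = "intron_retention", nt_delta = 9L,
                        cdna_hgvs = "c.792_793ins9", junction_desc = "",
                        score = NA_real_, mrna = paste(ex, collapse = ""),
                        junctions = list(exon_junctions(g)))
  out <- translate_to_ptc(g, ins)
  expect_match(out$hgvs_p, "ins3$")
  expect_false(out$frameshift)
  expect_true(is.na(out$stop_offset_n))

  # in-frame exon skip (150 nt) realigns too
  sites <- scan_acceptors(g, "c.793-1G>A")
  skip <- enumerate_outcomes(g, "c.793-1G>A", sites[0, ], include_skip = TRUE)
  out <- translate_to_ptc(g, skip)
  expect_match(out$hgvs_p, "del$")
  expect_false(out$frameshift)
})

test_that("frameshift law holds across randomized toy genes", {
  for (s in 1:8) {
    spec <- random_toy_spec(1000 + s)
    g <- make_toy_gene(spec)
    v <- toy_variant(spec)
    tr <- translate_to_ptc(g, enumerate_outcomes(g, v, scan_acceptors(g, v)))
    expect_true(all(tr$frameshift == (tr$nt_delta %% 3L != 0L)))
    # truncated_length formula never disagrees with the literal walk
    done <- !tr$no_ptc & !is.na(tr$truncated_length)
    walked <- vapply(tr$mrna[done], walk_protein_length, integer(1),
                     USE.NAMES = FALSE)
    expect_equal(tr$truncated_length[done], walked)
  }
})

test_that("the NMD boundary rule is applied to the final junction", {
  # PTC 10 nt upstream of the last junction: inside the boundary, no NMD
  expect_false(predict_nmd(ptc_codon = 30, junctions = c(50, 97), cds_start = 0))
  # PTC 60 nt upstream: substrate
  expect_true(predict_nmd(ptc_codon = 30, junctions = c(50, 148), cds_start = 0))
  # single-exon transcripts are never substrates
  expect_false(predict_nmd(ptc_codon = 5, junctions = integer(0)))
})
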