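study_construct <- function(seqs = FALSE) {
  if (!seqs) {
    seg <- tibble::tibble(label = c("exon4", "intron4_part", "exon5"),
                          role = c("exon", "intron_part", "exon"),
                          length = c(147L, 1708L, 150L))
  } else {
    g <- msh_gene()
    seg <- tibble::tibble(label = c("exon4", "intron4_part", "exon5"),
                          role = c("exon", "intron_part", "exon"),
                          length = c(147L, 1708L, 150L),
                          seq = unname(c(exon_seqs(g)[4], intron_seqs(g)[4],
                                         exon_seqs(g)[5])))
  }
  minigene_assemble(seg, flank_total = 160L)
}

test_that("construct assembly computes the published insert length", {
  cons <- study_construct()
  expect_equal(insert_length(cons), 2005L)
  expect_equal(insert_length(minigene_assemble(
    tibble::tibble(label = "e", role = "exon", length = 100L))), 100L)
  expect_error(minigene_assemble(tibble::tibble(label = character(0),
                                                role = character(0),
                                                length = integer(0))),
               "at least one")
  expect_error(minigene_assemble(tibble::tibble(label = "e", role = "exon",
                                                length = 0L)), "positive")
})

test_that("RT-PCR product sizes follow flank + exonic arithmetic", {
  cons <- study_construct()
  wt <- rtpcr_size(cons)
  expect_equal(wt$size_bp, 457L)                 # 160 flank + 147 + 150
  expect_equal(attr(wt, "target_bp"), 297L)      # the gene-derived portion
  iso <- tibble::tibble(kind = c("exon_truncation", "intron_retention"),
                        nt_delta = c(-1L, 51L))
  bands <- rtpcr_size(cons, iso)
  expect_equal(bands$size_bp, c(457L, 456L, 508L))
  expect_equal(bands$band_label, c("a", "b", "c"))
})

test_that("band-size shifts equal nt_delta on randomized constructs", {
  set.seed(5)
  for (rep in 1:20) {
    seg <- tibble::tibble(
      label = c("eL", "i", "eR"), role = c("exon", "intron_part", "exon"),
      length = c(sample(50:300, 1), sample(100:2000, 1), sample(50:300, 1)))
    cons <- minigene_assemble(seg, flank_total = sample(0:200, 1))
    deltas <- sample(c(-30:-1, 1:60), 5)
    iso <- tibble::tibble(kind = "intron_retention", nt_delta = deltas)
    bands <- rtpcr_size(cons, iso)
    expect_equal(bands$size_bp[-1] - bands$size_bp[1], deltas)
  }
})

test_that("junction strings slice the isoform junctions correctly", {
  cons <- study_construct(seqs = TRUE)
  g <- msh_gene()
  e4 <- exon_seqs(g)[4]; e5 <- exon_seqs(g)[5]; i4 <- intron_seqs(g)[4]

  wt <- junction_strings(cons, NULL, k = 8)
  expect_equal(wt$kmer,
               paste0(substr(e4, 140, 147), substr(e5, 1, 8)))

  tr <- junction_strings(cons, tibble::tibble(kind = "exon_truncation",
                                              nt_delta = -1L), k = 8)
  expect_equal(tr$kmer, paste0(substr(e4, 140, 147), substr(e5, 2, 9)))

  rt <- junction_strings(cons, tibble::tibble(kind = "intron_retention",
                                              nt_delta = 51L), k = 8)
  expect_equal(rt$kmer,
               paste0(substr(e4, 140, 147), substr(i4, 1658, 1665)))

  expect_warning(junction_strings(minigene_assemble(
    tibble::tibble(label = c("a", "b"), role = c("exon", "exon"),
                   length = c(4L, 6L), seq = c("ACGT", "GGCCTT"))), k = 8),
    "trimmed")
})

test_that("segment order changes junctions but not the insert length", {
  g <- msh_gene()
  seg <- tibble::tibble(label = c("exon4", "exon5"),
                        role = c("exon", "exon"),
                        length = c(147L, 150L),
                        seq = unname(c(exon_seqs(g)[4], exon_seqs(g)[5])))
  a <- minigene_assemble(seg)
  b <- minigene_assemble(seg[2:1, ])
  expect_equal(insert_length(a), insert_length(b))
  expect_false(identical(junction_strings(a)$kmer, junction_strings(b)$kmer))
})
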