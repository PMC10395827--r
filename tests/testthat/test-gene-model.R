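test_that("gene_model validates structure, strand and sequences", {
  seg <- tibble::tibble(role = c("exon", "intron", "exon"),
                        index = c(1L, 1L, 2L),
                        seq = c("ATGGTT", "GTTTTTTTTTTTTAG", "CCTTAA"))
  g <- gene_model(seg, name = "toy")
  expect_s3_class(g, "gene_model")
  expect_equal(spliced_mrna(g), "ATGGTTCCTTAA")
  expect_equal(exon_junctions(g), 6L)

  expect_error(gene_model(seg, strand = "-"), "plus-strand")
  expect_error(gene_model(dplyr::mutate(seg, seq = sub("^A", "N", seq))), "non-ACGT")
  expect_error(gene_model(seg[c(1, 3), ]), "alternate")
  expect_error(gene_model(dplyr::mutate(seg, length = c(5L, 15L, 6L))),
               "disagrees")
  expect_error(gene_model(dplyr::mutate(seg, seq = c("CCGGTT", seq[2:3]))),
               "start codon")
})

test_that("spliced transcript length equals the sum of exon lengths", {
  g <- msh_gene()
  expect_equal(nchar(spliced_mrna(g)), sum(g$length[g$role == "exon"]))
  for (s in 1:5) {
    g2 <- make_toy_gene(small_spec(s))
    expect_equal(nchar(spliced_mrna(g2)), sum(g2$length[g2$role == "exon"]))
  }
})

test_that("cds_to_codon places c.793 in codon 265 and obeys the codon law", {
  expect_equal(cds_to_codon(793)$codon_index, 265L)
  expect_equal(cds_to_codon(793)$phase, 1L)
  expect_equal(cds_to_codon(1)$codon_index, 1L)
  expect_equal(cds_to_codon(792)$codon_index, 264L)
  expect_equal(cds_to_codon(792)$phase, 3L)

  all_bases <- cds_to_codon(1:10000)
  expect_true(all(3L * (all_bases$codon_index - 1L) + all_bases$phase ==
                    all_bases$cds_base))
  expect_error(cds_to_codon(0), "positive")
  expect_error(cds_to_codon(-5), "positive")
})

test_that("resolve_variant anchors intronic offsets at exon boundaries", {
  g <- msh_gene()
  co <- resolve_variant(g, "c.793-1G>A")
  expect_equal(co$region, "intron")
  expect_equal(co$region_index, 4L)
  expect_equal(co$offset, 1708L - 1L)   # final intron base, 0-based

  # reference checking happens at resolution
  expect_error(resolve_variant(g, "c.793A>G"),
               class = "splicetriage_ref_mismatch")
  # walking past the intron boundary is a coordinate error
  expect_error(resolve_variant(g, "c.793-5000G>A"),
               class = "splicetriage_coord_error")
  # a negative offset must hang off an exon-initial base
  expect_error(resolve_variant(g, "c.795-1G>A"),
               class = "splicetriage_coord_error")
})

test_that("coordinate resolution round-trips at exon-adjacent positions", {
  g <- msh_gene()
  elens <- g$length[g$role == "exon"]
  starts <- cumsum(c(0L, elens[-length(elens)])) + 1L
  for (e in 2:length(elens)) {
    first_cds <- starts[e]
    for (off in c(-1L, -2L)) {
      v <- tibble::tibble(hgvs = NA, kind = "substitution",
                          cds_base = first_cds, intron_offset = off,
                          cds_end = NA, ref = NA_character_,
                          alt = NA_character_, ins_len = NA, ins_seq = NA)
      co <- resolve_variant(g, v)
      back <- coordinate_to_hgvs(g, co$region, co$region_index, co$offset)
      expect_equal(back$cds_base, first_cds)
      expect_equal(back$intron_offset, off)
    }
  }
  # exonic identity
  co <- resolve_variant(g, "c.793G>A")
  back <- coordinate_to_hgvs(g, co$region, co$region_index, co$offset)
  expect_equal(back$cds_base, 793L)
  expect_equal(back$intron_offset, 0L)
})
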