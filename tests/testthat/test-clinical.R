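panel_calls <- function(n_unstable) {
  markers <- c("BAT25", "BAT26", "D2S123", "D5S346", "D17S250")
  tibble::tibble(marker = markers,
                 status = c(rep("unstable", n_unstable),
                            rep("stable", 5 - n_unstable)))
}

test_that("the 40% rule classifies the five-marker panel", {
  r <- classify_msi(panel_calls(2))
  expect_equal(r$fraction_unstable, 0.40)
  expect_equal(r$msi_class, "MSI-H")
  expect_equal(classify_msi(panel_calls(0))$msi_class, "MSS")
  expect_equal(classify_msi(panel_calls(5))$msi_class, "MSI-H")
  expect_equal(classify_msi(panel_calls(1))$msi_class, "MSI-L")
  expect_warning(classify_msi(tibble::tibble(marker = "NR-21",
                                             status = "unstable")),
                 "outside the NCI panel")
  expect_error(classify_msi(panel_calls(2)[0, ]), "at least one")
})

test_that("adding an unstable call never downgrades the MSI class", {
  rank <- c(MSS = 0, `MSI-L` = 1, `MSI-H` = 2)
  for (u in 0:4) {
    before <- classify_msi(panel_calls(u))$msi_class
    after <- classify_msi(panel_calls(u + 1))$msi_class
    expect_gte(rank[[after]], rank[[before]])
  }
})

test_that("IHC dimer logic implicates the right MMR gene", {
  # the two observed patterns: MSH2-/MSH6- and isolated MSH2-
  p1 <- c(MLH1 = "retained", MSH2 = "lost", MSH6 = "lost", PMS2 = "retained")
  p2 <- c(MLH1 = "retained", MSH2 = "lost", MSH6 = "retained", PMS2 = "retained")
  expect_equal(infer_mmr_gene(p1)$gene[1], "MSH2")
  expect_equal(infer_mmr_gene(p2)$gene[1], "MSH2")
  expect_equal(infer_mmr_gene(
    c(MLH1 = "retained", MSH2 = "retained", MSH6 = "lost",
      PMS2 = "retained"))$gene[1], "MSH6")
  expect_equal(infer_mmr_gene(
    c(MLH1 = "lost", MSH2 = "retained", MSH6 = "retained",
      PMS2 = "lost"))$gene[1], "MLH1")
  expect_equal(infer_mmr_gene(
    c(MLH1 = "retained", MSH2 = "retained", MSH6 = "retained",
      PMS2 = "lost"))$gene[1], "PMS2")
  all_kept <- c(MLH1 = "retained", MSH2 = "retained", MSH6 = "retained",
                PMS2 = "retained")
  expect_equal(nrow(infer_mmr_gene(all_kept)), 0L)
})

test_that("IHC inference is total over all sixteen patterns", {
  states <- c("retained", "lost")
  grid <- expand.grid(MLH1 = states, MSH2 = states, MSH6 = states,
                      PMS2 = states, stringsAsFactors = FALSE)
  for (j in seq_len(nrow(grid))) {
    pat <- unlist(grid[j, ])
    out <- infer_mmr_gene(pat)
    expect_s3_class(out, "tbl_df")
    lost <- names(pat)[pat == "lost"]
    # the obligate dimer rule: MSH2 loss always implicates MSH2; MLH1 likewise
    if ("MSH2" %in% lost) expect_true("MSH2" %in% out$gene)
    if ("MLH1" %in% lost) expect_true("MLH1" %in% out$gene)
    if (!length(lost)) expect_equal(nrow(out), 0L)
    if (length(lost)) expect_gte(nrow(out), 1L)
  }
})

test_that("the Lynch-family pedigree meets Amsterdam II", {
  ped <- make_clinical_fixtures(1)$pedigree
  r <- amsterdam_ii(ped)
  expect_true(r$met)
  expect_equal(r$three_affected_first_degree, "met")
  expect_true(r$two_successive_generations)
  expect_true(r$diagnosis_before_50)
})

test_that("degenerate pedigrees fail the criteria for the right reason", {
  solo <- tibble::tibble(id = "P1", father = NA, mother = NA,
                         cancer = "colorectal", age_dx = 40)
  r <- amsterdam_ii(solo)
  expect_false(r$met)

  # three affected cousins in one generation, none first-degree linked
  cousins <- tibble::tibble(
    id = c("A", "B", "C", "fA", "mA", "fB", "mB", "fC", "mC"),
    father = c("fA", "fB", "fC", NA, NA, NA, NA, NA, NA),
    mother = c("mA", "mB", "mC", NA, NA, NA, NA, NA, NA),
    cancer = c(rep("colorectal", 3), rep(NA, 6)),
    age_dx = c(40, 45, 48, rep(NA, 6)))
  r <- amsterdam_ii(cousins)
  expect_false(r$met)
  expect_equal(r$three_affected_first_degree, "unmet")

  # unknown kinship makes the trio criterion indeterminate, not failed
  orphans <- tibble::tibble(id = c("A", "B", "C"), father = NA, mother = NA,
                            cancer = "colorectal", age_dx = c(40, 45, 48))
  r <- amsterdam_ii(orphans)
  expect_equal(r$three_affected_first_degree, "indeterminate")
  expect_false(r$evaluable)

  # withdrawing the attestations withdraws the diagnosis
  ped <- make_clinical_fixtures(1)$pedigree
  expect_false(amsterdam_ii(ped, fap_excluded = FALSE)$met)
})

test_that("Amsterdam II is invariant to row order and unaffected padding", {
  ped <- make_clinical_fixtures(1)$pedigree
  base <- amsterdam_ii(ped)
  shuffled <- ped[sample(nrow(ped)), ]
  expect_equal(amsterdam_ii(shuffled), base)
  padded <- dplyr::bind_rows(ped, tibble::tibble(
    id = c("X1", "X2"), father = NA, mother = NA,
    cancer = NA, age_dx = NA))
  expect_equal(amsterdam_ii(padded), base)
})
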