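test_that("percent change reproduces the published consensus-value deltas", {
  expect_equal(round(percent_change(86.74, 58.87), 2), -32.13)
  expect_equal(round(percent_change(10.35, 1.6), 2), -84.54)
  expect_equal(round(percent_change(-2.15, 5.8), 2), 369.77)
  for (x in c(-3.2, 0.5, 42)) expect_equal(percent_change(x, x), 0)
  expect_error(percent_change(0, 5), "baseline")
})

test_that("percent change is sign-consistent", {
  set.seed(42)
  wt <- runif(200, -50, 50)
  wt <- wt[abs(wt) > 1e-6]
  mut <- wt + runif(length(wt), -30, 30)
  pc <- percent_change(wt, mut)
  expect_true(all(sign(pc) == sign(mut - wt)))
})

test_that("acceptor scoring is normalized, frozen and directionally right", {
  pwm <- acceptor_pwm()
  expect_true(all(abs(rowSums(pwm$weights) - 1) < 1e-9))
  # per-position modal window scores the scale maximum by construction
  consensus <- paste(colnames(pwm$weights)[apply(pwm$weights, 1, which.max)],
                     collapse = "")
  expect_equal(score_acceptor(pwm, consensus), 100)
  # frozen values, computed with an independent loop over the same table
  expect_equal(score_acceptor(pwm, "TTAATTTTAGGTTGCA"), 82.52440432856046,
               tolerance = 1e-10)
  expect_equal(score_acceptor(pwm, "TTAATTTTAAGTTGCA"), 64.30185913836172,
               tolerance = 1e-10)
  # the wild-type junction outscores its terminal g>a mutant
  expect_gt(score_acceptor(pwm, "TTAATTTTAGGTTGCA"),
            score_acceptor(pwm, "TTAATTTTAAGTTGCA"))
  expect_error(score_acceptor(pwm, "TTAATTTTANGTTGCA"), "alphabet")
  expect_error(score_acceptor(pwm, "ACGT"), "16 nt")
})

test_that("moving any position off the modal base never raises the score", {
  pwm <- acceptor_pwm()
  modal <- colnames(pwm$weights)[apply(pwm$weights, 1, which.max)]
  set.seed(7)
  for (rep in 1:100) {
    w <- paste(sample(c("A", "C", "G", "T"), 16, replace = TRUE), collapse = "")
    i <- sample(16, 1)
    w_modal <- w; substr(w_modal, i, i) <- modal[i]
    other <- setdiff(c("A", "C", "G", "T"), modal[i])
    w_off <- w_modal; substr(w_off, i, i) <- sample(other, 1)
    expect_lte(score_acceptor(pwm, w_off), score_acceptor(pwm, w_modal))
  }
})

test_that("the cryptic scanner agrees with brute-force AG enumeration", {
  pwm <- acceptor_pwm()
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(40:200, 1)
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    from <- sample(1:(n - 20), 1)
    to <- from + sample(10:19, 1)
    got <- scan_cryptic_acceptors(s, from, to, pwm)
    expect_setequal(got$a_pos, brute_force_ag(s, from, to))
  }
  expect_equal(nrow(scan_cryptic_acceptors("TTTTTTTT", 1, 8)), 0)
  expect_equal(nrow(scan_cryptic_acceptors("ACGTACGT", 5, 5)), 0)  # empty window
})

test_that("scanner output is ranked by score, ties broken by proximity", {
  s <- paste0(strrep("C", 12), "AG", strrep("C", 6), "AG", strrep("C", 19))
  got <- scan_cryptic_acceptors(s, 11, 30, canonical_g = 30)
  expect_equal(nrow(got), 2L)
  expect_false(any(is.na(got$score)))
  expect_equal(got$score, sort(got$score, decreasing = TRUE), tolerance = 1e-12)
})

test_that("junction scans find the expected site census at the mutated junction", {
  g <- msh_gene()
  wt <- scan_acceptors(g, "c.793-1G>A", context = "wt")
  # canonical ag at the intron terminus is reported, flagged non-candidate
  expect_true(any(wt$provenance == "canonical" & wt$retained == 0))
  expect_false(any(wt$candidate[wt$provenance == "canonical"]))
  expect_true(any(wt$retained == 51, na.rm = TRUE))

  mut <- scan_acceptors(g, "c.793-1G>A", context = "mutant")
  expect_false(any(mut$provenance == "canonical"))
  # the AG one position 3' of the lost canonical site: mutated a + exon G
  expect_true(any(mut$location == "exon" & mut$exon_g_index == 1))
  expect_true(any(mut$location == "intron" & mut$retained == 51))
  expect_equal(nrow(mut), 2L)
})

test_that("site calls follow the loss/gain thresholds", {
  expect_equal(call_site(percent_change(86.74, 58.87), -10, 10, TRUE), "site_loss")
  expect_equal(call_site(percent_change(-2.15, 5.8), -10, 10, FALSE), "new_site_gain")
  expect_equal(call_site(percent_change(50, 49), -10, 10, TRUE), "site_maintained")
  # gains are only called away from the canonical position
  expect_equal(call_site(200, -10, 10, TRUE), "site_maintained")
  d <- splice_delta(86.74, 58.87)
  expect_equal(d$call, "site_loss")
  expect_equal(round(d$percent_change, 2), -32.13)
})
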