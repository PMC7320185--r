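# Locus discovery, confirmation, distances and matching.

mk_gwas <- function(pos, p, chrom = "1", rsid = NULL) {
  rsid <- rsid %||% sprintf("rs%d", seq_along(pos))
  z <- qnorm(p / 2) # magnitude irrelevant here
  tibble::tibble(
    rsid = rsid, chrom = chrom, pos = pos,
    allele_effect = "A", allele_other = "G",
    beta = z * 0.01, se = 0.01, z = z, pvalue = p, maf = 0.3, n = 1e5
  )
}

test_that("greedy clumping absorbs nearby hits and separates distant ones", {
  one <- find_loci(mk_gwas(5e5, 4e-8))
  expect_equal(nrow(one), 1)
  expect_equal(one$window_start, 5e5 - 250000)
  expect_equal(one$window_end, 5e5 + 250000)

  near <- find_loci(mk_gwas(c(5e5, 6e5), c(1e-9, 4e-8)))
  expect_equal(nrow(near), 1)
  expect_equal(near$lead_rsid, "rs1")

  far <- find_loci(mk_gwas(c(5e5, 11e5), c(1e-9, 4e-8)))
  expect_equal(nrow(far), 2)
  # threshold is strict: exactly 5e-8 is not significant
  expect_equal(nrow(find_loci(mk_gwas(5e5, 5e-8))), 0)
})

test_that("greedy clumping matches a brute-force pass on a toy table", {
  set.seed(3)
  pos <- sort(sample(1:5e6, 60))
  p <- 10^runif(60, -12, -5)
  gwas <- mk_gwas(pos, p)
  got <- find_loci(gwas)
  # brute force: same greedy definition written independently
  df <- data.frame(rsid = gwas$rsid, pos = pos, p = p)
  df <- df[df$p < 5e-8, ]
  leads <- character(0)
  while (nrow(df)) {
    i <- which.min(df$p)
    leads <- c(leads, df$rsid[i])
    df <- df[abs(df$pos - df$pos[i]) > 250000, ]
  }
  expect_setequal(got$lead_rsid, leads)
  # no locus window contains another locus's lead
  for (i in seq_len(nrow(got))) {
    others <- got$lead_pos[-i]
    expect_true(all(others < got$window_start[i] | others > got$window_end[i]))
  }
})

test_that("confirmation keeps and re-anchors loci on the confirming lead", {
  loci <- find_loci(mk_gwas(5e5, 1e-9))
  euro <- mk_gwas(c(4.5e5, 5.2e5), c(1e-8, 1e-5), rsid = c("rsE1", "rsE2"))
  conf <- confirm_loci(loci, euro)
  expect_equal(nrow(conf), 1)
  expect_equal(conf$lead_rsid, "rsE1")
  expect_equal(conf$window_start, 4.5e5 - 250000)

  # threshold strict: best P exactly 6e-7 drops the locus
  weak <- mk_gwas(5e5, 6e-7, rsid = "rsW")
  conf2 <- confirm_loci(loci, weak)
  expect_equal(nrow(conf2), 0)
  expect_equal(attr(conf2, "dropped")$drop_reason, "below confirmation threshold")

  # no coverage in the window
  off <- mk_gwas(5e6, 1e-9, rsid = "rsO")
  conf3 <- confirm_loci(loci, off)
  expect_equal(nrow(conf3), 0)
  expect_match(attr(conf3, "dropped")$drop_reason, "no coverage")
})

test_that("lead distances reproduce the printed overlapping-pair distances", {
  a <- tibble::tibble(chrom = "6", lead_pos = 160740721)
  b <- tibble::tibble(chrom = "6", lead_pos = 161010118)
  expect_equal(lead_distance(a, b), 269397)
  expect_equal(distance_kb(lead_distance(a, b)), 269.4)
  c1 <- tibble::tibble(chrom = "12", lead_pos = 111884608)
  c2 <- tibble::tibble(chrom = "12", lead_pos = 112228849)
  expect_equal(lead_distance(c1, c2), 344241)
  expect_equal(distance_kb(lead_distance(c1, c2)), 344.2)
  expect_equal(lead_distance(a, a), 0)
  expect_equal(lead_distance(a, c1), Inf)
})

test_that("locus matching is strict at 250 kb and pairs closest-first", {
  mk_loci <- function(pos, rsid, chrom = "1") {
    tibble::tibble(
      lead_rsid = rsid, chrom = chrom, lead_pos = pos,
      window_start = pos - 250000, window_end = pos + 250000,
      lead_pvalue = 1e-9, source_dataset = "x"
    )
  }
  # the printed 269,397 bp pair must NOT match
  a <- mk_loci(160740721, "rs3103349", "6")
  b <- mk_loci(161010118, "rs10455872", "6")
  res <- match_loci(a, b)
  expect_equal(nrow(res$pairs), 0)
  expect_equal(nrow(res$unmatched_a), 1)
  expect_equal(nrow(res$unmatched_b), 1)

  res2 <- match_loci(mk_loci(1e6, "a1"), mk_loci(1.1e6, "b1"))
  expect_equal(res2$pairs$distance, 1e5)

  # two A loci compete for one B locus: the closer one wins
  a3 <- mk_loci(c(1.00e6, 1.15e6), c("a1", "a2"))
  b3 <- mk_loci(1.05e6, "b1")
  res3 <- match_loci(a3, b3)
  expect_equal(res3$pairs$lead_a, "a1")
  expect_equal(res3$unmatched_a$lead_rsid, "a2")
  # symmetric up to orientation
  res4 <- match_loci(b3, a3)
  expect_equal(res4$pairs$lead_b, res3$pairs$lead_a)
})
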