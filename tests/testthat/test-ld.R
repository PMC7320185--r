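# Panel reading, pairwise LD and LD grouping.

test_that("a VCF panel reads with biallelic filtering and dosage hard calls", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(path)
  panel <- read_panel(path, "vcf", maf_min = 0)
  expect_s3_class(panel, "genotype_panel")
  expect_equal(length(panel$samples), 4)
  expect_equal(nrow(panel$variants), 3)
  expect_equal(unname(panel$dosage[, "rsA"]), c(0, 1, 2, 1))

  path2 <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(path2, extra_triallelic = TRUE)
  panel2 <- read_panel(path2, "vcf", maf_min = 0)
  expect_false("rsD" %in% panel2$variants$rsid)
  expect_equal(unname(drop_log(panel2$variants)["multiallelic"]), 1L)
})

test_that("a dosage-matrix panel reads and excludes constant columns", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "rs1 rs2 rs3",
    "0 1 2",
    "1 1 0",
    "2 1 1",
    "0 1 2"
  ), path)
  panel <- read_panel(path, "dosage", maf_min = 0)
  expect_false("rs2" %in% panel$variants$rsid) # zero variance
  expect_equal(unname(drop_log(panel$variants)["monomorphic"]), 1L)
  expect_equal(ncol(panel$dosage), 2)
})

test_that("pairwise r matches a hand Pearson computation and its symmetries", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "a b mirror_a copy_a",
    "0 0 2 0",
    "0 1 2 0",
    "1 1 1 1",
    "2 2 0 2"
  ), path)
  panel <- read_panel(path, "dosage", maf_min = 0)
  expect_equal(pairwise_r(panel, "a", "copy_a"), 1)
  expect_equal(pairwise_r(panel, "a", "mirror_a"), -1)
  # hand computation: r = 2 / sqrt(2.75 * 2) = 0.85280...
  expect_equal(pairwise_r(panel, "a", "b"), 2 / sqrt(2.75 * 2), tolerance = 1e-12)
  expect_equal(pairwise_r(panel, "a", "a"), 1)
  expect_error(pairwise_r(panel, "a", "nope"), "not in panel")
})

test_that("ld_matrix is symmetric with unit diagonal; independent SNPs near zero", {
  cfg <- sim_config("null", n_individuals = 10000, n_snps = 6, ld_rho = 0,
                    seed = 21)
  panel <- simulate_panel(cfg)
  ld <- ld_matrix(panel, panel$variants$rsid)
  expect_equal(ld$r, t(ld$r))
  expect_equal(unname(diag(ld$r)), rep(1, 6))
  off <- ld$r[upper.tri(ld$r)]
  expect_true(max(abs(off)) < 0.05)
  one <- ld_matrix(panel, panel$variants$rsid[1])
  expect_equal(unname(one$r), matrix(1, 1, 1))
})

test_that("AR(1) panels approach the tetrachoric-induced adjacent correlation", {
  # brute-force oracle: huge independent re-simulation of one SNP pair
  rho <- 0.9
  maf <- 0.5
  set.seed(77)
  n_oracle <- 200000
  z1 <- rnorm(n_oracle)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n_oracle)
  h1 <- z1 < qnorm(maf)
  h2 <- z2 < qnorm(maf)
  # two haplotypes per individual
  g1 <- h1[1:(n_oracle / 2)] + h1[(n_oracle / 2 + 1):n_oracle]
  g2 <- h2[1:(n_oracle / 2)] + h2[(n_oracle / 2 + 1):n_oracle]
  r_oracle <- cor(g1, g2)

  cfg <- sim_config("null", n_individuals = 10000, n_snps = 10, ld_rho = rho,
                    maf_range = c(0.499, 0.5), seed = 31)
  panel <- simulate_panel(cfg)
  ld <- ld_matrix(panel, panel$variants$rsid)
  adj <- diag(ld$r[-1, -ncol(ld$r)])
  expect_true(all(abs(adj - r_oracle) < 0.1))
})

test_that("LD grouping reproduces transitive closure at the 0.8 threshold", {
  rs <- c("s1", "s2", "s3")
  mk_r <- function(r12, r23, r13) {
    r <- diag(3)
    r[1, 2] <- r[2, 1] <- r12
    r[2, 3] <- r[3, 2] <- r23
    r[1, 3] <- r[3, 1] <- r13
    dimnames(r) <- list(rs, rs)
    as_ld_view(r)
  }
  links <- tibble::tibble(
    snp = c("s1", "s2", "s3", "s1"),
    gene = c("A", "B", "C", "D"),
    source = "x"
  )
  # same rsid -> same group regardless of matrix
  same <- ld_group_links(links[c(1, 4), ], mk_r(0, 0, 0))
  expect_equal(length(unique(same$ld_group)), 1)
  # r2 just above vs just below threshold
  hi <- ld_group_links(links[1:2, ], mk_r(sqrt(0.81), 0, 0))
  expect_equal(length(unique(hi$ld_group)), 1)
  lo <- ld_group_links(links[1:2, ], mk_r(sqrt(0.79), 0, 0))
  expect_equal(length(unique(lo$ld_group)), 2)
  # chain s1-s2-s3 with weak s1-s3: one component via closure
  chain <- ld_group_links(links[1:3, ], mk_r(sqrt(0.9), sqrt(0.9), sqrt(0.5)))
  expect_equal(length(unique(chain$ld_group)), 1)
  # matches the brute-force component oracle
  adj <- matrix(c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE), 3)
  oracle <- components_oracle(adj)
  expect_equal(length(unique(oracle)), 1)
})

test_that("LD grouping is a partition and unknown SNPs become singletons", {
  set.seed(13)
  rs <- sprintf("v%02d", 1:8)
  ld <- toy_ld(rs, rho = 0.95)
  links <- tibble::tibble(
    snp = c(sample(rs, 12, replace = TRUE), "missing1"),
    gene = letters[1:13],
    source = "x"
  )
  grouped <- suppressWarnings(ld_group_links(links, ld))
  expect_equal(nrow(grouped), nrow(links))
  expect_true(all(!is.na(grouped$ld_group)))
  expect_false(grouped$snp_known[grouped$snp == "missing1"])
  # each SNP maps to exactly one group
  per_snp <- tapply(grouped$ld_group, grouped$snp, function(g) length(unique(g)))
  expect_true(all(per_snp == 1))
})
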