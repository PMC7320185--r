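# Reading, validation, harmonization and SNP filtering.

test_that("a well-formed table reads back intact with an empty drop log", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(toy_gwas(), path)
  out <- read_sumstats(path)
  expect_equal(nrow(out), 3)
  expect_true(all(drop_log(out) == 0))
  expect_equal(out$rsid, c("rs1", "rs2", "rs3"))
})

test_that("rows violating record invariants are dropped and counted", {
  tab <- toy_gwas()
  tab$se[2] <- 0
  out <- read_sumstats(tab)
  expect_equal(nrow(out), 2)
  expect_equal(unname(drop_log(out)["bad_se"]), 1L)

  tab <- toy_gwas()
  tab$maf[1] <- 0.7
  out <- read_sumstats(tab)
  expect_equal(unname(drop_log(out)["bad_maf"]), 1L)

  tab <- toy_gwas()
  tab$z[3] <- tab$z[3] + 1 # inconsistent with beta/se
  out <- read_sumstats(tab)
  expect_equal(unname(drop_log(out)["z_inconsistent"]), 1L)
})

test_that("z is filled as beta/se and p from the normal tail when missing", {
  tab <- toy_gwas(beta = c(0.1, 0.1, 0.1), se = c(0.05, 0.05, 0.05))
  tab$z <- NULL
  tab$pvalue <- NULL
  out <- read_sumstats(tab)
  expect_equal(out$z, rep(2, 3))
  expect_equal(out$pvalue, rep(2 * pnorm(-2), 3))
})

test_that("missing mandatory columns and empty tables raise named errors", {
  tab <- toy_gwas()
  tab$rsid <- NULL
  expect_error(read_sumstats(tab), "rsid")
  expect_error(read_sumstats(toy_gwas()[0, ]), "[Ee]mpty")
  # dialect maps a nonstandard column name
  tab <- toy_gwas()
  names(tab)[names(tab) == "pvalue"] <- "p"
  out <- read_sumstats(tab, dialect = sumstats_dialect(pvalue = "p"))
  expect_equal(out$pvalue, toy_gwas()$pvalue)
})

test_that("harmonization aligns swapped alleles by negating the eQTL effect", {
  gwas <- read_sumstats(toy_gwas())
  same <- read_sumstats(toy_eqtl(beta = c(0.3, 0.2, 0.1)))
  h <- harmonize_sumstats(gwas, same)
  expect_equal(h$b_eqtl, c(0.3, 0.2, 0.1))

  flipped_tab <- toy_eqtl(beta = c(0.3, 0.2, 0.1), a1 = "G", a2 = "A")
  h2 <- harmonize_sumstats(gwas, read_sumstats(flipped_tab))
  expect_equal(h2$b_eqtl, c(-0.3, -0.2, -0.1))
  expect_equal(h2$z_eqtl, -read_sumstats(flipped_tab)$z)

  mismatch <- toy_eqtl(a1 = "A", a2 = "C")
  expect_error(harmonize_sumstats(gwas, read_sumstats(mismatch)), "compatible")
  mixed <- dplyr::bind_rows(
    read_sumstats(toy_eqtl())[1:2, ],
    read_sumstats(toy_eqtl(a1 = "A", a2 = "C"))[3, ]
  )
  h3 <- harmonize_sumstats(gwas, mixed)
  expect_equal(nrow(h3), 2)
  expect_equal(unname(drop_log(h3)["incompatible_alleles"]), 1L)
})

test_that("harmonization is idempotent and a double flip is the identity", {
  gwas <- read_sumstats(toy_gwas())
  eqtl <- read_sumstats(toy_eqtl(beta = c(0.3, -0.2, 0.1)))
  h1 <- harmonize_sumstats(gwas, eqtl)
  # feed the aligned eQTL side back through: nothing changes
  realigned <- eqtl
  realigned$beta <- h1$b_eqtl
  realigned$z <- h1$z_eqtl
  h2 <- harmonize_sumstats(gwas, realigned)
  expect_equal(h2$b_eqtl, h1$b_eqtl)
  # flip alleles twice -> original record exactly
  flip_once <- toy_eqtl(beta = c(0.3, -0.2, 0.1), a1 = "G", a2 = "A")
  flip_once$beta <- -flip_once$beta
  flip_once$z <- -flip_once$z
  h3 <- harmonize_sumstats(gwas, read_sumstats(flip_once))
  expect_equal(h3$b_eqtl, h1$b_eqtl)
})

test_that("SNP filters use inclusive thresholds in both datasets", {
  h <- toy_harmonized(
    rsid = c("a", "b", "c", "d"),
    z_gwas = c(4, 3.163, 3.15, 5), # 3.163^2 > 10 > 3.15^2
    z_eqtl = c(3, 3, 3, 3)
  )
  h$maf_eqtl <- c(0.02, 0.03, 0.3, 0.3)
  f <- filter_snps(h, maf_min = 0.03, z2_min = 10)
  expect_false("a" %in% f$analysis$rsid) # maf below threshold in one dataset
  expect_true("b" %in% f$analysis$rsid) # maf exactly at threshold kept
  expect_true("c" %in% f$analysis$rsid)
  expect_false("c" %in% f$instruments$rsid) # z^2 = 9.9 below 10
  expect_true(all(f$instruments$rsid %in% f$analysis$rsid))
  # exact boundary z^2 = 10
  h2 <- toy_harmonized("e", z_gwas = sqrt(10), z_eqtl = 2)
  f2 <- filter_snps(h2)
  expect_true("e" %in% f2$instruments$rsid)
})

test_that("analysis set shrinks monotonically as the MAF filter tightens", {
  set.seed(5)
  h <- toy_harmonized(
    rsid = sprintf("s%02d", 1:40),
    z_gwas = rnorm(40), z_eqtl = rnorm(40),
    maf = runif(40, 0.01, 0.5)
  )
  h$maf_eqtl <- runif(40, 0.01, 0.5)
  sizes <- vapply(
    c(0.01, 0.03, 0.05, 0.1, 0.2),
    function(m) nrow(filter_snps(h, maf_min = m)$analysis),
    numeric(1)
  )
  expect_true(all(diff(sizes) <= 0))
})

test_that("top-SNP selection takes the argmin with deterministic ties", {
  h <- toy_harmonized(c("x", "y"), z_gwas = c(6, 5.7), z_eqtl = c(3, 3))
  f <- filter_snps(h)
  expect_equal(select_top_snp(f$instruments), "x")
  # equal p: position breaks the tie
  h2 <- toy_harmonized(c("far", "near"), z_gwas = c(6, 6), z_eqtl = c(3, 3),
                       pos = c(200, 100))
  expect_equal(select_top_snp(filter_snps(h2)$instruments), "near")
  # empty candidates: NA with a reason
  empty <- filter_snps(toy_harmonized("z", z_gwas = 1, z_eqtl = 1))$instruments
  top <- select_top_snp(empty)
  expect_true(is.na(top))
  expect_equal(attr(top, "reason"), "no instrument")
})
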