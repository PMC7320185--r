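# The packaged 51-locus evidence table and its accounting.

ev <- load_locus_evidence()

test_that("the packaged table loads, validates and matches spot-checked loci", {
  expect_s3_class(ev, "locus_evidence")
  expect_equal(nrow(ev$loci), 51)
  l1 <- ev$loci[ev$loci$locus_id == 1, ]
  expect_equal(l1$lead_rsid, "rs17114036")
  expect_equal(l1$chrom, "1")
  expect_equal(l1$lead_pos, 56962821)
  expect_equal(l1$conclusion, "causal")
  expect_equal(l1$verdict_genes[[1]], "PLPP3")
  l7 <- ev$loci[ev$loci$locus_id == 7, ]
  expect_equal(l7$conclusion, "none")
  expect_equal(length(l7$verdict_genes[[1]]), 0)
  # the two overlapping pairs are flagged reciprocally
  expect_equal(ev$loci$overlaps_locus[ev$loci$locus_id == 21], 22L)
  expect_equal(ev$loci$overlaps_locus[ev$loci$locus_id == 22], 21L)
  expect_equal(ev$loci$overlaps_locus[ev$loci$locus_id == 36], 37L)
  expect_equal(ev$loci$overlaps_locus[ev$loci$locus_id == 37], 36L)
})

test_that("schema violations are rejected with locus and field named", {
  bad <- ev
  bad$genes$braenne_score[which(!is.na(bad$genes$braenne_score))[1]] <- 99L
  expect_error(validate_locus_evidence(bad), "braenne_score")
  bad2 <- ev
  bad2$loci$conclusion[5] <- "maybe"
  expect_error(validate_locus_evidence(bad2), "conclusion")
  bad3 <- ev
  bad3$loci$verdict_genes[[which(bad3$loci$conclusion == "none")[1]]] <- "X"
  expect_error(validate_locus_evidence(bad3), "verdict")
})

test_that("the table round-trips through serialization unchanged", {
  path <- withr::local_tempfile(fileext = ".json")
  write_locus_evidence(ev, path)
  back <- load_locus_evidence(path)
  expect_equal(back$loci, ev$loci)
  expect_equal(back$genes, ev$genes)
})

test_that("conclusion accounting partitions the loci", {
  s <- summarize_conclusions(ev)
  expect_equal(sum(s$by_category$n_loci), 51)
  expect_equal(s$n_causal_loci + s$n_no_inference_loci, 51)
})

test_that("candidate multiplicity reproduces the single- and max-candidate loci", {
  cm <- candidate_multiplicity(ev)
  n_of <- function(id) cm$per_locus$n_candidates[cm$per_locus$locus_id == id]
  expect_equal(n_of(14), 1) # single proposed candidate
  expect_equal(n_of(29), 1)
  expect_equal(n_of(40), 1)
  expect_equal(n_of(7), 0) # no evidence at all
  expect_equal(n_of(50), 14) # the largest candidate set
})

test_that("alias normalization deduplicates within a locus", {
  # a synthetic two-record locus where one record's symbol is the other's alias
  toy <- ev
  toy$loci <- ev$loci[1, ]
  toy$genes <- tibble::tibble(
    locus_id = 1L,
    symbol = c("PLPP3", "PAP2B"),
    aliases = list(c("PAP2B", "PPAP2B"), character(0)),
    smr_heidi = c(TRUE, FALSE),
    literature = c("strong", NA),
    braenne_score = c(NA_integer_, 3L),
    lempiainen_score = c(NA_integer_, NA_integer_),
    vanderharst = FALSE, vanderharst_converging = FALSE,
    svishcheva_datasets = 0L,
    g_smr = list(integer(0)), g_braenne = list(integer(0)),
    g_lempiainen = list(integer(0)), g_vanderharst = list(integer(0)),
    sources = list("smr_heidi", "braenne")
  )
  cm <- candidate_multiplicity(toy)
  expect_equal(cm$per_locus$n_candidates, 1L)
})

test_that("arrow LD groups are reproducible from links plus r2 via ld_group_links", {
  # Synthetic stand-in for the per-SNP LD detail behind the arrow
  # annotations (the real SNP identities live in supplementary data not
  # packaged here): three SNPs where s1-s2 are in high LD and s3 is not,
  # mirroring a two-group locus like #34.
  rs <- c("s1", "s2", "s3")
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- sqrt(0.9)
  r[1, 3] <- r[3, 1] <- sqrt(0.2)
  r[2, 3] <- r[3, 2] <- sqrt(0.25)
  dimnames(r) <- list(rs, rs)
  links <- tibble::tibble(
    snp = c("s1", "s2", "s1", "s3", "s3"),
    gene = c("SIPA1", "MAP3K11", "RELA", "CTSW", "FIBP"),
    source = c("smr", "smr", "braenne", "smr", "smr")
  )
  grouped <- ld_group_links(links, as_ld_view(r), r2_min = 0.8)
  expect_equal(length(unique(grouped$ld_group)), 2)
  g1 <- grouped$ld_group[grouped$gene %in% c("SIPA1", "MAP3K11", "RELA")]
  g2 <- grouped$ld_group[grouped$gene %in% c("CTSW", "FIBP")]
  expect_equal(length(unique(g1)), 1)
  expect_equal(length(unique(g2)), 1)
  expect_false(unique(g1) == unique(g2))
})

test_that("Spearman score correlation handles identity, reversal and ties", {
  a <- setNames(c(1, 2, 3, 4, 5), letters[1:5])
  expect_equal(score_correlation(a, a), 1)
  expect_equal(score_correlation(a, setNames(rev(a), names(a))), -1)
  # rank-formula hand computation: d = (-1, 1, -1, 1, 0), rho = 1 - 24/120
  b <- setNames(c(2, 1, 4, 3, 5), letters[1:5])
  expect_equal(score_correlation(a, b), 0.8)
  # restriction set applies before ranking
  expect_equal(score_correlation(a, b, restrict = c("a", "b", "c")), 0.5)
  expect_error(score_correlation(a[1:2], b[1:2]), "Fewer than 3")
  # average ranks for ties: rho computed through cor's tie handling
  tied <- setNames(c(1, 1, 2, 3), letters[1:4])
  other <- setNames(c(4, 5, 6, 7), letters[1:4])
  expect_equal(
    score_correlation(tied, other),
    cor(rank(tied), rank(other))
  )
})

test_that("the heuristic scorer ranks multi-source genes above singletons", {
  ranked <- rank_locus_genes(ev$genes)
  l32 <- ranked[ranked$locus_id == 32, ]
  expect_equal(l32$symbol[1], "LIPA") # five sources beat SMR-only records
  expect_true(all(diff(l32$evidence_score) <= 0))
})
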