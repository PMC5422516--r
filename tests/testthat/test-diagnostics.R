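test_that("fixed substitutions are exactly the monomorphic contrasting columns", {
  aln <- make_aln(c(A1 = "ACGT", A2 = "ACGT", B1 = "ACCT", B2 = "ACCT"))
  taxa <- make_taxa(aln$samples)
  s <- suppressWarnings(find_fixed_substitutions(aln, taxa))
  expect_equal(s$position, 3L)
  expect_equal(s$base_a, "G")
  expect_equal(s$base_b, "C")
  # an ambiguity code in one parental sample disqualifies the column
  aln2 <- make_aln(c(A1 = "ACGT", A2 = "ACRT", B1 = "ACCT", B2 = "ACCT"))
  expect_equal(nrow(suppressWarnings(find_fixed_substitutions(aln2, taxa))), 0L)
  # a parental gap disqualifies too
  aln3 <- make_aln(c(A1 = "ACGT", A2 = "AC-T", B1 = "ACCT", B2 = "ACCT"))
  expect_equal(nrow(suppressWarnings(find_fixed_substitutions(aln3, taxa))), 0L)
})

test_that("strict and lenient missing-data modes differ only at N columns", {
  aln <- make_aln(c(A1 = "ACGT", A2 = "NCGT", B1 = "TCCT", B2 = "TCCT"))
  taxa <- make_taxa(aln$samples)
  strict <- suppressWarnings(find_fixed_substitutions(aln, taxa))
  expect_equal(strict$position, c(3L))  # column 1 lost to the parental N
  lenient <- suppressWarnings(
    find_fixed_substitutions(aln, taxa, max_missing_frac = 0.5))
  expect_equal(lenient$position, c(1L, 3L))
})

test_that("too few parental samples refuse; small panels warn", {
  aln <- make_aln(c(A1 = "ACGT", B1 = "ACCT", B2 = "ACCT"))
  taxa <- make_taxa(aln$samples)
  expect_error(find_fixed_substitutions(aln, taxa), ">= 2 samples")
  aln2 <- make_aln(c(A1 = "ACGT", A2 = "ACGT", B1 = "ACCT", B2 = "ACCT"))
  expect_warning(find_fixed_substitutions(aln2, make_taxa(aln2$samples)),
                 "weakly supported")
})

test_that("detected sites match a brute-force column scan on random alignments", {
  withr::local_seed(401)
  for (rep in 1:30) {
    aln <- random_parental_aln(n_a = sample(2:4, 1), n_b = sample(2:4, 1),
                               len = sample(10:50, 1))
    taxa <- make_taxa(aln$samples)
    got <- suppressWarnings(find_fixed_substitutions(aln, taxa))
    want <- oracle_fixed_sites(aln, taxa)
    expect_equal(got$position, want$position)
    expect_equal(got$base_a, want$base_a)
    expect_equal(got$base_b, want$base_b)
  }
})

test_that("swapping parental labels swaps bases but preserves the site set", {
  withr::local_seed(402)
  aln <- random_parental_aln(len = 40)
  taxa <- make_taxa(aln$samples)
  swapped <- taxa
  r <- swapped$assignments$role
  swapped$assignments$role <- ifelse(r == "parentA", "parentB",
                                     ifelse(r == "parentB", "parentA", r))
  a <- suppressWarnings(find_fixed_substitutions(aln, taxa))
  b <- suppressWarnings(find_fixed_substitutions(aln, swapped))
  expect_equal(a$position, b$position)
  expect_equal(a$base_a, b$base_b)
  expect_equal(a$base_b, b$base_a)
})

test_that("adding parental samples can only remove fixed sites", {
  withr::local_seed(403)
  for (rep in 1:10) {
    aln <- random_parental_aln(n_a = 4, n_b = 4, len = 30)
    sub_rows <- aln$seqs[c("A1", "A2", "B1", "B2")]
    sub <- make_aln(sub_rows)
    s_small <- suppressWarnings(
      find_fixed_substitutions(sub, make_taxa(sub$samples)))
    s_big <- suppressWarnings(
      find_fixed_substitutions(aln, make_taxa(aln$samples)))
    expect_true(all(s_big$position %in% s_small$position))
  }
})

test_that("fixed indels count maximal shared gap runs as single events", {
  rows <- c(A1 = "AAA------GG", A2 = "AAA------GG",
            B1 = "AAATCACATGG", B2 = "AAATCACATGG")
  aln <- make_aln(rows)
  ind <- suppressWarnings(find_fixed_indels(aln, make_taxa(aln$samples)))
  expect_equal(nrow(ind), 1L)
  expect_equal(ind$start, 4L)
  expect_equal(ind$end, 9L)
  expect_equal(ind$present_in, "parentB")
  expect_equal(ind$inserted_sequence, "TCACAT")
  # gap-free alignment: nothing
  aln2 <- make_aln(c(A1 = "ACGT", A2 = "ACGT", B1 = "TGCA", B2 = "TGCA"))
  expect_equal(nrow(suppressWarnings(
    find_fixed_indels(aln2, make_taxa(aln2$samples)))), 0L)
})

test_that("a gap run differing in length across gapped samples is not fixed", {
  # one parentA sample is gapped one column short of the others
  rows <- c(A1 = "AAA------GG", A2 = "AAA-----TGG",
            B1 = "AAATCACATGG", B2 = "AAATCACATGG")
  aln <- make_aln(rows)
  ind <- suppressWarnings(find_fixed_indels(aln, make_taxa(aln$samples)))
  expect_equal(nrow(ind), 0L)
})

test_that("additivity scoring reproduces the canonical verdicts", {
  aln <- make_aln(c(A1 = "ACGT", A2 = "ACGT", B1 = "TCCA", B2 = "TCCA",
                    C1 = "WCST", C2 = "ACGT", C3 = "TCCA", C4 = "ACNT"))
  taxa <- make_taxa(aln$samples)
  sites <- suppressWarnings(find_fixed_substitutions(aln, taxa))  # cols 1, 3, 4
  expect_equal(sites$position, c(1L, 3L, 4L))
  r1 <- score_additivity(sites, NULL, aln, "C1", taxa)
  expect_equal(r1$n_additive, 2L)  # W at 1, S at 3; T at 4 is parentA-like
  expect_equal(r1$n_A, 1L)
  r2 <- score_additivity(sites, NULL, aln, "C2", taxa)
  expect_equal(r2$n_A, 3L)
  expect_equal(r2$n_additive, 0L)
  r3 <- score_additivity(sites, NULL, aln, "C3", taxa)
  expect_equal(r3$n_B, 3L)
  r4 <- score_additivity(sites, NULL, aln, "C4", taxa)
  expect_equal(r4$n_other, 1L)  # N can never satisfy a two-parent test
  expect_equal(r4$n_additive + r4$n_A + r4$n_B + r4$n_other, nrow(sites))
  expect_error(score_additivity(sites, NULL, aln, "nope", taxa), "absent")
})

test_that("per-locus and grand totals add up", {
  s <- data.frame(locus_id = c("l1", "l1", "l2"), position = c(1L, 5L, 2L),
                  base_a = "A", base_b = "C")
  i <- data.frame(locus_id = "l2", start = 7L, end = 9L,
                  present_in = "parentA", inserted_sequence = "AAA")
  loci <- data.frame(locus_id = c("l1", "l2"),
                     compartment = c("nuclear", "chloroplast"))
  sm <- summarize_fixed_differences(s, i, loci)
  expect_equal(sm$total_substitutions, 3L)
  expect_equal(sm$total_indels, 1L)
  expect_equal(sm$per_locus$n_substitutions, c(2L, 1L))
  empty <- summarize_fixed_differences(s[0, ], i[0, ], loci)
  expect_equal(empty$total_substitutions, 0L)
  expect_equal(empty$total_indels, 0L)
})
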