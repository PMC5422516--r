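# build a minimal additivity report by hand
mk_report <- function(sample_id, locus, verdicts, indel_verdicts = character()) {
  structure(list(
    sample_id = sample_id,
    site_verdicts = data.frame(
      locus_id = rep(locus, length(verdicts)),
      position = seq_along(verdicts), state = "?", verdict = verdicts,
      stringsAsFactors = FALSE),
    indel_verdicts = data.frame(
      locus_id = rep(locus, length(indel_verdicts)),
      start = seq_along(indel_verdicts), end = seq_along(indel_verdicts),
      verdict = indel_verdicts, stringsAsFactors = FALSE),
    n_additive = sum(verdicts == "additive"),
    n_A = sum(verdicts == "parentA_like"),
    n_B = sum(verdicts == "parentB_like"),
    n_other = sum(verdicts == "other")), class = "additivity_report")
}

test_that("multilocus genotype patterns map to the expected classes", {
  AB <- rep("additive", 3)
  AA <- rep("parentA_like", 3)
  BB <- rep("parentB_like", 3)
  rep_of <- function(locus, v) mk_report("s", locus, v)
  cls <- function(reports) classify_sample(reports)$class

  expect_equal(cls(list(l1 = rep_of("l1", AB), l2 = rep_of("l2", AB),
                        l3 = rep_of("l3", AB))), "F1")
  expect_equal(cls(list(l1 = rep_of("l1", AB), l2 = rep_of("l2", AA))),
               "backcross_A")
  expect_equal(cls(list(l1 = rep_of("l1", AB), l2 = rep_of("l2", BB))),
               "backcross_B")
  expect_equal(cls(list(l1 = rep_of("l1", AA), l2 = rep_of("l2", AA))),
               "parentA")
  expect_equal(cls(list(l1 = rep_of("l1", BB))), "parentB")
  expect_equal(cls(list(l1 = rep_of("l1", AA), l2 = rep_of("l2", BB))),
               "complex")
  # a locus mixing additive and homozygous verdicts is internally
  # inconsistent -> complex
  expect_equal(cls(list(l1 = rep_of("l1", c("additive", "parentA_like",
                                            "additive")))), "complex")
  # 'other' verdicts above tolerance -> ambiguous
  expect_equal(cls(list(l1 = rep_of("l1", c("additive", "other")))),
               "ambiguous")
  expect_equal(classify_sample(
    list(l1 = rep_of("l1", c("additive", "other"))), tolerance = 1)$class,
    "F1")
  # heterozygous indel verdicts count as both-alleles-present evidence
  expect_equal(cls(list(l1 = mk_report("s", "l1", AB, "heterozygous"))), "F1")
  expect_error(classify_sample(list()), "no evaluable loci")
})

test_that("a single-locus AB/AA mixture cannot support a backcross call", {
  # within one locus a mixture is 'mixed' (complex), never backcross
  r <- mk_report("s", "l1", c("additive", "additive"))
  expect_equal(classify_sample(list(l1 = r))$class, "F1")
})

test_that("classification is invariant to locus order and label swap", {
  reports <- list(l1 = mk_report("s", "l1", rep("additive", 2)),
                  l2 = mk_report("s", "l2", rep("parentA_like", 2)))
  expect_equal(classify_sample(reports)$class,
               classify_sample(rev(reports))$class)
  # swapping A and B labels swaps the class accordingly
  swapped <- lapply(reports, function(r) {
    r$site_verdicts$verdict <- ifelse(
      r$site_verdicts$verdict == "parentA_like", "parentB_like",
      ifelse(r$site_verdicts$verdict == "parentB_like", "parentA_like",
             r$site_verdicts$verdict))
    r
  })
  expect_equal(classify_sample(swapped)$class, "backcross_B")
})

test_that("maternal assignment matches chloroplast haplotypes exactly", {
  inv <- structure(list(
    inventory = data.frame(
      taxon = c("pa", "pa", "pb", "pb"),
      locus_id = "cp",
      label = c("H1", "H2", "H1", "H2"),
      count = c(9L, 1L, 8L, 2L),
      sequence = c("AAAA", "AAAT", "CCCC", "CCCA"),
      stringsAsFactors = FALSE),
    pairs = NULL, cp_locus = "cp"), class = "haplotype_inventory")
  expect_equal(assign_maternal("CCCC", inv, "pa", "pb")$maternal, "parentB")
  expect_equal(assign_maternal("GGGG", inv, "pa", "pb")$maternal,
               "unassigned")
  expect_equal(assign_maternal("GGGG", inv, "pa", "pb")$note, "novel")
  # match to the rare single-carrier variant is still an assignment
  m <- assign_maternal("AAAT", inv, "pa", "pb")
  expect_equal(m$maternal, "parentA")
  expect_equal(m$note, "rare_variant")
  # a haplotype shared by both parents is uninformative
  inv$inventory$sequence[3] <- "AAAA"
  u <- assign_maternal("AAAA", inv, "pa", "pb")
  expect_equal(u$maternal, "unassigned")
  expect_equal(u$note, "uninformative")
})

test_that("clone groups partition candidates by multilocus identity", {
  pairs <- data.frame(
    sample_id = rep(c("c1", "c2", "c3"), each = 2),
    taxon = "cand",
    locus_id = rep(c("l1", "cp"), 3),
    hap1 = c("AA", "TT", "AA", "TT", "AA", "TA"),
    hap2 = c("CC", NA, "CC", NA, "CC", NA),
    status = rep(c("phased", "haploid"), 3),
    stringsAsFactors = FALSE)
  inv <- structure(list(inventory = NULL, pairs = pairs, cp_locus = "cp"),
                   class = "haplotype_inventory")
  cg <- assess_clonality(inv, c("c1", "c2", "c3"))
  expect_equal(cg$n_groups, 2L)
  expect_false(cg$single_clone)
  g <- stats::setNames(cg$groups$clone_group, cg$groups$sample_id)
  expect_equal(g[["c1"]], g[["c2"]])
  expect_false(g[["c1"]] == g[["c3"]])
  # every candidate in exactly one group
  expect_setequal(cg$groups$sample_id, c("c1", "c2", "c3"))
  expect_error(assess_clonality(inv, "c1"), "at least two")
})

test_that("the reference hybrids are one F1 clone group with parentB mother", {
  fx <- get_fixture()
  calls <- suppressWarnings(classify_all(fx$fx$alignments, fx$fx$taxa,
                                         max_het = 16))
  expect_equal(nrow(calls), 30L)
  expect_true(all(calls$class == "F1"))
  expect_true(all(calls$maternal == "parentB"))
  expect_true(all(calls$maternal_note == "rare_variant"))
  expect_equal(length(unique(calls$clone_group)), 1L)
})
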