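# small, fast study design used across these tests
small_config <- function(...) {
  loci <- data.frame(
    locus_id = c("n1", "n2", "n3", "pt"),
    compartment = c("nuclear", "nuclear", "nuclear", "chloroplast"),
    length = c(120L, 100L, 90L, 80L),
    n_substitutions = c(4L, 3L, 3L, 3L),
    stringsAsFactors = FALSE)
  loci$indel_lengths <- list(integer(), 4L, integer(), integer())
  hap_counts <- rbind(
    data.frame(taxon = "parentA", locus_id = c("n1", "n2", "n3", "cp"),
               n = c(2L, 1L, 1L, 1L)),
    data.frame(taxon = "parentB", locus_id = c("n1", "n2", "n3", "cp"),
               n = c(1L, 2L, 1L, 2L)))
  simulation_config(loci = loci, hap_counts = hap_counts,
                    n_parentA = 5L, n_parentB = 5L, ...)
}

test_that("the same seed reproduces the dataset byte for byte", {
  cfg <- small_config(n_f1_clones = 3L, n_backcross_A = 1L)
  s1 <- simulate_dataset(cfg, seed = 99)
  s2 <- simulate_dataset(cfg, seed = 99)
  expect_identical(lapply(s1$alignments, `[[`, "seqs"),
                   lapply(s2$alignments, `[[`, "seqs"))
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_dataset(cfg, seed = 100)
  expect_false(identical(lapply(s1$alignments, `[[`, "seqs"),
                         lapply(s3$alignments, `[[`, "seqs")))
})

test_that("generated parents carry the configured fixed differences", {
  cfg <- small_config(n_f1_clones = 2L)
  sim <- simulate_dataset(cfg, seed = 7)
  for (l in c("n1", "n2", "n3", "pt")) {
    s <- suppressWarnings(find_fixed_substitutions(sim$alignments[[l]],
                                                   sim$taxa))
    expect_equal(nrow(s),
                 cfg$loci$n_substitutions[cfg$loci$locus_id == l],
                 info = l)
    expect_equal(s$position, sim$diagnostic_positions[[l]])
  }
  ind <- suppressWarnings(find_fixed_indels(sim$alignments[["n2"]], sim$taxa))
  expect_equal(nrow(ind), 1L)
  expect_equal(ind$end - ind$start + 1L, 4L)
})

test_that("parental populations share no haplotypes", {
  sim <- simulate_dataset(small_config(n_f1_clones = 2L), seed = 21)
  inv <- suppressWarnings(build_inventory(sim$alignments, sim$taxa))
  expect_equal(nrow(shared_haplotypes(inv, "parentA", "parentB")), 0L)
  # configured haplotype counts are realised
  d <- inv$inventory
  expect_equal(sum(d$taxon == "parentA" & d$locus_id == "n1"), 2L)
  expect_equal(sum(d$taxon == "parentB" & d$locus_id == inv$cp_locus), 2L)
})

test_that("downstream verdicts recover the truth table exactly", {
  cfg <- small_config(n_f1_clones = 3L, n_f1_independent = 1L,
                      n_backcross_A = 1L, n_backcross_B = 1L,
                      n_parental_mislabeled = 1L)
  sim <- simulate_dataset(cfg, seed = 33)
  calls <- suppressWarnings(classify_all(sim$alignments, sim$taxa))
  m <- merge(calls, sim$truth, by = "sample_id")
  expect_equal(m$class, m$true_class)
  expect_equal(m$maternal, m$true_maternal)
  # clone groups agree as partitions (labels may differ)
  same <- function(g) outer(g, g, "==")
  expect_identical(same(m$clone_group), same(m$true_clone_group))
})

test_that("independent F1s from different draws split into clone groups", {
  cfg <- small_config(n_f1_clones = 3L, n_f1_independent = 2L)
  sim <- simulate_dataset(cfg, seed = 55)
  cand <- sim$truth$sample_id[sim$truth$role == "candidate"]
  inv <- suppressWarnings(build_inventory(sim$alignments, sim$taxa))
  cg <- assess_clonality(inv, cand)
  # oracle: pairwise comparison of raw rows across all loci
  key <- vapply(cand, function(s)
    paste(vapply(sim$alignments, function(a) a$seqs[[s]], ""), collapse = ";"),
    "")
  expect_equal(cg$n_groups, length(unique(key)))
  expect_identical(
    outer(cg$groups$clone_group, cg$groups$clone_group, "=="),
    outer(unname(key[cg$groups$sample_id]),
          unname(key[cg$groups$sample_id]), "=="))
})

test_that("zero candidates yield a parental-only dataset and empty calls", {
  cfg <- small_config(n_f1_clones = 0L)
  sim <- simulate_dataset(cfg, seed = 8)
  expect_false(any(sim$truth$role == "candidate"))
  calls <- suppressWarnings(classify_all(sim$alignments, sim$taxa))
  expect_equal(nrow(calls), 0L)
})

test_that("explicit diagnostic positions colliding with indels refuse", {
  cfg <- small_config(n_f1_clones = 1L)
  sim <- simulate_dataset(cfg, seed = 3)
  ind <- sim$indel_events
  bad <- cfg
  bad$diag_positions <- stats::setNames(
    list(ind$start[1] + 0:2), ind$locus_id[1])
  expect_error(simulate_dataset(bad, seed = 3), "collision")
})

test_that("simulated flow streams place the standard above a diploid sample", {
  ev <- simulate_flow(1.09, 2.5, cv = 0.03, n_events = 2000, seed = 5)
  pk <- find_peaks(ev, standard_window = c(230, 270), min_events = 100)
  expect_gt(pk$standard_mean, pk$sample_mean)
  expect_error(simulate_flow(1.09, 2.5, cv = 0.03, n_events = 500, seed = 5))
  expect_error(simulate_flow(1.09, seed = 5, cv = 0))
})

test_that("noise injection perturbs heterozygous consensus calls", {
  cfg_clean <- small_config(n_f1_clones = 2L)
  cfg_noisy <- small_config(n_f1_clones = 2L, dropout_rate = 1)
  clean <- simulate_dataset(cfg_clean, seed = 17)
  noisy <- simulate_dataset(cfg_noisy, seed = 17)
  cand <- clean$truth$sample_id[clean$truth$role == "candidate"][1]
  row_c <- clean$alignments[["n1"]]$seqs[[cand]]
  row_n <- noisy$alignments[["n1"]]$seqs[[cand]]
  expect_true(grepl("[RYSWKM]", row_c))
  # full dropout leaves no ambiguity codes in the consensus
  expect_false(grepl("[RYSWKM]", row_n))
})
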