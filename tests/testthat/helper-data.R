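# Small in-code builders used across the suite.

# Alignment from a named character vector of rows.
make_aln <- function(rows, locus_id = "L1", compartment = "nuclear") {
  locus_alignment(locus_id, compartment, rows)
}

# Taxon map for samples named A1.., B1.., C1.. (parentA / parentB /
# candidate by prefix).
make_taxa <- function(samples, het_indels = NULL) {
  role <- c(A = "parentA", B = "parentB", C = "candidate", O = "other")
  taxon_map(data.frame(
    sample_id = samples,
    taxon = paste0("taxon", substr(samples, 1, 1)),
    role = unname(role[substr(samples, 1, 1)]),
    stringsAsFactors = FALSE), het_indels)
}

# Random toy alignment with two parental taxa for property tests.
random_parental_aln <- function(n_a = 3L, n_b = 3L, len = 30L,
                                alphabet = c("A", "C", "G", "T", "R", "-")) {
  rows <- c(
    stats::setNames(replicate(n_a, paste(sample(alphabet, len, TRUE),
                                         collapse = "")),
                    paste0("A", seq_len(n_a))),
    stats::setNames(replicate(n_b, paste(sample(alphabet, len, TRUE),
                                         collapse = "")),
                    paste0("B", seq_len(n_b))))
  make_aln(rows)
}

# The reference dataset, built once per test run.
fixture_env <- new.env()
get_fixture <- function() {
  if (is.null(fixture_env$fx)) {
    fixture_env$fx <- cotoneaster_alignments()
    fixture_env$nuc <- Filter(function(a) a$compartment == "nuclear",
                              fixture_env$fx$alignments)
    fixture_env$cp <- concatenate_loci(fixture_env$fx$alignments,
                                       "chloroplast", locus_id = "cp")
    fixture_env$sites <- do.call(rbind, lapply(
      fixture_env$nuc, find_fixed_substitutions, taxa = fixture_env$fx$taxa))
    rownames(fixture_env$sites) <- NULL
    fixture_env$indels <- do.call(rbind, lapply(
      fixture_env$nuc, find_fixed_indels, taxa = fixture_env$fx$taxa))
    rownames(fixture_env$indels) <- NULL
  }
  fixture_env
}

# Cached haplotype inventory of the reference dataset (phasing cap raised
# to cover the 14 heterozygous DUF columns of the hybrid).
get_fixture_inv <- function() {
  if (is.null(fixture_env$inv)) {
    fx <- get_fixture()
    fixture_env$inv <- suppressWarnings(
      build_inventory(fx$fx$alignments, fx$fx$taxa, max_het = 16))
  }
  fixture_env$inv
}
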