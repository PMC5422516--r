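#' Run configuration
#'
#' A run is configured by a single YAML (or list) with paths and
#' thresholds; command-line callers can override individual fields.
#'
#' Fields: `loci` (TSV with columns `locus_id`, `compartment`, `file`),
#' `taxon_map` (TSV, see [read_taxon_map()]), `out_dir`; optional
#' `parent_a`/`parent_b` taxon labels; thresholds `min_per_taxon`
#' (default 2), `max_het` (12), `epsilon` (0), `tolerance` (0); ploidy
#' settings `standard_2c` (2.5), `reference_2c`, `reference_ploidy` (2),
#' `standard_window`; and `seed` where randomness is involved.
#'
#' @param path YAML file, or a named list of the same fields.
#' @param ... overrides applied on top of the file's values.
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path, ...) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  } else as.list(path)
  dots <- list(...)
  cfg[names(dots)] <- dots
  defaults <- list(min_per_taxon = 2L, max_het = 12L, epsilon = 0L,
                   tolerance = 0L, standard_2c = 2.5, reference_ploidy = 2L)
  for (f in names(defaults))
    if (is.null(cfg[[f]])) cfg[[f]] <- defaults[[f]]
  if (is.character(path)) {
    base <- dirname(path)
    for (f in c("loci", "taxon_map"))
      if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
        cfg[[f]] <- file.path(base, cfg[[f]])
  }
  structure(cfg, class = "run_config")
}

load_inputs <- function(config) {
  for (f in c("loci", "taxon_map"))
    if (is.null(config[[f]]) || !file.exists(config[[f]]))
      stop("input file missing: ", f, " (", config[[f]], ")")
  loci <- utils::read.delim(config$loci, stringsAsFactors = FALSE,
                            check.names = FALSE)
  taxa <- read_taxon_map(config$taxon_map)
  base <- dirname(config$loci)
  alignments <- stats::setNames(lapply(seq_len(nrow(loci)), function(i) {
    p <- loci$file[i]
    if (!file.exists(p)) p <- file.path(base, loci$file[i])
    read_locus_fasta(p, loci$locus_id[i], loci$compartment[i])
  }), loci$locus_id)
  list(loci = loci, taxa = taxa, alignments = alignments)
}

#' Run the full diagnostic pipeline
#'
#' Detects fixed substitutions and indels per nuclear locus and on the
#' concatenated chloroplast system, scores every candidate for additivity,
#' builds haplotype inventories, classifies candidates (class, maternal
#' parent, clone groups), exports per-locus haplotype networks, and writes
#' a JSON summary with the headline counts.
#'
#' @param config a [read_run_config()] result, a YAML path, or a list.
#' @return the summary list, invisibly; all reports are written under
#'   `config$out_dir`.
#' @export
run_diagnose <- function(config) {
  if (!inherits(config, "run_config")) config <- read_run_config(config)
  inp <- load_inputs(config)
  out <- config$out_dir %||% "."
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  comp <- vapply(inp$alignments, `[[`, "", "compartment")
  nuc <- inp$alignments[comp == "nuclear"]
  cp <- inp$alignments[comp == "chloroplast"]
  analysis <- nuc
  if (length(cp))
    analysis$cp <- concatenate_loci(cp, locus_id = "cp")

  sites <- list(); indels <- list()
  for (l in names(analysis)) {
    sites[[l]] <- find_fixed_substitutions(analysis[[l]], inp$taxa,
                                           config$min_per_taxon)
    indels[[l]] <- find_fixed_indels(analysis[[l]], inp$taxa,
                                     config$min_per_taxon)
    message(sprintf("[diagnose] %s: %d fixed substitutions, %d fixed indels",
                    l, nrow(sites[[l]]), nrow(indels[[l]])))
  }
  all_sites <- do.call(rbind, sites)
  all_indels <- do.call(rbind, c(indels, list(make.row.names = FALSE)))
  meta <- data.frame(
    locus_id = names(analysis),
    compartment = vapply(analysis, `[[`, "", "compartment"),
    stringsAsFactors = FALSE)
  summ <- summarize_fixed_differences(all_sites, all_indels, meta)
  utils::write.table(all_sites, file.path(out, "diagnostic_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(all_indels, file.path(out, "diagnostic_indels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # additivity of every candidate at the nuclear diagnostics
  candidates <- samples_of(inp$taxa, "candidate")
  nuc_sites <- all_sites[all_sites$locus_id %in% names(nuc), , drop = FALSE]
  nuc_indels <- all_indels[all_indels$locus_id %in% names(nuc), , drop = FALSE]
  add_rows <- lapply(candidates, function(s) {
    r <- score_additivity(nuc_sites, nuc_indels, nuc, s, inp$taxa)
    data.frame(sample_id = s, n_additive = r$n_additive, n_A = r$n_A,
               n_B = r$n_B, n_other = r$n_other,
               indel_het = sum(r$indel_verdicts$verdict == "heterozygous"),
               stringsAsFactors = FALSE)
  })
  additivity <- do.call(rbind, add_rows)
  if (!is.null(additivity))
    utils::write.table(additivity, file.path(out, "additivity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  inv <- build_inventory(inp$alignments, inp$taxa,
                         max_het = config$max_het)
  utils::write.table(inv$inventory, file.path(out, "haplotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  calls <- classify_all(inp$alignments, inp$taxa,
                        parentA_taxon = config$parent_a,
                        parentB_taxon = config$parent_b,
                        min_per_taxon = config$min_per_taxon,
                        max_het = config$max_het,
                        tolerance = config$tolerance)
  utils::write.table(calls, file.path(out, "calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  for (l in names(analysis)) {
    reg <- indels[[l]][c("start", "end")]
    net <- tryCatch(
      network_from_inventory(inv, l, if (nrow(reg)) reg else NULL,
                             epsilon = config$epsilon),
      error = function(e) NULL)
    if (is.null(net)) next
    export_network(net, file.path(out, paste0("network_", l, ".tsv")), "tsv")
    export_network(net, file.path(out, paste0("network_", l, ".dot")), "dot")
  }

  nuclear_subs <- sum(all_sites$locus_id %in% names(nuc))
  cp_subs <- sum(all_sites$locus_id == "cp")
  summary <- list(
    nuclear_fixed_substitutions = nuclear_subs,
    cp_fixed_substitutions = cp_subs,
    total_fixed_substitutions = nuclear_subs + cp_subs,
    indel_events = nrow(all_indels),
    n_candidates = length(candidates),
    classes = as.list(table(calls$class)),
    maternal = as.list(table(calls$maternal)),
    n_clone_groups = if (nrow(calls)) length(unique(calls$clone_group)) else 0L,
    per_locus = summ$per_locus)
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  message(sprintf(
    "[diagnose] totals: %d fixed substitutions (%d nuclear + %d cp), %d indel events",
    summary$total_fixed_substitutions, nuclear_subs, cp_subs,
    summary$indel_events))
  invisible(summary)
}

#' Simulate a dataset and write it to a directory
#'
#' @param config a [simulation_config()] (or NULL for the defaults).
#' @param out_dir output directory.
#' @param seed integer seed.
#' @return the output directory, invisibly.
#' @export
run_simulate <- function(config = NULL, out_dir, seed) {
  if (is.null(config)) config <- simulation_config()
  sim <- simulate_dataset(config, seed)
  write_dataset(sim, out_dir)
  message(sprintf("[simulate] wrote %d loci x %d samples to %s",
                  nrow(config$loci), nrow(sim$truth), out_dir))
  invisible(out_dir)
}

#' Build and export haplotype networks for every locus of a dataset
#'
#' @inheritParams run_diagnose
#' @return invisibly, the list of networks.
#' @export
run_network <- function(config) {
  if (!inherits(config, "run_config")) config <- read_run_config(config)
  inp <- load_inputs(config)
  out <- config$out_dir %||% "."
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  inv <- build_inventory(inp$alignments, inp$taxa, max_het = config$max_het)
  nets <- list()
  for (l in unique(inv$inventory$locus_id)) {
    aln <- if (l == "cp")
      concatenate_loci(inp$alignments, "chloroplast", locus_id = "cp")
    else inp$alignments[[l]]
    reg <- find_fixed_indels(aln, inp$taxa, config$min_per_taxon)
    nets[[l]] <- network_from_inventory(inv, l,
                                        if (nrow(reg)) reg[c("start", "end")]
                                        else NULL,
                                        epsilon = config$epsilon)
    export_network(nets[[l]], file.path(out, paste0("network_", l, ".tsv")),
                   "tsv")
    export_network(nets[[l]], file.path(out, paste0("network_", l, ".dot")),
                   "dot")
    message(sprintf("[network] %s: %d nodes, %d edges", l,
                    nrow(nets[[l]]$nodes), nrow(nets[[l]]$edges)))
  }
  invisible(nets)
}

#' Call ploidy for a set of flow-cytometry event CSVs
#'
#' Each CSV must have a column `fl_area` (and optionally `cluster`); the
#' sample named by `reference_sample` anchors the ploidy scale with
#' `reference_ploidy`, unless `reference_2c` is given directly.
#'
#' @param files named character vector of CSV paths (names = sample IDs).
#' @param standard_window channel window of the internal-standard peak.
#' @param standard_2c internal-standard 2C in pg (default 2.5).
#' @param reference_2c known 2C anchoring the ploidy scale, or `NULL` to
#'   use `reference_sample`'s estimate.
#' @param reference_sample sample whose 2C is the reference.
#' @param reference_ploidy ploidy of the reference (default 2).
#' @param out_dir optional directory for the calls TSV.
#' @return data.frame `sample`, `sample_2c`, `cv`, `ploidy`, `flag`.
#' @export
run_ploidy <- function(files, standard_window = NULL, standard_2c = 2.5,
                       reference_2c = NULL, reference_sample = NULL,
                       reference_ploidy = 2L, out_dir = NULL) {
  est <- lapply(files, function(f) {
    ev <- utils::read.csv(f)
    pk <- find_peaks(ev, standard_window)
    list(c2 = estimate_2c(pk$sample_mean, pk$standard_mean, standard_2c),
         cv = pk$sample_cv)
  })
  if (is.null(reference_2c)) {
    if (is.null(reference_sample))
      stop("give reference_2c or reference_sample")
    reference_2c <- est[[reference_sample]]$c2
  }
  calls <- do.call(rbind, lapply(names(est), function(s) {
    pc <- infer_ploidy(est[[s]]$c2, reference_2c, reference_ploidy)
    data.frame(sample = s, sample_2c = pc$sample_2c, cv = est[[s]]$cv,
               ploidy = pc$ploidy,
               flag = if (pc$low_confidence) "low_confidence" else "",
               stringsAsFactors = FALSE)
  }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(calls, file.path(out_dir, "ploidy_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  calls
}
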