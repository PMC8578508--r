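#' Run configuration for an end-to-end analysis
#'
#' Collects every tunable threshold of the pipeline with its default in one
#' structure so a run is fully described by (config, seed): the
#' significance rule (0.5 Da absolute, 2.3x SD), the EX1 mode-separation
#' threshold, the region-calling parameters and the XL concordance window.
#'
#' @param state_a,state_b state labels compared as `state_a - state_b`.
#' @param abs_threshold,sd_multiplier,sd_mode see [significance_config()].
#' @param ex1_delta_min EX1 mode separation threshold, Da (default 2).
#' @param region_min_abs per-residue threshold for region calling,
#'   Da/residue (`NULL`, the default, applies the half-maximum rule of
#'   [call_protected_regions()]).
#' @param region_min_run minimum region length, residues (default 5).
#' @param concordance_window XL/HDX concordance slack, residues
#'   (default 5).
#' @param seed integer seed recorded in all outputs.
#' @return Object of class `run_config`.
#' @export
run_config <- function(state_a = "unphos", state_b = "phos",
                       abs_threshold = 0.5, sd_multiplier = 2.3,
                       sd_mode = "per_peptide", ex1_delta_min = 2,
                       region_min_abs = NULL, region_min_run = 5L,
                       concordance_window = 5L, seed = 1L) {
  structure(list(state_a = state_a, state_b = state_b,
                 significance = significance_config(abs_threshold,
                                                    sd_multiplier, sd_mode),
                 ex1_delta_min = ex1_delta_min,
                 region_min_abs = region_min_abs,
                 region_min_run = as.integer(region_min_run),
                 concordance_window = as.integer(concordance_window),
                 seed = as.integer(seed)),
            class = "run_config")
}

# stable content hash of the configuration (hex md5 of its deparsed form)
.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}

#' End-to-end differential HDX report
#'
#' Runs the full pipeline on an uptake table (measured or simulated):
#' differential analysis between the two configured states, EX1 flag
#' propagation, residue projection, protected-region calling, and — when
#' cross-link sets are supplied — classification and HDX concordance.
#' Writes `differential_peptides.csv`, `residue_profile.csv`,
#' `protected_regions.csv`, optional `crosslink_classification.csv`, and a
#' `run_manifest.json` carrying the seed, the config hash and record
#' counts at each stage. Outputs are byte-stable for a fixed
#' (input, config) pair.
#'
#' @param records uptake table (see [read_uptake_table()]).
#' @param map peptide map used for the residue projection.
#' @param construct the construct (defaults to the map's).
#' @param config a [run_config()].
#' @param ex1_peptides optional EX1-flagged peptides (`Start`, `End`).
#' @param monomer_links,dimer_links optional [crosslinks()] tables.
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @return List of class `hdx_report` with `differential`, `profile`,
#'   `regions`, `xl` (or `NULL`), `concordance` (or `NA`), `manifest`.
#' @export
hdx_report <- function(records, map, construct = attr(map, "construct"),
                       config = run_config(), ex1_peptides = NULL,
                       monomer_links = NULL, dimer_links = NULL,
                       out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  diff <- hdx_differential(records, config$state_a, config$state_b,
                           config = config$significance,
                           ex1_peptides = ex1_peptides)
  profile <- residue_projection(diff, map, construct)
  regions <- call_protected_regions(profile, min_abs = config$region_min_abs,
                                    min_run = config$region_min_run)
  xl <- NULL
  concordance <- NA_real_
  if (!is.null(monomer_links) && !is.null(dimer_links)) {
    xl <- assert_self_links_inter(classify_by_sample(monomer_links,
                                                     dimer_links))
    concordance <- hdx_concordance(xl$inter, regions,
                                   window = config$concordance_window)
  }
  manifest <- list(
    seed = config$seed,
    config_hash = .config_hash(config),
    states = c(config$state_a, config$state_b),
    n_records = nrow(records),
    n_peptides = nrow(diff$by_peptide),
    n_significant_timepoints = sum(diff$by_timepoint$significant),
    n_ex1_flagged = sum(diff$by_peptide$ex1_flag),
    n_residues_covered = sum(profile$covered),
    n_regions_called = nrow(regions),
    n_inter_links = if (is.null(xl)) NA_integer_ else nrow(xl$inter),
    concordance = concordance
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(diff$by_peptide,
                     file.path(out_dir, "differential_peptides.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(profile),
                     file.path(out_dir, "residue_profile.csv"),
                     row.names = FALSE)
    utils::write.csv(regions, file.path(out_dir, "protected_regions.csv"),
                     row.names = FALSE)
    if (!is.null(xl)) {
      tab <- rbind(cbind(class = "intra", as.data.frame(xl$intra)),
                   cbind(class = "inter", as.data.frame(xl$inter)),
                   cbind(class = "shared", as.data.frame(xl$shared)))
      utils::write.csv(tab,
                       file.path(out_dir, "crosslink_classification.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(manifest,
                         file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  structure(list(differential = diff, profile = profile, regions = regions,
                 xl = xl, concordance = concordance, manifest = manifest),
            class = "hdx_report")
}

#' @export
print.hdx_report <- function(x, ...) {
  m <- x$manifest
  cat("<hdx_report> ", m$states[1], " - ", m$states[2], "\n",
      "  peptides: ", m$n_peptides, " (", m$n_significant_timepoints,
      " significant peptide-timepoints, ", m$n_ex1_flagged,
      " EX1-flagged)\n",
      "  residues covered: ", m$n_residues_covered,
      ", regions called: ", m$n_regions_called, "\n", sep = "")
  if (!is.na(m$concordance))
    cat("  XL/HDX concordance:", round(m$concordance, 3), "\n")
  invisible(x)
}

#' Simulate a complete two-state differential HDX study
#'
#' Convenience generator used throughout the test-suite and examples: a
#' construct with a designated protected segment, a two-state exchange
#' model in which `state_a` (e.g. unphosphorylated) exchanges freely in
#' that segment while `state_b` is protected `fold_change`-fold more, an
#' overlapping peptide map, and triplicate uptake tables for both states.
#'
#' @param n_residues construct length (default 150).
#' @param protected_start,protected_end the segment protected in
#'   `state_b` (defaults 71 and 92: a 22-residue segment).
#' @param fold_change protection-factor increase in `state_b`
#'   (default 20).
#' @param base_protection protection factor elsewhere (default 50).
#' @param ex1 optional EX1 segment spec for `state_a`
#'   (data.frame `start`, `end`, `k_op`).
#' @param protocol a [labeling_protocol()].
#' @param seed RNG seed controlling the sequence, rates, map and noise.
#' @return List with `construct`, `model`, `map`, `records` (both states
#'   row-bound), `truth` (the protected interval).
#' @export
simulate_two_state_study <- function(n_residues = 150L,
                                     protected_start = 71L,
                                     protected_end = 92L,
                                     fold_change = 20,
                                     base_protection = 50,
                                     ex1 = NULL,
                                     protocol = labeling_protocol(seed = seed),
                                     seed = 1L) {
  aa <- setdiff(names(.aa_avg), "P")  # proline-free for clean amide counts
  seq <- with_seed(seed, paste(sample(aa, n_residues, replace = TRUE),
                               collapse = ""))
  cs <- construct(seq, name = "synthetic_construct")
  prot_a <- rep(base_protection, n_residues)
  prot_b <- prot_a
  prot_b[protected_start:protected_end] <-
    base_protection * fold_change
  model <- exchange_model(cs, states = list(
    unphos = list(protection = prot_a, ex1 = ex1),
    phos = list(protection = prot_b)), seed = seed + 1L)
  map <- generate_peptide_map(cs, length_range = c(6, 20), redundancy = 3,
                              seed = seed + 2L)
  rec_a <- simulate_uptake(model, map, protocol, "unphos")
  rec_b <- simulate_uptake(model, map, protocol, "phos")
  records <- validate_uptake_table(rbind(rec_a, rec_b))
  list(construct = cs, model = model, map = map, records = records,
       truth = c(start = protected_start, end = protected_end))
}

#' Jaccard overlap of two residue intervals
#' @param a,b intervals `c(start, end)`.
#' @return |intersection| / |union| over residue sets.
#' @export
interval_jaccard <- function(a, b) {
  ia <- a[1]:a[2]; ib <- b[1]:b[2]
  length(intersect(ia, ib)) / length(union(ia, ib))
}
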