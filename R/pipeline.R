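# End-to-end orchestration: the discovery phase runs the trio cascade on
# files and writes a kept-variant VCF, a trace TSV and a summary JSON;
# the replication phase computes the case/control statistics table from
# a genotype counts file.

REPLICATION_TESTS <- c("hwe", "fisher2x3", "allele", "armitage")

#' Load and validate a run configuration
#'
#' A configuration is a named list (or a YAML file containing one) with
#' input paths and settings. Discovery uses `vcf`, `pedigree`,
#' `annotations`, `network_edges`, `disease_genes`, optional
#' `quality_key` and a `cascade` sub-list of [cascade_config()]
#' overrides. Replication uses `counts`, `tests`, `mc_reps`, `seed`.
#' Both use `out_dir`.
#'
#' @param config A named list or path to a YAML file.
#' @return A validated `run_config` list.
#' @export
load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("Config must be a named list or a YAML path")
  defaults <- list(quality_key = "GQ", cascade = list(),
                   tests = REPLICATION_TESTS, mc_reps = 10000L, seed = 1L,
                   out_dir = NULL)
  config <- modifyList(defaults, config)
  bad_tests <- setdiff(config$tests, REPLICATION_TESTS)
  if (length(bad_tests) > 0L) {
    abort(paste0("Unknown test name(s): ", paste(bad_tests, collapse = ", "),
                 " (available: ", paste(REPLICATION_TESTS, collapse = ", "),
                 ")"))
  }
  for (key in c("vcf", "pedigree", "annotations", "network_edges",
                "disease_genes", "counts")) {
    if (!is.null(config[[key]]) && !file.exists(config[[key]])) {
      abort(paste0("Config path does not exist: ", key, " = ", config[[key]]))
    }
  }
  config$cascade <- do.call(cascade_config, config$cascade)
  structure(config, class = "run_config")
}

run_info <- function(config) {
  list(
    package = "trioscreen",
    version = as.character(utils::packageVersion("trioscreen")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config))
  )
}

#' Run the discovery phase: trio cascade over files
#'
#' Reads the VCF, pedigree, annotation table and gene network named in
#' the config, runs [run_cascade()], and (when `out_dir` is set) writes
#' `kept.vcf`, `trace.tsv`, `summary.json` and `run_info.json`.
#'
#' @param config A [load_run_config()] input (list or YAML path) with the
#'   discovery keys set.
#' @return The `cascade_result`, invisibly.
#' @export
run_discovery <- function(config) {
  config <- load_run_config(config)
  for (key in c("vcf", "pedigree", "annotations", "network_edges",
                "disease_genes")) {
    if (is.null(config[[key]])) abort(paste0("Discovery needs config$", key))
  }
  pedigree <- read_pedigree(config$pedigree)
  variants <- read_trio_vcf(config$vcf, pedigree,
                            quality_key = config$quality_key)
  annotations <- read_annotations(config$annotations)
  network <- read_gene_network(config$network_edges, config$disease_genes)
  result <- run_cascade(variants, annotations, pedigree, network,
                        config$cascade)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trio_vcf(result$kept, file.path(config$out_dir, "kept.vcf"),
                   quality_key = config$quality_key)
    readr::write_tsv(result$trace, file.path(config$out_dir, "trace.tsv"),
                     progress = FALSE)
    jsonlite::write_json(
      list(n_input = if (nrow(result$summary)) result$summary$n_in[1L] else 0L,
           n_kept = nrow(result$kept),
           stages = result$summary),
      file.path(config$out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA
    )
    jsonlite::write_json(run_info(config),
                         file.path(config$out_dir, "run_info.json"),
                         auto_unbox = TRUE)
  }
  invisible(result)
}

#' Read a replication genotype-counts file
#'
#' Tab-separated with columns `variant`, `population`, `arm`
#' (`case`/`control`), `n_hom_ref`, `n_het`, `n_hom_alt`.
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_counts <- function(path) {
  counts <- read_tsv_quiet(path, col_types = readr::cols(
    variant = readr::col_character(), population = readr::col_character(),
    arm = readr::col_character(), n_hom_ref = readr::col_integer(),
    n_het = readr::col_integer(), n_hom_alt = readr::col_integer()
  ))
  need <- c("variant", "population", "arm", "n_hom_ref", "n_het", "n_hom_alt")
  if (!all(need %in% names(counts))) {
    abort(paste("Counts file needs columns:", paste(need, collapse = ", ")))
  }
  counts
}

replicate_one <- function(counts, tests, mc_reps, seed) {
  # counts: rows of one (variant, population) group
  label <- paste(counts$variant[1L], counts$population[1L])
  arms <- split(counts, counts$arm)
  n_of <- function(arm) {
    if (is.null(arms[[arm]])) 0L else
      sum(arms[[arm]][, c("n_hom_ref", "n_het", "n_hom_alt")])
  }
  hwe_p <- function(arm) {
    if (n_of(arm) == 0L || !"hwe" %in% tests) return(NA_real_)
    hwe_chisq(arms[[arm]])$p_value
  }
  out <- tibble::tibble(
    variant = counts$variant[1L], population = counts$population[1L],
    n_case = n_of("case"), n_control = n_of("control"),
    hwe_case_p = hwe_p("case"), hwe_control_p = hwe_p("control"),
    fisher_genotype_p = NA_real_, fisher_allele_p = NA_real_,
    armitage_p = NA_real_, armitage_mc_p = NA_real_
  )
  if (n_of("case") == 0L || n_of("control") == 0L) {
    warn(paste0("Skipping association tests for ", label,
                ": an arm has no samples"))
    return(out)
  }
  tab <- genotype_counts(
    as.integer(arms[["case"]][1L, c("n_hom_ref", "n_het", "n_hom_alt")]),
    as.integer(arms[["control"]][1L, c("n_hom_ref", "n_het", "n_hom_alt")])
  )
  if ("fisher2x3" %in% tests) {
    out$fisher_genotype_p <- fisher_exact_2x3(tab)$p_value
  }
  if ("allele" %in% tests) {
    out$fisher_allele_p <- fisher_exact_allele_2x2(tab)$p_value
  }
  if ("armitage" %in% tests) {
    out$armitage_p <- armitage_trend(tab, mode = "asymptotic")$p_value
    out$armitage_mc_p <- armitage_trend(tab, mode = "monte_carlo",
                                        reps = mc_reps, seed = seed)$p_value
  }
  out
}

#' Run the replication phase: per-variant case/control statistics
#'
#' For every `(variant, population)` group in the counts file, computes
#' per-arm genotype frequencies, per-arm HWE p-values, the exact 2x3
#' genotype and 2x2 allele Fisher p-values and the Armitage trend
#' p-values (asymptotic and Monte-Carlo), then flags rows whose 2x3
#' Fisher p-value is below 0.05 — and nothing else: no multiplicity
#' adjustment is applied. Groups with an empty arm keep their HWE
#' results and skip the association tests with a warning.
#'
#' @param config A [load_run_config()] input with `counts` set (plus
#'   `tests`, `mc_reps`, `seed`, `out_dir`).
#' @return A tibble, one row per (variant, population); also written to
#'   `replication.tsv` under `out_dir` when set.
#' @export
run_replication <- function(config) {
  config <- load_run_config(config)
  if (is.null(config$counts)) abort("Replication needs config$counts")
  counts <- read_counts(config$counts)
  groups <- split(counts, paste(counts$variant, counts$population))
  rows <- purrr::map(groups, replicate_one, tests = config$tests,
                     mc_reps = config$mc_reps, seed = config$seed)
  result <- dplyr::bind_rows(rows) |>
    dplyr::mutate(significant = !is.na(.data$fisher_genotype_p) &
                    .data$fisher_genotype_p < 0.05) |>
    dplyr::arrange(.data$variant, .data$population)
  freq <- counts |>
    dplyr::rowwise() |>
    dplyr::mutate(n_arm = sum(.data$n_hom_ref, .data$n_het,
                              .data$n_hom_alt)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$n_arm > 0L) |>
    dplyr::mutate(
      pct_hom_ref = 100 * .data$n_hom_ref / .data$n_arm,
      pct_het = 100 * .data$n_het / .data$n_arm,
      pct_hom_alt = 100 * .data$n_hom_alt / .data$n_arm
    ) |>
    dplyr::select("variant", "population", "arm", dplyr::starts_with("pct_")) |>
    tidyr::pivot_wider(names_from = "arm",
                       values_from = dplyr::starts_with("pct_"))
  result <- dplyr::left_join(result, freq, by = c("variant", "population"))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(result, file.path(config$out_dir, "replication.tsv"),
                     progress = FALSE)
    jsonlite::write_json(run_info(config),
                         file.path(config$out_dir, "run_info.json"),
                         auto_unbox = TRUE)
  }
  result
}
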