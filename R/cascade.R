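# The five-stage trio prioritization cascade. Stages are applied in a
# fixed order (confidence, common variants, predicted deleterious,
# genetic model, biological context); each stage is a pure predicate
# returning a per-variant decision tibble, and the trace records the
# first failing stage only.

CASCADE_STAGES <- c("confidence", "common_variants", "deleteriousness",
                    "genetic_model", "biological_context")

#' Call accuracy implied by a Phred-scaled quality
#'
#' Phred quality is \eqn{-10 \log_{10}} of the error probability, so the
#' implied percent call accuracy is \eqn{100 (1 - 10^{-q/10})}; the
#' cascade's default confidence threshold of 20 corresponds to 99%.
#'
#' @param quality Numeric vector of Phred-scaled qualities.
#' @return Percent call accuracy.
#' @examples
#' phred_accuracy(20)  # 99
#' @export
phred_accuracy <- function(quality) {
  100 * (1 - 10^(-quality / 10))
}

#' Cascade configuration
#'
#' Thresholds of the prioritization cascade. Defaults follow the
#' autosomal-dominant trio design: Phred call quality at least 20 (99%
#' call accuracy), population allele frequency below 3% in all panels,
#' splice-region changes up to 2 bases into the intron, alternate alleles
#' carried by at least 2 case samples at the gene level and by no control
#' sample at the variant level.
#'
#' @param quality_threshold Minimum Phred call quality (default 20).
#' @param af_cutoff Population allele-frequency cutoff as a fraction
#'   (default 0.03); variants at or above it in any panel are removed.
#' @param splice_max_offset Maximum intronic offset (bases) for a
#'   splice-region change to count as deleterious (default 2).
#' @param min_case_samples Minimum distinct case carriers per gene
#'   (default 2).
#' @param max_control_samples Maximum control carriers per variant
#'   (default 0).
#' @param quality_group_rule `"any_group"` (default): carrier calls must
#'   clear the quality threshold within cases or within controls;
#'   `"all_groups"`: within both.
#' @return A `cascade_config` list.
#' @export
cascade_config <- function(quality_threshold = 20,
                           af_cutoff = 0.03,
                           splice_max_offset = 2,
                           min_case_samples = 2L,
                           max_control_samples = 0L,
                           quality_group_rule = c("any_group", "all_groups")) {
  quality_group_rule <- match.arg(quality_group_rule)
  vals <- c(quality_threshold, af_cutoff, splice_max_offset,
            min_case_samples, max_control_samples)
  if (any(is.na(vals)) || any(vals < 0)) {
    abort("All cascade thresholds must be non-negative")
  }
  structure(
    list(quality_threshold = quality_threshold, af_cutoff = af_cutoff,
         splice_max_offset = splice_max_offset,
         min_case_samples = as.integer(min_case_samples),
         max_control_samples = as.integer(max_control_samples),
         quality_group_rule = quality_group_rule),
    class = "cascade_config"
  )
}

decision_tibble <- function(variant_id, kept, reason) {
  tibble::tibble(variant_id = variant_id, kept = kept,
                 reason = ifelse(kept, NA_character_, reason))
}

#' Stage 1 — call-confidence filter
#'
#' A carrier call is one with at least one alternate allele. Within a
#' pedigree group (cases or controls) the quality criterion holds when the
#' group has at least one carrier call with a non-missing quality and
#' every such quality is at or above the threshold. Under the default
#' `any_group` rule a variant is kept when either group satisfies the
#' criterion; under `all_groups`, both must. Variants with no carrier
#' quality information in any group are removed with reason
#' `"no qualified call"`.
#'
#' @param variants Variant table (see [read_trio_vcf()]).
#' @param pedigree Pedigree tibble.
#' @param config A [cascade_config()].
#' @return A decision tibble with columns `variant_id`, `kept`, `reason`.
#' @export
confidence_filter <- function(variants, pedigree, config = cascade_config()) {
  pedigree <- as_pedigree(pedigree)
  calls <- dplyr::left_join(genotype_calls(variants), pedigree, by = "sample")
  per_group <- calls |>
    dplyr::filter(is_carrier_call(.data$allele1, .data$allele2)) |>
    dplyr::group_by(.data$variant_id, .data$role) |>
    dplyr::summarise(
      n_qual = sum(!is.na(.data$quality)),
      all_ok = .data$n_qual > 0 &&
        all(.data$quality >= config$quality_threshold, na.rm = TRUE),
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(names_from = "role",
                       values_from = c("n_qual", "all_ok"))
  for (col in c("n_qual_case", "n_qual_control", "all_ok_case", "all_ok_control")) {
    if (!col %in% names(per_group)) {
      per_group[[col]] <- if (grepl("^n_", col)) 0L else FALSE
    }
  }
  per_group <- dplyr::mutate(
    per_group,
    dplyr::across(dplyr::starts_with("n_qual"), ~ tidyr::replace_na(.x, 0L)),
    dplyr::across(dplyr::starts_with("all_ok"), ~ tidyr::replace_na(.x, FALSE))
  )
  scored <- dplyr::left_join(
    dplyr::select(variants, "variant_id"), per_group, by = "variant_id"
  ) |>
    dplyr::mutate(
      dplyr::across(dplyr::starts_with("n_qual"), ~ tidyr::replace_na(.x, 0L)),
      dplyr::across(dplyr::starts_with("all_ok"), ~ tidyr::replace_na(.x, FALSE)),
      no_info = .data$n_qual_case + .data$n_qual_control == 0L,
      kept = if (config$quality_group_rule == "any_group") {
        .data$all_ok_case | .data$all_ok_control
      } else {
        .data$all_ok_case & .data$all_ok_control
      }
    )
  decision_tibble(scored$variant_id, scored$kept,
                  ifelse(scored$no_info, "no qualified call",
                         "low call quality"))
}

# Per-(variant, alt) annotation join: unrolls multi-allelic records so each
# alternate allele meets its own annotation row.
per_alt_annotations <- function(variants, annotations) {
  per_alt <- variants |>
    dplyr::select("variant_id", "chrom", "pos", "ref", "alts") |>
    tidyr::unnest_longer("alts", values_to = "alt_allele") |>
    dplyr::mutate(alt_key = variant_key(.data$chrom, .data$pos, .data$ref,
                                        .data$alt_allele))
  dplyr::left_join(
    per_alt,
    dplyr::rename(annotations, alt_key = "variant_id"),
    by = "alt_key", suffix = c("", ".ann")
  )
}

#' Stage 2 — common-variant filter
#'
#' Removes alternate alleles with allele frequency at or above the cutoff
#' (default 3%, inclusive) in any of the three population panels (1000
#' Genomes, public Complete Genomics genomes, NHLBI ESP exomes). Missing
#' frequencies compare as "not common". A multi-allelic record is kept if
#' any of its alternate alleles is rare.
#'
#' @inheritParams confidence_filter
#' @param annotations Annotation tibble (see [read_annotations()]).
#' @return A decision tibble.
#' @export
common_variant_filter <- function(variants, annotations,
                                  config = cascade_config()) {
  ann <- per_alt_annotations(variants, annotations)
  ge <- function(x) !is.na(x) & x >= config$af_cutoff
  scored <- ann |>
    dplyr::mutate(common = ge(.data$af_1kg) | ge(.data$af_cg69) |
                    ge(.data$af_esp)) |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(kept = any(!.data$common), .groups = "drop")
  scored <- scored[match(variants$variant_id, scored$variant_id), ]
  decision_tibble(variants$variant_id, scored$kept,
                  sprintf("common variant (AF >= %g)", config$af_cutoff))
}

#' Stage 3 — predicted-deleterious filter
#'
#' Keeps a variant when any of an OR-chained list of evidence criteria
#' holds for one of its alternate alleles: a clinical assertion
#' (pathogenic, possibly pathogenic, or unknown significance),
#' an established or predicted gain of function (literature, inferred
#' activating, BSIFT), a microRNA binding site, a frameshift / in-frame
#' indel / stop-codon change / structural consequence, a missense change
#' not predicted innocuous by SIFT (score at most 0.05 or missing), or a
#' splice-region change at most `splice_max_offset` bases into the
#' intron. Unannotated alleles carry no evidence and are removed.
#'
#' @inheritParams common_variant_filter
#' @return A decision tibble.
#' @export
deleteriousness_filter <- function(variants, annotations,
                                   config = cascade_config()) {
  ann <- per_alt_annotations(variants, annotations)
  flag <- function(x) !is.na(x) & x
  scored <- ann |>
    dplyr::mutate(
      asserted = !is.na(.data$clinical_assertion) & .data$clinical_assertion %in%
        c("pathogenic", "possibly_pathogenic", "unknown_significance"),
      severe = !is.na(.data$consequence) & .data$consequence %in%
        c("frameshift", "inframe_indel", "stop_change", "structural"),
      damaging_missense = !is.na(.data$consequence) &
        .data$consequence == "missense" &
        (is.na(.data$sift_score) | .data$sift_score <= 0.05),
      near_splice = !is.na(.data$consequence) &
        .data$consequence == "splice_region" &
        !is.na(.data$splice_intron_offset) &
        abs(.data$splice_intron_offset) <= config$splice_max_offset,
      deleterious = .data$asserted | flag(.data$gof_literature) |
        flag(.data$inferred_activating) | flag(.data$bsift_gof) |
        flag(.data$mirna_site) | .data$severe | .data$damaging_missense |
        .data$near_splice
    ) |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(kept = any(.data$deleterious), .groups = "drop")
  scored <- scored[match(variants$variant_id, scored$variant_id), ]
  decision_tibble(variants$variant_id, scored$kept,
                  "not predicted deleterious")
}

#' Stage 4 — genetic-model (segregation) filter
#'
#' Implements the autosomal-dominant segregation rule with gene-level case
#' counting: a variant is kept when (a) at least `min_case_samples`
#' distinct case samples carry a qualifying genotype (heterozygous,
#' homozygous alternate, heterozygous with two alternate alleles,
#' ambiguous heterozygous, or hemizygous with the alternate) at any
#' variant of the same gene among the variants passed in — so compound
#' heterozygotes accumulate across a gene — and (b) at most
#' `max_control_samples` control samples carry the variant itself.
#' Variants without a gene symbol are counted against themselves.
#'
#' @inheritParams confidence_filter
#' @return A decision tibble.
#' @export
genetic_model_filter <- function(variants, pedigree,
                                 config = cascade_config()) {
  pedigree <- as_pedigree(pedigree)
  n_cases <- sum(pedigree$role == "case")
  if (n_cases < config$min_case_samples) {
    abort(sprintf(
      "Pedigree has %d case sample(s) but the genetic filter requires %d",
      n_cases, config$min_case_samples))
  }
  if (sum(pedigree$role == "control") < 1L) {
    abort("The genetic filter requires at least one control sample")
  }
  qualifying <- c("heterozygous", "homozygous", "heterozygous_alt",
                  "heterozygous_amb", "hemizygous")
  calls <- dplyr::left_join(genotype_calls(variants), pedigree,
                            by = "sample") |>
    dplyr::mutate(
      gene_group = dplyr::coalesce(.data$gene, .data$variant_id),
      qualifies = .data$zygosity %in% qualifying &
        is_carrier_call(.data$allele1, .data$allele2)
    )
  gene_cases <- calls |>
    dplyr::filter(.data$role == "case", .data$qualifies) |>
    dplyr::distinct(.data$gene_group, .data$sample) |>
    dplyr::count(.data$gene_group, name = "n_case_carriers")
  control_hits <- calls |>
    dplyr::filter(.data$role == "control", .data$qualifies) |>
    dplyr::distinct(.data$variant_id, .data$sample) |>
    dplyr::count(.data$variant_id, name = "n_control_carriers")
  scored <- variants |>
    dplyr::mutate(gene_group = dplyr::coalesce(.data$gene, .data$variant_id)) |>
    dplyr::left_join(gene_cases, by = "gene_group") |>
    dplyr::left_join(control_hits, by = "variant_id") |>
    dplyr::mutate(
      n_case_carriers = tidyr::replace_na(.data$n_case_carriers, 0L),
      n_control_carriers = tidyr::replace_na(.data$n_control_carriers, 0L),
      case_ok = .data$n_case_carriers >= config$min_case_samples,
      control_ok = .data$n_control_carriers <= config$max_control_samples
    )
  decision_tibble(scored$variant_id, scored$case_ok & scored$control_ok,
                  ifelse(!scored$control_ok, "control carrier",
                         "insufficient case carriers at gene level"))
}

#' Stage 5 — biological-context filter
#'
#' Keeps variants whose gene is in the disease-gene set or one hop from
#' it in the interaction network, in either direction (the gene regulates
#' a disease gene, or a disease gene regulates it). Variants without a
#' gene symbol are removed with reason `"no gene"`.
#'
#' @inheritParams confidence_filter
#' @param network A [gene_network()].
#' @return A decision tibble.
#' @export
biological_context_filter <- function(variants, network) {
  stopifnot(inherits(network, "gene_network"))
  d <- network$disease_genes
  neighbours <- unique(c(
    d,
    network$edges$regulator[network$edges$target %in% d],
    network$edges$target[network$edges$regulator %in% d]
  ))
  has_gene <- !is.na(variants$gene) & nzchar(variants$gene)
  kept <- has_gene & variants$gene %in% neighbours
  decision_tibble(variants$variant_id, kept,
                  ifelse(has_gene, "outside disease-gene neighbourhood",
                         "no gene"))
}

#' Run the full five-stage prioritization cascade
#'
#' Applies the stages in their fixed order, removing variants at the
#' first failing stage; the trace records, for every input variant, one
#' decision row per stage reached, so the input set always equals the
#' kept set plus the per-stage removals (conservation).
#'
#' @inheritParams common_variant_filter
#' @param pedigree Pedigree tibble.
#' @param network A [gene_network()].
#' @return A `cascade_result` with elements `kept` (variant table),
#'   `trace` (tibble: `variant_id`, `stage`, `kept`, `reason`), `summary`
#'   (per-stage attrition counts) and `config`. [tidy()] returns the
#'   trace, [glance()] the attrition summary, [autoplot()] an attrition
#'   plot.
#' @export
run_cascade <- function(variants, annotations, pedigree, network,
                        config = cascade_config()) {
  stages <- list(
    confidence = function(v) confidence_filter(v, pedigree, config),
    common_variants = function(v) common_variant_filter(v, annotations, config),
    deleteriousness = function(v) deleteriousness_filter(v, annotations, config),
    genetic_model = function(v) genetic_model_filter(v, pedigree, config),
    biological_context = function(v) biological_context_filter(v, network)
  )
  current <- variants
  trace <- list()
  summary <- list()
  for (stage in CASCADE_STAGES) {
    if (nrow(current) == 0L) {
      summary[[stage]] <- tibble::tibble(stage = stage, n_in = 0L,
                                         n_removed = 0L, n_kept = 0L)
      next
    }
    decision <- stages[[stage]](current)
    trace[[stage]] <- dplyr::mutate(decision, stage = stage,
                                    .after = "variant_id")
    summary[[stage]] <- tibble::tibble(
      stage = stage, n_in = nrow(current),
      n_removed = sum(!decision$kept), n_kept = sum(decision$kept)
    )
    current <- current[current$variant_id %in%
                         decision$variant_id[decision$kept], ]
  }
  structure(
    list(kept = current,
         trace = dplyr::bind_rows(trace),
         summary = dplyr::bind_rows(summary),
         config = config),
    class = "cascade_result"
  )
}

#' @exportS3Method base::print
print.cascade_result <- function(x, ...) {
  n_in <- if (nrow(x$summary) > 0L) x$summary$n_in[1L] else 0L
  cat("<cascade_result> ", n_in, " variants in, ", nrow(x$kept),
      " kept\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @rdname tidy
#' @export
tidy.cascade_result <- function(x, ...) x$trace

#' @rdname glance
#' @export
glance.cascade_result <- function(x, ...) {
  n_in <- if (nrow(x$summary) > 0L) x$summary$n_in[1L] else 0L
  out <- tibble::tibble(n_input = n_in, n_kept = nrow(x$kept))
  removed <- stats::setNames(
    as.list(x$summary$n_removed),
    paste0("removed_", x$summary$stage)
  )
  dplyr::bind_cols(out, tibble::as_tibble(removed))
}
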