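# Seeded synthetic data: a sequenced trio with a planted autosomal-
# dominant variant among background variation, and case/control genotype
# cohorts under a multiplicative genotype-relative-risk model. One global
# seed drives a named stream per component, so enlarging the trio does
# not perturb cohort draws.

#' The study trio pedigree
#'
#' Father (control), mother and daughter (cases): the configuration in
#' which a dominant, highly penetrant variant is transmitted mother to
#' daughter.
#'
#' @return A pedigree tibble (`sample`, `role`, `relation`).
#' @export
trio_pedigree <- function() {
  tibble::tibble(
    sample = c("III-1", "III-2", "IV-3"),
    role = c("control", "case", "case"),
    relation = c("father", "mother", "daughter")
  )
}

#' Specification for a synthetic trio
#'
#' Defaults emulate a whole-genome trio screen: a few thousand candidate
#' background variants whose population allele-frequency spectrum is a
#' Beta(0.3, 3) truncated to (0.0005, 0.5) — so both common (at or above
#' 3%) and rare alleles occur — with Phred call qualities around 45 and a
#' 15% low-quality fraction (below 20), plus one planted causal variant:
#' a rare frameshift-class deletion-insertion carried heterozygously by
#' mother and daughter and absent from the father, annotated so that it
#' survives the frequency, deleteriousness and biological-context
#' filters.
#'
#' @param n_background Number of background variants (default 2000).
#' @param af_spectrum List with `shape1`, `shape2` (Beta parameters) and
#'   truncation bounds `min`, `max` for background population allele
#'   frequencies.
#' @param quality_model List with `mean`, `sd` of Phred call quality and
#'   `low_quality_fraction`, the fraction of calls re-drawn uniformly
#'   below quality 20.
#' @param planted List describing the causal variant: `chrom`, `pos`,
#'   `ref`, `alt`, `gene`, `consequence`, `sift_score`, and panel
#'   frequencies `af_1kg`, `af_cg69`, `af_esp` (`NA` = absent from the
#'   panel, as for a novel variant).
#' @param penetrance Probability that an affected sample carries the
#'   planted allele (default 1: the fully penetrant dominant pattern).
#' @param network_fraction Fraction of background genes connected to the
#'   disease-gene set (default 0.1).
#' @param seed Integer global seed.
#' @return A `trio_sim_spec` list.
#' @export
trio_sim_spec <- function(n_background = 2000L,
                          af_spectrum = list(shape1 = 0.3, shape2 = 3,
                                             min = 0.0005, max = 0.5),
                          quality_model = list(mean = 45, sd = 8,
                                               low_quality_fraction = 0.15),
                          planted = list(chrom = "2", pos = 777777L,
                                         ref = "AA", alt = "G",
                                         gene = "GENE_CAUSAL",
                                         consequence = "frameshift",
                                         sift_score = 0.01,
                                         af_1kg = NA_real_,
                                         af_cg69 = NA_real_,
                                         af_esp = NA_real_),
                          penetrance = 1,
                          network_fraction = 0.1,
                          seed = 1L) {
  if (!is_scalar_number(n_background) || n_background < 0) {
    abort("n_background must be a non-negative count")
  }
  if (!is_scalar_number(penetrance) || penetrance <= 0 || penetrance > 1) {
    abort("penetrance must lie in (0, 1]")
  }
  structure(
    list(n_background = as.integer(n_background), af_spectrum = af_spectrum,
         quality_model = quality_model, planted = planted,
         penetrance = penetrance, network_fraction = network_fraction,
         seed = as.integer(seed)),
    class = "trio_sim_spec"
  )
}

rbeta_truncated <- function(n, shape1, shape2, lower, upper) {
  lo <- stats::pbeta(lower, shape1, shape2)
  hi <- stats::pbeta(upper, shape1, shape2)
  stats::qbeta(runif(n, lo, hi), shape1, shape2)
}

draw_quality <- function(n, model) {
  q <- round(pmin(pmax(rnorm(n, model$mean, model$sd), 0), 99), 1)
  low <- runif(n) < model$low_quality_fraction
  q[low] <- pmin(round(runif(sum(low), 0, 19.9), 1), 19.9)
  q
}

# One child allele from each parent, uniformly.
inherit_allele <- function(a1, a2) {
  ifelse(runif(length(a1)) < 0.5, a1, a2)
}

# Number of alternate alleles among 4 parental copies at frequency af,
# conditioned on at least one (zero-truncated Binomial(4, af)); vectorized
# over af.
truncated_binom4 <- function(af) {
  n <- length(af)
  if (n == 0L) return(integer())
  pk <- matrix(vapply(1:4, function(k) stats::dbinom(k, 4L, af), numeric(n)),
               nrow = n, ncol = 4L)
  cum <- pk %*% upper.tri(matrix(1, 4L, 4L), diag = TRUE)
  u <- runif(n) * cum[, 4L]
  as.integer(1L + (u > cum[, 1L]) + (u > cum[, 2L]) + (u > cum[, 3L]))
}

#' Simulate a sequenced trio with one planted dominant variant
#'
#' Background variants receive HWE genotypes at their population allele
#' frequency for the parents and Mendelian-consistent genotypes for the
#' daughter, with Phred call qualities from the spec's quality model.
#' Panel allele frequencies track the simulation frequency (with noise
#' and occasional missingness), consequences and predictor scores are
#' drawn from a realistic mix, and a configurable fraction of background
#' genes is wired to the disease-gene set. The planted variant is
#' heterozygous in the affected mother and daughter, absent from the
#' father, confidently called, rare, deleterious by annotation and inside
#' the disease-gene neighbourhood — so it survives the full cascade by
#' construction.
#'
#' @param spec A [trio_sim_spec()].
#' @return A list of class `trio_sim`: `variants` (variant table),
#'   `annotations`, `pedigree`, `network` and `truth` (the planted
#'   variant's key).
#' @export
simulate_trio <- function(spec = trio_sim_spec()) {
  stopifnot(inherits(spec, "trio_sim_spec"))
  pl <- spec$planted
  afs <- c(pl$af_1kg, pl$af_cg69, pl$af_esp)
  if (any(!is.na(afs) & afs >= 0.03)) {
    abort(paste("Contradictory spec: the planted variant must pass the",
                "common-variant filter but has a panel frequency >= 3%"))
  }
  withr::with_seed(derive_seed(spec$seed, "trio"), {
    n <- spec$n_background
    ped <- trio_pedigree()

    # --- background variants ---------------------------------------------
    af <- rbeta_truncated(n, spec$af_spectrum$shape1, spec$af_spectrum$shape2,
                          spec$af_spectrum$min, spec$af_spectrum$max)
    chrom <- as.character(sample(1:22, n, replace = TRUE))
    pos <- sample.int(2.5e8, n)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- unname(vapply(ref, function(r) sample(setdiff(bases, r), 1L), ""))
    gene <- paste0("BG", formatC(sample.int(max(1L, ceiling(n / 2)), n,
                                            replace = TRUE),
                                 width = 5, flag = "0"))

    # Parental alleles are HWE draws at the population frequency,
    # conditioned on at least one alternate allele among the four parental
    # copies: a family variant list only contains sites called in the
    # family, and the daughter can only carry what a parent does.
    k_alt <- truncated_binom4(af)
    slots <- matrix(0L, nrow = n, ncol = 4L)
    for (i in seq_len(n)) {
      slots[i, sample.int(4L, k_alt[i])] <- 1L
    }
    m1 <- slots[, 1L]; m2 <- slots[, 2L]               # mother
    f1 <- slots[, 3L]; f2 <- slots[, 4L]               # father
    d1 <- inherit_allele(m1, m2)                        # daughter
    d2 <- inherit_allele(f1, f2)
    qual <- matrix(draw_quality(3L * n, spec$quality_model), ncol = 3L)

    # --- planted variant --------------------------------------------------
    mother_carries <- runif(1) < spec$penetrance
    daughter_carries <- runif(1) < spec$penetrance
    chrom <- c(chrom, pl$chrom)
    pos <- c(pos, pl$pos)
    ref <- c(ref, pl$ref)
    alt <- c(alt, pl$alt)
    gene <- c(gene, pl$gene)
    m1 <- c(m1, 0L); m2 <- c(m2, as.integer(mother_carries))
    f1 <- c(f1, 0L); f2 <- c(f2, 0L)
    d1 <- c(d1, as.integer(daughter_carries)); d2 <- c(d2, 0L)
    qual <- rbind(qual, round(runif(3, 30, 60), 1))
    af <- c(af, 0.001)

    ord <- order(suppressWarnings(as.integer(chrom)), chrom, pos)
    relabel <- function(x) x[ord]
    chrom <- relabel(chrom); pos <- relabel(pos); ref <- relabel(ref)
    alt <- relabel(alt); gene <- relabel(gene); af <- relabel(af)
    m1 <- relabel(m1); m2 <- relabel(m2); f1 <- relabel(f1)
    f2 <- relabel(f2); d1 <- relabel(d1); d2 <- relabel(d2)
    qual <- qual[ord, , drop = FALSE]
    n_all <- length(chrom)
    planted_idx <- which(chrom == pl$chrom & pos == pl$pos & ref == pl$ref &
                           alt == pl$alt)

    a1_long <- as.vector(rbind(f1, m1, d1))
    a2_long <- as.vector(rbind(f2, m2, d2))
    calls <- make_call_column(
      n_all, ped$sample, a1_long, a2_long, rep(2L, 3L * n_all),
      as.vector(t(qual))
    )
    variants <- new_variant_table(chrom, pos, ref,
                                  as.list(alt), gene, calls)

    # --- annotations ------------------------------------------------------
    noisy_af <- function() {
      x <- pmin(pmax(af * exp(rnorm(n_all, 0, 0.2)), 0), 1)
      x[runif(n_all) < 0.1] <- NA_real_
      x
    }
    consequence <- sample(
      CONSEQUENCE_LEVELS, n_all, replace = TRUE,
      prob = c(0.03, 0.02, 0.02, 0.35, 0.32, 0.10, 0.01, 0.15)
    )
    sift <- ifelse(consequence == "missense" & runif(n_all) >= 0.1,
                   round(runif(n_all), 3), NA_real_)
    splice_off <- ifelse(consequence == "splice_region",
                         sample(c(-10:-1, 1:10), n_all, replace = TRUE),
                         NA_integer_)
    clinical <- sample(c(NA, "benign", "unknown_significance",
                         "possibly_pathogenic", "pathogenic"),
                       n_all, replace = TRUE,
                       prob = c(0.90, 0.06, 0.025, 0.01, 0.005))
    ann <- tibble::tibble(
      chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
      af_1kg = noisy_af(), af_cg69 = noisy_af(), af_esp = noisy_af(),
      clinical_assertion = clinical,
      gof_literature = runif(n_all) < 0.005,
      inferred_activating = runif(n_all) < 0.005,
      bsift_gof = runif(n_all) < 0.005,
      mirna_site = runif(n_all) < 0.01,
      consequence = consequence,
      splice_intron_offset = as.integer(splice_off),
      sift_score = sift,
      provean_score = round(rnorm(n_all, -1, 1.5), 2)
    )
    ann[planted_idx, c("af_1kg", "af_cg69", "af_esp")] <-
      tibble::tibble(af_1kg = pl$af_1kg, af_cg69 = pl$af_cg69,
                     af_esp = pl$af_esp)
    ann$clinical_assertion[planted_idx] <- NA_character_
    ann$consequence[planted_idx] <- pl$consequence
    ann$sift_score[planted_idx] <- pl$sift_score
    ann$gof_literature[planted_idx] <- FALSE
    ann$inferred_activating[planted_idx] <- FALSE
    ann$bsift_gof[planted_idx] <- FALSE
    ann$mirna_site[planted_idx] <- FALSE
    ann$splice_intron_offset[planted_idx] <- NA_integer_
    annotations <- as_annotations(ann)

    # --- gene network -----------------------------------------------------
    disease_genes <- c(pl$gene, paste0("DIS", 1:5))
    bg_genes <- setdiff(unique(gene), pl$gene)
    linked <- bg_genes[runif(length(bg_genes)) < spec$network_fraction]
    edges <- tibble::tibble(regulator = character(), target = character())
    if (length(linked) > 0L) {
      partner <- sample(disease_genes, length(linked), replace = TRUE)
      outward <- runif(length(linked)) < 0.5
      edges <- tibble::tibble(
        regulator = ifelse(outward, linked, partner),
        target = ifelse(outward, partner, linked)
      )
    }
    network <- gene_network(edges, disease_genes)

    truth <- list(
      variant_id = variants$variant_id[planted_idx],
      chrom = pl$chrom, pos = pl$pos, ref = pl$ref, alt = pl$alt,
      gene = pl$gene,
      mother_carrier = mother_carries, daughter_carrier = daughter_carries
    )
    structure(
      list(variants = variants, annotations = annotations, pedigree = ped,
           network = network, truth = truth, spec = spec),
      class = "trio_sim"
    )
  })
}

#' @exportS3Method base::print
print.trio_sim <- function(x, ...) {
  cat("<trio_sim> ", nrow(x$variants), " variants (planted: ",
      x$truth$variant_id, ")\n", sep = "")
  invisible(x)
}

#' Write a simulated trio to disk in the formats the readers consume
#'
#' Emits `trio.vcf`, `pedigree.ped`, `annotations.tsv`,
#' `network_edges.tsv`, `disease_genes.txt` and `truth.json` under `dir`.
#'
#' @param sim A `trio_sim` from [simulate_trio()].
#' @param dir Output directory (created if absent).
#' @return A named list of the paths written, invisibly.
#' @export
write_trio_bundle <- function(sim, dir) {
  stopifnot(inherits(sim, "trio_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    vcf = file.path(dir, "trio.vcf"),
    pedigree = file.path(dir, "pedigree.ped"),
    annotations = file.path(dir, "annotations.tsv"),
    network_edges = file.path(dir, "network_edges.tsv"),
    disease_genes = file.path(dir, "disease_genes.txt"),
    truth = file.path(dir, "truth.json")
  )
  write_trio_vcf(sim$variants, paths$vcf)
  utils::write.table(sim$pedigree, paths$pedigree, quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  write_annotations(sim$annotations, paths$annotations)
  write_gene_network(sim$network, paths$network_edges, paths$disease_genes)
  jsonlite::write_json(sim$truth, paths$truth, auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Specification for a synthetic case/control cohort
#'
#' Defaults mirror the larger replication cohort of the study design: 109
#' cases and 111 controls, genotyped at a biallelic site with alternate
#' allele frequency 0.2, under the null (genotype relative risk 1).
#'
#' @param allele_freq Population alternate-allele frequency, in (0, 1).
#' @param n_cases,n_controls Cohort sizes.
#' @param grr Genotype relative risk of the multiplicative model: risk
#'   scales by `grr` per alternate allele, so case genotype probabilities
#'   are proportional to HWE probabilities times `(1, grr, grr^2)`.
#' @param seed Integer global seed.
#' @return A `cohort_sim_spec` list.
#' @export
cohort_sim_spec <- function(allele_freq = 0.2, n_cases = 109L,
                            n_controls = 111L, grr = 1, seed = 1L) {
  if (!is_scalar_number(allele_freq) || allele_freq <= 0 || allele_freq >= 1) {
    abort("allele_freq must lie strictly inside (0, 1)")
  }
  if (!is_scalar_number(grr) || grr <= 0) abort("grr must be positive")
  if (!is_scalar_number(n_cases) || !is_scalar_number(n_controls) ||
        n_cases < 1 || n_controls < 1) {
    abort("Cohort sizes must be positive")
  }
  structure(
    list(allele_freq = allele_freq, n_cases = as.integer(n_cases),
         n_controls = as.integer(n_controls), grr = grr,
         seed = as.integer(seed)),
    class = "cohort_sim_spec"
  )
}

#' Genotype probabilities of the cohort model
#'
#' Controls follow HWE at the spec's allele frequency; case probabilities
#' are the HWE probabilities reweighted by `(1, grr, grr^2)` and
#' renormalized.
#'
#' @param spec A [cohort_sim_spec()].
#' @return A tibble with columns `arm`, `p_hom_ref`, `p_het`,
#'   `p_hom_alt`.
#' @export
cohort_genotype_probs <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  p <- spec$allele_freq
  hwe <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  case <- hwe * c(1, spec$grr, spec$grr^2)
  case <- case / sum(case)
  tibble::tibble(
    arm = c("case", "control"),
    p_hom_ref = c(case[1L], hwe[1L]),
    p_het = c(case[2L], hwe[2L]),
    p_hom_alt = c(case[3L], hwe[3L])
  )
}

#' Simulate a case/control genotype count table
#'
#' Draws control counts from a multinomial with HWE probabilities and
#' case counts from the reweighted case distribution (see
#' [cohort_genotype_probs()]).
#'
#' @param spec A [cohort_sim_spec()].
#' @return A `genotype_counts` table.
#' @export
simulate_cohort_table <- function(spec = cohort_sim_spec()) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  probs <- cohort_genotype_probs(spec)
  withr::with_seed(derive_seed(spec$seed, "cohort"), {
    cases <- drop(rmultinom(1L, spec$n_cases,
                            as.numeric(probs[1L, -1L])))
    controls <- drop(rmultinom(1L, spec$n_controls,
                               as.numeric(probs[2L, -1L])))
    genotype_counts(cases, controls)
  })
}
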