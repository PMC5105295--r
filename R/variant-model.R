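# Core tabular data model: variants with nested per-sample genotype calls,
# pedigree, annotation table, gene network. Coordinates are 1-based
# throughout (VCF convention); multi-allelic records are kept intact.

ZYGOSITY_LEVELS <- c(
  "hom_ref", "heterozygous", "homozygous", "heterozygous_alt",
  "heterozygous_amb", "hemizygous", "missing"
)

CONSEQUENCE_LEVELS <- c(
  "frameshift", "inframe_indel", "stop_change", "missense", "synonymous",
  "splice_region", "structural", "other"
)

CLINICAL_LEVELS <- c(
  "pathogenic", "possibly_pathogenic", "unknown_significance", "benign",
  "none"
)

#' Derive the zygosity class of a diploid or haploid genotype call
#'
#' The class is a pure function of the allele indices (0 = reference,
#' k = k-th alternate) and the ploidy of the call:
#' \describe{
#'   \item{hemizygous}{single-allele call, whatever the allele}
#'   \item{hom_ref}{`0/0`}
#'   \item{heterozygous}{one reference and one alternate allele}
#'   \item{homozygous}{two copies of the same alternate allele}
#'   \item{heterozygous_alt}{two distinct alternate alleles}
#'   \item{heterozygous_amb}{one alternate allele, the other allele
#'     uncalled (`1/.`)}
#'   \item{missing}{no alternate evidence: `./.`, `.` at ploidy 2, or `0/.`}
#' }
#'
#' @param allele1,allele2 Integer allele indices; `NA` for an uncalled
#'   allele. `allele2` is ignored when `ploidy` is 1.
#' @param ploidy Integer, 1 or 2 (default 2).
#' @return Character vector of zygosity classes.
#' @examples
#' zygosity_class(0, 1)            # heterozygous
#' zygosity_class(1, 2)            # heterozygous_alt
#' zygosity_class(NA, NA)          # missing
#' zygosity_class(1, NA, ploidy = 1)  # hemizygous
#' @export
zygosity_class <- function(allele1, allele2, ploidy = 2L) {
  n <- max(length(allele1), length(allele2), length(ploidy))
  a1 <- rep_len(as.integer(allele1), n)
  a2 <- rep_len(as.integer(allele2), n)
  pl <- rep_len(as.integer(ploidy), n)
  out <- rep_len("missing", n)
  hap <- pl == 1L
  out[hap & !is.na(a1)] <- "hemizygous"
  dip <- !hap
  both <- dip & !is.na(a1) & !is.na(a2)
  out[both & a1 == 0L & a2 == 0L] <- "hom_ref"
  out[both & ((a1 == 0L) != (a2 == 0L))] <- "heterozygous"
  out[both & a1 > 0L & a2 > 0L & a1 == a2] <- "homozygous"
  out[both & a1 > 0L & a2 > 0L & a1 != a2] <- "heterozygous_alt"
  one <- dip & (is.na(a1) != is.na(a2))
  known <- ifelse(is.na(a1), a2, a1)
  out[one & !is.na(known) & known > 0L] <- "heterozygous_amb"
  out
}

# TRUE when a call carries at least one alternate allele.
is_carrier_call <- function(allele1, allele2) {
  (!is.na(allele1) & allele1 > 0L) | (!is.na(allele2) & allele2 > 0L)
}

# Build the nested per-variant calls list-column from call vectors laid out
# variant-major (all samples of variant 1, then variant 2, ...). new_tibble
# skips per-record validation, which matters at whole-genome variant counts.
make_call_column <- function(n_variants, samples, allele1, allele2, ploidy,
                             quality) {
  k <- length(samples)
  zyg <- zygosity_class(allele1, allele2, ploidy)
  lapply(seq_len(n_variants), function(i) {
    j <- (k * (i - 1L) + 1L):(k * i)
    tibble::new_tibble(
      list(sample = samples, allele1 = allele1[j], allele2 = allele2[j],
           ploidy = ploidy[j], quality = quality[j], zygosity = zyg[j]),
      nrow = k
    )
  })
}

parse_gt_field <- function(gt) {
  # Returns a data.frame(allele1, allele2, ploidy, malformed).
  gt <- ifelse(is.na(gt) | gt == "", ".", gt)
  ok <- grepl("^(\\.|[0-9]+)([/|](\\.|[0-9]+))?$", gt)
  parts <- stringr::str_split(ifelse(ok, gt, "."), "[/|]")
  a1 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
  a2c <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else NA_character_, "")
  a2 <- suppressWarnings(as.integer(a2c))
  ploidy <- ifelse(vapply(parts, length, 1L) == 1L & gt != ".", 1L, 2L)
  # a bare "." is a missing diploid call, not a haploid one
  data.frame(allele1 = a1, allele2 = a2, ploidy = ploidy, malformed = !ok)
}

new_variant_table <- function(chrom, pos, ref, alts, gene, calls) {
  tibble::tibble(
    variant_id = variant_key(chrom, pos, ref,
                             vapply(alts, paste, "", collapse = ",")),
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref = as.character(ref),
    alt = vapply(alts, paste, "", collapse = ","),
    gene = as.character(gene),
    alts = alts,
    calls = calls
  )
}

validate_alleles <- function(ref, alts) {
  symbolic <- function(x) grepl("^<.+>$", x)
  ok_seq <- function(x) nzchar(x) & grepl("^[ACGTNacgtn]+$", x)
  bad_ref <- !ok_seq(ref)
  bad_alt <- vapply(alts, function(a) {
    length(a) == 0L || any(!(ok_seq(a) | symbolic(a)))
  }, TRUE)
  if (any(bad_ref) || any(bad_alt)) {
    abort(paste0(
      "Malformed allele strings at record(s): ",
      paste(which(bad_ref | bad_alt), collapse = ", ")
    ))
  }
  invisible(TRUE)
}

#' Read a pedigree / phenotype file
#'
#' Whitespace-delimited file with at least three columns: sample id, role
#' (`case` or `control`) and a free-text relation label (e.g. `mother`,
#' `father`, `daughter`). The genetic-model filter requires at least two
#' case samples and one control sample.
#'
#' @param path Path to the pedigree file.
#' @return A tibble with columns `sample`, `role`, `relation`.
#' @export
read_pedigree <- function(path) {
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("sample", "role", "relation"),
                           colClasses = "character", fill = FALSE)
  as_pedigree(tibble::as_tibble(raw))
}

#' Construct and validate a pedigree table
#'
#' @param df Data frame with columns `sample`, `role` (`case`/`control`)
#'   and `relation`.
#' @return A validated tibble.
#' @export
as_pedigree <- function(df) {
  df <- tibble::as_tibble(df)
  need <- c("sample", "role", "relation")
  if (!all(need %in% names(df))) {
    abort(paste("Pedigree needs columns:", paste(need, collapse = ", ")))
  }
  if (!all(df$role %in% c("case", "control"))) {
    abort("Pedigree roles must be 'case' or 'control'")
  }
  if (anyDuplicated(df$sample)) abort("Duplicate sample ids in pedigree")
  df[need]
}

#' Read trio (or larger family) genotypes from a VCF file
#'
#' Reads a VCF v4.2+ file with per-sample `GT` and a per-sample quality
#' FORMAT field (default `GQ`; configurable because platforms differ in how
#' they expose call quality) into a variant table: one row per VCF data
#' line, multi-allelic records intact, with a nested `calls` tibble per
#' record holding allele indices, Phred-scaled quality and the derived
#' zygosity class for each pedigree sample.
#'
#' @param path VCF file path.
#' @param pedigree Pedigree tibble (see [read_pedigree()]); every pedigree
#'   sample must have a genotype column in the VCF.
#' @param quality_key FORMAT key holding the per-call Phred quality
#'   (default `"GQ"`).
#' @return A tibble with columns `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `gene`, `alts` (list), `calls` (list of tibbles with `sample`,
#'   `allele1`, `allele2`, `ploidy`, `quality`, `zygosity`).
#' @export
read_trio_vcf <- function(path, pedigree, quality_key = "GQ") {
  pedigree <- as_pedigree(pedigree)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(new_variant_table(character(), integer(), character(),
                             list(), character(), list()))
  }
  samples <- colnames(vcf@gt)[-1L]
  missing_samples <- setdiff(pedigree$sample, samples)
  if (length(missing_samples) > 0L) {
    abort(paste0("VCF is missing sample column(s) required by the pedigree: ",
                 paste(missing_samples, collapse = ", ")))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gq <- suppressWarnings(
    vcfR::extract.gt(vcf, element = quality_key, as.numeric = TRUE)
  )
  if (is.null(gq)) gq <- matrix(NA_real_, nrow = nrow(fix), ncol = length(samples))
  gene <- vcfR::extract.info(vcf, element = "GENE")
  if (is.null(gene)) gene <- rep(NA_character_, nrow(fix))
  alts <- stringr::str_split(fix$ALT, ",")
  validate_alleles(fix$REF, alts)

  n_rec <- nrow(fix)
  gt_sub <- matrix(gt[, pedigree$sample], nrow = n_rec)
  gq_sub <- matrix(as.numeric(gq[, pedigree$sample]), nrow = n_rec)
  g <- parse_gt_field(as.vector(t(gt_sub)))      # variant-major layout
  q <- as.vector(t(gq_sub))
  q[g$malformed] <- NA_real_
  calls <- make_call_column(n_rec, pedigree$sample, g$allele1, g$allele2,
                            g$ploidy, q)
  bad_rec <- unique(ceiling(which(g$malformed) / nrow(pedigree)))
  if (length(bad_rec) > 0L) {
    keys <- variant_key(fix$CHROM[bad_rec], fix$POS[bad_rec],
                        fix$REF[bad_rec], fix$ALT[bad_rec])
    warn(paste0("Malformed genotype(s) treated as missing in ",
                length(bad_rec), " record(s): ",
                paste(head(keys, 5L), collapse = "; "),
                if (length(bad_rec) > 5L) " ..." else ""))
  }
  new_variant_table(fix$CHROM, as.integer(fix$POS), fix$REF, alts, gene, calls)
}

#' Write a variant table to a VCF v4.2 file
#'
#' Emits the dialect [read_trio_vcf()] reads: `GENE` in INFO, `GT` and a
#' Float-typed quality key per sample. Qualities are written to one
#' decimal place.
#'
#' @param variants Variant table.
#' @param path Output file path.
#' @param quality_key FORMAT key for call quality (default `"GQ"`).
#' @return `path`, invisibly.
#' @export
write_trio_vcf <- function(variants, path, quality_key = "GQ") {
  samples <- if (nrow(variants) > 0L) variants$calls[[1L]]$sample else character()
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=trioscreen",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    sprintf("##FORMAT=<ID=%s,Number=1,Type=Float,Description=\"Phred-scaled call quality\">",
            quality_key),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  fmt_call <- function(a1, a2, pl, q) {
    gt <- if (pl == 1L) {
      if (is.na(a1)) "." else as.character(a1)
    } else {
      paste(ifelse(is.na(c(a1, a2)), ".", c(a1, a2)), collapse = "/")
    }
    paste0(gt, ":", if (is.na(q)) "." else sprintf("%.1f", q))
  }
  body <- vapply(seq_len(nrow(variants)), function(i) {
    cl <- variants$calls[[i]]
    sample_fields <- vapply(seq_len(nrow(cl)), function(j) {
      fmt_call(cl$allele1[j], cl$allele2[j], cl$ploidy[j], cl$quality[j])
    }, "")
    info <- if (is.na(variants$gene[i])) "." else paste0("GENE=", variants$gene[i])
    paste(c(variants$chrom[i], variants$pos[i], ".", variants$ref[i],
            variants$alt[i], ".", "PASS", info, paste0("GT:", quality_key),
            sample_fields), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Unnest per-sample genotype calls into a long tibble
#'
#' @param variants Variant table with nested `calls`.
#' @return A tibble with one row per (variant, sample).
#' @export
genotype_calls <- function(variants) {
  tidyr::unnest(
    dplyr::select(variants, "variant_id", "gene", "calls"),
    "calls"
  )
}

ANNOTATION_COLUMNS <- c(
  "chrom", "pos", "ref", "alt", "gene", "af_1kg", "af_cg69", "af_esp",
  "clinical_assertion", "gof_literature", "inferred_activating",
  "bsift_gof", "mirna_site", "consequence", "splice_intron_offset",
  "sift_score", "provean_score"
)

#' Read a variant annotation table
#'
#' Tab-separated with header columns `chrom, pos, ref, alt, gene, af_1kg,
#' af_cg69, af_esp, clinical_assertion, gof_literature,
#' inferred_activating, bsift_gof, mirna_site, consequence,
#' splice_intron_offset, sift_score, provean_score`. The three `af_*`
#' columns are population allele frequencies (1000 Genomes, the 69 public
#' Complete Genomics genomes, NHLBI ESP exomes). Absent cells become `NA`
#' (never zero); each cascade stage applies its own missing-value rule.
#'
#' @param path TSV file path.
#' @return A tibble keyed by `(chrom, pos, ref, alt)` with a `variant_id`
#'   column.
#' @export
read_annotations <- function(path) {
  ann <- read_tsv_quiet(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    ref = readr::col_character(), alt = readr::col_character(),
    gene = readr::col_character(),
    af_1kg = readr::col_double(), af_cg69 = readr::col_double(),
    af_esp = readr::col_double(),
    clinical_assertion = readr::col_character(),
    gof_literature = readr::col_logical(),
    inferred_activating = readr::col_logical(),
    bsift_gof = readr::col_logical(), mirna_site = readr::col_logical(),
    consequence = readr::col_character(),
    splice_intron_offset = readr::col_integer(),
    sift_score = readr::col_double(), provean_score = readr::col_double()
  ))
  missing_cols <- setdiff(ANNOTATION_COLUMNS, names(ann))
  if (length(missing_cols) > 0L) {
    abort(paste("Annotation table is missing column(s):",
                paste(missing_cols, collapse = ", ")))
  }
  as_annotations(ann)
}

#' Validate an in-memory annotation table
#'
#' @param df Data frame with the columns documented in
#'   [read_annotations()].
#' @return A validated tibble with a `variant_id` column.
#' @export
as_annotations <- function(df) {
  ann <- tibble::as_tibble(df)
  key <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  if (anyDuplicated(key)) {
    abort(paste("Duplicate annotation key(s):",
                paste(unique(key[duplicated(key)]), collapse = ", ")))
  }
  for (col in c("af_1kg", "af_cg69", "af_esp", "sift_score")) {
    bad <- which(!is.na(ann[[col]]) & (ann[[col]] < 0 | ann[[col]] > 1))
    if (length(bad) > 0L) {
      abort(sprintf("%s outside [0,1] at row(s): %s", col,
                    paste(bad, collapse = ", ")))
    }
  }
  bad_cons <- which(!is.na(ann$consequence) &
                      !ann$consequence %in% CONSEQUENCE_LEVELS)
  if (length(bad_cons) > 0L) {
    abort(sprintf("Unknown consequence at row(s): %s",
                  paste(bad_cons, collapse = ", ")))
  }
  bad_clin <- which(!is.na(ann$clinical_assertion) &
                      !ann$clinical_assertion %in% CLINICAL_LEVELS)
  if (length(bad_clin) > 0L) {
    abort(sprintf("Unknown clinical assertion at row(s): %s",
                  paste(bad_clin, collapse = ", ")))
  }
  ann$variant_id <- key
  dplyr::relocate(ann, "variant_id")
}

#' Write an annotation table to TSV
#'
#' @param annotations Annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  readr::write_tsv(annotations[ANNOTATION_COLUMNS], path, progress = FALSE)
  invisible(path)
}

#' Construct a gene interaction network with a disease-gene set
#'
#' Directed regulator-to-target edges plus a set of genes known or
#' predicted to affect the disease under study. The biological-context
#' filter keeps genes that are in the disease set or one hop away from it
#' in either direction.
#'
#' @param edges Data frame with character columns `regulator`, `target`
#'   (extra columns dropped); duplicate edges are collapsed.
#' @param disease_genes Character vector of disease gene symbols.
#' @return A `gene_network` object.
#' @export
gene_network <- function(edges, disease_genes) {
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) > 0L) {
    if (!all(c("regulator", "target") %in% names(edges))) {
      names(edges)[1:2] <- c("regulator", "target")
    }
    edges <- dplyr::distinct(edges[, c("regulator", "target")])
    if (any(!nzchar(edges$regulator) | !nzchar(edges$target) |
              is.na(edges$regulator) | is.na(edges$target))) {
      abort("Network edges must have non-empty gene symbols at both ends")
    }
  } else {
    edges <- tibble::tibble(regulator = character(), target = character())
  }
  disease_genes <- unique(as.character(disease_genes))
  disease_genes <- disease_genes[nzchar(disease_genes) & !is.na(disease_genes)]
  if (length(disease_genes) == 0L) {
    warn("Empty disease-gene set: the biological-context filter will remove every variant")
  }
  structure(list(edges = edges, disease_genes = disease_genes),
            class = "gene_network")
}

#' @exportS3Method base::print
print.gene_network <- function(x, ...) {
  cat("<gene_network> ", nrow(x$edges), " edges, ",
      length(x$disease_genes), " disease genes\n", sep = "")
  invisible(x)
}

#' Read a gene network from an edge list and a disease-gene list
#'
#' @param path Two-column TSV of directed edges (regulator, target); a
#'   header row named `regulator<TAB>target` is allowed and skipped.
#' @param disease_genes_path Text file, one gene symbol per line.
#' @return A `gene_network` object.
#' @export
read_gene_network <- function(path, disease_genes_path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) > 0L && grepl("^regulator\\ttarget$", lines[1L])) {
    lines <- lines[-1L]
  }
  if (length(lines) > 0L) {
    parts <- stringr::str_split_fixed(lines, "\t", 2L)
    edges <- tibble::tibble(regulator = parts[, 1L], target = parts[, 2L])
  } else {
    edges <- tibble::tibble(regulator = character(), target = character())
  }
  genes <- trimws(readLines(disease_genes_path))
  genes <- genes[nzchar(genes)]
  gene_network(edges, genes)
}

#' Write a gene network to disk
#'
#' @param network A `gene_network`.
#' @param edges_path,disease_genes_path Output paths for the edge list and
#'   the disease-gene list.
#' @return `edges_path`, invisibly.
#' @export
write_gene_network <- function(network, edges_path, disease_genes_path) {
  readr::write_tsv(network$edges, edges_path, progress = FALSE)
  writeLines(network$disease_genes, disease_genes_path)
  invisible(edges_path)
}
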