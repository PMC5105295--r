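# Independent brute-force oracle for the exact 2xK Fisher test: enumerates
# candidate first rows by recursion and scores each fixed-margin table with
# the factorial form of the multivariate hypergeometric mass — a different
# route from the package's choose-product enumeration.
oracle_fisher_2xk <- function(m, tie_tol = 1e-7) {
  r <- rowSums(m)
  cs <- colSums(m)
  n <- sum(m)
  rows1 <- list()
  recurse <- function(prefix, remaining) {
    j <- length(prefix) + 1L
    if (j == length(cs)) {
      last <- remaining
      if (last >= 0 && last <= cs[j]) {
        rows1[[length(rows1) + 1L]] <<- c(prefix, last)
      }
      return(invisible())
    }
    for (x in 0:min(remaining, cs[j])) recurse(c(prefix, x), remaining - x)
  }
  recurse(integer(), r[1L])
  log_prob <- function(x1) {
    x2 <- cs - x1
    sum(lfactorial(r)) + sum(lfactorial(cs)) - lfactorial(n) -
      sum(lfactorial(c(x1, x2)))
  }
  lp <- vapply(rows1, log_prob, 0)
  lp_obs <- log_prob(m[1L, ])
  sum(exp(lp[lp <= lp_obs + log1p(tie_tol)]))
}

# Variant-table builder for hand-crafted cascade cases. Genotypes are GT
# strings in pedigree order (father III-1, mother III-2, daughter IV-3 by
# default).
mk_variant <- function(chrom = "1", pos = 100L, ref = "A", alt = "T",
                       gene = "G1", gts = c("0/0", "0/1", "0/1"),
                       quals = c(50, 50, 50),
                       samples = c("III-1", "III-2", "IV-3")) {
  parts <- strsplit(gts, "[/|]")
  a1 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
  a2 <- suppressWarnings(as.integer(vapply(
    parts, function(p) if (length(p) >= 2L) p[[2L]] else NA_character_, ""
  )))
  ploidy <- ifelse(lengths(parts) == 1L & gts != ".", 1L, 2L)
  alts <- strsplit(alt, ",")[[1L]]
  tibble::tibble(
    variant_id = paste(chrom, pos, ref, alt, sep = ":"),
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    gene = gene, alts = list(alts),
    calls = list(tibble::tibble(
      sample = samples, allele1 = a1, allele2 = a2, ploidy = ploidy,
      quality = as.numeric(quals),
      zygosity = zygosity_class(a1, a2, ploidy)
    ))
  )
}

mk_variants <- function(...) dplyr::bind_rows(...)

# Annotation rows aligned to mk_variant keys; unspecified fields are missing.
mk_annotation <- function(chrom = "1", pos = 100L, ref = "A", alt = "T",
                          gene = "G1", af_1kg = NA, af_cg69 = NA,
                          af_esp = NA, clinical_assertion = NA,
                          gof_literature = FALSE, inferred_activating = FALSE,
                          bsift_gof = FALSE, mirna_site = FALSE,
                          consequence = NA, splice_intron_offset = NA,
                          sift_score = NA, provean_score = NA) {
  as_annotations(tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt, gene = gene,
    af_1kg = as.numeric(af_1kg), af_cg69 = as.numeric(af_cg69),
    af_esp = as.numeric(af_esp),
    clinical_assertion = as.character(clinical_assertion),
    gof_literature = gof_literature,
    inferred_activating = inferred_activating, bsift_gof = bsift_gof,
    mirna_site = mirna_site, consequence = as.character(consequence),
    splice_intron_offset = as.integer(splice_intron_offset),
    sift_score = as.numeric(sift_score),
    provean_score = as.numeric(provean_score)
  ))
}

mk_annotations <- function(...) {
  tabs <- lapply(list(...), tibble::as_tibble)
  as_annotations(dplyr::bind_rows(tabs))
}

trio_ped <- function() trio_pedigree()
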