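# Case-control replication statistics, implemented from first principles:
# HWE chi-square goodness of fit, exact Fisher tests on the 2x3 genotype
# table (full fixed-margin enumeration) and the collapsed 2x2 allele
# table, and the Cochran-Armitage trend test (asymptotic and Monte-Carlo
# permutation). All operate on a two-row genotype count table.

#' Build a case/control genotype count table
#'
#' @param cases,controls Length-3 non-negative integer vectors of
#'   (hom-ref, het, hom-alt) counts.
#' @return A `genotype_counts` tibble with rows `case`, `control` and
#'   columns `arm`, `n_hom_ref`, `n_het`, `n_hom_alt`.
#' @examples
#' genotype_counts(cases = c(80, 25, 4), controls = c(90, 20, 1))
#' @export
genotype_counts <- function(cases, controls) {
  as_genotype_counts(tibble::tibble(
    arm = c("case", "control"),
    n_hom_ref = c(cases[1L], controls[1L]),
    n_het = c(cases[2L], controls[2L]),
    n_hom_alt = c(cases[3L], controls[3L])
  ))
}

#' Coerce and validate a genotype count table
#'
#' @param x A data frame with columns `arm` (`"case"`/`"control"`),
#'   `n_hom_ref`, `n_het`, `n_hom_alt`, or a 2x3 matrix with rows
#'   (case, control).
#' @return A validated `genotype_counts` tibble.
#' @export
as_genotype_counts <- function(x) {
  if (is.matrix(x)) {
    x <- tibble::tibble(arm = c("case", "control"),
                        n_hom_ref = x[, 1L], n_het = x[, 2L],
                        n_hom_alt = x[, 3L])
  }
  x <- tibble::as_tibble(x)
  need <- c("arm", "n_hom_ref", "n_het", "n_hom_alt")
  if (!all(need %in% names(x))) {
    abort(paste("Genotype counts need columns:", paste(need, collapse = ", ")))
  }
  counts <- as.matrix(x[, need[-1L]])
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    abort("Genotype counts must be non-negative integers")
  }
  if (!setequal(x$arm, c("case", "control")) || nrow(x) != 2L) {
    abort("Genotype counts need exactly one 'case' and one 'control' row")
  }
  out <- x[match(c("case", "control"), x$arm), need]
  class(out) <- c("genotype_counts", class(tibble::tibble()))
  out
}

count_matrix <- function(table) {
  table <- as_genotype_counts(table)
  m <- as.matrix(table[, c("n_hom_ref", "n_het", "n_hom_alt")])
  storage.mode(m) <- "double"
  rownames(m) <- c("case", "control")
  m
}

new_assoc_result <- function(method, statistic, p_value, mc_reps = NA_integer_,
                             seed = NA_integer_, flags = character()) {
  structure(
    list(method = method, statistic = statistic, p_value = p_value,
         mc_reps = mc_reps, seed = seed, flags = flags),
    class = "assoc_result"
  )
}

#' @exportS3Method base::print
print.assoc_result <- function(x, ...) {
  cat("<assoc_result> ", x$method,
      if (!is.na(x$statistic)) sprintf("  statistic = %.4g", x$statistic),
      sprintf("  p = %.4g", x$p_value),
      if (!is.na(x$mc_reps)) sprintf("  (%d Monte-Carlo reps)", x$mc_reps),
      if (length(x$flags)) paste0("  [", paste(x$flags, collapse = ","), "]"),
      "\n", sep = "")
  invisible(x)
}

#' @rdname tidy
#' @export
tidy.assoc_result <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    statistic = x$statistic,
    p.value = x$p_value,
    mc.reps = x$mc_reps,
    seed = x$seed,
    flags = paste(x$flags, collapse = ";")
  )
}

#' @rdname glance
#' @export
glance.assoc_result <- function(x, ...) tidy(x)

#' Hardy-Weinberg equilibrium chi-square goodness-of-fit test
#'
#' Estimates the allele frequency from the genotype counts, compares the
#' observed counts to the HWE expectations \eqn{n\hat p^2, 2n\hat p\hat q,
#' n\hat q^2}, and refers the chi-square statistic to 1 degree of freedom
#' (one estimated parameter, no continuity correction). `p_hat` is the
#' frequency of the allele counted by `n_hom_ref`.
#'
#' @param counts Length-3 vector of (hom-ref, het, hom-alt) counts, or a
#'   one-row data frame with columns `n_hom_ref`, `n_het`, `n_hom_alt`.
#' @return An `hwe_result` with `chi2`, `df`, `p_value`, `p_hat`, `n` and
#'   a `monomorphic` flag; monomorphic samples return `chi2 = 0`,
#'   `p_value = 1`.
#' @examples
#' hwe_chisq(c(49, 42, 9))   # exact HWE proportions: chi2 = 0
#' @export
hwe_chisq <- function(counts) {
  if (is.data.frame(counts)) {
    counts <- as.numeric(counts[1L, c("n_hom_ref", "n_het", "n_hom_alt")])
  }
  counts <- as.numeric(counts)
  if (length(counts) != 3L || any(is.na(counts)) || any(counts < 0)) {
    abort("HWE test needs three non-negative genotype counts")
  }
  n <- sum(counts)
  if (n <= 0) abort("HWE test needs a positive sample size")
  p_hat <- (2 * counts[1L] + counts[2L]) / (2 * n)
  monomorphic <- p_hat %in% c(0, 1)
  if (monomorphic) {
    chi2 <- 0
  } else {
    expected <- n * c(p_hat^2, 2 * p_hat * (1 - p_hat), (1 - p_hat)^2)
    keep <- expected > 0
    chi2 <- sum((counts[keep] - expected[keep])^2 / expected[keep])
  }
  structure(
    list(chi2 = chi2, df = 1L,
         p_value = pchisq(chi2, df = 1L, lower.tail = FALSE),
         p_hat = p_hat, n = n, monomorphic = monomorphic),
    class = "hwe_result"
  )
}

#' @exportS3Method base::print
print.hwe_result <- function(x, ...) {
  cat(sprintf("<hwe_result> chi2 = %.4g (df = 1), p = %.4g, p_hat = %.4g, n = %d%s\n",
              x$chi2, x$p_value, x$p_hat, as.integer(x$n),
              if (x$monomorphic) " [monomorphic]" else ""))
  invisible(x)
}

#' Tidy association and HWE results
#'
#' @param x An `assoc_result` or `hwe_result`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @name tidy
NULL

#' One-row summaries of association and HWE results
#'
#' @param x An `assoc_result` or `hwe_result`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @name glance
NULL

#' @rdname tidy
#' @export
tidy.hwe_result <- function(x, ...) {
  tibble::tibble(
    method = "hwe_chisq", statistic = x$chi2, df = x$df,
    p.value = x$p_value, p.hat = x$p_hat, n = x$n,
    monomorphic = x$monomorphic
  )
}

#' @rdname glance
#' @export
glance.hwe_result <- function(x, ...) tidy(x)

# Enumerate every 2xK table with the given margins and return the exact
# two-sided p by the point-probability (minlike) criterion: the total
# multivariate-hypergeometric mass of tables no more probable than the
# observed one (relative tie tolerance 1e-7).
fisher_fixed_margin_p <- function(row1, col_sums, tie_tol = 1e-7) {
  n <- sum(col_sums)
  r1 <- sum(row1)
  k <- length(col_sums)
  log_denom <- lchoose(n, r1)
  cells <- lapply(col_sums[-k], function(cj) 0:min(r1, cj))
  grid <- as.matrix(expand.grid(cells))
  last <- r1 - rowSums(grid)
  keep <- last >= 0 & last <= col_sums[k]
  grid <- cbind(grid[keep, , drop = FALSE], last[keep])
  logp <- matrix(lchoose(rep(col_sums, each = nrow(grid)), as.vector(grid)),
                 nrow = nrow(grid))
  logp <- rowSums(logp) - log_denom
  logp_obs <- sum(lchoose(col_sums, row1)) - log_denom
  sum(exp(logp[logp <= logp_obs + log1p(tie_tol)]))
}

#' Exact Fisher test on a 2x3 case/control genotype table
#'
#' Enumerates every table sharing the observed row and column margins,
#' computes each table's multivariate-hypergeometric probability, and sums
#' the probabilities of tables no more probable than the observed one
#' (point-probability two-sided criterion, relative tie tolerance 1e-7).
#' Enumeration is exact and feasible at cohort scale (hundreds of samples
#' per arm). Genotype columns with zero total are dropped, reducing to a
#' 2x2 (or degenerate) problem; a table with a single non-zero column has
#' `p = 1`.
#'
#' @param table A `genotype_counts` table (see [genotype_counts()]).
#' @return An `assoc_result`; `statistic` is the observed table
#'   probability.
#' @export
fisher_exact_2x3 <- function(table) {
  m <- count_matrix(table)
  if (any(rowSums(m) <= 0)) abort("Both arms need a positive sample size")
  nz <- colSums(m) > 0
  flags <- character()
  if (sum(nz) <= 1L) {
    return(new_assoc_result("fisher_exact_2x3", statistic = 1, p_value = 1,
                            flags = "degenerate"))
  }
  if (!all(nz)) flags <- "zero_column_dropped"
  m <- m[, nz, drop = FALSE]
  p_obs <- exp(sum(lchoose(colSums(m), m[1L, ])) - lchoose(sum(m), sum(m[1L, ])))
  p <- fisher_fixed_margin_p(m[1L, ], colSums(m))
  new_assoc_result("fisher_exact_2x3", statistic = p_obs,
                   p_value = min(p, 1), flags = flags)
}

#' Collapse a genotype table to allele counts
#'
#' Each arm contributes two alleles per sample: the reference-allele count
#' is `2 * n_hom_ref + n_het` and the alternate count `2 * n_hom_alt +
#' n_het`.
#'
#' @param table A `genotype_counts` table.
#' @return A tibble with columns `arm`, `n_ref`, `n_alt`.
#' @examples
#' allele_counts(genotype_counts(c(49, 42, 9), c(50, 40, 10)))
#' @export
allele_counts <- function(table) {
  m <- count_matrix(table)
  tibble::tibble(
    arm = rownames(m),
    n_ref = unname(2 * m[, 1L] + m[, 2L]),
    n_alt = unname(2 * m[, 3L] + m[, 2L])
  )
}

#' Exact Fisher test on the collapsed 2x2 allele table
#'
#' Collapses genotypes to allele counts (see [allele_counts()]) and
#' applies the two-sided exact test with the point-probability criterion
#' on the hypergeometric distribution of the case reference-allele count.
#'
#' @param table A `genotype_counts` table.
#' @return An `assoc_result`; `statistic` is the observed table
#'   probability.
#' @export
fisher_exact_allele_2x2 <- function(table) {
  ac <- allele_counts(table)
  row1 <- c(ac$n_ref[1L], ac$n_alt[1L])
  cols <- c(sum(ac$n_ref), sum(ac$n_alt))
  if (sum(row1) <= 0 || sum(cols) - sum(row1) <= 0) {
    abort("Both arms need a positive allele count")
  }
  if (any(cols == 0)) {
    return(new_assoc_result("fisher_exact_allele_2x2", statistic = 1,
                            p_value = 1, flags = "degenerate"))
  }
  p_obs <- exp(sum(lchoose(cols, row1)) - lchoose(sum(cols), sum(row1)))
  p <- fisher_fixed_margin_p(row1, cols)
  new_assoc_result("fisher_exact_allele_2x2", statistic = p_obs,
                   p_value = min(p, 1))
}

armitage_chi2 <- function(case_row, col_sums, n_case, n_total, scores) {
  # Classical Cochran-Armitage trend chi-square (1 df) on scored genotype
  # counts; vectorized over rows of case_row (a matrix, one table per row).
  s1 <- drop(case_row %*% scores)
  s2 <- sum(scores * col_sums)
  s3 <- sum(scores^2 * col_sums)
  denom <- n_case * (n_total - n_case) * (n_total * s3 - s2^2)
  if (denom <= 0) return(rep(NA_real_, length(s1)))
  n_total * (n_total * s1 - n_case * s2)^2 / denom
}

#' Cochran-Armitage trend test with asymptotic or Monte-Carlo p-value
#'
#' Tests for a linear trend in case proportion across scored genotype
#' categories (default additive scores 0, 1, 2 for hom-ref, het,
#' hom-alt). The asymptotic mode refers the classical trend chi-square to
#' 1 df. The Monte-Carlo mode permutes case/control labels by drawing,
#' conditional on all margins, from the multivariate hypergeometric
#' distribution, and uses the add-one estimator
#' \eqn{p = (1 + \#\{\chi^2_{perm} \ge \chi^2_{obs}\}) / (reps + 1)},
#' which can never return zero and is a valid p-value. When the pooled
#' sample is concentrated on a single score the statistic is undefined and
#' `p = 1` is returned with a `zero_variance` flag.
#'
#' @param table A `genotype_counts` table.
#' @param scores Numeric length-3 genotype scores (default `c(0, 1, 2)`).
#' @param mode `"asymptotic"` or `"monte_carlo"`.
#' @param reps Number of Monte-Carlo permutations (default 10000).
#' @param seed Integer seed for the Monte-Carlo draw; `NULL` uses the
#'   current RNG state.
#' @return An `assoc_result`; `statistic` is the trend chi-square.
#' @export
armitage_trend <- function(table, scores = c(0, 1, 2),
                           mode = c("asymptotic", "monte_carlo"),
                           reps = 10000L, seed = NULL) {
  mode <- match.arg(mode)
  m <- count_matrix(table)
  if (any(rowSums(m) <= 0)) abort("Both arms need a positive sample size")
  if (length(scores) != ncol(m)) abort("Need one score per genotype column")
  col_sums <- colSums(m)
  n_total <- sum(m)
  n_case <- sum(m[1L, ])
  s2 <- sum(scores * col_sums)
  s3 <- sum(scores^2 * col_sums)
  method <- paste0("armitage_trend_", mode)
  if (n_total * s3 - s2^2 <= 0) {
    return(new_assoc_result(method, statistic = NA_real_, p_value = 1,
                            flags = "zero_variance"))
  }
  chi2_obs <- armitage_chi2(matrix(m[1L, ], nrow = 1L), col_sums,
                            n_case, n_total, scores)
  if (mode == "asymptotic") {
    return(new_assoc_result(method, statistic = chi2_obs,
                            p_value = pchisq(chi2_obs, 1L, lower.tail = FALSE)))
  }
  reps <- as.integer(reps)
  if (is.na(reps) || reps < 1L) abort("Monte-Carlo mode needs reps >= 1")
  # Permuting labels conditions on all margins; sampling the smaller arm
  # makes the draw (and hence the p-value, at a fixed seed) symmetric in
  # the two labels.
  k_star <- min(n_case, n_total - n_case)
  draw <- function() {
    x1 <- rhyper(reps, col_sums[1L], n_total - col_sums[1L], k_star)
    x2 <- rhyper(reps, col_sums[2L], col_sums[3L], k_star - x1)
    cbind(x1, x2, k_star - x1 - x2)
  }
  perm <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  chi2_perm <- armitage_chi2(perm, col_sums, k_star, n_total, scores)
  hits <- sum(chi2_perm >= chi2_obs - 1e-12)
  new_assoc_result(method, statistic = chi2_obs,
                   p_value = (1 + hits) / (reps + 1),
                   mc_reps = reps,
                   seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Per-arm genotype frequencies as percentages
#'
#' @param table A `genotype_counts` table.
#' @param digits Optional rounding (e.g. `0` for whole-percent reporting);
#'   `NULL` leaves the percentages exact.
#' @return A tibble with columns `arm`, `pct_hom_ref`, `pct_het`,
#'   `pct_hom_alt`; each row sums to 100 up to rounding.
#' @export
genotype_frequencies <- function(table, digits = NULL) {
  m <- count_matrix(table)
  if (any(rowSums(m) <= 0)) abort("Both arms need a positive sample size")
  pct <- sweep(m, 1L, rowSums(m), "/") * 100
  if (!is.null(digits)) pct <- round(pct, digits)
  tibble::tibble(
    arm = rownames(m),
    pct_hom_ref = pct[, 1L], pct_het = pct[, 2L], pct_hom_alt = pct[, 3L]
  )
}
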