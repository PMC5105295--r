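# Internal helpers shared across modules.

#' Derive a named random stream seed from a global seed
#'
#' Each simulation component draws from its own stream so that, e.g., adding
#' background variants to a trio does not perturb cohort draws made under the
#' same global seed. The stream seed is a deterministic hash of
#' `(seed, stream)` folded into the 32-bit signed integer range.
#'
#' @param seed Integer global seed.
#' @param stream Character stream label.
#' @return An integer seed.
#' @keywords internal
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)) * 131)
  ((abs(as.numeric(seed)) * 48271 + h) %% 2147483629) + 1
}

# Variant key shared by readers, simulator and cascade: one string per record.
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x)
}

# readr, quietly
read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, ...)
}
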