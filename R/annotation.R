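# HGVS coding-coordinate arithmetic and predictor-score classification.

#' Map a 1-based CDS position to its 1-based codon (amino-acid) index
#'
#' Coding positions 1-3 fall in codon 1, 4-6 in codon 2, and so on:
#' `ceiling(cds_pos / 3)`.
#'
#' @param cds_pos Integer vector of 1-based coding-DNA positions.
#' @return Integer vector of codon indices.
#' @examples
#' cds_to_codon(c(1, 3, 4))   # 1 1 2
#' cds_to_codon(745)          # 249
#' @export
cds_to_codon <- function(cds_pos) {
  if (any(is.na(cds_pos)) || any(cds_pos < 1) || any(cds_pos != floor(cds_pos))) {
    abort("CDS positions must be integers >= 1")
  }
  as.integer(ceiling(cds_pos / 3))
}

#' Classify a coding deletion-insertion by its effect on the reading frame
#'
#' @param deleted,inserted Character vectors of deleted and inserted
#'   sequence (either may be empty, `""`).
#' @return Character vector: `"substitution"` when lengths are equal,
#'   `"frameshift"` when the net length change is not a multiple of 3,
#'   `"inframe_delins"` otherwise.
#' @examples
#' classify_delins("AA", "G")    # frameshift (net -1)
#' classify_delins("CC", "TA")   # substitution
#' classify_delins("TGA", "")    # inframe_delins (net -3)
#' @export
classify_delins <- function(deleted, inserted) {
  n <- max(length(deleted), length(inserted))
  del <- rep_len(ifelse(is.na(deleted), "", deleted), n)
  ins <- rep_len(ifelse(is.na(inserted), "", inserted), n)
  net <- nchar(ins) - nchar(del)
  dplyr::case_when(
    net == 0L ~ "substitution",
    net %% 3L != 0L ~ "frameshift",
    TRUE ~ "inframe_delins"
  )
}

#' Classify a SIFT score
#'
#' SIFT scores lie in \eqn{[0, 1]}; scores of at most 0.05 predict a
#' damaging substitution, larger scores a tolerated one.
#'
#' @param score Numeric vector in \eqn{[0, 1]}; `NA` allowed.
#' @return `"damaging"`, `"tolerated"` or `"unknown"` per score.
#' @examples
#' sift_classify(c(0.010, 0.140, 0.05, NA))
#' @export
sift_classify <- function(score) {
  if (any(!is.na(score) & (score < 0 | score > 1))) {
    abort("SIFT scores must lie in [0, 1]")
  }
  dplyr::case_when(
    is.na(score) ~ "unknown",
    score <= 0.05 ~ "damaging",
    TRUE ~ "tolerated"
  )
}

#' Classify a PROVEAN score
#'
#' PROVEAN's binary classification calls scores below the threshold
#' (default -2.5) deleterious and scores above it neutral. A score exactly
#' at the threshold is classified neutral — the conservative,
#' non-deleterious call for a boundary the binary split leaves undefined.
#'
#' @param score Numeric vector; `NA` allowed.
#' @param threshold Decision threshold (default -2.5).
#' @return `"deleterious"`, `"neutral"` or `"unknown"` per score.
#' @examples
#' provean_classify(c(-1.97, -3.0, -2.5, NA))
#' @export
provean_classify <- function(score, threshold = -2.5) {
  dplyr::case_when(
    is.na(score) ~ "unknown",
    score < threshold ~ "deleterious",
    TRUE ~ "neutral"
  )
}

#' Parse simple HGVS coding-DNA descriptions
#'
#' Supports exactly two forms: substitutions `c.<N><X>><Y>` (e.g.
#' `c.1919G>A`) and deletion-insertions `c.<N>_<M>del<XX>ins<YY>` (e.g.
#' `c.745_746delAAinsG`). Anything else raises an "unsupported HGVS form"
#' error — the full HGVS grammar is out of scope.
#'
#' @param hgvs Character vector of `c.`-style descriptions.
#' @return A tibble with columns `hgvs`, `cds_start`, `cds_end`,
#'   `deleted`, `inserted`.
#' @export
parse_hgvs_c <- function(hgvs) {
  sub_m <- stringr::str_match(hgvs, "^c\\.([0-9]+)([ACGT])>([ACGT])$")
  del_m <- stringr::str_match(
    hgvs, "^c\\.([0-9]+)_([0-9]+)del([ACGT]+)ins([ACGT]+)$"
  )
  bad <- is.na(sub_m[, 1L]) & is.na(del_m[, 1L])
  if (any(bad)) {
    abort(paste0("unsupported HGVS form: ",
                 paste(hgvs[bad], collapse = ", ")))
  }
  start <- ifelse(!is.na(sub_m[, 1L]),
                  as.integer(sub_m[, 2L]), as.integer(del_m[, 2L]))
  end <- ifelse(!is.na(sub_m[, 1L]), start, as.integer(del_m[, 3L]))
  if (any(end < start)) {
    abort("HGVS range end precedes start")
  }
  tibble::tibble(
    hgvs = hgvs,
    cds_start = start,
    cds_end = end,
    deleted = ifelse(!is.na(sub_m[, 1L]), sub_m[, 3L], del_m[, 4L]),
    inserted = ifelse(!is.na(sub_m[, 1L]), sub_m[, 4L], del_m[, 5L])
  )
}

#' Describe coding changes: codon index and reading-frame consequence
#'
#' Convenience wrapper combining [parse_hgvs_c()], [cds_to_codon()] (on
#' the first affected CDS position) and [classify_delins()].
#'
#' @param hgvs Character vector of supported HGVS `c.` descriptions.
#' @return A tibble with the parsed fields plus `codon` and `class`.
#' @examples
#' describe_coding_change(c("c.1919G>A", "c.745_746delAAinsG"))
#' @export
describe_coding_change <- function(hgvs) {
  parsed <- parse_hgvs_c(hgvs)
  dplyr::mutate(
    parsed,
    codon = cds_to_codon(.data$cds_start),
    class = classify_delins(.data$deleted, .data$inserted)
  )
}
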