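#' Compute tumor mutation burden for one sample and one method
#'
#' TMB is the number of qualifying somatic coding variants divided by the
#' coding footprint interrogated, in megabases. The numerator is the size of
#' [filter_variants()] applied to the sample's records under the given
#' policy; the denominator is the footprint's `total_mb`.
#'
#' @param variants Variant tibble (may contain several samples).
#' @param policy An [inclusion_policy()].
#' @param fp The `panel_footprint` used as denominator. By design this may
#'   differ from `policy$region` only in pathological setups; by default the
#'   policy's own region is used.
#' @param sample_id Sample to count.
#' @param method_label Label for this counting method, e.g. `"WES.nonsyn"`.
#' @return One-row tibble: `sample_id`, `method_label`, `variant_count`,
#'   `footprint_mb`, `tmb` (variants per megabase, full floating precision).
#' @export
compute_tmb <- function(variants, policy, fp = policy$region, sample_id,
                        method_label = fp$panel_name) {
  if (!is.finite(fp$total_mb) || fp$total_mb <= 0) {
    stop("zero or invalid footprint for '", fp$panel_name,
         "': cannot compute TMB")
  }
  recs <- variants[variants$sample_id == sample_id, , drop = FALSE]
  kept <- filter_variants(recs, policy)
  n <- nrow(kept)
  tibble::tibble(sample_id = sample_id, method_label = method_label,
                 variant_count = n, footprint_mb = fp$total_mb,
                 tmb = n / fp$total_mb)
}

#' Define a TMB counting method
#'
#' @param label Unique method label (panel name plus policy tag).
#' @param policy An [inclusion_policy()].
#' @param fp Denominator footprint; defaults to the policy's region.
#' @return A `tmb_method` list.
#' @export
tmb_method <- function(label, policy, fp = policy$region) {
  stopifnot(inherits(policy, "inclusion_policy"),
            inherits(fp, "panel_footprint"))
  structure(list(label = label, policy = policy, fp = fp),
            class = "tmb_method")
}

#' Cohort TMB matrix
#'
#' Computes TMB for every sample under every counting method. Samples listed
#' in `samples` but absent from the variant table get a count of zero rather
#' than a missing value (an empty variant list is a real observation for a
#' tumor with no qualifying mutations).
#'
#' @param variants Variant tibble for the whole cohort.
#' @param methods List of [tmb_method()] objects; labels must be unique.
#' @param samples Ordered sample ids; defaults to the distinct
#'   `sample_id`s present in `variants`.
#' @return Long tibble of class `tmb_matrix`: one row per (sample, method)
#'   with `sample_id`, `method_label`, `variant_count`, `footprint_mb`,
#'   `tmb`.
#' @export
tmb_matrix <- function(variants, methods, samples = NULL) {
  stopifnot(length(methods) >= 1)
  labels <- vapply(methods, function(m) m$label, character(1))
  if (anyDuplicated(labels)) stop("duplicate method labels: ",
                                  paste(labels[duplicated(labels)], collapse = ", "))
  if (is.null(samples)) samples <- unique(variants$sample_id)
  if (!length(samples)) stop("no samples to compute TMB for")
  # One filter pass per method, then per-sample counts; equivalent to
  # calling compute_tmb per cell but linear in cohort size.
  rows <- lapply(methods, function(m) {
    kept <- filter_variants(variants, m$policy)
    counts <- table(factor(kept$sample_id, levels = samples))
    tibble::tibble(sample_id = samples,
                   method_label = m$label,
                   variant_count = as.integer(counts),
                   footprint_mb = m$fp$total_mb,
                   tmb = as.integer(counts) / m$fp$total_mb)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("tmb_matrix", class(tibble::tibble())))
}

#' Widen a TMB matrix to samples x methods
#'
#' @param m A `tmb_matrix` (long form).
#' @param value Which column to spread: `"tmb"` (default) or
#'   `"variant_count"`.
#' @return Tibble with one row per sample and one column per method.
#' @export
tmb_wide <- function(m, value = c("tmb", "variant_count")) {
  value <- match.arg(value)
  tidyr::pivot_wider(tibble::as_tibble(m)[, c("sample_id", "method_label", value)],
                     names_from = "method_label", values_from = dplyr::all_of(value))
}
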