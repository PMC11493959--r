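# maxMAF for targeted-panel validation cohorts: filter a variant report to
# somatic hotspots and return the maximum mutant allele frequency.

#' Classify targeted-panel variant calls
#'
#' A variant is a somatic `hotspot` when its nucleotide change was observed
#' in at least 20 cancer cases of the reference catalogue (`recurrence`),
#' a `putative_germline` when it is a non-hotspot with MAF above 40%, and a
#' `non_hotspot` otherwise. Hotspots are retained regardless of MAF (the
#' germline filter applies to non-hotspots only); hotspots above 40% MAF are
#' flagged for review by [max_maf()].
#'
#' @param recurrence integer vector of catalogue recurrence counts.
#' @param maf numeric vector of mutant allele frequencies (percent, 0-100).
#' @return character vector in `c("hotspot", "putative_germline",
#'   "non_hotspot")`.
#' @export
classify_variant <- function(recurrence, maf) {
  if (any(recurrence < 0)) delfi_error("negative recurrence count", "delfi_validation_error")
  if (any(maf < 0 | maf > 100)) delfi_error("MAF outside [0, 100]", "delfi_validation_error")
  ifelse(recurrence >= 20L, "hotspot",
         ifelse(maf > 40, "putative_germline", "non_hotspot"))
}

#' Maximum MAF over somatic hotspot variants
#'
#' Filters the variant table to somatic hotspots and returns the maximum MAF.
#' Undefined (NA, with a reason) when no hotspot survives.
#'
#' @param variants data.frame with columns `maf` and `recurrence` (and
#'   optionally `gene`, `variant`).
#' @return list with `max_maf` (percent or NA), `n_hotspots`, `flags`
#'   (character; currently "hotspot_maf_gt_40" when the maximum comes from a
#'   hotspot above 40% MAF), `reason` when undefined.
#' @export
max_maf <- function(variants) {
  if (is.null(variants) || nrow(variants) == 0L)
    return(list(max_maf = NA_real_, n_hotspots = 0L, flags = character(),
                reason = "no variants"))
  cls <- classify_variant(variants$recurrence, variants$maf)
  hs <- variants$maf[cls == "hotspot"]
  if (!length(hs))
    return(list(max_maf = NA_real_, n_hotspots = 0L, flags = character(),
                reason = "no hotspot variants"))
  flags <- if (max(hs) > 40) "hotspot_maf_gt_40" else character()
  list(max_maf = max(hs), n_hotspots = length(hs), flags = flags, reason = NULL)
}
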