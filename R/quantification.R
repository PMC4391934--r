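# Per-field and per-core quantification: Ki67 sum, CK sum, Ki67/CK ratio.

#' Quantify one view field
#'
#' Sums the unmixed Ki67 and CK abundances over all pixels above a threshold.
#' "Signal" is the summed unmixed intensity (a.u.); supra-threshold pixel
#' counts are reported alongside as diagnostics.
#'
#' @param maps An `abundance_maps` object (autofluorescence is ignored here;
#'   apply [drop_autofluorescence()] upstream for explicit background
#'   deletion).
#' @param threshold Intensity threshold (a.u., >= 0); pixels with abundance
#'   strictly above it contribute. Default 0: everything the unmixer assigns
#'   is summed.
#' @return An object of class `field_quant` with `ki67_signal`, `ck_signal`,
#'   `n_pixels_ki67`, `n_pixels_ck`.
#' @export
quantify_field <- function(maps, threshold = 0) {
  stopifnot(inherits(maps, "abundance_maps"))
  if (!is.finite(threshold) || threshold < 0)
    stop("threshold must be a non-negative number", call. = FALSE)
  ki <- maps$ki67_map > threshold
  ck <- maps$ck_map > threshold
  structure(list(
    ki67_signal = sum(maps$ki67_map[ki]),
    ck_signal = sum(maps$ck_map[ck]),
    n_pixels_ki67 = sum(ki),
    n_pixels_ck = sum(ck)), class = "field_quant")
}

#' @export
print.field_quant <- function(x, ...) {
  cat(sprintf("field: Ki67 signal %.6g (%d px), CK signal %.6g (%d px)\n",
              x$ki67_signal, x$n_pixels_ki67, x$ck_signal, x$n_pixels_ck))
  invisible(x)
}

#' Ki67/CK ratio
#'
#' The core proliferation statistic: total Ki67 signal divided by total CK
#' signal. It represents the proportion of tumour signal attributable to
#' actively proliferating cells and may exceed 1.
#'
#' @param ki67_sum Total Ki67 signal (a.u., >= 0).
#' @param ck_sum Total CK signal (a.u., must be > 0).
#' @return `ki67_sum / ck_sum`.
#' @examples
#' compute_ratio(1.86e6, 1.0e7)  # 0.186
#' @export
compute_ratio <- function(ki67_sum, ck_sum) {
  if (!is.finite(ki67_sum) || ki67_sum < 0)
    stop("ki67_sum must be a non-negative number", call. = FALSE)
  if (!is.finite(ck_sum) || ck_sum <= 0)
    stop("degenerate core: ck_sum must be positive", call. = FALSE)
  ki67_sum / ck_sum
}

#' Aggregate view fields into a core quantification
#'
#' Sums Ki67 and CK signals over the fields of one tissue-microarray core
#' (six fields in a standard acquisition) and computes the Ki67/CK ratio.
#'
#' @param fields List of `field_quant` objects from [quantify_field()].
#' @param expected_fields Number of fields a faithful acquisition should
#'   have; a different count triggers a warning, not an error. Default 6.
#' @return An object of class `core_quant` with `ki67_sum`, `ck_sum`,
#'   `ratio`, `n_fields`.
#' @export
aggregate_core <- function(fields, expected_fields = 6) {
  if (length(fields) < 1)
    stop("invalid input: at least one field is required", call. = FALSE)
  stopifnot(all(vapply(fields, inherits, logical(1), "field_quant")))
  if (length(fields) != expected_fields)
    warning(sprintf("core aggregated from %d fields (expected %d)",
                    length(fields), expected_fields), call. = FALSE)
  ki67_sum <- sum(vapply(fields, `[[`, numeric(1), "ki67_signal"))
  ck_sum <- sum(vapply(fields, `[[`, numeric(1), "ck_signal"))
  structure(list(ki67_sum = ki67_sum, ck_sum = ck_sum,
                 ratio = compute_ratio(ki67_sum, ck_sum),
                 n_fields = length(fields)), class = "core_quant")
}

#' @export
print.core_quant <- function(x, ...) {
  cat(sprintf("core (%d fields): Ki67 sum %.6g, CK sum %.6g, Ki67/CK ratio %.4g\n",
              x$n_fields, x$ki67_sum, x$ck_sum, x$ratio))
  invisible(x)
}
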