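#' Bundled sorghum straw-ash reference dataset
#'
#' The package ships the quantitative phase analysis (Rietveld, internal
#' standard), bulk chemical analysis and straw composition of four ashes
#' produced at 550 degrees C from the straw of two sorghum varieties — the
#' grain sorghum Razinieh and the sweet sorghum Della — each grown on
#' phosphate-supplemented ("normal") and phosphate-depleted ("low") soil.
#'
#' @return `sorghum_ash_samples()` returns the four sample ids.
#' @examples
#' sorghum_ash_samples()
#' sorghum_ash_phases("razinieh_normal")
#' @export
sorghum_ash_samples <- function() {
  c("razinieh_normal", "razinieh_low", "della_normal", "della_low")
}

sorghum_file <- function(prefix, sample) {
  sample <- match.arg(sample, sorghum_ash_samples())
  path <- system.file("extdata", paste0(prefix, "_", sample, ".tsv"),
                      package = "ashbalance")
  if (!nzchar(path)) stop("bundled file missing for ", sample, call. = FALSE)
  path
}

#' @rdname sorghum_ash_samples
#' @param sample one of `sorghum_ash_samples()`.
#' @return `sorghum_ash_phases()` returns a [phase_assemblage()].
#' @export
sorghum_ash_phases <- function(sample) {
  read_phase_table(sorghum_file("ash_phases", sample), label = sample)
}

#' @rdname sorghum_ash_samples
#' @return `sorghum_ash_bulk()` returns a [bulk_composition()].
#' @export
sorghum_ash_bulk <- function(sample) {
  read_bulk_table(sorghum_file("ash_bulk", sample), label = sample)
}

#' @rdname sorghum_ash_samples
#' @return `sorghum_straw()` returns a [straw_composition()].
#' @export
sorghum_straw <- function(sample) {
  read_straw_table(sorghum_file("straw", sample), label = sample)
}
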