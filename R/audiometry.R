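#' Audiometric frequencies carried by a cohort table
#'
#' Per-ear thresholds are stored in columns `L_<freq>` and `R_<freq>` with
#' frequency in kHz. The standard pure-tone average (PTA) uses 0.5, 1, 2 and
#' 4 kHz; the high-frequency PTA uses 1, 2, 4 and 8 kHz, always across both
#' ears.
#'
#' @name audiogram-frequencies
#' @keywords internal
NULL

audiogram_freqs <- c(0.25, 0.5, 1, 2, 3, 4, 6, 8)
pta_freqs <- list(standard = c(0.5, 1, 2, 4), high_frequency = c(1, 2, 4, 8))

audiogram_cols <- function(ears = c("L", "R"), freqs = audiogram_freqs) {
  as.vector(t(outer(ears, freqs, paste, sep = "_")))
}

#' Bilateral pure-tone average
#'
#' Unweighted arithmetic mean of the audiometric thresholds at the four PTA
#' frequencies, pooled across the left and right ears (8 values in total).
#'
#' @param audiogram A data frame with per-ear threshold columns named
#'   `L_<freq>` / `R_<freq>` (frequency in kHz, e.g. `L_0.5`), one row per
#'   participant.
#' @param variant `"standard"` (0.5/1/2/4 kHz) or `"high_frequency"`
#'   (1/2/4/8 kHz).
#' @return Numeric vector of PTAs in dB HL, one per row.
#' @examples
#' aud <- tibble::tibble(L_0.5 = 5, L_1 = 10, L_2 = 15, L_4 = 20,
#'                       R_0.5 = 5, R_1 = 10, R_2 = 15, R_4 = 20)
#' pta(aud)  # 12.5
#' @export
pta <- function(audiogram, variant = c("standard", "high_frequency")) {
  variant <- match.arg(variant)
  cols <- audiogram_cols(freqs = pta_freqs[[variant]])
  missing_cols <- setdiff(cols, names(audiogram))
  if (length(missing_cols)) {
    stop(sprintf("Audiogram is missing required %s-PTA column(s): %s",
                 gsub("_", "-", variant), paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  rowMeans(as.matrix(audiogram[cols]))
}

#' Between-ear audiometric asymmetry
#'
#' Absolute left-right threshold differences at every frequency present in
#' both ears, together with the maximum over all frequencies and the maximum
#' restricted to frequencies below 2 kHz (the band in which the study
#' required near-symmetric hearing).
#'
#' @param audiogram A one-or-more-row data frame with `L_<freq>` / `R_<freq>`
#'   columns.
#' @return A tibble with one row per input row: one `asym_<freq>` column per
#'   matched frequency plus `asym_max` and `asym_max_below_2k` (dB).
#' @examples
#' aud <- tibble::tibble(L_0.5 = 10, L_1 = 10, L_4 = 40,
#'                       R_0.5 = 10, R_1 = 10, R_4 = 15)
#' bilateral_asymmetry(aud)
#' @export
bilateral_asymmetry <- function(audiogram) {
  l_cols <- grep("^L_", names(audiogram), value = TRUE)
  freqs <- sort(as.numeric(sub("^L_", "", l_cols)))
  freqs <- freqs[paste0("R_", freqs) %in% names(audiogram)]
  if (!length(freqs)) {
    stop("No matched L_/R_ frequency columns found in the audiogram.",
         call. = FALSE)
  }
  diffs <- matrix(NA_real_, nrow = nrow(audiogram), ncol = length(freqs),
                  dimnames = list(NULL, paste0("asym_", freqs)))
  for (j in seq_along(freqs)) {
    diffs[, j] <- abs(audiogram[[paste0("L_", freqs[j])]] -
                        audiogram[[paste0("R_", freqs[j])]])
  }
  out <- tibble::as_tibble(diffs)
  low <- freqs < 2
  out$asym_max <- if (nrow(diffs)) apply(diffs, 1, max) else numeric(0)
  out$asym_max_below_2k <- if (!any(low)) rep(NA_real_, nrow(diffs)) else
    if (nrow(diffs)) apply(diffs[, low, drop = FALSE], 1, max) else numeric(0)
  out
}

#' Synthesize an audiogram that hits a target standard PTA
#'
#' Builds a flat-plus-sloping bilateral audiogram (flat loss through 1 kHz,
#' linear increase in dB per octave above) whose standard bilateral PTA
#' equals the requested value. Only the PTA feeds the normative models, so
#' the spectral shape is a plausible sensorineural profile rather than a
#' fitted one.
#'
#' @param target_pta Numeric vector of target standard PTAs (dB HL).
#' @param hf_fraction Fraction of the PTA expressed as the per-octave
#'   high-frequency slope (default 0.6, a gently sloping loss).
#' @return A tibble with the 16 `L_`/`R_` audiogram columns.
#' @keywords internal
synth_audiogram <- function(target_pta, hf_fraction = 0.6) {
  slope <- hf_fraction * target_pta           # dB per octave above 1 kHz
  base <- target_pta - 0.75 * slope           # PTA_ST = base + 0.75 * slope
  octaves <- pmax(0, log2(audiogram_freqs))
  thr <- outer(base, rep(1, length(audiogram_freqs))) +
    outer(slope, octaves)
  thr <- pmin(pmax(thr, -10), 120)
  colnames(thr) <- paste0("L_", audiogram_freqs)
  out <- tibble::as_tibble(thr)
  for (f in audiogram_freqs) out[[paste0("R_", f)]] <- out[[paste0("L_", f)]]
  out[audiogram_cols()]
}
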