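# RPU normalization of plate-reader measurements.
#
# Promoter strength is reported as the background-free per-OD fluorescence
# gain Fluo = (fluorescence_4h - fluorescence_2h) / OD600, standardized to
# an on-plate reference promoter: RPU_test = Fluo_test * RPU_ref / Fluo_ref.

#' Per-OD fluorescence gain of a well
#'
#' `Fluo = (fluor_4h - fluor_2h) / od600`, vectorized over wells. Negative
#' values (possible for blanks) are passed through.
#'
#' @param fluor_2h,fluor_4h Fluorescence readings at 2 h and 4 h (AU).
#' @param od600 Optical density used for normalization (the 4 h reading);
#'   must be > 0.
#' @return Numeric per-OD fluorescence gain.
#' @examples
#' compute_fluo(200, 1200, 0.5)  # 2000
#' @export
compute_fluo <- function(fluor_2h, fluor_4h, od600) {
  if (any(od600 <= 0)) stop("od600 must be > 0")
  if (any(fluor_2h < 0) || any(fluor_4h < 0))
    stop("fluorescence readings must be >= 0")
  (fluor_4h - fluor_2h) / od600
}

#' Relative promoter units of a test promoter
#'
#' `RPU_test = Fluo_test * RPU_ref / Fluo_ref`; invariant under any global
#' instrument gain applied to all wells.
#'
#' @param fluo_test Per-OD fluorescence of the test promoter.
#' @param fluo_ref Per-OD fluorescence of the reference standard; must be > 0.
#' @param rpu_ref Assigned strength of the reference standard (default 1).
#' @return Promoter strength in RPU.
#' @export
compute_rpu <- function(fluo_test, fluo_ref, rpu_ref = 1) {
  if (any(fluo_ref <= 0)) stop("reference Fluo must be > 0 (reference failed)")
  fluo_test * rpu_ref / fluo_ref
}

#' Normalize a plate-measurement table to RPU
#'
#' Computes per-well Fluo, normalizes each well to the mean reference Fluo of
#' its own plate, and aggregates replicates per (promoter, condition) to mean,
#' sd and n. Wells whose `promoter` equals `ref_name` are the on-plate
#' reference standards; wells named `blank_name` are dropped (after optional
#' autofluorescence subtraction).
#'
#' @param measurements Data frame with columns `plate`, `well`, `promoter`,
#'   `condition`, `replicate`, `od600_4h`, `fluor_2h`, `fluor_4h`.
#' @param rpu_ref Assigned RPU of the reference standard (default 1).
#' @param ref_name Promoter id of reference wells (default `"reference"`).
#' @param blank_name Promoter id of blank wells (default `"blank"`).
#' @param subtract_blank If `TRUE`, the per-plate mean blank Fluo is
#'   subtracted from every well before normalization (off by default).
#' @return Data frame of class `rpu_result`: columns `promoter`, `condition`,
#'   `fluo`, `rpu`, `rpu_sd`, `n`.
#' @export
normalize_plate <- function(measurements, rpu_ref = 1, ref_name = "reference",
                            blank_name = "blank", subtract_blank = FALSE) {
  need <- c("plate", "well", "promoter", "condition", "replicate",
            "od600_4h", "fluor_2h", "fluor_4h")
  miss <- setdiff(need, names(measurements))
  if (length(miss))
    stop("measurement table lacks column(s): ", paste(miss, collapse = ", "))
  m <- as.data.frame(measurements)
  m$fluo <- compute_fluo(m$fluor_2h, m$fluor_4h, m$od600_4h)
  m$rpu <- NA_real_

  for (pl in unique(m$plate)) {
    idx <- m$plate == pl
    if (!any(m$promoter[idx] == ref_name))
      stop("plate '", pl, "' has no reference wells ('", ref_name, "')")
    if (subtract_blank) {
      bl <- idx & m$promoter == blank_name
      if (any(bl)) m$fluo[idx] <- m$fluo[idx] - mean(m$fluo[bl])
    }
    fluo_ref <- mean(m$fluo[idx & m$promoter == ref_name])
    if (fluo_ref <= 0)
      stop("plate '", pl, "': reference Fluo <= 0 (reference failed)")
    m$rpu[idx] <- compute_rpu(m$fluo[idx], fluo_ref, rpu_ref)
  }
  m <- m[m$promoter != blank_name, , drop = FALSE]

  key <- interaction(m$promoter, m$condition, drop = TRUE, sep = "\r")
  agg <- lapply(split(m, key), function(g) {
    data.frame(promoter = g$promoter[1L], condition = g$condition[1L],
               fluo = mean(g$fluo), rpu = mean(g$rpu),
               rpu_sd = if (nrow(g) > 1L) stats::sd(g$rpu) else NA_real_,
               n = nrow(g), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$promoter, out$condition), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rpu_result", "data.frame")
  out
}

#' Convert normalized RPU results to an observation table for fitting
#'
#' Joins per-well RPU values with library part labels, yielding the
#' `variant, minus35, minus10, condition, replicate, rate_rpu` layout the
#' free-energy fit consumes. Reference and blank wells are dropped.
#'
#' @param measurements Raw plate table (see [normalize_plate()]).
#' @param library A `promoter_library` from [assemble_library()].
#' @inheritParams normalize_plate
#' @return Data frame with one row per well.
#' @export
observations_from_plate <- function(measurements, library, rpu_ref = 1,
                                    ref_name = "reference", blank_name = "blank") {
  m <- as.data.frame(measurements)
  m$fluo <- compute_fluo(m$fluor_2h, m$fluor_4h, m$od600_4h)
  m$rpu <- NA_real_
  for (pl in unique(m$plate)) {
    idx <- m$plate == pl
    if (!any(m$promoter[idx] == ref_name))
      stop("plate '", pl, "' has no reference wells ('", ref_name, "')")
    fluo_ref <- mean(m$fluo[idx & m$promoter == ref_name])
    m$rpu[idx] <- compute_rpu(m$fluo[idx], fluo_ref, rpu_ref)
  }
  m <- m[!m$promoter %in% c(ref_name, blank_name), , drop = FALSE]
  i <- match(m$promoter, library$id)
  if (anyNA(i))
    stop("promoter id(s) not in library: ",
         paste(unique(m$promoter[is.na(i)]), collapse = ", "))
  data.frame(variant = m$promoter, minus35 = library$minus35[i],
             minus10 = library$minus10[i], condition = m$condition,
             replicate = m$replicate, rate_rpu = m$rpu,
             stringsAsFactors = FALSE)
}
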