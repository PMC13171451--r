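# Partition TSSs into repeat/non-repeat classes from a softmask interval set
# and summarise per-class counts, percentages and length-normalised
# densities.
#
# Containment is half-open, matching BED: a TSS exactly at an interval's end
# coordinate belongs to the following interval. Class lengths come from the
# SAME mask used for classification, so masks and TSS calls must share a
# coordinate system (matching sequence names are enforced).

#' Classify TSSs as repeat or non-repeat
#'
#' Each TSS is assigned the class of the mask interval containing its
#' position (0-based, half-open containment).
#'
#' @param tss Data.frame of TSS calls (`name`, `strand`, `pos`).
#' @param mask Mask intervals (`name`, `start`, `end`, `class`) tiling each
#'   sequence, as from [case_mask_intervals()] or [read_bed()].
#' @return A list with `n_repeat`, `n_nonrepeat`, and `classes` (per-TSS
#'   class labels in input order).
#' @export
classify_tss <- function(tss, mask) {
  if (nrow(tss) == 0) {
    return(list(n_repeat = 0L, n_nonrepeat = 0L, classes = character()))
  }
  classes <- character(nrow(tss))
  for (nm in unique(tss$name)) {
    sel <- tss$name == nm
    mi <- mask[mask$name == nm, , drop = FALSE]
    if (nrow(mi) == 0) {
      stop("no mask intervals for sequence '", nm, "'", call. = FALSE)
    }
    mi <- mi[order(mi$start), , drop = FALSE]
    pos <- tss$pos[sel]
    if (any(pos < mi$start[1]) || any(pos >= mi$end[nrow(mi)])) {
      stop("TSS position outside mask coverage for '", nm, "'",
           call. = FALSE)
    }
    idx <- findInterval(pos, mi$start)
    if (any(pos >= mi$end[idx])) {
      stop("mask intervals for '", nm, "' do not tile the sequence",
           call. = FALSE)
    }
    classes[sel] <- mi$class[idx]
  }
  list(n_repeat = sum(classes == "repeat"),
       n_nonrepeat = sum(classes == "non_repeat"),
       classes = classes)
}

#' Per-class TSS counts, percentages and densities
#'
#' Percentages are rounded half-up to one decimal place (report precision);
#' densities (TSS per kb of class sequence) are left at full precision so
#' that `density_repeat * repeat_kb + density_nonrepeat * nonrepeat_kb`
#' recovers the total TSS count exactly.
#'
#' @param counts Result of [classify_tss()], or a list/vector with elements
#'   `n_repeat` and `n_nonrepeat`.
#' @param mask Mask intervals used for the classification (class lengths are
#'   summed from it).
#' @param label Dataset label.
#' @return One-row data.frame with columns `dataset`, `n_repeat_tss`,
#'   `n_nonrepeat_tss`, `pct_repeat`, `pct_nonrepeat`, `repeat_length`,
#'   `nonrepeat_length`, `density_repeat`, `density_nonrepeat`.
#' @export
class_summary <- function(counts, mask, label = "") {
  n_rep <- as.numeric(counts[["n_repeat"]])
  n_non <- as.numeric(counts[["n_nonrepeat"]])
  total <- n_rep + n_non
  widths <- mask$end - mask$start
  rep_len <- sum(widths[mask$class == "repeat"])
  non_len <- sum(widths[mask$class == "non_repeat"])
  if ((n_rep > 0 && rep_len == 0) || (n_non > 0 && non_len == 0)) {
    stop("TSSs assigned to a class of zero length", call. = FALSE)
  }
  data.frame(
    dataset = label,
    n_repeat_tss = n_rep,
    n_nonrepeat_tss = n_non,
    pct_repeat = if (total > 0) round_half_up(100 * n_rep / total, 1) else NA_real_,
    pct_nonrepeat = if (total > 0) round_half_up(100 * n_non / total, 1) else NA_real_,
    repeat_length = rep_len,
    nonrepeat_length = non_len,
    density_repeat = if (rep_len > 0) n_rep / (rep_len / 1000) else NA_real_,
    density_nonrepeat = if (non_len > 0) n_non / (non_len / 1000) else NA_real_,
    stringsAsFactors = FALSE
  )
}
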