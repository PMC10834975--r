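#' Relative miRNA abundance per compartment and age
#'
#' Within each compartment-age group (e.g. Worm/D1, EV/D8), the
#' replicate-mean UMI count of every detected miRNA is divided by the sum
#' of replicate means over the detected set, so fractions sum to one over
#' the detected miRNAome. Undetected miRNAs are excluded from both the
#' denominator and the table.
#'
#' @param x \code{ExpressionMatrix} of UMI counts (compartments as tissue
#'   labels).
#' @param detection \code{DetectionTable} from \code{\link{call_detection_umi}}.
#' @return Data frame: mature_id, compartment, age, mean_umi, fraction.
#' @export
relative_abundance <- function(x, detection) {
  stopifnot(inherits(x, "ExpressionMatrix"), inherits(detection, "DetectionTable"))
  d <- dimnames(detection$per_group)
  rows <- list()
  for (comp in d[[2]]) {
    for (a in d[[3]]) {
      idx <- which(x$samples$tissue == comp & x$samples$age == a)
      if (length(idx) == 0) next
      det <- detection$per_group[, comp, a]
      det[is.na(det)] <- FALSE
      if (!any(det)) stop("no detected miRNA in group (", comp, ", ", a, ")")
      means <- rowMeans(x$values[det, idx, drop = FALSE])
      rows[[length(rows) + 1]] <- data.frame(
        mature_id = names(means), compartment = comp, age = a,
        mean_umi = unname(means), fraction = unname(means / sum(means)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' EV loading ratio and age change
#'
#' The loading ratio of a miRNA at an age is its relative abundance among
#' detected EV miRNAs divided by its relative abundance among detected
#' whole-worm miRNAs; the age change is the D8 ratio over the D1 ratio.
#' MiRNAs missing either side at either age cannot be given a finite ratio
#' and are marked undetermined with a reason code.
#'
#' @param rel Output of \code{\link{relative_abundance}} covering the
#'   "Worm" and "EV" compartments at D1 and D8.
#' @return Data frame: mature_id, rel_worm_d1, rel_ev_d1, ratio_d1,
#'   rel_worm_d8, rel_ev_d8, ratio_d8, age_change, reason.
#' @export
loading_ratio <- function(rel) {
  need <- c("Worm", "EV")
  if (!all(need %in% rel$compartment)) {
    stop("relative-abundance table must cover compartments Worm and EV")
  }
  get <- function(comp, age) {
    sub <- rel[rel$compartment == comp & rel$age == age, ]
    setNames(sub$fraction, sub$mature_id)
  }
  w1 <- get("Worm", "D1"); e1 <- get("EV", "D1")
  w8 <- get("Worm", "D8"); e8 <- get("EV", "D8")
  ids <- sort(unique(rel$mature_id))
  pick <- function(v) unname(v[ids])
  out <- data.frame(mature_id = ids,
                    rel_worm_d1 = pick(w1), rel_ev_d1 = pick(e1),
                    rel_worm_d8 = pick(w8), rel_ev_d8 = pick(e8),
                    stringsAsFactors = FALSE)
  ratio_at <- function(ev, worm) {
    bad_zero <- !is.na(ev) & !is.na(worm) & worm == 0
    if (any(bad_zero)) {
      stop("zero worm abundance for detected miRNA(s): ",
           paste(out$mature_id[bad_zero], collapse = ", "))
    }
    ifelse(is.na(ev) | is.na(worm), NA_real_, ev / worm)
  }
  out$ratio_d1 <- ratio_at(out$rel_ev_d1, out$rel_worm_d1)
  out$ratio_d8 <- ratio_at(out$rel_ev_d8, out$rel_worm_d8)
  out$age_change <- ifelse(is.na(out$ratio_d1) | is.na(out$ratio_d8),
                           NA_real_, out$ratio_d8 / out$ratio_d1)
  out$reason <- ifelse(!is.na(out$age_change), "ok",
                ifelse(is.na(out$ratio_d1) & is.na(out$ratio_d8), "missing_both_ages",
                ifelse(is.na(out$ratio_d1), "missing_d1", "missing_d8")))
  out[, c("mature_id", "rel_worm_d1", "rel_ev_d1", "ratio_d1",
          "rel_worm_d8", "rel_ev_d8", "ratio_d8", "age_change", "reason")]
}

#' Classify age-dependent selective secretion
#'
#' A miRNA's secretion is promoted by ageing when its loading-ratio age
#' change strictly exceeds the fold threshold, suppressed when strictly
#' below its reciprocal, stable in between (an age change of exactly the
#' threshold is stable), and undetermined when the ratio is unavailable at
#' either age.
#'
#' @param table Output of \code{\link{loading_ratio}}.
#' @param fold_threshold Strict fold bound. Default 2.
#' @return List with the annotated \code{table} (column
#'   \code{secretion_class}), per-class \code{counts} and \code{sets}.
#' @export
classify_secretion <- function(table, fold_threshold = 2) {
  stopifnot(fold_threshold > 1)
  cls <- ifelse(is.na(table$age_change), "undetermined",
         ifelse(table$age_change > fold_threshold, "promoted",
         ifelse(table$age_change < 1 / fold_threshold, "suppressed", "stable")))
  table$secretion_class <- cls
  lv <- c("promoted", "suppressed", "stable", "undetermined")
  counts <- setNames(vapply(lv, function(l) sum(cls == l), integer(1)), lv)
  sets <- lapply(setNames(lv, lv), function(l) table$mature_id[cls == l])
  list(table = table, counts = counts, sets = sets)
}
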