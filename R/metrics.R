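#' Epoch-level agreement metrics for sleep-wake classification
#'
#' Standard definitions on equal-length binary sequences: Cohen's kappa,
#' F1, sensitivity and specificity, each reported with sleep (label 1) and
#' wake (label 0) as positive class. A single-class reference makes kappa
#' undefined; it is returned as `NA` with a `reason` attribute.
#'
#' @param pred,ref binary 0/1 vectors of equal length.
#' @return List: `kappa`, `confusion` (2x2, reference in rows), and per
#'   class `f1`, `sensitivity`, `specificity`.
#' @export
epoch_metrics <- function(pred, ref) {
  stopifnot(length(pred) == length(ref))
  pred <- as.integer(pred)
  ref <- as.integer(ref)
  cm <- matrix(0, 2, 2, dimnames = list(ref = c("0", "1"),
                                        pred = c("0", "1")))
  for (r in 0:1) for (p in 0:1)
    cm[r + 1, p + 1] <- sum(ref == r & pred == p)
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (length(unique(ref)) < 2) {
    structure(NA_real_, reason = "reference contains a single class")
  } else if (pe >= 1) 1 else (po - pe) / (1 - pe)

  one_class <- function(pos) {
    tp <- sum(ref == pos & pred == pos)
    fp <- sum(ref != pos & pred == pos)
    fn <- sum(ref == pos & pred != pos)
    tn <- sum(ref != pos & pred != pos)
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
    list(f1 = f1, sensitivity = sens, specificity = spec)
  }
  list(kappa = kappa, confusion = cm,
       sleep = one_class(1L), wake = one_class(0L))
}

#' Estimate total sleep time from a binary sleep track
#' @param sleep_binary per-30-s-epoch 0/1 vector.
#' @return TST in hours.
#' @export
estimate_tst <- function(sleep_binary) sum(sleep_binary == 1L) * EPOCH_S / 3600

#' Apnea-hypopnea index: events per hour of sleep
#'
#' Undefined (NA with a `reason` attribute) when `tst_h` is zero while
#' events were detected; such subjects are excluded from AHI agreement.
#'
#' @param n_events number of detected events.
#' @param tst_h total sleep time (h).
#' @return Events per hour.
#' @export
estimate_ahi <- function(n_events, tst_h) {
  stopifnot(tst_h >= 0)
  if (tst_h == 0) {
    if (n_events > 0)
      return(structure(NA_real_, reason = "events detected but TST = 0"))
    return(0)
  }
  n_events / tst_h
}

#' Respiratory event index: events per hour of time in bed
#' @param n_events number of detected events.
#' @param tib_h time in bed (h, > 0).
#' @return Events per hour.
#' @export
estimate_rei <- function(n_events, tib_h) {
  stopifnot(tib_h > 0)
  n_events / tib_h
}

#' SDB severity class from an AHI value
#'
#' Half-open interval convention: normal `[0, 5)`, mild `[5, 15)`,
#' moderate `[15, 30)`, severe `[30, Inf)`.
#'
#' @param ahi numeric vector of AHI values (>= 0).
#' @return Factor with levels normal, mild, moderate, severe.
#' @export
severity_class <- function(ahi) {
  if (any(ahi < 0, na.rm = TRUE)) stop("AHI must be non-negative")
  cut(ahi, c(0, 5, 15, 30, Inf), right = FALSE,
      labels = c("normal", "mild", "moderate", "severe"))
}

#' Default near-boundary zone half-widths
#'
#' 10% of each severity boundary: 0.5, 1.5 and 3.0 events/h at the 5, 15
#' and 30 events/h boundaries.
#' @return Named numeric vector of half-widths.
#' @export
nbl_zones_default <- function() c(`5` = 0.5, `15` = 1.5, `30` = 3.0)

#' Near-boundary double-labeling: admissible severity classes
#'
#' A subject whose AHI lies within a boundary's zone half-width belongs to
#' both flanking classes; otherwise to its single class.
#'
#' @param ahi scalar AHI (>= 0).
#' @param zones named half-widths as in [nbl_zones_default()].
#' @return Character vector of 1-2 class names.
#' @export
nbl_classes <- function(ahi, zones = nbl_zones_default()) {
  if (ahi < 0) stop("AHI must be non-negative")
  base <- as.character(severity_class(ahi))
  bounds <- as.numeric(names(zones))
  lvls <- c("normal", "mild", "moderate", "severe")
  out <- base
  for (k in seq_along(bounds)) {
    if (abs(ahi - bounds[k]) <= zones[k])
      out <- union(out, c(lvls[k], lvls[k + 1]))
  }
  lvls[sort(match(out, lvls))]
}

#' Severity confusion matrix, accuracy and kappa, with or without NBL
#'
#' Without NBL, the standard 4x4 confusion of reference vs estimated
#' class. With NBL, an estimate counts as correct when it falls in either
#' class admissible for the reference AHI ([nbl_classes()]); a
#' correct-by-NBL pair is tallied on the diagonal of the reference class.
#'
#' @param ahi_ref,ahi_est paired numeric vectors of reference and
#'   estimated AHI.
#' @param nbl apply near-boundary double-labeling?
#' @param zones NBL zone half-widths.
#' @return List: `confusion`, `accuracy`, `kappa`.
#' @export
severity_confusion <- function(ahi_ref, ahi_est, nbl = FALSE,
                               zones = nbl_zones_default()) {
  if (length(ahi_ref) != length(ahi_est))
    stop("ahi_ref and ahi_est must have the same length")
  lvls <- c("normal", "mild", "moderate", "severe")
  ref <- severity_class(ahi_ref)
  est <- severity_class(ahi_est)
  cm <- matrix(0, 4, 4, dimnames = list(ref = lvls, est = lvls))
  for (i in seq_along(ref)) {
    r <- as.integer(ref[i])
    e <- as.integer(est[i])
    if (nbl && as.character(est[i]) %in% nbl_classes(ahi_ref[i], zones))
      e <- r
    cm[r, e] <- cm[r, e] + 1
  }
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (pe >= 1) 1 else (po - pe) / (1 - pe)
  list(confusion = cm, accuracy = po, kappa = kappa)
}

#' Bland-Altman agreement statistics
#'
#' Differences are `est - ref`; bias is their mean and the 95% limits of
#' agreement are `bias +/- 1.96 * SD` (sample standard deviation).
#'
#' @param ref,est paired finite numeric vectors, `n >= 3`.
#' @return List: `bias`, `loa_low`, `loa_high`, `sd`.
#' @export
bland_altman <- function(ref, est) {
  stopifnot(length(ref) == length(est), length(ref) >= 3,
            all(is.finite(ref)), all(is.finite(est)))
  d <- est - ref
  s <- sd(d)
  list(bias = mean(d), loa_low = mean(d) - 1.96 * s,
       loa_high = mean(d) + 1.96 * s, sd = s)
}

#' Spearman rank correlation (average ranks for ties)
#' @param ref,est paired numeric vectors.
#' @return Correlation coefficient, or `NA` (with `reason`) for constant
#'   input.
#' @export
spearman_r <- function(ref, est) {
  if (sd(ref) == 0 || sd(est) == 0)
    return(structure(NA_real_, reason = "constant input"))
  cor(ref, est, method = "spearman")
}

#' Mean absolute error
#' @param ref,est paired numeric vectors.
#' @return Mean of `|est - ref|`.
#' @export
mae <- function(ref, est) mean(abs(est - ref))

#' Sleep-efficiency sweep of AHI/REI estimation performance
#'
#' For each sleep-efficiency cutoff, subjects with reference efficiency
#' `<= cutoff` are pooled and Spearman R and MAE are computed for
#' `ahi_est` vs `ahi_ref` (multi-task) and `rei_est` vs `ahi_ref`
#' (single-task comparison). Subsets with fewer than 3 subjects are
#' reported as missing.
#'
#' @param report per-subject data frame with columns `se_ref`, `ahi_ref`,
#'   `ahi_est` and `rei_est`.
#' @param cutoffs sleep-efficiency cutoffs in (0, 1].
#' @return Data frame with one row per cutoff: `cutoff`, `n`, `r_ahi`,
#'   `mae_ahi`, `r_rei`, `mae_rei`.
#' @export
efficiency_sweep <- function(report, cutoffs = seq(0.5, 1, by = 0.05)) {
  stopifnot(nrow(report) > 0,
            all(c("se_ref", "ahi_ref", "ahi_est", "rei_est") %in%
                  names(report)))
  rows <- lapply(cutoffs, function(cut) {
    sub <- report[report$se_ref <= cut & is.finite(report$ahi_est), ,
                  drop = FALSE]
    n <- nrow(sub)
    if (n < 3)
      return(data.frame(cutoff = cut, n = n, r_ahi = NA_real_,
                        mae_ahi = NA_real_, r_rei = NA_real_,
                        mae_rei = NA_real_))
    data.frame(cutoff = cut, n = n,
               r_ahi = as.numeric(spearman_r(sub$ahi_ref, sub$ahi_est)),
               mae_ahi = mae(sub$ahi_ref, sub$ahi_est),
               r_rei = as.numeric(spearman_r(sub$ahi_ref, sub$rei_est)),
               mae_rei = mae(sub$ahi_ref, sub$rei_est))
  })
  do.call(rbind, rows)
}
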