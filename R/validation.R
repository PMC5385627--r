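#' Match detected turns against reference annotations
#'
#' One-to-one greedy matching of detected and reference events by the
#' absolute difference of their interval midpoints. A pair is eligible when
#' the intervals overlap or the midpoints differ by at most `tolerance`
#' seconds; eligible pairs are accepted nearest-first, ties breaking toward
#' the earlier detected event (then the earlier reference event), so the
#' result is deterministic. Matched pairs count as true positives, unmatched
#' detected events as false positives, unmatched reference events as false
#' negatives.
#'
#' @param detected,reference [turn_events()] tables, each sorted and
#'   non-overlapping within itself.
#' @param tolerance Matching tolerance in seconds (default 2.5, covering the
#'   spread of detection-time differences seen against human annotation).
#' @return List with `pairs` (data.frame: `detected`, `reference` row
#'   indices, `dt_start` = detected start minus reference start, `d_mag`,
#'   `d_dur`), and counts `TP`, `FP`, `FN`.
#' @export
match_events <- function(detected, reference, tolerance = 2.5) {
  if (!is.numeric(tolerance) || tolerance <= 0)
    stop("tolerance must be a positive number of seconds")
  detected <- as.data.frame(detected)
  reference <- as.data.frame(reference)
  nd <- nrow(detected); nr <- nrow(reference)
  pairs <- data.frame(detected = integer(0), reference = integer(0),
                      dt_start = numeric(0), d_mag = numeric(0),
                      d_dur = numeric(0))
  if (nd && nr) {
    mid_d <- (detected$t_start + detected$t_end) / 2
    mid_r <- (reference$t_start + reference$t_end) / 2
    cand <- expand.grid(detected = seq_len(nd), reference = seq_len(nr))
    cand$dist <- abs(mid_d[cand$detected] - mid_r[cand$reference])
    overlap <- detected$t_start[cand$detected] <=
      reference$t_end[cand$reference] &
      reference$t_start[cand$reference] <= detected$t_end[cand$detected]
    cand <- cand[overlap | cand$dist <= tolerance, , drop = FALSE]
    cand <- cand[order(cand$dist, cand$detected, cand$reference), ,
                 drop = FALSE]
    used_d <- logical(nd); used_r <- logical(nr)
    keep <- integer(0)
    for (k in seq_len(nrow(cand))) {
      i <- cand$detected[k]; j <- cand$reference[k]
      if (!used_d[i] && !used_r[j]) {
        used_d[i] <- TRUE; used_r[j] <- TRUE
        keep <- c(keep, k)
      }
    }
    if (length(keep)) {
      m <- cand[keep, , drop = FALSE]
      pairs <- data.frame(detected = m$detected, reference = m$reference,
                          dt_start = detected$t_start[m$detected] -
                            reference$t_start[m$reference],
                          d_mag = detected$magnitude[m$detected] -
                            reference$magnitude[m$reference],
                          d_dur = detected$duration[m$detected] -
                            reference$duration[m$reference])
      pairs <- pairs[order(pairs$reference), , drop = FALSE]
      rownames(pairs) <- NULL
    }
  }
  list(pairs = pairs, TP = nrow(pairs), FP = nd - nrow(pairs),
       FN = nr - nrow(pairs))
}

#' Count true negatives as clean gaps between reference turns
#'
#' Event-level detection has no natural "non-turn" unit, so the true
#' negative count is defined here as the number of maximal gaps between
#' consecutive reference turns (including the gap before the first and after
#' the last turn, bounded by the recording span) that last at least
#' `duration_min` seconds and contain no detected-turn midpoint. This is one
#' of several defensible definitions; it is isolated in this function so an
#' alternative (e.g. fixed windows) can be swapped in.
#'
#' @param detected,reference [turn_events()] tables.
#' @param span Length-2 numeric, recording start and end time in seconds.
#' @param duration_min Minimum gap duration to count, seconds (default 0.1).
#' @return Integer TN count.
#' @export
count_true_negatives <- function(detected, reference, span,
                                 duration_min = 0.1) {
  detected <- as.data.frame(detected)
  reference <- as.data.frame(reference)
  stopifnot(length(span) == 2L, span[2L] > span[1L])
  edges_start <- c(span[1L], reference$t_end)
  edges_end <- c(reference$t_start, span[2L])
  len <- edges_end - edges_start
  mid_d <- if (nrow(detected)) (detected$t_start + detected$t_end) / 2
  else numeric(0)
  tn <- 0L
  for (g in seq_along(len)) {
    if (len[g] < duration_min) next
    if (!any(mid_d > edges_start[g] & mid_d < edges_end[g])) tn <- tn + 1L
  }
  tn
}

#' Confusion counts
#'
#' @param TP,FP,TN,FN Non-negative integer event counts.
#' @return List of class `confusion_counts` with the four counts and the
#'   derived totals `n_algorithm = TP + FP`, `n_reference = TP + FN`.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers")
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN,
                 n_algorithm = TP + FP, n_reference = TP + FN),
            class = "confusion_counts")
}

#' Agreement statistics from confusion counts
#'
#' Standard definitions: sensitivity TP/(TP+FN), specificity TN/(TN+FP),
#' accuracy (TP+TN)/N, positive predictive value TP/(TP+FP), negative
#' predictive value TN/(TN+FN). A zero denominator yields `NA` (undefined),
#' never 0.
#'
#' @param c A [confusion_counts()] object (or anything with TP/FP/TN/FN).
#' @return Named numeric vector `sensitivity`, `specificity`, `accuracy`,
#'   `ppv`, `npv`, at full precision (round at the reporting layer).
#' @export
confusion_stats <- function(c) {
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  with(c, c(sensitivity = safe(TP, TP + FN),
            specificity = safe(TN, TN + FP),
            accuracy = safe(TP + TN, TP + FP + TN + FN),
            ppv = safe(TP, TP + FP),
            npv = safe(TN, TN + FN)))
}

#' Cohen's kappa for event detection
#'
#' Chance-corrected agreement between the algorithm and the reference rater
#' over the N = TP+FP+TN+FN decision units:
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement
#' `p_o = (TP+TN)/N` and chance agreement
#' `p_e = ((TP+FP)(TP+FN) + (FN+TN)(FP+TN)) / N^2`. Kappa is invariant
#' under exchanging the two raters and equals 1 exactly when FP = FN = 0.
#'
#' @param c A [confusion_counts()] object.
#' @return Kappa in \[-1, 1\], or `NA` when chance agreement is exactly 1.
#' @export
cohens_kappa <- function(c) {
  N <- c$TP + c$FP + c$TN + c$FN
  if (N == 0) stop("empty confusion table")
  p_o <- (c$TP + c$TN) / N
  p_e <- ((c$TP + c$FP) * (c$TP + c$FN) +
            (c$FN + c$TN) * (c$FP + c$TN)) / N^2
  if (abs(1 - p_e) < .Machine$double.eps) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

#' Bland-Altman agreement summary
#'
#' For paired per-event differences (by default detected start time minus
#' reference start time), reports the mean difference, its standard error
#' (SD/sqrt(n)), and the limits of agreement mean +/- 1.96 SD. The limits
#' are also labelled `ci95_lower`/`ci95_upper` because method-comparison
#' reports sometimes print them as a 95% confidence interval of the
#' difference.
#'
#' @param differences Numeric vector of paired differences (seconds for
#'   detection times), length >= 2.
#' @return Named numeric vector: `mean_diff`, `sd`, `sem`, `loa_lower`,
#'   `loa_upper`, `ci95_lower`, `ci95_upper`, `n`.
#' @export
bland_altman <- function(differences) {
  differences <- as.numeric(differences)
  n <- length(differences)
  if (n < 2L) stop("Bland-Altman needs at least 2 paired differences")
  m <- mean(differences)
  s <- stats::sd(differences)
  c(mean_diff = m, sd = s, sem = s / sqrt(n),
    loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s,
    ci95_lower = m - 1.96 * s, ci95_upper = m + 1.96 * s, n = n)
}

#' Validate detected turns against reference annotations
#'
#' Matches events, counts the confusion table (true negatives via
#' [count_true_negatives()]), and derives sensitivity, specificity,
#' accuracy, predictive values, Cohen's kappa, and the Bland-Altman summary
#' of detection-time differences.
#'
#' @param detected,reference [turn_events()] tables.
#' @param span Recording span `c(start, end)` in seconds; defaults to the
#'   range covered by the union of both event lists.
#' @param cfg A [detection_config()] (supplies `match_tolerance` and
#'   `duration_min`).
#' @return Object of class `turn_validation`: list with `counts`
#'   ([confusion_counts()]), `stats`, `kappa`, `bland_altman` (or `NULL`
#'   with fewer than 2 pairs), `pairs`, `tolerance`.
#' @export
validate_turns <- function(detected, reference, span = NULL,
                           cfg = detection_config()) {
  if (is.null(span)) {
    all_t <- c(detected$t_start, detected$t_end,
               reference$t_start, reference$t_end)
    if (!length(all_t)) stop("no events and no span given")
    span <- range(all_t)
  }
  m <- match_events(detected, reference, tolerance = cfg$match_tolerance)
  tn <- count_true_negatives(detected, reference, span,
                             duration_min = cfg$duration_min)
  counts <- confusion_counts(m$TP, m$FP, tn, m$FN)
  ba <- if (nrow(m$pairs) >= 2L) bland_altman(m$pairs$dt_start) else NULL
  structure(list(counts = counts, stats = confusion_stats(counts),
                 kappa = cohens_kappa(counts), bland_altman = ba,
                 pairs = m$pairs, tolerance = cfg$match_tolerance,
                 span = span),
            class = "turn_validation")
}

# two-decimal report rounding, half away from zero
round_half_away <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.turn_validation <- function(x, ...) {
  c_ <- x$counts
  cat("Turn detection validation (matching tolerance ", x$tolerance,
      " s)\n", sep = "")
  cat("  TP ", c_$TP, "  FP ", c_$FP, "  TN ", c_$TN, "  FN ", c_$FN,
      "  (algorithm ", c_$n_algorithm, ", reference ", c_$n_reference,
      ")\n", sep = "")
  s <- round_half_away(c(x$stats, kappa = x$kappa))
  cat("  sens ", s[["sensitivity"]], "  spec ", s[["specificity"]],
      "  acc ", s[["accuracy"]], "  ppv ", s[["ppv"]], "  npv ",
      s[["npv"]], "  kappa ", s[["kappa"]], "\n", sep = "")
  if (!is.null(x$bland_altman)) {
    b <- x$bland_altman
    cat("  detection time: mean diff ", format(round(b[["mean_diff"]], 3)),
        " s (SEM ", format(round(b[["sem"]], 3)), " s; LoA ",
        format(round(b[["loa_lower"]], 2)), " to ",
        format(round(b[["loa_upper"]], 2)), " s)\n", sep = "")
  }
  invisible(x)
}

#' Magnitude-threshold sweep
#'
#' Re-runs turn filtering and validation for each magnitude threshold,
#' producing one report row per threshold — the experiment used to pick the
#' operating threshold by balancing detected-turn counts against agreement
#' with the reference rater. Detected-turn counts are monotone
#' non-increasing in the threshold.
#'
#' @param x A `turn_detection` object from [detect_turns()] (its merged
#'   segments are re-filtered per threshold), or an [imu_recording()] (the
#'   pipeline is run once and segments reused).
#' @param reference Reference [turn_events()].
#' @param thresholds Ascending magnitude thresholds in degrees (default
#'   `c(45, 60, 70, 80, 90, 100, 110)`).
#' @param cfg Base [detection_config()].
#' @return `data.frame` with one row per threshold: `threshold`, `kappa`,
#'   `accuracy`, `sensitivity`, `specificity`, `ppv`, `npv`, `TP`, `FP`,
#'   `TN`, `FN`.
#' @export
threshold_sweep <- function(x, reference,
                            thresholds = c(45, 60, 70, 80, 90, 100, 110),
                            cfg = detection_config()) {
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly ascending")
  if (inherits(x, "imu_recording")) x <- detect_turns(x, cfg)
  stopifnot(inherits(x, "turn_detection"))
  rows <- lapply(thresholds, function(th) {
    cfg_th <- cfg
    cfg_th$magnitude_threshold <- th
    ev <- filter_turns(x$merged, cfg_th)
    v <- validate_turns(ev, reference, span = x$span, cfg = cfg_th)
    data.frame(threshold = th, kappa = v$kappa,
               accuracy = v$stats[["accuracy"]],
               sensitivity = v$stats[["sensitivity"]],
               specificity = v$stats[["specificity"]],
               ppv = v$stats[["ppv"]], npv = v$stats[["npv"]],
               TP = v$counts$TP, FP = v$counts$FP, TN = v$counts$TN,
               FN = v$counts$FN)
  })
  do.call(rbind, rows)
}
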