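#' Matching configuration
#'
#' Rules for classifying sound spots against reference streams: spots match
#' a reference within `tolerance_s` (±1 s in the field protocol); stretches
#' of at least `silence_s` with neither spot nor reference activity score
#' correct negatives; a spot paired at the right time but the wrong location
#' is counted as a false negative or a correct positive according to
#' `location_policy`.
#'
#' @param tolerance_s pairing tolerance (s)
#' @param silence_s minimum silent stretch for a correct negative (s)
#' @param location_policy `"wrong_as_FN"` or `"wrong_as_CP"`
#' @param reference_mode `"sound"`, `"behaviour"`, or `"sound_or_behaviour"`
#'   (a spot is correct if either stream validates it)
#' @param cn_mode `"floor"`: each maximal silent stretch contributes
#'   `floor(length / silence_s)` correct negatives; `"per_stretch"`: one per
#'   qualifying stretch
#' @param collapse_clouds collapse clusters of >= 5 spots within 1 s and
#'   0.3 m to their first spot before matching (slowed-replay observation:
#'   clouds start with one spot in the right place)
#' @param sound_table,behaviour_table [correspondence_table()]s for location
#'   correctness
#' @return object of class `fc_match_config`
#' @export
match_config <- function(tolerance_s = 1.0, silence_s = 2.0,
                         location_policy = c("wrong_as_FN", "wrong_as_CP"),
                         reference_mode = c("sound", "behaviour",
                                            "sound_or_behaviour"),
                         cn_mode = c("floor", "per_stretch"),
                         collapse_clouds = TRUE,
                         sound_table = correspondence_table("study1_sound"),
                         behaviour_table = correspondence_table("study2_behaviour")) {
  if (tolerance_s <= 0 || silence_s <= 0)
    stop("tolerance_s and silence_s must be positive")
  structure(list(tolerance_s = tolerance_s, silence_s = silence_s,
                 location_policy = match.arg(location_policy),
                 reference_mode = match.arg(reference_mode),
                 cn_mode = match.arg(cn_mode),
                 collapse_clouds = collapse_clouds,
                 sound_table = sound_table,
                 behaviour_table = behaviour_table),
            class = "fc_match_config")
}

#' Confusion counts
#'
#' @param CP,FP,FN,CN non-negative integer tallies
#' @return object of class `fc_counts`
#' @export
confusion_counts <- function(CP = 0, FP = 0, FN = 0, CN = 0) {
  v <- c(CP = CP, FP = FP, FN = FN, CN = CN)
  if (any(v < 0)) stop("counts must be non-negative")
  structure(list(CP = CP, FP = FP, FN = FN, CN = CN,
                 total = CP + FP + FN + CN), class = "fc_counts")
}

#' @export
print.fc_counts <- function(x, ...) {
  cat(sprintf("Confusion counts: CP %d, FP %d, FN %d, CN %d (total %d)\n",
              x$CP, x$FP, x$FN, x$CN, x$total))
  invisible(x)
}

# Maximum-cardinality one-to-one pairing of spots and reference events
# within a time tolerance: greedy over edges ordered by time distance (then
# time, for determinism), completed by augmenting paths so the pairing is
# maximum. Returns integer vector: pair[i] = ref index for spot i, NA if
# unpaired.
pair_streams <- function(spot_t, ref_start, ref_end, tol) {
  ns <- length(spot_t); nr <- length(ref_start)
  pair <- rep(NA_integer_, ns)
  if (!ns || !nr) return(pair)
  # candidate edges via interval distance
  ei <- integer(0); ej <- integer(0); ed <- numeric(0)
  ord <- order(ref_start)
  for (i in seq_len(ns)) {
    lo <- spot_t[i] - tol; hi <- spot_t[i] + tol
    js <- ord[ref_start[ord] <= hi]
    js <- js[ref_end[js] >= lo]
    if (length(js)) {
      d <- pmax(0, pmax(ref_start[js] - spot_t[i], spot_t[i] - ref_end[js]))
      ei <- c(ei, rep.int(i, length(js))); ej <- c(ej, js); ed <- c(ed, d)
    }
  }
  if (!length(ei)) return(pair)
  o <- order(ed, spot_t[ei], ref_start[ej])
  ei <- ei[o]; ej <- ej[o]
  ref_of <- rep(NA_integer_, nr)
  for (k in seq_along(ei)) {
    if (is.na(pair[ei[k]]) && is.na(ref_of[ej[k]])) {
      pair[ei[k]] <- ej[k]; ref_of[ej[k]] <- ei[k]
    }
  }
  # augmenting paths (Kuhn) for any spot left unpaired
  adj <- split(ej, ei)
  seen <- rep(FALSE, nr)
  try_augment <- function(i) {
    for (j in adj[[as.character(i)]]) {
      if (seen[j]) next
      seen[j] <<- TRUE
      if (is.na(ref_of[j]) || try_augment(ref_of[j])) {
        pair[i] <<- j; ref_of[j] <<- i
        return(TRUE)
      }
    }
    FALSE
  }
  for (i in seq_len(ns)) {
    if (is.na(pair[i]) && !is.null(adj[[as.character(i)]])) {
      seen <- rep(FALSE, nr)
      try_augment(i)
    }
  }
  pair
}

# Collapse spot clouds (>= min_spots within window_s and radius_m) to their
# first spot.
collapse_cloud_spots <- function(spots, min_spots = 5, window_s = 1,
                                 radius_m = 0.3) {
  if (nrow(spots) < min_spots) return(spots)
  t <- spots$time_s; x <- spots$x_m; y <- spots$y_m
  drop <- logical(nrow(spots))
  for (i in seq_len(nrow(spots))) {
    if (drop[i]) next
    near <- which(!drop & t >= t[i] & t - t[i] <= window_s &
                    sqrt((x - x[i])^2 + (y - y[i])^2) <= radius_m)
    if (length(near) >= min_spots)
      drop[setdiff(near, i)] <- TRUE
  }
  spots[!drop, , drop = FALSE]
}

# Union of intervals -> matrix with columns start, end (merged, sorted).
merge_intervals <- function(start, end) {
  keep <- end > start | (end == start)
  start <- start[keep]; end <- end[keep]
  if (!length(start)) return(cbind(start = numeric(), end = numeric()))
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  outs <- numeric(0); oute <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) me <- max(me, end[i])
    else { outs <- c(outs, ms); oute <- c(oute, me); ms <- start[i]; me <- end[i] }
  }
  cbind(start = c(outs, ms), end = c(oute, me))
}

count_correct_negatives <- function(activity, t_range, silence_s, cn_mode) {
  iv <- merge_intervals(pmax(activity[, 1], t_range[1]),
                        pmin(activity[, 2], t_range[2]))
  # zero-length (point) activity still interrupts a silent stretch
  iv <- iv[iv[, 2] >= iv[, 1], , drop = FALSE]
  gaps_start <- c(t_range[1], iv[, 2])
  gaps_end <- c(iv[, 1], t_range[2])
  glen <- pmax(0, gaps_end - gaps_start)
  if (cn_mode == "floor") sum(floor(glen / silence_s))
  else sum(glen >= silence_s)
}

# Behaviour states whose label maps to at least one real zone — "active"
# reference behaviour an observer would score as an event to detect.
active_behaviour_labels <- function(table) {
  lab <- normalise_label(table$label)
  unique(lab[!table$zone %in% c("none") & lab != "none"])
}

#' Classify sound spots against reference streams
#'
#' The core validation step: spots are paired one-to-one with audible
#' sounds within the time tolerance (maximum-cardinality pairing, nearest
#' pairs first); behaviours validate spots by interval containment (with
#' the tolerance at interval edges) plus zone correspondence. A paired,
#' location-correct spot is a correct positive; a paired spot at the wrong
#' location is a false negative or correct positive per the location
#' policy; unpaired spots are false positives; unmatched references are
#' false negatives; stretches with no spot and no reference activity of at
#' least `silence_s` score correct negatives. In `sound_or_behaviour` mode
#' a spot is correct if either stream validates it.
#'
#' @param spots spot [event_log] (zone-annotated)
#' @param audible audible-sound [event_log] (`reference_mode` "sound" or
#'   "sound_or_behaviour")
#' @param behaviour behaviour [event_log] or [generate_behaviour()] script
#' @param cfg a [match_config()]
#' @param t_range observation window `c(t0, t1)` for correct-negative
#'   counting; defaults to the span of all provided streams
#' @return object of class `fc_match`: list with `counts` (under
#'   `cfg$location_policy`), `n_wrong_location`, `spot_class` and
#'   `ref_class` data frames, `t_range`, `config`
#' @export
match_events <- function(spots, audible = NULL, behaviour = NULL,
                         cfg = match_config(), t_range = NULL) {
  mode <- cfg$reference_mode
  if (mode %in% c("sound", "sound_or_behaviour") && is.null(audible))
    stop("reference_mode '", mode, "' needs an audible log")
  if (mode %in% c("behaviour", "sound_or_behaviour") && is.null(behaviour))
    stop("reference_mode '", mode, "' needs a behaviour log")
  for (lg in list(spots, audible)) {
    if (!is.null(lg) && is.unsorted(lg$time_s))
      stop("input logs must be time-sorted")
  }
  spots <- as_event_log(spots)
  sp <- as.data.frame(spots[spots$stream == "spot", , drop = FALSE])
  if (cfg$collapse_clouds) sp <- collapse_cloud_spots(sp)

  aud <- if (!is.null(audible)) {
    a <- as_event_log(audible)
    as.data.frame(a[a$stream == "audible", , drop = FALSE])
  } else NULL
  beh <- if (!is.null(behaviour)) behaviour_intervals(behaviour) else NULL

  ns <- nrow(sp)
  s_pair <- rep(NA_integer_, ns); s_corr <- rep(FALSE, ns)
  if (mode %in% c("sound", "sound_or_behaviour") && nrow(aud)) {
    s_pair <- pair_streams(sp$time_s, aud$time_s,
                           aud$time_s + aud$duration_s, cfg$tolerance_s)
    ok <- !is.na(s_pair)
    if (any(ok))
      s_corr[ok] <- is_location_correct(sp$zone[ok], aud$label[s_pair[ok]],
                                        cfg$sound_table)
  }

  b_cover <- rep(FALSE, ns); b_corr <- rep(FALSE, ns)
  beh_detected <- NULL
  if (mode %in% c("behaviour", "sound_or_behaviour") && !is.null(beh) &&
      nrow(beh)) {
    lab <- normalise_label(beh$state)
    active_lab <- lab %in% active_behaviour_labels(cfg$behaviour_table)
    beh_detected <- rep(FALSE, nrow(beh))
    for (i in seq_len(ns)) {
      inside <- which(sp$time_s[i] >= beh$start_s - cfg$tolerance_s &
                        sp$time_s[i] <= beh$end_s + cfg$tolerance_s)
      if (!length(inside)) next
      corr <- is_location_correct(rep(sp$zone[i], length(inside)),
                                  lab[inside], cfg$behaviour_table)
      # a spot is "covered" (candidate for the wrong-location policy) only
      # by an active behaviour; inactive states such as lying validate a
      # spot solely through their own zone correspondence
      b_cover[i] <- any(active_lab[inside])
      if (any(corr)) {
        b_corr[i] <- TRUE
        beh_detected[inside[corr]] <- TRUE
      }
    }
  }

  paired <- switch(mode,
                   sound = !is.na(s_pair),
                   behaviour = b_cover,
                   sound_or_behaviour = !is.na(s_pair) | b_cover)
  correct <- switch(mode,
                    sound = s_corr,
                    behaviour = b_corr,
                    sound_or_behaviour = s_corr | b_corr)
  wrong_loc <- paired & !correct
  n_wrong <- sum(wrong_loc)
  FP <- sum(!paired)

  # reference-side misses
  FN_refs <- 0L
  if (mode %in% c("sound", "sound_or_behaviour") && !is.null(aud) && nrow(aud)) {
    matched_ref <- unique(s_pair[!is.na(s_pair)])
    FN_refs <- FN_refs + (nrow(aud) - length(matched_ref))
  }
  if (mode %in% c("behaviour", "sound_or_behaviour") && !is.null(beh) &&
      nrow(beh)) {
    act <- normalise_label(beh$state) %in%
      active_behaviour_labels(cfg$behaviour_table)
    FN_refs <- FN_refs + sum(act & !beh_detected)
  }

  # correct negatives: nothing visible or audible
  if (is.null(t_range)) {
    ends <- c(sp$time_s, if (!is.null(aud)) aud$time_s + aud$duration_s,
              if (!is.null(beh)) beh$end_s)
    starts <- c(sp$time_s, if (!is.null(aud)) aud$time_s,
                if (!is.null(beh)) beh$start_s)
    t_range <- if (length(starts)) c(min(starts), max(ends)) else c(0, 0)
  }
  act_iv <- rbind(
    if (ns) cbind(sp$time_s, sp$time_s + sp$duration_s),
    if (mode != "behaviour" && !is.null(aud) && nrow(aud))
      cbind(aud$time_s, aud$time_s + aud$duration_s),
    if (mode != "sound" && !is.null(beh) && nrow(beh)) {
      act <- normalise_label(beh$state) %in%
        active_behaviour_labels(cfg$behaviour_table)
      if (any(act)) cbind(beh$start_s[act], beh$end_s[act])
    })
  if (is.null(act_iv)) act_iv <- cbind(numeric(), numeric())
  CN <- count_correct_negatives(act_iv, t_range, cfg$silence_s, cfg$cn_mode)

  base_CP <- sum(correct)
  counts <- if (cfg$location_policy == "wrong_as_CP")
    confusion_counts(CP = base_CP + n_wrong, FP = FP, FN = FN_refs, CN = CN)
  else confusion_counts(CP = base_CP, FP = FP, FN = FN_refs + n_wrong, CN = CN)

  spot_class <- if (ns) data.frame(
    time_s = sp$time_s, zone = sp$zone,
    class = ifelse(!paired, "FP",
                   ifelse(correct, "CP",
                          ifelse(cfg$location_policy == "wrong_as_CP",
                                 "CP_wrong_location", "FN_wrong_location"))),
    paired_ref = s_pair, stringsAsFactors = FALSE)
  else data.frame(time_s = numeric(), zone = character(),
                  class = character(), paired_ref = integer())

  structure(list(counts = counts, n_wrong_location = n_wrong,
                 CP_correct = base_CP, FP = FP, FN_refs = FN_refs, CN = CN,
                 spot_class = spot_class, t_range = t_range, config = cfg),
            class = "fc_match")
}

#' @export
print.fc_match <- function(x, ...) {
  cat(sprintf("Spot matching (%s, %s): ", x$config$reference_mode,
              x$config$location_policy))
  print(x$counts)
  cat(sprintf("  wrong-location pairs: %d\n", x$n_wrong_location))
  invisible(x)
}

#' Re-resolve wrong-location pairs under a location policy
#'
#' Moves every paired-but-wrong-location unit between the false-negative
#' and correct-positive tallies; false positives and correct negatives are
#' unaffected by the policy.
#'
#' @param x an [match_events()] result, or a [confusion_counts()] whose
#'   wrong-location pairs are counted as false negatives
#' @param policy `"wrong_as_FN"` or `"wrong_as_CP"`
#' @param n_wrong_location number of wrong-location pairs (required for
#'   plain counts input)
#' @return a [confusion_counts()]
#' @export
apply_location_policy <- function(x, policy = c("wrong_as_FN", "wrong_as_CP"),
                                  n_wrong_location = NULL) {
  policy <- match.arg(policy)
  if (inherits(x, "fc_match")) {
    nw <- x$n_wrong_location
    base <- confusion_counts(CP = x$CP_correct, FP = x$FP,
                             FN = x$FN_refs + nw, CN = x$CN)
  } else if (inherits(x, "fc_counts")) {
    if (is.null(n_wrong_location))
      stop("n_wrong_location is required for plain counts input")
    nw <- n_wrong_location
    if (nw > x$FN) stop("n_wrong_location exceeds the false-negative count")
    base <- x
  } else stop("x must be an fc_match or fc_counts object")
  if (policy == "wrong_as_FN") base
  else confusion_counts(CP = base$CP + nw, FP = base$FP, FN = base$FN - nw,
                        CN = base$CN)
}
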