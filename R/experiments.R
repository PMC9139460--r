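#' Map a stored firing rate to a recall probability
#'
#' Memory fidelity is read out from the stored rate through a logistic link:
#' \deqn{p(r) = \frac{1}{1 + \exp(-k (r / r_{plateau} - c))},}
#' clamped to exactly 0 at or below the forgetting threshold
#' (`forget_frac * r_plateau`). The link is monotone nondecreasing and
#' bounded in `[0, 1]`; any monotone link preserves the trend-level
#' behaviour of the experiments, so the particular sigmoid is a convenience,
#' not a claim.
#'
#' @param rate current firing rate(s), rate units.
#' @param plateau storage plateau rate the item was encoded at.
#' @param k logistic steepness (default 10).
#' @param c logistic midpoint as a fraction of the plateau (default 0.5).
#' @param forget_frac forgetting threshold fraction (default 0.1).
#' @return recall probability/-ies in `[0, 1]`.
#' @export
recall_probability <- function(rate, plateau, k = 10, c = 0.5,
                               forget_frac = 0.1) {
  p <- 1 / (1 + exp(-k * (rate / plateau - c)))
  p[rate <= forget_frac * plateau] <- 0
  p
}

experiment_result <- function(id, grid, extra = list()) {
  structure(c(list(id = id, grid = grid), extra),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> study %s\n", x$id))
  print(x$grid)
  invisible(x)
}

# recall probability of one feature in one SDN channel (0 if not held)
channel_recall <- function(state, feature_id, ...) {
  held <- held_items(state)
  row <- held[held$feature_id == feature_id, , drop = FALSE]
  if (!nrow(row)) return(0)
  recall_probability(row$rate[1L], row$stored_rate[1L],
                     forget_frac = state$forget_frac, ...)
}

#' Study A: delayed-response forgetting
#'
#' One cue is stored and recalled after increasing delays, emulating an
#' oculomotor delayed-response task: a brief visual cue, an unfilled delay,
#' then a response from memory. The stored rate decays during the delay, so
#' recall probability is non-increasing in delay and reaches 0 once the
#' rate crosses the forgetting threshold (total forgetting). The result
#' also reports the spread of firing rates across the network's components
#' (the cued SET against the unstimulated ones), which is widest at
#' response onset and shrinks as the trace decays.
#'
#' @param delays numeric vector of delays in ms, sorted ascending, all
#'   `>= 0`.
#' @param amplitude storage amplitude, rate units.
#' @param sdn_factory zero-argument function building a fresh SDN per
#'   delay condition.
#' @return an `experiment_result` whose `grid` has columns `delay_ms`,
#'   `recall_p`, `rate`, `rate_spread`.
#' @export
run_delay_experiment <- function(delays, amplitude = 50,
                                 sdn_factory = build_sdn) {
  if (any(delays < 0)) stop("delays must be >= 0")
  if (is.unsorted(delays)) stop("delays must be sorted ascending")
  rows <- lapply(delays, function(d) {
    st <- sdn_factory()
    st <- present_stimulus(st, "cue", amplitude)
    if (d > 0) st <- advance_time(st, d)
    held <- held_items(st)
    rate <- if (nrow(held)) held$rate[1L] else 0
    data.frame(delay_ms = d,
               recall_p = channel_recall(st, "cue"),
               rate = rate,
               rate_spread = rate)  # unstimulated components sit at rest
  })
  experiment_result("A", do.call(rbind, rows))
}

#' Study B/C: sequence storage with identity-position association
#'
#' A sequence of items is presented at a fixed pace; each item is split
#' into an identity feature and a position feature, stored in two parallel
#' SDN channels under a shared item id (one SDN per characteristic). An
#' item counts as recallable only when *both* channels still hold its
#' features above threshold, so association is a conjunction. With more
#' items than the four-SET capacity, early items are evicted first-in
#' first-out and only the most recent ones remain recallable — the
#' updating behaviour probed by last-`k`-recall designs.
#'
#' @param n_items number of items presented (>= 1).
#' @param hold_time retention interval after the last item, ms.
#' @param item_duration,item_gap presentation pacing, ms (defaults 200 ms
#'   on, 800 ms blank).
#' @param amplitude storage amplitude.
#' @param sdn_factory zero-argument function building a fresh SDN.
#' @return an `experiment_result` whose `grid` has one row per item:
#'   `item`, `recallable`, `recall_p`, `p_identity`, `p_position`.
#' @export
run_association_experiment <- function(n_items, hold_time = 0,
                                       item_duration = 200,
                                       item_gap = 800, amplitude = 50,
                                       sdn_factory = build_sdn) {
  if (n_items < 1) stop("`n_items` must be >= 1")
  period <- item_duration + item_gap
  onsets <- (seq_len(n_items) - 1) * period
  sched <- function(prefix) data.frame(
    t = onsets, feature_id = paste0(prefix, seq_len(n_items)),
    amplitude = amplitude)
  identity_ch <- run_sdn_schedule(sdn_factory(), sched("id"))
  position_ch <- run_sdn_schedule(sdn_factory(), sched("pos"))
  if (hold_time > 0) {
    identity_ch <- advance_time(identity_ch, hold_time)
    position_ch <- advance_time(position_ch, hold_time)
  }
  p_id <- vapply(seq_len(n_items), function(k)
    channel_recall(identity_ch, paste0("id", k)), 0)
  p_pos <- vapply(seq_len(n_items), function(k)
    channel_recall(position_ch, paste0("pos", k)), 0)
  grid <- data.frame(item = seq_len(n_items), recallable = p_id > 0 &
                       p_pos > 0, recall_p = p_id * p_pos,
                     p_identity = p_id, p_position = p_pos)
  experiment_result("B", grid,
                    list(identity_events = sdn_events(identity_ch),
                         position_events = sdn_events(position_ch)))
}

#' Study D: feature binding and change detection
#'
#' Objects carrying a colour and a shape are stored across three SDN
#' channels: one per feature plus one for the colour-shape conjunction
#' (the binding). After a retention interval, change detection is read
#' out per probe condition: single-feature probes need only the
#' corresponding feature channel, the mixed condition averages the two,
#' and the binding condition requires the conjunction channel as well —
#' its performance can therefore never exceed the single-feature
#' conditions.
#'
#' @param probe_type one or more of `"color"`, `"shape"`, `"either"`,
#'   `"binding"`.
#' @param n_objects number of objects in the display (default 3).
#' @param retention retention interval, ms (default 906, a classic blank
#'   interval between study display and test display).
#' @param amplitude storage amplitude.
#' @param sdn_factory zero-argument function building a fresh SDN.
#' @return an `experiment_result` whose `grid` has columns `probe_type`
#'   and `detect_p` (mean change-detection probability over objects).
#' @export
run_binding_experiment <- function(probe_type = c("color", "shape",
                                                  "either", "binding"),
                                   n_objects = 3, retention = 906,
                                   amplitude = 50,
                                   sdn_factory = build_sdn) {
  probe_type <- match.arg(probe_type, several.ok = TRUE)
  onsets <- (seq_len(n_objects) - 1) * 300
  channels <- lapply(c("col", "shp", "bind"), function(prefix) {
    run_sdn_schedule(sdn_factory(), data.frame(
      t = onsets, feature_id = paste0(prefix, seq_len(n_objects)),
      amplitude = amplitude))
  })
  names(channels) <- c("col", "shp", "bind")
  channels <- lapply(channels, advance_time, dt_total = retention)
  p_col <- vapply(seq_len(n_objects), function(k)
    channel_recall(channels$col, paste0("col", k)), 0)
  p_shp <- vapply(seq_len(n_objects), function(k)
    channel_recall(channels$shp, paste0("shp", k)), 0)
  p_bnd <- vapply(seq_len(n_objects), function(k)
    channel_recall(channels$bind, paste0("bind", k)), 0)
  detect <- vapply(probe_type, function(pt) switch(
    pt,
    color = mean(p_col),
    shape = mean(p_shp),
    either = mean((p_col + p_shp) / 2),
    binding = mean(p_col * p_shp * p_bnd)), 0)
  experiment_result("D", data.frame(probe_type = probe_type,
                                    detect_p = unname(detect)))
}

#' Study E: serial position and rehearsal
#'
#' A list of words is presented at a fixed pace (defaults: 1 s per word at
#' 2 s onsets). Without rehearsal the four-SET capacity plus decay produce
#' a pure recency profile: only the most recent words survive eviction and
#' the latest has the freshest trace. With rehearsal, the earliest list
#' positions (`rehearse_positions`) are covertly re-presented during every
#' inter-word gap; their traces stay at plateau, they escape eviction, and
#' the recall curve gains a primacy limb alongside recency — at the
#' rehearsed positions recall can only improve relative to the
#' no-rehearsal run.
#'
#' @param n_words list length (>= 2; default 8).
#' @param rehearsal logical; rehearse the early positions during gaps?
#' @param rehearse_positions which positions are rehearsed when
#'   `rehearsal = TRUE` (default `1:2`).
#' @param word_duration,interval presentation pacing, ms (word shown
#'   `word_duration`, onsets `interval` apart).
#' @param amplitude storage amplitude.
#' @param sdn_factory zero-argument function building a fresh SDN.
#' @return an `experiment_result` whose `grid` has columns `position`,
#'   `recall_p`.
#' @export
run_serial_position_experiment <- function(n_words = 8, rehearsal = FALSE,
                                           rehearse_positions = 1:2,
                                           word_duration = 1000,
                                           interval = 2000,
                                           amplitude = 50,
                                           sdn_factory = build_sdn) {
  if (n_words < 2) stop("`n_words` must be >= 2")
  st <- sdn_factory()
  for (k in seq_len(n_words)) {
    onset <- (k - 1) * interval
    if (onset > st$clock) st <- advance_time(st, onset - st$clock)
    st <- present_stimulus(st, paste0("w", k), amplitude)
    # covert rehearsal during the blank gap after the word
    if (rehearsal) {
      gap_t <- onset + word_duration
      if (gap_t > st$clock) st <- advance_time(st, gap_t - st$clock)
      held <- held_items(st)
      for (rp in rehearse_positions) {
        f <- paste0("w", rp)
        if (rp < k && f %in% held$feature_id)
          st <- present_stimulus(st, f, amplitude)
      }
    }
  }
  end_t <- (n_words - 1) * interval + word_duration
  if (end_t > st$clock) st <- advance_time(st, end_t - st$clock)
  p <- vapply(seq_len(n_words), function(k)
    channel_recall(st, paste0("w", k)), 0)
  experiment_result("E", data.frame(position = seq_len(n_words),
                                    recall_p = p),
                    list(events = sdn_events(st), rehearsal = rehearsal))
}
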