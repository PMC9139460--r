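#' Selector-circuit topology of the storage distribution network
#'
#' Returns the fixed wiring of the SDN selector circuit: an input pyramidal
#' cell `E00` fanning out to four branches of pyramidal relay cells, each
#' branch ending in a gate cell that activates one of four SET storage
#' handles, plus seven interneurons. Each branch's gate cell drives a *lock*
#' interneuron (I12, I22, I32, I41) that silences the branch's guard
#' interneuron and suppresses already-used gates, so that successive stimuli
#' are routed to successive free branches; the *guard* interneurons (I11,
#' I21, I31) implement winner-take-all during a single routing event by
#' suppressing the sibling branches of the current winner.
#'
#' @return A list describing nodes, excitatory edges, inhibitory edges,
#'   branch membership, gate cells and their lock interneurons.
#' @export
sdn_topology <- function() {
  exc_edges <- rbind(
    data.frame(from = "E00", to = c("E11", "E22", "E32", "E42")),
    data.frame(from = c("E11", "E11", "E12"),
               to = c("I11", "E12", "I12")),
    data.frame(from = c("E22", "E22", "E23"),
               to = c("I21", "E23", "I22")),
    data.frame(from = c("E32", "E33", "E33", "E34"),
               to = c("E33", "I31", "E34", "I32")),
    data.frame(from = c("E42", "E43", "E44", "E45"),
               to = c("E43", "E44", "E45", "I41")))
  inh_edges <- rbind(
    data.frame(from = "I11", to = c("E22", "E32", "E42")),
    data.frame(from = "I12", to = c("I11", "E12")),
    data.frame(from = "I21", to = c("E33", "E43")),
    data.frame(from = "I22", to = c("I11", "I21", "E12", "E23")),
    data.frame(from = "I31", to = "E44"),
    # I32 silencing E34 closes branch 3 after its storage event, matching
    # the lock role the other branches' terminal interneurons play.
    data.frame(from = "I32", to = c("I11", "I21", "I31", "E34")),
    data.frame(from = "I41", to = c("I21", "I31", "E23", "E34", "E45")))
  list(
    e_nodes = c("E00", "E11", "E12", "E22", "E23", "E32", "E33", "E34",
                "E42", "E43", "E44", "E45"),
    i_nodes = c("I11", "I12", "I21", "I22", "I31", "I32", "I41"),
    exc_edges = exc_edges, inh_edges = inh_edges,
    branches = list(c("E11", "E12"), c("E22", "E23"),
                    c("E32", "E33", "E34"),
                    c("E42", "E43", "E44", "E45")),
    gates = c("E12", "E23", "E34", "E45"),
    locks = c("I12", "I22", "I32", "I41"),
    guards = list(c("I11"), c("I21"), c("I31"), character()),
    sets = c("set11", "set21", "set31", "set41"))
}

#' Synaptic weight configuration of the SDN selector circuit
#'
#' The selector circuit works only if inhibition dominates: wherever an
#' interneuron converges on a cell that also receives excitatory drive, the
#' inhibitory weight must exceed the excitatory one, otherwise the
#' winner-take-all and branch-locking logic breaks down. Weights default to
#' a uniform excitatory drive of 1 and inhibitory weight of 2; individual
#' edges can be overridden by name (e.g. `"I11->E22" = 0.5`), which
#' [build_sdn()] will then validate.
#'
#' @param drive uniform excitatory edge weight (> 0).
#' @param inhibition uniform inhibitory edge weight (> 0).
#' @param overrides named numeric vector of per-edge weights, names in the
#'   form `"FROM->TO"`.
#' @return An object of class `sdn_weights`.
#' @export
sdn_weights <- function(drive = 1, inhibition = 2, overrides = NULL) {
  if (drive <= 0 || inhibition <= 0)
    stop("`drive` and `inhibition` must be > 0")
  structure(list(drive = drive, inhibition = inhibition,
                 overrides = overrides),
            class = "sdn_weights")
}

edge_weight <- function(w, from, to, base) {
  key <- paste0(from, "->", to)
  if (!is.null(w$overrides) && key %in% names(w$overrides))
    unname(w$overrides[[key]]) else base
}

#' Build a storage distribution network
#'
#' Assembles an SDN in its resting state: all selector-circuit nodes at
#' rest and all four SETs free. The weight configuration is validated
#' against the inhibition-dominance constraints before anything else: every
#' inhibitory edge onto an excitatory cell must outweigh the excitatory
#' drive converging on that cell, or the build is rejected naming the
#' violated edge.
#'
#' Two abstraction levels are available. In `"logic"` mode (default) the
#' nodes are binary threshold units and a routing event is resolved by a
#' deterministic causal cascade. In `"rate"` mode every node is simulated
#' as a leaky firing-rate unit with Naka-Rushton transfer and the winner is
#' the first gate cell whose rate crosses the gate threshold.
#'
#' Stored items decay between rehearsals under hybrid-feedback dynamics
#' with marginally subcritical positive feedback: the stored rate follows
#' the closed-form solution of the HPNF unit with `decay_params`, giving an
#' effective time constant `(tau + w_der) / (1 - w_pos)` (120 s under the
#' defaults). An item is forgotten — and its SET freed — when its rate
#' falls below `forget_frac` of the storage plateau.
#'
#' @param weights an [sdn_weights()].
#' @param mode `"logic"` or `"rate"`.
#' @param decay_params a [feedback_params()] with `w_pos < 1` governing the
#'   slow decay of stored items.
#' @param forget_frac forgetting threshold as a fraction of the storage
#'   plateau (default 0.1).
#' @param activation_threshold minimum stimulus amplitude that engages the
#'   selector circuit (default 25 rate units).
#' @return An object of class `sdn_state`: resting topology, four free
#'   SETs, empty event log, clock at 0 ms.
#' @export
build_sdn <- function(weights = sdn_weights(),
                      mode = c("logic", "rate"),
                      decay_params = feedback_params(tau = 20,
                                                     w_pos = 0.999,
                                                     w_der = 100),
                      forget_frac = 0.1,
                      activation_threshold = 25) {
  mode <- match.arg(mode)
  stopifnot(inherits(weights, "sdn_weights"),
            inherits(decay_params, "feedback_params"))
  if (decay_params$w_pos >= 1)
    stop("`decay_params$w_pos` must be < 1 so stored items decay")
  if (forget_frac <= 0 || forget_frac >= 1)
    stop("`forget_frac` must lie in (0, 1)")
  topo <- sdn_topology()
  # Inhibition-dominance check: every I -> E edge must beat the excitatory
  # drive converging on the same target.
  for (k in seq_len(nrow(topo$inh_edges))) {
    from <- topo$inh_edges$from[k]; to <- topo$inh_edges$to[k]
    if (!startsWith(to, "E")) next
    w_inh <- edge_weight(weights, from, to, weights$inhibition)
    exc_in <- topo$exc_edges[topo$exc_edges$to == to, , drop = FALSE]
    w_exc <- if (nrow(exc_in))
      max(vapply(seq_len(nrow(exc_in)), function(j)
        edge_weight(weights, exc_in$from[j], to, weights$drive), 0))
    else weights$drive
    if (w_inh <= w_exc)
      stop("inhibition-dominance violated on edge ", from, "->", to,
           " (inhibitory weight ", w_inh,
           " must exceed excitatory drive ", w_exc, ")")
  }
  sets <- stats::setNames(vector("list", 4L), topo$sets)
  structure(list(topology = topo, weights = weights, mode = mode,
                 decay = decay_params, forget_frac = forget_frac,
                 activation_threshold = activation_threshold,
                 clock = 0, sets = sets, events = list(), pending = NULL,
                 nodes = character()),
            class = "sdn_state")
}

#' @export
print.sdn_state <- function(x, ...) {
  held <- held_items(x)
  cat(sprintf("<sdn_state> mode=%s clock=%g ms, %d/4 SETs occupied\n",
              x$mode, x$clock, nrow(held)))
  if (nrow(held)) print(held)
  invisible(x)
}

decay_tau_eff <- function(decay)
  (decay$tau + decay$w_der) / (1 - decay$w_pos)

item_rate <- function(item, clock, decay)
  item$stored_rate * exp(-(clock - item$last_refresh) / decay_tau_eff(decay))

#' Currently held items of an SDN
#'
#' @param state an `sdn_state`.
#' @return a data frame with one row per held item: `set_id`, `feature_id`,
#'   `stored_rate` (storage plateau), `rate` (current, decayed),
#'   `store_time`, `last_refresh`.
#' @export
held_items <- function(state) {
  stopifnot(inherits(state, "sdn_state"))
  occ <- !vapply(state$sets, is.null, TRUE)
  rows <- lapply(state$sets[occ], function(it)
    data.frame(set_id = it$set_id, feature_id = it$feature_id,
               stored_rate = it$stored_rate,
               rate = item_rate(it, state$clock, state$decay),
               store_time = it$store_time,
               last_refresh = it$last_refresh))
  if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
  else data.frame(set_id = character(), feature_id = character(),
                  stored_rate = numeric(), rate = numeric(),
                  store_time = numeric(), last_refresh = numeric())
}

log_event <- function(state, t, event, feature_id, set_id, rate) {
  state$events[[length(state$events) + 1L]] <-
    list(t = t, event = event, feature_id = feature_id, set_id = set_id,
         rate = rate)
  state
}

#' Event log of an SDN as a data frame
#'
#' @param state an `sdn_state`.
#' @return data frame with columns `t`, `event` (one of `stored`,
#'   `refreshed`, `evicted`, `forgotten`), `feature_id`, `set_id`, `rate`.
#' @export
sdn_events <- function(state) {
  stopifnot(inherits(state, "sdn_state"))
  if (!length(state$events))
    return(data.frame(t = numeric(), event = character(),
                      feature_id = character(), set_id = character(),
                      rate = numeric()))
  do.call(rbind, lapply(state$events, function(e)
    data.frame(t = e$t, event = e$event, feature_id = e$feature_id,
               set_id = e$set_id, rate = e$rate)))
}

# Deterministic causal cascade over the selector circuit (logic mode).
# Returns the winning branch index (or NA), the set of excitatory nodes
# that fired and the interneurons active at the end of the event.
route_cascade_logic <- function(state) {
  topo <- state$topology
  occupied <- !vapply(state$sets, is.null, TRUE)
  # Gate cells are locked by occupancy: each occupied branch's lock
  # interneuron holds its own gate down. Tonic locks additionally silence
  # other interneurons (e.g. I12 keeps I11 quiet on later stimuli), but
  # their cross-branch edges onto gate cells act only within a routing
  # event — a branch freed by forgetting must be reachable again.
  tonic <- topo$locks[occupied]
  locked_gates <- topo$gates[occupied]
  inh <- topo$inh_edges
  inhibited_by <- function(node, active) {
    if (startsWith(node, "E")) active <- setdiff(active, tonic)
    any(inh$from %in% active & inh$to == node)
  }
  fired <- "E00"
  active_i <- tonic
  winner <- NA_integer_
  for (b in seq_along(topo$branches)) {
    chain <- topo$branches[[b]]
    prev <- "E00"
    for (node in chain) {
      driven <- any(topo$exc_edges$from == prev & topo$exc_edges$to == node)
      if (!driven || node %in% locked_gates ||
          inhibited_by(node, active_i)) break
      fired <- c(fired, node)
      # fire this cell's interneuron targets (unless themselves inhibited)
      itargets <- topo$exc_edges$to[topo$exc_edges$from == node]
      itargets <- itargets[startsWith(itargets, "I")]
      for (i_node in itargets) {
        if (!inhibited_by(i_node, active_i)) {
          active_i <- union(active_i, i_node)
          # an interneuron firing can silence other interneurons at once
          silenced <- inh$to[inh$from == i_node]
          active_i <- setdiff(active_i, silenced[startsWith(silenced, "I")])
        }
      }
      prev <- node
    }
    if (length(fired) && chain[length(chain)] %in% fired) {
      winner <- b
      break
    }
  }
  list(winner = winner, fired = fired, active_i = active_i)
}

# Firing-rate simulation of one routing event (rate mode): every node is a
# leaky rate unit with Naka-Rushton transfer; the winner is the first gate
# whose rate crosses `gate_level`. Lock interneurons of occupied branches
# fire tonically throughout the event.
route_cascade_rate <- function(state, drive_current = 100,
                               gate_level = 35, horizon = 300, dt = 0.5,
                               tau_e = 10, tau_i = 5) {
  topo <- state$topology
  nr <- naka_rushton_params()
  w <- state$weights
  nodes <- c(topo$e_nodes, topo$i_nodes)
  occupied <- !vapply(state$sets, is.null, TRUE)
  tonic <- topo$locks[occupied]
  r <- stats::setNames(numeric(length(nodes)), nodes)
  r[tonic] <- nr$m_max * 0.8
  tau <- ifelse(startsWith(nodes, "I"), tau_i, tau_e)
  names(tau) <- nodes
  exc <- topo$exc_edges; inh <- topo$inh_edges
  exc$w <- vapply(seq_len(nrow(exc)), function(k)
    edge_weight(w, exc$from[k], exc$to[k], w$drive), 0)
  inh$w <- vapply(seq_len(nrow(inh)), function(k)
    edge_weight(w, inh$from[k], inh$to[k], w$inhibition), 0)
  # As in logic mode, tonic lock interneurons silence other interneurons
  # but do not reach across branches onto gate cells; occupied gates are
  # held down directly by their branch's stored activity.
  inh$w[inh$from %in% tonic & startsWith(inh$to, "E")] <- 0
  locked_gates <- topo$gates[occupied]
  for (step in seq_len(ceiling(horizon / dt))) {
    input <- stats::setNames(numeric(length(nodes)), nodes)
    input["E00"] <- drive_current
    input[locked_gates] <- -10 * drive_current
    for (k in seq_len(nrow(exc)))
      input[exc$to[k]] <- input[exc$to[k]] + exc$w[k] * r[exc$from[k]]
    for (k in seq_len(nrow(inh)))
      input[inh$to[k]] <- input[inh$to[k]] - inh$w[k] * r[inh$from[k]]
    r <- r + dt / tau * (-r + naka_rushton(input, nr))
    r[tonic] <- nr$m_max * 0.8  # clamped by the stored SET's activity
    crossed <- which(r[topo$gates] >= gate_level)
    if (length(crossed))
      return(list(winner = crossed[1L],
                  fired = names(r)[startsWith(names(r), "E") &
                                     r >= gate_level],
                  active_i = names(r)[startsWith(names(r), "I") &
                                        r >= gate_level]))
  }
  list(winner = NA_integer_,
       fired = names(r)[startsWith(names(r), "E") & r >= gate_level],
       active_i = names(r)[startsWith(names(r), "I") & r >= gate_level])
}

#' Route a stimulus through the SDN selector circuit
#'
#' Presents one feature stimulus to the network input `E00` and resolves
#' which SET it is routed to. Exactly one SET is selected per
#' super-threshold stimulus:
#' \itemize{
#'   \item a feature already held resonates with the SET storing it, which
#'     is re-selected (memory retelling);
#'   \item otherwise the selector cascade runs and the first branch whose
#'     gate cell is not locked wins, the winner's guard interneuron
#'     silencing the sibling branches (winner-take-all);
#'   \item when every branch is locked (four items held), the branch of the
#'     SET with the lowest current firing rate is released and wins, which
#'     under pure decay is the earliest-stored item (FIFO).
#' }
#' A sub-threshold stimulus does not engage the circuit: the state is
#' returned unchanged with a warning and `set_id = NA`.
#'
#' The routing decision is stashed in the state; [store_or_update()]
#' consumes it.
#'
#' @param state an `sdn_state` from [build_sdn()].
#' @param feature_id character label of the feature to store.
#' @param amplitude stimulus amplitude in rate units; it becomes the
#'   storage plateau of the item.
#' @return A list with elements `state` (updated) and `set_id` (selected
#'   SET, or `NA` for a sub-threshold stimulus).
#' @export
route_stimulus <- function(state, feature_id, amplitude) {
  stopifnot(inherits(state, "sdn_state"))
  if (amplitude < state$activation_threshold) {
    warning("sub-threshold stimulus (amplitude ", amplitude, " < ",
            state$activation_threshold, "); no routing")
    return(list(state = state, set_id = NA_character_))
  }
  topo <- state$topology
  held <- held_items(state)
  if (feature_id %in% held$feature_id) {
    set_id <- held$set_id[held$feature_id == feature_id][1L]
    b <- match(set_id, topo$sets)
    state$nodes <- c("E00", topo$branches[[b]])
  } else {
    res <- if (state$mode == "logic") route_cascade_logic(state)
    else route_cascade_rate(state)
    if (is.na(res$winner)) {
      # all branches locked: the weakest SET's branch is released
      rates <- held$rate
      weakest <- order(rates, held$store_time)[1L]
      set_id <- held$set_id[weakest]
      b <- match(set_id, topo$sets)
      state$nodes <- c("E00", topo$branches[[b]])
    } else {
      set_id <- topo$sets[res$winner]
      state$nodes <- res$fired
    }
  }
  state$pending <- list(feature_id = feature_id, amplitude = amplitude,
                        set_id = set_id)
  list(state = state, set_id = set_id)
}

#' Store or update a memory item in its routed SET
#'
#' Consumes the routing decision of the immediately preceding
#' [route_stimulus()] call. A free SET stores the new item; the SET already
#' holding the same feature is refreshed to the storage plateau (rehearsal);
#' a SET holding a different item — which only happens when all four were
#' occupied and the weakest was released — atomically evicts its old item
#' and stores the new one. Every transition is appended to the event log.
#'
#' @param state an `sdn_state` whose `pending` slot was set by
#'   [route_stimulus()].
#' @param set_id the SET returned by [route_stimulus()].
#' @param feature_id the feature label given to [route_stimulus()].
#' @return the updated `sdn_state`.
#' @export
store_or_update <- function(state, set_id, feature_id) {
  stopifnot(inherits(state, "sdn_state"))
  p <- state$pending
  if (is.null(p) || !identical(p$set_id, set_id) ||
      !identical(p$feature_id, feature_id))
    stop("`set_id` must come from the immediately preceding route_stimulus()")
  state$pending <- NULL
  old <- state$sets[[set_id]]
  now <- state$clock
  if (!is.null(old) && old$feature_id == feature_id) {
    old$stored_rate <- p$amplitude
    old$last_refresh <- now
    state$sets[[set_id]] <- old
    return(log_event(state, now, "refreshed", feature_id, set_id,
                     p$amplitude))
  }
  if (!is.null(old)) {
    state <- log_event(state, now, "evicted", old$feature_id, set_id,
                       item_rate(old, now, state$decay))
    state$sets[set_id] <- list(NULL)
  }
  state$sets[[set_id]] <- list(feature_id = feature_id,
                               stored_rate = p$amplitude,
                               store_time = now, last_refresh = now,
                               set_id = set_id)
  log_event(state, now, "stored", feature_id, set_id, p$amplitude)
}

#' Let time pass: decay and forget
#'
#' Advances the SDN clock by `dt_total` ms. Stored items decay continuously
#' under the closed-form HPNF solution; any item whose rate crosses the
#' forgetting threshold within the interval is marked forgotten at the
#' exact crossing time and its SET is freed.
#'
#' @param state an `sdn_state`.
#' @param dt_total time to advance, ms (> 0).
#' @return the updated `sdn_state`.
#' @export
advance_time <- function(state, dt_total) {
  stopifnot(inherits(state, "sdn_state"))
  if (!is.numeric(dt_total) || dt_total <= 0)
    stop("`dt_total` must be > 0")
  target <- state$clock + dt_total
  tau_eff <- decay_tau_eff(state$decay)
  for (set_id in names(state$sets)) {
    it <- state$sets[[set_id]]
    if (is.null(it)) next
    t_cross <- it$last_refresh + tau_eff * log(1 / state$forget_frac)
    if (t_cross <= target) {
      state <- log_event(state, t_cross, "forgotten", it$feature_id,
                         set_id, state$forget_frac * it$stored_rate)
      state$sets[set_id] <- list(NULL)
    }
  }
  state$clock <- target
  state
}

#' Present one stimulus: route, then store
#'
#' Convenience wrapper running [route_stimulus()] followed by
#' [store_or_update()].
#'
#' @inheritParams route_stimulus
#' @return the updated `sdn_state` (selected SET in attribute `set_id`).
#' @export
present_stimulus <- function(state, feature_id, amplitude = 50) {
  routed <- route_stimulus(state, feature_id, amplitude)
  if (is.na(routed$set_id)) return(routed$state)
  out <- store_or_update(routed$state, routed$set_id, feature_id)
  attr(out, "set_id") <- routed$set_id
  out
}

#' Run a timed stimulus schedule through an SDN
#'
#' Replays a schedule of feature presentations in time order, advancing the
#' clock (and therefore decay/forgetting) between presentations.
#'
#' @param state an `sdn_state`.
#' @param schedule data frame with columns `t` (ms), `feature_id`,
#'   `amplitude`.
#' @return the final `sdn_state`; inspect [sdn_events()] for the history.
#' @export
run_sdn_schedule <- function(state, schedule) {
  stopifnot(inherits(state, "sdn_state"),
            all(c("t", "feature_id", "amplitude") %in% names(schedule)))
  schedule <- schedule[order(schedule$t), , drop = FALSE]
  for (k in seq_len(nrow(schedule))) {
    if (schedule$t[k] > state$clock)
      state <- advance_time(state, schedule$t[k] - state$clock)
    state <- present_stimulus(state, schedule$feature_id[k],
                              schedule$amplitude[k])
  }
  state
}
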