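#' Paralysable per-module dead time
#'
#' A single is recorded iff no prior arrival (recorded or not) occurred on
#' the same module within `tau_ns` before it; every arrival extends the
#' dead period.  Applied to all interacting singles *before* the energy
#' window, because the detector is busy regardless of the accepted energy.
#'
#' @param singles time-ordered singles data.table (columns `t_ns`, `module`)
#' @param tau_ns dead time (ns)
#' @param model only `"paralysable"`
#' @return the surviving singles, same columns and order
#' @export
apply_dead_time <- function(singles, tau_ns = 300,
                            model = c("paralysable")) {
  model <- match.arg(model)
  singles <- as_singles_dt(singles)
  if (is.unsorted(singles$t_ns)) stop("singles must be time-ordered")
  if (tau_ns <= 0 || nrow(singles) == 0L) return(singles)
  t_ns <- .I <- NULL  # NSE notes
  keep <- singles[, .I[{
    gap <- t_ns - shift(t_ns)
    is.na(gap) | gap > tau_ns
  }], by = "module"]$V1
  singles[sort(keep)]
}

as_singles_dt <- function(singles) {
  if (inherits(singles, "pet_singles")) singles <- singles$singles
  stopifnot(is.data.frame(singles))
  as.data.table(singles)
}

#' Energy window filter
#'
#' Keeps singles whose measured energy lies in the closed window.
#'
#' @param singles singles data.table with column `energy`
#' @param window keV pair, default the 440-650 keV acquisition window
#' @return filtered singles
#' @export
energy_window_filter <- function(singles, window = c(440, 650)) {
  singles <- as_singles_dt(singles)
  stopifnot(length(window) == 2L, window[1] < window[2])
  energy <- NULL
  singles[energy >= window[1] & energy <= window[2]]
}

#' Pair singles into prompt coincidences
#'
#' Sliding-window pairing: each group opens a window of `window_ns` at its
#' first single's timestamp.  Exactly two singles on distinct modules give
#' one prompt; larger groups (multiples) are discarded under the default
#' `"killAll"` policy or expanded to all distinct-module pairs under
#' `"takeAllGoods"`.  Same-module pairs are always discarded.
#'
#' @param singles time-ordered, dead-time- and energy-filtered singles
#' @param window_ns coincidence window, interpreted as |t1 - t2| <= window
#' @param policy multiples policy
#' @return data.table of coincidences with both endpoint records, the time
#'   difference `dt_ns = t1 - t2`, and ground-truth lineage
#' @export
pair_coincidences <- function(singles, window_ns = 3,
                              policy = c("killAll", "takeAllGoods")) {
  policy <- match.arg(policy)
  singles <- as_singles_dt(singles)
  if (is.unsorted(singles$t_ns)) stop("singles must be time-ordered")
  pr <- pair_coincidences_cpp(singles$t_ns, singles$module, window_ns,
                              if (policy == "killAll") 0L else 1L)
  i <- pr$i; j <- pr$j
  coin <- data.table(
    decay_id1 = singles$decay_id[i], decay_id2 = singles$decay_id[j],
    module1 = singles$module[i], module2 = singles$module[j],
    x1 = singles$x[i], y1 = singles$y[i], z1 = singles$z[i],
    x2 = singles$x[j], y2 = singles$y[j], z2 = singles$z[j],
    e1 = singles$energy[i], e2 = singles$energy[j],
    t1 = singles$t_ns[i], t2 = singles$t_ns[j],
    nscat1 = singles$n_scatters[i], nscat2 = singles$n_scatters[j]
  )
  coin[, "dt_ns" := coin$t1 - coin$t2]
  attr(coin, "window_ns") <- window_ns
  attr(coin, "policy") <- policy
  coin
}

#' Classify coincidences by ground truth
#'
#' Same decay and no phantom scatter on either photon: true; same decay
#' with any phantom scatter: scatter; different decays: random.
#'
#' @param coin coincidences from [pair_coincidences()]
#' @return the same table with a `truth` column
#' @export
classify_truth <- function(coin) {
  need <- c("decay_id1", "decay_id2", "nscat1", "nscat2")
  if (!all(need %in% names(coin)) ||
      anyNA(coin$decay_id1) || anyNA(coin$decay_id2)) {
    stop("ground-truth lineage missing: cannot classify")
  }
  coin <- as.data.table(coin)
  truth <- fifelse(coin$decay_id1 != coin$decay_id2, "random",
                   fifelse(coin$nscat1 + coin$nscat2 > 0L, "scatter", "true"))
  coin[, "truth" := truth]
  coin
}

#' Full singles-to-labelled-coincidences chain
#'
#' Dead time (per module, before the energy window), energy window, window
#' pairing, ground-truth classification.
#'
#' @param sim a `pet_singles` run (or a singles table)
#' @param tau_ns,window,pair_window_ns,policy processing parameters; when
#'   `sim` is a full run the scanner configuration supplies the defaults
#' @param dead_time_first apply the dead time to all interacting singles
#'   before the energy window instead of after it.  The default (`FALSE`)
#'   follows the standard GATE digitizer chain, where the dead-time module
#'   sits behind the energy thresholds.
#' @return list: `coincidences` (labelled), `counts` (prompts and per-class
#'   tallies), `duration_s`
#' @export
process_coincidences <- function(sim, tau_ns = NULL, window = NULL,
                                 pair_window_ns = NULL,
                                 policy = "killAll",
                                 dead_time_first = FALSE) {
  duration <- NA_real_
  if (inherits(sim, "pet_singles")) {
    cfg <- sim$scenario$geometry$config
    if (is.null(tau_ns)) tau_ns <- cfg$dead_time_ns
    if (is.null(window)) window <- cfg$energy_window
    if (is.null(pair_window_ns)) pair_window_ns <- cfg$coincidence_window_ns
    duration <- sim$duration_s
  } else {
    if (is.null(tau_ns)) tau_ns <- 300
    if (is.null(window)) window <- c(440, 650)
    if (is.null(pair_window_ns)) pair_window_ns <- 3
  }
  if (dead_time_first) {
    s <- energy_window_filter(apply_dead_time(sim, tau_ns), window)
  } else {
    s <- apply_dead_time(energy_window_filter(sim, window), tau_ns)
  }
  coin <- pair_coincidences(s, pair_window_ns, policy)
  coin <- classify_truth(coin)
  counts <- c(prompts = nrow(coin),
              trues = sum(coin$truth == "true"),
              scatters = sum(coin$truth == "scatter"),
              randoms = sum(coin$truth == "random"))
  list(coincidences = coin, counts = counts, duration_s = duration)
}
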