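# Independent brute-force excursion finder: scans every (start, end)
# sample pair, checks the elevation predicate in full, then merges
# qualifying stretches. Used as the ground-truth oracle for
# detect_excursions(); deliberately naive.
oracle_excursions <- function(trace, threshold = 1, min_dur = 60,
                              ref_window = 30, max_gap = 30) {
  n <- nrow(trace)
  t_min <- as.numeric(trace$timestamp) / 60
  g <- trace$glucose
  pairs_s <- integer(0); pairs_e <- integer(0); pair_ref <- numeric(0)
  for (s in seq_len(n)) {
    in_ref <- t_min >= t_min[s] - ref_window & t_min < t_min[s]
    if (!any(in_ref)) next
    ref <- min(g[in_ref])
    for (e in s:n) {
      # once any sample in s:e breaks the elevation or continuity, every
      # longer stretch from s is broken too, so stopping here is exact
      if (g[e] < ref + threshold ||
          (e > s && t_min[e] - t_min[e - 1L] > max_gap)) break
      if (t_min[e] - t_min[s] >= min_dur) {
        pairs_s <- c(pairs_s, s); pairs_e <- c(pairs_e, e)
        pair_ref <- c(pair_ref, ref)
      }
    }
  }
  if (!length(pairs_s)) {
    return(tibble::tibble(onset = as.POSIXct(character(), tz = "UTC"),
                          end = as.POSIXct(character(), tz = "UTC"),
                          reference = numeric(), peak = numeric(),
                          sustained_minutes = numeric()))
  }
  ord <- order(pairs_s, pairs_e)
  pairs_s <- pairs_s[ord]; pairs_e <- pairs_e[ord]; pair_ref <- pair_ref[ord]
  # merge pairs whose sample ranges overlap or abut
  grp <- integer(length(pairs_s)); grp[1] <- 1L; cur_end <- pairs_e[1]
  for (k in seq_along(pairs_s)[-1]) {
    if (pairs_s[k] <= cur_end + 1L) {
      grp[k] <- grp[k - 1L]
    } else {
      grp[k] <- grp[k - 1L] + 1L
    }
    cur_end <- max(cur_end, pairs_e[k])
  }
  out <- lapply(split(seq_along(pairs_s), grp), function(idx) {
    s <- min(pairs_s[idx]); e <- max(pairs_e[idx])
    tibble::tibble(onset = trace$timestamp[s], end = trace$timestamp[e],
                   reference = pair_ref[idx][which.min(pairs_s[idx])],
                   peak = max(g[s:e]),
                   sustained_minutes = t_min[e] - t_min[s])
  })
  dplyr::bind_rows(out)
}

# regular-cadence trace builder for fixtures
make_trace <- function(glucose, cadence = 15,
                       start = as.POSIXct("2022-03-01 04:00:00", tz = "UTC"),
                       participant = "P01") {
  tibble::tibble(
    participant = participant,
    timestamp = start + (seq_along(glucose) - 1) * cadence * 60,
    glucose = glucose
  )
}

# rectangular step fixture: baseline with a raised plateau
step_trace <- function(base = 5, high = 6.5, n_before = 8, n_high = 7,
                       n_after = 8, cadence = 15) {
  make_trace(c(rep(base, n_before), rep(high, n_high), rep(base, n_after)),
             cadence = cadence)
}
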