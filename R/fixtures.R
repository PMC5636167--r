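#' Scripted plasticity scenarios for hand-checkable tests
#'
#' Deterministic spike-train scenarios whose expected STDP traces can be
#' verified by hand from the trace formula `K exp(-|dt|/T_c)` with `K = 0.04`
#' and `T_c = 40` ms: zero lag, +/-40 ms lags, the pairing-window boundary,
#' multi-spike pairing, and the 6-epoch trace expiry.
#'
#' @return A named list of scenarios; each has `pre`, `post` (spike times in
#'   ms), `expected` (a data frame of expected pairings, ordered as
#'   [collect_pairings()] returns them), and, for the expiry scenario,
#'   `created_epoch` and `expired_epoch`.
#' @export
make_trace_scenarios <- function() {
  K <- 0.04
  Tc <- 40
  list(
    zero_lag = list(
      pre = 10, post = 10,
      expected = data.frame(t_pre = 10, t_post = 10, value = K)),
    lag_plus_40ms = list(
      pre = 0, post = 40,
      expected = data.frame(t_pre = 0, t_post = 40, value = K * exp(-1))),
    lag_minus_40ms = list(
      pre = 40, post = 0,
      expected = data.frame(t_pre = 40, t_post = 0, value = -K * exp(-1))),
    window_boundary = list(
      pre = 0, post = c(120, 121),
      expected = data.frame(t_pre = 0, t_post = 120,
                            value = K * exp(-120 / Tc))),
    multi_pair = list(
      pre = c(0, 1), post = 2,
      expected = data.frame(t_pre = c(0, 1), t_post = c(2, 2),
                            value = K * exp(-c(2, 1) / Tc))),
    expiry = list(
      pre = 0, post = 1,
      expected = data.frame(t_pre = 0, t_post = 1,
                            value = K * exp(-1 / Tc)),
      created_epoch = 1, expired_epoch = 8)
  )
}

#' Build a miniature world from a text layout
#'
#' Thin wrapper around [read_world()] for tests: rows of `.` (empty), `o`
#' (single food), `H`/`V` (pattern cells) and optionally `@` (agent).
#'
#' @param layout Character vector of rows, or one string with newlines.
#' @param task Optional task label (inferred from content by default).
#' @return A `forage_world` object.
#' @export
make_tiny_world <- function(layout, task = NULL) {
  if (length(layout) == 1L && grepl("\n", layout)) {
    layout <- strsplit(layout, "\n")[[1]]
    layout <- layout[nzchar(layout)]
  }
  read_world(layout, task = task)
}
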