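# Independent brute-force oracle for the 5-move lookahead: enumerates all
# 8^5 move sequences in plain R, tracking consumed food, and returns the
# optimal first moves under the same ordering (food count, then earlier
# acquisition times, lexicographically).
lookahead_oracle <- function(field) {
  offs <- direction_offsets()
  best_score <- NULL
  best_first <- integer(0)
  better <- function(a, b) {
    if (is.null(b)) return(TRUE)
    if (a$count != b$count) return(a$count > b$count)
    for (k in seq_len(5)) {
      if (a$times[k] != b$times[k]) return(a$times[k] < b$times[k])
    }
    FALSE
  }
  for (d1 in 1:8) for (d2 in 1:8) for (d3 in 1:8) for (d4 in 1:8) {
    for (d5 in 1:8) {
      r <- 0L; c <- 0L
      consumed <- logical(49)
      times <- rep(1000L, 5)
      cnt <- 0L
      ok <- TRUE
      dirs <- c(d1, d2, d3, d4, d5)
      for (step in 1:5) {
        r <- r + offs[dirs[step], 1]
        c <- c + offs[dirs[step], 2]
        if (abs(r) > 3 || abs(c) > 3) { ok <- FALSE; break }
        idx <- (r + 3) * 7 + (c + 3) + 1
        if (field[idx] && !consumed[idx]) {
          consumed[idx] <- TRUE
          cnt <- cnt + 1L
          times[cnt] <- step - 1L
        }
      }
      if (!ok) next
      sc <- list(count = cnt, times = times)
      if (better(sc, best_score)) {
        best_score <- sc
        best_first <- d1
      } else if (!better(best_score, sc)) {
        best_first <- union(best_first, d1)
      }
    }
  }
  sort(best_first)
}

# A small field with food at the given (dr, dc) offsets from the agent.
field_with_food <- function(...) {
  f <- logical(49)
  for (p in list(...)) f[(p[1] + 3) * 7 + (p[2] + 3) + 1] <- TRUE
  f
}

# Quiet wrapper for short training runs used by several tests.
quick_train <- function(n_epochs, seed, task = "single", ...) {
  train(network_config(...), n_epochs = n_epochs, seed = seed, task = task)
}
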