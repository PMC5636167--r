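#' Random-move override policy
#'
#' The agent ignores the network output and moves in a uniformly random
#' direction with a probability that escapes movement loops: it starts at
#' `start`, grows by `incr` for every move in which no food is obtained, is
#' reset to `start` whenever food is obtained (single-food task only), and is
#' never below `floor` (the constant 1% chance) nor above 1. In the pattern
#' task the schedule grows faster (1% per foodless move) because approach and
#' avoidance behavior makes the agent far more prone to getting stuck.
#'
#' @param task `"single"` or `"pairs"`.
#' @return An object of class `decision_policy` (a mutable environment).
#' @export
decision_policy <- function(task = c("single", "pairs")) {
  task <- match.arg(task)
  e <- new.env(parent = emptyenv())
  e$task <- task
  e$floor <- 0.01
  e$start <- if (task == "single") 0.005 else 0.01
  e$incr <- if (task == "single") 0.005 else 0.01
  e$sched <- e$start
  class(e) <- "decision_policy"
  e
}

#' Current random-override probability of a policy
#' @param policy A [decision_policy()] object.
#' @return Probability in `[floor, 1]`.
#' @export
policy_prob <- function(policy) min(max(policy$sched, policy$floor), 1)

#' Advance the override schedule after a move
#' @param policy A [decision_policy()] object.
#' @param got_food Did the move acquire food (any kind)?
#' @return The policy, invisibly (updated in place).
#' @export
policy_step <- function(policy, got_food) {
  if (got_food && policy$task == "single") {
    policy$sched <- policy$start
  } else if (!got_food) {
    policy$sched <- policy$sched + policy$incr
  }
  invisible(policy)
}

#' Choose a movement direction from the output-layer response
#'
#' With the policy's current probability the network output is ignored and a
#' uniformly random direction taken. Otherwise the output cell (among the 8
#' direction-mapped cells; the center cell of the 3x3 output layer maps to no
#' direction) with the most spikes in the first half of the epoch wins; ties
#' are broken uniformly at random; if no direction cell fired, the previous
#' direction is kept.
#'
#' @param half_counts Integer vector of length 9: first-half spike counts of
#'   the output cells in row-major order.
#' @param policy A [decision_policy()] object (or `NULL` to disable random
#'   overrides).
#' @param prev_direction Direction 1..8 taken on the previous epoch.
#' @return A list with `direction`, and flags `random`, `tie`, `zero`.
#' @export
decide <- function(half_counts, policy, prev_direction) {
  stopifnot(length(half_counts) == 9)
  if (!is.null(policy) && stats::runif(1) < policy_prob(policy)) {
    return(list(direction = sample.int(8L, 1L), random = TRUE,
                tie = FALSE, zero = FALSE))
  }
  cnt <- half_counts[c(1:4, 6:9)] # drop the center cell
  if (all(cnt == 0L)) {
    return(list(direction = prev_direction, random = FALSE,
                tie = FALSE, zero = TRUE))
  }
  best <- which(cnt == max(cnt))
  dir <- if (length(best) > 1L) best[sample.int(length(best), 1L)] else best
  list(direction = dir, random = FALSE, tie = length(best) > 1L, zero = FALSE)
}

#' Reward scaling factor for a move outcome
#'
#' Food acquisition is rewarded with `s_rp = 1`. Acquiring toxic food
#' (vertical pairs in the pattern task) is punished with `s_rp = -0.5` (half
#' the reward magnitude -- the regime in which learning is reliable). Foodless
#' moves carry a small punishment: `-0.1` in the single-food task and `-0.01`
#' in the pattern task.
#'
#' @param outcome One of `"none"`, `"food"`, `"good_food"`, `"bad_food"`.
#' @param task `"single"` or `"pairs"`.
#' @return The scalar `s_rp`.
#' @export
reward_for <- function(outcome, task = c("single", "pairs")) {
  task <- match.arg(task)
  switch(outcome,
         food = 1,
         good_food = 1,
         bad_food = -0.5,
         none = if (task == "single") -0.1 else -0.01,
         stop("unknown outcome: ", outcome))
}

#' Train the foraging network
#'
#' Runs the full perception-decision-action-reward loop: each epoch the visual
#' field stimulates the input layer, [run_epoch()] simulates the spiking
#' dynamics (applying non-rewarded STDP and recording eligibility traces), the
#' first-half output activity picks a move, the move resolves food
#' acquisition, the resulting reward signal converts stored traces into weight
#' changes, and [epoch_housekeeping()] applies homeostatic scaling. The food
#' acquisition rate is tracked as an exponential moving average per move
#' (smoothing constant `ema_alpha`, about a 500-move memory).
#'
#' @param config A [network_config()] object; mechanism switches there drive
#'   the ablation experiments, and `config$synapse$release_cv` the noise
#'   sweeps. `inhibition_in = NULL` resolves to on for `task = "single"` and
#'   off for `task = "pairs"`.
#' @param n_epochs Number of movement cycles.
#' @param seed Integer seed (controls build, environment, noise, decisions).
#' @param task `"single"` (any food rewarded) or `"pairs"` (horizontal pairs
#'   rewarded, vertical pairs punished).
#' @param ema_alpha Smoothing constant of the acquisition-rate EMA (0.002).
#' @param world Optionally a prebuilt [init_world()] object.
#' @param net Optionally a prebuilt [build_network()] object.
#' @return An object of class `forage_run`: a list with `metrics` (a data
#'   frame with one row per epoch: outcome codes, chosen direction, flags,
#'   spike counts, acquisition EMA), the final `net`, `world`, and `task`.
#' @export
train <- function(config = network_config(), n_epochs = 1000L, seed = 1L,
                  task = c("single", "pairs"), ema_alpha = 0.002,
                  world = NULL, net = NULL) {
  task <- match.arg(task)
  if (is.null(config$inhibition_in)) {
    config$inhibition_in <- (task == "single")
  }
  if (is.null(config$w_max_in_factor)) {
    config$w_max_in_factor <- if (task == "single") 1.5 else 0.6
  }
  if (is.null(net)) net <- build_network(config, seed = seed)
  set.seed(seed + 1L)
  if (is.null(world)) world <- init_world(task)
  policy <- decision_policy(task)
  prev_dir <- sample.int(8L, 1L)

  outcome_code <- c(none = 0L, food = 1L, good_food = 2L, bad_food = 3L)
  mt <- list(outcome = integer(n_epochs), direction = integer(n_epochs),
             random = logical(n_epochs), tie = logical(n_epochs),
             zero = logical(n_epochs), hid_spikes = integer(n_epochs),
             out_spikes = integer(n_epochs), out_half = integer(n_epochs),
             ema = numeric(n_epochs))
  ema <- 0

  for (e in seq_len(n_epochs)) {
    stim <- visual_field(world)
    step <- run_epoch(net, stim)
    net <- step$net
    rec <- step$record

    d <- decide(rec$half_out, policy, prev_dir)
    mv <- apply_move(world, d$direction)
    world <- mv$world
    got <- mv$outcome != "none"

    net <- reward_network(net, reward_for(mv$outcome, task))
    net <- epoch_housekeeping(net, rec$counts)
    policy_step(policy, got)
    prev_dir <- d$direction

    ema <- ema * (1 - ema_alpha) + ema_alpha * as.numeric(got)
    mt$outcome[e] <- outcome_code[[mv$outcome]]
    mt$direction[e] <- d$direction
    mt$random[e] <- d$random
    mt$tie[e] <- d$tie
    mt$zero[e] <- d$zero
    mt$hid_spikes[e] <- rec$hid_spikes
    mt$out_spikes[e] <- rec$out_spikes
    mt$out_half[e] <- sum(rec$half_out)
    mt$ema[e] <- ema
  }
  structure(list(metrics = as.data.frame(mt), net = net, world = world,
                 task = task, seed = seed, ema_alpha = ema_alpha),
            class = "forage_run")
}

#' @export
print.forage_run <- function(x, ...) {
  n <- nrow(x$metrics)
  cat("<forage_run>", x$task, "task,", n, "epochs\n")
  cat("  final acquisition EMA:",
      sprintf("%.1f%%", 100 * x$metrics$ema[n]), "\n")
  if (x$task == "pairs") {
    cat("  good-food fraction (last 2000 moves):",
        sprintf("%.1f%%", 100 * discrimination_accuracy(x)), "\n")
  }
  invisible(x)
}

#' Tie and zero-response counters
#'
#' Counts the epochs whose movement decision involved a tie between output
#' neurons with nonzero spike counts, and the epochs in which no direction
#' cell fired at all (the agent kept its previous direction). Random-override
#' epochs are not counted in either.
#'
#' @param run A [train()] result (or its `metrics` data frame).
#' @return A named integer vector with `ties` and `zeros`.
#' @export
measure_ties_and_zeros <- function(run) {
  m <- if (inherits(run, "forage_run")) run$metrics else run
  c(ties = sum(m$tie), zeros = sum(m$zero))
}

#' Discrimination accuracy on the pattern task
#'
#' Fraction of rewarded ("good", horizontal-pair) food among all food acquired
#' over the trailing `window` moves.
#'
#' @param run A [train()] result from the pairs task.
#' @param window Number of trailing moves (default 2000).
#' @return The good-food fraction (NaN if no food was acquired in the window).
#' @export
discrimination_accuracy <- function(run, window = 2000L) {
  m <- run$metrics
  tail_idx <- seq.int(max(1L, nrow(m) - window + 1L), nrow(m))
  good <- sum(m$outcome[tail_idx] == 2L)
  bad <- sum(m$outcome[tail_idx] == 3L)
  good / (good + bad)
}

#' Coefficient of variation of per-epoch layer activity
#'
#' Standard deviation over mean of the per-epoch spike counts of a layer,
#' the statistic that diagnoses loss of feed-forward inhibition (layers not
#' receiving inhibition show far greater variance in their activity per
#' epoch).
#'
#' @param run A [train()] result.
#' @param layer `"hidden"` or `"output"`.
#' @param discard Initial fraction of epochs to discard as transient
#'   (default 0.2).
#' @return The coefficient of variation.
#' @export
activity_cv <- function(run, layer = c("output", "hidden"), discard = 0.2) {
  layer <- match.arg(layer)
  x <- if (layer == "output") run$metrics$out_spikes else
    run$metrics$hid_spikes
  x <- x[-seq_len(floor(length(x) * discard))]
  stats::sd(x) / mean(x)
}
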