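#' One step of the random-walk baseline
#'
#' With 98% probability the agent keeps its previous direction; otherwise it
#' turns 45 degrees left or right (1% each). The first step (no previous
#' direction) is uniform.
#'
#' @param prev_direction Previous direction 1..8, or `NA` on the first step.
#' @return A direction code 1..8.
#' @export
random_walk_step <- function(prev_direction = NA) {
  if (is.na(prev_direction)) return(sample.int(8L, 1L))
  u <- stats::runif(1)
  if (u < 0.98) return(as.integer(prev_direction))
  pos <- match(prev_direction, COMPASS_ORDER)
  turn <- if (u < 0.99) -1L else 1L
  COMPASS_ORDER[((pos - 1L + turn) %% 8L) + 1L]
}

field_positions <- function(field) {
  idx <- which(field) - 1L
  cbind(dr = idx %/% 7L - 3L, dc = idx %% 7L - 3L)
}

dir_from_offset <- function(dr, dc) {
  sr <- sign(dr) + 2L
  sc <- sign(dc) + 2L
  lut <- matrix(c(1L, 2L, 3L, 4L, NA, 5L, 6L, 7L, 8L), 3, 3, byrow = TRUE)
  lut[sr, sc]
}

#' One step of the adjacent-grab baseline
#'
#' Moves onto a food particle if one is directly adjacent (uniformly among
#' adjacent particles); otherwise behaves as the random walk.
#'
#' @param field Logical visual field of length 49 (see [visual_field()]).
#' @param prev_direction Previous direction (for the random-walk fallback).
#' @return A direction code 1..8.
#' @export
adjacent_grab_step <- function(field, prev_direction = NA) {
  pos <- field_positions(field)
  adj <- pos[pmax(abs(pos[, 1]), abs(pos[, 2])) == 1L, , drop = FALSE]
  if (nrow(adj) == 0L) return(random_walk_step(prev_direction))
  k <- if (nrow(adj) > 1L) sample.int(nrow(adj), 1L) else 1L
  dir_from_offset(adj[k, 1], adj[k, 2])
}

#' One step of the nearest-food baseline
#'
#' Moves one cell toward the closest food particle in the visual field
#' (Chebyshev distance, consistent with 8-directional movement; ties broken
#' uniformly); falls back to the random walk when no food is visible.
#'
#' @inheritParams adjacent_grab_step
#' @return A direction code 1..8.
#' @export
nearest_food_step <- function(field, prev_direction = NA) {
  pos <- field_positions(field)
  if (nrow(pos) == 0L) return(random_walk_step(prev_direction))
  d <- pmax(abs(pos[, 1]), abs(pos[, 2]))
  near <- which(d == min(d))
  k <- if (length(near) > 1L) near[sample.int(length(near), 1L)] else near
  dir_from_offset(pos[k, 1], pos[k, 2])
}

#' One step of the exhaustive 5-move-lookahead baseline
#'
#' Enumerates every 5-move sequence confined to the 7x7 visual field, scores
#' each by the food it would collect (food consumed earlier in the rollout is
#' not re-counted), prefers sequences acquiring more food, breaks ties in
#' favor of earlier acquisition, breaks remaining ties uniformly at random,
#' and takes the first move of the winning sequence. With no food visible it
#' behaves as the random walk.
#'
#' @inheritParams adjacent_grab_step
#' @return A direction code 1..8.
#' @export
exhaustive5_step <- function(field, prev_direction = NA) {
  if (!any(field)) return(random_walk_step(prev_direction))
  cand <- exhaustive5_cpp(as.integer(field))
  if (length(cand) > 1L) cand[sample.int(length(cand), 1L)] else cand
}

#' Run a heuristic baseline agent
#'
#' Drives one of the four reference agents through the single-food environment
#' and measures its food acquisition rate per move.
#'
#' @param kind One of `"random_walk"`, `"adjacent_grab"`, `"nearest_food"`,
#'   `"exhaustive5"`.
#' @param n_moves Number of moves.
#' @param seed Integer seed.
#' @param density Food density (default 0.10).
#' @param world Optionally a prebuilt world.
#' @return A list with `rate` (food per move), `acquired`, `n_moves`, `kind`.
#' @export
run_heuristic <- function(kind = c("random_walk", "adjacent_grab",
                                   "nearest_food", "exhaustive5"),
                          n_moves = 10000L, seed = 1L, density = 0.10,
                          world = NULL) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (is.null(world)) world <- init_world("single", density = density)
  prev <- NA
  acquired <- 0L
  for (k in seq_len(n_moves)) {
    dir <- switch(kind,
      random_walk = random_walk_step(prev),
      adjacent_grab = adjacent_grab_step(visual_field(world), prev),
      nearest_food = nearest_food_step(visual_field(world), prev),
      exhaustive5 = exhaustive5_step(visual_field(world), prev))
    mv <- apply_move(world, dir)
    world <- mv$world
    if (mv$outcome != "none") acquired <- acquired + 1L
    prev <- dir
  }
  list(rate = acquired / n_moves, acquired = acquired, n_moves = n_moves,
       kind = kind)
}
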