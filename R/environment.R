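# Direction conventions shared by the environment, the agent and the network
# output layer. Directions 1..8 are the 3x3 neighborhood in row-major order
# with the center skipped; rows grow downward ("north" = -1 row offset).
DIR_OFFSETS <- matrix(c(-1L, -1L, -1L, 0L, -1L, 1L,
                        0L, -1L, 0L, 1L,
                        1L, -1L, 1L, 0L, 1L, 1L),
                      ncol = 2, byrow = TRUE,
                      dimnames = list(c("NW", "N", "NE", "W", "E",
                                        "SW", "S", "SE"), c("dr", "dc")))
# Directions in compass order (for 45-degree turns of the random-walk agent).
COMPASS_ORDER <- c(2L, 3L, 5L, 8L, 7L, 6L, 4L, 1L) # N NE E SE S SW W NW

#' Direction codes and offsets
#'
#' The eight movement directions are numbered 1..8 in the row-major order of
#' the 3x3 output layer with the center cell skipped (1 = NW, 2 = N, 3 = NE,
#' 4 = W, 5 = E, 6 = SW, 7 = S, 8 = SE).
#'
#' @return An 8-by-2 integer matrix of (row, column) offsets, with direction
#'   names as row names.
#' @export
direction_offsets <- function() DIR_OFFSETS

wrap_pos <- function(x, n) ((x - 1L) %% n) + 1L

#' Create a foraging world
#'
#' A toroidal `n`-by-`n` grid of food particles. In the `single` task each
#' food particle occupies one cell, at a fixed density (10% = 250 particles on
#' the default 50x50 grid), and is respawned at a random empty cell when
#' consumed. In the `pairs` task food comes in two-cell patterns -- horizontal
#' pairs (rewarded) and vertical pairs (punished) in equal numbers -- placed
#' so that no pattern touches another in the 8-neighborhood; the rewarded
#' particle density is 25% of the single-task density. The agent starts at a
#' random empty cell.
#'
#' @param task `"single"` or `"pairs"`.
#' @param density Food density for the single task (default 0.10); for the
#'   pairs task the rewarded (horizontal) particle density is `density / 4`
#'   and the same number of vertical pairs is added.
#' @param seed Optional integer seed (uses the current RNG stream if `NULL`).
#' @param n Grid side length (default 50).
#' @return An object of class `forage_world`.
#' @export
init_world <- function(task = c("single", "pairs"), density = 0.10,
                       seed = NULL, n = 50) {
  task <- match.arg(task)
  if (!is.null(seed)) set.seed(seed)
  grid <- matrix(0L, n, n)
  pat_id <- matrix(0L, n, n)
  world <- structure(list(grid = grid, pat_id = pat_id, pats = list(),
                          n = as.integer(n), task = task, density = density,
                          agent = c(1L, 1L), heading = sample.int(8L, 1L)),
                     class = "forage_world")
  if (task == "single") {
    n_food <- round(density * n * n)
    if (n_food > 0) {
      cells <- sample.int(n * n, n_food)
      world$grid[cells] <- 1L
    }
  } else {
    n_pairs <- floor(density / 4 * n * n / 2) # rewarded particles / 2 cells
    for (k in seq_len(n_pairs)) world <- place_pair(world, "H")
    for (k in seq_len(n_pairs)) world <- place_pair(world, "V")
  }
  empty <- which(world$grid == 0L)
  pos <- empty[sample.int(length(empty), 1L)]
  world$agent <- c(row(world$grid)[pos], col(world$grid)[pos])
  world
}

pair_cells <- function(r, c, type, n) {
  if (type == "H") rbind(c(r, c), c(r, wrap_pos(c + 1L, n)))
  else rbind(c(r, c), c(wrap_pos(r + 1L, n), c))
}

neighborhood_clear <- function(world, cells, skip_id = 0L) {
  n <- world$n
  for (k in seq_len(nrow(cells))) {
    for (dr in -1:1) for (dc in -1:1) {
      r <- wrap_pos(cells[k, 1] + dr, n)
      c <- wrap_pos(cells[k, 2] + dc, n)
      if (world$grid[r, c] != 0L && world$pat_id[r, c] != skip_id) {
        return(FALSE)
      }
    }
  }
  TRUE
}

place_pair <- function(world, type, avoid_agent = FALSE, reuse_id = NULL,
                       max_tries = 10000L) {
  n <- world$n
  for (try in seq_len(max_tries)) {
    r <- sample.int(n, 1L)
    c <- sample.int(n, 1L)
    cells <- pair_cells(r, c, type, n)
    if (avoid_agent &&
        any(cells[, 1] == world$agent[1] & cells[, 2] == world$agent[2])) {
      next
    }
    if (!neighborhood_clear(world, cells)) next
    id <- if (is.null(reuse_id)) length(world$pats) + 1L else reuse_id
    for (k in 1:2) {
      world$grid[cells[k, 1], cells[k, 2]] <- if (type == "H") 2L else 3L
      world$pat_id[cells[k, 1], cells[k, 2]] <- id
    }
    world$pats[[id]] <- list(cells = cells, type = type)
    return(world)
  }
  stop("could not place a food pattern after ", max_tries, " tries")
}

#' The agent's 7x7 visual field
#'
#' Food presence in the 7-by-7 window centered on the agent, flattened
#' row-major (index 25 is the agent's own cell and is always `FALSE`: food at
#' the agent's location is consumed on arrival). The grid is toroidal, so the
#' window wraps at the edges.
#'
#' @param world A [init_world()] object.
#' @return A logical vector of length 49.
#' @export
visual_field <- function(world) {
  rows <- wrap_pos(world$agent[1] + (-3:3), world$n)
  cols <- wrap_pos(world$agent[2] + (-3:3), world$n)
  block <- world$grid[rows, cols] != 0L
  field <- as.vector(t(block))
  field[25] <- FALSE
  field
}

#' Move the agent and resolve food acquisition
#'
#' Displaces the agent one cell in the given direction (wrapping at the grid
#' edges). Landing on a single-task food particle consumes it and respawns one
#' particle at a random empty cell; landing on either cell of a food pair
#' removes both cells and respawns a fresh pair of the same orientation at a
#' random location obeying the non-adjacency constraint.
#'
#' @param world A [init_world()] object.
#' @param direction Direction code 1..8 (see [direction_offsets()]).
#' @return A list with the updated `world` and `outcome`: one of `"none"`,
#'   `"food"` (single task), `"good_food"` (horizontal pair), `"bad_food"`
#'   (vertical pair).
#' @export
apply_move <- function(world, direction) {
  stopifnot(direction %in% 1:8)
  off <- DIR_OFFSETS[direction, ]
  r <- wrap_pos(world$agent[1] + off[[1]], world$n)
  c <- wrap_pos(world$agent[2] + off[[2]], world$n)
  world$agent <- c(r, c)
  world$heading <- as.integer(direction)
  cell <- world$grid[r, c]
  if (cell == 0L) return(list(world = world, outcome = "none"))
  if (cell == 1L) {
    world$grid[r, c] <- 0L
    empty <- which(world$grid == 0L)
    empty <- empty[empty != (r + (c - 1L) * world$n)]
    world$grid[empty[sample.int(length(empty), 1L)]] <- 1L
    return(list(world = world, outcome = "food"))
  }
  id <- world$pat_id[r, c]
  pat <- world$pats[[id]]
  for (k in 1:2) {
    world$grid[pat$cells[k, 1], pat$cells[k, 2]] <- 0L
    world$pat_id[pat$cells[k, 1], pat$cells[k, 2]] <- 0L
  }
  world <- place_pair(world, pat$type, avoid_agent = TRUE, reuse_id = id)
  outcome <- if (pat$type == "H") "good_food" else "bad_food"
  list(world = world, outcome = outcome)
}

#' Validate the pairs-task invariants of a world
#'
#' Checks that every occupied cell belongs to exactly one two-cell pattern of
#' the declared orientation and that no pattern touches another pattern in the
#' 8-neighborhood.
#'
#' @param world A pairs-task world.
#' @return `TRUE` invisibly; stops with an error describing the violation.
#' @export
validate_pairs <- function(world) {
  occ <- which(world$grid != 0L, arr.ind = TRUE)
  ids <- world$pat_id[world$grid != 0L]
  if (any(ids == 0L)) stop("occupied cell without a pattern id")
  for (id in unique(ids)) {
    cells <- which(world$pat_id == id & world$grid != 0L, arr.ind = TRUE)
    if (nrow(cells) != 2L) stop("pattern ", id, " does not have 2 cells")
    type <- world$grid[cells[1, 1], cells[1, 2]]
    dr <- abs(cells[1, 1] - cells[2, 1])
    dc <- abs(cells[1, 2] - cells[2, 2])
    dr <- min(dr, world$n - dr)
    dc <- min(dc, world$n - dc)
    ok <- if (type == 2L) (dr == 0L && dc == 1L) else (dr == 1L && dc == 0L)
    if (!ok) stop("pattern ", id, " is not a contiguous pair")
  }
  for (k in seq_len(nrow(occ))) {
    id <- world$pat_id[occ[k, 1], occ[k, 2]]
    for (dr in -1:1) for (dc in -1:1) {
      r <- wrap_pos(occ[k, 1] + dr, world$n)
      c <- wrap_pos(occ[k, 2] + dc, world$n)
      if (world$grid[r, c] != 0L && world$pat_id[r, c] != id) {
        stop("patterns ", id, " and ", world$pat_id[r, c], " are adjacent")
      }
    }
  }
  invisible(TRUE)
}

#' Serialize a world to its plain-text grid format
#'
#' One line per grid row: `.` empty, `o` single food, `H` horizontal-pair
#' cell, `V` vertical-pair cell, `@` the agent.
#'
#' @param world A world object.
#' @return A character vector of lines.
#' @export
format_world <- function(world) {
  chars <- c("." , "o", "H", "V")[world$grid + 1L]
  m <- matrix(chars, world$n, world$n)
  m[world$agent[1], world$agent[2]] <- "@"
  apply(m, 1, paste0, collapse = "")
}

#' Parse a world from its plain-text grid format
#'
#' Inverse of [format_world()]; used to build small hand-checkable fixture
#' worlds. `H` cells must form horizontal pairs, `V` cells vertical pairs, and
#' patterns must not touch (validated via [validate_pairs()] when patterns are
#' present). If no `@` marker is present the agent is placed at the grid
#' center.
#'
#' @param lines Character vector of grid rows.
#' @param task Task label; inferred from the content if missing.
#' @return A `forage_world` object.
#' @export
read_world <- function(lines, task = NULL) {
  n_r <- length(lines)
  stopifnot(n_r > 0, all(nchar(lines) == nchar(lines[1])))
  n_c <- nchar(lines[1])
  if (n_r != n_c) stop("world grids must be square")
  m <- do.call(rbind, strsplit(lines, ""))
  grid <- matrix(0L, n_r, n_c)
  grid[m == "o"] <- 1L
  grid[m == "H"] <- 2L
  grid[m == "V"] <- 3L
  agent <- which(m == "@", arr.ind = TRUE)
  if (nrow(agent) > 1) stop("more than one agent marker")
  if (nrow(agent) == 0) agent <- matrix(ceiling(c(n_r, n_c) / 2), 1)
  if (is.null(task)) task <- if (any(grid > 1L)) "pairs" else "single"
  world <- structure(list(grid = grid, pat_id = matrix(0L, n_r, n_c),
                          pats = list(), n = as.integer(n_r), task = task,
                          density = mean(grid != 0L),
                          agent = as.integer(agent[1, ]), heading = 5L),
                     class = "forage_world")
  world <- index_patterns(world)
  if (any(grid > 1L)) validate_pairs(world)
  world
}

# Reconstruct pattern ids for a parsed pairs world.
index_patterns <- function(world) {
  n <- world$n
  for (type_code in c(2L, 3L)) {
    type <- if (type_code == 2L) "H" else "V"
    cells <- which(world$grid == type_code & world$pat_id == 0L,
                   arr.ind = TRUE)
    for (k in seq_len(nrow(cells))) {
      r <- cells[k, 1]; c <- cells[k, 2]
      if (world$pat_id[r, c] != 0L) next
      r2 <- if (type == "V") wrap_pos(r + 1L, n) else r
      c2 <- if (type == "H") wrap_pos(c + 1L, n) else c
      if (world$grid[r2, c2] != type_code || world$pat_id[r2, c2] != 0L) {
        # the cell may be the trailing member of a pair wrapping the torus
        r2 <- if (type == "V") wrap_pos(r - 1L, n) else r
        c2 <- if (type == "H") wrap_pos(c - 1L, n) else c
        if (world$grid[r2, c2] != type_code || world$pat_id[r2, c2] != 0L) {
          stop("unpaired ", type, " cell at (", r, ",", c, ")")
        }
      }
      id <- length(world$pats) + 1L
      world$pat_id[r, c] <- id
      world$pat_id[r2, c2] <- id
      world$pats[[id]] <- list(cells = rbind(c(r, c), c(r2, c2)), type = type)
    }
  }
  world
}

#' Count occupied food cells
#' @param world A world object.
#' @return Integer count of occupied grid cells.
#' @export
food_count <- function(world) sum(world$grid != 0L)
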