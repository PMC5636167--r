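test_that("single-task worlds hold exactly density * n^2 food cells", {
  w <- init_world("single", density = 0.10, seed = 1)
  expect_equal(food_count(w), 250)
  w0 <- init_world("single", density = 0, seed = 1)
  expect_equal(food_count(w0), 0)
})

test_that("occupancy is conserved across moves (single task)", {
  set.seed(2)
  w <- init_world("single", seed = 2)
  got <- 0
  for (k in 1:300) {
    mv <- apply_move(w, sample.int(8, 1))
    w <- mv$world
    expect_equal(food_count(w), 250)
    if (mv$outcome == "food") got <- got + 1
    expect_false(w$grid[w$agent[1], w$agent[2]] != 0)
  }
  expect_gt(got, 0) # the walk does encounter food
})

test_that("pairs worlds are disjoint non-adjacent 2-cell patterns", {
  w <- init_world("pairs", seed = 3)
  expect_equal(food_count(w), 124) # 31 horizontal + 31 vertical pairs
  expect_equal(sum(w$grid == 2L), 62)
  expect_equal(sum(w$grid == 3L), 62)
  expect_true(validate_pairs(w))
  set.seed(4)
  for (k in 1:200) {
    mv <- apply_move(w, sample.int(8, 1))
    w <- mv$world
  }
  expect_true(validate_pairs(w))
  expect_equal(food_count(w), 124)
})

test_that("consuming either cell of a pair removes both and respawns", {
  w <- init_world("pairs", seed = 5)
  # park the agent next to a horizontal pair and step onto it
  pat <- NULL
  for (p in w$pats) if (p$type == "H") { pat <- p; break }
  cell <- pat$cells[1, ]
  w$agent <- c(((cell[1] - 2) %% w$n) + 1, cell[2]) # one row up
  mv <- apply_move(w, 7) # move south onto the pattern
  expect_equal(mv$outcome, "good_food")
  w2 <- mv$world
  expect_equal(w2$grid[pat$cells[1, 1], pat$cells[1, 2]], 0L)
  expect_equal(w2$grid[pat$cells[2, 1], pat$cells[2, 2]], 0L)
  expect_equal(food_count(w2), 124)
  expect_true(validate_pairs(w2))
})

test_that("visual field sees the 7x7 window, center always empty", {
  empty <- make_tiny_world(paste(rep(paste(rep(".", 9), collapse = ""), 9),
                                 collapse = "\n"))
  expect_false(any(visual_field(empty)))

  lay <- rep(strrep(".", 9), 9)
  lay[5] <- "....@...."
  lay[4] <- ".....o..." # one step NE of the agent
  w <- make_tiny_world(paste(lay, collapse = "\n"))
  f <- visual_field(w)
  expect_equal(sum(f), 1)
  expect_true(f[(2 * 7) + 5]) # dr=-1, dc=+1 -> row-major index 19
  expect_false(f[25])
})

test_that("visual field is translation-equivariant on the torus", {
  set.seed(6)
  w <- init_world("single", seed = 6)
  f0 <- visual_field(w)
  # shift agent and every food cell by the same offset
  for (shift in list(c(3, -7), c(25, 25), c(-1, 49))) {
    w2 <- w
    idx <- which(w$grid != 0L, arr.ind = TRUE)
    w2$grid <- matrix(0L, w$n, w$n)
    r2 <- ((idx[, 1] - 1 + shift[1]) %% w$n) + 1
    c2 <- ((idx[, 2] - 1 + shift[2]) %% w$n) + 1
    w2$grid[cbind(r2, c2)] <- w$grid[idx]
    w2$agent <- c(((w$agent[1] - 1 + shift[1]) %% w$n) + 1,
                  ((w$agent[2] - 1 + shift[2]) %% w$n) + 1)
    expect_identical(visual_field(w2), f0)
  }
})

test_that("world text round-trips and malformed layouts are rejected", {
  w <- init_world("pairs", seed = 7)
  txt <- format_world(w)
  w2 <- read_world(txt)
  expect_identical(w2$grid[w$agent[1], w$agent[2]], 0L) # agent cell shown as @
  g <- w$grid
  g[w$agent[1], w$agent[2]] <- 0L
  expect_identical(w2$grid, g)
  expect_identical(w2$agent, w$agent)
  expect_true(validate_pairs(w2))

  bad <- c("HH.VV",
           ".....",
           ".....",
           ".....",
           ".....")
  expect_error(make_tiny_world(bad), "adjacent|unpaired")
})

test_that("moves wrap on the torus", {
  lay <- rep(strrep(".", 9), 9)
  lay[1] <- "@........"
  w <- make_tiny_world(paste(lay, collapse = "\n"))
  mv <- apply_move(w, 1) # NW from the corner wraps to the opposite corner
  expect_equal(mv$world$agent, c(9L, 9L))
})
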