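# Programmatic fixtures shared across test files.

# One full 384-well plate as a wells tibble: 352 samples, 16 DMSO
# negative controls (col 0), 16 TSA positive controls (col 1).
make_plate_wells <- function(plate_id = "P1", arm = "V1", seed = 42) {
  set.seed(seed)
  grid <- expand.grid(row = 0:15, col = 0:23)
  role <- ifelse(grid$col == 0, "neg_control",
                 ifelse(grid$col == 1, "pos_control", "sample"))
  tibble::tibble(
    arm = arm, plate_id = plate_id,
    row = grid$row, col = grid$col,
    compound_id = ifelse(role == "sample",
                         sprintf("c%03d", seq_len(nrow(grid))), NA),
    role = role,
    nluc = stats::runif(nrow(grid), 50, 150),
    fluc = stats::runif(nrow(grid), 50, 150)
  )
}

# Random matrix with purely additive structure: overall + row + col.
make_additive_matrix <- function(nr, nc) {
  overall <- stats::rnorm(1, 10)
  outer(stats::rnorm(nr), stats::rnorm(nc), `+`) + overall
}

# Small, fast simulation configuration for unit tests.
small_config <- function(...) {
  do.call(simulation_config,
          utils::modifyList(list(seed = 7, n_plates_per_arm = 2L),
                            list(...)))
}

# Long per-well score table in the shape normalize_screen() emits, built
# directly from given per-compound (x, y) pairs (one well per arm).
make_score_table <- function(compound_id, x, y) {
  dplyr::bind_rows(
    tibble::tibble(arm = "V1", plate_id = "P1", row = 0L,
                   col = seq_along(x) - 1L, compound_id = compound_id,
                   role = "sample", concentration = NA_real_,
                   ratio = NA_real_, bscore = x, converged = TRUE),
    tibble::tibble(arm = "V2", plate_id = "P1", row = 0L,
                   col = seq_along(y) - 1L, compound_id = compound_id,
                   role = "sample", concentration = NA_real_,
                   ratio = NA_real_, bscore = y, converged = TRUE)
  )
}
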