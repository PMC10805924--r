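#' Build one plateau/transition cycle of an ACVS schedule
#'
#' A cycle starts with a plateau on which all distractors share one shape
#' state, runs through a transition in which one distractor per trial
#' switches to the other shape, reaches the opposite plateau, and
#' transitions back. With the default lengths a cycle spans
#' `2 * (plateau_len + transition_len) = 32` trials.
#'
#' @param starting_plateau `"star"` or `"pentagon"`: the shape all
#'   distractors share on the first plateau. On a star plateau every
#'   distractor is a star, so the pentagon target is the unique shape.
#' @param plateau_len Number of trials per plateau (default 3).
#' @param transition_len Number of trials per transition (default 13).
#' @param n_distractors Total distractors per display (default 14).
#' @return A data.frame with one row per trial: `phase` (`"P1"`..,
#'   `"T1"`..), `n_star`, `n_pentagon` (distractor counts), and `plateau`
#'   (`"star"`, `"pentagon"`, or `NA` on transitions).
#' @examples
#' cyc <- build_cycle("star")
#' nrow(cyc)           # 32
#' cyc$n_pentagon[1:3] # 0 0 0: star plateau
#' @export
build_cycle <- function(starting_plateau = c("star", "pentagon"),
                        plateau_len = 3, transition_len = 13,
                        n_distractors = 14) {
  starting_plateau <- match.arg(starting_plateau)
  if (plateau_len < 1 || transition_len < 1)
    stop("plateau_len and transition_len must be >= 1")
  if (n_distractors < transition_len)
    stop("n_distractors must be >= transition_len (one distractor switches per transition trial)")

  p_lab <- paste0("P", seq_len(plateau_len))
  t_lab <- paste0("T", seq_len(transition_len))
  # pentagon-distractor count along one cycle, star start:
  # plateau at 0, rise by 1 per trial, plateau at n_distractors, fall back
  up <- seq_len(transition_len)
  n_pent <- c(rep(0L, plateau_len), up,
              rep(n_distractors, plateau_len), rev(seq_len(transition_len)))
  if (starting_plateau == "pentagon") n_pent <- n_distractors - n_pent
  phase <- c(p_lab, t_lab, p_lab, t_lab)
  plateau <- rep(NA_character_, length(phase))
  plateau[n_pent == 0] <- "star"
  plateau[n_pent == n_distractors] <- "pentagon"
  data.frame(phase = phase,
             n_star = n_distractors - n_pent,
             n_pentagon = n_pent,
             plateau = plateau,
             stringsAsFactors = FALSE)
}

#' Build a full experimental session schedule
#'
#' A session is a sequence of blocks; each block concatenates a number of
#' cycles and appends a final plateau so that the block both starts and
#' ends on its starting-plateau type. The starting plateau alternates
#' between consecutive blocks. With the defaults, a practice block has
#' `1 * 32 + 3 = 35` trials and a main block `3 * 32 + 3 = 99` trials, so a
#' session with 2 practice and 4 main blocks has 466 trials and one with
#' 2 practice and 8 main blocks has 862.
#'
#' @param n_practice,n_main Number of practice / main blocks.
#' @param cycles_per_practice,cycles_per_main Cycles per block type.
#' @param first_block_start Starting plateau of the first block.
#' @param plateau_len,transition_len,n_distractors Passed to [build_cycle()].
#' @return A data.frame with one row per trial: `block`, `block_type`
#'   (`"practice"`/`"main"`), `block_start`, `trial` (1-based index within
#'   block), `cycle_pos` (position within the repeating cycle pattern),
#'   plus the columns of [build_cycle()].
#' @export
build_session <- function(n_practice = 2, n_main = 4,
                          cycles_per_practice = 1, cycles_per_main = 3,
                          first_block_start = c("star", "pentagon"),
                          plateau_len = 3, transition_len = 13,
                          n_distractors = 14) {
  first_block_start <- match.arg(first_block_start)
  if (n_practice < 0 || n_main < 0) stop("block counts must be >= 0")
  n_blocks <- n_practice + n_main
  if (n_blocks == 0) {
    out <- build_cycle(first_block_start, plateau_len, transition_len,
                       n_distractors)[0, ]
    out <- cbind(block = integer(0), block_type = character(0),
                 block_start = character(0), trial = integer(0),
                 cycle_pos = integer(0), out)
    return(out)
  }
  starts <- rep(c(first_block_start,
                  setdiff(c("star", "pentagon"), first_block_start)),
                length.out = n_blocks)
  types <- c(rep("practice", n_practice), rep("main", n_main))
  n_cycles <- ifelse(types == "practice", cycles_per_practice, cycles_per_main)
  cyc_len <- 2L * (plateau_len + transition_len)

  blocks <- lapply(seq_len(n_blocks), function(b) {
    cyc <- build_cycle(starts[b], plateau_len, transition_len, n_distractors)
    trials <- do.call(rbind, rep(list(cyc), n_cycles[b]))
    trials <- rbind(trials, cyc[seq_len(plateau_len), ])  # final plateau
    n <- nrow(trials)
    cbind(block = b, block_type = types[b], block_start = starts[b],
          trial = seq_len(n),
          cycle_pos = ((seq_len(n) - 1L) %% cyc_len) + 1L,
          trials)
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

# VCS-style angle labels for the four shape variants per class (stars at
# one pole of the circular shape space, pentagons at the other, 12 degrees
# apart). Labels only; no bitmaps are rendered.
.variant_angles <- list(star = c(342L, 354L, 6L, 18L),
                        pentagon = c(162L, 174L, 186L, 198L))

#' Render a concrete search display for one schedule trial
#'
#' Places 16 items (14 black distractors, one blue star target, one blue
#' pentagon target) on distinct cells of an imaginary 5 x 7 grid. Target
#' digits are two distinct random digits from 1-4; distractor digits are
#' random digits from 5-8. Pixel centers are the cell centers of a
#' `canvas` (width, height) with the origin at the top-left, used for
#' fixation-to-item assignment.
#'
#' @param schedule_trial One row of a schedule data.frame (needs `n_star`
#'   and `n_pentagon`).
#' @param seed Integer seed; the same seed reproduces the same display.
#' @param canvas Pixel canvas as `c(width, height)`.
#' @return A data.frame with 16 rows: `item`, `grid_row` (0-4), `grid_col`
#'   (0-6), `role` (`"target"`/`"distractor"`), `shape`, `variant`
#'   (angle label), `color`, `digit`, `x_px`, `y_px`.
#' @export
render_display <- function(schedule_trial, seed = NULL,
                           canvas = c(1920, 1080)) {
  n_star <- as.integer(schedule_trial$n_star[1])
  n_pent <- as.integer(schedule_trial$n_pentagon[1])
  if (is.na(n_star) || is.na(n_pent) || n_star < 0 || n_pent < 0)
    stop("schedule_trial must carry non-negative n_star and n_pentagon")
  if (!is.null(seed)) set.seed(seed)
  n_items <- n_star + n_pent + 2L
  n_rows <- 5L; n_cols <- 7L
  if (n_items > n_rows * n_cols) stop("more items than grid cells")

  cells <- sample.int(n_rows * n_cols, n_items)
  grid_row <- (cells - 1L) %/% n_cols
  grid_col <- (cells - 1L) %% n_cols
  shape <- c("star", "pentagon",
             rep("star", n_star), rep("pentagon", n_pent))
  role <- c("target", "target", rep("distractor", n_star + n_pent))
  variant <- vapply(shape, function(s) sample(.variant_angles[[s]], 1L),
                    integer(1))
  target_digits <- sample(1:4, 2)
  digit <- c(target_digits,
             sample(5:8, n_star + n_pent, replace = TRUE))
  data.frame(item = seq_len(n_items),
             grid_row = grid_row, grid_col = grid_col,
             role = role, shape = shape, variant = variant,
             color = ifelse(role == "target", "blue", "black"),
             digit = digit,
             x_px = (grid_col + 0.5) * canvas[1] / n_cols,
             y_px = (grid_row + 0.5) * canvas[2] / n_rows,
             stringsAsFactors = FALSE)
}
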