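.trial_key <- function(d) paste(d$participant, d$block, d$trial, sep = ".")

#' Assign fixations to the nearest display item
#'
#' Each fixation is assigned to the item whose pixel center is closest
#' (Euclidean distance). Exact ties go to the lowest item index and are
#' flagged; fixations outside the canvas are still assigned to the
#' nearest item and flagged.
#'
#' @param fixations Data.frame with `x_px`, `y_px` (one row per fixation,
#'   any additional columns are preserved).
#' @param display A display data.frame from [render_display()].
#' @param canvas Canvas size `c(width, height)` used for the off-canvas
#'   flag.
#' @return `fixations` with added columns `item`, `shape`, `role`,
#'   `tie` and `off_canvas`.
#' @export
assign_fixations <- function(fixations, display, canvas = c(1920, 1080)) {
  stopifnot(all(c("x_px", "y_px") %in% names(fixations)))
  if (nrow(fixations) == 0) {
    fixations$item <- integer(0); fixations$shape <- character(0)
    fixations$role <- character(0); fixations$tie <- logical(0)
    fixations$off_canvas <- logical(0)
    return(fixations)
  }
  dx <- outer(fixations$x_px, display$x_px, "-")
  dy <- outer(fixations$y_px, display$y_px, "-")
  d2 <- dx^2 + dy^2
  idx <- apply(d2, 1, which.min)         # which.min takes the first minimum
  tie <- vapply(seq_len(nrow(d2)),
                function(i) sum(d2[i, ] == d2[i, idx[i]]) > 1, logical(1))
  fixations$item <- display$item[idx]
  fixations$shape <- display$shape[idx]
  fixations$role <- display$role[idx]
  fixations$tie <- tie
  fixations$off_canvas <- fixations$x_px < 0 | fixations$x_px > canvas[1] |
    fixations$y_px < 0 | fixations$y_px > canvas[2]
  fixations
}

#' Assign a multi-trial fixation table against its displays
#'
#' Convenience wrapper over [assign_fixations()] for tables spanning many
#' trials; fixations and display items are matched on
#' `participant`/`block`/`trial`.
#'
#' @param fixations Fixation data.frame with `participant`, `block`,
#'   `trial`, `x_px`, `y_px`.
#' @param displays Item data.frame (stacked [render_display()] outputs
#'   with `participant`, `block`, `trial` columns), as produced by
#'   [simulate_study()].
#' @return The assigned fixation table.
#' @export
assign_fixation_table <- function(fixations, displays) {
  fk <- .trial_key(fixations)
  parts <- lapply(split(seq_len(nrow(fixations)), fk), function(i) {
    disp <- displays[.trial_key(displays) == fk[i[1]], , drop = FALSE]
    if (nrow(disp) == 0) stop("no display found for trial ", fk[i[1]])
    assign_fixations(fixations[i, , drop = FALSE], disp)
  })
  out <- do.call(rbind, parts)
  out <- out[order(match(.trial_key(out), unique(fk)), out$fix_index), ]
  rownames(out) <- NULL
  out
}

.select_fix <- function(d, which) {
  switch(which,
         first = d[which.min(d$fix_index), , drop = FALSE],
         last = d[which.max(d$fix_index), , drop = FALSE],
         total = d)
}

#' Normalized fixation proportions per shape and cycle position
#'
#' For each trial the proportion of the selected fixations (first, last,
#' or all) landing on each shape class is divided by the number of
#' displayed items of that shape, equating chance levels across unequal
#' subsets (a uniformly random single fixation gives 1/16 = .0625 for
#' both shapes). Trial values are then averaged at each cycle position
#' within each starting-plateau condition.
#'
#' @param fixtab Assigned fixation table (see [assign_fixation_table()])
#'   with `fix_index` and `shape` columns.
#' @param trials Trial data.frame supplying `n_star`, `n_pentagon`,
#'   `cycle_pos` and `block_start` per trial.
#' @param which `"first"`, `"last"` or `"total"`.
#' @return Data.frame with `block_start`, `cycle_pos`, `shape`,
#'   `norm_prop` (mean normalized proportion), `se` and `n_trials`.
#' @export
normalized_shape_proportions <- function(fixtab, trials,
                                         which = c("first", "last", "total")) {
  which <- match.arg(which)
  tk <- .trial_key(trials)
  per_trial <- lapply(split(fixtab, .trial_key(fixtab)), function(d) {
    tr <- trials[tk == .trial_key(d)[1], , drop = FALSE]
    if (nrow(tr) == 0) return(NULL)
    sel <- .select_fix(d, which)
    counts <- c(star = tr$n_star + 1, pentagon = tr$n_pentagon + 1)
    vals <- vapply(c("star", "pentagon"), function(s) {
      if (counts[[s]] == 0) return(NA_real_)
      mean(sel$shape == s) / counts[[s]]
    }, numeric(1))
    data.frame(block_start = tr$block_start, cycle_pos = tr$cycle_pos,
               shape = c("star", "pentagon"), norm_prop = vals,
               stringsAsFactors = FALSE)
  })
  pt <- do.call(rbind, per_trial)
  if (is.null(pt) || nrow(pt) == 0) stop("no fixation/trial overlap")
  pt <- pt[!is.na(pt$norm_prop), , drop = FALSE]
  agg <- do.call(rbind, lapply(
    split(pt, list(pt$block_start, pt$cycle_pos, pt$shape), drop = TRUE),
    function(g) data.frame(block_start = g$block_start[1],
                           cycle_pos = g$cycle_pos[1], shape = g$shape[1],
                           norm_prop = mean(g$norm_prop),
                           se = stats::sd(g$norm_prop) / sqrt(nrow(g)),
                           n_trials = nrow(g),
                           stringsAsFactors = FALSE)))
  agg <- agg[order(agg$block_start, agg$cycle_pos, agg$shape), ]
  rownames(agg) <- NULL
  agg
}

#' Chosen- versus non-chosen-shape fixations on plateau trials
#'
#' Restricts to plateau trials and splits them by whether the
#' unique-shape target was eventually chosen. Within each class it
#' reports, per measure, the group mean of per-participant values:
#' the proportion of first fixations on items of the chosen target's
#' shape vs. the non-chosen shape, the same for last fixations, and the
#' mean number of fixations per trial on each shape. Differences
#' (chosen minus non-chosen) carry nonparametric bootstrap HDIs over
#' participants.
#'
#' @param fixtab Assigned fixation table.
#' @param trials Trial data.frame with `plateau`, `choice` and key
#'   columns.
#' @param n_boot Bootstrap resamples (default 10000).
#' @param mass HDI mass (default 0.95).
#' @param seed Bootstrap seed.
#' @return List with elements `unique_chosen` and `nonunique_chosen`;
#'   each is a data.frame with rows `first`/`last`/`total` and columns
#'   `chosen`, `nonchosen`, `diff`, `diff_lo`, `diff_hi`,
#'   `n_participants`.
#' @export
chosen_vs_nonchosen_plateau <- function(fixtab, trials, n_boot = 10000,
                                        mass = 0.95, seed = 1) {
  stopifnot(all(c("plateau", "choice") %in% names(trials)))
  pl <- trials[!is.na(trials$plateau), , drop = FALSE]
  if (nrow(pl) == 0) stop("no plateau trials in the data")
  pl$unique_shape <- ifelse(pl$plateau == "star", "pentagon", "star")
  pl$unique_chosen <- pl$choice == pl$unique_shape
  fk <- .trial_key(fixtab)

  per_trial <- function(tr) {
    d <- fixtab[fk == .trial_key(tr), , drop = FALSE]
    if (nrow(d) == 0) return(NULL)
    ch <- tr$choice
    nc <- setdiff(c("star", "pentagon"), ch)
    c(first_ch = as.numeric(.select_fix(d, "first")$shape == ch),
      first_nc = as.numeric(.select_fix(d, "first")$shape == nc),
      last_ch = as.numeric(.select_fix(d, "last")$shape == ch),
      last_nc = as.numeric(.select_fix(d, "last")$shape == nc),
      total_ch = sum(d$shape == ch),
      total_nc = sum(d$shape == nc))
  }

  one_class <- function(cls) {
    sub <- pl[pl$unique_chosen == cls, , drop = FALSE]
    rows <- lapply(seq_len(nrow(sub)), function(i) {
      v <- per_trial(sub[i, ])
      if (is.null(v)) NULL else
        cbind(data.frame(participant = sub$participant[i]), as.data.frame(t(v)))
    })
    tt <- do.call(rbind, rows)
    if (is.null(tt) || nrow(tt) == 0) return(NULL)
    pm <- do.call(rbind, lapply(split(tt, tt$participant),
                                function(g) colMeans(g[, -1])))
    measures <- c("first", "last", "total")
    set.seed(seed)
    boots <- matrix(sample.int(nrow(pm), nrow(pm) * n_boot, replace = TRUE),
                    nrow = n_boot)
    out <- do.call(rbind, lapply(measures, function(m) {
      dch <- pm[, paste0(m, "_ch")]; dnc <- pm[, paste0(m, "_nc")]
      dd <- dch - dnc
      bd <- apply(boots, 1, function(ii) mean(dd[ii]))
      h <- hdi(bd, mass)
      data.frame(measure = m, chosen = mean(dch), nonchosen = mean(dnc),
                 diff = mean(dd), diff_lo = h[1], diff_hi = h[2],
                 n_participants = nrow(pm), stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  }

  list(unique_chosen = one_class(TRUE),
       nonunique_chosen = one_class(FALSE))
}

#' Proportion of first fixations landing on a target, by cycle position
#'
#' Tracks whether early attention guidance is modulated over the
#' distractor cycle: for every cycle position, the proportion of trials
#' whose first fixation was assigned to either blue target (chance for a
#' uniformly random first fixation: 2/16).
#'
#' @param fixtab Assigned fixation table.
#' @param trials Trial data.frame with `cycle_pos`.
#' @return Data.frame with `cycle_pos`, `prop`, `se`, `n_trials`.
#' @export
first_fixation_on_target_by_position <- function(fixtab, trials) {
  tk <- .trial_key(trials)
  firsts <- do.call(rbind, lapply(split(fixtab, .trial_key(fixtab)),
                                  function(d) .select_fix(d, "first")))
  m <- match(.trial_key(firsts), tk)
  ok <- !is.na(m)
  df <- data.frame(cycle_pos = trials$cycle_pos[m[ok]],
                   on_target = firsts$role[ok] == "target")
  agg <- do.call(rbind, lapply(split(df, df$cycle_pos), function(g) {
    p <- mean(g$on_target)
    data.frame(cycle_pos = g$cycle_pos[1], prop = p,
               se = sqrt(p * (1 - p) / nrow(g)), n_trials = nrow(g))
  }))
  agg <- agg[order(agg$cycle_pos), ]
  rownames(agg) <- NULL
  agg
}
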