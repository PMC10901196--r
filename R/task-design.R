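# Task structure of the probabilistic learning go/no-go task (PLGT):
# four cue categories crossing motivational valence (win / avoid) with the
# required action (go / no-go), two fractal images per category, and 80/20
# probabilistic feedback. This file is the single source of truth for cue
# coding, favorable-outcome rules, and feedback sampling; both the simulator
# and the scoring functions build on it.

#' Cue categories of the go/no-go task
#'
#' Returns the eight cue images of the task: the four conditions obtained by
#' crossing valence (win money vs avoid shock) with the required action
#' (go vs no-go), with two images per condition. A favorable outcome is a
#' reward (+1) on win cues and a null outcome (0) on avoid cues; an
#' unfavorable outcome is null (0) on win cues and a shock (-1) on avoid
#' cues.
#'
#' @return A data frame with one row per cue image and columns
#'   \code{valence} ("win"/"avoid"), \code{required_action} ("go"/"nogo"),
#'   \code{image_id} (1 or 2 within the condition), \code{condition}
#'   (e.g. "go_to_win") and \code{image} (global index 1..8).
#' @export
#' @examples
#' cue_conditions()
cue_conditions <- function() {
  grid <- expand.grid(
    image_id = 1:2,
    required_action = c("go", "nogo"),
    valence = c("win", "avoid"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("valence", "required_action", "image_id")]
  grid$condition <- paste0(grid$required_action, "_to_", grid$valence)
  grid$image <- cue_image_index(grid$valence, grid$required_action, grid$image_id)
  grid[order(grid$image), ]
}

# Global image index 1..8 from the (valence, required_action, image_id) key.
cue_image_index <- function(valence, required_action, image_id) {
  cat_idx <- (valence == "avoid") * 2L + (required_action == "nogo")
  as.integer(cat_idx * 2L + image_id)
}

#' Build a randomized trial schedule
#'
#' Creates the ordered sequence of cue presentations for one subject:
#' \code{n_per_cue} presentations of each of the eight cue images, distributed
#' across \code{n_runs} runs by blocked shuffling (each run receives an
#' approximately equal share of each image, then the order within each run is
#' randomized). The study design this emulates used four runs with
#' approximately 50 trials per cue.
#'
#' @param n_per_cue Number of presentations of each cue image (>= 1).
#' @param n_runs Number of runs the trials are split across (>= 1).
#' @param seed Integer seed; identical seeds give identical schedules.
#' @return A data frame with columns \code{run}, \code{trial} (index within
#'   run), \code{valence}, \code{required_action}, \code{image_id},
#'   \code{condition}, and \code{image}; \code{8 * n_per_cue} rows.
#' @export
#' @examples
#' sched <- build_schedule(n_per_cue = 5, n_runs = 2, seed = 1)
#' table(sched$condition)
build_schedule <- function(n_per_cue, n_runs, seed) {
  if (!is.numeric(n_per_cue) || length(n_per_cue) != 1L || n_per_cue < 1) {
    stop("`n_per_cue` must be a positive count", call. = FALSE)
  }
  if (!is.numeric(n_runs) || length(n_runs) != 1L || n_runs < 1) {
    stop("`n_runs` must be a positive count", call. = FALSE)
  }
  n_per_cue <- as.integer(n_per_cue)
  n_runs <- as.integer(n_runs)
  cues <- cue_conditions()
  with_seed(seed, {
    # counts[image, run]: floor share everywhere, remainder rotated across
    # runs by image so run lengths stay as equal as possible
    base <- n_per_cue %/% n_runs
    rem <- n_per_cue %% n_runs
    runs <- vector("list", n_runs)
    for (r in seq_len(n_runs)) {
      counts <- rep(base, 8L)
      if (rem > 0L) {
        extra_runs <- outer(1:8, seq_len(rem) - 1L, function(i, k) ((i + k - 1L) %% n_runs) + 1L)
        counts <- counts + rowSums(extra_runs == r)
      }
      imgs <- rep.int(cues$image, counts)
      runs[[r]] <- imgs[sample.int(length(imgs))]
    }
    out <- do.call(rbind, lapply(seq_len(n_runs), function(r) {
      data.frame(run = r, trial = seq_along(runs[[r]]), image = runs[[r]])
    }))
    out <- merge(out, cues, by = "image", sort = FALSE)
    out <- out[order(out$run, out$trial),
               c("run", "trial", "valence", "required_action", "image_id",
                 "condition", "image")]
    rownames(out) <- NULL
    out
  })
}

#' Sample probabilistic feedback for chosen actions
#'
#' Implements the task's feedback rule: a correct response (action equal to
#' the required action) yields a favorable outcome with probability
#' \code{p_correct} (0.8 in the task design), an incorrect response with
#' probability \code{1 - p_correct}. On win cues the favorable outcome is a
#' reward (+1) and the unfavorable one null (0); on avoid cues the favorable
#' outcome is null (0) and the unfavorable one a shock (-1). When shock
#' feedback is displayed, the shock is actually delivered only half of the
#' time; the flag is recorded but the displayed outcome \code{-1} is what the
#' learning models see.
#'
#' Vectorized over trials; consumes the current R random stream, so seed the
#' generator (or wrap in a seeded caller) for reproducibility.
#'
#' @param valence Character vector, "win" or "avoid" per trial.
#' @param correct Logical vector: was the chosen action the required one?
#' @param p_correct Probability that a correct response is rewarded/spared
#'   (must lie in (0.5, 1]).
#' @param p_shock_delivered Probability that displayed shock feedback is
#'   physically delivered.
#' @return A data frame with columns \code{outcome} (+1/0/-1),
#'   \code{favorable} (logical) and \code{shock_delivered} (logical, NA
#'   except on shock feedback trials).
#' @export
sample_feedback <- function(valence, correct, p_correct = 0.8,
                            p_shock_delivered = 0.5) {
  if (!(p_correct > 0.5 && p_correct <= 1)) {
    stop("`p_correct` must lie in (0.5, 1]", call. = FALSE)
  }
  n <- length(valence)
  stopifnot(length(correct) == n)
  p_fav <- ifelse(correct, p_correct, 1 - p_correct)
  favorable <- runif(n) < p_fav
  outcome <- integer(n)
  outcome[valence == "win" & favorable] <- 1L
  outcome[valence == "avoid" & !favorable] <- -1L
  shock_delivered <- rep(NA, n)
  shock_idx <- which(outcome == -1L)
  if (length(shock_idx)) {
    shock_delivered[shock_idx] <- runif(length(shock_idx)) < p_shock_delivered
  }
  data.frame(outcome = outcome, favorable = favorable,
             shock_delivered = shock_delivered)
}
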