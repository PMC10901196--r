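# Behavioral summaries: condition accuracy, the stay/switch index, and
# model-implied action-value-difference trajectories. These feed group-level
# statistics (ANOVA, correlations) that live outside the package; functions
# here return tidy per-subject tables.

CONDITION_LEVELS <- c("go_to_win", "nogo_to_win", "go_to_avoid", "nogo_to_avoid")

#' Accuracy by task condition
#'
#' A response is correct when the chosen action equals the cue's required
#' action; correctness is independent of the sampled (probabilistic)
#' outcome. Accuracy is the proportion correct per subject in each of the
#' four (valence x required action) conditions.
#'
#' @param trials Multi-subject trial data frame.
#' @return Data frame with columns \code{subject_id}, \code{condition},
#'   \code{valence}, \code{required_action}, \code{accuracy}, \code{n}.
#'   Conditions without trials get \code{NA} accuracy and \code{n = 0}.
#' @export
accuracy_by_condition <- function(trials) {
  correct <- trials$action == trials$required_action
  ids <- unique(trials$subject_id)
  grid <- expand.grid(subject_id = ids, condition = CONDITION_LEVELS,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  agg <- aggregate(correct,
                   by = list(subject_id = trials$subject_id,
                             condition = trials$condition),
                   FUN = function(z) c(acc = mean(z), n = length(z)))
  agg <- data.frame(subject_id = agg$subject_id, condition = agg$condition,
                    accuracy = agg$x[, "acc"], n = agg$x[, "n"])
  out <- merge(grid, agg, by = c("subject_id", "condition"), all.x = TRUE)
  out$n[is.na(out$n)] <- 0
  parts <- strsplit(out$condition, "_to_")
  out$required_action <- vapply(parts, `[[`, "", 1L)
  out$valence <- vapply(parts, `[[`, "", 2L)
  out <- out[order(out$subject_id, match(out$condition, CONDITION_LEVELS)),
             c("subject_id", "condition", "valence", "required_action",
               "accuracy", "n")]
  rownames(out) <- NULL
  out
}

#' Stay/switch index
#'
#' For every unfavorable-feedback event, looks up the subject's next
#' presentation of the same cue and scores a switch when the response
#' differs; the index is 100 x switches / eligible events, per condition.
#' High values indicate inconsistent responding ("reward chasing") rather
#' than learning. Because responses are cue-conditional, "the next trial" is
#' interpreted as the next presentation of the same cue image by default;
#' \code{match = "category"} instead matches the next cue of the same
#' condition (either image).
#'
#' @param trials Multi-subject trial data frame (needs \code{favorable}).
#' @param match \code{"image"} (default) or \code{"category"}.
#' @return Data frame with columns \code{subject_id}, \code{condition},
#'   \code{switch_pct} (NA when no eligible events), \code{n_eligible}.
#' @export
stay_switch_index <- function(trials, match = c("image", "category")) {
  match <- match.arg(match)
  if (!"favorable" %in% names(trials)) {
    stop("trials need a `favorable` column for the stay/switch index",
         call. = FALSE)
  }
  res <- lapply(split_subjects(trials), function(tr) {
    key <- if (match == "image") {
      cue_image_index(tr$valence, tr$required_action, tr$image_id)
    } else {
      tr$condition
    }
    n <- nrow(tr)
    # next presentation of the same key after each trial
    next_idx <- rep(NA_integer_, n)
    last_seen <- list()
    for (t in rev(seq_len(n))) {
      k <- as.character(key[t])
      next_idx[t] <- if (is.null(last_seen[[k]])) NA_integer_ else last_seen[[k]]
      last_seen[[k]] <- t
    }
    eligible <- which(!tr$favorable & !is.na(next_idx))
    switched <- tr$action[eligible] != tr$action[next_idx[eligible]]
    stats <- lapply(CONDITION_LEVELS, function(cond) {
      idx <- eligible[tr$condition[eligible] == cond]
      n_el <- length(idx)
      pct <- if (n_el == 0L) NA_real_ else
        100 * sum(tr$action[idx] != tr$action[next_idx[idx]]) / n_el
      data.frame(subject_id = tr$subject_id[1], condition = cond,
                 switch_pct = pct, n_eligible = n_el)
    })
    do.call(rbind, stats)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Action-value-difference trajectories
#'
#' Replays each subject's sequence under the given parameters and records,
#' before each choice, the difference between the required action's value
#' and the alternative's: \code{Q(go) - Q(nogo)} for go cues and
#' \code{Q(nogo) - Q(go)} for no-go cues, so successful learning is
#' positive-going for every cue type.
#'
#' @param trials Multi-subject trial data frame.
#' @param params Either one named natural-space parameter vector used for
#'   every subject, or a matrix with one named row per subject (rownames =
#'   subject ids), e.g. the \code{estimates} of a \code{\link{em_fit}}.
#' @param spec A \code{plgt_model_spec}.
#' @return Data frame with columns \code{subject_id}, \code{condition},
#'   \code{image}, \code{presentation} (per-image encounter index), and
#'   \code{value_diff}.
#' @export
value_difference_trajectory <- function(trials, params, spec) {
  subj <- split_subjects(trials)
  res <- lapply(names(subj), function(id) {
    tr <- subj[[id]]
    p <- if (is.matrix(params)) params[id, ] else params
    rp <- replay_sequence(tr, p, spec)
    qd <- ifelse(tr$required_action == "go", rp$q_diff, -rp$q_diff)
    img <- cue_image_index(tr$valence, tr$required_action, tr$image_id)
    pres <- stats::ave(seq_along(img), img, FUN = seq_along)
    data.frame(subject_id = tr$subject_id[1], condition = tr$condition,
               image = img, presentation = pres, value_diff = qd)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' One-call behavioral summary
#'
#' Convenience wrapper returning the per-subject condition accuracies and
#' stay/switch indices as a named list of tidy tables.
#'
#' @param trials Multi-subject trial data frame.
#' @param match Stay/switch matching rule (see
#'   \code{\link{stay_switch_index}}).
#' @return List with elements \code{accuracy} and \code{stay_switch}.
#' @export
behavior_summary <- function(trials, match = "image") {
  list(accuracy = accuracy_by_condition(trials),
       stay_switch = stay_switch_index(trials, match = match))
}
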