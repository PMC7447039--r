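# Two-stage contrast analysis of mental time-travel response times.
# Stage 1 reduces each participant to a future-minus-past mean log-RT
# difference per session; stage 2 compares the pre-to-post change of that
# difference between stimulation groups. In balanced complete designs this
# interaction score carries exactly the fixed-effects group x session x
# event-time regression coefficient.

#' Per-cell mean log response times
#'
#' Means of `log_rt` per participant x session x event time. Rows for
#' which an `exclude` column is TRUE are dropped first, if present.
#'
#' @param trials Time-travel trial data frame (`participant_id`, `group`,
#'   `session`, `event_time`, `log_rt`).
#' @return Data frame of cell means with trial counts.
#' @export
rt_cell_means <- function(trials) {
  stopifnot(nrow(trials) > 0)
  if ("exclude" %in% names(trials)) trials <- trials[!trials$exclude, ]
  agg <- stats::aggregate(log_rt ~ participant_id + group + session + event_time,
                          data = trials, FUN = mean)
  cnt <- stats::aggregate(cbind(n = log_rt) ~ participant_id + group +
                            session + event_time, data = trials, FUN = length)
  merge(agg, cnt)
}

#' Per-participant session x event-time interaction scores
#'
#' For each participant, the future-minus-past mean log-RT difference is
#' computed per session; the interaction score is the post-session minus
#' the pre-session difference. Positive scores mean future-event
#' judgements slowed from pre to post relative to past events.
#' Participants missing any of the four contributing cells are excluded
#' with a warning.
#'
#' @param trials Time-travel trial data frame.
#' @return Data frame of class `rt_contrasts`: `participant_id`, `group`,
#'   `diff_pre`, `diff_post`, `score`.
#' @export
rt_interaction_scores <- function(trials) {
  cm <- rt_cell_means(trials)
  out <- list(); dropped <- character(0)
  for (id in unique(cm$participant_id)) {
    sub <- cm[cm$participant_id == id, ]
    cell <- function(sess, et)
      sub$log_rt[sub$session == sess & sub$event_time == et]
    cells <- list(cell("pre", "future"), cell("pre", "past"),
                  cell("post", "future"), cell("post", "past"))
    if (any(vapply(cells, length, 0L) != 1L)) {
      dropped <- c(dropped, id)
      next
    }
    d_pre <- cells[[1]] - cells[[2]]
    d_post <- cells[[3]] - cells[[4]]
    out[[id]] <- data.frame(participant_id = id, group = sub$group[1],
                            diff_pre = d_pre, diff_post = d_post,
                            score = d_post - d_pre, stringsAsFactors = FALSE)
  }
  if (length(dropped))
    warning("participants excluded for empty design cells: ",
            paste(dropped, collapse = ", "))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("rt_contrasts", class(res))
  res
}

#' Group test of the stimulation x session x event-time interaction
#'
#' Mann-Whitney comparison of the per-participant interaction scores
#' between rTPJ and vertex groups. The positive direction is "rTPJ
#' stimulation slows future-event processing post-stimulation".
#'
#' @param contrasts Output of [rt_interaction_scores()].
#' @param tail,direction Passed to [mann_whitney()].
#' @return A `group_test`.
#' @export
interaction_test <- function(contrasts, tail = c("one", "two"),
                             direction = c("greater", "less")) {
  tail <- match.arg(tail); direction <- match.arg(direction)
  stopifnot(all(c("rTPJ", "vertex") %in% contrasts$group))
  mann_whitney(contrasts$score[contrasts$group == "rTPJ"],
               contrasts$score[contrasts$group == "vertex"],
               tail = tail, direction = direction)
}

#' Cross-task correlation of stimulation effects
#'
#' Spearman correlation (via [spearman_correlation()]) between the RT
#' interaction scores and the pre-to-post change in the discount scaling
#' parameter, matched by participant across both groups pooled.
#'
#' @param rt_scores Data frame with `participant_id` and `score`.
#' @param delta_s Data frame with `participant_id` and `delta_s` (or a
#'   `score` column).
#' @param tail,direction Passed to [spearman_correlation()].
#' @return List with `rho`, `p`, `n`.
#' @export
crosstask_correlation <- function(rt_scores, delta_s, tail = c("one", "two"),
                                  direction = c("greater", "less")) {
  tail <- match.arg(tail); direction <- match.arg(direction)
  ycol <- if ("delta_s" %in% names(delta_s)) "delta_s" else "score"
  m <- merge(rt_scores[, c("participant_id", "score")],
             delta_s[, c("participant_id", ycol)], by = "participant_id")
  if (nrow(m) != nrow(rt_scores) || nrow(m) != nrow(delta_s))
    stop("crosstask_correlation: participants do not match between tasks")
  res <- spearman_correlation(m$score, m[[ycol]], tail = tail,
                              direction = direction)
  c(res, list(n = nrow(m)))
}
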