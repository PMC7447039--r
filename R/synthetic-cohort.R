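#' Configuration for a synthetic two-group, two-session cohort
#'
#' Describes the stated world of the simulated study: a between-group
#' stimulation design (rTPJ vs. vertex control) with a pre- and a
#' post-stimulation session. Choices come from generalized hyperbolic
#' discounting plus softmax; stimulation acts multiplicatively on the
#' scaling parameter `s` of the rTPJ group only. Time-travel response times
#' are log-normal with factorial effects.
#'
#' Population parameter distributions are not identifiable from group-level
#' statistics, so they are declared here and documented as modelling
#' choices: log-normal `k` (median 0.01/day), `s` (median 1) and
#' `beta_temp` (median 1/CHF).
#'
#' @param n_per_group Participants per stimulation group (default 30).
#' @param reward_grid LL reward levels in CHF (default the 9 task levels).
#' @param delay_grid Delays in days (default the 9 task delays).
#' @param repeats_per_session Repetitions of the full reward x delay cross
#'   per session (default 2, i.e. 162 choice trials per session).
#' @param param_population Named list of `c(meanlog, sdlog)` pairs for
#'   `k`, `s`, `beta_temp`.
#' @param ctbs_effect_s Multiplicative post-session shift of `s` for the
#'   rTPJ group (1 = no effect / null world).
#' @param session_noise_sd Log-scale SD of multiplicative pre-to-post
#'   parameter noise applied to both groups (test-retest variability).
#' @param susceptibility_sd Log-scale SD of a per-participant latent
#'   susceptibility that scales both the stimulation effect on `s` and the
#'   stimulation effect on response times, coupling the two tasks
#'   (0 = effects uncorrelated across tasks).
#' @param rt_effects Coefficient list for the log-RT generator; see
#'   [default_rt_effects()].
#' @param events_per_cell Time-travel events per design cell per session
#'   (default 9, i.e. 72 events).
#' @param seed Master seed; all randomness in [simulate_cohort()] flows
#'   from it through named substreams.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 30,
                          reward_grid = c(10, 11, 12, 13, 14, 15, 16, 18, 20),
                          delay_grid = c(1, 5, 10, 20, 40, 60, 90, 120, 180),
                          repeats_per_session = 2,
                          param_population = list(
                            k = c(meanlog = log(0.01), sdlog = 0.5),
                            s = c(meanlog = 0, sdlog = 0.3),
                            beta_temp = c(meanlog = 0, sdlog = 0.5)),
                          ctbs_effect_s = 1.3,
                          session_noise_sd = 0.1,
                          susceptibility_sd = 0.5,
                          rt_effects = default_rt_effects(),
                          events_per_cell = 9,
                          seed = 1L) {
  stopifnot(n_per_group >= 1, length(reward_grid) > 0, length(delay_grid) > 0,
            repeats_per_session >= 1, events_per_cell >= 1,
            ctbs_effect_s > 0, session_noise_sd >= 0, susceptibility_sd >= 0)
  for (p in c("k", "s", "beta_temp"))
    stopifnot(p %in% names(param_population),
              param_population[[p]]["sdlog"] >= 0)
  structure(list(n_per_group = n_per_group, reward_grid = reward_grid,
                 delay_grid = delay_grid,
                 repeats_per_session = repeats_per_session,
                 param_population = param_population,
                 ctbs_effect_s = ctbs_effect_s,
                 session_noise_sd = session_noise_sd,
                 susceptibility_sd = susceptibility_sd,
                 rt_effects = rt_effects, events_per_cell = events_per_cell,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default log-RT generator coefficients
#'
#' Units are log-seconds. The session x event-time coefficient (practice
#' speed-up for future events) and the group x session x event-time
#' coefficient (stimulation slows future-event judgements in the rTPJ
#' group) take the reported factorial values; main effects and noise scales
#' are plausible choices for a 3-second response window, declared once.
#'
#' @return Named list of coefficients.
#' @export
default_rt_effects <- function() {
  list(intercept = log(1.5),       # baseline median RT 1.5 s
       perspective = 0.04,         # future perspective slower
       event_type = 0.04,          # nonpersonal events slower
       event_time = 0.05,          # relative-future events slower
       session_x_event_time = -0.032,
       ctbs_x_session_x_event_time = 0.045,
       participant_sd = 0.15,      # random intercept SD
       noise_sd = 0.25)            # residual log-RT SD
}

# Deterministic substream seeds below 2^31, derived from the master seed and
# a stream label so per-participant/task streams are reproducible and
# distinct.
substream_seed <- function(master, label) {
  h <- 5381
  for (ch in utf8ToInt(paste0(label, ":", master)))
    h <- (h * 33 + ch) %% 2147483647
  as.integer(h)
}

#' Build the intertemporal choice design
#'
#' Fully crosses the reward and delay grids (81 combinations with the
#' default grids), repeats the cross `repeats` times, and randomizes trial
#' order. With two repeats the 162 trials of a session are split evenly
#' across two runs.
#'
#' @param reward_grid,delay_grid Reward (CHF) and delay (days) levels.
#' @param repeats Number of repetitions of the full cross.
#' @param seed Optional seed for the order shuffle; `NULL` leaves the
#'   design in systematic order.
#' @return Data frame with columns `reward_ll`, `delay`, `run`.
#' @export
make_choice_design <- function(reward_grid = c(10, 11, 12, 13, 14, 15, 16, 18, 20),
                               delay_grid = c(1, 5, 10, 20, 40, 60, 90, 120, 180),
                               repeats = 1, seed = NULL) {
  stopifnot(length(reward_grid) > 0, length(delay_grid) > 0, repeats >= 1)
  cross <- expand.grid(reward_ll = reward_grid, delay = delay_grid,
                       KEEP.OUT.ATTRS = FALSE)
  des <- cross[rep(seq_len(nrow(cross)), repeats), , drop = FALSE]
  if (!is.null(seed)) {
    set.seed(seed)
    des <- des[sample.int(nrow(des)), , drop = FALSE]
  }
  n <- nrow(des)
  # first half of the (shuffled) session is run 1, second half run 2
  des$run <- 1L + as.integer(seq_len(n) > ceiling(n / 2))
  rownames(des) <- NULL
  des
}

#' Build the mental time-travel design
#'
#' 2 (personal/nonpersonal) x 2 (now/future perspective) x 2 (relative
#' past/future event time) factorial with `events_per_cell` events per cell
#' per session (72 events with the default 9), split evenly across 2 runs.
#'
#' @param events_per_cell Events per design cell (default 9).
#' @param seed Optional order-shuffle seed.
#' @return Data frame with columns `event_type`, `perspective`,
#'   `event_time`, `run`.
#' @export
make_timetravel_design <- function(events_per_cell = 9, seed = NULL) {
  stopifnot(events_per_cell >= 1)
  cells <- expand.grid(event_type = c("personal", "nonpersonal"),
                       perspective = c("now", "future"),
                       event_time = c("past", "future"),
                       stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  des <- cells[rep(seq_len(nrow(cells)), each = events_per_cell), , drop = FALSE]
  if (!is.null(seed)) {
    set.seed(seed)
    des <- des[sample.int(nrow(des)), , drop = FALSE]
  }
  des$run <- rep(1:2, length.out = nrow(des))
  rownames(des) <- NULL
  des
}

#' Draw participant-level discount parameters for both sessions
#'
#' Draws generalized hyperbolic parameters (`k`, `s`, `beta_temp`)
#' log-normally per participant, applies multiplicative session noise to
#' the post session of both groups, and multiplies post-session `s` by
#' `ctbs_effect_s^susceptibility` for rTPJ-group participants only.
#'
#' @param config A [cohort_config()].
#' @param seed Seed (defaults to a substream of the config master seed).
#' @return Data frame with one row per participant x session: columns
#'   `participant_id`, `group`, `session`, `k`, `s`, `beta_temp`,
#'   `susceptibility`.
#' @export
sample_participant_params <- function(config,
                                      seed = substream_seed(config$seed, "params")) {
  set.seed(seed)
  n <- config$n_per_group
  ids <- sprintf("P%03d", seq_len(2 * n))
  group <- rep(c("rTPJ", "vertex"), each = n)
  pp <- config$param_population
  draw <- function(p, m) stats::rlnorm(m, pp[[p]]["meanlog"], pp[[p]]["sdlog"])
  k <- draw("k", 2 * n); s <- draw("s", 2 * n); bt <- draw("beta_temp", 2 * n)
  suscept <- exp(stats::rnorm(2 * n, 0, config$susceptibility_sd))
  noise <- function(m) exp(stats::rnorm(m, 0, config$session_noise_sd))
  post_s <- s * noise(2 * n) *
    ifelse(group == "rTPJ", config$ctbs_effect_s^suscept, 1)
  pre <- data.frame(participant_id = ids, group = group, session = "pre",
                    k = k, s = s, beta_temp = bt, susceptibility = suscept,
                    stringsAsFactors = FALSE)
  post <- data.frame(participant_id = ids, group = group, session = "post",
                     k = k * noise(2 * n), s = post_s,
                     beta_temp = bt * noise(2 * n), susceptibility = suscept,
                     stringsAsFactors = FALSE)
  rbind(pre, post)
}

#' Simulate softmax choices for one participant-session
#'
#' Each design trial's choice is Bernoulli with
#' `P(LL) = choice_prob(SV(trial), beta_temp)`.
#'
#' @param params A [discount_params()] object.
#' @param design Data frame from [make_choice_design()].
#' @param seed Seed.
#' @param ss_amount Smaller-sooner amount (CHF).
#' @return `design` with a `choice` column (`"LL"`/`"SS"`).
#' @export
simulate_choices <- function(params, design, seed = 1L, ss_amount = 10) {
  set.seed(seed)
  sv <- subjective_value(params, design$reward_ll, design$delay)
  p <- choice_prob(sv, params$beta_temp, ss_amount)
  design$choice <- ifelse(stats::runif(nrow(design)) < p, "LL", "SS")
  design
}

#' Simulate mental time-travel response times for a cohort
#'
#' Generates log-normal RTs under the factorial model
#' \deqn{\log RT = b_0 + u_i + b_p[future\ perspective] +
#'   b_e[nonpersonal] + b_t[future\ event] + b_{st}[post][future\ event] +
#'   w_i b_{gst}[rTPJ][post][future\ event] + \epsilon,}
#' where \eqn{u_i} is a participant intercept, \eqn{w_i} the participant's
#' stimulation susceptibility, and \eqn{\epsilon} Gaussian noise. RTs are
#' truncated at the 3 s response window; no omissions are generated.
#'
#' @param config A [cohort_config()].
#' @param participants Data frame with `participant_id`, `group`,
#'   `susceptibility` (one row per participant); defaults to a fresh draw
#'   consistent with `config`.
#' @param seed Seed.
#' @return Data frame of trials with factor levels, `rt` (s) and `log_rt`.
#' @export
simulate_timetravel_rts <- function(config, participants = NULL,
                                    seed = substream_seed(config$seed, "rt")) {
  set.seed(seed)
  if (is.null(participants)) {
    pp <- sample_participant_params(config)
    participants <- unique(pp[pp$session == "pre",
                              c("participant_id", "group", "susceptibility")])
  }
  ef <- config$rt_effects
  u <- stats::rnorm(nrow(participants), 0, ef$participant_sd)
  out <- vector("list", nrow(participants) * 2L)
  idx <- 1L
  for (i in seq_len(nrow(participants))) {
    for (sess in c("pre", "post")) {
      des <- make_timetravel_design(config$events_per_cell,
        seed = substream_seed(seed, paste0("des:", i, ":", sess)))
      is_post <- as.numeric(sess == "post")
      is_rtpj <- as.numeric(participants$group[i] == "rTPJ")
      ft <- as.numeric(des$event_time == "future")
      mu <- ef$intercept + u[i] +
        ef$perspective * (des$perspective == "future") +
        ef$event_type * (des$event_type == "nonpersonal") +
        ef$event_time * ft +
        ef$session_x_event_time * is_post * ft +
        ef$ctbs_x_session_x_event_time * participants$susceptibility[i] *
          is_rtpj * is_post * ft
      lrt <- mu + stats::rnorm(nrow(des), 0, ef$noise_sd)
      rt <- pmin(exp(lrt), 3)
      out[[idx]] <- data.frame(
        participant_id = participants$participant_id[i],
        group = participants$group[i], session = sess, run = des$run,
        event_type = des$event_type, perspective = des$perspective,
        event_time = des$event_time, rt = rt, log_rt = log(rt),
        stringsAsFactors = FALSE)
      idx <- idx + 1L
    }
  }
  do.call(rbind, out)
}

#' Simulate the full synthetic cohort
#'
#' Draws participant parameters, simulates per-session choice data under
#' generalized hyperbolic discounting and the time-travel RT table, all
#' from named substreams of the master seed.
#'
#' @param config A [cohort_config()].
#' @return List of class `cohort` with elements `choices`, `rts`, `params`
#'   (true generating parameters), and `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  pp <- sample_participant_params(config)
  choice_rows <- vector("list", nrow(pp))
  for (i in seq_len(nrow(pp))) {
    row <- pp[i, ]
    par <- discount_params("generalized_hyperbolic", k = row$k, s = row$s,
                           beta_temp = row$beta_temp)
    des <- make_choice_design(config$reward_grid, config$delay_grid,
      repeats = config$repeats_per_session,
      seed = substream_seed(config$seed,
                            paste0("cdes:", row$participant_id, ":", row$session)))
    ch <- simulate_choices(par, des,
      seed = substream_seed(config$seed,
                            paste0("choice:", row$participant_id, ":", row$session)))
    choice_rows[[i]] <- data.frame(participant_id = row$participant_id,
                                   group = row$group, session = row$session,
                                   run = ch$run, reward_ll = ch$reward_ll,
                                   delay = ch$delay, choice = ch$choice,
                                   stringsAsFactors = FALSE)
  }
  participants <- unique(pp[pp$session == "pre",
                            c("participant_id", "group", "susceptibility")])
  rts <- simulate_timetravel_rts(config, participants,
                                 seed = substream_seed(config$seed, "rt"))
  structure(list(choices = do.call(rbind, choice_rows), rts = rts,
                 params = pp, config = config), class = "cohort")
}

#' Write a cohort to CSV files plus a JSON manifest
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(choices = file.path(dir, "choices.csv"),
             rts = file.path(dir, "rts.csv"),
             params = file.path(dir, "params.csv"),
             manifest = file.path(dir, "manifest.json"))
  utils::write.csv(cohort$choices, paths["choices"], row.names = FALSE)
  utils::write.csv(cohort$rts, paths["rts"], row.names = FALSE)
  utils::write.csv(cohort$params, paths["params"], row.names = FALSE)
  cfg <- cohort$config
  jsonlite::write_json(unclass(cfg), paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read a choice table written by [write_cohort()]
#' @param path CSV path with columns `participant_id`, `group`, `session`,
#'   `run`, `reward_ll`, `delay`, `choice`.
#' @return Data frame.
#' @export
read_choices <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "group", "session", "run", "reward_ll",
            "delay", "choice")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("choice table missing columns: ", paste(missing, collapse = ", "))
  df
}
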