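# Evaluation harness: seeded synthetic protocols producing Suc/Vic/Rate
# tables, confusion matrices and paired strategy comparisons.

#' Metadata for the eight study activities
#'
#' Which extremity each activity uses, its laterality, whether it is a
#' posture or a movement, whether its body use is global or bounded, and
#' whether it is a sink activity (easily detected, prone to absorbing
#' other activities' samples).
#'
#' @return A data frame with columns `name`, `extremity`, `laterality`,
#'   `kind`, `body_use`, `sink`.
#' @export
study_roster <- function() {
  data.frame(
    name = c(
      "Stand", "Stay Seated", "Walk [D]", "Walk Backwards [D]",
      "Drink [D]", "Grab Object [D]", "Leg Flexion [I]",
      "Leg Circular Swing [I]"
    ),
    extremity = c(
      "both", "both", "both", "both", "arm", "arm", "leg", "leg"
    ),
    laterality = c(
      "symmetric", "symmetric", "D", "D", "D", "D", "I", "I"
    ),
    kind = c(
      "posture", "posture", "movement", "movement", "movement",
      "movement", "movement", "movement"
    ),
    body_use = c(rep("global", 4L), rep("bounded", 4L)),
    sink = c(rep(TRUE, 4L), rep(FALSE, 4L)),
    stringsAsFactors = FALSE
  )
}

#' Build study templates for a joint-set variant
#'
#' Generates the single key sample of every roster activity from its
#' noiseless script (recorded by a reference body) and attaches the
#' relevant joints of the requested variant.
#'
#' @param variant `"vB"`, `"vT"` or `"vC"`.
#' @param body Reference `body_model` performing the key samples.
#' @param fps Frames per second of the key samples.
#' @param activities Subset of roster activity names (default all 8).
#' @return Named list of [activity_template()] objects in roster order.
#' @export
build_study_templates <- function(variant, body, fps = 15,
                                  activities = study_roster()$name) {
  roster <- study_roster()
  roster <- roster[match(activities, roster$name), , drop = FALSE]
  if (anyNA(roster$name)) {
    stop("unknown study activity", call. = FALSE)
  }
  scripts <- activity_scripts()
  out <- list()
  for (i in seq_len(nrow(roster))) {
    a <- roster[i, ]
    seq0 <- generate_sequence(scripts[[a$name]], body, fps, noise_none())
    key <- if (a$kind == "posture") seq0$frames[[1L]] else seq0
    spec <- activity_spec(a$name, a$extremity, a$laterality)
    tpl <- suppressWarnings(activity_template(
      name = a$name, kind = a$kind, key_sample = key,
      relevant_joints = variant_joints(spec, variant),
      laterality = a$laterality, body_use = a$body_use, sink = a$sink
    ))
    out[[a$name]] <- tpl
  }
  out
}

#' Protocol configuration
#'
#' @param participants Number of synthetic participants.
#' @param repetitions Repetitions of each activity per participant.
#' @param activities Activity names from [study_roster()].
#' @param variants Joint-set variants to run (at least one).
#' @param limits A [limit_table()] applied at prediction time, or `NULL`
#'   for pure argmax.
#' @param master_seed Master seed; every trial derives its own stream from
#'   it, so identical configurations reproduce identical tables.
#' @param fps Frames per second of generated sequences and templates.
#' @param noise [noise_params()] giving jitter/spike/sway/execution levels
#'   (each trial overrides only the seed).
#' @param body_ranges Body-proportion ranges for participant sampling.
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(participants = 5, repetitions = 25,
                            activities = study_roster()$name,
                            variants = c("vB", "vT", "vC"),
                            limits = NULL, master_seed = 1L, fps = 15,
                            noise = noise_params(),
                            body_ranges = default_body_ranges()) {
  stopifnot(
    participants >= 1, repetitions >= 1, length(activities) >= 1,
    length(variants) >= 1, all(variants %in% c("vB", "vT", "vC")),
    all(activities %in% study_roster()$name),
    inherits(noise, "noise_params")
  )
  if (!is.null(limits)) stopifnot(inherits(limits, "limit_table"))
  structure(
    list(
      participants = as.integer(participants),
      repetitions = as.integer(repetitions),
      activities = activities, variants = unique(variants),
      limits = limits, master_seed = as.integer(master_seed),
      fps = fps, noise = noise, body_ranges = body_ranges
    ),
    class = "protocol_config"
  )
}

# --- fast scoring ----------------------------------------------------------

# precompute template direction matrices for the fast scorer
.precompute_templates <- function(templates) {
  topo <- skeleton_topology()
  ep21 <- .bone_endpoints(topo$bone)
  lapply(templates, function(tpl) {
    bidx <- match(tpl$relevant_bones, topo$bone)
    ep <- .bone_endpoints(tpl$relevant_bones)
    if (tpl$kind == "posture") {
      dirs <- .dir_matrix(tpl$key_sample$positions, ep)
      list(
        name = tpl$name, kind = "posture", bidx = bidx, dirs = dirs,
        m = 1L, duration = 0
      )
    } else {
      m <- length(tpl$key_sample$frames)
      dirs <- do.call(rbind, lapply(tpl$key_sample$frames, function(fr) {
        .dir_matrix(fr$positions, ep)
      }))
      list(
        name = tpl$name, kind = "movement", bidx = bidx, dirs = dirs,
        m = m, duration = sequence_duration(tpl$key_sample)
      )
    }
  })
}

# all-bone unit directions of every frame, stacked frame-major:
# row (f-1)*21 + b is bone b of frame f (NA rows for degenerate bones)
.observation_dirs <- function(seq) {
  topo <- skeleton_topology()
  ep21 <- .bone_endpoints(topo$bone)
  n <- length(seq$frames)
  P <- do.call(rbind, lapply(seq$frames, `[[`, "positions"))
  off <- rep((seq_len(n) - 1L) * 20L, each = 21L)
  d <- P[off + ep21[, 2L], , drop = FALSE] - P[off + ep21[, 1L], , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  len[len < .DEGENERATE_BONE_TOL] <- NA_real_
  list(dirs = d / len, n = n,
    ts = vapply(seq$frames, `[[`, numeric(1), "timestamp")
  )
}

# score one precomputed template against precomputed observation directions
.score_fast <- function(obs, pre, tolerance = 0.2, posture_window = 1) {
  if (pre$kind == "posture") {
    keep <- which(obs$ts >= obs$ts[obs$n] - posture_window - 1e-9)
    k <- length(pre$bidx)
    rows <- rep((keep - 1L) * 21L, each = k) + pre$bidx
    return(mean(.sim_rows(
      obs$dirs[rows, , drop = FALSE],
      pre$dirs[rep(seq_len(k), length(keep)), , drop = FALSE]
    ), na.rm = TRUE))
  }
  t_end <- obs$ts[obs$n]
  keep <- which(obs$ts >= t_end - pre$duration - 1e-9)
  if (length(keep) < 2L) {
    return(NA_real_)
  }
  dw <- obs$ts[keep[length(keep)]] - obs$ts[keep[1L]]
  if (abs(dw - pre$duration) > tolerance * pre$duration) {
    return(NA_real_)
  }
  map <- keep[.resample_map(length(keep), pre$m)]
  k <- length(pre$bidx)
  rows <- rep((map - 1L) * 21L, each = k) + pre$bidx
  mean(.sim_rows(obs$dirs[rows, , drop = FALSE], pre$dirs), na.rm = TRUE)
}

# --- protocol runner -------------------------------------------------------

# generate all trials and score them under every requested variant;
# returns metadata plus a trials x templates x variants score array
.run_trials <- function(config) {
  roster <- study_roster()
  scripts <- activity_scripts()
  tpl_body <- generate_participant(
    config$body_ranges, derive_seed(config$master_seed, "template-body")
  )
  templates <- lapply(
    stats::setNames(config$variants, config$variants),
    function(v) {
      build_study_templates(v, tpl_body, config$fps, config$activities)
    }
  )
  pre <- lapply(templates, .precompute_templates)

  n_trials <- config$participants * length(config$activities) *
    config$repetitions
  meta <- data.frame(
    participant = integer(n_trials), activity = character(n_trials),
    rep = integer(n_trials), stringsAsFactors = FALSE
  )
  scores <- array(
    NA_real_,
    dim = c(n_trials, length(config$activities), length(config$variants)),
    dimnames = list(NULL, config$activities, config$variants)
  )
  i <- 0L
  for (p in seq_len(config$participants)) {
    body <- generate_participant(
      config$body_ranges, derive_seed(config$master_seed, "participant", p)
    )
    for (a in config$activities) {
      script <- scripts[[a]]
      is_leg <- roster$extremity[roster$name == a] == "leg"
      if (is_leg && config$noise$sway_amplitude > 0) {
        script <- with_balance_sway(script, config$noise$sway_amplitude)
      }
      for (r in seq_len(config$repetitions)) {
        i <- i + 1L
        noise_r <- config$noise
        noise_r$seed <- derive_seed(config$master_seed, p, a, r)
        obs <- .observation_dirs(
          generate_sequence(script, body, config$fps, noise_r)
        )
        meta$participant[i] <- p
        meta$activity[i] <- a
        meta$rep[i] <- r
        for (v in config$variants) {
          scores[i, , v] <- vapply(
            pre[[v]], .score_fast, numeric(1), obs = obs
          )
        }
      }
    }
  }
  list(meta = meta, scores = scores, templates = templates)
}

# assemble records / confusion / trial log for one strategy arm
.assemble_arm <- function(meta, scores, variants, limits, repetitions) {
  activities <- dimnames(scores)[[2L]]
  participants <- sort(unique(meta$participant))
  n_trials <- nrow(meta)
  with_vic <- length(variants) >= 2L

  vic_winner <- rep(NA_character_, n_trials)
  if (with_vic) {
    true_scores <- vapply(variants, function(v) {
      scores[cbind(seq_len(n_trials), match(meta$activity, activities),
        rep(match(v, dimnames(scores)[[3L]]), n_trials)
      )]
    }, numeric(n_trials))
    best <- max.col(true_scores, ties.method = "first")
    # strict win only: ties award no variant
    is_tie <- rowSums(
      abs(true_scores - true_scores[cbind(seq_len(n_trials), best)]) < 1e-12
    ) > 1L
    vic_winner[!is_tie] <- variants[best[!is_tie]]
  }

  trials <- NULL
  records <- NULL
  confusion <- list()
  for (v in variants) {
    sv <- scores[, , v, drop = FALSE]
    dim(sv) <- dim(scores)[1:2]
    colnames(sv) <- activities
    pred <- character(n_trials)
    for (i in seq_len(n_trials)) {
      pred[i] <- .predict_from_scores(
        stats::setNames(sv[i, ], activities), list(), limits
      )$label
    }
    correct <- pred == meta$activity
    true_s <- sv[cbind(seq_len(n_trials), match(meta$activity, activities))]
    trials <- rbind(trials, data.frame(
      participant = meta$participant, activity = meta$activity,
      rep = meta$rep, variant = v, predicted = pred, correct = correct,
      true_score = true_s,
      vic = if (with_vic) !is.na(vic_winner) & vic_winner == v else NA,
      stringsAsFactors = FALSE
    ))
    cm <- table(
      factor(meta$activity, levels = activities),
      factor(pred, levels = c(activities, "UNKNOWN"))
    )
    confusion[[v]] <- unclass(cm)
    for (p in participants) {
      for (a in activities) {
        sel <- meta$participant == p & meta$activity == a
        records <- rbind(records, data.frame(
          participant = p, activity = a, variant = v,
          Suc = sum(correct[sel]),
          Vic = if (with_vic) {
            sum(!is.na(vic_winner[sel]) & vic_winner[sel] == v)
          } else {
            NA_integer_
          },
          trials = sum(sel),
          Rate = 100 * sum(correct[sel]) / sum(sel),
          stringsAsFactors = FALSE
        ))
      }
    }
  }
  list(records = records, confusion = confusion, trials = trials)
}

#' Run a synthetic evaluation protocol
#'
#' For every (participant, activity, repetition) one synthetic sequence is
#' generated (with compensatory arm sway superimposed on leg activities
#' when `noise$sway_amplitude > 0`) and classified under every configured
#' joint-set variant, applying `config$limits` if given. `Suc` counts
#' correct predictions; when at least two variants are compared, `Vic`
#' counts the trials where a variant's similarity with the true activity
#' was strictly greatest (ties award no variant).
#'
#' @param config A [protocol_config()].
#' @return An object of class `protocol_result`: list with `records` (one
#'   row per participant x activity x variant, columns `Suc`, `Vic`,
#'   `Rate`), `confusion` (one matrix per variant, rows = true activity,
#'   columns = predicted incl. `UNKNOWN`), `trials` (the full per-trial
#'   log) and `config`.
#' @export
run_protocol <- function(config) {
  stopifnot(inherits(config, "protocol_config"))
  rt <- .run_trials(config)
  arm <- .assemble_arm(
    rt$meta, rt$scores, config$variants, config$limits, config$repetitions
  )
  structure(
    c(arm, list(config = config)),
    class = "protocol_result"
  )
}

#' @export
print.protocol_result <- function(x, ...) {
  s <- summarize_records(x$records)
  cat("<protocol_result>", nrow(x$trials), "trial evaluations\n")
  print(s$overall)
  invisible(x)
}

#' Totals by activity, by participant and overall
#'
#' Pools `Suc`/`Vic` counts and recomputes rates per variant: overall Rate
#' is `100 * sum(Suc) / trials`.
#'
#' @param records The `records` data frame of a [run_protocol()] result
#'   (must carry the per-record `trials` count).
#' @return List of data frames `by_activity`, `by_participant`, `overall`.
#' @export
summarize_records <- function(records) {
  stopifnot(is.data.frame(records), "trials" %in% names(records))
  pool <- function(df, keys) {
    agg <- stats::aggregate(
      df[, c("Suc", "Vic", "trials"), drop = FALSE],
      by = df[, keys, drop = FALSE],
      FUN = function(z) if (all(is.na(z))) NA_integer_ else sum(z, na.rm = TRUE)
    )
    agg$Rate <- 100 * agg$Suc / agg$trials
    agg
  }
  list(
    by_activity = pool(records, c("variant", "activity")),
    by_participant = pool(records, c("variant", "participant")),
    overall = pool(records, "variant")
  )
}

#' Paired comparison of improvement strategies
#'
#' Runs the protocol's trials once and evaluates several strategy arms on
#' the identical seeded trials, so arm differences are not confounded by
#' sampling noise:
#' * `"variants"`: the joint-set variants of `config$variants`, no limits;
#' * `"limits"`: the single set `vB` with the minimum limits of prediction
#'   (no `Vic` — there are no sets to compare);
#' * `"combined"`: the variants with the limits.
#'
#' The limits default to [default_limits()] when `config$limits` is `NULL`.
#'
#' @param config A [protocol_config()] (its `variants` are used by the
#'   variants/combined arms).
#' @param arms Which arms to evaluate (>= 2).
#' @return An object of class `strategy_comparison`: named list of arms,
#'   each with `records`, `confusion`, `trials`, plus `config`.
#' @export
compare_strategies <- function(config,
                               arms = c("variants", "limits", "combined")) {
  stopifnot(inherits(config, "protocol_config"))
  arms <- match.arg(arms, several.ok = TRUE)
  if (length(arms) < 2L) {
    stop("compare_strategies needs at least two arms", call. = FALSE)
  }
  limits <- if (is.null(config$limits)) default_limits() else config$limits
  run_cfg <- config
  run_cfg$variants <- unique(c(config$variants, "vB"))
  rt <- .run_trials(run_cfg)
  out <- list()
  for (arm in arms) {
    out[[arm]] <- switch(arm,
      variants = .assemble_arm(
        rt$meta, rt$scores, config$variants, NULL, config$repetitions
      ),
      limits = .assemble_arm(
        rt$meta, rt$scores, "vB", limits, config$repetitions
      ),
      combined = .assemble_arm(
        rt$meta, rt$scores, config$variants, limits, config$repetitions
      )
    )
  }
  structure(
    c(out, list(config = config)),
    class = "strategy_comparison"
  )
}

#' @export
print.strategy_comparison <- function(x, ...) {
  for (arm in setdiff(names(x), "config")) {
    cat("--", arm, "--\n")
    print(summarize_records(x[[arm]]$records)$overall)
  }
  invisible(x)
}
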