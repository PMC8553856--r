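# Trial timing of the slow event-related design: 9 s triad probe, 7.77 s
# active baseline, 1.36 s fixation gap -> 18.13 s per trial, 15 trials per
# run.
.TRIAL_LEN <- 18.13
.STIM_LEN <- 9
.BASELINE_LEN <- 7.77

# City order over runs: permutation blocks of the three cities, so each city
# is tested once before any repeats, rejecting orders that test a city twice
# in a row (including across block boundaries).
.cityOrder <- function(nblocks, cities = 1:3) {
  ord <- integer(0)
  for (b in seq_len(nblocks)) {
    repeat {
      perm <- sample(cities)
      if (length(ord) == 0L || perm[1] != ord[length(ord)]) break
    }
    ord <- c(ord, perm)
  }
  ord
}

# Sample the 15 triads of one spatial run: 9 unequal + 6 equal, forcing at
# least one triad of each sharing class present in the city's pool so every
# between-city similarity condition is populated.
.sampleSpatialRun <- function(pool) {
  pickQuota <- function(sub, n) {
    chosen <- integer(0)
    for (lev in c("three_shared", "two_shared", "unique")) {
      cand <- setdiff(which(sub$sharing == lev), chosen)
      if (length(cand)) chosen <- c(chosen, cand[sample.int(length(cand), 1)])
    }
    chosen <- chosen[seq_len(min(length(chosen), n))]
    rest <- setdiff(seq_len(nrow(sub)), chosen)
    c(chosen, rest[sample.int(length(rest), n - length(chosen))])
  }
  eq <- pool[pool$equality == "equal", ]
  uq <- pool[pool$equality == "unequal", ]
  sel <- rbind(eq[pickQuota(eq, 6L), ], uq[pickQuota(uq, 9L), ])
  sel[sample.int(nrow(sel)), ]
}

#' Generate a retrieval-session trial schedule
#'
#' Builds the 12-run retrieval schedule: one task block of six spatial runs
#' and one of six temporal runs (two runs per city per task), 15 trials per
#' run, 180 trials in total, with 60\% unequal and 40\% equal comparisons.
#' City order is pseudorandomized so that no city is tested twice in a row
#' and each city is tested once before any city repeats.  Spatial triads are
#' sampled from the city's full triad space under the equal/unequal quota
#' with all sharing classes represented; each temporal run presents all 15
#' bottom-store pairs (center store on top) exactly once, which meets the
#' same 9:6 unequal:equal quota.
#'
#' Trials run on the slow event-related timing: a 9 s probe, a 7.77 s active
#' baseline and a 1.36 s fixation gap (18.13 s per trial).
#'
#' @param env a \linkS4class{CityEnvironment}.
#' @param seed integer root seed; the schedule is deterministic given
#'   \code{seed}.
#' @param accuracy probability a trial is retrieved correctly (flag
#'   \code{correct}).
#' @param censor_rate probability a trial is censored for head motion
#'   (framewise displacement above 0.5 mm during the modeled response).
#' @param task_order character vector, which task block comes first.
#' @return data.frame with one row per trial: onset (s, within run),
#'   duration (modeled, s), trial_type, trial, run, run_trial, city, task,
#'   store_top, store_bl, store_br, equality, correct, censored.
#' @examples
#' env <- buildEnvironment()
#' sched <- generateRetrievalSchedule(env, seed = 7)
#' nrow(sched)                      # 180
#' mean(sched$equality == "unequal")  # 0.6
#' @export
generateRetrievalSchedule <- function(env, seed = 1, accuracy = 0.9,
                                      censor_rate = 0.05,
                                      task_order = c("spatial", "temporal")) {
  task_order <- match.arg(task_order, c("spatial", "temporal"),
                          several.ok = TRUE)
  stopifnot(length(task_order) == 2L, !anyDuplicated(task_order))
  .withSeed(.substream(seed, "retrieval-schedule"), {
    cityNames <- names(env@cities)
    ord_all <- .cityOrder(4L, seq_along(cityNames))
    runs <- list()
    run_id <- 0L
    for (task in task_order) {
      ord <- ord_all[if (task == task_order[1]) 1:6 else 7:12]
      for (ci in ord) {
        run_id <- run_id + 1L
        cityName <- cityNames[ci]
        if (task == "spatial") {
          pool <- enumerateSpatialTriads(env, cityName)
          sel <- .sampleSpatialRun(pool)
          tri <- sel[, c("store_top", "store_bl", "store_br", "equality")]
        } else {
          ids <- env@cities[[cityName]]
          pairs <- t(utils::combn(ids, 2))
          flip <- sample(c(TRUE, FALSE), nrow(pairs), replace = TRUE)
          bl <- ifelse(flip, pairs[, 2], pairs[, 1])
          br <- ifelse(flip, pairs[, 1], pairs[, 2])
          dsum <- env@stores$duration_s[match(bl, env@stores$id)] -
            env@stores$duration_s[match(br, env@stores$id)]
          tri <- data.frame(
            store_top = env@center_id, store_bl = bl, store_br = br,
            equality = ifelse(dsum == 0, "equal", "unequal")
          )
          tri <- tri[sample.int(nrow(tri)), ]
        }
        n <- nrow(tri)
        runs[[run_id]] <- data.frame(
          onset = (seq_len(n) - 1) * .TRIAL_LEN,
          duration = .STIM_LEN,
          trial_type = paste0(task, "_retrieval"),
          run = run_id, run_trial = seq_len(n),
          city = ci, task = task,
          tri, row.names = NULL
        )
      }
    }
    sched <- do.call(rbind, runs)
    sched$trial <- seq_len(nrow(sched))
    sched$correct <- stats::runif(nrow(sched)) < accuracy
    sched$censored <- stats::runif(nrow(sched)) < censor_rate
    rownames(sched) <- NULL
    sched
  })
}

# One localizer run ordering: each old store 3x with inter-repetition
# intervals between 2 and 12 trials; found by seeded rejection sampling.
.localizerOrder <- function(old_stores, n_rep = 3L, max_tries = 20000L) {
  for (i in seq_len(max_tries)) {
    ord <- sample(rep(old_stores, n_rep))
    ok <- TRUE
    for (s in old_stores) {
      gaps <- diff(which(ord == s))
      if (any(gaps < 2L | gaps > 12L)) { ok <- FALSE; break }
    }
    if (ok) return(ord)
  }
  stop("could not satisfy localizer inter-repetition constraints")
}

#' Generate a localizer-session trial schedule
#'
#' Two runs of 18 trials.  Each of the six studied ("old") stores (2, 4, 6,
#' 7, 8, 9) appears three times per run, once in each triad position (top,
#' bottom-left, bottom-right), with 2-12 trials between repetitions; the
#' remaining two positions of each triad are filled with unstudied filler
#' stores (ids 101-124).  Trial timing matches the retrieval task.
#'
#' @param env a \linkS4class{CityEnvironment}.
#' @param seed integer root seed.
#' @param old_stores the studied stores that get templates.
#' @param n_fillers number of unstudied filler stores available.
#' @return data.frame in the same shape as [generateRetrievalSchedule()],
#'   with \code{store_old} naming the studied store of each trial and
#'   \code{position} its triad position; \code{city} is \code{NA} (the
#'   localizer is environment-independent).
#' @export
generateLocalizerSchedule <- function(env, seed = 1,
                                      old_stores = c(2L, 4L, 6L, 7L, 8L, 9L),
                                      n_fillers = 24L) {
  stopifnot(all(old_stores %in% env@stores$id))
  fillers <- 100L + seq_len(n_fillers)
  .withSeed(.substream(seed, "localizer-schedule"), {
    runs <- list()
    for (r in 1:2) {
      ord <- .localizerOrder(old_stores)
      pos <- lapply(old_stores, function(s) sample(c("top", "bl", "br")))
      names(pos) <- as.character(old_stores)
      seen <- stats::setNames(rep(0L, length(old_stores)),
                              as.character(old_stores))
      n <- length(ord)
      top <- bl <- br <- integer(n)
      position <- character(n)
      for (i in seq_len(n)) {
        s <- ord[i]
        seen[as.character(s)] <- seen[as.character(s)] + 1L
        p <- pos[[as.character(s)]][seen[as.character(s)]]
        fill <- sample(fillers, 2L)
        trio <- switch(p,
          top = c(s, fill[1], fill[2]),
          bl  = c(fill[1], s, fill[2]),
          br  = c(fill[1], fill[2], s))
        top[i] <- trio[1]; bl[i] <- trio[2]; br[i] <- trio[3]
        position[i] <- p
      }
      runs[[r]] <- data.frame(
        onset = (seq_len(n) - 1) * .TRIAL_LEN,
        duration = .STIM_LEN,
        trial_type = "localizer",
        run = r, run_trial = seq_len(n),
        city = NA_integer_, task = "localizer",
        store_top = top, store_bl = bl, store_br = br,
        store_old = ord, position = position,
        equality = NA_character_
      )
    }
    sched <- do.call(rbind, runs)
    sched$trial <- seq_len(nrow(sched))
    sched$correct <- TRUE
    sched$censored <- FALSE
    rownames(sched) <- NULL
    sched
  })
}
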