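#' Build the three-city overlapping-store environment
#'
#' Constructs the default design: six peripheral stores per city on a circle
#' of radius \code{radius} around a shared center store (id 0) at the
#' origin.  City 1 holds stores \{1..6\}; City 2 is City 1 with store 4
#' replaced by store 7 on the same slot; City 3 is City 2 with stores 2 and
#' 6 replaced by stores 8 and 9.  Hence Cities 1 and 2 share 5 stores,
#' Cities 2 and 3 share 4, Cities 1 and 3 share 3, and stores 1, 3, 5 are
#' common to all three.  Peripheral slots sit at angles \code{(k-1) * 60}
#' degrees, a regular hexagon; travel durations from the center are 8 s for
#' stores 3, 5, 6, 9 and 16 s for stores 1, 2, 4, 7, 8.
#'
#' @param radius circle radius for peripheral stores (length units).
#' @param cities named list of three integer vectors (6 peripheral store ids
#'   each) overriding the default sharing structure.
#' @param slots named integer vector mapping store id to coordinate slot
#'   (1..6); stores replacing another store must reuse its slot so all
#'   cities share the same physical layout.
#' @param durations named numeric vector mapping store id to encoded travel
#'   duration (8 or 16 s).
#' @return A validated \linkS4class{CityEnvironment}.
#' @examples
#' env <- buildEnvironment()
#' length(intersect(env@cities$city1, env@cities$city2))  # 5
#' @export
buildEnvironment <- function(radius = 1,
                             cities = list(
                               city1 = 1:6,
                               city2 = c(1, 2, 3, 5, 6, 7),
                               city3 = c(1, 3, 5, 7, 8, 9)
                             ),
                             slots = c(`1` = 1, `2` = 2, `3` = 3, `4` = 4,
                                       `5` = 5, `6` = 6, `7` = 4, `8` = 2,
                                       `9` = 6),
                             durations = c(`1` = 16, `2` = 16, `3` = 8,
                                           `4` = 16, `5` = 8, `6` = 8,
                                           `7` = 16, `8` = 16, `9` = 8)) {
  ids <- as.integer(names(slots))
  for (nm in names(cities)) {
    cty <- as.integer(cities[[nm]])
    if (length(cty) != 6L || anyDuplicated(cty)) {
      stop("city '", nm, "' must list 6 distinct peripheral store ids")
    }
    if (!all(cty %in% ids)) stop("city '", nm, "' names unknown store ids")
    cities[[nm]] <- cty
  }
  angle <- (slots - 1) * pi / 3
  stores <- data.frame(
    id = c(0L, ids),
    slot = c(0L, as.integer(slots)),
    angle = c(0, angle),
    radius = c(0, rep(radius, length(ids))),
    duration_s = c(NA_real_, as.numeric(durations[as.character(ids)]))
  )
  stores$x <- stores$radius * cos(stores$angle)
  stores$y <- stores$radius * sin(stores$angle)
  env <- new("CityEnvironment", stores = stores, cities = cities,
             center_id = 0L)
  validObject(env)
  env
}

.storeRow <- function(env, id) {
  i <- match(id, env@stores$id)
  if (anyNA(i)) stop("unknown store id: ", paste(id[is.na(i)], collapse = ", "))
  i
}

#' Classify the sharing level of a store or triad
#'
#' A store is attributable to every city containing it; a triad is
#' attributable to a city only if all three of its stores belong to that
#' city.  The sharing level follows the number of attributable cities:
#' \code{unique} (1), \code{two_shared} (2), \code{three_shared} (3).
#' The center store belongs to every city.
#'
#' @param stores integer vector of one store id or the three ids of a triad.
#' @param env a \linkS4class{CityEnvironment}.
#' @return list with \code{level} and \code{attributable_cities} (names of
#'   the cities the store/triad can be attributed to).
#' @examples
#' env <- buildEnvironment()
#' classifySharing(c(1, 4, 5), env)$level       # "unique" (City 1 only)
#' classifySharing(c(1, 3, 5), env)$level       # "three_shared"
#' @export
classifySharing <- function(stores, env) {
  .storeRow(env, stores)  # id check
  stores <- setdiff(as.integer(stores), env@center_id)
  attributable <- names(env@cities)[vapply(
    env@cities, function(cty) all(stores %in% cty), logical(1)
  )]
  n <- length(attributable)
  if (n == 0L) {
    return(list(level = "none", attributable_cities = character(0)))
  }
  level <- c("unique", "two_shared", "three_shared")[n]
  list(level = level, attributable_cities = attributable)
}

#' Spatial-distance index of a triad
#'
#' The behavioral index of a spatial triad: the sum of the two Euclidean
#' distances from the top store to each bottom store, on the environment's
#' coordinate layout.  Invariant to swapping the two bottom stores.
#'
#' @param top,bottom_left,bottom_right store ids (vectors are recycled
#'   elementwise, so whole schedules can be indexed in one call).
#' @param env a \linkS4class{CityEnvironment}.
#' @return numeric distance index (length units).
#' @export
spatialDistanceIndex <- function(top, bottom_left, bottom_right, env) {
  st <- env@stores
  it <- .storeRow(env, top)
  il <- .storeRow(env, bottom_left)
  ir <- .storeRow(env, bottom_right)
  d1 <- sqrt((st$x[it] - st$x[il])^2 + (st$y[it] - st$y[il])^2)
  d2 <- sqrt((st$x[it] - st$x[ir])^2 + (st$y[it] - st$y[ir])^2)
  d1 + d2
}

#' Temporal-interval index of a triad
#'
#' The sum of the encoded travel durations from the center store (always the
#' top store of a temporal triad) to the two bottom stores.  With 8 and 16 s
#' legs the index takes values 16, 24 or 32 s.
#'
#' @param top store id(s); must equal the environment's center store.
#' @param bottom_left,bottom_right peripheral store ids.
#' @param env a \linkS4class{CityEnvironment}.
#' @return numeric interval index (seconds).
#' @export
temporalIntervalIndex <- function(top, bottom_left, bottom_right, env) {
  if (!all(top == env@center_id)) {
    stop("temporal triads must have the center store on top")
  }
  st <- env@stores
  st$duration_s[.storeRow(env, bottom_left)] +
    st$duration_s[.storeRow(env, bottom_right)]
}

#' Enumerate all valid spatial triads of a city
#'
#' Lists every spatial triad (three distinct peripheral stores, one on top)
#' for one city, with its distance index and equality label.  Used both by
#' the schedule generator and as a brute-force oracle for the set of
#' distinct distance-index values realizable on a layout.
#'
#' @param env a \linkS4class{CityEnvironment}.
#' @param city city name (e.g. \code{"city1"}); \code{NULL} pools all
#'   cities (duplicated store-set/top combinations removed across cities
#'   share identical geometry but keep their city label).
#' @param tol numeric tolerance for labeling the two summand distances equal.
#' @return data.frame with columns city, store_top, store_bl, store_br,
#'   dist_index, equality, sharing.
#' @export
enumerateSpatialTriads <- function(env, city = NULL, tol = 1e-9) {
  cities <- if (is.null(city)) names(env@cities) else city
  out <- list()
  st <- env@stores
  for (nm in cities) {
    ids <- env@cities[[nm]]
    if (is.null(ids)) stop("unknown city: ", nm)
    for (top in ids) {
      rest <- setdiff(ids, top)
      pairs <- utils::combn(rest, 2)
      for (k in seq_len(ncol(pairs))) {
        bl <- pairs[1, k]; br <- pairs[2, k]
        i <- .storeRow(env, c(top, bl, br))
        d1 <- sqrt((st$x[i[1]] - st$x[i[2]])^2 + (st$y[i[1]] - st$y[i[2]])^2)
        d2 <- sqrt((st$x[i[1]] - st$x[i[3]])^2 + (st$y[i[1]] - st$y[i[3]])^2)
        out[[length(out) + 1L]] <- data.frame(
          city = nm, store_top = top, store_bl = bl, store_br = br,
          dist_index = d1 + d2,
          equality = if (abs(d1 - d2) < tol) "equal" else "unequal",
          sharing = classifySharing(c(top, bl, br), env)$level
        )
      }
    }
  }
  do.call(rbind, out)
}

#' Write / read schedules as BIDS-style events tables
#'
#' Schedules are exchanged as tab-separated events files with one row per
#' trial (columns: onset, duration, trial_type, run, city, task, store_top,
#' store_bl, store_br, equality, correct, censored), and an environment as a
#' JSON file holding store coordinates, durations and city membership.
#'
#' @param schedule a schedule data.frame from [generateRetrievalSchedule()]
#'   or [generateLocalizerSchedule()].
#' @param path output file path.
#' @return \code{readEventsTsv} returns the schedule data.frame; the writers
#'   return \code{path} invisibly.
#' @export
writeEventsTsv <- function(schedule, path) {
  first <- intersect(c("onset", "duration", "trial_type"), names(schedule))
  cols <- c(first, setdiff(names(schedule), first))
  utils::write.table(schedule[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeEventsTsv
#' @export
readEventsTsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' @rdname writeEventsTsv
#' @param env a \linkS4class{CityEnvironment}.
#' @export
writeEnvironmentJson <- function(env, path) {
  jsonlite::write_json(
    list(stores = env@stores, cities = env@cities,
         center_id = env@center_id),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname writeEventsTsv
#' @export
readEnvironmentJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("CityEnvironment", stores = as.data.frame(x$stores),
      cities = lapply(x$cities, as.integer),
      center_id = as.integer(x$center_id))
}
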