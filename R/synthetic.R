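#' Effect specification for the synthetic-data generator
#'
#' Collects the latent effect strengths the analyses are designed to
#' recover, each planted independently into simulated trial patterns:
#'
#' \describe{
#'   \item{eta_holistic}{reinstatement strength of a city's unpresented
#'     unique stores into that city's trial patterns (unitless, >= 0).}
#'   \item{rho_shared}{target correlation between a shared store's neural
#'     code across the cities sharing it; positive = shared code, ~0 =
#'     pattern separation, negative = repulsion.  Imposed exactly on the
#'     sampled vectors (see [makeStoreCodes()]).  A length-2 vector sets
#'     separate correlations for two-shared and three-shared stores.}
#'   \item{beta_schema}{linear gain of a distance-index code common to all
#'     cities (pattern units per length unit), carried only by regions
#'     simulated with \code{schema = TRUE}.}
#'   \item{gamma_city}{strength of an additive city-identity code.}
#'   \item{kappa_interval}{strength of a temporal-interval class code;
#'     \code{interval_shared} chooses whether that code generalizes across
#'     cities or is city-specific.}
#'   \item{lambda_slot}{strength of a coordinate-slot code shared across
#'     cities (drives same-location vs different-location similarity).}
#'   \item{sigma_noise}{per-trial voxel noise SD at the reference tSNR;
#'     per-voxel noise scales inversely with that voxel's tSNR.}
#'   \item{tsnr_meanlog, tsnr_sdlog}{lognormal parameters of the per-voxel
#'     tSNR distribution.}
#' }
#'
#' @param eta_holistic,rho_shared,beta_schema,gamma_city,kappa_interval,lambda_slot,sigma_noise numeric effect strengths, see Details.
#' @param interval_shared logical; does the interval code generalize across
#'   cities?
#' @param tsnr_meanlog,tsnr_sdlog lognormal tSNR profile.
#' @return list of class \code{"EffectSpec"}.
#' @export
effectSpec <- function(eta_holistic = 0, rho_shared = 0, beta_schema = 0,
                       gamma_city = 0, kappa_interval = 0,
                       interval_shared = TRUE, lambda_slot = 0,
                       sigma_noise = 1, tsnr_meanlog = log(40),
                       tsnr_sdlog = 0.3) {
  if (!length(rho_shared) %in% 1:2 || any(rho_shared < -1 | rho_shared > 1)) {
    stop("rho_shared must be one or two values in [-1, 1]")
  }
  stopifnot(eta_holistic >= 0, beta_schema >= 0, gamma_city >= 0,
            kappa_interval >= 0, lambda_slot >= 0, sigma_noise >= 0)
  structure(
    list(eta_holistic = eta_holistic, rho_shared = rho_shared,
         beta_schema = beta_schema, gamma_city = gamma_city,
         kappa_interval = kappa_interval, interval_shared = interval_shared,
         lambda_slot = lambda_slot, sigma_noise = sigma_noise,
         tsnr_meanlog = tsnr_meanlog, tsnr_sdlog = tsnr_sdlog),
    class = "EffectSpec"
  )
}

# n mean-zero, unit-sd vectors with exact pairwise correlation rho:
# an orthonormal mean-zero basis (QR of centered Gaussians) rotated by the
# Cholesky factor of the target Gram matrix, so the empirical correlation
# matrix equals the target exactly (no Monte-Carlo slack).
.exactCorrVectors <- function(n_neurons, m, rho) {
  Z <- matrix(stats::rnorm(n_neurons * m), n_neurons, m)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(Z))
  if (abs(rho - 1) < 1e-12) {
    V <- Q[, rep(1L, m), drop = FALSE]
  } else {
    if (m > 1 && rho <= -1 / (m - 1) + 1e-12) {
      stop("rho_shared = ", rho, " is not achievable for a store shared by ",
           m, " cities (must exceed ", round(-1 / (m - 1), 4), ")")
    }
    G <- matrix(rho, m, m); diag(G) <- 1
    V <- Q %*% chol(G)
  }
  V * sqrt(n_neurons - 1)
}

.stdVec <- function(n) as.numeric(scale(stats::rnorm(n)))

#' Latent neural codes for stores, cities, slots and indices
#'
#' Samples the per-(store, city) latent neuron vectors that drive the
#' simulation.  A store unique to one city gets one vector; a store shared
#' by several cities gets one vector per city with their pairwise
#' correlation equal to \code{rho_shared} exactly.  Distinct stores' vectors
#' are independent draws (near-orthogonal in expectation).  Also samples the
#' auxiliary codes: per-city identity vectors, a distance-index (schema)
#' direction, per-slot location vectors and temporal-interval class vectors.
#'
#' @param env a \linkS4class{CityEnvironment}.
#' @param effect an [effectSpec()].
#' @param n_neurons latent neuron count per region.
#' @param seed integer root seed.
#' @return list of class \code{"StoreCodes"} with elements \code{store}
#'   (list store id -> list city -> neuron vector), \code{identity} (list
#'   store id -> city-averaged identity vector used for localizer
#'   templates), \code{city}, \code{schema}, \code{slot}, \code{interval},
#'   plus \code{n_neurons} and the generating \code{effect}.
#' @export
makeStoreCodes <- function(env, effect = effectSpec(), n_neurons = 200,
                           seed = 1) {
  .withSeed(.substream(seed, "store-codes"), {
    periph <- setdiff(env@stores$id, env@center_id)
    store <- list(); identity <- list()
    for (s in periph) {
      in_cities <- names(env@cities)[vapply(env@cities, function(x) s %in% x,
                                            logical(1))]
      m <- length(in_cities)
      rho <- effect$rho_shared
      if (length(rho) == 2L && m > 1L) rho <- rho[m - 1L]
      V <- if (m == 1L) {
        matrix(.stdVec(n_neurons), ncol = 1)
      } else {
        .exactCorrVectors(n_neurons, m, rho[1])
      }
      colnames(V) <- in_cities
      store[[as.character(s)]] <- lapply(stats::setNames(in_cities, in_cities),
                                         function(cn) V[, cn])
      idv <- rowMeans(V)
      identity[[as.character(s)]] <- if (stats::sd(idv) > 0) {
        as.numeric(scale(idv))
      } else .stdVec(n_neurons)
    }
    # center store: one vector common to all cities
    ctr <- .stdVec(n_neurons)
    store[[as.character(env@center_id)]] <- lapply(
      stats::setNames(names(env@cities), names(env@cities)), function(cn) ctr)
    identity[[as.character(env@center_id)]] <- ctr

    city <- lapply(stats::setNames(names(env@cities), names(env@cities)),
                   function(cn) .stdVec(n_neurons))
    slot <- lapply(stats::setNames(1:6, paste0("slot", 1:6)),
                   function(k) .stdVec(n_neurons))
    interval_levels <- c("16", "24", "32")
    interval <- if (isTRUE(effect$interval_shared)) {
      lapply(stats::setNames(interval_levels, interval_levels),
             function(k) .stdVec(n_neurons))
    } else {
      lapply(stats::setNames(names(env@cities), names(env@cities)),
             function(cn) lapply(stats::setNames(interval_levels,
                                                 interval_levels),
                                 function(k) .stdVec(n_neurons)))
    }
    structure(
      list(store = store, identity = identity, city = city,
           schema = .stdVec(n_neurons), slot = slot, interval = interval,
           n_neurons = n_neurons, effect = effect),
      class = "StoreCodes"
    )
  })
}

#' Nonnegative neuron-to-voxel mixing map
#'
#' Each voxel pools a random nonnegative combination of latent neurons
#' (gamma-distributed weights, so every voxel pools every neuron with
#' strictly positive weight), with columns normalized to unit length.  This
#' is the bridge used to ask whether separation/repulsion imposed at the
#' neuron level survives aggregation into voxel-level patterns.
#'
#' @param n_neurons,n_voxels dimensions of the map.
#' @param seed integer seed.
#' @param shape gamma shape of the weights; smaller values make pooling
#'   sparser and more heterogeneous.
#' @return list of class \code{"NeuronToVoxelMap"} with the weights matrix
#'   (neurons x voxels).
#' @export
neuronToVoxelMap <- function(n_neurons = 200, n_voxels = 100, seed = 1,
                             shape = 1) {
  .withSeed(.substream(seed, "neuron-voxel-map"), {
    W <- matrix(stats::rgamma(n_neurons * n_voxels, shape = shape),
                n_neurons, n_voxels)
    W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
    structure(list(weights = W, n_neurons = n_neurons, n_voxels = n_voxels),
              class = "NeuronToVoxelMap")
  })
}

# Neuron-space signal for one retrieval trial row.
.trialNeuronSignal <- function(row, codes, env, effect, D_centered,
                               schema, slots, interval) {
  cityName <- names(env@cities)[row$city]
  trio <- c(row$store_top, row$store_bl, row$store_br)
  sig <- 0
  # the center store is identical in every environment and present in every
  # temporal trial; its code is a constant that carries no condition
  # information but would unbalance pair conditions through task
  # composition, so it contributes no signal
  for (s in setdiff(trio, env@center_id)) {
    v <- codes$store[[as.character(s)]][[cityName]]
    if (is.null(v)) v <- codes$identity[[as.character(s)]]
    sig <- sig + v
  }
  if (effect$eta_holistic > 0) {
    cty <- env@cities[[cityName]]
    uniq <- cty[vapply(cty, function(s)
      classifySharing(s, env)$level == "unique", logical(1))]
    for (s in setdiff(uniq, trio)) {
      sig <- sig + effect$eta_holistic *
        codes$store[[as.character(s)]][[cityName]]
    }
  }
  if (effect$gamma_city > 0) sig <- sig + effect$gamma_city * codes$city[[cityName]]
  if (schema && effect$beta_schema > 0 && row$task == "spatial") {
    sig <- sig + effect$beta_schema * D_centered * codes$schema
  }
  if (slots && effect$lambda_slot > 0) {
    sl <- env@stores$slot[match(trio, env@stores$id)]
    for (k in sl[sl > 0]) {
      sig <- sig + effect$lambda_slot * codes$slot[[paste0("slot", k)]]
    }
  }
  if (interval && effect$kappa_interval > 0 && row$task == "temporal") {
    Tlev <- as.character(temporalIntervalIndex(row$store_top, row$store_bl,
                                               row$store_br, env))
    v <- if (isTRUE(effect$interval_shared)) codes$interval[[Tlev]] else
      codes$interval[[cityName]][[Tlev]]
    sig <- sig + effect$kappa_interval * v
  }
  sig
}

.sampleTSNR <- function(n_voxels, effect) {
  stats::rlnorm(n_voxels, effect$tsnr_meanlog, effect$tsnr_sdlog)
}

.addVoxelNoise <- function(signal, tsnr, effect) {
  # lower-tSNR voxels get proportionally more noise; the median-tSNR voxel
  # gets sd = sigma_noise
  sdv <- effect$sigma_noise * stats::median(tsnr) / tsnr
  signal + matrix(stats::rnorm(length(signal), sd = rep(sdv, each = nrow(signal))),
                  nrow(signal), ncol(signal))
}

#' Simulate single-trial voxel patterns for a retrieval schedule
#'
#' Composes, per trial, the planted neuron-space signal (presented store
#' codes, holistic reinstatement of unpresented unique stores, a city
#' code, and optionally schema-distance, slot-location and interval codes),
#' mixes it into voxel space through a nonnegative neuron-to-voxel map, and
#' adds Gaussian voxel noise scaled inversely by each voxel's tSNR.
#'
#' @param schedule retrieval schedule from [generateRetrievalSchedule()].
#' @param codes a \code{StoreCodes} object from [makeStoreCodes()].
#' @param map a [neuronToVoxelMap()]; its neuron count must match
#'   \code{codes}.
#' @param effect the [effectSpec()] (defaults to the one stored in
#'   \code{codes}).
#' @param env the \linkS4class{CityEnvironment} the schedule was built for.
#' @param seed integer seed for noise and tSNR draws.
#' @param roiName region label.
#' @param schema,slots,interval logicals: does this region carry the
#'   schema-distance, slot-location, interval codes?  (The schema code is
#'   planted only in designated "schema" regions, mirroring a
#'   prefrontal-but-not-hippocampal distance code.)
#' @return A \linkS4class{PatternSet} (trials x voxels).
#' @export
simulateTrialPatterns <- function(schedule, codes, map, env,
                                  effect = codes$effect, seed = 1,
                                  roiName = "ROI", schema = FALSE,
                                  slots = FALSE, interval = FALSE) {
  stopifnot(inherits(codes, "StoreCodes"), inherits(map, "NeuronToVoxelMap"))
  if (map$n_neurons != codes$n_neurons) {
    stop("map and codes disagree on neuron count")
  }
  .withSeed(.substream(seed, paste0("trial-patterns-", roiName)), {
    D <- rep(NA_real_, nrow(schedule))
    sp <- schedule$task == "spatial"
    if (any(sp)) {
      D[sp] <- spatialDistanceIndex(schedule$store_top[sp],
                                    schedule$store_bl[sp],
                                    schedule$store_br[sp], env)
      D[sp] <- D[sp] - mean(D[sp])
    }
    neuron <- matrix(0, nrow(schedule), codes$n_neurons)
    for (i in seq_len(nrow(schedule))) {
      neuron[i, ] <- .trialNeuronSignal(schedule[i, ], codes, env, effect,
                                        D[i], schema, slots, interval)
    }
    vox <- neuron %*% map$weights
    tsnr <- .sampleTSNR(ncol(vox), effect)
    vox <- .addVoxelNoise(vox, tsnr, effect)
    PatternSet(vox, schedule, voxelTSNR = tsnr, roiName = roiName)
  })
}

#' Simulate localizer voxel patterns
#'
#' Localizer trials carry the environment-independent identity code of the
#' studied store plus independent codes for the two unstudied filler stores,
#' mixed to voxels and noised exactly as retrieval trials are.  Templates
#' built from these patterns probe store identity without city information.
#'
#' @inheritParams simulateTrialPatterns
#' @param schedule localizer schedule from [generateLocalizerSchedule()].
#' @return A \linkS4class{PatternSet}.
#' @export
simulateLocalizerPatterns <- function(schedule, codes, map,
                                      effect = codes$effect, seed = 1,
                                      roiName = "ROI") {
  stopifnot(inherits(codes, "StoreCodes"), inherits(map, "NeuronToVoxelMap"))
  .withSeed(.substream(seed, paste0("localizer-patterns-", roiName)), {
    fillers <- sort(unique(c(schedule$store_top, schedule$store_bl,
                             schedule$store_br)))
    fillers <- fillers[fillers > 100L]
    fcodes <- lapply(stats::setNames(fillers, fillers),
                     function(s) .stdVec(codes$n_neurons))
    neuron <- matrix(0, nrow(schedule), codes$n_neurons)
    for (i in seq_len(nrow(schedule))) {
      trio <- c(schedule$store_top[i], schedule$store_bl[i],
                schedule$store_br[i])
      for (s in trio) {
        v <- if (s > 100L) fcodes[[as.character(s)]] else
          codes$identity[[as.character(s)]]
        neuron[i, ] <- neuron[i, ] + v
      }
    }
    vox <- neuron %*% map$weights
    tsnr <- .sampleTSNR(ncol(vox), effect)
    vox <- .addVoxelNoise(vox, tsnr, effect)
    PatternSet(vox, schedule, voxelTSNR = tsnr, roiName = roiName)
  })
}

#' Simulate run-level patterns for city classification
#'
#' Produces the 12 run-level t-maps (four runs per city: two tasks times two
#' runs) as a city-identity code of strength \code{gamma_city} plus Gaussian
#' noise.  With \code{gamma_city = 0} the maps contain no city information
#' and the city classifier is calibrated at its 1/3 chance level.
#'
#' @param env a \linkS4class{CityEnvironment}.
#' @param effect an [effectSpec()]; only \code{gamma_city},
#'   \code{sigma_noise} and the tSNR profile are used.
#' @param n_voxels voxels per run map.
#' @param seed integer seed.
#' @param codes optional \code{StoreCodes} whose city codes should be reused
#'   (sampled fresh when \code{NULL}, in voxel space directly).
#' @param map optional [neuronToVoxelMap()] used with \code{codes}.
#' @return A \linkS4class{PatternSet} with 12 rows and trialData columns
#'   \code{run}, \code{city}, \code{task}.
#' @export
simulateRunPatterns <- function(env, effect = effectSpec(), n_voxels = 100,
                                seed = 1, codes = NULL, map = NULL) {
  .withSeed(.substream(seed, "run-patterns"), {
    meta <- data.frame(
      run = 1:12,
      city = rep(rep(seq_along(env@cities), each = 2), 2),
      task = rep(c("spatial", "temporal"), each = 6),
      correct = TRUE, censored = FALSE
    )
    if (!is.null(codes)) {
      stopifnot(!is.null(map))
      cityvox <- vapply(names(env@cities),
                        function(cn) as.numeric(codes$city[[cn]] %*% map$weights),
                        numeric(map$n_voxels))
      n_voxels <- map$n_voxels
    } else {
      cityvox <- matrix(stats::rnorm(n_voxels * length(env@cities)),
                        n_voxels, length(env@cities))
      cityvox <- scale(cityvox)
    }
    tsnr <- .sampleTSNR(n_voxels, effect)
    sig <- effect$gamma_city * t(cityvox[, meta$city, drop = FALSE])
    vox <- .addVoxelNoise(sig, tsnr, effect)
    PatternSet(vox, meta, voxelTSNR = tsnr, roiName = "run-maps")
  })
}
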