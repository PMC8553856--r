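# Shared fixtures, built once per test file and cached.
.fx <- new.env()

fxEnv <- function() {
  if (is.null(.fx$env)) .fx$env <- buildEnvironment()
  .fx$env
}

fxSchedule <- function(seed = 11) {
  key <- paste0("sched", seed)
  if (is.null(.fx[[key]])) .fx[[key]] <- generateRetrievalSchedule(fxEnv(),
                                                                  seed = seed)
  .fx[[key]]
}

fxLocalizer <- function(seed = 11) {
  key <- paste0("loc", seed)
  if (is.null(.fx[[key]])) .fx[[key]] <- generateLocalizerSchedule(fxEnv(),
                                                                  seed = seed)
  .fx[[key]]
}

# One simulated subject: retrieval + localizer patterns for one region.
fxSubject <- function(seed, effect, schema = FALSE, slots = FALSE,
                      interval = FALSE, roiName = "ROI") {
  env <- fxEnv()
  codes <- makeStoreCodes(env, effect, seed = seed)
  map <- neuronToVoxelMap(seed = seed)
  sched <- fxSchedule()
  loc <- fxLocalizer()
  list(
    codes = codes, map = map,
    retrieval = simulateTrialPatterns(sched, codes, map, env, seed = seed,
                                      roiName = roiName, schema = schema,
                                      slots = slots, interval = interval),
    localizer = simulateLocalizerPatterns(loc, codes, map, seed = seed,
                                          roiName = roiName)
  )
}
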