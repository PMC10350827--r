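# shared fixtures: small cohorts and fitted models are expensive, build once

.unitVolumeVector <- function() {
    v <- setNames(rep(1, 19), segmentNames())
    c(v, ecsf = 3, lateral_ventricles = 2)
}

.randomVolumeVector <- function(seed = 1) {
    set.seed(seed)
    v <- setNames(runif(19, 1, 60), segmentNames())
    c(v, ecsf = runif(1, 10, 60), lateral_ventricles = runif(1, 1, 6),
      unlabeled_intracranial = runif(1, 0, 2))
}

# brute-force all-pairs dominance oracle, shared by several files
bruteCliffs <- function(x, y) {
    gt <- 0; lt <- 0
    for (xi in x) for (yj in y) {
        if (xi > yj) gt <- gt + 1
        if (xi < yj) lt <- lt + 1
    }
    (gt - lt) / (length(x) * length(y))
}

# module-level cache so several test files can share one fitted model
.fixtureEnv <- new.env(parent = emptyenv())

fixtureControls <- function(n = 220, seed = 101) {
    key <- paste0("controls_", n, "_", seed)
    if (is.null(.fixtureEnv[[key]]))
        .fixtureEnv[[key]] <- generateControls(cohortSpec(n = n, seed = seed))
    .fixtureEnv[[key]]
}

fixtureModel <- function(measure = "cerebellum", n = 220, seed = 101,
                         restarts = 3L) {
    key <- paste0("model_", measure, "_", n, "_", seed)
    if (is.null(.fixtureEnv[[key]]))
        .fixtureEnv[[key]] <- fitNormative(fixtureControls(n, seed),
                                           measure = measure, seed = seed,
                                           restarts = restarts)
    .fixtureEnv[[key]]
}
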