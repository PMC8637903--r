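# Heavy phantom-study runs shared across acceptance tests, computed once per
# session. Frame counts are reduced relative to the full protocols so the
# whole suite stays desk-sized; the studies themselves are defined by
# studyConfig().
.runCache <- new.env(parent = emptyenv())

acceptanceRun <- function(name) {
  if (!is.null(.runCache[[name]])) return(.runCache[[name]])
  cfg <- switch(name,
    dense = studyConfig("two_tube_dense", seed = 11),
    sparse = studyConfig("two_tube_sparse", seed = 11, nFrames = 150),
    ladder = studyConfig("depth_ladder", seed = 11, nFrames = 80))
  .runCache[[name]] <- runPipeline(cfg)
  .runCache[[name]]
}
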