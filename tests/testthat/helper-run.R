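# One default pipeline run (and its dataset) shared across test files.
# Built lazily on first use and memoised for the session.
.run_cache <- new.env(parent = emptyenv())

default_run <- function() {
  if (is.null(.run_cache$run)) {
    dir <- file.path(tempdir(), "paleoplastid-default-run")
    .run_cache$run <- run_pipeline(list(seed = 1L, outdir = dir))
    .run_cache$outdir <- dir
  }
  .run_cache$run
}

default_run_outdir <- function() {
  invisible(default_run())
  .run_cache$outdir
}

default_dataset <- function() default_run()$dataset
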