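# Named random streams derived from one master seed.
#
# Scenario comparisons rely on common random numbers: baseline and
# intervention runs must share profile sampling, outcome uniforms and
# parameter draws, while intervention/medication assignment uniforms are
# pre-drawn per person so a scenario can never perturb another stream.
# Each named stream gets its own 32-bit seed derived deterministically
# from the master seed.

.STREAM_OFFSETS <- c(profile = 11L, outcome = 23L, intervention = 37L,
                     medication = 53L, params = 71L, trend = 89L)

stream_seed <- function(master_seed, stream, run = 0L) {
  off <- .STREAM_OFFSETS[[stream]]
  # keep everything well inside 2^31
  as.integer((as.double(master_seed) * 7919 + off * 104729 +
                as.double(run) * 15485863) %% 2147483629)
}

with_stream <- function(master_seed, stream, expr, run = 0L) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(stream_seed(master_seed, stream, run))
  expr
}
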