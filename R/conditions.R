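# Classed conditions so callers can branch on failure mode rather than
# matching message text. All abort conditions inherit from "venoxim_error".

stop_venoxim <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "venoxim_error"),
                      call = call))
}

stop_invalid_input <- function(message) {
  stop_venoxim(message, "venoxim_invalid_input")
}

stop_config <- function(message) {
  stop_venoxim(message, "venoxim_config_error")
}

stop_insufficient_data <- function(message) {
  stop_venoxim(message, "venoxim_insufficient_data")
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}
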