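# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a temporarily fixed RNG state; restores the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

stop_mds <- function(..., class = "mdsrisk_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

warn_mds <- function(..., class = "mdsrisk_warning") {
  warning(structure(class = c(class, "warning", "condition"),
                    list(message = paste0(...), call = sys.call(-1))))
}

# Path to a shipped configuration file.
mds_config_path <- function(file) {
  p <- system.file("extdata", "config", file, package = "mdsrisk")
  if (!nzchar(p)) stop_mds("config file not found: ", file)
  p
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x == floor(x)

round1 <- function(x) round(x, 1)
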