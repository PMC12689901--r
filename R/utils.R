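## internal helpers shared across modules

## substring by character offsets, 0-based half-open (the Doccano convention)
slice_text <- function(text, start, end) {
  substr(rep_len(text, length(start)), start + 1L, end)
}

upfirst <- function(x) {
  has <- nchar(x) > 0L
  x[has] <- paste0(toupper(substr(x[has], 1L, 1L)), substring(x[has], 2L))
  x
}

## run code under a fixed seed without disturbing the caller's RNG stream
with_preserved_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
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
  force(code)
}

## stable md5 of an arbitrary configuration object, used to stamp outputs
config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(
    jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE, null = "null"),
    tf, useBytes = TRUE
  )
  unname(tools::md5sum(tf))
}

## condition constructors: validation problems exit 1, I/O problems exit 2
stop_validation <- function(msg, ...) {
  abort(msg, class = "clinspan_validation_error", ...)
}
stop_io <- function(msg, ...) {
  abort(msg, class = "clinspan_io_error", ...)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_validation(sprintf("`%s` must be a single number in [0, 1], got %s",
                            name, paste(format(x), collapse = ", ")))
  }
  as.numeric(x)
}
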