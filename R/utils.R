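#' @keywords internal
"_PACKAGE"

# Event coding used throughout: 0 = censored, 1 = death, 2 = transplant.
EVENT_CENSORED <- 0L
EVENT_DEATH <- 1L
EVENT_TRANSPLANT <- 2L
EVENT_NAMES <- c("death", "transplant")

#' Resolve an event identifier
#'
#' Accepts the integer codes 1 (death) / 2 (transplant) or the strings
#' `"death"` / `"transplant"` and returns the integer code.
#'
#' @param event event id as integer or name.
#' @return integer, 1 or 2.
#' @keywords internal
resolve_event <- function(event) {
  if (is.character(event)) {
    idx <- match(match.arg(event, EVENT_NAMES), EVENT_NAMES)
    return(as.integer(idx))
  }
  event <- as.integer(event)
  if (!event %in% c(EVENT_DEATH, EVENT_TRANSPLANT)) {
    stop("unknown event id: ", event, " (expected 1/death or 2/transplant)",
         call. = FALSE)
  }
  event
}

# Deterministic per-stage seed stream: one master seed fans out into
# independent 31-bit stage seeds so that stages can be re-run in isolation.
derive_seeds <- function(master_seed, n) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Run expr under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Small stable string hash (FNV-style, 31-bit) for feature-schema checks.
schema_hash <- function(feature_names) {
  bytes <- utf8ToInt(paste(feature_names, collapse = "\x1f"))
  h <- 0
  for (b in bytes) {
    h <- (bitwXor(as.integer(h), as.integer(b)) * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
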