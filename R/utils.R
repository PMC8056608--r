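#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules. Images are represented throughout as
# numeric matrices (single channel) or H x W x C arrays with intensities on
# [0, 1]; 16-bit files are mapped onto that scale at I/O time.

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# population (not sample) moments -- the image-processing convention used by
# every statistic in this package
pop_var <- function(x) mean((x - mean(x))^2)
pop_sd <- function(x) sqrt(pop_var(x))

#' Derive a stage-specific seed from a global seed
#'
#' Stable fan-out of one user-facing seed into independent per-stage /
#' per-field streams, so that e.g. changing the blur setting of a field does
#' not perturb its noise draw. The derivation is a fixed integer hash kept
#' below 2^31.
#'
#' @param seed integer global seed.
#' @param tag character tag naming the consumer (e.g. `"noise"`, `"field3"`).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- as.double(seed) %% 2147483647
  for (b in utf8ToInt(as.character(tag))) {
    h <- (h * 69069 + b) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

stop_phenoscreen <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)

# channel accessor for field images
field_channel <- function(field, role) {
  stopifnot(inherits(field, "field_image"))
  i <- match(role, field$roles)
  if (is.na(i)) {
    stop_phenoscreen("field '", field$id, "' has no channel with role '", role,
                     "' (available: ", paste(field$roles, collapse = ", "), ")")
  }
  field$channels[, , i]
}
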