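#' @importFrom rlang abort warn .data
#' @importFrom stats median mad quantile optim rpois rgeom runif rbinom plogis
#'   qlogis pnorm setNames lm.wfit complete.cases sd
#' @importFrom utils head combn modifyList
NULL

SECONDS_PER_DAY <- 86400

ARM_LEVELS <- c("select", "difficulty", "random")

#' Derive a reproducible sub-seed from a root seed and a label
#'
#' All randomness in the package flows from one root seed through named
#' substreams, so that individual components (arm assignment, session
#' arrivals, recall draws, per-learner policy streams) can be re-run or
#' varied independently. The derivation is a small FNV-1a style hash of the
#' label folded into the root seed, reduced modulo 2^31 - 1.
#'
#' @param seed integer root seed.
#' @param label character label naming the substream (e.g. `"arrivals"`,
#'   or a learner id for per-learner policy streams).
#' @return an integer in `[1, 2^31 - 1]` usable with [set.seed()].
#' @export
#' @examples
#' substream_seed(1, "arrivals")
#' substream_seed(1, "learner-0007")
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 2166136261 %% 2147483647
  for (byte in utf8ToInt(paste0(label, ":", seed))) {
    low <- h %% 256
    h <- ((h - low + bitwXor(as.integer(low), as.integer(byte))) *
            16777619) %% 2147483647
  }
  as.integer(h %% 2147483646 + 1)
}

#' Stable content hash for provenance records
#'
#' A dependency-free FNV-1a hash of a character string, printed as 8 hex
#' digits. Used to stamp output artifacts with the configuration that
#' produced them; not cryptographic.
#'
#' @param x character scalar.
#' @return 8-character hex string.
#' @keywords internal
fnv1a_hash <- function(x) {
  h <- 2166136261
  for (byte in utf8ToInt(x)) {
    low <- h %% 256
    h <- ((h - low + bitwXor(as.integer(low), as.integer(byte))) *
            16777619) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (strict_lower && x <= lower) {
    abort(sprintf("`%s` must be > %s", name, format(lower)))
  }
  if (!strict_lower && x < lower) {
    abort(sprintf("`%s` must be >= %s", name, format(lower)))
  }
  if (x > upper) {
    abort(sprintf("`%s` must be <= %s", name, format(upper)))
  }
  invisible(x)
}
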