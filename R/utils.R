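#' @keywords internal
"_PACKAGE"

# logical-matrix helpers shared across modules

as_binary_matrix <- function(x, what = "mask") {
  if (is.logical(x)) {
    m <- x
  } else if (is.numeric(x)) {
    m <- x > 0
  } else {
    stop(sprintf("%s must be a logical or numeric matrix", what), call. = FALSE)
  }
  if (!is.matrix(m)) stop(sprintf("%s must be a matrix", what), call. = FALSE)
  storage.mode(m) <- "logical"
  m[is.na(m)] <- FALSE
  m
}

check_spacing <- function(spacing_mm) {
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 2)
  if (length(spacing_mm) != 2 || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("pixel spacing must be one or two positive values (mm/pixel)", call. = FALSE)
  spacing_mm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stable hexadecimal hash of an R object
#'
#' FNV-1a hash of the object's canonical JSON serialization. Used to stamp
#' every study output with the configuration that produced it, so stages can
#' check lineage without re-reading configs.
#'
#' @param x an R object (typically a config list)
#' @return a character scalar of 8 hex digits
#' @export
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte (b < 256); keep h in double precision
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # FNV prime multiplication mod 2^32, split to stay within exact doubles
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# deterministic sub-seed derivation so that stages consuming the same global
# seed do not share RNG streams
derive_seed <- function(seed, tag) {
  bytes <- utf8ToInt(tag)
  h <- (seed %% 2147483647)
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
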