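# Internal helpers: deterministic seed derivation, scoped RNG, validation.

MOD31 <- 2147483647  # 2^31 - 1

#' Derive a reproducible sub-seed from a master seed and a key sequence
#'
#' Mixes the master seed with an arbitrary sequence of integer, numeric,
#' date or character keys using a Lehmer-style multiplicative congruential
#' step modulo 2^31 - 1. Used to give every simulated day, donor and
#' replicate its own reproducible random-number substream, so that
#' composing steps (e.g. advancing the waiting list in two calls rather
#' than one) and distributing replicates over workers cannot change
#' results.
#'
#' @param seed master seed (integer).
#' @param ... keys; characters are hashed bytewise, dates via their day
#'   number.
#' @return an integer in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, ...) {
  h <- (abs(as.numeric(seed)) %% MOD31)
  for (key in list(...)) {
    if (inherits(key, "Date")) key <- as.integer(key)
    if (is.character(key)) key <- utf8ToInt(paste(key, collapse = "\x1f"))
    for (k in as.numeric(key)) {
      h <- (h * 48271 + (abs(k) %% MOD31) + 1) %% MOD31
    }
  }
  as.integer(h %% (MOD31 - 2) + 1)
}

# Evaluate expr under a given seed without disturbing the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# stopifnot with a formatted message
kap_assert <- function(ok, ..., class = "kap_error") {
  if (!isTRUE(ok)) {
    stop(errorCondition(sprintf(...), class = c(class, "error")))
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

BLOOD_GROUPS <- c("O", "A", "B", "AB")
STATES <- c("NSW", "ACT", "VIC", "TAS", "WA", "SA", "NT", "QLD")
CENTRES <- c("NSW/ACT", "QLD", "SA/NT", "VIC/TAS", "WA")

AGE_BAND_BREAKS <- c(-Inf, 18, 45, 65, Inf)
AGE_BAND_LABELS <- c("<18", "18-44", "45-64", "65+")

#' Age band used for stratification
#'
#' Bands are `<18`, `18-44`, `45-64`, `65+`; the pediatric cut matches the
#' under-18 definition used throughout the allocation model.
#' @param age numeric vector of ages in years.
#' @return factor with the four band levels.
#' @export
age_band <- function(age) {
  cut(age, breaks = AGE_BAND_BREAKS, labels = AGE_BAND_LABELS, right = FALSE)
}

PRA_BAND_LABELS <- c("0", "1-20", "21-50", "51-80", "81-100")

#' PRA sensitization band used for stratification
#'
#' Unsensitized candidates (PRA exactly 0) form their own band; the rest
#' are split at 20, 50 and 80 percent.
#' @param pra numeric vector of panel-reactive antibody percentages (0-100).
#' @return factor with five band levels.
#' @export
pra_band <- function(pra) {
  out <- cut(pra, breaks = c(0, 20, 50, 80, 100),
             labels = PRA_BAND_LABELS[-1], include.lowest = TRUE)
  out <- factor(ifelse(pra == 0, "0", as.character(out)),
                levels = PRA_BAND_LABELS)
  out
}
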