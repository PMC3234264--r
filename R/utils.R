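# Internal helpers shared across modules.

#' Run code with a temporarily-seeded RNG
#'
#' Seeds the global RNG, runs `code`, and restores the previous RNG state so
#' that library calls do not perturb a caller's random stream.
#'
#' @param seed integer scalar seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
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
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific 31-bit sub-seed from a master seed.
sub_seed <- function(seed, k) {
  (as.integer(seed) * 48271L + as.integer(k) * 7919L) %% 2147483647L
}

stopifnot_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must be a probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

# Genotype call vocabulary used throughout the package.
GENO_LEVELS <- c("AA", "AB", "BB", "FAILED")

check_calls <- function(calls) {
  bad <- !(calls %in% GENO_LEVELS)
  if (any(bad)) {
    stop("invalid genotype call(s): ",
         paste(utils::head(unique(calls[bad]), 5), collapse = ", "),
         call. = FALSE)
  }
  invisible(calls)
}

# Column-wise cumulative sum mod 2 of a 0/1 matrix, looping over the (short)
# row dimension so the vectorized work is over columns.
col_cumsum_mod2 <- function(m) {
  out <- m
  if (nrow(m) < 2L) return(out)
  cur <- m[1L, ]
  for (i in 2L:nrow(m)) {
    cur <- (cur + m[i, ]) %% 2L
    out[i, ] <- cur
  }
  out
}
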