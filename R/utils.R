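#' @importFrom stats rbinom rgeom rlnorm rmultinom runif rnorm median
#' @importFrom utils read.delim write.table head modifyList
NULL

DNA_ALPHABET <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child RNG seed from a master seed
#'
#' All stochastic stages of the pipeline draw their seeds through this
#' helper so that one master seed fixes every random choice while stages
#' remain independently re-runnable. Seeds stay below 2^31 - 1.
#'
#' @param seed master integer seed
#' @param stream character label of the consuming stage
#' @return an integer seed
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- sum(as.integer(charToRaw(stream)) * seq_along(charToRaw(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 2654435) %% 2147483647)
}

random_dna <- function(n, length) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_ALPHABET, length, replace = TRUE), collapse = "")
  }, character(1))
}

## Mutate a DNA string at a per-base error rate, split over substitutions,
## insertions and deletions (default 80:10:10).
mutate_sequence <- function(seq, rate, sub_frac = 0.8, ins_frac = 0.1) {
  if (rate <= 0) return(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(bases)
  hit <- which(runif(n) < rate)
  if (!length(hit)) return(seq)
  kind <- sample(c("sub", "ins", "del"), length(hit), replace = TRUE,
                 prob = c(sub_frac, ins_frac, 1 - sub_frac - ins_frac))
  out <- as.list(bases)
  for (j in seq_along(hit)) {
    i <- hit[j]
    if (kind[j] == "sub") {
      out[[i]] <- sample(setdiff(DNA_ALPHABET, bases[i]), 1L)
    } else if (kind[j] == "ins") {
      out[[i]] <- c(bases[i], sample(DNA_ALPHABET, 1L))
    } else {
      out[[i]] <- character(0)
    }
  }
  paste(unlist(out), collapse = "")
}

stop_cbc <- function(...) stop(sprintf(...), call. = FALSE)

## sample() without the scalar-x surprise: always samples from x itself
resample <- function(x, size = 1L, ...) x[sample.int(length(x), size, ...)]

check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || any(x < lo) || any(x > hi))
    stop_cbc("%s must lie in [%g, %g]", name, lo, hi)
  invisible(x)
}
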