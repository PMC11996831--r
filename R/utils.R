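## Internal helpers: deterministic hashing and scoped RNG.

#' @importFrom stats rnorm runif sd
#' @importFrom utils head tail
NULL

# Polynomial rolling hash of a string, in [0, 2^31 - 2]. Used to derive
# per-record RNG substreams and k-mer coordinates so results do not depend
# on batch order.
.hashString <- function(x, salt = 0L) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- (as.numeric(salt) %% 2147483647) + 17
  for (b in utf8ToInt(x)) {
    h <- (h * 31 + b) %% 2147483647
  }
  h
}

# Mix two non-negative integers into one seed below 2^31.
.mixSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 2654435761 + as.numeric(stream)) %% 2147483647)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# The 20 canonical amino-acid one-letter codes.
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Distinct k-mers of a residue string (character scalar).
.kmerSet <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, seq_len(n - k + 1L), k:n))
}

.stopIfNot <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
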