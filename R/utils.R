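#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from one root seed. Each stochastic
#' stage draws from its own named substream so that partial reruns (e.g.
#' regenerating only the super-enhancer sequences) reproduce exactly the
#' same values as a full run.
#'
#' @param seed integer root seed.
#' @param stream character scalar naming the substream.
#' @return An integer seed in `[0, 2^31)`, deterministic in `(seed, stream)`.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream),
            length(stream) == 1L)
  m <- 2147480009 # large prime < 2^31, keeps seeds valid 32-bit integers
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% m
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% m)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so library code never
#' clobbers user-level reproducibility.
#'
#' @param seed integer seed passed to [set.seed()].
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## row-wise z-score with a zero-variance convention: constant rows map to 0
## and are flagged in the "constant" attribute rather than producing NaN
.row_zscore <- function(x) {
  mu <- rowMeans(x)
  sdv <- apply(x, 1L, stats::sd)
  const <- sdv == 0 | !is.finite(sdv)
  z <- (x - mu) / ifelse(const, 1, sdv)
  z[const, ] <- 0
  attr(z, "constant") <- rownames(x)[const]
  z
}

.row_minmax <- function(x) {
  lo <- apply(x, 1L, min)
  hi <- apply(x, 1L, max)
  const <- hi == lo
  z <- (x - lo) / ifelse(const, 1, hi - lo)
  z[const, ] <- 0
  attr(z, "constant") <- rownames(x)[const]
  z
}

.check_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric genes x cells matrix", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene rownames and cell colnames", call. = FALSE)
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("gene and cell identifiers must be unique", call. = FALSE)
  invisible(counts)
}
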